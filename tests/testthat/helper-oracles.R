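# Independent brute-force oracles for the descriptor panel. These are
# deliberately written in a different style from the package internals:
# explicit enumeration and plain loops, no shared helpers.

oracle_adjacency <- function(g) {
  n <- nrow(g$atoms)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(g$bonds))) {
    A[g$bonds$i[r], g$bonds$j[r]] <- 1
    A[g$bonds$j[r], g$bonds$i[r]] <- 1
  }
  A
}

oracle_bond_order <- function(g, i, j) {
  for (r in seq_len(nrow(g$bonds))) {
    if ((g$bonds$i[r] == i && g$bonds$j[r] == j) ||
        (g$bonds$i[r] == j && g$bonds$j[r] == i)) {
      return(g$bonds$order[r])
    }
  }
  NA_character_
}

# all directed simple paths with exactly k edges, as a list of vertex
# sequences, by plain recursive extension
oracle_paths <- function(A, k) {
  n <- nrow(A)
  paths <- lapply(seq_len(n), function(i) list(i))
  for (step in seq_len(k)) {
    nxt <- list()
    for (p in paths) {
      v <- p[[length(p)]]
      for (w in which(A[v, ] > 0)) {
        if (!(w %in% unlist(p))) nxt[[length(nxt) + 1]] <- c(p, list(w))
      }
    }
    paths <- nxt
  }
  lapply(paths, unlist)
}

# walks of length k starting at i by explicit recursive stepping
oracle_walk_count <- function(A, i, k) {
  if (k == 0) return(1)
  total <- 0
  for (w in which(A[i, ] > 0)) total <- total + oracle_walk_count(A, w, k - 1)
  total
}

oracle_entropy2 <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

oracle_gnar <- function(A) {
  deg <- rowSums(A)
  prod(deg)^(1 / nrow(A))
}

oracle_pw <- function(g, k) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  total <- 0
  for (i in seq_len(n)) {
    p_i <- sum(vapply(oracle_paths(A, k), function(p) p[1] == i, logical(1)))
    w_i <- oracle_walk_count(A, i, k)
    if (w_i > 0) total <- total + p_i / w_i
  }
  total / n
}

oracle_ivde <- function(A) {
  oracle_entropy2(table(rowSums(A)))
}

ORACLE_ZV <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, P = 5, S = 6, Cl = 7, Br = 7, I = 7)
ORACLE_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17, Br = 35, I = 53)

oracle_delta_v <- function(g) {
  el <- g$atoms$element
  dv <- numeric(length(el))
  for (i in seq_along(el)) {
    denom <- ORACLE_Z[[el[i]]] - ORACLE_ZV[[el[i]]] - 1
    if (denom < 1) denom <- 1
    dv[i] <- (ORACLE_ZV[[el[i]]] - g$atoms$hcount[i]) / denom
  }
  dv
}

oracle_chi_v <- function(g, k) {
  A <- oracle_adjacency(g)
  dv <- oracle_delta_v(g)
  total <- 0
  npaths <- 0
  for (p in oracle_paths(A, k)) {
    if (p[1] < p[length(p)]) {
      total <- total + 1 / sqrt(prod(dv[p]))
      npaths <- npaths + 1
    }
  }
  list(chi = total, npaths = npaths)
}

oracle_bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (is.infinite(D[s, w])) {
            D[s, w] <- d
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
  }
  D
}

oracle_ggi <- function(g, k) {
  A <- oracle_adjacency(g)
  D <- oracle_bfs_distances(A)
  n <- nrow(A)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) Q[i, j] <- D[i, j]^-2
  CT <- A %*% Q
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] == k) total <- total + abs(CT[i, j] - CT[j, i])
  }
  total
}

oracle_eeig <- function(g, rank) {
  m <- nrow(g$bonds)
  if (m < rank) return(0)
  wt <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  B <- matrix(0, m, m)
  for (e in seq_len(m)) {
    B[e, e] <- wt[[g$bonds$order[e]]]
    for (f in seq_len(m)) {
      if (e != f && length(intersect(c(g$bonds$i[e], g$bonds$j[e]),
                                     c(g$bonds$i[f], g$bonds$j[f]))) > 0) {
        B[e, f] <- 1
      }
    }
  }
  rev(sort(Re(eigen(B)$values)))[rank]
}

oracle_aac <- function(g) {
  syms <- c(g$atoms$element, rep("H", sum(g$atoms$hcount)))
  oracle_entropy2(table(syms))
}

oracle_me <- function(g) {
  en <- sanderson_electronegativity()
  lookup <- stats::setNames(en$scaled, en$element)
  vals <- lookup[g$atoms$element]
  (sum(vals) + sum(g$atoms$hcount) * lookup[["H"]]) /
    (nrow(g$atoms) + sum(g$atoms$hcount))
}

oracle_pcr <- function(g) {
  A <- oracle_adjacency(g)
  wt <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  num <- 0
  den <- 0
  for (k in seq_len(nrow(A) - 1)) {
    for (p in oracle_paths(A, k)) {
      if (p[1] < p[length(p)]) {
        wprod <- 1
        for (s in seq_len(length(p) - 1)) {
          wprod <- wprod * wt[[oracle_bond_order(g, p[s], p[s + 1])]]
        }
        num <- num + wprod^(1 / k)
        den <- den + 1
      }
    }
  }
  if (den == 0) 0 else num / den
}

oracle_descriptors <- function(g) {
  A <- oracle_adjacency(g)
  x2 <- oracle_chi_v(g, 2)
  x3 <- oracle_chi_v(g, 3)
  c(
    NN = sum(g$atoms$element == "N"),
    GNar = oracle_gnar(A),
    X2v = x2$chi,
    EEig10r = oracle_eeig(g, 10),
    GGI8 = oracle_ggi(g, 8),
    Me = oracle_me(g),
    PW2 = oracle_pw(g, 2),
    PW3 = oracle_pw(g, 3),
    PCR = oracle_pcr(g),
    X3Av = if (x3$npaths > 0) x3$chi / x3$npaths else 0,
    AAC = oracle_aac(g),
    IVDE = oracle_ivde(A)
  )
}
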