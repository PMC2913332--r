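#' Names of the descriptor panel
#'
#' The fourteen hydrogen-suppressed-graph descriptors computed by
#' [compute_descriptors()]: seven used by the fuzzy-partition branch
#' (`NN`, `GNar`, `X2v`, `EEig10r`, `GGI8`, `nCconj`, `O-058`) and seven
#' used by the perceptron branch (`Me`, `PW2`, `PW3`, `PCR`, `X3Av`,
#' `AAC`, `IVDE`).
#'
#' @param branch `"all"` (default), `"afp"` or `"mlp"`.
#' @return Character vector of descriptor names.
#' @export
descriptor_names <- function(branch = c("all", "afp", "mlp")) {
  branch <- match.arg(branch)
  afp <- c("NN", "GNar", "X2v", "EEig10r", "GGI8", "nCconj", "O-058")
  mlp <- c("Me", "PW2", "PW3", "PCR", "X3Av", "AAC", "IVDE")
  switch(branch, all = c(afp, mlp), afp = afp, mlp = mlp)
}

BOND_ORDER_WEIGHT <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

# Resonance-integral edge weights for the weighted edge adjacency matrix.
# Fixed, documented constants: single 1, aromatic 1.5, double 2, triple 3.
RESONANCE_WEIGHT <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

adjacency_matrix <- function(g) {
  n <- nrow(g$atoms)
  A <- matrix(0, n, n)
  if (nrow(g$bonds) > 0) {
    A[cbind(g$bonds$i, g$bonds$j)] <- 1
    A[cbind(g$bonds$j, g$bonds$i)] <- 1
  }
  A
}

bond_weight_matrix <- function(g, weights = BOND_ORDER_WEIGHT) {
  n <- nrow(g$atoms)
  W <- matrix(0, n, n)
  if (nrow(g$bonds) > 0) {
    w <- weights[g$bonds$order]
    W[cbind(g$bonds$i, g$bonds$j)] <- w
    W[cbind(g$bonds$j, g$bonds$i)] <- w
  }
  W
}

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17, Br = 35, I = 53)
VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, P = 5, S = 6, Cl = 7, Br = 7, I = 7)

# Kier-Hall valence vertex degree: (Zv - h) / (Z - Zv - 1)
valence_degrees <- function(g) {
  el <- g$atoms$element
  if (!all(el %in% names(ATOMIC_NUMBER))) {
    abort(sprintf(
      "no valence-degree parameters for element(s): %s",
      paste(unique(el[!el %in% names(ATOMIC_NUMBER)]), collapse = ", ")
    ), class = "skinqsar_descriptor_error")
  }
  z <- ATOMIC_NUMBER[el]
  zv <- VALENCE_ELECTRONS[el]
  dv <- (zv - g$atoms$hcount) / pmax(z - zv - 1, 1)
  bad <- which(dv <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "valence degree not positive for atom %d (%s with %d H)",
      bad[1], el[bad[1]], g$atoms$hcount[bad[1]]
    ), class = "skinqsar_descriptor_error")
  }
  unname(dv)
}

# One DFS pass over all simple paths up to `max_len` edges, accumulating
#  - per-start directed path counts (atomic path counts)
#  - undirected path counts, geometric-mean conventional-bond-order path
#    weights, and inverse-sqrt valence-degree products (chi terms) per length
path_census <- function(g, max_len, dv = NULL) {
  n <- nrow(g$atoms)
  W <- bond_weight_matrix(g)
  adj <- lapply(seq_len(n), function(i) which(W[i, ] > 0))
  atomic <- matrix(0, n, max(max_len, 1))
  count <- numeric(max(max_len, 1))
  wsum <- numeric(max(max_len, 1))
  chi <- numeric(max(max_len, 1))
  if (n < 2 || max_len < 1) {
    return(list(atomic = atomic, count = count, wsum = wsum, chi = chi))
  }
  in_path <- logical(n)
  path <- integer(max_len + 1)
  dfs <- function(v, depth, wprod, dvprod) {
    for (w in adj[[v]]) {
      if (in_path[w]) next
      len <- depth # edges after adding w
      wp <- wprod * W[v, w]
      dp <- if (is.null(dv)) 1 else dvprod * dv[w]
      atomic[path[1], len] <<- atomic[path[1], len] + 1
      if (path[1] < w) {
        count[len] <<- count[len] + 1
        wsum[len] <<- wsum[len] + wp^(1 / len)
        chi[len] <<- chi[len] + 1 / sqrt(dp)
      }
      if (len < max_len) {
        in_path[w] <<- TRUE
        path[len + 1] <<- w
        dfs(w, depth + 1, wp, dp)
        in_path[w] <<- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    in_path[] <- FALSE
    in_path[s] <- TRUE
    path[1] <- s
    dfs(s, 1, 1, if (is.null(dv)) 1 else dv[s])
  }
  list(atomic = atomic, count = count, wsum = wsum, chi = chi)
}

#' Atom and fragment counts
#'
#' Counts three substructural descriptors on a molecular graph: `NN`, the
#' number of nitrogen atoms; `O058`, the number of oxygens double-bonded to
#' a heavy atom (the `=O` atom-centred fragment); and `nCconj`, the number
#' of non-aromatic sp2 carbons whose double bond is conjugated — separated
#' by one single bond — with another double, triple or aromatic bond.
#'
#' @param g A [parse_smiles()] graph.
#' @return A named list with `NN`, `O058` and `nCconj` (integers).
#' @examples
#' atom_counts(parse_smiles("C=CC=C"))$nCconj # butadiene: 4
#' @export
atom_counts <- function(g) {
  el <- g$atoms$element
  NN <- sum(el == "N")
  O058 <- 0L
  if (nrow(g$bonds) > 0) {
    dbl <- g$bonds[g$bonds$order == "double", ]
    O058 <- sum(el[dbl$i] == "O" | el[dbl$j] == "O")
    # an oxygen in two double bonds (e.g. central O, not chemically common)
    # would be counted once per =O fragment, matching the fragment reading
  }
  list(NN = as.integer(NN), O058 = as.integer(O058), nCconj = count_conjugated_sp2(g))
}

# Multiple-bond incidence per atom, used by the conjugation rule.
count_conjugated_sp2 <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  b <- g$bonds
  multi <- b$order %in% c("double", "triple", "aromatic")
  bears_multi <- function(atom, excl) {
    any(multi & (b$i == atom | b$j == atom) & seq_len(nrow(b)) != excl)
  }
  conj_carbons <- integer(0)
  for (bi in which(b$order == "double")) {
    u <- b$i[bi]; v <- b$j[bi]
    if (g$atoms$aromatic[u] && g$atoms$aromatic[v]) next
    conjugated <- FALSE
    for (end in c(u, v)) {
      singles <- which(b$order == "single" & (b$i == end | b$j == end))
      for (si in singles) {
        w <- if (b$i[si] == end) b$j[si] else b$i[si]
        if (bears_multi(w, si)) { conjugated <- TRUE; break }
      }
      if (conjugated) break
    }
    if (conjugated) {
      for (end in c(u, v)) {
        if (g$atoms$element[end] == "C" && !g$atoms$aromatic[end]) {
          conj_carbons <- union(conj_carbons, end)
        }
      }
    }
  }
  length(conj_carbons)
}

#' Topological shape and information indices
#'
#' Computes, on the hydrogen-depleted graph with `A` heavy atoms and vertex
#' degrees `d_i`:
#' * `GNar` — Narumi geometric index, `(prod d_i)^(1/A)`;
#' * `PW2`, `PW3` — Randic path/walk shape indices,
#'   `(1/A) * sum_i p_i(k)/w_i(k)` with `p_i(k)` the simple paths and
#'   `w_i(k)` the walks of length `k` starting at atom `i`;
#' * `IVDE` — mean information content on vertex degree equality,
#'   the base-2 entropy of the vertex-degree class distribution.
#'
#' Single-atom graphs return 0 for all four indices so that fragment
#' batches can proceed.
#'
#' @param g A [parse_smiles()] graph.
#' @return Named list with `GNar`, `PW2`, `PW3`, `IVDE`.
#' @export
graph_topology_indices <- function(g) {
  n <- nrow(g$atoms)
  if (n < 2) return(list(GNar = 0, PW2 = 0, PW3 = 0, IVDE = 0))
  A <- adjacency_matrix(g)
  deg <- rowSums(A)
  GNar <- prod(deg)^(1 / n)
  census <- path_census(g, 3)
  pw <- function(k) {
    Ak <- A
    for (i in seq_len(k - 1)) Ak <- Ak %*% A
    walks <- rowSums(Ak)
    paths <- census$atomic[, k]
    ratio <- ifelse(walks > 0, paths / walks, 0)
    mean(ratio)
  }
  classes <- table(deg)
  p <- as.numeric(classes) / n
  IVDE <- -sum(p * log2(p))
  list(GNar = GNar, PW2 = pw(2), PW3 = pw(3), IVDE = IVDE)
}

#' Kier-Hall valence connectivity indices
#'
#' Valence connectivity of order `k`: the sum over simple paths of `k + 1`
#' heavy atoms of the inverse square root of the product of valence vertex
#' degrees `dv = (Zv - h)/(Z - Zv - 1)`, together with its average over the
#' number of such paths (0 when no path of that length exists).
#'
#' @param g A [parse_smiles()] graph.
#' @param order Path length in bonds, 2 or 3.
#' @return Named list with `chi_v` and `chi_v_avg`.
#' @examples
#' valence_connectivity(parse_smiles("CCC"), 2)$chi_v # 1/sqrt(2)
#' @export
valence_connectivity <- function(g, order) {
  stopifnot(order %in% c(2, 3))
  if (nrow(g$atoms) < order + 1) return(list(chi_v = 0, chi_v_avg = 0))
  dv <- valence_degrees(g)
  census <- path_census(g, order, dv = dv)
  npaths <- census$count[order]
  chi <- census$chi[order]
  list(chi_v = chi, chi_v_avg = if (npaths > 0) chi / npaths else 0)
}

#' Galvez topological charge index
#'
#' `GGI_k` per Galvez: with adjacency matrix `M` and `Q` the matrix of
#' inverse squared topological distances (zero diagonal), the charge-term
#' matrix is `CT = M Q`; the index sums `|CT_ij - CT_ji|` over atom pairs
#' at topological distance exactly `k`.
#'
#' @param g A [parse_smiles()] graph.
#' @param k Topological distance (default 8).
#' @return A single number; 0 when no atom pair lies at distance `k`.
#' @export
galvez_charge_index <- function(g, k = 8) {
  n <- nrow(g$atoms)
  if (n < 2) return(0)
  M <- adjacency_matrix(g)
  D <- igraph::distances(igraph_from_graph(g))
  Q <- ifelse(D > 0, 1 / D^2, 0)
  CT <- M %*% Q
  sel <- D == k & upper.tri(D)
  if (!any(sel)) return(0)
  sum(abs(CT - t(CT))[sel])
}

igraph_from_graph <- function(g) {
  ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  if (nrow(g$bonds) > 0) ig <- igraph::add_edges(ig, rbind(g$bonds$i, g$bonds$j))
  ig
}

#' Charge and edge-eigenvalue descriptors
#'
#' `GGI8` is the Galvez topological charge index of order 8
#' ([galvez_charge_index()]). `EEig10r` is the 10th-largest eigenvalue of
#' the edge adjacency matrix weighted by resonance-integral bond weights
#' (single 1, aromatic 1.5, double 2, triple 3): off-diagonal entry
#' `(e, f)` is 1 when edges `e` and `f` share an atom, and the diagonal
#' carries each bond's resonance weight. Since line-graph spectra are
#' bounded below by -2, the index is bounded below by `min(w) - 2` (-1 for
#' saturated skeletons). Graphs with fewer than 10 bonds return 0 (zero
#' padding below the edge count).
#'
#' @param g A [parse_smiles()] graph.
#' @return Named list with `GGI8` and `EEig10r`.
#' @export
charge_and_edge_eigen <- function(g) {
  list(GGI8 = galvez_charge_index(g, 8), EEig10r = edge_eigenvalue(g, 10))
}

edge_eigenvalue <- function(g, rank) {
  m <- nrow(g$bonds)
  if (m < rank) return(0)
  # edge adjacency: edges are adjacent when they share an atom
  E <- matrix(0, m, m)
  for (e in seq_len(m - 1)) {
    for (f in (e + 1):m) {
      if (length(intersect(
        c(g$bonds$i[e], g$bonds$j[e]),
        c(g$bonds$i[f], g$bonds$j[f])
      )) > 0) E[e, f] <- E[f, e] <- 1
    }
  }
  w <- RESONANCE_WEIGHT[g$bonds$order]
  diag(E) <- w
  ev <- sort(eigen(E, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev[rank]
}

#' Composition and path-ratio descriptors
#'
#' * `AAC` — mean information index on atomic composition: base-2 entropy
#'   of the element distribution over all atoms including hydrogens;
#' * `Me` — mean carbon-scaled Sanderson electronegativity over all atoms
#'   including hydrogens;
#' * `PCR` — ratio of the multiple (bond-order-weighted) path count over
#'   the simple path count, both over paths of length 1..A-1 on the
#'   hydrogen-depleted graph, with conventional bond orders as weights
#'   (aromatic = 1.5). Saturated skeletons give exactly 1.
#'
#' @param g A [parse_smiles()] graph.
#' @param en Electronegativity table, by default
#'   [sanderson_electronegativity()]; must cover every element present.
#' @return Named list with `AAC`, `Me`, `PCR`.
#' @export
composition_indices <- function(g, en = sanderson_electronegativity()) {
  n_heavy <- nrow(g$atoms)
  n_h <- sum(g$atoms$hcount)
  n_all <- n_heavy + n_h
  counts <- table(c(g$atoms$element, rep("H", n_h)))
  p <- as.numeric(counts) / n_all
  AAC <- -sum(p * log2(p))

  idx <- match(g$atoms$element, en$element)
  if (anyNA(idx)) {
    abort(sprintf(
      "element(s) missing from electronegativity table: %s",
      paste(unique(g$atoms$element[is.na(idx)]), collapse = ", ")
    ), class = "skinqsar_descriptor_error")
  }
  en_h <- en$scaled[match("H", en$element)]
  Me <- (sum(en$scaled[idx]) + n_h * en_h) / n_all

  PCR <- 0
  if (n_heavy >= 2) {
    census <- path_census(g, n_heavy - 1)
    total <- sum(census$count)
    PCR <- if (total > 0) sum(census$wsum) / total else 0
  }
  list(AAC = AAC, Me = Me, PCR = PCR)
}

descriptor_vector <- function(g) {
  ac <- atom_counts(g)
  topo <- graph_topology_indices(g)
  x2 <- valence_connectivity(g, 2)
  x3 <- valence_connectivity(g, 3)
  ce <- charge_and_edge_eigen(g)
  comp <- composition_indices(g)
  out <- c(
    NN = ac$NN, GNar = topo$GNar, X2v = x2$chi_v, EEig10r = ce$EEig10r,
    GGI8 = ce$GGI8, nCconj = ac$nCconj, `O-058` = ac$O058,
    Me = comp$Me, PW2 = topo$PW2, PW3 = topo$PW3, PCR = comp$PCR,
    X3Av = x3$chi_v_avg, AAC = comp$AAC, IVDE = topo$IVDE
  )
  out[descriptor_names()]
}

#' Compute the descriptor table for a batch of structures
#'
#' Parses each SMILES and computes the full fourteen-descriptor panel.
#' Structures that fail to parse or that raise a descriptor error are
#' recorded in a failure log (attribute `"failures"`) without aborting the
#' batch.
#'
#' @param data A data frame with an identifier column and a SMILES column,
#'   e.g. from [read_smi()].
#' @param smiles Name of the SMILES column (default `"smiles"`).
#' @param id Name of the identifier column (default `"id"`).
#' @return A tibble with `id` plus one column per descriptor, one row per
#'   successfully processed compound, in input order. The attribute
#'   `"failures"` is a tibble (`id`, `stage`, `message`) of skipped rows.
#' @examples
#' compute_descriptors(tibble::tibble(id = c("ethanol", "benzene"),
#'                                    smiles = c("CCO", "c1ccccc1")))
#' @export
compute_descriptors <- function(data, smiles = "smiles", id = "id") {
  stopifnot(is.data.frame(data))
  if (!smiles %in% names(data)) abort(sprintf("column '%s' not found", smiles))
  if (!id %in% names(data)) abort(sprintf("column '%s' not found", id))
  rows <- list()
  failures <- list()
  for (r in seq_len(nrow(data))) {
    cid <- as.character(data[[id]][r])
    res <- tryCatch(
      {
        g <- parse_smiles(data[[smiles]][r], id = cid)
        c(list(id = cid), as.list(descriptor_vector(g)))
      },
      error = function(e) {
        failures[[length(failures) + 1]] <<- tibble(
          id = cid,
          stage = if (inherits(e, "skinqsar_parse_error")) "parse" else "descriptor",
          message = conditionMessage(e)
        )
        NULL
      }
    )
    if (!is.null(res)) rows[[length(rows) + 1]] <- as_tibble(res)
  }
  out <- if (length(rows) > 0) bind_rows(rows) else {
    empty <- c(list(id = character(0)), setNames(rep(list(numeric(0)), 14), descriptor_names()))
    as_tibble(empty)
  }
  attr(out, "failures") <- if (length(failures) > 0) {
    bind_rows(failures)
  } else {
    tibble(id = character(0), stage = character(0), message = character(0))
  }
  out
}
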