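#' Parse a SMILES string into a molecular graph
#'
#' Builds a hydrogen-suppressed molecular graph from a SMILES string:
#' atoms carry element, formal charge, aromatic flag and implicit hydrogen
#' count; bonds carry an order in `single`, `double`, `triple`, `aromatic`.
#' Aromaticity is taken from lowercase (aromatic) notation and, in addition,
#' six-membered carbocycles and azines written in Kekule form (alternating
#' single/double bonds) are perceived as aromatic. Multi-fragment input
#' (e.g. salts written with `.`) is reduced to the largest connected
#' fragment with a warning, since all descriptors here are whole-graph
#' quantities.
#'
#' The supported dialect covers the organic subset (`B C N O P S F Cl Br I`
#' and aromatic `b c n o p s`), bracket atoms with charge and explicit H
#' count, branches, ring-bond closures (including `%nn`), and the bond
#' symbols `- = # :` (`/` and `\` are read as single bonds; stereochemistry
#' is not retained).
#'
#' @param smiles A single SMILES string.
#' @param id Identifier stored on the graph (defaults to the SMILES itself).
#' @return An object of class `molecular_graph`: a list with `atoms`
#'   (tibble: `element`, `charge`, `aromatic`, `hcount`), `bonds`
#'   (tibble: `i`, `j`, `order`) and `id`.
#' @examples
#' g <- parse_smiles("c1ccccc1O", id = "phenol")
#' g$atoms
#' @export
parse_smiles <- function(smiles, id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) || nchar(smiles) == 0) {
    abort("`smiles` must be a single non-empty string.", class = "skinqsar_parse_error")
  }
  toks <- tokenize_smiles(smiles)
  g <- build_graph(toks, smiles)
  g$id <- id
  g <- keep_largest_fragment(g)
  g <- perceive_kekule_aromaticity(g)
  g$atoms$hcount <- assign_implicit_h(g)
  validate_graph(g)
  g
}

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMENTS <- c("b", "c", "n", "o", "p", "s")

parse_error <- function(smiles, pos, msg) {
  abort(
    sprintf("SMILES parse error in \"%s\" at position %d: %s", smiles, pos, msg),
    class = "skinqsar_parse_error", position = pos
  )
}

# Tokens: atom (organic / aromatic / bracket), bond, open, close, ring, dot.
tokenize_smiles <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1
  push <- function(type, value, pos) toks[[length(toks) + 1]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      push("bond", ch, i); i <- i + 1
    } else if (ch == "(") {
      push("open", ch, i); i <- i + 1
    } else if (ch == ")") {
      push("close", ch, i); i <- i + 1
    } else if (ch == ".") {
      push("dot", ch, i); i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      push("ring", ch, i); i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1], chars[i + 2]))) {
        parse_error(smiles, i, "'%' must be followed by two digits")
      }
      push("ring", paste0(chars[i + 1], chars[i + 2]), i); i <- i + 3
    } else if (ch == "[") {
      j <- i + 1
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) parse_error(smiles, i, "unclosed bracket atom")
      push("bracket", paste(chars[(i + 1):(j - 1)], collapse = ""), i)
      i <- j + 1
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        push("atom", two, i); i <- i + 2
      } else if (ch %in% c(ORGANIC_SUBSET, AROMATIC_ELEMENTS)) {
        push("atom", ch, i); i <- i + 1
      } else {
        parse_error(smiles, i, sprintf("unknown atom symbol '%s'", ch))
      }
    } else {
      parse_error(smiles, i, sprintf("unexpected character '%s'", ch))
    }
  }
  toks
}

parse_bracket_atom <- function(body, smiles, pos) {
  # [isotope? symbol chirality? Hcount? charge?]  (atom class ignored)
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Z][a-z]?|[bcnops])(@{0,2})(H[0-9]*)?(\\+{1,2}|-{1,2}|\\+[0-9]|-[0-9])?(:[0-9]+)?$",
    body
  ))[[1]]
  if (length(m) == 0) parse_error(smiles, pos, sprintf("malformed bracket atom '[%s]'", body))
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_ELEMENTS
  element <- if (aromatic) toupper(sym) else sym
  known <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
  if (!element %in% known) {
    parse_error(smiles, pos, sprintf("unsupported element '%s'", element))
  }
  hcount <- 0L
  if (nzchar(m[5])) {
    hcount <- if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
  }
  charge <- 0L
  if (nzchar(m[6])) {
    cs <- m[6]
    charge <- if (grepl("[0-9]", cs)) {
      as.integer(substr(cs, 2, 2)) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
    } else {
      nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
    }
  }
  list(element = element, aromatic = aromatic, hcount = hcount, charge = charge, bracket = TRUE)
}

build_graph <- function(toks, smiles) {
  atoms <- list()
  bonds <- list()
  stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NULL
  ring_open <- list()

  add_atom <- function(a) {
    atoms[[length(atoms) + 1]] <<- a
    length(atoms)
  }
  add_bond <- function(i, j, order, pos) {
    if (i == j) parse_error(smiles, pos, "ring bond to the same atom")
    key <- paste(min(i, j), max(i, j))
    if (any(vapply(bonds, function(b) b$key == key, logical(1)))) {
      parse_error(smiles, pos, "duplicate bond")
    }
    bonds[[length(bonds) + 1]] <<- list(i = min(i, j), j = max(i, j), order = order, key = key)
  }
  bond_order_between <- function(sym, a1, a2) {
    if (!is.null(sym)) {
      switch(sym$value,
        "-" = "single", "/" = "single", "\\" = "single",
        "=" = "double", "#" = "triple", ":" = "aromatic"
      )
    } else if (atoms[[a1]]$aromatic && atoms[[a2]]$aromatic) "aromatic" else "single"
  }

  for (tok in toks) {
    if (tok$type %in% c("atom", "bracket")) {
      a <- if (tok$type == "bracket") {
        parse_bracket_atom(tok$value, smiles, tok$pos)
      } else {
        list(
          element = if (tok$value %in% AROMATIC_ELEMENTS) toupper(tok$value) else tok$value,
          aromatic = tok$value %in% AROMATIC_ELEMENTS,
          hcount = NA_integer_, charge = 0L, bracket = FALSE
        )
      }
      idx <- add_atom(a)
      if (!is.na(prev)) add_bond(prev, idx, bond_order_between(pending_bond, prev, idx), tok$pos)
      prev <- idx
      pending_bond <- NULL
    } else if (tok$type == "bond") {
      if (is.na(prev)) parse_error(smiles, tok$pos, "bond symbol with no preceding atom")
      pending_bond <- tok
    } else if (tok$type == "open") {
      if (is.na(prev)) parse_error(smiles, tok$pos, "branch opened before any atom")
      stack <- c(stack, prev)
    } else if (tok$type == "close") {
      if (length(stack) == 0) parse_error(smiles, tok$pos, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok$type == "ring") {
      if (is.na(prev)) parse_error(smiles, tok$pos, "ring closure before any atom")
      key <- tok$value
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      } else {
        opener <- ring_open[[key]]
        sym <- pending_bond %||% opener$bond
        add_bond(opener$atom, prev, bond_order_between(sym, opener$atom, prev), tok$pos)
        ring_open[[key]] <- NULL
      }
      pending_bond <- NULL
    } else if (tok$type == "dot") {
      prev <- NA_integer_
      pending_bond <- NULL
    }
  }
  if (length(stack) > 0) parse_error(smiles, nchar(smiles), "unclosed branch '('")
  open_rings <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_rings) > 0) {
    parse_error(smiles, nchar(smiles), sprintf("unclosed ring bond '%s'", open_rings[1]))
  }
  if (length(atoms) == 0) parse_error(smiles, 1, "no atoms")

  structure(list(
    atoms = tibble(
      element = map_chr(atoms, "element"),
      charge = map_int(atoms, "charge"),
      aromatic = map_lgl_(atoms, "aromatic"),
      hcount = map_int(atoms, function(a) a$hcount %||% NA_integer_),
      bracket = map_lgl_(atoms, "bracket")
    ),
    bonds = if (length(bonds) == 0) {
      tibble(i = integer(0), j = integer(0), order = character(0))
    } else {
      tibble(
        i = map_int(bonds, "i"), j = map_int(bonds, "j"),
        order = map_chr(bonds, "order")
      )
    },
    id = NA_character_
  ), class = "molecular_graph")
}

map_lgl_ <- function(x, f) vapply(x, if (is.function(f)) f else function(e) e[[f]], logical(1))

keep_largest_fragment <- function(g) {
  n <- nrow(g$atoms)
  if (n <= 1 || nrow(g$bonds) == 0) comp <- seq_len(n) else comp <- graph_components(g)
  if (length(unique(comp)) == 1) return(g)
  warn(sprintf(
    "SMILES '%s' has %d fragments; keeping the largest (descriptors are whole-graph quantities).",
    g$id %||% "?", length(unique(comp))
  ))
  keep_comp <- as.integer(names(which.max(table(comp))))
  keep <- which(comp == keep_comp)
  remap <- match(seq_len(n), keep)
  g$atoms <- g$atoms[keep, ]
  b <- g$bonds[g$bonds$i %in% keep & g$bonds$j %in% keep, ]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  g$bonds <- b
  g
}

graph_components <- function(g) {
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$i, g$bonds$j), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, nrow(g$atoms) - igraph::vcount(ig)))
  igraph::components(ig)$membership
}

# Kekule aromaticity: mark a 6-ring aromatic when all members are C/N,
# none already aromatic, and ring bonds alternate single/double.
perceive_kekule_aromaticity <- function(g) {
  n <- nrow(g$atoms)
  if (n < 6 || nrow(g$bonds) < 6) return(g)
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$i, g$bonds$j), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
  bond_key <- paste(g$bonds$i, g$bonds$j)
  order_of <- function(i, j) g$bonds$order[match(paste(min(i, j), max(i, j)), bond_key)]
  # candidate 6-cycles from the fundamental cycle space
  rings <- find_six_rings(ig)
  for (ring in rings) {
    elems <- g$atoms$element[ring]
    if (!all(elems %in% c("C", "N"))) next
    if (any(g$atoms$aromatic[ring])) next
    orders <- vapply(seq_along(ring), function(k) {
      order_of(ring[k], ring[k %% length(ring) + 1])
    }, character(1))
    if (all(orders %in% c("single", "double")) &&
        all(orders != c(orders[-1], orders[1]))) {
      g$atoms$aromatic[ring] <- TRUE
      for (k in seq_along(ring)) {
        i <- ring[k]; j <- ring[k %% length(ring) + 1]
        g$bonds$order[match(paste(min(i, j), max(i, j)), bond_key)] <- "aromatic"
      }
    }
  }
  g
}

find_six_rings <- function(ig) {
  n <- igraph::vcount(ig)
  if (n < 6) return(list())
  rings <- list()
  seen <- character(0)
  adj <- igraph::as_adj_list(ig)
  # bounded DFS for 6-cycles through each start vertex; molecules are tiny
  for (start in seq_len(n)) {
    path <- integer(0)
    dfs <- function(v, depth) {
      path[depth] <<- v
      if (depth == 6) {
        if (start %in% as.integer(adj[[v]])) {
          key <- paste(sort(path), collapse = "-")
          if (!(key %in% seen)) {
            seen <<- c(seen, key)
            rings[[length(rings) + 1]] <<- path
          }
        }
        return(invisible())
      }
      for (w in as.integer(adj[[v]])) {
        if (w > start && !(w %in% path[seq_len(depth)])) dfs(w, depth + 1)
      }
    }
    dfs(start, 1)
  }
  rings
}

STANDARD_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

# Implicit hydrogens for organic-subset atoms; bracket atoms keep their
# explicit H count (SMILES convention). Aromatic C/N receive one extra
# valence unit for the in-ring double bond (pyrrole-type N must be [nH]).
assign_implicit_h <- function(g) {
  orders <- c(single = 1L, double = 2L, triple = 3L, aromatic = 1L)
  n <- nrow(g$atoms)
  h <- g$atoms$hcount
  for (k in seq_len(n)) {
    if (g$atoms$bracket[k]) {
      if (is.na(h[k])) h[k] <- 0L
      next
    }
    deg_sum <- 0L
    if (nrow(g$bonds) > 0) {
      rows <- g$bonds$i == k | g$bonds$j == k
      deg_sum <- sum(orders[g$bonds$order[rows]])
    }
    if (g$atoms$aromatic[k] && g$atoms$element[k] %in% c("C", "N")) deg_sum <- deg_sum + 1L
    vals <- STANDARD_VALENCES[[g$atoms$element[k]]]
    if (is.null(vals)) abort(sprintf("no standard valence for element '%s'", g$atoms$element[k]))
    fit <- vals[vals >= deg_sum]
    h[k] <- if (length(fit) == 0) 0L else as.integer(fit[1] - deg_sum)
  }
  as.integer(h)
}

validate_graph <- function(g) {
  n <- nrow(g$atoms)
  if (nrow(g$bonds) > 0) {
    stopifnot(
      all(g$bonds$i >= 1 & g$bonds$i <= n),
      all(g$bonds$j >= 1 & g$bonds$j <= n),
      all(g$bonds$i != g$bonds$j)
    )
  }
  stopifnot(all(g$atoms$hcount >= 0))
  invisible(g)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf(
    "<molecular_graph> %s: %d heavy atoms, %d bonds\n",
    x$id %||% "?", nrow(x$atoms), nrow(x$bonds)
  ))
  invisible(x)
}

#' Read a SMILES file
#'
#' Reads a `.smi`-dialect file: one structure per line as
#' `SMILES whitespace identifier`, with `#` comment lines and blank lines
#' ignored. Lines without an identifier use the SMILES as identifier.
#'
#' @param path Path to the file.
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) abort(sprintf("SMILES file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  tibble(
    id = map_chr(parts, function(p) if (length(p) > 1) p[2] else p[1]),
    smiles = map_chr(parts, 1)
  )
}
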