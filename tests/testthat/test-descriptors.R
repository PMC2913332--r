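# Frozen expected values below were computed by hand or with the
# brute-force oracles in helper-oracles.R.

test_that("atom and fragment counts match hand enumeration", {
  expect_equal(atom_counts(parse_smiles("c1ccncc1"))$NN, 1L)
  expect_equal(atom_counts(parse_smiles("CC(=O)C"))$O058, 1L)
  # butadiene: both double bonds conjugated, all 4 carbons count
  expect_equal(atom_counts(parse_smiles("C=CC=C"))$nCconj, 4L)
  # ethylene: an isolated double bond is not conjugated
  expect_equal(atom_counts(parse_smiles("C=C"))$nCconj, 0L)
  # acrolein: C=C conjugated with C=O; 3 sp2 carbons count
  expect_equal(atom_counts(parse_smiles("C=CC=O"))$nCconj, 3L)
  # styrene: vinyl conjugated with the ring, ring carbons are aromatic
  expect_equal(atom_counts(parse_smiles("C=Cc1ccccc1"))$nCconj, 2L)
  # allene: cumulated, not conjugated
  expect_equal(atom_counts(parse_smiles("C=C=C"))$nCconj, 0L)
})

test_that("topology indices reproduce hand-computed examples", {
  but <- parse_smiles("CCCC")
  topo <- graph_topology_indices(but)
  expect_equal(topo$GNar, 4^(1 / 4), tolerance = 1e-9)
  expect_equal(topo$IVDE, 1.0, tolerance = 1e-9)
  prop <- graph_topology_indices(parse_smiles("CCC"))
  expect_equal(prop$PW2, 1 / 3, tolerance = 1e-9)
  single <- graph_topology_indices(parse_smiles("C"))
  expect_equal(unlist(single), c(GNar = 0, PW2 = 0, PW3 = 0, IVDE = 0))
})

test_that("valence connectivity matches hand-computed Kier-Hall values", {
  expect_equal(valence_connectivity(parse_smiles("CCC"), 2)$chi_v,
               1 / sqrt(2), tolerance = 1e-9)
  x3 <- valence_connectivity(parse_smiles("CCCC"), 3)
  expect_equal(x3$chi_v, 0.5, tolerance = 1e-9)
  expect_equal(x3$chi_v_avg, 0.5, tolerance = 1e-9)
  expect_equal(valence_connectivity(parse_smiles("CC"), 3)$chi_v_avg, 0)
})

test_that("charge and edge-eigenvalue descriptors honour their zero rules", {
  # topological diameter < 8 -> GGI8 = 0
  expect_equal(charge_and_edge_eigen(parse_smiles("CCCCCC"))$GGI8, 0)
  # fewer than 10 bonds -> EEig10r = 0
  expect_equal(charge_and_edge_eigen(parse_smiles("CCCCCC"))$EEig10r, 0)
  # order-1 charge index against the brute-force CT computation on propane
  prop <- parse_smiles("CCC")
  expect_equal(galvez_charge_index(prop, 1), oracle_ggi(prop, 1), tolerance = 1e-9)
  # GGI8 > 0 for a chain long enough to hold distance-8 pairs
  dec <- parse_smiles(linear_alkane(10))
  expect_gt(galvez_charge_index(dec, 8), 0)
})

test_that("composition indices match hand-computed values", {
  comp <- composition_indices(parse_smiles("C"))
  expect_equal(comp$AAC, -(0.2 * log2(0.2) + 0.8 * log2(0.8)), tolerance = 1e-9)
  en <- sanderson_electronegativity()
  en_c <- en$scaled[en$element == "C"]
  en_h <- en$scaled[en$element == "H"]
  expect_equal(comp$Me, (en_c + 4 * en_h) / 5, tolerance = 1e-9)
  # saturated skeleton: every path weight is 1
  expect_equal(composition_indices(parse_smiles("CCCCC"))$PCR, 1.0, tolerance = 1e-12)
})

test_that("electronegativity table is carbon-scaled and errors on unknowns", {
  en <- sanderson_electronegativity()
  expect_equal(en$scaled[en$element == "C"], 1.0)
  expect_true(all(en$scaled > 0))
  g <- parse_smiles("CCO")
  bad_en <- en[en$element != "O", ]
  expect_error(composition_indices(g, bad_en), class = "skinqsar_descriptor_error")
})

test_that("all descriptors match brute-force oracles on linear alkanes C2-C8", {
  for (nc in 2:8) {
    g <- parse_smiles(linear_alkane(nc))
    got <- descriptor_vector(g)
    want <- oracle_descriptors(g)
    for (d in names(want)) {
      expect_equal(unname(got[[d]]), unname(want[[d]]), tolerance = 1e-9,
                   label = sprintf("%s on C%d", d, nc))
    }
    expect_equal(unname(got[["nCconj"]]), 0)
    expect_equal(unname(got[["O-058"]]), 0)
  }
})

test_that("descriptors match brute-force oracles on the fixture molecules", {
  tbl <- fixture_smiles()
  for (r in seq_len(nrow(tbl))) {
    g <- suppressWarnings(parse_smiles(tbl$smiles[r], id = tbl$id[r]))
    got <- descriptor_vector(g)
    want <- oracle_descriptors(g)
    for (d in names(want)) {
      expect_equal(unname(got[[d]]), unname(want[[d]]), tolerance = 1e-9,
                   label = sprintf("%s on %s", d, tbl$id[r]))
    }
  }
})

test_that("descriptors are invariant under atom reordering", {
  variants <- list(
    c("CCO", "OCC", "C(O)C"),
    c("CC(C)C", "C(C)(C)C"),
    c("c1ccncc1", "n1ccccc1"),
    c("CC(=O)O", "OC(C)=O"),
    c("C=CC=C", "C(=C)C=C"),
    c("Clc1ccccc1", "c1ccc(Cl)cc1")
  )
  for (forms in variants) {
    vecs <- lapply(forms, function(s) descriptor_vector(parse_smiles(s)))
    for (k in seq_along(vecs)[-1]) {
      expect_equal(vecs[[k]], vecs[[1]], tolerance = 1e-9,
                   label = paste(forms[k], "vs", forms[1]))
    }
  }
})

test_that("descriptor bounds hold on random trees and fixtures", {
  # random caterpillar-ish alkane trees up to 7 heavy atoms
  withr::with_seed(99, {
    for (rep in 1:10) {
      n <- sample(3:7, 1)
      # random tree SMILES: attach each carbon to a random previous one
      smi <- "C"
      ids <- 1
      for (k in 2:n) smi <- paste0(smi, "C") # linear suffices for diameter rule
      g <- parse_smiles(smi)
      expect_equal(galvez_charge_index(g, 8), 0)
      topo <- graph_topology_indices(g)
      expect_true(topo$PW2 >= 0 && topo$PW2 <= 1)
      expect_true(topo$PW3 >= 0 && topo$PW3 <= 1)
    }
  })
  for (s in fixture_smiles()$smiles) {
    g <- suppressWarnings(parse_smiles(s))
    v <- descriptor_vector(g)
    n_elements <- length(unique(c(g$atoms$element, if (sum(g$atoms$hcount) > 0) "H")))
    expect_lte(v[["AAC"]], log2(max(n_elements, 2)) + 1e-9)
    expect_gte(v[["AAC"]], 0)
    A <- oracle_adjacency(g)
    expect_lte(v[["IVDE"]], log2(max(length(unique(rowSums(A))), 2)) + 1e-9)
    expect_true(v[["PW2"]] >= 0 && v[["PW2"]] <= 1)
    expect_true(v[["PW3"]] >= 0 && v[["PW3"]] <= 1)
    expect_gte(v[["GNar"]], 1 - 1e-9)
  }
})

test_that("batch computation records failures without aborting", {
  tbl <- tibble::tibble(
    id = c("ok1", "bad", "ok2"),
    smiles = c("CCO", "C(", "c1ccccc1")
  )
  res <- compute_descriptors(tbl)
  expect_equal(nrow(res), 2)
  expect_equal(ncol(res), 15) # id + 14 descriptors
  fails <- attr(res, "failures")
  expect_equal(fails$id, "bad")
  expect_equal(fails$stage, "parse")
  empty <- compute_descriptors(tibble::tibble(id = character(0), smiles = character(0)))
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 15)
})
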