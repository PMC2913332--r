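test_that("correlation stage removes exactly one of a duplicated pair", {
  withr::with_seed(1, {
    d <- tibble::tibble(a = rnorm(40), c = rnorm(40))
    d$b <- d$a # exact duplicate, |r| = 1
    res <- filter_collinear(d, r_max = 0.9)
    expect_true(xor("a" %in% res$selected, "b" %in% res$selected))
    expect_true("c" %in% res$selected)
    r <- abs(cor(d[res$selected]))
    diag(r) <- 0
    expect_lte(max(r), 0.9)
  })
})

test_that("orthogonal descriptors all survive the filter", {
  withr::with_seed(2, {
    d <- tibble::as_tibble(matrix(rnorm(400), 100, 4,
                                  dimnames = list(NULL, letters[1:4])))
    res <- filter_collinear(d, r_max = 0.9, vif_max = 10)
    expect_setequal(res$selected, letters[1:4])
  })
})

test_that("exact linear combinations fall to the VIF stage first", {
  withr::with_seed(3, {
    base <- matrix(rnorm(700), 100, 7)
    colnames(base) <- paste0("v", 1:7)
    d <- tibble::as_tibble(base)
    # three exact linear combinations, built to dodge the pairwise stage
    d$lc1 <- (d$v1 + d$v2 + d$v3) / sqrt(3)
    d$lc2 <- (d$v2 - d$v4 + d$v5) / sqrt(3)
    d$lc3 <- (d$v3 + d$v6 - d$v7) / sqrt(3)
    r <- abs(cor(d)); diag(r) <- 0
    expect_lte(max(r), 0.9) # pairwise stage has nothing to do
    res <- filter_collinear(d, r_max = 0.9, vif_max = 10)
    vif_removed <- res$removed$descriptor[res$removed$stage == "vif"]
    expect_length(vif_removed, 3)
    # brute-force VIF on the surviving set is within bounds
    for (cl in res$selected) {
      others <- setdiff(res$selected, cl)
      r2 <- suppressWarnings(summary(lm(d[[cl]] ~ ., data = d[others]))$r.squared)
      expect_lte(1 / (1 - r2), 10 + 1e-6)
    }
  })
})

test_that("filter rejects degenerate input", {
  expect_error(filter_collinear(tibble::tibble(a = rep(1, 10), b = rep(2, 10))),
               "constant")
  expect_error(filter_collinear(tibble::tibble(a = rnorm(10))), "at least 2")
})

test_that("hsa_select returns the single descriptor without GA iterations", {
  d <- tibble::tibble(x = rnorm(30))
  res <- hsa_select(d, rep(c("a", "b"), 15), hsa_config(seed = 1))
  expect_equal(res$selected, "x")
  expect_length(res$trace, 0)
})

test_that("hsa_select recovers a planted informative descriptor quickly", {
  withr::with_seed(10, {
    n <- 80
    d <- tibble::tibble(
      inf = c(runif(n / 2, -1, -0.3), runif(n / 2, 0.3, 1)),
      j1 = runif(n, -1, 1), j2 = runif(n, -1, 1), j3 = runif(n, -1, 1)
    )
    lab <- rep(c("a", "b"), each = n / 2)
  })
  cfg <- hsa_config(seed = 3, generations = 4, chromosomes = 6, initial_active = 2)
  res <- hsa_select(d, lab, cfg)
  expect_true("inf" %in% res$selected)
  # best-so-far trace is monotone non-decreasing
  expect_true(all(diff(res$trace) >= -1e-12))
})

test_that("an exact duplicate of an informative descriptor is dropped", {
  withr::with_seed(11, {
    n <- 80
    inf <- c(runif(n / 2, -1, -0.3), runif(n / 2, 0.3, 1))
    d <- tibble::tibble(inf1 = inf, dup = inf, j1 = runif(n, -1, 1))
    lab <- rep(c("a", "b"), each = n / 2)
  })
  res <- hsa_select(d, lab, hsa_config(seed = 2, generations = 4, chromosomes = 6,
                                       initial_active = 2))
  expect_true(xor("inf1" %in% res$selected, "dup" %in% res$selected))
})

test_that("hsa_select is reproducible for a fixed seed", {
  pp <- planted_pair(n = 60, n_noise = 4, seed = 8)
  cfg <- hsa_config(seed = 7, generations = 3, chromosomes = 6, initial_active = 3)
  r1 <- hsa_select(pp$data, pp$labels, cfg)
  r2 <- hsa_select(pp$data, pp$labels, cfg)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$fitness, r2$fitness)
})

test_that("hsa_select rejects single-class labels", {
  d <- tibble::tibble(x = rnorm(10), y = rnorm(10))
  expect_error(hsa_select(d, rep("a", 10)), "2 classes")
})

test_that("selection results serialize and tidy round-trip", {
  res <- new_selection_result(c("a", "b"), trace = c(0.5, 0.6), fitness = 0.6)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_result(res, path)
  back <- read_selection_result(path)
  expect_equal(back$selected, res$selected)
  expect_equal(back$fitness, res$fitness)
  expect_equal(tidy(res)$descriptor, c("a", "b"))
  expect_equal(glance(res)$n_selected, 2)
})

test_that("hsa config validates and reads from JSON", {
  expect_error(hsa_config(ascending = -1))
  expect_error(hsa_config(mutation_fraction = 2))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(generations = 3, seed = 9), path, auto_unbox = TRUE)
  cfg <- read_hsa_config(path)
  expect_equal(cfg$generations, 3)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$weighting, 1.5)
  jsonlite::write_json(list(bogus = 1), path, auto_unbox = TRUE)
  expect_error(read_hsa_config(path), "unknown")
})
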