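test_that("trapezoid geometry follows the p/w and q/w ratios", {
  # interval [0,1]: support [-0.125, 1.125], core [0.275, 0.725]
  expect_equal(trapezoid_membership(c(-0.125, 0.275, 0.5, 0.725, 1.125), 0, 1),
               c(0, 1, 1, 1, 0))
  # midpoint of the rising shoulder carries membership exactly 0.5
  expect_equal(trapezoid_membership(0.075, 0, 1), 0.5)
  # monotone along the shoulders
  xs <- seq(-0.2, 0.5, by = 0.01)
  expect_true(all(diff(trapezoid_membership(xs, 0, 1)) >= -1e-12))
  # open sides saturate outward
  expect_equal(trapezoid_membership(c(-5, 0.5), 0, 1, open = c(TRUE, FALSE)), c(1, 1))
  # zero-width interval degenerates to an indicator
  expect_equal(trapezoid_membership(c(0.3, 0.31), 0.3, 0.3), c(1, 0))
})

test_that("separable 1-D classes give two rules with the optimal cut", {
  sep <- separable_1d()
  fit <- train_afp(sep$data, sep$labels)
  expect_length(fit$rules, 2)
  cut <- fit$rules[[1]]$sets$x$iv[2]
  # brute-force scan: the midpoint candidate inside the gap maximises the
  # between-child purity difference
  u <- sort(unique(sep$data$x))
  mids <- (u[-1] + u[-length(u)]) / 2
  purity_diff <- vapply(mids, function(t) {
    left <- sep$labels[sep$data$x <= t]
    right <- sep$labels[sep$data$x > t]
    abs(mean(left == "A") - mean(right == "A"))
  }, numeric(1))
  expect_equal(cut, mids[which.max(purity_diff)])
  expect_gt(cut, -0.15)
  expect_lt(cut, 0.15)
  # training batch: 100% correct, none unpredicted
  pred <- predict(fit, sep$data)
  expect_equal(mean(pred$outcome == sep$labels), 1.0)
  expect_equal(sum(pred$outcome == "unpredicted"), 0)
})

test_that("single-class input yields a universal rule", {
  fit <- train_afp(tibble::tibble(x = 1:5 / 5), rep("only", 5))
  pred <- predict(fit, tibble::tibble(x = c(-10, 0.2, 99)))
  expect_true(all(pred$outcome == "only"))
  expect_true(all(pred$degree_only == 1))
})

test_that("membership profile honours the strict 0.5 threshold", {
  sep <- separable_1d()
  fit <- train_afp(sep$data, sep$labels)
  # force a closed-interval single-axis weight-1 rule to probe the shoulder
  rule <- list(class = "A", weight = 1, n = 10,
               sets = list(x = list(iv = c(0, 1), open = c(FALSE, FALSE))))
  probe <- fit
  probe$rules <- list(rule)
  probe$classes <- "A"
  at <- function(x) predict(probe, tibble::tibble(x = x))
  expect_equal(at(0.5)$degree_A, 1)       # core
  expect_equal(at(0.5)$outcome, "A")
  expect_equal(at(0.075)$degree_A, 0.5)   # shoulder midpoint
  expect_equal(at(0.075)$outcome, "unpredicted") # strictly greater than 0.5
  expect_equal(at(-3)$degree_A, 0)        # outside all supports
  expect_equal(at(-3)$outcome, "unpredicted")
})

test_that("prediction errors when a model axis is missing", {
  sep <- separable_1d()
  fit <- train_afp(sep$data, sep$labels)
  expect_error(predict(fit, tibble::tibble(y = 1)), "missing model axis")
})

test_that("empty batches and empty tables behave", {
  sep <- separable_1d()
  fit <- train_afp(sep$data, sep$labels)
  pred <- predict(fit, tibble::tibble(x = numeric(0)))
  expect_equal(nrow(pred), 0)
  expect_error(train_afp(tibble::tibble(x = numeric(0)), character(0)), "empty")
})

test_that("training is deterministic and respects the structural caps", {
  pb <- planted_boxes(n_per_class = 60, d = 3, label_noise = 0.1, seed = 21)
  f1 <- train_afp(pb$data, pb$labels)
  f2 <- train_afp(pb$data, pb$labels)
  expect_identical(f1$rules, f2$rules)
  cfg <- afp_config(max_cuts_per_axis = 2, max_iterations = 4)
  withr::with_seed(31, {
    for (rep in 1:3) {
      n <- 60
      d <- tibble::as_tibble(matrix(runif(n * 3, -1, 1), n, 3,
                                    dimnames = list(NULL, c("a", "b", "c"))))
      lab <- sample(c("x", "y"), n, replace = TRUE)
      fit <- train_afp(d, lab, cfg)
      expect_lte(max(fit$cuts_per_axis), 2)
      expect_lte(fit$iterations, 4)
      expect_lte(sum(vapply(fit$rules, function(r) r$class == "x", logical(1))), 30)
      expect_true(all(vapply(fit$rules, function(r) r$n, numeric(1)) >= 2))
      deg <- predict(fit, d)
      degs <- as.matrix(deg[startsWith(names(deg), "degree_")])
      expect_true(all(degs >= 0 & degs <= 1))
    }
  })
})

test_that("noise-free planted boxes are recovered exactly", {
  pb <- planted_boxes(n_per_class = 80, d = 2, gap = 0.3, label_noise = 0, seed = 13)
  fit <- train_afp(pb$data, pb$labels)
  pred <- predict(fit, pb$data)
  expect_equal(mean(pred$outcome == pb$labels), 1.0)
  expect_equal(sum(pred$outcome == "unpredicted"), 0)
  # every cut lies strictly inside the empty margin between the boxes
  cuts <- unlist(lapply(fit$rules, function(r) {
    lapply(r$sets, function(s) s$iv[!s$open])
  }))
  expect_true(all(cuts > -0.3 & cuts < 0.3))
})

test_that("suppressing unpredicted rows leaves the predicted counts unchanged", {
  pb <- planted_boxes(n_per_class = 60, d = 2, label_noise = 0.05, seed = 17)
  fit <- train_afp(pb$data, pb$labels)
  wide <- pb$data
  wide[1, ] <- 99 # far outside every support -> unpredicted
  pred <- predict(fit, wide)
  cm_all <- confusion_metrics(pred$outcome, pb$labels, positive = "pos",
                              suppress_unpredicted = TRUE)
  keep <- pred$outcome != "unpredicted"
  cm_sub <- confusion_metrics(pred$outcome[keep], pb$labels[keep], positive = "pos",
                              suppress_unpredicted = FALSE)
  expect_identical(cm_all$counts[c("TP", "FP", "TN", "FN")],
                   cm_sub$counts[c("TP", "FP", "TN", "FN")])
})

test_that("AFP models serialize to versioned JSON and round-trip", {
  pb <- planted_boxes(n_per_class = 40, d = 2, seed = 23)
  fit <- train_afp(pb$data, pb$labels)
  path <- withr::local_tempfile(fileext = ".json")
  norm <- normalize_minmax(pb$data)$params
  write_afp_model(fit, path, normalization = norm)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$version, "1")
  back <- read_afp_model(path)
  expect_equal(predict(back, pb$data), predict(fit, pb$data))
  expect_equal(attr(back, "normalization")$descriptor, norm$descriptor)
})

test_that("tidy/glance/autoplot expose the rule structure", {
  sep <- separable_1d()
  fit <- train_afp(sep$data, sep$labels)
  td <- tidy(fit)
  expect_true(all(c("rule", "class", "weight", "axis", "lo", "hi") %in% names(td)))
  expect_true(all(td$support_lo <= td$lo & td$hi <= td$support_hi))
  expect_true(all(td$lo <= td$core_lo & td$core_hi <= td$hi))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(glance(fit)$n_rules, 2)
})
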