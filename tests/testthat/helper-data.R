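# Shared fixtures built in code.

linear_alkane <- function(n_carbons) paste(rep("C", n_carbons), collapse = "")

fixture_smiles <- function() {
  read_smi(system.file("extdata", "example_molecules.smi", package = "skinqsar"))
}

# Two well-separated 1-D classes with a gap around zero.
separable_1d <- function(n_per_class = 40, gap = 0.15, seed = 42) {
  x <- NULL
  withr::with_seed(seed, {
    x <- c(runif(n_per_class, -1, -gap), runif(n_per_class, gap, 1))
  })
  list(
    data = tibble::tibble(x = x),
    labels = rep(c("A", "B"), each = n_per_class)
  )
}

# Axis-aligned class boxes in `d` dimensions with an optional label-noise
# fraction; boxes are [-1, -gap] and [gap, 1] on every axis.
planted_boxes <- function(n_per_class = 150, d = 5, gap = 0.2,
                          label_noise = 0, seed = 7) {
  out <- NULL
  withr::with_seed(seed, {
    x <- rbind(
      matrix(runif(n_per_class * d, -1, -gap), n_per_class, d),
      matrix(runif(n_per_class * d, gap, 1), n_per_class, d)
    )
    colnames(x) <- paste0("d", seq_len(d))
    lab <- rep(c("neg", "pos"), each = n_per_class)
    flip <- runif(2 * n_per_class) < label_noise
    lab <- ifelse(flip, ifelse(lab == "neg", "pos", "neg"), lab)
    out <- list(data = tibble::as_tibble(x), labels = lab, flipped = which(flip))
  })
  out
}

# Diagonal two-descriptor signal among pure-noise descriptors: the class
# depends on inf1 + inf2, so neither informative descriptor suffices alone.
planted_pair <- function(n = 120, n_noise = 18, margin = 0.25, seed = 1) {
  out <- NULL
  withr::with_seed(seed, {
    kept <- matrix(numeric(0), 0, 2)
    while (nrow(kept) < n) {
      cand <- matrix(runif(2 * n, -1, 1), ncol = 2)
      keep <- abs(cand[, 1] + cand[, 2]) > margin
      kept <- rbind(kept, cand[keep, , drop = FALSE])
    }
    kept <- kept[seq_len(n), ]
    lab <- ifelse(kept[, 1] + kept[, 2] > 0, "pos", "neg")
    noise <- matrix(runif(n * n_noise, -1, 1), n, n_noise)
    colnames(noise) <- paste0("junk", seq_len(n_noise))
    d <- dplyr::bind_cols(
      tibble::tibble(inf1 = kept[, 1], inf2 = kept[, 2]),
      tibble::as_tibble(noise)
    )
    out <- list(data = d, labels = lab)
  })
  out
}

xor_clusters <- function(n_per_center = 50, sd = 0.25, seed = 4) {
  out <- NULL
  withr::with_seed(seed, {
    cx <- c(-1, 1, -1, 1)
    cy <- c(-1, -1, 1, 1)
    cl <- c("pos", "neg", "neg", "pos")
    out <- list(
      data = tibble::tibble(
        x = rep(cx, each = n_per_center) + rnorm(4 * n_per_center, 0, sd),
        y = rep(cy, each = n_per_center) + rnorm(4 * n_per_center, 0, sd)
      ),
      labels = rep(cl, each = n_per_center)
    )
  })
  out
}
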