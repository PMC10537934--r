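# Independent brute-force oracles used to cross-check the implementation.

# maximal all-true rectangle area by exhaustive row-pair enumeration
brute_rect_area <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  best <- 0L
  for (r1 in seq_len(nr)) {
    colsum <- integer(nc)
    for (r2 in r1:nr) {
      colsum <- colsum + m[r2, ]
      h <- r2 - r1 + 1L
      runs <- rle(colsum == h)
      w <- max(c(0L, runs$lengths[runs$values]))
      best <- max(best, h * w)
    }
  }
  best
}

# naive double-loop gray tally
brute_histogram <- function(img) {
  counts <- integer(256)
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      g <- img[i, j]
      counts[g + 1L] <- counts[g + 1L] + 1L
    }
  }
  counts
}

# naive per-GLV reassignment into 16 white-ordered bins
brute_bin_pcts <- function(counts) {
  pct <- numeric(16)
  for (g in 0:255) {
    for (b in 1:16) {
      if (g >= 256 - 16 * b && g <= 271 - 16 * b) {
        pct[b] <- pct[b] + counts[g + 1L]
      }
    }
  }
  100 * pct / sum(counts)
}

random_mask <- function(nr, nc, density = 0.5) {
  repeat {
    m <- matrix(runif(nr * nc) < density, nr, nc)
    if (any(m)) return(m)
  }
}

# feature tibble with i.i.d. uniform-ish compositional bins and an
# unrelated outcome, for purely mechanical model tests
random_features <- function(n, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(rgamma(n * 16L, shape = 2), n, 16L)
    bins <- 100 * g / rowSums(g)
    colnames(bins) <- sprintf("bin_%02d", 1:16)
    out <- tibble::as_tibble(bins)
    out$patient_id <- sprintf("P%03d", seq_len(n))
    out$pmd_observed <- runif(n, 0.05, 0.95)
    out
  })
}

small_cohort_config <- function(n_patients = 40, seed = 1, ...) {
  generator_config(n_patients = n_patients, image_height = 120,
                   image_width = 120, seed = seed, ...)
}
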