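# Shared fixtures and independent oracles for the test suite.

# Brute-force co-occurrence counting: an explicit double loop over pixel
# pairs, independent of the vectorized implementation it checks.
brute_force_glcm_counts <- function(levels, n, direction) {
  counts <- matrix(0L, n, n)
  off <- if (direction == "horizontal") c(0L, 1L) else c(1L, 0L)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 > nrow(levels) || c2 > ncol(levels)) next
      a <- levels[r, c]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1L
    }
  }
  counts
}

quantized <- function(levels, n) {
  structure(list(levels = levels, n = as.integer(n)), class = "quantized_roi")
}

# The 4x4 two-level checker image whose horizontal GLCM is known by hand.
checker_image <- function() {
  rbind(c(1L, 1L, 2L, 2L),
        c(1L, 1L, 2L, 2L),
        c(2L, 2L, 1L, 1L),
        c(2L, 2L, 1L, 1L))
}

# A uniform slice of the given HU value.
uniform_slice <- function(hu, size = 16) ct_slice(matrix(hu, size, size))

full_mask <- function(size = 16) roi_mask(matrix(TRUE, size, size))

# A tiny simulation config for tests that only need ground-truth draws.
tiny_sim <- function(...) {
  sim_config(image_size = 16, n_slices = 1, ...)
}
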