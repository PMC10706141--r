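#' Histogram features of a region of interest
#'
#' The five intensity features of the signature: mean, sample (n-1) standard
#' deviation, skewness (central third moment / sd^3), kurtosis (central fourth
#' moment / sd^4, non-excess), and Shannon entropy in bits of a 64-bin
#' equal-width histogram over \[ROI min, ROI max\] (empty bins contribute 0).
#' A constant ROI returns sd = skewness = kurtosis = entropy = 0 by
#' convention.
#'
#' @param slice A [ct_slice()].
#' @param mask An [roi_mask()] with at least 16 in-mask pixels.
#' @return Named numeric of length 5:
#'   `mean`, `sd`, `skewness`, `kurtosis`, `entropy`.
#' @examples
#' sl <- ct_slice(matrix(c(0, 0, 100, 100), 8, 8))
#' histogram_features(sl, roi_mask(matrix(TRUE, 8, 8)))
#' @export
histogram_features <- function(slice, mask) {
  x <- roi_values(slice, mask)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0, entropy = 0))
  }
  skew <- mean((x - m)^3) / s^3
  kurt <- mean((x - m)^4) / s^4
  breaks <- seq(min(x), max(x), length.out = 65)
  counts <- tabulate(pmin(64L, findInterval(x, breaks, rightmost.closed = TRUE)),
                     nbins = 64L)
  p <- counts[counts > 0] / length(x)
  ent <- -sum(p * log2(p))
  c(mean = m, sd = s, skewness = skew, kurtosis = kurt, entropy = ent)
}

roi_values <- function(slice, mask) {
  stopifnot(inherits(slice, "ct_slice"), inherits(mask, "roi_mask"))
  if (!identical(dim(slice$hu), dim(mask$mask))) {
    stop("slice and mask shapes differ", call. = FALSE)
  }
  if (sum(mask$mask) < 16) {
    stop(roi_too_small_error(sum(mask$mask)))
  }
  slice$hu[mask$mask]
}

#' Quantize ROI intensities to discrete gray levels
#'
#' Linear equal-width binning of in-ROI HU from \[min, max\] into levels
#' `1..n` (half-open bins, top edge closed, so the maximum maps to `n`).
#' A constant ROI maps everything to level 1. Because binning is
#' ROI-range-relative, adding a constant HU shift leaves the quantization —
#' and hence all GLCM features — unchanged.
#'
#' @inheritParams histogram_features
#' @param n Number of gray levels (>= 2); the signature uses 16, 32, 64, 128.
#' @return A `quantized_roi`: list with `levels` (integer matrix, `NA`
#'   outside the ROI) and `n`.
#' @examples
#' sl <- ct_slice(matrix(seq(0, 100, length.out = 64), 8, 8))
#' q <- quantize_roi(sl, roi_mask(matrix(TRUE, 8, 8)), n = 2)
#' range(q$levels)
#' @export
quantize_roi <- function(slice, mask, n) {
  if (length(n) != 1 || n < 2) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  x <- roi_values(slice, mask)
  mn <- min(x); mx <- max(x)
  lv <- matrix(NA_integer_, nrow(slice$hu), ncol(slice$hu))
  if (mx == mn) {
    lv[mask$mask] <- 1L
  } else {
    lv[mask$mask] <- as.integer(pmin(n, floor((x - mn) / (mx - mn) * n) + 1))
  }
  structure(list(levels = lv, n = as.integer(n)), class = "quantized_roi")
}

#' Gray-level co-occurrence matrix of a quantized ROI
#'
#' Counts ordered pixel pairs `(p, p + offset)` with both pixels inside the
#' ROI; entry `(i, j)` is the number of pairs whose first pixel has level `i`
#' and second level `j`. The offset is one pixel to the right (`horizontal`)
#' or one pixel down (`vertical`); accumulation is asymmetric (no reverse
#' pairs). Probabilities are counts normalized by the pair total.
#'
#' @param q A `quantized_roi` from [quantize_roi()].
#' @param direction `"horizontal"` or `"vertical"`.
#' @return A `glcm`: list with `counts`, `probs` (both `n x n`), `direction`,
#'   `n`.
#' @section Errors: Zero valid pairs signals a ROI too fragmented for texture
#'   analysis.
#' @examples
#' img <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(2, 2, 1, 1), c(2, 2, 1, 1))
#' q <- structure(list(levels = img, n = 2L), class = "quantized_roi")
#' compute_glcm(q, "horizontal")$counts
#' @export
compute_glcm <- function(q, direction = c("horizontal", "vertical")) {
  stopifnot(inherits(q, "quantized_roi"))
  direction <- match.arg(direction)
  lv <- q$levels
  n <- q$n
  if (direction == "horizontal") {
    a <- lv[, -ncol(lv), drop = FALSE]
    b <- lv[, -1, drop = FALSE]
  } else {
    a <- lv[-nrow(lv), , drop = FALSE]
    b <- lv[-1, , drop = FALSE]
  }
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    stop("ROI too fragmented: no valid in-ROI pixel pairs at offset 1",
         call. = FALSE)
  }
  idx <- (a[ok] - 1L) * n + b[ok]
  counts <- matrix(tabulate(idx, nbins = n * n), n, n, byrow = TRUE)
  structure(list(counts = counts, probs = counts / sum(counts),
                 direction = direction, n = n),
            class = "glcm")
}

#' Haralick statistics of a co-occurrence matrix
#'
#' The five GLCM statistics of the signature, with level indices
#' `i, j` running `1..n` and marginal moments taken over the row/column
#' indices of the probability matrix `p`:
#' contrast `sum (i-j)^2 p(i,j)`; correlation
#' `(sum i*j*p(i,j) - mu_i*mu_j) / (sigma_i*sigma_j)` (0 when either marginal
#' sd is 0); energy `sum p^2`; homogeneity `sum p / (1 + |i-j|)`; variance
#' `sum (i - mu_i)^2 p(i,j)`.
#'
#' @param g A `glcm` from [compute_glcm()].
#' @return Named numeric of length 5:
#'   `contrast`, `correlation`, `energy`, `homogeneity`, `variance`.
#' @examples
#' img <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(2, 2, 1, 1), c(2, 2, 1, 1))
#' q <- structure(list(levels = img, n = 2L), class = "quantized_roi")
#' glcm_statistics(compute_glcm(q, "horizontal"))
#' @export
glcm_statistics <- function(g) {
  stopifnot(inherits(g, "glcm"))
  p <- g$probs
  if (abs(sum(p) - 1) > 1e-9) {
    stop("GLCM probabilities must sum to 1", call. = FALSE)
  }
  n <- g$n
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mu_i <- sum(seq_len(n) * pi_)
  mu_j <- sum(seq_len(n) * pj_)
  var_i <- sum((seq_len(n) - mu_i)^2 * pi_)
  var_j <- sum((seq_len(n) - mu_j)^2 * pj_)
  contrast <- sum((i - j)^2 * p)
  s <- sqrt(var_i * var_j)
  correlation <- if (s == 0) 0 else (sum(i * j * p) - mu_i * mu_j) / s
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, variance = var_i)
}

#' Position of a feature in the 45-entry signature
#'
#' The signature is indexed `j = 1..45`: the five histogram statistics occupy
#' `j = k` for `k = 1..5`, and GLCM statistic `n` of direction `l`
#' (1 horizontal, 2 vertical) at level-set `m` (1..4 for 16, 32, 64, 128
#' levels) occupies `j = 5 + (l-1)*20 + (m-1)*5 + n` — the lexicographic
#' order of the (direction, levels, statistic) nesting, giving 5 + 40 = 45.
#'
#' @param kind `"histogram"` or `"glcm"`.
#' @param k Histogram statistic index 1..5 (mean, sd, skewness, kurtosis,
#'   entropy).
#' @param l,m,n GLCM direction (1..2), level-set (1..4), statistic (1..5:
#'   contrast, correlation, energy, homogeneity, variance).
#' @return Integer `j` in 1..45.
#' @examples
#' feature_index("histogram", k = 1)        # 1
#' feature_index("glcm", l = 1, m = 1, n = 1)  # 6
#' feature_index("glcm", l = 2, m = 4, n = 5)  # 45
#' @export
feature_index <- function(kind = c("histogram", "glcm"),
                          k = NULL, l = NULL, m = NULL, n = NULL) {
  kind <- match.arg(kind)
  if (kind == "histogram") {
    if (is.null(k) || k < 1 || k > 5) stop("`k` must be in 1..5", call. = FALSE)
    return(as.integer(k))
  }
  if (is.null(l) || l < 1 || l > 2) stop("`l` must be in 1..2", call. = FALSE)
  if (is.null(m) || m < 1 || m > 4) stop("`m` must be in 1..4", call. = FALSE)
  if (is.null(n) || n < 1 || n > 5) stop("`n` must be in 1..5", call. = FALSE)
  as.integer(5 + (l - 1) * 20 + (m - 1) * 5 + n)
}

#' Map from feature index j to its meaning
#'
#' @return A 45-row tibble with columns `j`, `kind`, `k`, `l`, `m`, `n`,
#'   `levels` (gray-level count for GLCM features), `direction`, and a
#'   human-readable `label`.
#' @examples
#' feature_index_map()
#' @export
feature_index_map <- function() {
  hist_names <- c("mean", "sd", "skewness", "kurtosis", "entropy")
  stat_names <- c("contrast", "correlation", "energy", "homogeneity", "variance")
  level_sets <- c(16L, 32L, 64L, 128L)
  dir_names <- c("horizontal", "vertical")
  hist_part <- tibble::tibble(
    j = 1:5, kind = "histogram", k = 1:5,
    l = NA_integer_, m = NA_integer_, n = NA_integer_,
    levels = NA_integer_, direction = NA_character_,
    label = paste0("hist_", hist_names)
  )
  grid <- expand.grid(n = 1:5, m = 1:4, l = 1:2)  # n fastest, l slowest
  glcm_part <- tibble::tibble(
    j = 5L + (grid$l - 1L) * 20L + (grid$m - 1L) * 5L + grid$n,
    kind = "glcm", k = NA_integer_,
    l = grid$l, m = grid$m, n = grid$n,
    levels = level_sets[grid$m],
    direction = dir_names[grid$l],
    label = sprintf("glcm_%s_n%d_%s", substr(dir_names[grid$l], 1, 1),
                    level_sets[grid$m], stat_names[grid$n])
  )
  dplyr::arrange(dplyr::bind_rows(hist_part, glcm_part), j)
}

#' Extract the 45-feature texture signature of one ROI
#'
#' Computes the five histogram features and, for each of the eight GLCMs
#' (2 directions x 4 gray-level counts: 16, 32, 64, 128), the five Haralick
#' statistics — 45 features placed by [feature_index()]. Exactly eight GLCMs
#' are constructed (quantization at each level count is shared between the
#' two directions). A pure function of `(slice, mask)`.
#'
#' @inheritParams histogram_features
#' @return Named numeric of length 45 (names `j1..j45`), with the
#'   [feature_index_map()] attached as attribute `"index_map"`.
#' @examples
#' vol <- withr::with_seed(1, render_slice_stack(15, sim_config()))
#' sel <- select_roi(vol)
#' fv <- extract_feature_vector(sel$slice, sel$roi)
#' length(fv)
#' @export
extract_feature_vector <- function(slice, mask) {
  out <- numeric(45)
  out[1:5] <- histogram_features(slice, mask)
  level_sets <- c(16L, 32L, 64L, 128L)
  for (m in 1:4) {
    q <- quantize_roi(slice, mask, level_sets[m])
    for (l in 1:2) {
      g <- compute_glcm(q, c("horizontal", "vertical")[l])
      stats5 <- glcm_statistics(g)
      for (n in 1:5) {
        out[feature_index("glcm", l = l, m = m, n = n)] <- stats5[n]
      }
    }
  }
  if (!all(is.finite(out))) {
    stop("non-finite feature value encountered", call. = FALSE)
  }
  names(out) <- paste0("j", 1:45)
  attr(out, "index_map") <- feature_index_map()
  out
}

#' Concatenate two timepoints into a 90-feature change design
#'
#' Stacks a subject's timepoint-1 signature followed by the timepoint-2
#' signature (entry `j + 45` has the same meaning as entry `j`) and records
#' the change target `y2 - y1`.
#'
#' @param fv1,fv2 45-entry feature vectors from the same subject's two scans.
#' @param y1,y2 Reference values (g for BMC, g/cm2 for BMD) at the two
#'   timepoints.
#' @return List with `values` (named numeric of length 90, names `x1..x90`)
#'   and `target` (`y2 - y1`).
#' @examples
#' fv <- setNames(rnorm(45), paste0("j", 1:45))
#' d <- build_change_design(fv, fv, 15, 14.5)
#' length(d$values); d$target
#' @export
build_change_design <- function(fv1, fv2, y1, y2) {
  if (length(fv1) != 45 || length(fv2) != 45) {
    stop("feature vectors must have exactly 45 entries", call. = FALSE)
  }
  values <- c(unname(fv1), unname(fv2))
  names(values) <- paste0("x", 1:90)
  list(values = values, target = y2 - y1)
}

#' Extract the feature table of a whole cohort
#'
#' The pipeline's feature stage: for every scan in the cohort, run
#' [select_roi()] on its volume and [extract_feature_vector()] on the chosen
#' slice, returning one row per scan.
#'
#' @param cohort Cohort tibble with a `volume` list column (from
#'   [generate_cohort()] or [read_cohort()]).
#' @inheritParams select_roi
#' @return A tibble: the cohort's id/ground-truth columns, `slice_index`, and
#'   feature columns `j1..j45`.
#' @examples
#' co <- generate_cohort(sim_config(n_subjects = 2, seed = 1))
#' ft <- extract_cohort_features(co)
#' dim(ft)
#' @export
extract_cohort_features <- function(cohort, hu_low = 50, hu_high = 400,
                                    shrink = 0.9, close_radius = 3) {
  stopifnot(is.data.frame(cohort), "volume" %in% names(cohort))
  meta_cols <- intersect(c("subject_id", "timepoint", "bmc_true", "bmd_true"),
                         names(cohort))
  rows <- purrr::map(seq_len(nrow(cohort)), function(r) {
    sel <- select_roi(cohort$volume[[r]], hu_low = hu_low, hu_high = hu_high,
                      shrink = shrink, close_radius = close_radius)
    fv <- extract_feature_vector(sel$slice, sel$roi)
    dplyr::bind_cols(
      cohort[r, meta_cols, drop = FALSE],
      tibble::tibble(slice_index = sel$index),
      tibble::as_tibble(as.list(fv))
    )
  })
  dplyr::bind_rows(rows)
}

#' Pivot a per-scan feature table into the two-timepoint change design
#'
#' Joins each subject's timepoint-1 and timepoint-2 rows into one row with 90
#' feature columns `x1..x90` (`x1..x45` = timepoint 1, `x46..x90` = timepoint
#' 2) and change targets `d_bmc` / `d_bmd` where the ground-truth columns are
#' present.
#'
#' @param features A feature table from [extract_cohort_features()] with
#'   exactly two timepoints per `subject_id`.
#' @return A tibble with one row per subject.
#' @export
build_change_table <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("subject_id", "timepoint") %in% names(features)))
  fcols <- paste0("j", 1:45)
  if (!all(fcols %in% names(features))) {
    stop("feature table must contain columns j1..j45", call. = FALSE)
  }
  t1 <- dplyr::filter(features, .data$timepoint == 1)
  t2 <- dplyr::filter(features, .data$timepoint == 2)
  t1 <- dplyr::arrange(t1, .data$subject_id)
  t2 <- dplyr::arrange(t2, .data$subject_id)
  if (!identical(t1$subject_id, t2$subject_id)) {
    stop("every subject needs exactly one row per timepoint", call. = FALSE)
  }
  x1 <- as.matrix(t1[fcols]); colnames(x1) <- paste0("x", 1:45)
  x2 <- as.matrix(t2[fcols]); colnames(x2) <- paste0("x", 46:90)
  out <- dplyr::bind_cols(tibble::tibble(subject_id = t1$subject_id),
                          tibble::as_tibble(x1), tibble::as_tibble(x2))
  if ("bmc_true" %in% names(features)) {
    out$d_bmc <- t2$bmc_true - t1$bmc_true
  }
  if ("bmd_true" %in% names(features)) {
    out$d_bmd <- t2$bmd_true - t1$bmd_true
  }
  out
}
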