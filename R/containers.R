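#' CT image containers
#'
#' Lightweight S3 containers for axial CT data in Hounsfield Units (HU).
#' `ct_slice()` wraps a single 2-D HU matrix with its in-plane pixel spacing;
#' `ct_volume()` wraps an ordered stack of slices sharing one shape.
#'
#' HU are stored as plain numerics (water = 0, air ~ -1000; trabecular bone
#' typically ~50-400). Pixel indices are 1-based, row-major, with a pixel's
#' center at integer coordinates.
#'
#' @param hu Numeric matrix of Hounsfield Units, at least 8 x 8, all finite.
#' @param spacing Numeric length-2 (row mm, col mm) for a slice.
#' @return A `ct_slice` object.
#' @examples
#' sl <- ct_slice(matrix(0, 16, 16), spacing = c(0.7, 0.7))
#' dim(sl$hu)
#' @export
ct_slice <- function(hu, spacing = c(1, 1)) {
  if (!is.matrix(hu) || !is.numeric(hu)) {
    stop("`hu` must be a numeric matrix", call. = FALSE)
  }
  if (any(dim(hu) < 8)) {
    stop("CT slice must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (!all(is.finite(hu))) {
    stop("CT slice contains non-finite HU values", call. = FALSE)
  }
  stopifnot(length(spacing) == 2, all(spacing > 0))
  structure(list(hu = hu, spacing = as.numeric(spacing)), class = "ct_slice")
}

#' @rdname ct_slice
#' @param slices List of `ct_slice` objects, all with the same shape.
#' @param spacing_3d Numeric length-3 (row mm, col mm, slice mm) for a volume.
#' @return `ct_volume()` returns a `ct_volume` object with fields `slices` and
#'   `spacing`.
#' @export
ct_volume <- function(slices, spacing_3d = c(1, 1, 5)) {
  if (!length(slices)) stop("a ct_volume needs at least one slice", call. = FALSE)
  if (!all(vapply(slices, inherits, logical(1), "ct_slice"))) {
    stop("`slices` must be a list of ct_slice objects", call. = FALSE)
  }
  shapes <- vapply(slices, function(s) paste(dim(s$hu), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1) {
    stop("all slices in a volume must share one shape", call. = FALSE)
  }
  stopifnot(length(spacing_3d) == 3, all(spacing_3d > 0))
  structure(list(slices = slices, spacing = as.numeric(spacing_3d)),
            class = "ct_volume")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.3g x %.3g mm, HU range [%g, %g]\n",
              nrow(x$hu), ncol(x$hu), x$spacing[1], x$spacing[2],
              min(x$hu), max(x$hu)))
  invisible(x)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices[[1]]$hu)
  cat(sprintf("<ct_volume> %d slice(s) of %d x %d px, spacing %.3g x %.3g x %.3g mm\n",
              length(x$slices), d[1], d[2],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A boolean mask over one CT slice, optionally carrying the circular
#' parameterization it was cut to. The circle is `(center_row, center_col,
#' radius_px)` in 1-based pixel coordinates; when present, the mask equals the
#' set of pixels strictly inside that circle intersected with the mask the
#' circle was fit to.
#'
#' @param mask Logical matrix, same shape as the slice it refers to.
#' @param circle Optional numeric length-3 `(center_row, center_col, radius_px)`.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(mask, circle = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  if (!is.null(circle)) {
    stopifnot(is.numeric(circle), length(circle) == 3, circle[3] > 0)
    circle <- as.numeric(circle)
  }
  structure(list(mask = mask, circle = circle), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d in-mask pixel(s)",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  if (!is.null(x$circle)) {
    cat(sprintf(", circle center (%.2f, %.2f) radius %.2f px",
                x$circle[1], x$circle[2], x$circle[3]))
  }
  cat("\n")
  invisible(x)
}
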