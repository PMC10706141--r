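#' Threshold a CT slice to a trabecular-bone mask
#'
#' Marks every pixel whose HU lies in `[hu_low, hu_high]`. The default window
#' \[50, 400\] brackets typical trabecular attenuation between marrow and
#' cortical bone.
#'
#' @param slice A [ct_slice()].
#' @param hu_low,hu_high Inclusive HU window, `hu_low < hu_high`.
#' @return An [roi_mask()] with no circle.
#' @section Errors: An empty mask signals a `bonetex_no_trabecular_tissue`
#'   condition — the case-exclusion path for scans with no measurable
#'   trabecular section.
#' @examples
#' sl <- ct_slice(matrix(200, 16, 16))
#' sum(threshold_trabecular_mask(sl, 100, 300)$mask)
#' @export
threshold_trabecular_mask <- function(slice, hu_low = 50, hu_high = 400) {
  stopifnot(inherits(slice, "ct_slice"))
  if (hu_low >= hu_high) stop("`hu_low` must be below `hu_high`", call. = FALSE)
  m <- slice$hu >= hu_low & slice$hu <= hu_high
  if (!any(m)) {
    stop(no_trabecular_tissue_error("no pixels inside the HU window"))
  }
  roi_mask(m)
}

no_trabecular_tissue_error <- function(msg) {
  structure(
    class = c("bonetex_no_trabecular_tissue", "error", "condition"),
    list(message = paste0("no trabecular tissue: ", msg), call = NULL)
  )
}

#' Select the slice with the largest trabecular cross-section
#'
#' Scans a volume and returns the axial slice maximizing the number of pixels
#' inside the trabecular HU window. Ties are broken by the lowest slice index
#' so the choice is deterministic.
#'
#' @param volume A [ct_volume()].
#' @inheritParams threshold_trabecular_mask
#' @return A list with `index` (1-based slice index) and `slice` (the
#'   [ct_slice()]).
#' @examples
#' vol <- withr::with_seed(1, render_slice_stack(15, sim_config()))
#' select_largest_trabecular_slice(vol)$index  # central slice, 3 of 5
#' @export
select_largest_trabecular_slice <- function(volume, hu_low = 50, hu_high = 400) {
  stopifnot(inherits(volume, "ct_volume"))
  if (hu_low >= hu_high) stop("`hu_low` must be below `hu_high`", call. = FALSE)
  counts <- vapply(volume$slices,
                   function(s) sum(s$hu >= hu_low & s$hu <= hu_high),
                   numeric(1))
  if (all(counts == 0)) {
    stop(no_trabecular_tissue_error("all slices empty after thresholding"))
  }
  idx <- which.max(counts)  # which.max returns the first maximum
  list(index = idx, slice = volume$slices[[idx]])
}

#' Cut a circular region of interest inside a trabecular mask
#'
#' Fits the circle a reader would draw inside the trabecular area: centered at
#' the mask centroid, with radius `shrink` times the distance from the
#' centroid to the nearest mask-exterior point (pixels outside the image count
#' as exterior; the distance is taken to the near edge of the exterior pixel).
#' The returned mask is the input mask intersected with the circle's strict
#' interior. `shrink < 1` guards against cortical contamination at the rim.
#'
#' The rule assumes a solid (hole-free) mask; porous thresholded masks should
#' first be consolidated with [close_trabecular_mask()].
#'
#' @param mask An [roi_mask()].
#' @param shrink Radius shrink factor in (0, 1\]; default 0.9.
#' @return An [roi_mask()] carrying its circle parameterization.
#' @section Errors: Fewer than 16 surviving pixels signals a
#'   `bonetex_roi_too_small` condition.
#' @examples
#' full <- roi_mask(matrix(TRUE, 64, 64))
#' fit_circular_roi(full, shrink = 1)$circle
#' @export
fit_circular_roi <- function(mask, shrink = 0.9) {
  stopifnot(inherits(mask, "roi_mask"))
  if (shrink <= 0 || shrink > 1) stop("`shrink` must be in (0, 1]", call. = FALSE)
  m <- mask$mask
  if (!any(m)) stop(no_trabecular_tissue_error("empty mask"), call. = FALSE)
  idx <- which(m, arr.ind = TRUE)
  centroid <- colMeans(idx)

  # Exterior = FALSE pixels plus a one-pixel virtual border ring.
  nr <- nrow(m); nc <- ncol(m)
  ext <- which(!m, arr.ind = TRUE)
  border <- rbind(
    cbind(0, 0:(nc + 1)), cbind(nr + 1, 0:(nc + 1)),
    cbind(1:nr, 0), cbind(1:nr, nc + 1)
  )
  ext_all <- rbind(ext, border)
  d <- sqrt((ext_all[, 1] - centroid[1])^2 + (ext_all[, 2] - centroid[2])^2)
  radius <- shrink * max(min(d) - 0.5, 0)  # to the near edge of the pixel

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- (rows - centroid[1])^2 + (cols - centroid[2])^2 < radius^2
  out <- m & inside
  if (sum(out) < 16) {
    stop(roi_too_small_error(sum(out)))
  }
  roi_mask(out, circle = c(centroid[1], centroid[2], radius))
}

roi_too_small_error <- function(n) {
  structure(
    class = c("bonetex_roi_too_small", "error", "condition"),
    list(message = sprintf(
      "ROI too small: %d pixel(s) inside the fitted circle (need >= 16)", n
    ), call = NULL)
  )
}

#' Consolidate a porous trabecular mask into a solid region
#'
#' A thresholded trabecular mask is porous (marrow gaps between struts), which
#' defeats the inscribed-circle rule. Two consolidation strategies:
#'
#' * `"hull"` (default): fill the convex hull of the mask pixels. Robust at
#'   any bone fraction because a trabecular body (vertebral cross-section,
#'   femoral neck) is close to convex.
#' * `"closing"`: morphological closing with a disk of the given radius,
#'   followed by filling holes not connected to the image border. Preserves
#'   concavities but requires the closing radius to exceed the marrow-gap
#'   width.
#'
#' @param mask An [roi_mask()].
#' @param method `"hull"` or `"closing"`.
#' @param radius Closing disk radius in pixels (closing method only); should
#'   be at least the typical marrow-gap half-width (default 3).
#' @return An [roi_mask()] covering the solid region.
#' @export
close_trabecular_mask <- function(mask, method = c("hull", "closing"),
                                  radius = 3) {
  stopifnot(inherits(mask, "roi_mask"))
  method <- match.arg(method)
  m <- mask$mask
  if (!any(m)) stop(no_trabecular_tissue_error("empty mask"), call. = FALSE)
  if (method == "closing") {
    off <- disk_offsets(radius)
    closed <- erode_binary(dilate_binary(m, off), off)
    return(roi_mask(fill_holes(closed)))
  }
  pts <- which(m, arr.ind = TRUE)
  if (nrow(pts) < 3) return(roi_mask(m))
  hull <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  # expand hull by half a pixel so boundary pixel centers test inside
  cen <- colMeans(pts)
  d <- sqrt((hull[, 1] - cen[1])^2 + (hull[, 2] - cen[2])^2)
  d[d == 0] <- 1
  vy <- cen[1] + (hull[, 1] - cen[1]) * (1 + 0.5 / d)
  vx <- cen[2] + (hull[, 2] - cen[2]) * (1 + 0.5 / d)
  nr <- nrow(m); nc <- ncol(m)
  py <- rep(seq_len(nr), nc)
  px <- rep(seq_len(nc), each = nr)
  inside <- point_in_polygon(px, py, vx, vy)
  roi_mask(matrix(inside, nr, nc))
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  inside <- logical(length(px))
  j <- length(vx)
  for (i in seq_along(vx)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

shift_matrix <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate_binary <- function(m, off) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_matrix(m, off$dr[i], off$dc[i], fill = FALSE)
  }
  out
}

erode_binary <- function(m, off) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_matrix(m, off$dr[i], off$dc[i], fill = TRUE)
  }
  out
}

# Fill holes: background connected to the image border stays background,
# enclosed background becomes foreground. Iterative 4-neighbour flood.
fill_holes <- function(m) {
  bg <- !m
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[1, ] <- bg[1, ]; reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1] <- reach[, 1] | bg[, 1]
  reach[, ncol(m)] <- reach[, ncol(m)] | bg[, ncol(m)]
  repeat {
    grown <- reach |
      (bg & (shift_matrix(reach, 1, 0) | shift_matrix(reach, -1, 0) |
               shift_matrix(reach, 0, 1) | shift_matrix(reach, 0, -1)))
    if (identical(grown, reach)) break
    reach <- grown
  }
  !reach
}

#' One-call ROI selection for a volume
#'
#' The pipeline's ROI stage: threshold the trabecular window on every slice,
#' pick the slice with the largest trabecular section, consolidate its mask
#' with [close_trabecular_mask()], and cut the circular ROI. The returned ROI
#' is the full circle interior — bone and marrow alike — which is the region
#' whose histogram and texture carry the mineral signal.
#'
#' @inheritParams select_largest_trabecular_slice
#' @inheritParams fit_circular_roi
#' @param method Mask consolidation strategy, see [close_trabecular_mask()].
#' @param close_radius Structuring-element radius for the `"closing"` method.
#' @return A list with `index`, `slice`, and `roi` (an [roi_mask()] with its
#'   circle).
#' @examples
#' vol <- withr::with_seed(1, render_slice_stack(15, sim_config()))
#' sel <- select_roi(vol)
#' sel$index; sel$roi
#' @export
select_roi <- function(volume, hu_low = 50, hu_high = 400, shrink = 0.9,
                       method = c("hull", "closing"), close_radius = 3) {
  chosen <- select_largest_trabecular_slice(volume, hu_low, hu_high)
  thin <- threshold_trabecular_mask(chosen$slice, hu_low, hu_high)
  solid <- close_trabecular_mask(thin, method = method, radius = close_radius)
  roi <- fit_circular_roi(solid, shrink = shrink)
  list(index = chosen$index, slice = chosen$slice, roi = roi)
}
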