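#' Configuration for the synthetic trabecular-bone cohort generator
#'
#' Bundles every knob of the phantom generator. The defaults describe a
#' plausible first-lumbar-vertebra (L1) screening population: BMC around
#' 15 +/- 3 g, BMD around 1.0 +/- 0.15 g/cm2, a BMC-BMD correlation of 0.9,
#' and a small negative BMC drift of -0.5 +/- 0.5 g between the two
#' timepoints of each subject.
#'
#' Each rendered slice places a thresholded Gaussian-random-field trabecular
#' texture (struts at `hu_bone`, marrow at `hu_marrow`) inside a disk-shaped
#' "vertebral body" on a soft-tissue background (`hu_background`); the disk
#' radius peaks at the central slice so slice selection has a true maximum.
#' The fraction of bone pixels inside the disk is a monotone function of the
#' subject's true BMC, which is what gives downstream texture features their
#' signal.
#'
#' @param n_subjects Number of subjects; each contributes two timepoints.
#' @param image_size Pixels per side of each square slice (>= 16).
#' @param pixel_spacing In-plane pixel spacing, mm.
#' @param n_slices Slices per stack.
#' @param slice_thickness Slice spacing, mm.
#' @param hu_bone HU value of trabecular struts.
#' @param hu_marrow HU value of marrow between struts.
#' @param hu_background HU value of the soft tissue outside the vertebral body.
#' @param noise_sd Standard deviation of additive HU noise.
#' @param smoothing_sigma Gaussian smoothing length of the latent texture
#'   field, pixels; controls trabecular coarseness.
#' @param bmc_mean,bmc_sd Mean and SD of true BMC, grams.
#' @param bmd_mean,bmd_sd Mean and SD of true BMD, g/cm2.
#' @param bmc_bmd_corr Correlation between true BMC and BMD, in \[-1, 1\].
#' @param change_mean,change_sd Mean and SD of the timepoint-2 BMC shift, grams.
#' @param field_turnover Weight of the fresh latent field blended in at
#'   timepoint 2 (0 = identical texture, 1 = independent texture).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(n_subjects = 3, seed = 7)
#' cfg$bmc_mean
#' @export
sim_config <- function(n_subjects = 50,
                       image_size = 64,
                       pixel_spacing = 0.7,
                       n_slices = 5,
                       slice_thickness = 5,
                       hu_bone = 300,
                       hu_marrow = 0,
                       hu_background = -100,
                       noise_sd = 20,
                       smoothing_sigma = 2,
                       bmc_mean = 15, bmc_sd = 3,
                       bmd_mean = 1.0, bmd_sd = 0.15,
                       bmc_bmd_corr = 0.9,
                       change_mean = -0.5, change_sd = 0.5,
                       field_turnover = 0.15,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), image_size = as.integer(image_size),
    pixel_spacing = pixel_spacing, n_slices = as.integer(n_slices),
    slice_thickness = slice_thickness,
    hu_bone = hu_bone, hu_marrow = hu_marrow, hu_background = hu_background,
    noise_sd = noise_sd, smoothing_sigma = smoothing_sigma,
    bmc_mean = bmc_mean, bmc_sd = bmc_sd,
    bmd_mean = bmd_mean, bmd_sd = bmd_sd,
    bmc_bmd_corr = bmc_bmd_corr,
    change_mean = change_mean, change_sd = change_sd,
    field_turnover = field_turnover,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 1) {
    stop("`n_subjects` must be at least 1", call. = FALSE)
  }
  if (is.na(cfg$image_size) || cfg$image_size < 16) {
    stop("`image_size` must be at least 16", call. = FALSE)
  }
  if (cfg$n_slices < 1) stop("`n_slices` must be at least 1", call. = FALSE)
  if (cfg$bmc_sd < 0 || cfg$bmd_sd < 0 || cfg$noise_sd < 0 || cfg$change_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (abs(cfg$bmc_bmd_corr) > 1) {
    stop("`bmc_bmd_corr` must lie in [-1, 1]", call. = FALSE)
  }
  if (cfg$field_turnover < 0 || cfg$field_turnover > 1) {
    stop("`field_turnover` must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# Map true BMC (g) to the bone-pixel fraction inside the vertebral-body disk.
# Linear through the cohort mean (f = 0.5 at bmc_mean), clipped to [0.05, 0.95].
bone_fraction_from_bmc <- function(bmc_true, cfg) {
  pmin(0.95, pmax(0.05, bmc_true / (2 * cfg$bmc_mean)))
}

# Banded Gaussian smoothing matrix (rows normalized); smoothing a field is
# K %*% X %*% t(K), cheap at the image sizes used here.
gaussian_smoother <- function(size, sigma) {
  if (sigma <= 0) return(diag(size))
  d <- outer(seq_len(size), seq_len(size), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k / rowSums(k)
}

smooth_field <- function(white, smoother) smoother %*% white %*% t(smoother)

# Per-slice vertebral-body disk radius: largest at the central slice.
body_radius_profile <- function(cfg) {
  s <- cfg$n_slices
  base <- 0.42 * cfg$image_size
  if (s == 1) return(base)
  center <- (s + 1) / 2
  rel <- abs(seq_len(s) - center) / max(abs(1 - center), abs(s - center))
  base * (1 - 0.15 * rel)
}

disk_mask <- function(size, radius) {
  c0 <- (size + 1) / 2
  d2 <- outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+")
  d2 <= radius^2
}

# Render one slice from a latent smoothed field.
render_slice_from_field <- function(field, radius, fraction, cfg) {
  size <- cfg$image_size
  disk <- disk_mask(size, radius)
  v <- field[disk]
  thr <- stats::quantile(v, 1 - fraction, names = FALSE, type = 7)
  bone <- disk & (field >= thr)
  hu <- matrix(cfg$hu_background, size, size)
  hu[disk] <- cfg$hu_marrow
  hu[bone] <- cfg$hu_bone
  if (cfg$noise_sd > 0) {
    hu <- hu + stats::rnorm(size^2, 0, cfg$noise_sd)
  }
  hu <- round(hu)
  storage.mode(hu) <- "integer"  # scanners store integer HU
  ct_slice(hu, spacing = rep(cfg$pixel_spacing, 2))
}

draw_latent_fields <- function(cfg) {
  smoother <- gaussian_smoother(cfg$image_size, cfg$smoothing_sigma)
  lapply(seq_len(cfg$n_slices), function(k) {
    smooth_field(matrix(stats::rnorm(cfg$image_size^2), cfg$image_size),
                 smoother)
  })
}

render_volume_from_fields <- function(bmc_true, cfg, fields,
                                      bone_fraction = NULL) {
  frac <- if (is.null(bone_fraction)) {
    bone_fraction_from_bmc(bmc_true, cfg)
  } else {
    bone_fraction
  }
  radii <- body_radius_profile(cfg)
  slices <- lapply(seq_len(cfg$n_slices), function(k) {
    render_slice_from_field(fields[[k]], radii[k], frac, cfg)
  })
  ct_volume(slices,
            spacing_3d = c(cfg$pixel_spacing, cfg$pixel_spacing,
                           cfg$slice_thickness))
}

#' Render one synthetic trabecular CT slice stack
#'
#' Builds a stack of `n_slices` axial slices for a subject with the given true
#' BMC. The trabecular texture is a Gaussian-smoothed white-noise field
#' thresholded at the empirical quantile implied by the bone fraction
#' `f(bmc_true)` (monotone in BMC, clipped to \[0.05, 0.95\]), so the expected
#' mean HU inside the vertebral body increases strictly with BMC. The bone
#' cross-section peaks at the central slice.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] (or call via
#' [generate_cohort()]) for reproducibility.
#'
#' @param bmc_true True bone mineral content, grams (> 0).
#' @param config A [sim_config()].
#' @param bone_fraction Optional override of the bone-pixel fraction (mainly
#'   for testing degenerate textures, e.g. a fully bone-saturated disk).
#' @return A [ct_volume()].
#' @examples
#' vol <- withr::with_seed(1, render_slice_stack(15, sim_config(n_slices = 3)))
#' vol
#' @export
render_slice_stack <- function(bmc_true, config, bone_fraction = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (bmc_true <= 0) stop("`bmc_true` must be positive", call. = FALSE)
  fields <- draw_latent_fields(config)
  render_volume_from_fields(bmc_true, config, fields, bone_fraction)
}

#' Generate a synthetic two-timepoint cohort with known ground truth
#'
#' Draws per-subject (BMC, BMD) from a bivariate normal with the configured
#' correlation, shifts timepoint-2 BMC by `Normal(change_mean, change_sd)`
#' (floored at 0.1 g), and renders both timepoints' slice stacks. The
#' timepoint-2 texture reuses the subject's timepoint-1 latent fields blended
#' with a small fresh perturbation (`field_turnover`), so longitudinal scans
#' of one subject are correlated — the property the change regressor relies
#' on. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per scan (2 per subject): `subject_id`,
#'   `timepoint` (1 or 2), `bmc_true` (g), `bmd_true` (g/cm2), and `volume`
#'   (list column of [ct_volume()]). The config is attached as attribute
#'   `"sim_config"`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_subjects = 2, seed = 7))
#' cohort[, c("subject_id", "timepoint", "bmc_true")]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::local_seed(config$seed)
  w <- config$field_turnover
  rho <- config$bmc_bmd_corr

  records <- purrr::map(seq_len(config$n_subjects), function(i) {
    z <- stats::rnorm(2)
    bmc1 <- max(config$bmc_mean + config$bmc_sd * z[1], 0.1)
    bmd1 <- config$bmd_mean +
      config$bmd_sd * (rho * z[1] + sqrt(1 - rho^2) * z[2])
    delta <- stats::rnorm(1, config$change_mean, config$change_sd)
    bmc2 <- max(bmc1 + delta, 0.1)
    # BMD follows BMC at fixed projected area (BMD = BMC / area)
    bmd2 <- bmd1 * bmc2 / bmc1

    fields1 <- draw_latent_fields(config)
    fresh <- draw_latent_fields(config)
    fields2 <- purrr::map2(fields1, fresh,
                           function(a, b) sqrt(1 - w^2) * a + w * b)

    vol1 <- render_volume_from_fields(bmc1, config, fields1)
    vol2 <- render_volume_from_fields(bmc2, config, fields2)

    tibble::tibble(
      subject_id = sprintf("S%04d", i),
      timepoint = c(1L, 2L),
      bmc_true = c(bmc1, bmc2),
      bmd_true = c(bmd1, bmd2),
      volume = list(vol1, vol2)
    )
  })
  cohort <- dplyr::bind_rows(records)
  attr(cohort, "sim_config") <- config
  cohort
}

#' Write and re-read a synthetic cohort as portable text arrays
#'
#' `write_cohort()` serializes every slice as a plain-text TSV of stored
#' integer values using the DICOM rescale convention
#' `HU = stored * RescaleSlope + RescaleIntercept` (slope 1, intercept -1024),
#' so negative HU survive an unsigned integer encoding losslessly. Each scan
#' gets a directory with `slice_XX.tsv` plus a `meta.json` sidecar (shape,
#' spacing, rescale tags); a `manifest.csv` maps `subject_id`/`timepoint` to
#' paths and ground truth. `read_cohort()` reverses the process.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or [read_cohort()]).
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a cohort tibble with a `volume` list column.
#' @examples
#' co <- generate_cohort(sim_config(n_subjects = 1, n_slices = 2, seed = 1))
#' d <- tempfile()
#' manifest <- write_cohort(co, d)
#' co2 <- read_cohort(manifest)
#' identical(co$volume[[1]]$slices[[1]]$hu, co2$volume[[1]]$slices[[1]]$hu)
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.data.frame(cohort), "volume" %in% names(cohort))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  intercept <- -1024
  rows <- purrr::pmap(
    cohort[c("subject_id", "timepoint", "bmc_true", "bmd_true", "volume")],
    function(subject_id, timepoint, bmc_true, bmd_true, volume) {
      rel <- sprintf("%s_t%d", subject_id, timepoint)
      vdir <- file.path(dir, rel)
      dir.create(vdir, showWarnings = FALSE)
      for (k in seq_along(volume$slices)) {
        stored <- volume$slices[[k]]$hu - intercept
        if (any(stored < 0 | stored > 65535)) {
          stop("HU out of the 16-bit storable range for ", rel, call. = FALSE)
        }
        utils::write.table(stored, file.path(vdir, sprintf("slice_%02d.tsv", k)),
                           sep = "\t", row.names = FALSE, col.names = FALSE)
      }
      meta <- list(
        rows = nrow(volume$slices[[1]]$hu),
        cols = ncol(volume$slices[[1]]$hu),
        n_slices = length(volume$slices),
        spacing = volume$spacing,
        rescale_slope = 1, rescale_intercept = intercept
      )
      jsonlite::write_json(meta, file.path(vdir, "meta.json"),
                           auto_unbox = TRUE, digits = NA)
      tibble::tibble(subject_id = subject_id, timepoint = timepoint,
                     path = rel, bmc_true = bmc_true, bmd_true = bmd_true)
    }
  )
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  invisible(manifest_path)
}

#' @rdname write_cohort
#' @param manifest_path Path to a `manifest.csv` written by [write_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  root <- dirname(manifest_path)
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  manifest$volume <- purrr::map(manifest$path, function(rel) {
    vdir <- file.path(root, rel)
    meta <- jsonlite::read_json(file.path(vdir, "meta.json"),
                                simplifyVector = TRUE)
    slices <- lapply(seq_len(meta$n_slices), function(k) {
      stored <- as.matrix(utils::read.table(
        file.path(vdir, sprintf("slice_%02d.tsv", k)), sep = "\t"
      ))
      dimnames(stored) <- NULL
      ct_slice(stored * meta$rescale_slope + meta$rescale_intercept,
               spacing = meta$spacing[1:2])
    })
    ct_volume(slices, spacing_3d = meta$spacing)
  })
  manifest
}
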