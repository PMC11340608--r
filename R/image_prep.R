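# Image-side preprocessing: illumination correction, per-channel min-max
# normalization (PCN), plate-wise channel-wise standardization (PCS) from
# control-well pixel statistics, channel-weighted augmentation (CWA), and
# cropping/flips.

#' Correct an image with its illumination function
#'
#' Divides each channel pixelwise by the plate's illumination function,
#' removing the microscope's vignetting. Metadata is preserved.
#'
#' @param image A [image_stack()].
#' @param illum Named list of per-channel positive `H x W` matrices (as from
#'   [read_illumination()]), or a single matrix recycled to all channels.
#' @return Corrected [image_stack()].
#' @export
illumination_correct <- function(image, illum) {
  if (is.matrix(illum)) illum <- setNames(rep(list(illum), 5), CP_CHANNELS)
  px <- image$pixels
  for (ch in CP_CHANNELS) {
    m <- illum[[ch]]
    if (is.null(m) || !all(dim(m) == dim(px)[2:3])) {
      abort(sprintf("Illumination for channel %s missing or mis-shaped.", ch),
            class = "cvf_domain_error")
    }
    if (any(m <= 0)) {
      abort("Illumination function must be strictly positive.",
            class = "cvf_domain_error")
    }
    px[ch, , ] <- px[ch, , ] / m
  }
  out <- image
  out$pixels <- px
  out
}

#' Per-channel min-max normalization (PCN)
#'
#' Maps each channel independently to `[0, 1]` via
#' `(X - min(X)) / (max(X) - min(X))`. A constant channel maps to all zeros.
#'
#' @param image A [image_stack()].
#' @return Normalized [image_stack()].
#' @export
pcn <- function(image) {
  px <- image$pixels
  for (ch in seq_len(5)) {
    v <- px[ch, , ]
    rng <- range(v)
    px[ch, , ] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
  }
  out <- image
  out$pixels <- px
  out
}

#' Fit plate-wise channel-wise standardization statistics (PCS)
#'
#' Pools the pixels of all eligible control images per plate and channel and
#' extracts their mean, standard deviation (population convention), median
#' and median absolute deviation (unscaled). Control wells are identified
#' through the plate layouts; images of excluded compounds are skipped — by
#' default AMG900, the aurora-kinase positive control whose MOA coincides
#' with a treatment class.
#'
#' @param images List of [image_stack()] (controls and others; non-control
#'   images are ignored).
#' @param layouts Named list of [plate_layout()] keyed by plate id.
#' @param control_role `"poscon"` (default; found the more effective choice)
#'   or `"dmso"`.
#' @param exclude_compounds Compound ids whose images are excluded from the
#'   statistics.
#' @return Tibble of class `cvf_pcs` with columns `plate_id`, `channel`,
#'   `mean`, `sd`, `median`, `mad`, `control_role`, `n_control_images`.
#' @export
fit_pcs <- function(images, layouts, control_role = c("poscon", "dmso"),
                    exclude_compounds = "AMG900") {
  control_role <- match.arg(control_role)
  wells <- layout_wells(layouts)
  plates <- unique(vapply(images, function(im) im$plate_id, character(1)))
  rows <- list()
  for (pl in plates) {
    ctrl <- wells[wells$plate_id == pl & wells$role == control_role &
                    !(wells$compound_id %in% exclude_compounds), ]
    imgs <- Filter(function(im) {
      im$plate_id == pl && im$well_id %in% ctrl$well_id
    }, images)
    if (!length(imgs)) {
      abort(sprintf("Plate %s has no eligible %s control images.",
                    pl, control_role), class = "cvf_validation_error")
    }
    for (ch in seq_len(5)) {
      v <- unlist(lapply(imgs, function(im) as.vector(im$pixels[ch, , ])))
      rows[[length(rows) + 1]] <- tibble(
        plate_id = pl, channel = CP_CHANNELS[ch],
        mean = mean(v), sd = pop_sd(v),
        median = median(v), mad = mad(v, constant = 1),
        control_role = control_role, n_control_images = length(imgs)
      )
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("cvf_pcs", class(out))
  out
}

#' Apply plate-wise channel-wise standardization (PCS)
#'
#' Standardizes each channel with its plate's control statistics:
#' `(X - median) / MAD` in `"medmad"` mode (the default, more robust to pixel
#' outliers) or `(X - mean) / sd` in `"meansd"` mode. Zero spreads are
#' replaced by `eps` so degenerate control wells cannot poison a batch.
#'
#' @param image A [image_stack()].
#' @param stats A `cvf_pcs` table from [fit_pcs()].
#' @param mode `"medmad"` or `"meansd"`.
#' @param eps Guard for zero spread.
#' @return Standardized [image_stack()] (values centred near 0).
#' @export
apply_pcs <- function(image, stats, mode = c("medmad", "meansd"),
                      eps = 1e-6) {
  mode <- match.arg(mode)
  st <- stats[stats$plate_id == image$plate_id, ]
  if (nrow(st) != 5) {
    abort(sprintf("No PCS statistics for plate %s.", image$plate_id),
          class = "cvf_lookup_error")
  }
  px <- image$pixels
  for (ch in CP_CHANNELS) {
    row <- st[st$channel == ch, ]
    if (mode == "medmad") {
      centre <- row$median; spread <- row$mad
    } else {
      centre <- row$mean; spread <- row$sd
    }
    if (spread <= 0) spread <- eps
    px[ch, , ] <- (px[ch, , ] - centre) / spread
  }
  out <- image
  out$pixels <- px
  out
}

#' Channel-weighted augmentation parameters
#'
#' @param p_trigger Probability that augmentation fires for an image.
#' @param p_channel Probability, given a trigger, that each channel is
#'   augmented (independently).
#' @param intensity_range Uniform range of the multiplicative intensity shift
#'   `s` (channel is scaled by `1 + s`).
#' @param brightness_range Uniform range of the additive brightness change.
#' @param clip_bounds Output clipping bounds.
#' @return A `cvf_cwa_params` list.
#' @export
cwa_params <- function(p_trigger = 0.8, p_channel = 0.4,
                       intensity_range = c(-0.6, 0.6),
                       brightness_range = c(-0.1, 0.1),
                       clip_bounds = c(0, 1)) {
  stopifnot(p_trigger >= 0, p_trigger <= 1, p_channel >= 0, p_channel <= 1,
            intensity_range[1] <= intensity_range[2],
            brightness_range[1] <= brightness_range[2],
            clip_bounds[1] < clip_bounds[2])
  structure(list(p_trigger = p_trigger, p_channel = p_channel,
                 intensity_range = intensity_range,
                 brightness_range = brightness_range,
                 clip_bounds = clip_bounds),
            class = "cvf_cwa_params")
}

#' Channel-weighted augmentation (CWA)
#'
#' With probability `p_trigger` the augmentation fires; each channel is then
#' independently modified with probability `p_channel`: an intensity shift
#' `s ~ U(intensity_range)` and brightness change `b ~ U(brightness_range)`
#' give `channel <- clip((1 + s) * channel + b, clip_bounds)`. Untouched
#' channels are returned bit-identical.
#'
#' @param image A [image_stack()] with pixels inside `clip_bounds`.
#' @param params A [cwa_params()].
#' @param seed Optional integer seed for reproducibility; `NULL` uses the
#'   current RNG stream.
#' @return Augmented [image_stack()].
#' @export
cwa <- function(image, params = cwa_params(), seed = NULL) {
  run <- function() {
    px <- image$pixels
    if (runif(1) < params$p_trigger) {
      for (ch in seq_len(5)) {
        if (runif(1) < params$p_channel) {
          s <- runif(1, params$intensity_range[1], params$intensity_range[2])
          b <- runif(1, params$brightness_range[1], params$brightness_range[2])
          px[ch, , ] <- clamp((1 + s) * px[ch, , ] + b,
                              params$clip_bounds[1], params$clip_bounds[2])
        }
      }
    }
    out <- image
    out$pixels <- px
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Crop and flip an image
#'
#' Training mode takes a uniformly random crop of `size x size` followed by
#' independent vertical and horizontal flips (probability 0.5 each);
#' evaluation mode takes the deterministic centre crop with no flips. The
#' default crop size of 896 makes fields divisible into transformer patch
#' windows.
#'
#' @param image A [image_stack()] with `H, W >= size`.
#' @param size Crop side length.
#' @param train Logical; random crop + flips when `TRUE`.
#' @param seed Optional integer seed for the random draws.
#' @return Cropped [image_stack()].
#' @export
crop_flip <- function(image, size = 896L, train = FALSE, seed = NULL) {
  d <- dim(image$pixels)
  if (d[2] < size || d[3] < size) {
    abort(sprintf("Image (%dx%d) smaller than crop size %d.", d[2], d[3], size),
          class = "cvf_validation_error")
  }
  run <- function() {
    if (train) {
      ox <- sample.int(d[2] - size + 1L, 1)
      oy <- sample.int(d[3] - size + 1L, 1)
    } else {
      ox <- (d[2] - size) %/% 2L + 1L
      oy <- (d[3] - size) %/% 2L + 1L
    }
    px <- image$pixels[, ox:(ox + size - 1L), oy:(oy + size - 1L),
                       drop = FALSE]
    if (train) {
      if (runif(1) < 0.5) px <- px[, rev(seq_len(size)), , drop = FALSE]
      if (runif(1) < 0.5) px <- px[, , rev(seq_len(size)), drop = FALSE]
    }
    out <- image
    out$pixels <- px
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Rescale an image stack to [0, 1] per channel
#'
#' Identical mapping to [pcn()]; provided under its pipeline name for the
#' step that re-ranges standardized (PCS) images into the `[0, 1]` domain the
#' augmentation clipping expects.
#'
#' @inheritParams pcn
#' @export
rescale01 <- function(image) pcn(image)

#' Full image preprocessing pipeline
#'
#' Applies, in order: illumination correction, PCN, PCS, rescale to `[0, 1]`,
#' crop/flip, and (in training mode) CWA. PCS output is centred at zero, so a
#' per-image min-max rescale reconciles it with the `[0, 1]` clipping domain
#' of the augmentation; each stage can be disabled.
#'
#' @param image A [image_stack()].
#' @param illum Illumination function or `NULL` to skip correction.
#' @param stats PCS statistics from [fit_pcs()] or `NULL` to skip PCS.
#' @param pcs_mode Passed to [apply_pcs()].
#' @param size Crop size, or `NULL` to skip cropping.
#' @param train Training mode (random crop/flips and CWA).
#' @param params CWA parameters.
#' @param seed Optional integer seed.
#' @return Preprocessed [image_stack()].
#' @export
prep_image <- function(image, illum = NULL, stats = NULL,
                       pcs_mode = "medmad", size = 896L, train = FALSE,
                       params = cwa_params(), seed = NULL) {
  run <- function() {
    x <- image
    if (!is.null(illum)) x <- illumination_correct(x, illum)
    x <- pcn(x)
    if (!is.null(stats)) {
      x <- apply_pcs(x, stats, mode = pcs_mode)
      x <- rescale01(x)
    }
    if (!is.null(size)) x <- crop_flip(x, size = size, train = train)
    if (train) x <- cwa(x, params)
    x
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
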