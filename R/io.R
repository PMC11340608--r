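# Reading and writing of images, illumination functions, profile tables,
# plate layouts and dataset manifests.

#' Construct a five-channel image stack
#'
#' An image stack holds one field of view: five named fluorescence channels of
#' floating-point pixels plus its plate/well/source/microscope identity. The
#' channel order is canonicalized to (DNA, ER, RNA, AGP, Mito) everywhere in
#' the package.
#'
#' @param pixels Numeric array of dimension `5 x H x W`.
#' @param plate_id,well_id,source_id,microscope_id Identity strings.
#' @param field_index Integer field-of-view index within the well.
#' @param channel_names Channel names of `pixels` in storage order; reordered
#'   to the canonical order if given in another order.
#' @return An object of class `cvf_image`.
#' @export
image_stack <- function(pixels, plate_id = NA_character_, well_id = NA_character_,
                        field_index = 1L, source_id = NA_character_,
                        microscope_id = NA_character_,
                        channel_names = CP_CHANNELS) {
  if (!is.array(pixels) || length(dim(pixels)) != 3) {
    abort("`pixels` must be a 3-d array (channels x H x W).",
          class = "cvf_format_error")
  }
  if (dim(pixels)[1] != 5L) {
    abort(sprintf("An image stack must have exactly 5 channels, got %d.",
                  dim(pixels)[1]), class = "cvf_format_error")
  }
  if (!setequal(channel_names, CP_CHANNELS)) {
    abort(paste0("`channel_names` must be a permutation of: ",
                 paste(CP_CHANNELS, collapse = ", ")),
          class = "cvf_format_error")
  }
  if (!all(is.finite(pixels))) {
    abort("Image pixels must all be finite.", class = "cvf_format_error")
  }
  storage.mode(pixels) <- "double"
  pixels <- pixels[match(CP_CHANNELS, channel_names), , , drop = FALSE]
  dimnames(pixels) <- list(CP_CHANNELS, NULL, NULL)
  structure(
    list(pixels = pixels, plate_id = plate_id, well_id = well_id,
         field_index = as.integer(field_index), source_id = source_id,
         microscope_id = microscope_id),
    class = "cvf_image"
  )
}

#' @export
print.cvf_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<cvf_image> %dx%d px, channels (%s)\n", d[2], d[3],
              paste(CP_CHANNELS, collapse = ", ")))
  cat(sprintf("  plate %s well %s field %d source %s microscope %s\n",
              x$plate_id, x$well_id, x$field_index, x$source_id,
              x$microscope_id))
  rng <- range(x$pixels)
  cat(sprintf("  pixel range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Read a five-channel image from TIFF
#'
#' Accepts either one multi-page TIFF (five pages) or five per-channel TIFF
#' files. Integer pixels (8/16-bit) are loaded without rescaling; float TIFFs
#' are loaded as stored. Vendor channel names are mapped to the canonical
#' (DNA, ER, RNA, AGP, Mito) order through `channel_map`.
#'
#' @param path One path (multi-page) or a named character vector of five paths
#'   whose names are vendor channel names.
#' @param channel_map Named character vector mapping vendor names to canonical
#'   channel names, e.g. `c(MitoTracker = "Mito", Hoechst = "DNA", ...)`.
#'   Unnecessary when names are already canonical or for multi-page files
#'   (assumed stored in canonical order).
#' @inheritParams image_stack
#' @return A [image_stack()] object.
#' @export
read_image_stack <- function(path, channel_map = NULL,
                             plate_id = NA_character_, well_id = NA_character_,
                             field_index = 1L, source_id = NA_character_,
                             microscope_id = NA_character_) {
  read_one <- function(p) {
    probe <- tiff::readTIFF(p, all = TRUE, info = TRUE)
    bits <- attr(probe[[1]], "bits.per.sample") %||% 8L
    # 8/16-bit samples are unsigned integers (reload unscaled); 32-bit
    # samples are floats and the probe already holds the stored values
    if (bits >= 32) probe else tiff::readTIFF(p, all = TRUE, as.is = TRUE)
  }
  if (length(path) == 1L) {
    pages <- read_one(path)
    if (length(pages) != 5L) {
      abort(sprintf("Expected a 5-page TIFF, got %d pages in %s.",
                    length(pages), path), class = "cvf_format_error")
    }
    names_in <- CP_CHANNELS
  } else {
    if (length(path) != 5L) {
      abort(sprintf("Expected 5 channel files, got %d.", length(path)),
            class = "cvf_format_error")
    }
    pages <- lapply(path, function(p) read_one(p)[[1]])
    names_in <- names(path) %||% CP_CHANNELS
    if (!is.null(channel_map)) {
      mapped <- unname(channel_map[names_in])
      if (anyNA(mapped)) {
        abort(paste0("`channel_map` does not cover channel name(s): ",
                     paste(names_in[is.na(mapped)], collapse = ", ")),
              class = "cvf_format_error")
      }
      names_in <- mapped
    }
  }
  dims <- unname(vapply(pages, function(p) dim(p)[1:2], integer(2)))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("Channel images have mismatched shapes.", class = "cvf_format_error")
  }
  px <- array(0, c(5L, dims[1, 1], dims[2, 1]))
  for (i in seq_len(5)) px[i, , ] <- pages[[i]]
  image_stack(px, plate_id = plate_id, well_id = well_id,
              field_index = field_index, source_id = source_id,
              microscope_id = microscope_id, channel_names = names_in)
}

#' Write a five-channel image stack to a multi-page TIFF
#'
#' Integer-valued stacks are stored at the requested integer bit depth and
#' round-trip losslessly; non-integer stacks must lie in `[0, 1]` and are
#' stored as 32-bit float.
#'
#' @param image A [image_stack()] object.
#' @param path Output file path.
#' @param bits Integer bit depth for integer-valued stacks (8 or 16).
#' @export
write_image_stack <- function(image, path, bits = 16L) {
  px <- image$pixels
  mx <- 2^bits - 1
  is_int <- all(px == round(px)) && min(px) >= 0 && max(px) <= mx
  pages <- lapply(seq_len(5), function(i) px[i, , ])
  if (is_int) {
    tiff::writeTIFF(lapply(pages, function(p) p / mx), path,
                    bits.per.sample = as.integer(bits))
  } else {
    if (min(px) < 0 || max(px) > 1) {
      abort("Float image stacks must lie in [0, 1] to be written as TIFF.",
            class = "cvf_format_error")
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read / write an illumination function
#'
#' Illumination functions are per-plate, per-channel positive arrays matching
#' the image shape; a raw image is divided by its illumination function to
#' remove microscope vignetting. They are stored as 32-bit float multi-page
#' TIFFs, rescaled into `[0, 1]` with the scale factor kept in the TIFF
#' description tag so values round-trip.
#'
#' @param illum Named list of `H x W` matrices, one per canonical channel (a
#'   single matrix is recycled to all five channels).
#' @param path File path.
#' @details Stored as a six-page 32-bit float TIFF: five channel pages
#'   rescaled into `[0, 1]` plus a one-pixel page holding the reciprocal of
#'   the scale factor, so values above 1 round-trip exactly.
#' @return `read_illumination()` returns a named list of five positive
#'   matrices keyed by channel.
#' @export
write_illumination <- function(illum, path) {
  if (is.matrix(illum)) illum <- setNames(rep(list(illum), 5), CP_CHANNELS)
  stopifnot(setequal(names(illum), CP_CHANNELS))
  illum <- illum[CP_CHANNELS]
  vals <- unlist(illum)
  if (any(vals <= 0)) {
    abort("Illumination values must be strictly positive.",
          class = "cvf_domain_error")
  }
  scale <- max(max(vals), 1)
  pages <- c(lapply(illum, function(m) m / scale),
             list(matrix(1 / scale, 1, 1)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_illumination
#' @export
read_illumination <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 6L) {
    abort(sprintf("Expected a 6-page illumination TIFF, got %d pages.",
                  length(pages)), class = "cvf_format_error")
  }
  scale <- 1 / pages[[6]][1, 1]
  out <- lapply(pages[1:5], function(p) {
    m <- p * scale
    attributes(m) <- list(dim = dim(m))
    m
  })
  setNames(out, CP_CHANNELS)
}

#' Construct a plate layout
#'
#' A plate layout records, for one physical plate, the role of every well:
#' `treatment`, `dmso` (solvent negative control), `poscon` (positive control
#' compound) or `untreated`. On JUMP-style plates the outermost wells carry
#' positive controls and the next ring carries DMSO.
#'
#' @param plate_id,source_id,microscope_id Identity strings.
#' @param wells Tibble with columns `well_id` (letter-row/number-column, e.g.
#'   "B03"), `role`, and optionally `compound_id`, `moa_label`.
#' @return An object of class `cvf_layout` (a tibble with plate attributes).
#' @export
plate_layout <- function(plate_id, source_id, microscope_id, wells) {
  wells <- as_tibble(wells)
  if (!all(c("well_id", "role") %in% names(wells))) {
    abort("`wells` needs columns `well_id` and `role`.",
          class = "cvf_schema_error")
  }
  if (!"compound_id" %in% names(wells)) wells$compound_id <- NA_character_
  if (!"moa_label" %in% names(wells)) wells$moa_label <- NA_character_
  if (anyDuplicated(wells$well_id)) {
    abort(sprintf("Duplicate well ids on plate %s.", plate_id),
          class = "cvf_schema_error")
  }
  bad_role <- setdiff(unique(wells$role),
                      c("treatment", "dmso", "poscon", "untreated"))
  if (length(bad_role)) {
    abort(paste0("Unknown well role(s): ", paste(bad_role, collapse = ", ")),
          class = "cvf_schema_error")
  }
  orphan <- wells$role == "treatment" & is.na(wells$compound_id)
  if (any(orphan)) {
    abort(sprintf("Treatment wells without compound_id on plate %s: %s",
                  plate_id, paste(wells$well_id[orphan], collapse = ", ")),
          class = "cvf_schema_error")
  }
  structure(wells,
            plate_id = plate_id, source_id = source_id,
            microscope_id = microscope_id,
            class = c("cvf_layout", class(wells)))
}

layout_meta <- function(layout) {
  tibble(plate_id = attr(layout, "plate_id"),
         source_id = attr(layout, "source_id"),
         microscope_id = attr(layout, "microscope_id"))
}

#' Flatten a list of plate layouts into one well table
#'
#' @param layouts List of [plate_layout()] objects.
#' @return Tibble with one row per well and plate metadata columns.
#' @export
layout_wells <- function(layouts) {
  purrr::map_dfr(layouts, function(l) {
    bind_cols(layout_meta(l)[rep(1, nrow(l)), ], as_tibble(l))
  })
}

#' Load a dataset manifest
#'
#' A manifest summarises a MOA dataset with one row per class: the number of
#' unique compounds, of well datapoints (compound x replicate) and of images
#' (well datapoint x fields of view). An optional `Total` row is checked
#' against totals recomputed from the per-class rows; a mismatch triggers a
#' warning, and the recomputed totals are the ones reported.
#'
#' @param path CSV file with columns `moa_label`, `n_unique_compounds`,
#'   `n_well_datapoints`, `n_images`.
#' @return Tibble of per-class rows (class `cvf_manifest`) with the recomputed
#'   totals in `attr(, "totals")` and any stored totals in
#'   `attr(, "stored_totals")`.
#' @export
load_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("moa_label", "n_unique_compounds", "n_well_datapoints", "n_images")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    abort(paste0("Manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cvf_schema_error")
  }
  cnt <- c("n_unique_compounds", "n_well_datapoints", "n_images")
  if (any(as.matrix(m[cnt]) < 0, na.rm = TRUE)) {
    abort("Manifest counts must be non-negative.",
          class = "cvf_validation_error")
  }
  is_total <- tolower(m$moa_label) == "total"
  stored <- if (any(is_total)) unlist(m[is_total, ][1, cnt]) else NULL
  per_class <- m[!is_total, , drop = FALSE]
  totals <- vapply(per_class[cnt], function(x) sum(as.numeric(x)), numeric(1))
  if (!is.null(stored) && !isTRUE(all.equal(unname(totals),
                                            unname(as.numeric(stored))))) {
    warn(paste0(
      "Stored manifest totals disagree with recomputed per-class sums: ",
      paste(sprintf("%s stored %s vs recomputed %s", cnt, stored, totals),
            collapse = "; ")
    ))
  }
  if (nrow(per_class)) {
    bad <- per_class$n_well_datapoints < per_class$n_unique_compounds
    if (any(bad)) {
      warn(paste0("Classes with fewer well datapoints than compounds: ",
                  paste(per_class$moa_label[bad], collapse = ", ")))
    }
  }
  structure(per_class, totals = totals, stored_totals = stored,
            class = c("cvf_manifest", class(per_class)))
}

#' Totals of a dataset manifest
#'
#' @param manifest Result of [load_manifest()].
#' @return Named numeric vector with elements `n_unique_compounds`,
#'   `n_well_datapoints`, `n_images`.
#' @export
manifest_totals <- function(manifest) attr(manifest, "totals")

#' Write / load a profile table
#'
#' Profile tables are wells x features with metadata columns; round-trips are
#' lossless for values and column order. CSV is used for `.csv` paths and
#' Apache Parquet for `.parquet` paths (requires the arrow package).
#'
#' @param table Profile table.
#' @param path File path ending in `.csv` or `.parquet`.
#' @export
write_profiles <- function(table, path) {
  assert_profile_table(table)
  if (grepl("\\.parquet$", path)) {
    rlang::check_installed("arrow", reason = "to write Parquet profiles")
    arrow::write_parquet(table, path)
  } else {
    readr::write_csv(table, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_profiles
#' @export
load_profiles <- function(path) {
  tab <- if (grepl("\\.parquet$", path)) {
    rlang::check_installed("arrow", reason = "to read Parquet profiles")
    as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal")
  }
  if (anyDuplicated(names(tab))) {
    dup <- unique(names(tab)[duplicated(names(tab))])
    abort(paste0("Duplicate feature names in profile file: ",
                 paste(dup, collapse = ", ")), class = "cvf_schema_error")
  }
  n_missing <- sum(!vapply(tab[feature_cols(tab)], function(x) all(is.finite(x)),
                           logical(1)))
  if (n_missing > 0) {
    inform(sprintf("Loaded profiles contain %d feature column(s) with missing values.",
                   n_missing))
  }
  tab
}
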