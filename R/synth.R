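# Synthetic plate-structured Cell Painting data: layouts, five-channel field
# images, well-level profiles and compound structures, with controllable class
# signal and batch effects. All generators are fully determined by the config
# seed.

# A small pool of valid SMILES grouped into scaffold families; classes draw
# their compounds from a family chosen by class index, giving the
# class-correlated substructure usage that makes fingerprints informative.
SMILES_FAMILIES <- list(
  alkanols   = c("CCO", "CCCO", "CCCCO", "CC(C)O", "CC(C)CO", "CCC(C)O",
                 "CCCCCO", "CC(O)CC"),
  aromatics  = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Cc1ccccc1C",
                 "c1ccc2ccccc2c1", "CCc1ccccc1C", "Cc1cccc(C)c1",
                 "CCCc1ccccc1"),
  pyridines  = c("c1ccncc1", "Cc1ccncc1", "CCc1ccncc1", "c1ccnc(C)c1",
                 "Cc1ccnc(C)c1", "CCc1ccncc1C", "c1cc(CC)ncc1",
                 "Cc1ccncc1CC"),
  ketoacids  = c("CC(=O)C", "CCC(=O)C", "CC(=O)CC", "CC(=O)O", "CCC(=O)O",
                 "CC(=O)CCC", "CCCC(=O)O", "CCC(=O)CC"),
  amines     = c("CCN", "CCCN", "CCN(C)C", "CCCCN", "CC(C)N", "CCNCC",
                 "CCCNC", "CN(C)CC"),
  ethers     = c("CCOC", "CCOCC", "CCCOC", "COCCOC", "CCOCCC", "COCCCO",
                 "CCOCCO", "COCCN"),
  halides    = c("CCCl", "CCCCl", "CC(Cl)C", "CCBr", "CCCBr", "ClCCCl",
                 "CC(C)Cl", "BrCCC"),
  phenols    = c("Oc1ccccc1", "Cc1ccc(O)cc1", "Oc1ccc(CC)cc1",
                 "Oc1cccc(C)c1", "CCc1ccc(O)cc1", "Oc1ccc(C)cc1C",
                 "Oc1ccccc1C", "CCCc1ccc(O)cc1")
)

#' Configuration for the synthetic Cell Painting generator
#'
#' Defaults mirror the structure of a multi-source JUMP-style compound
#' dataset: several sources/microscopes with distinct intensity biases, 384
#' wells per plate with positive controls on the outermost ring and DMSO on
#' the next ring, 4-10 replicate wells per compound spread over at least two
#' sources, several fields of view per well and class-dependent morphology.
#'
#' @param n_sources Number of data-generating sources (laboratories).
#' @param plates_per_source Plates per source.
#' @param n_classes Number of MOA classes.
#' @param compounds_per_class Compounds per class.
#' @param replicates_range Inclusive (min, max) replicate wells per compound;
#'   the default (4, 10) mirrors the replicate-based selection rule used for
#'   compound datasets of this kind.
#' @param fields_per_well Fields of view imaged per well.
#' @param image_size Square field size in pixels; the default of 996 is a
#'   typical acquisition size for this assay.
#' @param n_features,n_informative Number of profile features and how many of
#'   them carry class signal.
#' @param class_effect_size Strength of the class signal: mean shift (in noise
#'   SD units) of informative profile features, and scale of the
#'   class-dependent cell-eccentricity shift in rendered images.
#' @param batch_offset_scale Scale of per-source gains and per-microscope
#'   offsets applied to images and profiles (0 disables batch effects).
#' @param illumination_gradient_scale Depth of the radial illumination
#'   fall-off applied per plate (0 disables vignetting).
#' @param noise_sd Additive Gaussian noise SD for profile features; images use
#'   `0.05 * noise_sd` in pixel units.
#' @param cells_per_field Mean number of cells rendered per field.
#' @param chem_families Number of SMILES scaffold families the classes cycle
#'   through; fewer families than classes makes chemistry only partially
#'   informative.
#' @param profile_class_groups,image_class_groups Optional integer vectors of
#'   length `n_classes` mapping classes to signal groups; classes in the same
#'   group share the profile (resp. image) signature, so a modality can be
#'   made blind to distinctions it should not carry. Default: every class its
#'   own group.
#' @param corrupt_fraction Fraction of well datapoints given a pathological
#'   quality score (for QC testing).
#' @param seed Integer seed; fully determines all generator output.
#' @return A validated `cvf_synth_config` list.
#' @export
synth_config <- function(n_sources = 3, plates_per_source = 2, n_classes = 10,
                         compounds_per_class = 5, replicates_range = c(4, 10),
                         fields_per_well = 4, image_size = 996,
                         n_features = 200, n_informative = 20,
                         class_effect_size = 1, batch_offset_scale = 0.5,
                         illumination_gradient_scale = 0.3, noise_sd = 1,
                         cells_per_field = 40, chem_families = 4,
                         profile_class_groups = NULL,
                         image_class_groups = NULL,
                         corrupt_fraction = 0, seed = 1L) {
  cfg <- list(
    n_sources = n_sources, plates_per_source = plates_per_source,
    n_classes = n_classes, compounds_per_class = compounds_per_class,
    replicates_range = as.integer(replicates_range),
    fields_per_well = fields_per_well, image_size = image_size,
    n_features = n_features, n_informative = n_informative,
    class_effect_size = class_effect_size,
    batch_offset_scale = batch_offset_scale,
    illumination_gradient_scale = illumination_gradient_scale,
    noise_sd = noise_sd, cells_per_field = cells_per_field,
    chem_families = min(chem_families, length(SMILES_FAMILIES)),
    profile_class_groups = profile_class_groups %||% seq_len(n_classes),
    image_class_groups = image_class_groups %||% seq_len(n_classes),
    corrupt_fraction = corrupt_fraction, seed = as.integer(seed)
  )
  if (cfg$n_informative > cfg$n_features) {
    abort("`n_informative` must not exceed `n_features`.",
          class = "cvf_config_error")
  }
  if (length(cfg$replicates_range) != 2 ||
      cfg$replicates_range[1] > cfg$replicates_range[2] ||
      cfg$replicates_range[1] < 1) {
    abort("`replicates_range` must be an increasing pair of positive integers.",
          class = "cvf_config_error")
  }
  if (length(cfg$profile_class_groups) != n_classes ||
      length(cfg$image_class_groups) != n_classes) {
    abort("Class-group vectors must have length `n_classes`.",
          class = "cvf_config_error")
  }
  if (cfg$illumination_gradient_scale < 0 ||
      cfg$illumination_gradient_scale >= 1) {
    abort("`illumination_gradient_scale` must lie in [0, 1).",
          class = "cvf_config_error")
  }
  structure(cfg, class = "cvf_synth_config")
}

# 384-well geometry: 16 rows (A-P) x 24 columns. Outermost ring = poscon,
# next ring = dmso, interior = treatment candidates.
plate_well_grid <- function() {
  rows <- LETTERS[1:16]
  grid <- expand.grid(row = seq_len(16), col = seq_len(24))
  grid$well_id <- sprintf("%s%02d", rows[grid$row], grid$col)
  outer <- grid$row %in% c(1, 16) | grid$col %in% c(1, 24)
  ring2 <- !outer & (grid$row %in% c(2, 15) | grid$col %in% c(2, 23))
  grid$role <- ifelse(outer, "poscon", ifelse(ring2, "dmso", "treatment"))
  as_tibble(grid[c("well_id", "role")])
}

# Fixed per-source / per-microscope batch deviations, deterministic in seed.
batch_deviations <- function(cfg) {
  withr::with_seed(string_seed(cfg$seed, "batch"), {
    list(
      source_gain = setNames(runif(cfg$n_sources, -0.5, 0.5),
                             sprintf("source_%d", seq_len(cfg$n_sources))),
      micro_offset = setNames(runif(2, -0.5, 0.5), c("M1", "M2"))
    )
  })
}

source_microscope <- function(s) sprintf("M%d", 1 + (s - 1) %% 2)

#' Generate plate layouts and a compound table
#'
#' Lays out positive controls on the outermost wells, DMSO controls on the
#' next ring, and treatment compounds on interior wells. Each compound gets a
#' replicate count drawn from `replicates_range` and its replicate wells are
#' spread round-robin across sources, so every compound with at least two
#' replicates appears in at least two sources. Compound SMILES are drawn from
#' bundled scaffold families with class-correlated usage.
#'
#' @param config A [synth_config()].
#' @return List with `layouts` (named list of [plate_layout()]) and
#'   `compounds` (tibble: `compound_id`, `moa_label`, `smiles`,
#'   `n_replicates`).
#' @export
make_layouts <- function(config) {
  cfg <- config
  withr::with_seed(string_seed(cfg$seed, "layouts"), {
    classes <- sprintf("MOA%02d", seq_len(cfg$n_classes))
    n_cpd <- cfg$n_classes * cfg$compounds_per_class
    compounds <- tibble(
      compound_id = sprintf("CPD%03d", seq_len(max(n_cpd, 0))),
      moa_label = rep(classes, each = cfg$compounds_per_class),
      class_idx = rep(seq_len(cfg$n_classes), each = cfg$compounds_per_class)
    )
    fam_of_class <- (seq_len(cfg$n_classes) - 1) %% cfg$chem_families + 1
    compounds$smiles <- vapply(seq_len(nrow(compounds)), function(i) {
      fam <- SMILES_FAMILIES[[fam_of_class[compounds$class_idx[i]]]]
      within_class <- (i - 1) %% cfg$compounds_per_class
      fam[within_class %% length(fam) + 1]
    }, character(1))
    rep_choices <- seq(cfg$replicates_range[1], cfg$replicates_range[2])
    compounds$n_replicates <- if (!nrow(compounds)) integer(0)
      else if (length(rep_choices) == 1) rep(rep_choices, nrow(compounds))
      else sample(rep_choices, nrow(compounds), replace = TRUE)

    grid <- plate_well_grid()
    n_plates <- cfg$n_sources * cfg$plates_per_source
    plate_ids <- character(n_plates)
    plate_source <- integer(n_plates)
    k <- 0
    for (s in seq_len(cfg$n_sources)) {
      for (p in seq_len(cfg$plates_per_source)) {
        k <- k + 1
        plate_ids[k] <- sprintf("S%02dP%02d", s, p)
        plate_source[k] <- s
      }
    }
    capacity <- n_plates * sum(grid$role == "treatment")
    demand <- sum(compounds$n_replicates)
    if (demand > capacity) {
      abort(sprintf(
        "Compound replicates (%d wells) exceed treatment-well capacity (%d).",
        demand, capacity), class = "cvf_capacity_error")
    }

    # per-plate shuffled queues of free treatment wells
    queues <- lapply(seq_len(n_plates), function(i) {
      sample(grid$well_id[grid$role == "treatment"])
    })
    used <- integer(n_plates)
    assignments <- vector("list", nrow(compounds))
    plate_cursor_of_source <- rep(1L, cfg$n_sources)
    for (i in seq_len(nrow(compounds))) {
      reps <- compounds$n_replicates[i]
      rows <- vector("list", reps)
      for (j in seq_len(reps)) {
        s <- (i + j - 2) %% cfg$n_sources + 1  # round-robin over sources
        cand <- which(plate_source == s)
        cand <- cand[order(used[cand])]
        pl <- NA_integer_
        for (cc in cand) {
          if (used[cc] < length(queues[[cc]])) { pl <- cc; break }
        }
        if (is.na(pl)) {  # source full; fall back to any plate with room
          alt <- which(used < lengths(queues))
          pl <- alt[which.min(used[alt])]
        }
        used[pl] <- used[pl] + 1L
        rows[[j]] <- tibble(plate = pl, well_id = queues[[pl]][used[pl]],
                            compound_id = compounds$compound_id[i],
                            moa_label = compounds$moa_label[i])
      }
      assignments[[i]] <- bind_rows(rows)
    }
    assigned <- bind_rows(c(
      list(tibble(plate = integer(), well_id = character(),
                  compound_id = character(), moa_label = character())),
      assignments))

    layouts <- lapply(seq_len(n_plates), function(pl) {
      wells <- grid
      wells$compound_id <- NA_character_
      wells$moa_label <- NA_character_
      # positive controls cycle through the eight JUMP poscon compounds
      pos_idx <- which(wells$role == "poscon")
      wells$compound_id[pos_idx] <-
        POSCON_COMPOUNDS[(seq_along(pos_idx) - 1) %% length(POSCON_COMPOUNDS) + 1]
      here <- assigned[assigned$plate == pl, ]
      m <- match(here$well_id, wells$well_id)
      wells$compound_id[m] <- here$compound_id
      wells$moa_label[m] <- here$moa_label
      # unused interior wells stay untreated
      unused <- wells$role == "treatment" & is.na(wells$compound_id)
      wells$role[unused] <- "untreated"
      plate_layout(plate_ids[pl],
                   sprintf("source_%d", plate_source[pl]),
                   source_microscope(plate_source[pl]), wells)
    })
    names(layouts) <- plate_ids
    list(layouts = layouts,
         compounds = select(compounds, -"class_idx"))
  })
}

# Eccentricity mean for a class signal group: groups are spread over
# [-0.5, 0.5] and scaled by 0.4 * class_effect_size around a base of 0.55.
group_eccentricity <- function(group, n_groups, effect) {
  dev <- if (n_groups > 1) (group - (n_groups + 1) / 2) / (n_groups - 1) else 0
  clamp(0.55 + 0.4 * effect * dev, 0.05, 0.9)
}

# Radial illumination surface in (0, 1]: 1 at the centre, 1 - scale at the
# corners.
illumination_surface <- function(size, scale) {
  cc <- (size + 1) / 2
  r2 <- outer((seq_len(size) - cc)^2, (seq_len(size) - cc)^2, "+")
  1 - scale * r2 / max(r2, 1)
}

#' Render one synthetic field of view
#'
#' Draws elliptical cells with class-dependent eccentricity (the class's image
#' signal group shifts the eccentricity mean by `class_effect_size`), applies
#' a per-plate radial illumination gradient, a per-source multiplicative gain
#' and per-microscope additive offset, and additive Gaussian noise. The
#' ground-truth illumination surface is attached as attribute `illumination`
#' so correction can be tested against truth.
#'
#' @param layout A [plate_layout()].
#' @param well_id Well to render.
#' @param config A [synth_config()].
#' @param field_index Field-of-view index (also seeds the field's RNG stream).
#' @return A [image_stack()] with attribute `illumination` (named list of
#'   per-channel `H x W` matrices).
#' @export
render_field <- function(layout, well_id, config, field_index = 1L) {
  cfg <- config
  w <- layout[layout$well_id == well_id, ]
  if (nrow(w) != 1) {
    abort(sprintf("Well %s is not on plate %s.", well_id,
                  attr(layout, "plate_id")), class = "cvf_validation_error")
  }
  meta <- layout_meta(layout)
  dev <- batch_deviations(cfg)
  size <- cfg$image_size
  classes <- sprintf("MOA%02d", seq_len(cfg$n_classes))
  cls <- match(w$moa_label, classes)
  groups <- cfg$image_class_groups
  n_groups <- max(groups)
  ecc_mean <- if (w$role == "treatment" && !is.na(cls)) {
    group_eccentricity(groups[cls], n_groups, cfg$class_effect_size)
  } else if (w$role == "poscon") {
    0.8  # positive controls carry a strong, distinct elongation phenotype
  } else {
    0.55
  }
  amp_base <- c(DNA = 0.9, ER = 0.6, RNA = 0.5, AGP = 0.6, Mito = 0.7)
  # class signal also modulates organelle staining intensity (opposite signs
  # on ER/AGP vs RNA/Mito so total brightness is roughly preserved)
  amp_sign <- c(DNA = 0, ER = 1, RNA = -1, AGP = 1, Mito = -1)
  grp_dev <- if (w$role == "treatment" && !is.na(cls) && n_groups > 1) {
    (groups[cls] - (n_groups + 1) / 2) / (n_groups - 1)
  } else 0
  amp_base <- amp_base * (1 + 0.5 * cfg$class_effect_size * grp_dev * amp_sign)

  # Seed the field's RNG by the plate's index within its source (not the
  # source itself), so that with batch effects and noise disabled the same
  # well renders identically across sources.
  plate_key <- sub("^S\\d+P", "P", meta$plate_id)
  seed <- string_seed(cfg$seed, "field", plate_key, well_id, field_index)
  px <- withr::with_seed(seed, {
    n_cells <- rpois(1, cfg$cells_per_field)
    img <- array(0.05, c(5, size, size))  # uniform background
    if (n_cells > 0) {
      cx <- runif(n_cells, 4, size - 3)
      cy <- runif(n_cells, 4, size - 3)
      th <- runif(n_cells, 0, pi)
      ecc <- clamp(rnorm(n_cells, ecc_mean, 0.05), 0, 0.98)
      a <- pmax(2, rnorm(n_cells, size / 18, size / 72))  # semi-major axis px
      b <- a * sqrt(1 - ecc^2)
      amp <- matrix(exp(rnorm(5 * n_cells, 0, 0.15)), nrow = n_cells)
      for (i in seq_len(n_cells)) {
        r <- ceiling(a[i]) + 2L
        xs <- max(1, floor(cx[i] - r)):min(size, ceiling(cx[i] + r))
        ys <- max(1, floor(cy[i] - r)):min(size, ceiling(cy[i] + r))
        dx <- outer(xs - cx[i], rep(1, length(ys)))
        dy <- outer(rep(1, length(xs)), ys - cy[i])
        u <- (dx * cos(th[i]) + dy * sin(th[i])) / a[i]
        v <- (-dx * sin(th[i]) + dy * cos(th[i])) / b[i]
        q <- u^2 + v^2
        blob <- exp(-3 * q)
        blob[q > 1.5] <- 0
        for (ch in seq_len(5)) {
          scale_ch <- if (ch == 1) 0.6 else 1  # nucleus smaller than cell body
          if (scale_ch != 1) {
            q2 <- (u / scale_ch)^2 + (v / scale_ch)^2
            blob_ch <- exp(-3 * q2)
            blob_ch[q2 > 1.5] <- 0
          } else blob_ch <- blob
          img[ch, xs, ys] <- img[ch, xs, ys] +
            amp_base[ch] * amp[i, ch] * blob_ch
        }
      }
    }
    gain <- 1 + cfg$batch_offset_scale * dev$source_gain[[meta$source_id]]
    offset <- 0.2 * cfg$batch_offset_scale *
      dev$micro_offset[[meta$microscope_id]]
    illum <- illumination_surface(size, cfg$illumination_gradient_scale)
    for (ch in seq_len(5)) {
      img[ch, , ] <- pmax((img[ch, , ] * gain + offset) * illum +
                            0.05 * cfg$noise_sd * rnorm(size * size), 0)
    }
    attr(img, "illum") <- illum
    img
  })
  illum <- attr(px, "illum")
  attr(px, "illum") <- NULL
  out <- image_stack(px, plate_id = meta$plate_id, well_id = well_id,
                     field_index = field_index, source_id = meta$source_id,
                     microscope_id = meta$microscope_id)
  attr(out, "illumination") <- setNames(rep(list(illum), 5), CP_CHANNELS)
  out
}

#' Generate well-level synthetic profiles
#'
#' One row per well datapoint. Informative features carry a class-group mean
#' shift of size `class_effect_size` (in noise-SD units); every feature
#' receives additive per-source and per-microscope offsets scaled by
#' `batch_offset_scale` plus Gaussian noise. DMSO wells draw from the null
#' class (no shift); positive-control wells share one strong signature.
#' Three quality-score columns (`qc_blur`, `qc_saturation`, `qc_focus`) are
#' independent uniforms unless `corrupt_fraction > 0`.
#'
#' @param layouts `layouts` element of [make_layouts()].
#' @param config A [synth_config()].
#' @return Profile table tibble.
#' @export
make_profiles <- function(layouts, config) {
  cfg <- config
  wells <- layout_wells(layouts)
  wells <- wells[wells$role %in% c("treatment", "dmso", "poscon"), ]
  classes <- sprintf("MOA%02d", seq_len(cfg$n_classes))
  groups <- cfg$profile_class_groups
  n_groups <- max(groups)
  feat_names <- sprintf("feat_%03d", seq_len(cfg$n_features))

  withr::with_seed(string_seed(cfg$seed, "profiles"), {
    # group signatures on the informative features
    mu <- matrix(0, n_groups + 1, cfg$n_features)  # last row: poscon signature
    if (cfg$n_informative > 0) {
      mu[, seq_len(cfg$n_informative)] <-
        cfg$class_effect_size *
        matrix(rnorm((n_groups + 1) * cfg$n_informative), n_groups + 1)
      mu[n_groups + 1, seq_len(cfg$n_informative)] <-
        3 * rnorm(cfg$n_informative)  # strong distinct poscon phenotype
    }
    src_off <- matrix(rnorm(cfg$n_sources * cfg$n_features, 0,
                            cfg$batch_offset_scale),
                      cfg$n_sources, cfg$n_features,
                      dimnames = list(sprintf("source_%d",
                                              seq_len(cfg$n_sources)), NULL))
    mic_off <- matrix(rnorm(2 * cfg$n_features, 0,
                            0.5 * cfg$batch_offset_scale),
                      2, cfg$n_features, dimnames = list(c("M1", "M2"), NULL))

    n <- nrow(wells)
    x <- matrix(rnorm(n * cfg$n_features, 0, cfg$noise_sd), n)
    cls <- match(wells$moa_label, classes)
    grp <- ifelse(wells$role == "treatment" & !is.na(cls), groups[cls], NA)
    for (i in seq_len(n)) {
      sig <- if (wells$role[i] == "poscon") {
        mu[n_groups + 1, ]
      } else if (!is.na(grp[i])) {
        mu[grp[i], ]
      } else rep(0, cfg$n_features)
      x[i, ] <- x[i, ] + sig + src_off[wells$source_id[i], ] +
        mic_off[wells$microscope_id[i], ]
    }
    colnames(x) <- feat_names

    qc <- tibble(qc_blur = runif(n), qc_saturation = runif(n),
                 qc_focus = runif(n))
    if (cfg$corrupt_fraction > 0) {
      bad <- sample(n, round(cfg$corrupt_fraction * n))
      which_col <- sample(3, length(bad), replace = TRUE)
      for (j in seq_along(bad)) {
        qc[[which_col[j]]][bad[j]] <- runif(1, 0.97, 1)
      }
    }
    bind_cols(
      wells[c("source_id", "microscope_id", "plate_id", "well_id",
              "compound_id", "moa_label", "role")],
      as_tibble(x), qc
    )
  })
}

#' Generate a coupled tri-modal benchmark dataset
#'
#' Builds layouts, profiles, per-well rendered images and compound SMILES
#' from one config, with each modality
#' carrying the class signal its config group structure allows. Used by the
#' fusion examples and tests.
#'
#' @param config A [synth_config()].
#' @param fields Fields of view to render per well (capped at
#'   `config$fields_per_well`).
#' @param wells_per_compound Optional cap on replicate wells per compound to
#'   keep image rendering cheap.
#' @return List with `layouts`, `compounds`, `profiles` (treatment wells
#'   only), and `images` (list of [image_stack()], one per rendered field).
#' @export
make_trimodal <- function(config, fields = 1L, wells_per_compound = NULL) {
  gen <- make_layouts(config)
  profiles <- make_profiles(gen$layouts, config)
  trt <- profiles[profiles$role == "treatment", ]
  if (!is.null(wells_per_compound)) {
    trt <- trt %>%
      group_by(.data$compound_id) %>%
      slice(seq_len(min(n(), wells_per_compound))) %>%
      ungroup()
  }
  images <- purrr::map(seq_len(nrow(trt)), function(i) {
    lapply(seq_len(min(fields, config$fields_per_well)), function(f) {
      render_field(gen$layouts[[trt$plate_id[i]]], trt$well_id[i], config,
                   field_index = f)
    })
  })
  images <- purrr::flatten(images)
  list(layouts = gen$layouts, compounds = gen$compounds,
       profiles = trt, images = images)
}
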