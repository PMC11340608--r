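# Shared small synthetic fixtures, built once per test run.

small_cfg <- function(...) {
  defaults <- list(n_sources = 2, plates_per_source = 1, n_classes = 3,
                   compounds_per_class = 3, replicates_range = c(4, 4),
                   image_size = 96, n_features = 30, n_informative = 5,
                   cells_per_field = 25, seed = 11)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# memoised generation keyed by the config hash
.fixture_env <- new.env(parent = emptyenv())
gen_fixture <- function(cfg) {
  key <- paste(deparse(unclass(cfg)), collapse = "")
  key <- as.character(sum(utf8ToInt(key) * seq_along(utf8ToInt(key))))
  if (is.null(.fixture_env[[key]])) {
    gen <- make_layouts(cfg)
    gen$profiles <- make_profiles(gen$layouts, cfg)
    .fixture_env[[key]] <- gen
  }
  .fixture_env[[key]]
}

# An image stack whose DNA channel holds the given values (other channels 0.5)
stack_with_dna <- function(values, plate_id = "P1", well_id = "B02") {
  n <- length(values)
  px <- array(0.5, c(5, 1, n))
  px[1, 1, ] <- values
  image_stack(px, plate_id = plate_id, well_id = well_id,
              source_id = "source_1", microscope_id = "M1")
}

# A minimal one-plate layout with the given control wells
tiny_layout <- function(plate_id = "P1",
                        wells = tibble::tibble(
                          well_id = c("A01", "B02", "C03"),
                          role = c("poscon", "dmso", "treatment"),
                          compound_id = c("Aloxistatin", NA, "CPD001"))) {
  plate_layout(plate_id, "source_1", "M1", wells)
}

# Nearest-centroid ("plain linear") classifier used as an independent oracle
# for class-signal checks on synthetic profiles.
centroid_predict <- function(x_train, y_train, x_test) {
  cents <- sapply(split(seq_len(nrow(x_train)), y_train), function(idx) {
    colMeans(x_train[idx, , drop = FALSE])
  })
  d <- as.matrix(stats::dist(rbind(t(cents), x_test)))
  k <- ncol(cents)
  d <- d[-(1:k), 1:k, drop = FALSE]
  colnames(cents)[max.col(-d, ties.method = "first")]
}
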