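# Internal helpers shared across modules.

# Deterministic 31-bit integer derived from a base seed and a string key, so
# that every plate/well/field gets its own reproducible RNG stream.
string_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647L
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

#' Identify feature columns of a profile table
#'
#' Feature columns are all numeric columns that are neither profile metadata
#' (`source_id`, `plate_id`, `well_id`, `compound_id`, `moa_label`, `role`,
#' `microscope_id`) nor quality-score columns (prefix `qc_`).
#'
#' @param table A profile table (data frame).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table) {
  nm <- names(table)
  cand <- setdiff(nm, PROFILE_METADATA)
  cand <- cand[!startsWith(cand, "qc_")]
  cand[vapply(table[cand], is.numeric, logical(1))]
}

# Extract the feature block as a plain numeric matrix.
feature_matrix <- function(table, features = feature_cols(table)) {
  m <- as.matrix(table[features])
  storage.mode(m) <- "double"
  m
}

assert_profile_table <- function(table, call = rlang::caller_env()) {
  if (!is.data.frame(table)) {
    abort("`table` must be a data frame of well-level profiles.", call = call)
  }
  if (anyDuplicated(names(table))) {
    dup <- unique(names(table)[duplicated(names(table))])
    abort(
      paste0("Duplicate column names in profile table: ",
             paste(dup, collapse = ", ")),
      class = "cvf_schema_error", call = call
    )
  }
  invisible(table)
}

# Column-wise population variance/sd (denominator n), used where pixel or
# control populations are treated as complete populations.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
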