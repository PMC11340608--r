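# Compound structure encoding: SMILES to fixed-length binary Morgan/ECFP
# substructure fingerprints.

#' Convert a SMILES string to a Morgan (ECFP) fingerprint
#'
#' Encodes the circular substructures of a molecule (neighbourhoods up to
#' `radius` bonds around each atom, ECFP`2*radius`) as a hashed binary bit
#' vector. Hashing is delegated to Open Babel's extended-connectivity
#' fingerprint implementation; its native bit vector is folded (bitwise OR of
#' halves) down to `n_bits`. Any valid SMILES spelling of the same molecule
#' yields the same fingerprint.
#'
#' @param smiles A single SMILES string.
#' @param n_bits Fingerprint length (default 2048).
#' @param radius Circular neighbourhood radius in bonds (default 2,
#'   ECFP4-equivalent).
#' @return A `cvf_fingerprint`: integer 0/1 vector of length `n_bits` with
#'   attributes `smiles`, `radius`, `n_bits`.
#' @export
smiles_to_fp <- function(smiles, n_bits = 2048L, radius = 2L) {
  rlang::check_installed("ChemmineOB", reason = "to compute fingerprints")
  stopifnot(length(smiles) == 1, is.character(smiles))
  if (!radius %in% 0:5) {
    abort("`radius` must be an integer in 0..5.", class = "cvf_validation_error")
  }
  mol <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) {
      abort(sprintf("Cannot parse SMILES '%s': %s", smiles, conditionMessage(e)),
            class = "cvf_parse_error")
    }
  )
  fp_name <- sprintf("ECFP%d", 2L * as.integer(radius))
  bits <- tryCatch(
    as.integer(ChemmineOB::fingerprint_OB(mol, fp_name)),
    error = function(e) {
      abort(sprintf("Fingerprinting failed for SMILES '%s': %s", smiles,
                    conditionMessage(e)), class = "cvf_parse_error")
    }
  )
  if (sum(bits) == 0) {
    abort(sprintf("SMILES '%s' produced an empty molecule.", smiles),
          class = "cvf_parse_error")
  }
  while (length(bits) > n_bits) {
    half <- length(bits) / 2
    bits <- as.integer(bits[seq_len(half)] | bits[half + seq_len(half)])
  }
  if (length(bits) != n_bits) {
    abort(sprintf(
      "Native fingerprint length %d cannot be folded to n_bits = %d.",
      length(bits), n_bits), class = "cvf_validation_error")
  }
  structure(bits, smiles = smiles, radius = as.integer(radius),
            n_bits = as.integer(n_bits), class = "cvf_fingerprint")
}

#' Fingerprint a compound table
#'
#' @param compounds Tibble with columns `compound_id` and `smiles`.
#' @inheritParams smiles_to_fp
#' @return Numeric 0/1 matrix with one row per compound (rownames =
#'   `compound_id`) and `n_bits` columns.
#' @export
fingerprint_table <- function(compounds, n_bits = 2048L, radius = 2L) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  m <- t(vapply(compounds$smiles, function(s) {
    as.numeric(smiles_to_fp(s, n_bits = n_bits, radius = radius))
  }, numeric(n_bits)))
  rownames(m) <- compounds$compound_id
  colnames(m) <- sprintf("fp_%04d", seq_len(n_bits))
  m
}
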