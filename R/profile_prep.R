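# Profile-side pipeline: quality-control scoring and filtering, standard
# (pycytominer-style) feature filtering, Shapley-ranked feature selection,
# MAD robustize, min-max normalization, ZCA-cor spherization and outlier
# removal.

#' Quality-control scores and exclusion flags
#'
#' Aggregates the raw blur, saturation and focus quality features (column
#' prefixes configurable; multiple columns per group are averaged), min-max
#' normalizes each group and post-processes: saturation is quantile-mapped to
#' a standard normal `z` and scored as `|tanh(z)|` so both saturation tails
#' score high; focus is inverted (`1 - x`) so high scores mean poor focus;
#' blur is kept as-is. A datapoint is excluded when any score exceeds its
#' group's 90th percentile over the dataset.
#'
#' @param table Profile table containing the quality columns.
#' @param blur,saturation,focus Regular expressions selecting each group's
#'   raw columns.
#' @param percentile Exclusion percentile (default 0.9).
#' @return Tibble with `blur_score`, `saturation_score`, `focus_score` in
#'   `[0, 1]` and logical `excluded`; the per-group thresholds are attached
#'   as attribute `thresholds`.
#' @export
qc_scores <- function(table, blur = "blur", saturation = "saturation",
                      focus = "focus", percentile = 0.9) {
  pick <- function(rx) {
    cols <- grep(rx, names(table), value = TRUE, ignore.case = TRUE)
    if (!length(cols)) {
      abort(sprintf("No quality columns match '%s'.", rx),
            class = "cvf_schema_error")
    }
    rowMeans(as.matrix(table[cols]))
  }
  minmax <- function(x, what) {
    rng <- range(x)
    if (rng[2] <= rng[1]) {
      warn(sprintf("Quality group '%s' has no spread; scores set to 0.", what))
      return(rep(0, length(x)))
    }
    (x - rng[1]) / (rng[2] - rng[1])
  }
  b <- minmax(pick(blur), "blur")
  s <- minmax(pick(saturation), "saturation")
  f <- minmax(pick(focus), "focus")
  # quantile map to a standard normal, then send both tails high
  z <- qnorm((rank(s, ties.method = "average") - 0.5) / length(s))
  s_score <- abs(tanh(z))
  f_score <- 1 - f
  scores <- tibble(blur_score = b, saturation_score = s_score,
                   focus_score = f_score)
  thr <- vapply(scores, quantile, numeric(1), probs = percentile, names = FALSE)
  scores$excluded <- scores$blur_score > thr[1] |
    scores$saturation_score > thr[2] | scores$focus_score > thr[3]
  attr(scores, "thresholds") <- setNames(thr, names(scores)[1:3])
  scores
}

#' Apply QC exclusion to a profile table
#'
#' @param table Profile table with quality columns.
#' @param ... Passed to [qc_scores()].
#' @return The table without excluded rows; the number removed is reported.
#' @export
qc_filter <- function(table, ...) {
  sc <- qc_scores(table, ...)
  inform(sprintf("QC excluded %d of %d well datapoints (%.1f%%).",
                 sum(sc$excluded), nrow(table),
                 100 * mean(sc$excluded)))
  table[!sc$excluded, , drop = FALSE]
}

#' Standard feature filtering (pycytominer-style)
#'
#' Removes, in order: features with any missing values, blocklisted feature
#' names, features with variance below `var_thresh`, and one member of each
#' pair with `|Pearson r| > corr_thresh`. For a violating pair the member
#' with the larger mean absolute correlation to all other features is
#' dropped; ties drop the later column.
#'
#' @param table Profile table.
#' @param var_thresh Variance threshold (features below are dropped).
#' @param corr_thresh Absolute Pearson correlation cutoff.
#' @param blocklist Character vector of feature names known to be unstable or
#'   noisy.
#' @return Character vector of retained feature names, in original order.
#' @export
pycyto_filter <- function(table, var_thresh = 1.0, corr_thresh = 0.9,
                          blocklist = character()) {
  assert_profile_table(table)
  feats <- feature_cols(table)
  x <- feature_matrix(table, feats)
  keep <- feats[colSums(!is.finite(x)) == 0]
  keep <- setdiff(keep, blocklist)
  if (length(keep)) {
    v <- apply(feature_matrix(table, keep), 2, var)
    keep <- keep[v >= var_thresh]
  }
  if (length(keep) > 1) {
    x <- feature_matrix(table, keep)
    cm <- abs(cor(x))
    diag(cm) <- 0
    while (TRUE) {
      mx <- max(cm)
      if (mx <= corr_thresh || !is.finite(mx)) break
      idx <- which(cm == mx, arr.ind = TRUE)[1, ]
      mean_abs <- rowMeans(cm)
      drop <- if (mean_abs[idx[1]] > mean_abs[idx[2]]) idx[1]
              else if (mean_abs[idx[2]] > mean_abs[idx[1]]) idx[2]
              else max(idx)
      keep <- keep[-drop]
      cm <- cm[-drop, -drop, drop = FALSE]
      if (length(keep) < 2) break
    }
  }
  if (!length(keep)) {
    abort("All features removed; relax `var_thresh`/`corr_thresh`.",
          class = "cvf_validation_error")
  }
  keep
}

#' Shapley-value feature ranking with gradient-boosted trees
#'
#' Fits an XGBoost multiclass model on the (training) rows and computes
#' per-sample, per-class feature contributions with the tree-path attribution
#' method (`predcontrib`). Global importance is the mean absolute
#' contribution over samples and classes; a per-class top-10 contribution
#' table is attached for interpretability.
#'
#' @param table Profile table (training rows only — pass the fold's training
#'   subset to avoid information leakage into feature selection).
#' @param labels Factor or character vector of MOA labels, one per row.
#' @param nrounds Boosting rounds.
#' @param max_depth,eta XGBoost tree depth and learning rate.
#' @param seed Integer seed (single-threaded fitting keeps this exact).
#' @return A `cvf_ranking` tibble of `(feature, importance)` in non-increasing
#'   importance order, with the per-class table in `attr(, "per_class")`.
#' @export
shapley_rank <- function(table, labels, nrounds = 50, max_depth = 4,
                         eta = 0.3, seed = 1L) {
  feats <- feature_cols(table)
  x <- feature_matrix(table, feats)
  if (!all(is.finite(x))) {
    abort("Features must be finite for Shapley ranking.",
          class = "cvf_validation_error")
  }
  y <- factor(labels)
  if (nlevels(y) < 2) {
    abort("Shapley ranking needs at least two classes.",
          class = "cvf_validation_error")
  }
  contrib <- withr::with_seed(as.integer(seed), {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = nlevels(y),
                    max_depth = max_depth, eta = eta, nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
    predict(booster, x, predcontrib = TRUE)  # n x class x (p + 1)
  })
  contrib <- contrib[, , seq_along(feats), drop = FALSE]  # drop bias column
  imp <- apply(abs(contrib), 3, mean)
  per_class <- apply(abs(contrib), c(2, 3), mean)
  rownames(per_class) <- levels(y)
  colnames(per_class) <- feats
  ord <- order(imp, decreasing = TRUE)
  out <- tibble(feature = feats[ord], importance = unname(imp[ord]))
  top10 <- purrr::map_dfr(levels(y), function(cl) {
    o <- order(per_class[cl, ], decreasing = TRUE)[1:min(10, length(feats))]
    tibble(moa_label = cl, feature = feats[o],
           contribution = unname(per_class[cl, o]), rank = seq_along(o))
  })
  structure(out, per_class = top10,
            class = c("cvf_ranking", class(out)))
}

#' Select the top-k ranked features
#'
#' @param ranking A `cvf_ranking` from [shapley_rank()].
#' @param k Number of features to keep (default 150, the point where marginal
#'   contribution from further features becomes negligible on datasets of
#'   this kind).
#' @return Character vector of the first `k` feature names.
#' @export
select_top_k <- function(ranking, k = 150) {
  if (k > nrow(ranking)) {
    abort(sprintf("k = %d exceeds ranking length %d.", k, nrow(ranking)),
          class = "cvf_validation_error")
  }
  head(ranking$feature, k)
}

#' MAD-robustize a profile table against plate controls
#'
#' Per plate and feature: subtract the median and divide by the (unscaled)
#' median absolute deviation of the control rows on the same plate, with an
#' `eps` guard so constant control features cannot produce infinities.
#' Metadata columns are untouched and row count is preserved.
#'
#' @param table Profile table.
#' @param control_role Role providing the normalization statistics
#'   (default `"dmso"`).
#' @param eps Guard added to the MAD denominator.
#' @return Robustized profile table.
#' @export
mad_robustize <- function(table, control_role = "dmso", eps = 1e-6) {
  assert_profile_table(table)
  feats <- feature_cols(table)
  out <- table
  for (pl in unique(table$plate_id)) {
    in_plate <- table$plate_id == pl
    ctrl <- table[in_plate & table$role == control_role, feats, drop = FALSE]
    if (!nrow(ctrl)) {
      abort(sprintf("Plate %s has no %s control rows.", pl, control_role),
            class = "cvf_validation_error")
    }
    med <- vapply(ctrl, median, numeric(1))
    md <- vapply(ctrl, mad, numeric(1), constant = 1)
    if (any(md == 0)) {
      warn(sprintf("Plate %s: %d control feature(s) with zero MAD; eps guard used.",
                   pl, sum(md == 0)))
    }
    xm <- feature_matrix(table[in_plate, ], feats)
    xm <- sweep(sweep(xm, 2, med), 2, md + eps, "/")
    out[in_plate, feats] <- as_tibble(xm)
  }
  out
}

#' Min-max normalize a profile table
#'
#' Per feature, maps values to `[0, 1]`; constant features map to 0.
#' Idempotent.
#'
#' @param table Profile table.
#' @return Normalized profile table.
#' @export
minmax_table <- function(table) {
  assert_profile_table(table)
  feats <- feature_cols(table)
  out <- table
  for (f in feats) {
    v <- table[[f]]
    rng <- range(v)
    out[[f]] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
  }
  out
}

#' Fit a ZCA-cor spherizing (whitening) transform
#'
#' Centres on the control mean, scales to unit variance, and whitens the
#' control correlation matrix with the zero-phase (ZCA) rotation, which keeps
#' the transformed profiles as close as possible to the untransformed ones.
#' Eigenvalues are regularized as `eigenvalue + lambda`, so the transform is
#' finite even with fewer controls than features.
#'
#' @param controls Profile table rows (or numeric matrix) of control wells.
#' @param lambda Regularization strength (default `1e-2`).
#' @return A `cvf_spherizer` with fields `center`, `W` (features x features)
#'   and `lambda`.
#' @export
fit_spherizer <- function(controls, lambda = 1e-2) {
  x <- if (is.data.frame(controls)) feature_matrix(controls) else as.matrix(controls)
  if (nrow(x) < 2) {
    abort("Spherizer needs at least two control rows.",
          class = "cvf_validation_error")
  }
  if (lambda <= 0) abort("`lambda` must be > 0.", class = "cvf_validation_error")
  center <- colMeans(x)
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1e-12
  xs <- sweep(sweep(x, 2, center), 2, sds, "/")
  cc <- cor(x)
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  eg <- eigen(cc, symmetric = TRUE)
  vals <- pmax(eg$values, 0) + lambda
  w_cor <- eg$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(eg$vectors)
  W <- diag(1 / sds, length(sds)) %*% w_cor
  structure(list(center = center, W = W, lambda = lambda,
                 features = colnames(x), variant = "zca_cor"),
            class = "cvf_spherizer")
}

#' Apply a spherizing transform to a profile table
#'
#' @param model A `cvf_spherizer` from [fit_spherizer()].
#' @param table Profile table (or numeric matrix) with the model's features.
#' @return Transformed table of the same shape.
#' @export
apply_spherizer <- function(model, table) {
  if (is.data.frame(table)) {
    feats <- model$features %||% feature_cols(table)
    x <- feature_matrix(table, feats)
    z <- sweep(x, 2, model$center) %*% model$W
    out <- table
    out[feats] <- as_tibble(`colnames<-`(z, feats))
    out
  } else {
    sweep(as.matrix(table), 2, model$center) %*% model$W
  }
}

#' Drop out-of-range features, then rows
#'
#' After normalization, features in which more than `feature_frac` of values
#' exceed `thresh` in absolute value are dropped first (a pervasively
#' out-of-range feature should not cost all its rows); then rows with any
#' remaining absolute value above `thresh` are dropped. Counts are reported
#' and attached as attributes.
#'
#' @param table Normalized profile table.
#' @param thresh Absolute-value threshold (default `1e2`).
#' @param feature_frac Fraction of out-of-range values above which the whole
#'   feature is dropped instead of its rows (default 0.01).
#' @return Filtered profile table with attributes `dropped_features` and
#'   `dropped_rows`.
#' @export
drop_outliers <- function(table, thresh = 1e2, feature_frac = 0.01) {
  assert_profile_table(table)
  feats <- feature_cols(table)
  x <- abs(feature_matrix(table, feats))
  bad_feats <- feats[colMeans(x > thresh) > feature_frac]
  keep_feats <- setdiff(feats, bad_feats)
  out <- table[, setdiff(names(table), bad_feats), drop = FALSE]
  bad_rows <- if (length(keep_feats)) {
    apply(abs(feature_matrix(out, keep_feats)), 1, max) > thresh
  } else rep(FALSE, nrow(out))
  out <- out[!bad_rows, , drop = FALSE]
  if (!nrow(out) || !length(keep_feats)) {
    abort("Outlier filtering removed everything; check the threshold.",
          class = "cvf_validation_error")
  }
  inform(sprintf("Dropped %d outlier feature(s) and %d outlier row(s).",
                 length(bad_feats), sum(bad_rows)))
  attr(out, "dropped_features") <- bad_feats
  attr(out, "dropped_rows") <- sum(bad_rows)
  out
}
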