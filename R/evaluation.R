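# Evaluation: compound-level double-stratified cross-validation,
# classification metrics, kBET batch-effect scoring, and the
# average-treatment-effect statistic with strength buckets.

#' Double-stratified compound-level cross-validation splits
#'
#' Compounds (never wells or images) are assigned to folds, so all replicates
#' of a compound live in the same train/validation/test set. Test sets are
#' class-stratified and partition the compounds across the `n_folds` folds,
#' each containing at least one compound of every class; the remaining
#' compounds are split into train and validation with class stratification at
#' the requested ratios.
#'
#' @param compounds Tibble with columns `compound_id`, `moa_label`.
#' @param n_folds Number of folds (default 5).
#' @param ratios Train/validation/test proportions (default 0.7/0.1/0.2).
#' @param seed Integer seed.
#' @return A `cvf_splits` list of folds, each with character vectors `train`,
#'   `val`, `test`.
#' @export
make_splits <- function(compounds, n_folds = 5, ratios = c(0.7, 0.1, 0.2),
                        seed = 1L) {
  cpd <- distinct(as_tibble(compounds[c("compound_id", "moa_label")]))
  counts <- count(cpd, .data$moa_label)
  small <- counts$moa_label[counts$n < n_folds]
  if (length(small)) {
    abort(paste0(
      "Every class needs at least ", n_folds, " compounds; too few in: ",
      paste(small, collapse = ", "), ". Merge or drop these classes."),
      class = "cvf_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    test_fold <- setNames(integer(nrow(cpd)), cpd$compound_id)
    for (cl in unique(cpd$moa_label)) {
      ids <- sample(cpd$compound_id[cpd$moa_label == cl])
      test_fold[ids] <- (seq_along(ids) - 1L) %% n_folds + 1L
    }
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- names(test_fold)[test_fold == f]
      rest <- cpd[!(cpd$compound_id %in% test), ]
      # stratified largest-remainder allocation of the validation quota
      val_frac <- ratios[2] / (ratios[1] + ratios[2])
      n_val_total <- round(val_frac * nrow(rest))
      cls <- unique(rest$moa_label)
      per_cl <- vapply(cls, function(cl) sum(rest$moa_label == cl), numeric(1))
      quota <- floor(val_frac * per_cl)
      remainder <- val_frac * per_cl - quota
      extra <- max(n_val_total - sum(quota), 0)
      if (extra > 0) {
        bump <- order(remainder, decreasing = TRUE)[seq_len(min(extra,
                                                                length(cls)))]
        quota[bump] <- quota[bump] + 1
      }
      val <- character()
      for (i in seq_along(cls)) {
        ids <- sample(rest$compound_id[rest$moa_label == cls[i]])
        val <- c(val, ids[seq_len(min(quota[i], length(ids)))])
      }
      train <- setdiff(rest$compound_id, val)
      list(train = sort(train), val = sort(val), test = sort(test))
    })
    structure(folds, ratios = ratios, seed = as.integer(seed),
              class = "cvf_splits")
  })
}

#' Check a split plan for leakage and coverage
#'
#' @param splits A `cvf_splits`.
#' @param compounds The compound table used to build it.
#' @return Invisibly `TRUE`; aborts on any violated invariant.
#' @export
check_splits <- function(splits, compounds) {
  cpd <- distinct(as_tibble(compounds[c("compound_id", "moa_label")]))
  all_test <- unlist(lapply(splits, `[[`, "test"))
  if (anyDuplicated(all_test) || !setequal(all_test, cpd$compound_id)) {
    abort("Test sets must partition the compounds.",
          class = "cvf_validation_error")
  }
  for (f in seq_along(splits)) {
    s <- splits[[f]]
    if (length(intersect(s$train, s$val)) || length(intersect(s$train, s$test)) ||
        length(intersect(s$val, s$test))) {
      abort(sprintf("Fold %d has overlapping compound sets.", f),
            class = "cvf_leakage_error")
    }
    covered <- unique(cpd$moa_label[cpd$compound_id %in% s$test])
    if (!setequal(covered, unique(cpd$moa_label))) {
      abort(sprintf("Fold %d test set misses class(es).", f),
            class = "cvf_validation_error")
    }
  }
  invisible(TRUE)
}

macro_f1 <- function(calls, truth) {
  lv <- levels(truth)
  f1 <- vapply(lv, function(cl) {
    tp <- sum(calls == cl & truth == cl)
    fp <- sum(calls == cl & truth != cl)
    fn <- sum(calls != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# One-vs-rest ROC AUC via the rank-sum (Mann-Whitney) statistic.
binary_auc <- function(score, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve by step-wise summation over
# descending score thresholds (each positive adds (dRecall * precision)).
binary_aupr <- function(score, pos) {
  if (!any(pos)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  pos <- pos[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  rec <- tp / sum(pos)
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics for compound-level predictions
#'
#' Computes accuracy, macro precision/recall/F1 from the argmax calls, and
#' macro one-vs-rest AUC and AUPR from the probability vectors. Macro
#' aggregates are unweighted class means; every class must appear in the
#' truth.
#'
#' @param preds A compound-level `cvf_predictions` (or tibble with
#'   `compound_id` and `prob_*` columns).
#' @param truth Tibble `compound_id`, `moa_label` (or a vector aligned with
#'   `preds`).
#' @return A `cvf_metrics` list: overall scalars plus a per-class tibble.
#' @export
score_predictions <- function(preds, truth) {
  classes <- attr(preds, "classes") %||%
    sub("^prob_", "", grep("^prob_", names(preds), value = TRUE))
  if (is.data.frame(truth)) {
    m <- match(preds$compound_id, truth$compound_id)
    if (anyNA(m)) {
      abort("Every predicted compound needs a truth label.",
            class = "cvf_validation_error")
    }
    truth <- truth$moa_label[m]
  }
  truth <- factor(truth, levels = classes)
  if (anyNA(truth) || !all(classes %in% truth)) {
    abort("Every class must appear in the truth labels.",
          class = "cvf_validation_error")
  }
  p <- as.matrix(preds[paste0("prob_", classes)])
  colnames(p) <- classes
  calls <- factor(classes[max.col(p, ties.method = "first")],
                  levels = classes)
  per_class <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(calls == cl & truth == cl)
    fp <- sum(calls == cl & truth != cl)
    fn <- sum(calls != cl & truth == cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble(moa_label = cl, n = sum(truth == cl), precision = precision,
           recall = recall, f1 = f1,
           auc = binary_auc(p[, cl], truth == cl),
           aupr = binary_aupr(p[, cl], truth == cl))
  })
  structure(list(
    accuracy = mean(calls == truth),
    precision = mean(per_class$precision),
    recall = mean(per_class$recall),
    macro_f1 = mean(per_class$f1),
    macro_auc = mean(per_class$auc),
    macro_aupr = mean(per_class$aupr),
    per_class = per_class, n = length(truth)
  ), class = "cvf_metrics")
}

#' @export
print.cvf_metrics <- function(x, ...) {
  cat(sprintf(
    "<cvf_metrics> n=%d  accuracy %.3f  macro-F1 %.3f  precision %.3f  recall %.3f  AUC %.3f  AUPR %.3f\n",
    x$n, x$accuracy, x$macro_f1, x$precision, x$recall, x$macro_auc,
    x$macro_aupr))
  invisible(x)
}

#' kBET batch-effect score
#'
#' For every point, compares the batch-label composition of its `k` nearest
#' neighbours (Euclidean, excluding self) with the global batch proportions
#' using a chi-squared test with `n_batches - 1` degrees of freedom. The
#' score is the fraction of points whose neighbourhood is accepted
#' (`p >= alpha`): 1 means batches are perfectly mixed (no detectable batch
#' effect), 0 means every neighbourhood is batch-pure.
#'
#' @param embeddings Numeric matrix, rows = points.
#' @param batch Batch label per row.
#' @param k Neighbourhood size; default `min(25, floor(n / 10))`.
#' @param alpha Significance level (default 0.05).
#' @return Scalar score in `[0, 1]`.
#' @export
kbet <- function(embeddings, batch, k = NULL, alpha = 0.05) {
  x <- as.matrix(embeddings)
  n <- nrow(x)
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) return(1.0)
  k <- k %||% min(25L, floor(n / 10))
  if (k >= n) abort("`k` must be smaller than the number of points.",
                    class = "cvf_validation_error")
  if (k < 1) abort("`k` must be at least 1.", class = "cvf_validation_error")
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  props <- as.numeric(table(batch)) / n
  expected <- k * props
  df <- nlevels(batch) - 1
  pvals <- vapply(seq_len(n), function(i) {
    nb <- batch[order(dm[i, ])[seq_len(k)]]
    obs <- as.numeric(table(nb))
    stat <- sum((obs - expected)^2 / expected)
    pchisq(stat, df = df, lower.tail = FALSE)
  }, numeric(1))
  mean(pvals >= alpha)
}

#' Average treatment effect per well and compound
#'
#' Per plate: a ZCA-cor spherizer (regularization `lambda`) is fitted on the
#' control wells and applied to all wells; the Euclidean distance of each
#' well to the plate's median control profile is z-scored against the mean
#' and (sample) SD of the control distances. A compound's ATE is the mean
#' z-score over its replicate wells across plates; compounds are bucketed
#' into strong (top 20%), medium (middle 20%) and weak (bottom 20%) of the
#' ATE distribution.
#'
#' @param profiles Profile table with control and treatment rows.
#' @param lambda Spherizer regularization (default `1e-2`).
#' @param control_role Role used as controls (default `"dmso"`).
#' @return A `cvf_ate` list with `wells` (per treatment well: `distance`,
#'   `z`) and `compounds` (per compound: `ate`, `bucket`).
#' @export
ate <- function(profiles, lambda = 1e-2, control_role = "dmso") {
  assert_profile_table(profiles)
  feats <- feature_cols(profiles)
  well_rows <- list()
  for (pl in unique(profiles$plate_id)) {
    pp <- profiles[profiles$plate_id == pl, ]
    ctrl <- pp[pp$role == control_role, ]
    if (nrow(ctrl) < 2) {
      abort(sprintf("Plate %s has %d %s control wells; at least 2 required.",
                    pl, nrow(ctrl), control_role),
            class = "cvf_validation_error")
    }
    sph <- fit_spherizer(ctrl, lambda = lambda)
    zc <- apply_spherizer(sph, feature_matrix(ctrl, feats))
    zt_all <- apply_spherizer(sph, feature_matrix(pp, feats))
    med <- apply(zc, 2, median)
    dist_of <- function(m) sqrt(rowSums(sweep(m, 2, med)^2))
    d_ctrl <- dist_of(zc)
    mu_c <- mean(d_ctrl)
    sd_c <- sd(d_ctrl)
    if (sd_c == 0) sd_c <- 1e-12
    trt <- pp$role == "treatment"
    if (any(trt)) {
      d_trt <- dist_of(zt_all[trt, , drop = FALSE])
      well_rows[[pl]] <- tibble(
        plate_id = pl, well_id = pp$well_id[trt],
        compound_id = pp$compound_id[trt], moa_label = pp$moa_label[trt],
        distance = d_trt, z = (d_trt - mu_c) / sd_c
      )
    }
  }
  wells <- bind_rows(well_rows)
  cpd <- wells %>%
    group_by(.data$compound_id) %>%
    summarise(moa_label = .data$moa_label[1], ate = mean(.data$z),
              n_replicates = n(), .groups = "drop") %>%
    arrange(desc(.data$ate), .data$compound_id)
  n <- nrow(cpd)
  q <- (rank(-cpd$ate, ties.method = "first") - 0.5) / n
  cpd$bucket <- case_when(
    q <= 0.2 ~ "strong",
    q > 0.4 & q <= 0.6 ~ "medium",
    q > 0.8 ~ "weak",
    TRUE ~ "unbucketed"
  )
  structure(list(wells = wells, compounds = cpd, lambda = lambda,
                 control_role = control_role),
            class = "cvf_ate")
}

#' Classification accuracy within ATE strength buckets
#'
#' @param preds Compound-level `cvf_predictions`.
#' @param ate_result A `cvf_ate`.
#' @param truth Optional truth table `compound_id`, `moa_label`; defaults to
#'   the labels recorded in the ATE result.
#' @return Tibble `bucket`, `n`, `accuracy` (buckets with no compounds are
#'   absent), plus an `overall` row.
#' @export
accuracy_by_bucket <- function(preds, ate_result, truth = NULL) {
  calls <- prediction_calls(preds)
  truth <- truth %||% ate_result$compounds[c("compound_id", "moa_label")]
  df <- calls %>%
    left_join(truth, by = "compound_id") %>%
    left_join(ate_result$compounds[c("compound_id", "bucket")],
              by = "compound_id") %>%
    filter(!is.na(.data$bucket))
  per <- df %>%
    group_by(.data$bucket) %>%
    summarise(n = n(), accuracy = mean(.data$call == .data$moa_label),
              .groups = "drop")
  bind_rows(per, tibble(bucket = "overall", n = nrow(df),
                        accuracy = mean(df$call == df$moa_label)))
}
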