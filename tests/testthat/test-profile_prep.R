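test_that("QC scoring excludes above-90th-percentile datapoints on any score", {
  withr::with_seed(8, {
    tab <- tibble::tibble(qc_blur = runif(200), qc_saturation = runif(200),
                          qc_focus = runif(200))
  })
  sc <- qc_scores(tab)
  expect_true(all(vapply(sc[1:3], function(x) all(x >= 0 & x <= 1),
                         logical(1))))
  thr <- attr(sc, "thresholds")
  # any-of rule
  manual <- sc$blur_score > thr[1] | sc$saturation_score > thr[2] |
    sc$focus_score > thr[3]
  expect_identical(sc$excluded, manual)
  # a datapoint below all thresholds is retained
  ok <- which(sc$blur_score < thr[1] & sc$saturation_score < thr[2] &
                sc$focus_score < thr[3])[1]
  expect_false(sc$excluded[ok])
  # saturation scoring sends both tails high
  expect_gt(sc$saturation_score[which.max(tab$qc_saturation)], 0.9)
  expect_gt(sc$saturation_score[which.min(tab$qc_saturation)], 0.9)
  # focus is inverted: the worst raw focus value scores lowest
  expect_lt(sc$focus_score[which.max(tab$qc_focus)], 0.05)
  # constant group scores zero with a warning
  tab$qc_blur <- 1
  expect_warning(qc_scores(tab), "no spread")
})

test_that("independent uniform scores are excluded at close to the 1 - 0.9^3 rate", {
  withr::with_seed(99, {
    tab <- tibble::tibble(qc_blur = runif(10000),
                          qc_saturation = runif(10000),
                          qc_focus = runif(10000))
  })
  sc <- qc_scores(tab)
  expect_lt(abs(mean(sc$excluded) - (1 - 0.9^3)), 0.015)
})

test_that("standard feature filtering removes NA, blocklist, low-variance and correlated features", {
  withr::with_seed(4, {
    base <- matrix(rnorm(60 * 15, sd = 2), 60)
    colnames(base) <- sprintf("f%02d", 1:15)
    tab <- tibble::as_tibble(base)
    tab$f16 <- tab$f01            # three planted duplicates
    tab$f17 <- tab$f02
    tab$f18 <- tab$f03
    tab$f19 <- NA_real_           # two NaN-bearing columns
    tab$f20 <- c(NaN, rnorm(59))
    tab$role <- "treatment"
    tab$plate_id <- "P1"
  })
  keep <- pycyto_filter(tab, var_thresh = 0.5)
  expect_equal(length(keep), 15)
  expect_false(any(c("f19", "f20") %in% keep))
  # exactly one member of each duplicated pair survives
  expect_equal(sum(c("f01", "f16") %in% keep), 1)

  # constant column removed by the variance threshold
  tab$f21 <- 1
  expect_false("f21" %in% pycyto_filter(tab, var_thresh = 0.5))

  # row order does not change the result
  keep2 <- pycyto_filter(tab[sample(nrow(tab)), ], var_thresh = 0.5)
  expect_setequal(keep2, pycyto_filter(tab, var_thresh = 0.5))

  expect_error(pycyto_filter(tab, var_thresh = 1e9),
               class = "cvf_validation_error")
})

test_that("Shapley ranking recovers a planted signal feature and is seed-stable", {
  withr::with_seed(10, {
    n <- 500
    y <- sample(c("A", "B", "C"), n, replace = TRUE)
    x <- matrix(rnorm(n * 500, sd = 1), n)
    colnames(x) <- sprintf("f%03d", 1:500)
    x[, 1] <- as.integer(factor(y)) + rnorm(n, sd = 0.1)
    tab <- tibble::as_tibble(x)
  })
  rk <- shapley_rank(tab, y, nrounds = 30, seed = 3)
  expect_identical(rk$feature[1], "f001")
  expect_true(all(diff(rk$importance) <= 0))
  rk2 <- shapley_rank(tab, y, nrounds = 30, seed = 3)
  expect_identical(rk$feature, rk2$feature)
  expect_equal(rk$importance, rk2$importance)
  # per-class table mirrors the top-10 interpretability view
  pc <- tidy(rk, per_class = TRUE)
  expect_setequal(unique(pc$moa_label), c("A", "B", "C"))
  expect_equal(max(pc$rank), 10)

  expect_error(shapley_rank(tab, rep("A", nrow(tab))),
               class = "cvf_validation_error")
  tab$f002[1] <- Inf
  expect_error(shapley_rank(tab, y), class = "cvf_validation_error")
})

test_that("pure-noise features yield no dominant importance", {
  counts <- vapply(1:3, function(s) {
    withr::with_seed(100 + s, {
      x <- matrix(rnorm(150 * 60), 150)
      colnames(x) <- sprintf("f%02d", 1:60)
      y <- sample(c("A", "B"), 150, replace = TRUE)
    })
    rk <- shapley_rank(tibble::as_tibble(x), y, nrounds = 20, seed = s)
    rk$importance[1] / max(median(rk$importance), 1e-12)
  }, numeric(1))
  expect_lt(mean(counts), 10)
})

test_that("select_top_k returns ordered prefixes and validates k", {
  rk <- structure(tibble::tibble(feature = sprintf("f%d", 1:40),
                                 importance = seq(40, 1)),
                  class = c("cvf_ranking", "tbl_df", "tbl", "data.frame"))
  expect_equal(select_top_k(rk, 5), sprintf("f%d", 1:5))
  expect_equal(select_top_k(rk, 0), character(0))
  expect_equal(length(select_top_k(rk, 40)), 40)
  expect_error(select_top_k(rk, 41), class = "cvf_validation_error")
})

test_that("MAD robustize centres on plate controls with the eps guard", {
  tab <- tibble::tibble(
    plate_id = "P1",
    role = c("dmso", "dmso", "dmso", "treatment"),
    feat_a = c(1, 2, 3, 5),
    feat_b = c(4, 4, 4, 9))
  expect_warning(out <- mad_robustize(tab), "zero MAD")
  expect_equal(out$feat_a[4], 3, tolerance = 1e-5)   # (5 - 2) / 1
  expect_true(all(is.finite(out$feat_b)))
  expect_equal(nrow(out), nrow(tab))
  expect_error(mad_robustize(tibble::tibble(plate_id = "P", role = "treatment",
                                            f = 1)),
               class = "cvf_validation_error")

  # transformed controls have median zero per plate and feature
  cfg <- small_cfg()
  gen <- gen_fixture(cfg)
  mr <- mad_robustize(gen$profiles)
  for (pl in unique(mr$plate_id)) {
    ctrl <- mr[mr$plate_id == pl & mr$role == "dmso", ]
    meds <- vapply(ctrl[feature_cols(ctrl)], median, numeric(1))
    expect_lt(max(abs(meds)), 1e-8)
  }
})

test_that("min-max table normalization maps features to [0,1] and is idempotent", {
  tab <- tibble::tibble(role = "treatment", f1 = c(2, 4, 6), f2 = c(7, 7, 7))
  out <- minmax_table(tab)
  expect_equal(out$f1, c(0, 0.5, 1))
  expect_equal(out$f2, c(0, 0, 0))
  expect_identical(minmax_table(out), out)
})

test_that("ZCA-cor spherization whitens control correlations", {
  withr::with_seed(12, {
    z <- rnorm(300)
    x <- cbind(a = z + rnorm(300, sd = 0.3), b = z + rnorm(300, sd = 0.3))
  })
  expect_gt(abs(cor(x)[1, 2]), 0.8)
  sph <- fit_spherizer(x, lambda = 1e-6)
  w <- apply_spherizer(sph, x)
  expect_lt(abs(cor(w)[1, 2]), 0.05)
  expect_lt(max(abs(colMeans(w))), 1e-8)

  # already-white controls: transform reduces to centring and scaling
  withr::with_seed(13, xw <- matrix(rnorm(4000), 1000, 4))
  sphw <- fit_spherizer(xw, lambda = 1e-9)
  off <- sphw$W - diag(diag(sphw$W))
  expect_lt(max(abs(off)), 0.1 * min(abs(diag(sphw$W))))

  # fewer controls than features still yields a finite transform
  withr::with_seed(14, xs <- matrix(rnorm(10 * 50), 10, 50))
  sph_reg <- fit_spherizer(xs, lambda = 1e-2)
  out <- apply_spherizer(sph_reg, xs)
  expect_true(all(is.finite(out)))
  expect_error(fit_spherizer(xs[1, , drop = FALSE]),
               class = "cvf_validation_error")
})

test_that("outlier dropping removes pervasive features first, then isolated rows", {
  n <- 100
  tab <- tibble::tibble(
    plate_id = "P1", role = "treatment",
    f1 = c(rep(1e5, 30), rnorm(n - 30)),   # pervasively bad feature
    f2 = rnorm(n),
    f3 = c(150, rnorm(n - 1)),             # one isolated bad row each
    f4 = c(rnorm(1), -200, rnorm(n - 2)))
  expect_message(out <- drop_outliers(tab, thresh = 1e2), "1 outlier feature")
  expect_false("f1" %in% names(out))
  expect_true("f3" %in% names(out))
  expect_equal(nrow(out), n - 2)
  expect_equal(attr(out, "dropped_rows"), 2)
  expect_identical(attr(out, "dropped_features"), "f1")

  clean <- tibble::tibble(role = "treatment", f1 = c(1, 2), f2 = c(-99, 99))
  expect_message(out2 <- drop_outliers(clean), "0 outlier feature")
  expect_equal(as.data.frame(out2), as.data.frame(clean), ignore_attr = TRUE)

  allbad <- tibble::tibble(role = "treatment", f1 = rep(1e9, 5))
  expect_error(suppressMessages(drop_outliers(allbad)),
               class = "cvf_validation_error")
})
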