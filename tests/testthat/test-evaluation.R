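test_that("split plans are stratified, leakage-free and deterministic", {
  cpd <- tibble::tibble(
    compound_id = sprintf("c%02d", 1:50),
    moa_label = rep(sprintf("M%02d", 1:10), each = 5))
  sp <- make_splits(cpd, seed = 1)
  expect_silent(check_splits(sp, cpd))
  # 10 classes x 5 compounds: each test fold holds exactly 1 per class
  for (f in sp) {
    expect_equal(length(f$test), 10)
    expect_equal(sort(unique(cpd$moa_label[cpd$compound_id %in% f$test])),
                 sprintf("M%02d", 1:10))
    # any compound appears in exactly one of the three sets
    for (id in cpd$compound_id) {
      expect_equal(sum(id %in% f$train, id %in% f$val, id %in% f$test), 1)
    }
  }
  expect_identical(make_splits(cpd, seed = 1), sp)
  expect_false(identical(make_splits(cpd, seed = 2), sp))
  # ratios are respected approximately on the non-test compounds
  expect_equal(length(sp[[1]]$val) / 40, 0.125, tolerance = 0.06)

  few <- cpd[cpd$compound_id %in% sprintf("c%02d", c(1:4, 6:50)), ]
  expect_error(make_splits(few), class = "cvf_validation_error")
})

test_that("classification metrics match hand-computed values", {
  perfect <- diag(4)[c(1, 2, 3, 4), ]
  colnames(perfect) <- sprintf("M%d", 1:4)
  ps <- prediction_set(perfect, "compound",
                       compound_id = sprintf("c%d", 1:4))
  truth <- tibble::tibble(compound_id = sprintf("c%d", 1:4),
                          moa_label = sprintf("M%d", 1:4))
  m <- score_predictions(ps, truth)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$macro_auc, 1)
  expect_equal(m$macro_aupr, 1)

  # truth (A,A,B,B) with calls (A,B,B,B): accuracy 3/4, macro F1 = 11/15
  p2 <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.3, 0.7), c(0.1, 0.9))
  colnames(p2) <- c("A", "B")
  ps2 <- prediction_set(p2, "compound", compound_id = sprintf("c%d", 1:4))
  t2 <- tibble::tibble(compound_id = sprintf("c%d", 1:4),
                       moa_label = c("A", "A", "B", "B"))
  m2 <- score_predictions(ps2, t2)
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$macro_f1, mean(c(2 / 3, 0.8)))
  g <- glance(m2)
  expect_equal(g$accuracy, 0.75)
  expect_equal(nrow(tidy(m2)), 2)

  # a class absent from the truth is an error
  t3 <- t2
  t3$moa_label <- "A"
  expect_error(score_predictions(ps2, t3), class = "cvf_validation_error")
})

test_that("one-vs-rest AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(20, {
    n <- 120
    score <- runif(n)
    pos <- rbinom(n, 1, plogis(4 * (score - 0.5))) == 1
  })
  ours <- asNamespace("cvfusion")$binary_auc(score, pos)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(pos, score,
                                                         quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("uniform random probabilities give chance-level macro AUC", {
  withr::with_seed(21, {
    n <- 400
    p <- matrix(runif(n * 4), n)
    p <- p / rowSums(p)
    colnames(p) <- sprintf("M%d", 1:4)
    truth <- sample(sprintf("M%d", 1:4), n, replace = TRUE)
  })
  ps <- prediction_set(p, "compound", compound_id = sprintf("c%d", 1:n))
  m <- score_predictions(ps, truth)
  expect_lt(abs(m$macro_auc - 0.5), 0.06)
})

test_that("kBET separates batch-pure data from well-mixed data", {
  expect_equal(kbet(matrix(rnorm(100), 50), rep("a", 50)), 1.0)

  withr::with_seed(30, {
    sep <- rbind(matrix(rnorm(200 * 2, mean = 0), ncol = 2),
                 matrix(rnorm(200 * 2, mean = 30), ncol = 2))
    batch_sep <- rep(c("b1", "b2"), each = 200)
  })
  expect_lt(kbet(sep, batch_sep, k = 25), 0.05)

  withr::with_seed(31, {
    null <- matrix(rnorm(1000 * 5), 1000)
    batch_null <- sample(c("b1", "b2"), 1000, replace = TRUE)
  })
  s_null <- kbet(null, batch_null, k = 25)
  expect_lt(abs(s_null - 0.95), 0.05)

  # invariance to batch-label permutation and orthogonal rotation
  relab <- ifelse(batch_null == "b1", "x2", "x1")
  expect_equal(kbet(null, relab, k = 25), s_null)
  withr::with_seed(32, q <- qr.Q(qr(matrix(rnorm(25), 5))))
  expect_equal(kbet(null %*% q, batch_null, k = 25), s_null, tolerance = 1e-12)

  expect_error(kbet(matrix(rnorm(20), 10), rep(c("a", "b"), 5), k = 10),
               class = "cvf_validation_error")
})

test_that("ATE distances and z-scores follow the plate-control geometry", {
  # two controls: their mean maps to the transformed median, so a treatment
  # equal to the control mean has distance zero
  withr::with_seed(40, {
    ctrl <- matrix(rnorm(2 * 4), 2)
    tab <- tibble::tibble(
      plate_id = "P1",
      well_id = sprintf("w%d", 1:3),
      compound_id = c(NA, NA, "cpd1"),
      moa_label = NA_character_,
      role = c("dmso", "dmso", "treatment"))
    feats <- as.data.frame(rbind(ctrl, colMeans(ctrl)))
    names(feats) <- sprintf("f%d", 1:4)
    tab <- dplyr::bind_cols(tab, feats)
  })
  res <- ate(tab, lambda = 1e-2)
  expect_equal(res$wells$distance, 0, tolerance = 1e-8)

  # control z-scores have mean zero per plate by construction
  cfg <- small_cfg()
  gen <- gen_fixture(cfg)
  prof <- gen$profiles
  sph_check <- lapply(unique(prof$plate_id), function(pl) {
    pp <- prof[prof$plate_id == pl, ]
    ctrl <- pp[pp$role == "dmso", ]
    sph <- fit_spherizer(ctrl, lambda = 1e-2)
    zc <- apply_spherizer(sph, as.matrix(ctrl[feature_cols(ctrl)]))
    med <- apply(zc, 2, median)
    d <- sqrt(rowSums(sweep(zc, 2, med)^2))
    (d - mean(d)) / sd(d)
  })
  for (z in sph_check) expect_lt(abs(mean(z)), 1e-10)

  expect_error(ate(tab[-1, ]), class = "cvf_validation_error")
})

test_that("planted effect-size gradient orders compounds into the right buckets", {
  withr::with_seed(41, {
    n_cpd <- 10
    n_feat <- 8
    rows <- list()
    for (pl in c("P1", "P2")) {
      ctrl <- matrix(rnorm(12 * n_feat, sd = 1), 12)
      for (i in seq_len(12)) {
        rows[[length(rows) + 1]] <- c(plate_id = pl,
                                      well_id = sprintf("%s_c%d", pl, i),
                                      compound_id = NA, moa_label = NA,
                                      role = "dmso", ctrl[i, ])
      }
      for (k in seq_len(n_cpd)) {
        for (r in 1:2) {
          x <- rnorm(n_feat, mean = 0.9 * k, sd = 0.5)
          rows[[length(rows) + 1]] <- c(plate_id = pl,
                                        well_id = sprintf("%s_t%d_%d", pl, k, r),
                                        compound_id = sprintf("cpd%02d", k),
                                        moa_label = "M", role = "treatment", x)
        }
      }
    }
    tab <- tibble::as_tibble(do.call(rbind, rows),
                            .name_repair = "minimal")
    names(tab) <- c("plate_id", "well_id", "compound_id", "moa_label", "role",
                    sprintf("f%d", seq_len(n_feat)))
    tab <- dplyr::mutate(tab, dplyr::across(dplyr::starts_with("f"),
                                            as.numeric))
  })
  res <- ate(tab)
  cpd <- res$compounds
  expect_setequal(cpd$compound_id[cpd$bucket == "strong"],
                  c("cpd10", "cpd09"))
  expect_setequal(cpd$compound_id[cpd$bucket == "weak"],
                  c("cpd01", "cpd02"))
  expect_equal(glance(res)$n_strong, 2)
})

test_that("bucket accuracies reflect prediction quality per bucket", {
  classes <- c("M1", "M2")
  cpd_ids <- sprintf("cpd%02d", 1:10)
  truth <- tibble::tibble(compound_id = cpd_ids,
                          moa_label = rep(classes, 5))
  fake_ate <- structure(list(compounds = tibble::tibble(
    compound_id = cpd_ids,
    moa_label = truth$moa_label,
    ate = 10:1,
    bucket = c("strong", "strong", "unbucketed", "unbucketed", "medium",
               "medium", "unbucketed", "unbucketed", "weak", "weak"))),
    class = "cvf_ate")
  # all correct -> every bucket 1.0
  p_good <- diag(2)[match(truth$moa_label, classes), ]
  colnames(p_good) <- classes
  ps_good <- prediction_set(p_good, "compound", compound_id = cpd_ids)
  acc <- accuracy_by_bucket(ps_good, fake_ate, truth)
  expect_true(all(acc$accuracy == 1))

  # wrong calls only in the weak bucket -> weak 0, strong 1
  p_mix <- p_good
  p_mix[9:10, ] <- p_good[c(10, 9), ]
  ps_mix <- prediction_set(p_mix, "compound", compound_id = cpd_ids)
  acc2 <- accuracy_by_bucket(ps_mix, fake_ate, truth)
  expect_equal(acc2$accuracy[acc2$bucket == "strong"], 1)
  expect_equal(acc2$accuracy[acc2$bucket == "weak"], 0)
  expect_gt(acc2$accuracy[acc2$bucket == "strong"],
            acc2$accuracy[acc2$bucket == "weak"])
})
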