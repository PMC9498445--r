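test_that("rank-statistic AUC handles separation, ties, and mixed cases", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(roc_auc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  withr::with_seed(71, {
    for (rep in 1:5) {
      sc <- rnorm(60)
      lab <- rbinom(60, 1, 0.4)
      if (sum(lab) %in% c(0, 60)) next
      want <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                             direction = "<")))
      expect_equal(roc_auc(sc, lab), want)
      expect_equal(roc_auc(exp(2 * sc) + 5, lab), roc_auc(sc, lab))
    }
  })
})

test_that("confusion metrics reproduce the hand-computed 2x2 table", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.6, 0.2, 0.15, 0.1, 0.05)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)   # TP=3 FN=2 FP=1 TN=4 at 0.5
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["sensitivity"]), 0.6)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["mcc"]), 10 / sqrt(4 * 5 * 5 * 6))

  p <- confusion_metrics(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0), 0.1)
  expect_equal(unname(p["sensitivity"]), 1)
  expect_equal(unname(p["specificity"]), 0)
  expect_equal(unname(p["mcc"]), 0)   # degenerate-denominator convention

  perfect <- confusion_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(perfect), c(1, 1, 1, 1))
})

test_that("Youden threshold selection matches an exhaustive sweep", {
  expect_equal(choose_threshold(c(0.9, 0.1), c(1, 0)), 0.9)
  expect_equal(choose_threshold(c(0.3, 0.3, 0.3), c(1, 0, 1)), 0.3)
  withr::with_seed(73, {
    for (rep in 1:10) {
      sc <- round(runif(12), 2)
      lab <- rbinom(12, 1, 0.5)
      if (sum(lab) %in% c(0, 12)) next
      cand <- sort(unique(sc))
      J <- vapply(cand, function(t) {
        tab <- table(factor(sc >= t, c(FALSE, TRUE)),
                     factor(lab, c(0, 1)))
        tab["TRUE", "1"] / sum(lab) + tab["FALSE", "0"] / sum(1 - lab) - 1
      }, numeric(1))
      expect_equal(choose_threshold(sc, lab), max(cand[J == max(J)]))
    }
  })
})

test_that("unity normalization maps each row onto [0, 1] endpoints", {
  X <- rbind(c(2, 4, 6), c(-1, 0, 3))
  N <- normalize_scores(X)
  expect_equal(N[1, ], c(0, 0.5, 1))
  expect_equal(N[2, ], c(0, 0.25, 1))
  expect_warning(Nc <- normalize_scores(rbind(c(1, 1, 1), c(0, 1, 2))),
                 "constant")
  expect_equal(Nc[1, ], c(0.5, 0.5, 0.5))
  withr::with_seed(79, {
    M <- matrix(rnorm(40), 5, 8)
    Nm <- normalize_scores(M)
    expect_equal(unname(apply(Nm, 1, min)), rep(0, 5))
    expect_equal(unname(apply(Nm, 1, max)), rep(1, 5))
  })
})

test_that("quartile classes follow the interpolated-quantile boundaries", {
  x <- as.numeric(1:100)
  cls <- quantile_classify(x)
  # independent enumeration against the interpolated quartiles
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  expect_equal(sum(cls == "Weak"), sum(x < q[1]))
  expect_equal(sum(cls == "Strong"), sum(x > q[2]))
  expect_equal(sum(cls == "Moderate"), sum(x >= q[1] & x <= q[2]))
  expect_equal(as.integer(table(cls)[c("Weak", "Moderate", "Strong")]),
               c(25L, 50L, 25L))
  expect_true(all(quantile_classify(rep(0.3, 10)) == "Moderate"))
  withr::with_seed(83, {
    y <- runif(50)
    expect_equal(quantile_classify(y)[which.max(y)], "Strong")
  })
  expect_error(quantile_classify(c(1, 2, 3)), "at least 4")
})

test_that("normalize-then-classify is invariant to positive row-affine maps", {
  withr::with_seed(89, {
    X <- matrix(rnorm(48), 6, 8)
    slopes <- runif(6, 0.5, 3)
    shifts <- rnorm(6)
  })
  X2 <- X * slopes + shifts
  n1 <- normalize_scores(X)
  n2 <- normalize_scores(X2)
  expect_equal(n1, n2)
  expect_equal(quantile_classify(as.vector(n1)),
               quantile_classify(as.vector(n2)))
})

test_that("a masked positive scores identically to a never-labeled cell", {
  pos <- cbind(c(1L, 2L, 3L, 1L), c(1L, 2L, 3L, 4L))
  dsA <- tiny_dataset(4L, 6L, positives = pos)
  cfg <- mirkron_config(negative_ratio = 1)
  repA <- loocv(dsA, cfg, seed = 5)
  rec <- repA$records
  masked <- rec$score[rec$mirna_id == "m01" & rec$site_id == "t01"]

  YB <- dsA$interactions
  YB["m01", "t01"] <- 0
  dsB <- mirna_dataset(dsA$mirnas, dsA$sites, YB)
  fkB <- feature_kernels(dsB, cfg)
  kB <- assemble_kernels(fkB, YB, cfg)
  never <- predict_scores(kron_rls_fit(kB$Sm, kB$St, YB,
                                       cfg$lambda))["m01", "t01"]
  expect_identical(masked, unname(never))
})

test_that("leave-one-out refuses datasets without positives", {
  ds <- tiny_dataset(3L, 3L, positives = cbind(1L, 1L))
  ds$interactions["m01", "t01"] <- 0
  expect_error(loocv(ds), "no positive")
})

test_that("leave-sites-out holds out the ceiling fraction, reproducibly", {
  pos <- cbind(c(1L, 1L, 2L, 3L), c(1L, 2L, 3L, 4L))
  ds <- tiny_dataset(3L, 4L, positives = pos)
  cfg <- mirkron_config(iterations = 3L)
  r1 <- lmitocv(ds, cfg, fraction = 0.5, seed = 9)
  r2 <- lmitocv(ds, cfg, fraction = 0.5, seed = 9)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$metrics, r2$metrics)
  held_per_iter <- tapply(r1$records$site_id, r1$records$fold,
                          function(x) length(unique(x)))
  expect_true(all(held_per_iter == 2L))  # ceiling(0.5 * 4)
  expect_error(lmitocv(ds, cfg, fraction = 0.1), "below 1")
  expect_error(lmitocv(ds, cfg, fraction = 1.2), "fraction")
})

test_that("reports carry normalized scores, classes and bounds", {
  spec <- synthetic_spec(n_families = 2L, mirnas_per_family = 5L,
                         sites_per_family = 8L, seed = 3L)
  ds <- generate_dataset(spec)
  cfg <- mirkron_config(negative_ratio = 2)
  rep <- loocv(ds, cfg, seed = 2)
  expect_s3_class(rep, "prediction_report")
  expect_true(all(rep$records$normalized >= 0 & rep$records$normalized <= 1))
  expect_true(all(rep$records$class %in% c("Weak", "Moderate", "Strong")))
  expect_equal(nrow(rep$bounds), nrow(ds$mirnas))
  expect_true(is.finite(rep$metrics$auc))
  f <- withr::local_tempfile()
  write_report(rep, f)
  expect_true(file.exists(paste0(f, ".tsv")))
  expect_true(file.exists(paste0(f, "_metrics.json")))
})
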