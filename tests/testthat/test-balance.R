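test_that("make_folds stratifies within one sample per class", {
  lab <- rep(c("benign", "malignant"), each = 10)
  plan <- make_folds(lab, 10, seed = 1)
  tab <- table(plan$assignments, lab)
  expect_true(all(tab == 1))

  # the archive's class sizes: 616 benign / 281 malignant over 10 folds
  lab2 <- rep(c("benign", "malignant"), c(616, 281))
  plan2 <- make_folds(lab2, 10, seed = 2)
  tab2 <- table(plan2$assignments, lab2)
  expect_true(all(tab2[, "benign"] %in% 61:62))
  expect_true(all(tab2[, "malignant"] %in% 28:29))
  expect_true(all(rowSums(tab2) %in% 89:91))

  expect_identical(make_folds(lab2, 10, seed = 7)$assignments,
                   make_folds(lab2, 10, seed = 7)$assignments)
  expect_error(make_folds(rep(c("a", "b"), c(50, 5)), 10), "fewer than")
})

test_that("smote generates the class-size gap exactly, on minority segments", {
  set.seed(3)
  minority <- matrix(rnorm(252 * 6), 252, 6)
  syn <- smote_oversample(minority, 550L, smote_config(5, seed = 4))
  expect_identical(nrow(syn), 298L)  # 550 - 252
  expect_identical(ncol(syn), 6L)

  balanced <- smote_oversample(minority, 252L, smote_config(5, seed = 4))
  expect_identical(nrow(balanced), 0L)

  expect_error(smote_oversample(minority[1:4, ], 10L, smote_config(5)),
               "smaller k")

  # brute-force: every synthetic point lies on a segment between a real
  # minority point and one of its 5 nearest minority neighbors
  mino <- matrix(rnorm(12 * 3), 12, 3)
  syn2 <- smote_oversample(mino, 30L, smote_config(5, seed = 9))
  dd <- as.matrix(dist(mino)); diag(dd) <- Inf
  on_segment <- function(p) {
    for (i in seq_len(nrow(mino))) {
      nn <- order(dd[i, ])[1:5]
      for (j in nn) {
        v <- mino[j, ] - mino[i, ]
        u <- sum((p - mino[i, ]) * v) / sum(v * v)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((p - mino[i, ] - u * v)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(apply(syn2, 1, on_segment)))
})

test_that("metric formulas reproduce hand-computed contingency values", {
  rep1 <- compute_metrics(contingency_counts(3, 1, 2, 4))
  expect_equal(rep1$precision, 0.75)
  expect_equal(rep1$recall, 0.60)
  expect_equal(rep1$accuracy, 0.70)
  expect_equal(rep1$f1, 2 * 0.75 * 0.6 / 1.35)

  perfect <- compute_metrics(contingency_counts(5, 0, 0, 7))
  expect_equal(unlist(perfect[c("recall", "precision", "accuracy", "f1")]),
               c(recall = 1, precision = 1, accuracy = 1, f1 = 1))

  suppressWarnings(zero <- compute_metrics(contingency_counts(0, 2, 3, 5)))
  expect_equal(zero$precision, 0)
  expect_equal(zero$recall, 0)
  expect_equal(zero$f1, 0)

  expect_error(contingency_counts(-1, 0, 0, 1), "non-negative")
})

test_that("metric identities hold on random contingency tables", {
  set.seed(10)
  for (rep in 1:20) {
    ct <- contingency_counts(sample(1:50, 1), sample(1:50, 1),
                             sample(1:50, 1), sample(1:50, 1))
    r <- compute_metrics(ct)
    # F1 is the harmonic mean of precision and recall
    expect_equal(r$f1, 2 / (1 / r$precision + 1 / r$recall), tolerance = 1e-12)
    # accuracy is the prevalence-weighted mix of sensitivity and specificity
    npos <- ct$TP + ct$FN; nneg <- ct$TN + ct$FP
    spec <- ct$TN / nneg
    expect_equal(r$accuracy,
                 (npos * r$recall + nneg * spec) / (npos + nneg),
                 tolerance = 1e-12)
    expect_true(all(unlist(r[c("recall", "precision", "accuracy", "f1")]) >= 0))
    expect_true(all(unlist(r[c("recall", "precision", "accuracy", "f1")]) <= 1))
  }
})

test_that("cross_validate keeps synthetic samples out of test folds", {
  td <- tiny_dataset()
  smp <- td$samples
  # imbalanced subset so SMOTE actually fires: 8 benign, 6 malignant
  sub <- smp[c(1:8, 9:14)]
  lab <- vapply(sub, `[[`, character(1), "label")
  plan <- make_folds(lab, 2, seed = 5)
  cfg <- unet_config(depth = 2, base_filters = 4, epochs = 2,
                     batch_size = 4, lr = 3e-3, seed = 5)
  res <- suppressWarnings(
    cross_validate(sub, cfg, plan, smote_config(3, seed = 5)))
  expect_length(res$per_fold, 2)
  # each training fold was balanced by exactly the class gap
  tab <- table(lab, plan$assignments)
  for (f in 1:2)
    expect_identical(res$n_synthetic[f],
                     as.integer(abs(diff(tab[, -f]))))
  # determinism end to end
  res2 <- suppressWarnings(
    cross_validate(sub, cfg, plan, smote_config(3, seed = 5)))
  expect_identical(res$pooled$accuracy, res2$pooled$accuracy)
  expect_identical(res$auc, res2$auc)
  # a run must start from real samples only
  fake <- sub
  fake[[1]]$is_synthetic <- TRUE
  expect_error(cross_validate(fake, cfg, plan, NULL), "real samples")
})
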