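#' Stratified cross-validation folds
#'
#' Partitions samples into `n_folds` folds preserving class proportions:
#' within each class the (seeded) shuffled members are dealt round-robin
#' starting at a random fold, so per-fold class counts differ by at most
#' one sample from exact proportionality.
#'
#' @param labels character or factor vector of per-sample classes.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed; the same seed always yields the same plan.
#' @return an object of class `fold_plan`: `n_folds`, `assignments`
#'   (integer fold id per sample), `seed`.
#' @export
make_folds <- function(labels, n_folds = 10L, seed = 0L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < n_folds))
    stopf("class '%s' has %d members, fewer than %d folds",
          names(tab)[which.min(tab)], min(tab), n_folds)
  assignments <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      start <- sample.int(n_folds, 1L)
      assignments[idx] <- ((seq_along(idx) + start - 2L) %% n_folds) + 1L
    }
  })
  structure(list(n_folds = n_folds, assignments = assignments,
                 seed = as.integer(seed)), class = "fold_plan")
}

#' SMOTE settings
#'
#' @param k_neighbors neighbors considered per minority point (classic
#'   default 5); must be smaller than the minority class size.
#' @param seed integer seed.
#' @return an object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5L, seed = 0L) {
  if (k_neighbors < 1L) stopf("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)), class = "smote_config")
}

#' SMOTE minority oversampling
#'
#' Generates exactly `nrow(majority) - nrow(minority)` synthetic
#' minority samples, bringing the classes to parity. Each synthetic
#' point is `x + u * (x_nn - x)` with `u` uniform on `[0, 1]` and
#' `x_nn` one of `x`'s `k` nearest minority neighbors (Euclidean); base
#' points are cycled through a shuffled order of the minority set.
#' Majority samples are never altered and minority samples never
#' removed.
#'
#' @param minority numeric matrix, one minority sample per row.
#' @param majority numeric matrix (only its row count matters) or a
#'   single integer majority count.
#' @param cfg a [smote_config()].
#' @return matrix of synthetic samples (possibly 0 rows), columns as in
#'   `minority`.
#' @export
smote_oversample <- function(minority, majority, cfg = smote_config()) {
  minority <- as.matrix(minority)
  n_min <- nrow(minority)
  n_maj <- if (is.matrix(majority)) nrow(majority) else as.integer(majority)
  if (n_min <= cfg$k_neighbors)
    stopf("minority size %d must exceed k_neighbors = %d; use a smaller k",
          n_min, cfg$k_neighbors)
  n_syn <- n_maj - n_min
  if (n_syn <= 0L)
    return(minority[integer(0L), , drop = FALSE])
  dd <- as.matrix(dist(minority))
  diag(dd) <- Inf
  nn <- t(apply(dd, 1L, function(r) order(r)[seq_len(cfg$k_neighbors)]))
  with_local_seed(cfg$seed, {
    base <- rep_len(sample.int(n_min), n_syn)
    pick <- nn[cbind(base, sample.int(cfg$k_neighbors, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    minority[base, , drop = FALSE] +
      u * (minority[pick, , drop = FALSE] - minority[base, , drop = FALSE])
  })
}

#' Contingency counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return an object of class `contingency_counts`.
#' @export
contingency_counts <- function(tp, fp, fn, tn) {
  v <- c(TP = as.numeric(tp), FP = as.numeric(fp),
         FN = as.numeric(fn), TN = as.numeric(tn))
  if (any(v < 0)) stopf("contingency counts must be non-negative")
  structure(as.list(v), class = "contingency_counts")
}

#' Classification metrics from contingency counts
#'
#' Recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/(TP+FP+FN+TN)` and F1, the harmonic mean of precision and
#' recall. A zero denominator yields 0 with a warning (in particular
#' F1 = 0 when precision + recall = 0).
#'
#' @param counts a [contingency_counts()] object.
#' @return an object of class `metrics_report` with fields `recall`,
#'   `precision`, `accuracy`, `f1`, all in `[0, 1]`.
#' @export
compute_metrics <- function(counts) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warnf("%s undefined (zero denominator); reporting 0", what)
      0
    } else num / den
  }
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  recall <- safe_div(tp, tp + fn, "recall")
  precision <- safe_div(tp, tp + fp, "precision")
  accuracy <- safe_div(tp + tn, tp + fp + fn + tn, "accuracy")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(recall = recall, precision = precision,
                 accuracy = accuracy, f1 = f1, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("recall %.4f  precision %.4f  accuracy %.4f  F1 %.4f\n",
              x$recall, x$precision, x$accuracy, x$f1))
  invisible(x)
}

# flatten a sample to the SMOTE feature space: gray volume plane and
# shape-matrix plane of the joint tensor, concatenated
flatten_sample <- function(s) as.vector(s$tensor)

unflatten_sample <- function(v, input_dim, label) {
  structure(list(tensor = array(v, c(1L, input_dim)), label = label,
                 is_synthetic = TRUE), class = "tensor4d_sample")
}

# rank-based AUC (Mann-Whitney); a convenience metric only
auc_from_scores <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated training with in-fold SMOTE
#'
#' For each fold: SMOTE is applied only to the training portion
#' (interpolating flattened joint tensors of the minority class to
#' parity with the majority), a fresh model is trained, and metrics are
#' computed on the untouched test fold. Malignant is the positive
#' class. The pooled report aggregates raw test-fold contingency
#' counts, which is unbiased under unequal fold sizes; no synthetic
#' sample can ever reach a test fold, and this is asserted on every
#' fold.
#'
#' @param samples list of [assemble_input()] samples.
#' @param unet_cfg a [unet_config()]; fold f trains with seed
#'   `unet_cfg$seed + f`.
#' @param fold_plan a [make_folds()] plan for these samples.
#' @param smote_cfg a [smote_config()], or `NULL` to skip balancing;
#'   `k_neighbors` is capped at the fold's minority count minus one.
#' @return list with `per_fold` (list of [compute_metrics()] reports),
#'   `pooled` (metrics on summed counts), `auc` (pooled rank AUC of the
#'   malignant probability) and `n_synthetic` per fold.
#' @export
cross_validate <- function(samples, unet_cfg, fold_plan,
                           smote_cfg = smote_config()) {
  labels <- vapply(samples, `[[`, character(1L), "label")
  if (length(fold_plan$assignments) != length(samples))
    stopf("fold plan covers %d samples, got %d",
          length(fold_plan$assignments), length(samples))
  if (any(vapply(samples, `[[`, logical(1L), "is_synthetic")))
    stopf("cross_validate must start from real samples only")
  input_dim <- dim(samples[[1L]]$tensor)[-1L]
  per_fold <- vector("list", fold_plan$n_folds)
  n_synthetic <- integer(fold_plan$n_folds)
  pooled <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  scores <- numeric(0L); truth <- logical(0L)
  for (f in seq_len(fold_plan$n_folds)) {
    test_idx <- which(fold_plan$assignments == f)
    train_idx <- setdiff(seq_along(samples), test_idx)
    train <- samples[train_idx]
    if (!is.null(smote_cfg)) {
      ytr <- labels[train_idx]
      tab <- table(ytr)
      if (length(tab) == 2L && tab[1L] != tab[2L]) {
        min_cl <- names(tab)[which.min(tab)]
        # small training folds cannot support the configured k
        k_use <- min(smote_cfg$k_neighbors, as.integer(min(tab)) - 1L)
        if (k_use < 1L)
          stopf("fold %d has too few minority samples (%d) for SMOTE",
                f, min(tab))
        feats_min <- t(vapply(train[ytr == min_cl], flatten_sample,
                              numeric(prod(c(1L, input_dim)))))
        syn <- smote_oversample(feats_min, as.integer(max(tab)),
                                smote_config(k_use, smote_cfg$seed + f))
        n_synthetic[f] <- nrow(syn)
        train <- c(train, lapply(seq_len(nrow(syn)), function(i)
          unflatten_sample(syn[i, ], input_dim, min_cl)))
      }
    }
    test <- samples[test_idx]
    stopifnot(!any(vapply(test, `[[`, logical(1L), "is_synthetic")))
    cfg_f <- unet_cfg
    cfg_f$seed <- unet_cfg$seed + f
    model <- build_unet(cfg_f, input_dim = input_dim)
    model <- calibrate_unet(model, train)
    model <- train_unet(model, train)
    probs <- predict(model, test)
    pred_mal <- probs[, "malignant"] >= 0.5
    is_mal <- labels[test_idx] == "malignant"
    pooled <- pooled + c(TP = sum(pred_mal & is_mal),
                         FP = sum(pred_mal & !is_mal),
                         FN = sum(!pred_mal & is_mal),
                         TN = sum(!pred_mal & !is_mal))
    scores <- c(scores, probs[, "malignant"])
    truth <- c(truth, is_mal)
    per_fold[[f]] <- compute_metrics(contingency_counts(
      sum(pred_mal & is_mal), sum(pred_mal & !is_mal),
      sum(!pred_mal & is_mal), sum(!pred_mal & !is_mal)))
  }
  list(per_fold = per_fold,
       pooled = compute_metrics(contingency_counts(
         pooled["TP"], pooled["FP"], pooled["FN"], pooled["TN"])),
       auc = auc_from_scores(scores, truth),
       n_synthetic = n_synthetic)
}
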