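#' Stratified fold assignment
#'
#' Assigns samples to `k` folds with a single continuous round-robin over
#' the (per-class shuffled) samples, class by class.  Class proportions per
#' fold differ by at most one sample and overall fold sizes are as equal as
#' possible (e.g. test folds of sizes 17, 17, 17, 16, 16 at n = 83).
#'
#' @param labels MI/MCI labels.
#' @param k Number of folds.
#' @param seed Integer seed for the per-class shuffles.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  y <- encode_labels(labels)
  n <- length(y)
  if (n < k) stop(sprintf("n = %d is smaller than k = %d folds", n, k),
                  call. = FALSE)
  folds <- integer(n)
  with_local_seed(seed, {
    pos <- 0L
    for (cls in sort(unique(y), decreasing = TRUE)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Trains the model on k-1 folds and predicts the held-out fold, for every
#' fold; all held-out predictions are pooled into a single confusion
#' matrix from which the metrics are computed.  Every sample is tested
#' exactly once.
#'
#' @param features Feature matrix/data frame (canonical column names).
#' @param labels MI/MCI labels.
#' @param config A [model_config()]; its seed fixes fold assignment and
#'   per-fold training.
#' @param k Number of folds (default 5).
#' @return List of class `cv_result`: `cm` (pooled [confusion_matrix()]),
#'   `metrics` ([compute_metrics()] of the pooled matrix), `folds` (fold
#'   ids) and `predictions` (per-sample probability/label in input order).
#' @export
kfold_cv <- function(features, labels, config = model_config(), k = 5) {
  y <- encode_labels(labels)
  n <- length(y)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present for cross-validation", call. = FALSE)
  }
  folds <- stratified_folds(labels, k = k, seed = config$seed)
  prob <- numeric(n)
  pred <- character(n)
  features <- as.data.frame(features)
  for (fold in seq_len(k)) {
    test_idx <- which(folds == fold)
    train_idx <- which(folds != fold)
    fold_config <- config
    fold_config$seed <- config$seed + fold
    model <- train_classifier(features[train_idx, , drop = FALSE],
                              y[train_idx], fold_config)
    out <- predict(model, features[test_idx, , drop = FALSE])
    prob[test_idx] <- out$probability
    pred[test_idx] <- out$label
  }
  cm <- cm_from_predictions(y, pred)
  structure(list(cm = cm, metrics = compute_metrics(cm), folds = folds,
                 predictions = data.frame(probability = prob, label = pred)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("pooled 5-fold CV:\n")
  print(x$metrics)
  invisible(x)
}

#' Baseline evaluation with full feature-family masks
#'
#' Cross-validates the classifier with all features of the named domain
#' active: all 9 angle features, all 7 PROMs, or all 16 combined.
#'
#' @param features Feature matrix/data frame.
#' @param labels MI/MCI labels.
#' @param domain `"angle"`, `"proms"` or `"both"`.
#' @param config A [model_config()]; its masks are overridden by the
#'   domain.
#' @param k Number of folds.
#' @return A `cv_result`.
#' @export
baseline_eval <- function(features, labels, domain = c("both", "angle",
                                                       "proms"),
                          config = model_config(), k = 5) {
  domain <- match.arg(domain)
  config$angle_mask <- rep(domain %in% c("angle", "both"), 9)
  config$proms_mask <- rep(domain %in% c("proms", "both"), 7)
  kfold_cv(features, labels, config, k = k)
}

mask_to_string <- function(mask) paste(as.integer(mask), collapse = "")

mask_int <- function(mask) sum(2^(which(mask) - 1L))

#' Exhaustive feature-subset search within one feature family
#'
#' Evaluates every subset of the domain's features (2^9 = 512 angle
#' subsets or 2^7 = 128 PROM subsets, empty set included) by pooled
#' stratified k-fold cross-validation, with a fixed per-subset seed derived
#' from the subset mask so results do not depend on evaluation order.  The
#' empty subset is enumerated but not trained: it is recorded as a
#' majority-class predictor.  Rows are ranked by F1, ties broken by
#' accuracy, then by fewer features (smallest adequate model first).
#'
#' @param features Feature matrix/data frame.
#' @param labels MI/MCI labels.
#' @param domain `"angle"` or `"proms"`.
#' @param config A [model_config()].
#' @param k Number of folds.
#' @return Data frame (class `subset_search`) with one row per subset:
#'   `mask` (bit string in canonical feature order), `n_features`,
#'   `features`, counts `tp fn fp tn`, the four metrics, and `rank`; the
#'   best subset has `rank == 1`.
#' @export
subset_search <- function(features, labels, domain = c("angle", "proms"),
                          config = model_config(), k = 5) {
  domain <- match.arg(domain)
  fam <- if (domain == "angle") ANGLE_FEATURES else PROMS_FEATURES
  d <- length(fam)
  y <- encode_labels(labels)
  majority <- if (sum(y == 1) >= sum(y == 0)) "MI" else "MCI"
  rows <- vector("list", 2^d)
  for (code in 0:(2^d - 1L)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(d) - 1L)) > 0)
    if (!any(mask)) {
      pred <- rep(majority, length(y))
      cm <- cm_from_predictions(y, pred)
      met <- compute_metrics(cm)
    } else {
      sub_config <- config
      sub_config$seed <- config$seed + code
      if (domain == "angle") {
        sub_config$angle_mask <- mask
        sub_config$proms_mask <- rep(FALSE, 7)
      } else {
        sub_config$angle_mask <- rep(FALSE, 9)
        sub_config$proms_mask <- mask
      }
      res <- kfold_cv(features, labels, sub_config, k = k)
      cm <- res$cm
      met <- res$metrics
    }
    rows[[code + 1L]] <- data.frame(
      mask = mask_to_string(mask), n_features = sum(mask),
      features = paste(fam[mask], collapse = ","),
      tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
      accuracy = met$accuracy, sensitivity = met$sensitivity,
      specificity = met$specificity, f1 = met$f1)
  }
  out <- do.call(rbind, rows)
  f1_key <- ifelse(is.na(out$f1), -1, out$f1)
  ord <- order(-f1_key, -out$accuracy, out$n_features)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  # never select the untrained empty subset as optimal
  if (out$rank[out$n_features == 0] == 1L && nrow(out) > 1L) {
    empty_i <- which(out$n_features == 0)
    runner <- which(out$rank == 2L)
    out$rank[empty_i] <- 2L
    out$rank[runner] <- 1L
  }
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("subset_search", "data.frame")
  attr(out, "domain") <- domain
  out
}

#' Per-feature ablation of a trained feature set
#'
#' For each active feature of `mask`, re-runs pooled k-fold
#' cross-validation with that feature removed and reports the accuracy
#' drop `accuracy(mask) - accuracy(mask minus feature)` in percentage
#' points (positive = the feature helps).
#'
#' @param features Feature matrix/data frame.
#' @param labels MI/MCI labels.
#' @param mask Named logical vector over the 16 canonical features, or a
#'   character vector of active feature names; at least 2 active features.
#' @param config A [model_config()].
#' @param k Number of folds.
#' @return Data frame with one row per active feature: `feature`,
#'   `accuracy_without` and `delta_accuracy`.
#' @export
ablation <- function(features, labels, mask, config = model_config(),
                     k = 5) {
  all_feats <- c(ANGLE_FEATURES, PROMS_FEATURES)
  if (is.character(mask)) {
    bad <- setdiff(mask, all_feats)
    if (length(bad)) stop(sprintf("unknown feature(s): %s",
                                  paste(bad, collapse = ", ")),
                          call. = FALSE)
    mask <- all_feats %in% mask
  }
  stopifnot(length(mask) == 16L)
  active <- all_feats[mask]
  if (length(active) < 2L) {
    stop("ablation requires at least 2 active features", call. = FALSE)
  }
  as_config <- function(m) {
    cfg <- config
    cfg$angle_mask <- m[1:9]
    cfg$proms_mask <- m[10:16]
    cfg
  }
  base_acc <- kfold_cv(features, labels, as_config(mask), k = k)$metrics$accuracy
  res <- lapply(active, function(f) {
    m <- mask & (all_feats != f)
    acc <- kfold_cv(features, labels, as_config(m), k = k)$metrics$accuracy
    data.frame(feature = f, accuracy_without = acc,
               delta_accuracy = base_acc - acc)
  })
  out <- do.call(rbind, res)
  attr(out, "baseline_accuracy") <- base_acc
  out
}
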