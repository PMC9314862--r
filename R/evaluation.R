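#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the chance that
#' a random positive outscores a random negative, ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels of the same length.
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve by step-wise interpolation
# (average-precision form; no trapezoids, so no optimistic bias).
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0L) stop("AUPR undefined without positives", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # collapse tied thresholds
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Full evaluation metric panel
#'
#' AUC, AUPR, and the thresholded metrics precision, recall, F1 and
#' Matthews correlation coefficient at the given score threshold
#' (prediction positive when `score >= threshold`).  The threshold that
#' maximises F1 is reported alongside.
#'
#' @param scores,labels Scores and 0/1 labels.
#' @param threshold Score threshold for the confusion matrix.
#' @return A `metric_panel` list: `auc`, `aupr`, `precision`, `recall`,
#'   `f1`, `mcc`, `threshold`, `f1_best`, `threshold_best`.
#' @export
metric_panel <- function(scores, labels, threshold = 0.5) {
  auc <- roc_auc(scores, labels)
  aupr <- pr_auc(scores, labels)
  conf <- confusion_metrics(scores, labels, threshold)
  best <- best_f1_threshold(scores, labels)
  structure(c(list(auc = auc, aupr = aupr), conf,
              list(threshold = threshold,
                   f1_best = best$f1, threshold_best = best$threshold)),
            class = "metric_panel")
}

confusion_metrics <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

best_f1_threshold <- function(scores, labels) {
  cand <- unique(sort(scores))
  f1 <- vapply(cand, function(th)
    confusion_metrics(scores, labels, th)$f1, numeric(1))
  i <- which.max(f1)
  list(threshold = cand[i], f1 = f1[i])
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf(
    "AUC %.4f | AUPR %.4f | F1 %.4f | recall %.4f | precision %.4f | MCC %.4f (threshold %.2f)\n",
    x$auc, x$aupr, x$f1, x$recall, x$precision, x$mcc, x$threshold))
  invisible(x)
}

# Deterministic small sub-seed for (repetition, fold) training runs.
fold_seed <- function(seed, rep, fold) {
  (as.integer(seed) * 1009L + rep * 101L + fold) %% 2147480000L
}

# Mask a set of positive entries (linear indices into bm) to zero.
mask_assoc <- function(assoc, idx) {
  bm <- assoc$bm
  bm[idx] <- 0
  assoc_matrix(bm, assoc$disease_index, assoc$mirna_index,
               assoc$n_duplicates)
}

# Shared inner step: recompute similarities from a masked association
# matrix, train on its positives, and score the requested pairs.
train_and_score <- function(assoc_masked, seqs, forest, params,
                            score_idx, train_seed) {
  sims <- similarity_pipeline(assoc_masked, seqs, forest, params)
  feats <- build_pair_features(sims$ms, sims$ds, assoc_masked)
  spec <- bgan_spec(ncol(feats$x), params$latent_dim, params$hidden_dims,
                    params$eta, params$dropout)
  cfg <- params; cfg$seed <- train_seed
  model <- bgan_train(build_networks(spec, seed = train_seed), feats, cfg)
  mi_col <- (score_idx - 1L) %/% nrow(assoc_masked$bm) + 1L
  di_row <- (score_idx - 1L) %% nrow(assoc_masked$bm) + 1L
  pairs <- data.frame(mirna = assoc_masked$mirna_index$names[mi_col],
                      disease = assoc_masked$disease_index$names[di_row],
                      stringsAsFactors = FALSE)
  pf <- build_pair_features(sims$ms, sims$ds, assoc_masked, pairs)
  bgan_score(model, pf$x)
}

#' Repeated k-fold cross-validation with per-fold similarity recomputation
#'
#' The known associations are randomly split into `k` folds.  For each
#' fold the test positives are zeroed in the association matrix, the
#' association-dependent similarities (functional similarity and both
#' GIP kernels) are recomputed from the masked matrix so no test signal
#' leaks into the features, the model is trained on the remaining
#' positives, and the test positives are scored against a seeded random
#' sample of unknown pairs (`params$neg_ratio` negatives per positive).
#' Scores are pooled over the `k` folds of a repetition into one metric
#' panel; the whole procedure is repeated `n_repetitions` times with
#' fresh fold assignments.
#'
#' @param assoc An [assoc_matrix()] (or a `gen_dataset()` list, from
#'   which `assoc`, `seqs` and `forest` are taken).
#' @param seqs,forest Optional sequence set and DAG forest.
#' @param params [bganmda_params()]; `n_repetitions` and
#'   `holdout_fraction` inside the training config still apply per fold.
#' @param k Number of folds.
#' @param n_repetitions Number of repetitions of the whole k-fold split.
#' @param seed Integer seed for fold assignment, negative sampling and
#'   training.
#' @return A `bganmda_cv` list: `panels` (one `metric_panel` per
#'   repetition), `fold_auc` (`n_repetitions x k` matrix), `scores`
#'   (pooled data frame), `k`, `seed`.
#' @export
five_fold_cv <- function(assoc, seqs = NULL, forest = NULL,
                         params = bganmda_params(), k = 5L,
                         n_repetitions = 3L, seed = 1L) {
  if (is.list(assoc) && !inherits(assoc, "assoc_matrix") &&
      !is.null(assoc$assoc)) {
    seqs <- assoc$seqs; forest <- assoc$forest; assoc <- assoc$assoc
  }
  stopifnot(inherits(assoc, "assoc_matrix"))
  pos <- which(assoc$bm == 1)
  if (length(pos) < k)
    stop("need at least ", k, " known associations for ", k,
         "-fold cross-validation", call. = FALSE)
  unknown <- which(assoc$bm == 0)
  panels <- vector("list", n_repetitions)
  fold_auc <- matrix(NA_real_, n_repetitions, k)
  pooled <- vector("list", n_repetitions)
  for (rep in seq_len(n_repetitions)) {
    set.seed(fold_seed(seed, rep, 0L))
    folds <- sample(rep_len(seq_len(k), length(pos)))
    rep_scores <- list()
    for (f in seq_len(k)) {
      test_idx <- pos[folds == f]
      set.seed(fold_seed(seed, rep, f))
      neg_idx <- sample(unknown,
                        min(length(unknown),
                            ceiling(params$neg_ratio * length(test_idx))))
      assoc_m <- mask_assoc(assoc, test_idx)
      stopifnot(all(assoc_m$bm[test_idx] == 0))  # leakage control
      idx <- c(test_idx, neg_idx)
      s <- train_and_score(assoc_m, seqs, forest, params, idx,
                           fold_seed(seed, rep, f))
      lab <- rep(c(1L, 0L), c(length(test_idx), length(neg_idx)))
      fold_auc[rep, f] <- roc_auc(s, lab)
      rep_scores[[f]] <- data.frame(score = s, label = lab, fold = f)
    }
    pooled[[rep]] <- do.call(rbind, rep_scores)
    panels[[rep]] <- metric_panel(pooled[[rep]]$score, pooled[[rep]]$label,
                                  params$threshold)
  }
  structure(list(panels = panels, fold_auc = fold_auc,
                 scores = pooled, k = k, seed = seed),
            class = "bganmda_cv")
}

#' @export
print.bganmda_cv <- function(x, ...) {
  auc <- vapply(x$panels, `[[`, numeric(1), "auc")
  cat(sprintf("%d-fold cross-validation, %d repetition(s)\n",
              x$k, length(x$panels)))
  cat(sprintf("mean AUC %.4f (sd %.4f)\n", mean(auc),
              if (length(auc) > 1) sd(auc) else 0))
  for (p in x$panels) print(p)
  invisible(x)
}

#' Leave-one-out cross-validation ranking
#'
#' Each known association is left out in turn: it is zeroed in the
#' association matrix, the association-dependent similarities are
#' recomputed, the model is retrained, and the left-out pair is ranked
#' among candidate pairs -- all unknown pairs in `"global"` mode, only
#' the unknown pairs of the same disease in `"local"` mode.  The AUC is
#' the mean, over cases, of the fraction of candidates the left-out pair
#' outscores (ties one half).  Cases whose local candidate set is empty
#' are skipped with a warning.
#'
#' @param assoc An [assoc_matrix()] (or a `gen_dataset()` list).
#' @param seqs,forest Optional inputs as in [five_fold_cv()].
#' @param params [bganmda_params()].
#' @param mode `"global"` or `"local"`.
#' @param seed Integer seed.
#' @param max_cases Optional cap on the number of left-out cases (a
#'   seeded subsample); `NULL` ranks every known association.
#' @param warm_start Reuse the previous case's parameters as
#'   initialisation instead of retraining from scratch (forces a single
#'   training repetition).
#' @return A `bganmda_loocv` list: `ranks` (data frame with `mirna`,
#'   `disease`, `rank`, `n_candidates`), `auc`, `mode`.
#' @export
loocv <- function(assoc, seqs = NULL, forest = NULL,
                  params = bganmda_params(),
                  mode = c("global", "local"), seed = 1L,
                  max_cases = NULL, warm_start = FALSE) {
  mode <- match.arg(mode)
  if (is.list(assoc) && !inherits(assoc, "assoc_matrix") &&
      !is.null(assoc$assoc)) {
    seqs <- assoc$seqs; forest <- assoc$forest; assoc <- assoc$assoc
  }
  stopifnot(inherits(assoc, "assoc_matrix"))
  pos <- which(assoc$bm == 1)
  if (length(pos) < 2L) stop("need at least 2 known associations",
                             call. = FALSE)
  set.seed(fold_seed(seed, 0L, 0L))
  if (!is.null(max_cases) && max_cases < length(pos))
    pos <- sort(sample(pos, max_cases))
  if (warm_start) { params$n_repetitions <- 1L }
  nd <- nrow(assoc$bm)
  unknown_all <- which(assoc$bm == 0)
  out <- vector("list", length(pos))
  prev <- NULL
  for (i in seq_along(pos)) {
    p <- pos[i]
    row <- (p - 1L) %% nd + 1L
    cand <- if (mode == "global") unknown_all else
      (which(assoc$bm[row, ] == 0) - 1L) * nd + row
    if (length(cand) == 0L) {
      warning("no unknown candidate pairs for disease `",
              assoc$disease_index$names[row], "`; case skipped",
              call. = FALSE)
      next
    }
    assoc_m <- mask_assoc(assoc, p)
    sims <- similarity_pipeline(assoc_m, seqs, forest, params)
    feats <- build_pair_features(sims$ms, sims$ds, assoc_m)
    spec <- bgan_spec(ncol(feats$x), params$latent_dim, params$hidden_dims,
                      params$eta, params$dropout)
    cfg <- params; cfg$seed <- fold_seed(seed, 1L, i)
    model <- build_networks(spec, seed = cfg$seed)
    if (warm_start && !is.null(prev)) {
      model$E <- prev$reps[[1]]$E
      model$G <- prev$reps[[1]]$G
      model$D <- prev$reps[[1]]$D
    }
    model <- bgan_train(model, feats, cfg)
    prev <- model
    idx <- c(p, cand)
    mi_col <- (idx - 1L) %/% nd + 1L
    di_row <- (idx - 1L) %% nd + 1L
    pairs <- data.frame(mirna = assoc$mirna_index$names[mi_col],
                        disease = assoc$disease_index$names[di_row],
                        stringsAsFactors = FALSE)
    pf <- build_pair_features(sims$ms, sims$ds, assoc_m, pairs)
    s <- bgan_score(model, pf$x)
    s_test <- s[1]; s_cand <- s[-1]
    rank <- 1 + sum(s_cand > s_test) + sum(s_cand == s_test) / 2
    out[[i]] <- data.frame(mirna = pairs$mirna[1],
                           disease = pairs$disease[1],
                           rank = rank,
                           n_candidates = length(cand),
                           concordance = (sum(s_cand < s_test) +
                                            sum(s_cand == s_test) / 2) /
                             length(cand),
                           stringsAsFactors = FALSE)
  }
  ranks <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  structure(list(ranks = ranks, auc = mean(ranks$concordance), mode = mode,
                 seed = seed),
            class = "bganmda_loocv")
}

#' @export
print.bganmda_loocv <- function(x, ...) {
  cat(sprintf("%s LOOCV over %d case(s): AUC %.4f, median rank %.1f\n",
              x$mode, nrow(x$ranks), x$auc, median(x$ranks$rank)))
  invisible(x)
}

#' Top-k candidate miRNAs for one disease
#'
#' Filters a scored pair list to the unknown (label-0) pairs of the given
#' disease and returns the `k` highest-scoring candidates; tied scores
#' are ordered lexicographically by miRNA name for determinism.
#'
#' @param scores A `scored_pairs` data frame (from [bgan_score()] or
#'   [predict.bganmda()]) with a `label` column.
#' @param disease Disease name.
#' @param k Number of candidates to return.
#' @return Data frame with `rank`, `mirna`, `disease`, `score`.
#' @export
rank_candidates <- function(scores, disease, k = 50L) {
  stopifnot(is.data.frame(scores),
            all(c("mirna", "disease", "score") %in% names(scores)))
  disease <- normalize_name(disease)
  if (!disease %in% scores$disease)
    stop("unknown disease: ", disease, call. = FALSE)
  sub <- scores[scores$disease == disease, , drop = FALSE]
  if ("label" %in% names(sub)) sub <- sub[sub$label == 0, , drop = FALSE]
  sub <- sub[order(-sub$score, sub$mirna), , drop = FALSE]
  sub <- head(sub, k)
  data.frame(rank = seq_len(nrow(sub)), mirna = sub$mirna,
             disease = sub$disease, score = sub$score,
             stringsAsFactors = FALSE)
}
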