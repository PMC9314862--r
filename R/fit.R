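#' Fit the miRNA-disease association model
#'
#' The one-call front end: builds every similarity matrix from the raw
#' inputs ([similarity_pipeline()]), assembles the per-pair concatenated
#' feature vectors ([build_pair_features()]), and trains the adversarial
#' encoder/generator/discriminator on the known-association vectors
#' ([bgan_train()]).  The fitted object scores any pair through
#' [predict.bganmda()].
#'
#' @param assoc An [assoc_matrix()], or a `gen_dataset()` list from
#'   which `assoc`, `seqs` and `forest` are taken.
#' @param seqs Optional `sequence_set` of miRNA sequences.
#' @param forest Optional disease [dag_forest()].
#' @param params [bganmda_params()] controlling similarity construction
#'   and training.
#' @param seed Convenience override for `params$seed`.
#' @return An object of class `bganmda` with elements `assoc`, `sims`
#'   (all similarity matrices), `model` (the trained `bgan_model`),
#'   `params` and `call`.
#' @examples
#' dat <- gen_dataset(synthetic_spec(nm = 12, nd = 8, latent_rank = 2,
#'                                   density = 0.2))
#' fit <- bganmda(dat, params = bganmda_params(latent_dim = 4,
#'                                             hidden_dims = c(12, 6),
#'                                             epochs = 30, batch_size = 8,
#'                                             n_repetitions = 1, seed = 1))
#' head(predict(fit))
#' @export
bganmda <- function(assoc, seqs = NULL, forest = NULL,
                    params = bganmda_params(), seed = NULL) {
  cl <- match.call()
  if (is.list(assoc) && !inherits(assoc, "assoc_matrix") &&
      !is.null(assoc$assoc)) {
    if (is.null(seqs)) seqs <- assoc$seqs
    if (is.null(forest)) forest <- assoc$forest
    assoc <- assoc$assoc
  }
  stopifnot(inherits(assoc, "assoc_matrix"))
  if (!is.null(seed)) params$seed <- as.integer(seed)
  if (is.null(params$seed)) params$seed <- 1L
  sims <- similarity_pipeline(assoc, seqs, forest, params)
  feats <- build_pair_features(sims$ms, sims$ds, assoc)
  spec <- bgan_spec(ncol(feats$x), params$latent_dim, params$hidden_dims,
                    params$eta, params$dropout)
  model <- build_networks(spec, seed = params$seed)
  model <- bgan_train(model, feats, params)
  structure(list(assoc = assoc, sims = sims, model = model,
                 params = params, call = cl),
            class = "bganmda")
}

#' @export
print.bganmda <- function(x, ...) {
  cat("miRNA-disease association model (bidirectional adversarial network)\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d miRNAs x %d diseases, %d known associations\n",
              length(x$assoc$mirna_index), length(x$assoc$disease_index),
              sum(x$assoc$bm)))
  print(x$model)
  invisible(x)
}

#' @export
summary.bganmda <- function(object, ...) {
  loss <- do.call(rbind, lapply(object$model$loss, function(tr)
    tr[nrow(tr), , drop = FALSE]))
  out <- list(
    nm = length(object$assoc$mirna_index),
    nd = length(object$assoc$disease_index),
    n_positive = sum(object$assoc$bm),
    feature_length = object$model$spec$n_features,
    latent_dim = object$model$spec$latent_dim,
    discriminator_input = object$model$spec$discriminator_dims[1],
    n_repetitions = length(object$model$reps),
    final_loss = colMeans(loss)
  )
  class(out) <- "summary.bganmda"
  out
}

#' @export
print.summary.bganmda <- function(x, ...) {
  cat(sprintf("miRNAs: %d  diseases: %d  known associations: %d\n",
              x$nm, x$nd, x$n_positive))
  cat(sprintf("feature length: %d (= nm + nd)  latent: %d  discriminator input: %d\n",
              x$feature_length, x$latent_dim, x$discriminator_input))
  cat(sprintf("training repetitions: %d\n", x$n_repetitions))
  cat(sprintf("mean final losses: discriminator %.4f, encoder/generator %.4f\n",
              x$final_loss["d_loss"], x$final_loss["eg_loss"]))
  invisible(x)
}

#' Score miRNA-disease pairs with a fitted model
#'
#' @param object A fitted [bganmda()] model.
#' @param newdata Optional data frame with columns `mirna` and `disease`
#'   naming the pairs to score; all `nm * nd` pairs when omitted.
#' @param ... Unused.
#' @return A `scored_pairs` data frame (`mirna`, `disease`, `score`,
#'   `label`), one row per requested pair.
#' @export
predict.bganmda <- function(object, newdata = NULL, ...) {
  pf <- build_pair_features(object$sims$ms, object$sims$ds, object$assoc,
                            pairs = newdata)
  bgan_score(object$model, pf)
}

#' Training-loss traces of a fitted model
#'
#' Plots the discriminator and encoder/generator binary cross-entropy
#' per training step, one panel pair per repetition overlayed.
#'
#' @param x A fitted [bganmda()] model.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.bganmda <- function(x, ...) {
  traces <- x$model$loss
  all <- do.call(cbind, traces)
  graphics::matplot(all, type = "l", lty = rep(1:2, length(traces)),
                    col = rep(seq_along(traces), each = 2),
                    xlab = "training step", ylab = "binary cross-entropy",
                    main = "Adversarial training loss", ...)
  graphics::legend("topright", bty = "n",
                   legend = c("discriminator", "encoder/generator"),
                   lty = 1:2)
  invisible(x)
}

#' Draw synthetic pair feature vectors from a fitted generator
#'
#' @param object A fitted [bganmda()] model.
#' @param nsim Number of vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Matrix of `nsim` generated feature vectors.
#' @export
simulate.bganmda <- function(object, nsim = 1, seed = NULL, ...) {
  bgan_generate(object$model, n = nsim, seed = seed)
}
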