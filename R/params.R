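#' Model and similarity hyper-parameters
#'
#' Collects every tunable of the pipeline in one validated list: the
#' similarity-construction weights, the network architecture and the
#' training schedule.  Defaults follow the reference configuration of the
#' method: a 0.6/0.4 blend of functional and sequence similarity, semantic
#' decay 0.5, unit Gaussian-kernel bandwidth base, edit costs 2 (substitute)
#' and 1 (insert/delete), a 100-dimensional latent space, LeakyReLU slope
#' 0.01, dropout 0.5, Adam at learning rate 2e-4 with batches of 128 for
#' 20000 steps, and five training repetitions each on a random 80%
#' subsample of the positive pairs.
#'
#' @param alpha Mixing weight of functional vs sequence similarity in the
#'   miRNA similarity network, in `[0,1]`.
#' @param mu Semantic decay factor applied per edge when ancestor
#'   contributions are propagated up a disease DAG, in `(0,1)`.
#' @param lambda_prime Bandwidth base of the Gaussian interaction profile
#'   kernel; the effective bandwidth is `lambda_prime` divided by the mean
#'   profile norm.
#' @param sub_cost,indel_cost Positive integer edit costs for the weighted
#'   Levenshtein distance between miRNA sequences.
#' @param functional_mode `"intersection"` sums semantic contributions over
#'   the shared disease set only; `"union_max"` sums best-match semantic
#'   similarity over both disease sets (the classical functional-similarity
#'   form).  See the methods vignette for the difference.
#' @param gip_norm `"squared"` (default) normalises the kernel bandwidth by
#'   the mean squared profile norm, `"linear"` by the mean norm.
#' @param latent_dim Width of the latent code produced by the encoder and
#'   consumed by the generator.
#' @param hidden_dims Integer vector of the two hidden-layer widths shared
#'   by encoder and generator (each network has three fully connected
#'   layers).  `NULL` interpolates geometrically between the input width
#'   and `latent_dim` at build time.
#' @param eta Negative-side slope of the LeakyReLU activation.
#' @param dropout Dropout rate applied to hidden activations during
#'   training.
#' @param lr Adam learning rate.
#' @param betas Adam exponential decay rates; `(0.5, 0.999)` is the usual
#'   adversarial-training choice.
#' @param batch_size Minibatch size per training step.
#' @param epochs Number of adversarial training steps.
#' @param d_steps Discriminator updates per encoder/generator update.
#'   Keeping the discriminator ahead of the players it judges preserves
#'   a usable scoring boundary; see the methods vignette.
#' @param n_repetitions Number of independent training repetitions; the
#'   final association score is the mean discriminator score over
#'   repetitions.
#' @param holdout_fraction Fraction of positive training vectors randomly
#'   removed in each repetition.
#' @param threshold Score threshold for the thresholded evaluation metrics.
#' @param neg_ratio Number of sampled unknown pairs per held-out positive
#'   when cross-validation metrics are computed.
#' @param seed Integer seed controlling all randomness, or `NULL`.
#' @return A named list of class `bganmda_params`.
#' @seealso [read_params()] to load the same keys from a YAML file.
#' @export
bganmda_params <- function(alpha = 0.6,
                           mu = 0.5,
                           lambda_prime = 1,
                           sub_cost = 2L,
                           indel_cost = 1L,
                           functional_mode = c("intersection", "union_max"),
                           gip_norm = c("squared", "linear"),
                           latent_dim = 100L,
                           hidden_dims = NULL,
                           eta = 0.01,
                           dropout = 0.5,
                           lr = 2e-4,
                           betas = c(0.5, 0.999),
                           batch_size = 128L,
                           epochs = 20000L,
                           d_steps = 2L,
                           n_repetitions = 5L,
                           holdout_fraction = 0.2,
                           threshold = 0.5,
                           neg_ratio = 1,
                           seed = NULL) {
  functional_mode <- match.arg(functional_mode)
  gip_norm <- match.arg(gip_norm)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0 || mu >= 1)
    stop("`mu` must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(lambda_prime) || lambda_prime <= 0)
    stop("`lambda_prime` must be positive", call. = FALSE)
  if (sub_cost <= 0 || indel_cost <= 0 ||
      sub_cost != round(sub_cost) || indel_cost != round(indel_cost))
    stop("edit costs must be positive integers", call. = FALSE)
  if (holdout_fraction < 0 || holdout_fraction >= 1)
    stop("`holdout_fraction` must be in [0, 1)", call. = FALSE)
  stopifnot(latent_dim >= 1, eta >= 0, dropout >= 0, dropout < 1,
            lr > 0, batch_size >= 1, epochs >= 0, d_steps >= 1,
            n_repetitions >= 1,
            length(betas) == 2L, all(betas > 0), all(betas < 1))
  structure(list(
    alpha = alpha, mu = mu, lambda_prime = lambda_prime,
    sub_cost = as.integer(sub_cost), indel_cost = as.integer(indel_cost),
    functional_mode = functional_mode, gip_norm = gip_norm,
    latent_dim = as.integer(latent_dim), hidden_dims = hidden_dims,
    eta = eta, dropout = dropout, lr = lr, betas = betas,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    d_steps = as.integer(d_steps),
    n_repetitions = as.integer(n_repetitions),
    holdout_fraction = holdout_fraction,
    threshold = threshold, neg_ratio = neg_ratio,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "bganmda_params")
}

#' Read hyper-parameters from a YAML config file
#'
#' Keys are the argument names of [bganmda_params()]; unknown keys are an
#' error, missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `bganmda_params` list.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(bganmda_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(bganmda_params, cfg)
}
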