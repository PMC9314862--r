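#' Leaky rectified linear activation
#'
#' `x` for non-negative inputs, `eta * x` for negative ones.
#'
#' @param x Numeric vector/matrix.
#' @param eta Negative-side slope.
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, eta = 0.01) {
  ifelse(x >= 0, x, eta * x)
}

#' Mean binary cross-entropy
#'
#' Predictions are clipped into `(eps, 1 - eps)` before the logarithms so
#' the loss is always finite.
#'
#' @param predicted Probabilities in `[0,1]`.
#' @param labels 0/1 vector of the same length.
#' @param eps Clipping constant.
#' @return Single non-negative number.
#' @export
bce_loss <- function(predicted, labels, eps = 1e-7) {
  if (length(predicted) != length(labels))
    stop("prediction and label lengths differ", call. = FALSE)
  p <- pmin(pmax(predicted, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

geometric_dims <- function(from, to) {
  round(exp(seq(log(from), log(to), length.out = 4)))[2:3]
}

#' Architecture of the adversarial networks
#'
#' Each of the three networks (encoder, generator, discriminator) has
#' exactly three fully connected layers with LeakyReLU activations and
#' dropout on the hidden layers.  The encoder maps a length-`n_features`
#' pair feature vector to a `latent_dim` code, the generator inverts the
#' shapes with a linear output layer, and the discriminator maps the
#' concatenated `(x, z)` pair -- width `n_features + latent_dim` -- to a
#' probability via a sigmoid.  Hidden widths default to geometric
#' interpolation between input and output width.
#'
#' @param n_features Feature-vector length (`nm + nd`).
#' @param latent_dim Latent code width.
#' @param hidden_dims Optional integer vector of length 2.
#' @param eta LeakyReLU slope.
#' @param dropout Dropout rate.
#' @return A `bgan_spec` list with `encoder_dims`, `generator_dims`,
#'   `discriminator_dims`, `latent_dim`, `leaky_slope`, `dropout_rate`.
#' @export
bgan_spec <- function(n_features, latent_dim = 100L, hidden_dims = NULL,
                      eta = 0.01, dropout = 0.5) {
  n_features <- as.integer(n_features)
  latent_dim <- as.integer(latent_dim)
  stopifnot(n_features >= 1, latent_dim >= 1)
  if (is.null(hidden_dims))
    hidden_dims <- geometric_dims(n_features, latent_dim)
  hidden_dims <- as.integer(hidden_dims)
  if (length(hidden_dims) != 2L || any(hidden_dims < 1L))
    stop("`hidden_dims` must be two positive widths", call. = FALSE)
  d_in <- n_features + latent_dim
  structure(list(
    n_features = n_features,
    latent_dim = latent_dim,
    encoder_dims = as.integer(c(n_features, hidden_dims, latent_dim)),
    generator_dims = as.integer(c(latent_dim, rev(hidden_dims), n_features)),
    discriminator_dims = as.integer(c(d_in, geometric_dims(d_in, 1L), 1L)),
    leaky_slope = eta,
    dropout_rate = dropout
  ), class = "bgan_spec")
}

# --- minimal MLP machinery (three dense layers, LeakyReLU hidden units,
#     inverted dropout, analytic backprop) ---------------------------------

mlp_init <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    list(W = matrix(rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                    fan_in, dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

mlp_forward <- function(net, x, eta, dropout = 0, training = FALSE,
                        out_act = c("linear", "sigmoid")) {
  out_act <- match.arg(out_act)
  L <- length(net)
  h <- vector("list", L + 1L); z <- vector("list", L)
  masks <- vector("list", L)
  h[[1L]] <- x
  for (l in seq_len(L)) {
    z[[l]] <- sweep(h[[l]] %*% net[[l]]$W, 2, net[[l]]$b, `+`)
    if (l < L) {
      a <- leaky_relu(z[[l]], eta)
      if (training && dropout > 0) {
        masks[[l]] <- matrix((runif(length(a)) >= dropout) / (1 - dropout),
                             nrow(a), ncol(a))
        a <- a * masks[[l]]
      }
      h[[l + 1L]] <- a
    } else {
      h[[l + 1L]] <- switch(out_act, linear = z[[l]], sigmoid = sigmoid(z[[l]]))
    }
  }
  list(out = h[[L + 1L]], h = h, z = z, masks = masks)
}

# `dz_out` is the loss gradient w.r.t. the output-layer pre-activation.
mlp_backward <- function(net, cache, dz_out, eta) {
  L <- length(net)
  gW <- vector("list", L); gb <- vector("list", L)
  dz <- dz_out
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$h[[l]], dz)
    gb[[l]] <- colSums(dz)
    if (l > 1L) {
      da <- tcrossprod(dz, net[[l]]$W)
      if (!is.null(cache$masks[[l - 1L]])) da <- da * cache$masks[[l - 1L]]
      dz <- da * ifelse(cache$z[[l - 1L]] >= 0, 1, eta)
    } else {
      dz <- tcrossprod(dz, net[[l]]$W)   # gradient w.r.t. the input
    }
  }
  list(gW = gW, gb = gb, dx = dz)
}

adam_init <- function(net) {
  lapply(net, function(l) list(mW = l$W * 0, vW = l$W * 0,
                               mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, lr, betas, t, eps = 1e-8) {
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (l in seq_along(net)) {
    state[[l]]$mW <- b1 * state[[l]]$mW + (1 - b1) * grads$gW[[l]]
    state[[l]]$vW <- b2 * state[[l]]$vW + (1 - b2) * grads$gW[[l]]^2
    state[[l]]$mb <- b1 * state[[l]]$mb + (1 - b1) * grads$gb[[l]]
    state[[l]]$vb <- b2 * state[[l]]$vb + (1 - b2) * grads$gb[[l]]^2
    net[[l]]$W <- net[[l]]$W -
      lr * (state[[l]]$mW / c1) / (sqrt(state[[l]]$vW / c2) + eps)
    net[[l]]$b <- net[[l]]$b -
      lr * (state[[l]]$mb / c1) / (sqrt(state[[l]]$vb / c2) + eps)
  }
  list(net = net, state = state)
}

#' Build untrained encoder, generator and discriminator networks
#'
#' Parameters are drawn with He initialisation under the given seed, so
#' the same seed always yields identical initial networks.
#'
#' @param spec A [bgan_spec()].
#' @param seed Integer seed.
#' @return A `bgan_model` with elements `spec`, `E`, `G`, `D`,
#'   `trained = FALSE`.
#' @export
build_networks <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "bgan_spec"))
  set.seed(seed)
  structure(list(spec = spec,
                 E = mlp_init(spec$encoder_dims),
                 G = mlp_init(spec$generator_dims),
                 D = mlp_init(spec$discriminator_dims),
                 trained = FALSE,
                 reps = NULL,
                 loss = NULL),
            class = "bgan_model")
}

#' @export
print.bgan_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<bgan_model: E %s | G %s | D %s%s>\n",
              paste(s$encoder_dims, collapse = "-"),
              paste(s$generator_dims, collapse = "-"),
              paste(s$discriminator_dims, collapse = "-"),
              if (x$trained) sprintf(", trained (%d repetition(s))",
                                     length(x$reps)) else ", untrained"))
  invisible(x)
}

#' Train the adversarial model on known-association feature vectors
#'
#' Only label-1 (known association) feature vectors form the real-data
#' distribution.  Each training step draws a minibatch `x`, latent noise
#' `z` from a standard normal prior, and alternates: the discriminator
#' takes `cfg$d_steps` binary cross-entropy steps toward labelling
#' encoder pairs `(x, E(x))` as 1 and generator pairs `(G(z), z)` as 0;
#' the encoder and generator then take one step with the targets flipped
#' (the non-saturating form of the minimax objective).  The whole procedure is
#' repeated `n_repetitions` times, each on a random
#' `1 - holdout_fraction` subsample of the positive vectors with freshly
#' initialised networks; scoring later averages the repetitions.  All
#' randomness is governed by `cfg$seed`.
#'
#' @param model A `bgan_model` from [build_networks()].
#' @param features A `pair_features` object (its label-1 rows are used)
#'   or a plain numeric matrix of positive-pair feature vectors.
#' @param cfg [bganmda_params()] supplying the training schedule.
#' @return The trained `bgan_model`: `reps` holds one `(E, G, D)`
#'   parameter set per repetition and `loss` one `epochs x 2` trace
#'   matrix (columns `d_loss`, `eg_loss`) per repetition.
#' @export
bgan_train <- function(model, features, cfg = bganmda_params()) {
  stopifnot(inherits(model, "bgan_model"))
  x_all <- if (inherits(features, "pair_features")) {
    features$x[features$label == 1, , drop = FALSE]
  } else as.matrix(features)
  if (nrow(x_all) == 0L)
    stop("no positive pairs to train on", call. = FALSE)
  if (ncol(x_all) != model$spec$n_features)
    stop("feature length ", ncol(x_all), " does not match model input ",
         model$spec$n_features, call. = FALSE)
  if (cfg$epochs == 0L) return(model)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  eta <- model$spec$leaky_slope
  drop_p <- model$spec$dropout_rate
  latent <- model$spec$latent_dim
  n <- nrow(x_all)
  reps <- vector("list", cfg$n_repetitions)
  losses <- vector("list", cfg$n_repetitions)
  for (r in seq_len(cfg$n_repetitions)) {
    keep <- sample(n, max(1L, ceiling((1 - cfg$holdout_fraction) * n)))
    x_r <- x_all[keep, , drop = FALSE]
    E <- if (r == 1L) model$E else mlp_init(model$spec$encoder_dims)
    G <- if (r == 1L) model$G else mlp_init(model$spec$generator_dims)
    D <- if (r == 1L) model$D else mlp_init(model$spec$discriminator_dims)
    sE <- adam_init(E); sG <- adam_init(G); sD <- adam_init(D)
    trace <- matrix(NA_real_, cfg$epochs, 2,
                    dimnames = list(NULL, c("d_loss", "eg_loss")))
    m <- min(cfg$batch_size, nrow(x_r))
    for (ep in seq_len(cfg$epochs)) {
      # -- discriminator step(s): (x, E(x)) -> 1, (G(z), z) -> 0
      for (k in seq_len(cfg$d_steps)) {
        xb <- x_r[sample(nrow(x_r), m), , drop = FALSE]
        zb <- matrix(rnorm(m * latent), m, latent)
        fe <- mlp_forward(E, xb, eta, drop_p, TRUE, "linear")
        fg <- mlp_forward(G, zb, eta, drop_p, TRUE, "linear")
        din <- rbind(cbind(xb, fe$out), cbind(fg$out, zb))
        fd <- mlp_forward(D, din, eta, drop_p, TRUE, "sigmoid")
        y <- rep(c(1, 0), each = m)
        p <- as.numeric(fd$out)
        trace[ep, 1] <- bce_loss(p, y)
        dz <- matrix((pmin(pmax(p, 1e-7), 1 - 1e-7) - y) / (2 * m), ncol = 1)
        gd <- mlp_backward(D, fd, dz, eta)
        up <- adam_step(D, gd, sD, cfg$lr, cfg$betas, ep)
        D <- up$net; sD <- up$state
      }
      xb <- x_r[sample(nrow(x_r), m), , drop = FALSE]
      zb <- matrix(rnorm(m * latent), m, latent)

      # -- encoder/generator step: flipped targets through frozen D
      fe <- mlp_forward(E, xb, eta, drop_p, TRUE, "linear")
      fg <- mlp_forward(G, zb, eta, drop_p, TRUE, "linear")
      din <- rbind(cbind(xb, fe$out), cbind(fg$out, zb))
      fd <- mlp_forward(D, din, eta, drop_p, TRUE, "sigmoid")
      y2 <- rep(c(0, 1), each = m)
      p2 <- as.numeric(fd$out)
      trace[ep, 2] <- bce_loss(p2, y2)
      dz2 <- matrix((pmin(pmax(p2, 1e-7), 1 - 1e-7) - y2) / (2 * m), ncol = 1)
      gdx <- mlp_backward(D, fd, dz2, eta)$dx
      nf <- model$spec$n_features
      de_out <- gdx[seq_len(m), nf + seq_len(latent), drop = FALSE]
      dg_out <- gdx[m + seq_len(m), seq_len(nf), drop = FALSE]
      ge <- mlp_backward(E, fe, de_out, eta)
      gg <- mlp_backward(G, fg, dg_out, eta)
      up <- adam_step(E, ge, sE, cfg$lr, cfg$betas, ep)
      E <- up$net; sE <- up$state
      up <- adam_step(G, gg, sG, cfg$lr, cfg$betas, ep)
      G <- up$net; sG <- up$state

      if (!all(is.finite(trace[ep, ])))
        stop("training diverged (non-finite loss) at epoch ", ep,
             " of repetition ", r, call. = FALSE)
    }
    reps[[r]] <- list(E = E, G = G, D = D)
    losses[[r]] <- trace
  }
  model$reps <- reps
  model$loss <- losses
  model$trained <- TRUE
  model$cfg <- cfg
  model
}

#' Score miRNA-disease pairs with a trained model
#'
#' The association score of a pair is the discriminator's probability on
#' the pair's feature vector with its own encoding,
#' `D(x, E(x))`, averaged over training repetitions.  Dropout is
#' disabled, so scoring is deterministic.
#'
#' @param model A trained `bgan_model`.
#' @param features A `pair_features` object or a feature matrix.
#' @return For `pair_features` input, a data frame (`mirna`, `disease`,
#'   `score`, `label`) of class `scored_pairs`; for a matrix, a numeric
#'   vector of scores in `(0, 1)`.
#' @export
bgan_score <- function(model, features) {
  stopifnot(inherits(model, "bgan_model"))
  if (!model$trained) stop("model is not trained", call. = FALSE)
  x <- if (inherits(features, "pair_features")) features$x else
    as.matrix(features)
  if (ncol(x) != model$spec$n_features)
    stop("feature length ", ncol(x), " does not match model input ",
         model$spec$n_features, call. = FALSE)
  eta <- model$spec$leaky_slope
  s <- rowMeans(matrix(vapply(model$reps, function(rep) {
    e <- mlp_forward(rep$E, x, eta, 0, FALSE, "linear")$out
    as.numeric(mlp_forward(rep$D, cbind(x, e), eta, 0, FALSE, "sigmoid")$out)
  }, numeric(nrow(x))), nrow = nrow(x)))
  if (inherits(features, "pair_features")) {
    structure(data.frame(mirna = features$mirna,
                         disease = features$disease,
                         score = s,
                         label = features$label,
                         stringsAsFactors = FALSE),
              class = c("scored_pairs", "data.frame"))
  } else s
}

#' Draw new pair feature vectors from the generator
#'
#' Samples latent codes from the standard normal prior and decodes them
#' with each repetition's generator.
#'
#' @param model A trained `bgan_model`.
#' @param n Number of vectors to draw.
#' @param seed Optional seed.
#' @return Matrix with `n` rows of length `n_features` (first
#'   repetition's generator).
#' @export
bgan_generate <- function(model, n = 1L, seed = NULL) {
  stopifnot(inherits(model, "bgan_model"), model$trained)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n * model$spec$latent_dim), n, model$spec$latent_dim)
  mlp_forward(model$reps[[1]]$G, z, model$spec$leaky_slope, 0, FALSE,
              "linear")$out
}

#' Save / load a trained model
#'
#' The parameter state is written as a single RDS file with a JSON
#' sidecar (`<path>.json`) describing the architecture; loading restores
#' the model bit-exactly.
#'
#' @param model A `bgan_model`.
#' @param path Destination path.
#' @return `write_bgan` returns `path` invisibly; `read_bgan` the model.
#' @export
write_bgan <- function(model, path) {
  stopifnot(inherits(model, "bgan_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bgan
#' @export
read_bgan <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bgan_model"))
  model
}
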