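#' VAE training configuration
#'
#' Hyper-parameters for the variational autoencoder that embeds binary
#' mutation profiles. Defaults follow the settings that work well for
#' clone-structured single-cell SNV matrices: two hidden layers of M/5 and
#' M/10 units, a 3-dimensional latent space, a small KL weight
#' (`kl_weight = 1e-4`) so that the reconstruction term dominates, RMSprop
#' with learning rate 1e-4 and batch size 64.
#'
#' @param latent_dim dimension D of the latent space (default 3).
#' @param hidden_sizes integer vector of hidden-layer widths for the encoder
#'   (the decoder mirrors them). `NULL` (default) means
#'   `c(floor(M/5), floor(M/10))`, each at least 1, computed from the data at
#'   training time.
#' @param kl_weight weight lambda on the KL divergence term (default 1e-4).
#' @param learning_rate RMSprop learning rate (default 1e-4).
#' @param batch_size minibatch size (default 64; a final partial batch is
#'   allowed).
#' @param epochs number of training epochs. The default `NULL` resolves at
#'   training time to a fixed budget of roughly 4800 gradient steps,
#'   `min(1200, max(150, ceiling(4800 / batches_per_epoch)))`: small
#'   matrices (few minibatches per epoch) train for more epochs, large ones
#'   for fewer, which keeps optimization effort roughly constant across
#'   dataset sizes (1000 cells resolve to the conventional 300 epochs).
#'   Pass an integer to fix it.
#' @param seed integer seed controlling weight initialization, minibatch
#'   shuffling and the reparameterization noise.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 3L, hidden_sizes = NULL, kl_weight = 1e-4,
                       learning_rate = 1e-4, batch_size = 64L, epochs = NULL,
                       seed = 1L) {
  stopifnot(latent_dim >= 1L, kl_weight >= 0, learning_rate > 0,
            batch_size >= 1L, is.null(epochs) || epochs >= 1L)
  if (!is.null(hidden_sizes)) stopifnot(all(hidden_sizes >= 1L))
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_sizes = if (is.null(hidden_sizes)) NULL else as.integer(hidden_sizes),
                 kl_weight = kl_weight, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = if (is.null(epochs)) NULL else as.integer(epochs),
                 seed = as.integer(seed)),
            class = "vae_config")
}

# M/5 and M/10, with floors: the proportional rule is calibrated for
# 1000-locus matrices and starves the network of capacity below ~300 loci
# (measured: at M = 50 a 10/5 stack under-separates clones that a 64/32
# stack resolves cleanly)
default_hidden_sizes <- function(m) {
  c(max(64L, m %/% 5L), max(32L, m %/% 10L))
}

# fixed total-gradient-step budget: few-batch (small-N) datasets get more
# epochs, many-batch (large-N) datasets fewer
default_epochs <- function(n, batch_size, target_steps = 4800L) {
  batches <- ceiling(n / batch_size)
  min(1200L, max(150L, as.integer(ceiling(target_steps / batches))))
}

#' Masked Bernoulli reconstruction loss
#'
#' Cross-entropy between an observed binary profile and the decoder's
#' Bernoulli probabilities, summed over the observed (non-missing) loci of
#' one cell: `-sum_j [x_j log(xhat_j) + (1 - x_j) log(1 - xhat_j)]` over
#' `j` with `x_j` not `NA`. Missing entries contribute nothing, so the loss
#' is invariant to whatever value is imputed at a missing position.
#'
#' @param x integer vector over `{0, 1, NA}` (one cell's profile).
#' @param xhat numeric vector of reconstruction probabilities in (0, 1).
#' @param eps probabilities are clamped to `[eps, 1 - eps]` before taking
#'   logs (default 1e-7).
#' @return Non-negative scalar. If every entry of `x` is missing, returns 0
#'   with a warning.
#' @export
reconstruction_loss <- function(x, xhat, eps = 1e-7) {
  if (length(x) != length(xhat)) {
    stop("x and xhat must have equal length", call. = FALSE)
  }
  obs <- !is.na(x)
  if (!any(obs)) {
    warning("all entries missing; reconstruction loss is 0")
    return(0)
  }
  p <- pmin(pmax(xhat[obs], eps), 1 - eps)
  xo <- x[obs]
  -sum(xo * log(p) + (1 - xo) * log1p(-p))
}

#' Gaussian KL divergence to the standard-normal prior
#'
#' Closed form of `KL(N(mu, diag(sigma^2)) || N(0, I))`:
#' `0.5 * sum_d (mu_d^2 + sigma_d^2 - 1 - log(sigma_d^2))`.
#'
#' @param mu numeric vector of posterior means.
#' @param sigma numeric vector of posterior standard deviations (> 0).
#' @return Non-negative scalar.
#' @export
kl_term <- function(mu, sigma) {
  if (length(mu) != length(sigma)) {
    stop("mu and sigma must have equal length", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
  0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log(sigma))
}

lrelu <- function(u, slope = 0.01) {
  neg <- u < 0
  u[neg] <- u[neg] * slope
  u
}

#' Train the variational autoencoder on a mutation matrix
#'
#' Fits an encoder/decoder pair of fully connected networks by minimizing
#' the per-batch mean of
#' `kl_weight * KL(q(z|x) || N(0, I)) + reconstruction_loss(x, xhat)`.
#' The encoder maps a cell's M-dimensional binary profile (missing entries
#' fed as 0) through LeakyReLU hidden layers to a posterior mean `mu_z` and
#' log-variance per latent dimension; `z` is drawn by the reparameterization
#' trick `z = mu + sigma * epsilon`; the decoder mirrors the encoder and
#' ends in a sigmoid, giving Bernoulli probabilities per locus. Missing
#' entries are excluded from the reconstruction loss. Optimization is plain
#' RMSprop; training is deterministic given `config$seed`.
#'
#' @param data a [mutation_matrix()].
#' @param config a [vae_config()].
#' @return An object of class `trained_vae` with elements `params` (weights),
#'   `config` (with `hidden_sizes` resolved), `n_loci` and `loss_history`
#'   (mean total loss per epoch).
#' @export
train_vae <- function(data, config = vae_config()) {
  stopifnot(inherits(data, "mutation_matrix"), inherits(config, "vae_config"))
  X <- unclass(data)
  storage.mode(X) <- "double"
  n <- nrow(X)
  m <- ncol(X)
  d <- config$latent_dim
  hs <- config$hidden_sizes
  if (is.null(hs)) hs <- default_hidden_sizes(m)
  if (length(hs) != 2L) stop("exactly two hidden layers are supported", call. = FALSE)
  h1 <- hs[1L]; h2 <- hs[2L]
  lam <- config$kl_weight
  lr <- config$learning_rate
  bs <- config$batch_size
  if (is.null(config$epochs)) config$epochs <- default_epochs(n, bs)

  W <- matrix(as.double(!is.na(X)), n, m)  # observation mask
  X0 <- X; X0[is.na(X0)] <- 0              # encoder input: missing as 0

  set.seed(config$seed)
  fit <- vae_train_cpp(X0, W, h1, h2, d, lam, lr, bs, config$epochs,
                       rho = 0.9, eps = 1e-8)
  p <- fit$params
  is_bias <- startsWith(names(p), "b")
  p[is_bias] <- lapply(p[is_bias], as.vector)

  structure(list(params = p, config = config, n_loci = m,
                 hidden_sizes = hs, loss_history = as.vector(fit$loss_history)),
            class = "trained_vae")
}

#' @export
print.trained_vae <- function(x, ...) {
  cat(sprintf(
    "trained_vae: %d -> %s -> %d latent; %d epochs, final mean loss %.3f\n",
    x$n_loci, paste(x$hidden_sizes, collapse = " -> "),
    x$config$latent_dim, length(x$loss_history),
    x$loss_history[length(x$loss_history)]
  ))
  invisible(x)
}

#' Embed cells into the latent space
#'
#' Deterministically maps each cell through the trained encoder and returns
#' the posterior mean `mu_z` per cell (no sampling). Missing entries are fed
#' to the encoder as 0, matching training.
#'
#' @param data a [mutation_matrix()] with the same number of loci the model
#'   was trained on.
#' @param model a `trained_vae` from [train_vae()].
#' @return An object of class `latent_embedding`: list with `coords`
#'   (N x D numeric matrix) and `cell_ids`.
#' @export
embed_cells <- function(data, model) {
  stopifnot(inherits(data, "mutation_matrix"), inherits(model, "trained_vae"))
  if (ncol(data) != model$n_loci) {
    stop(sprintf("model was trained on %d loci but data has %d",
                 model$n_loci, ncol(data)), call. = FALSE)
  }
  X0 <- unclass(data)
  storage.mode(X0) <- "double"
  X0[is.na(X0)] <- 0
  p <- model$params
  addb <- function(mat, b) sweep(mat, 2L, b, "+")
  H1 <- lrelu(addb(X0 %*% p$We1, p$be1))
  H2 <- lrelu(addb(H1 %*% p$We2, p$be2))
  mu <- addb(H2 %*% p$Wmu, p$bmu)
  if (!all(is.finite(mu))) stop("non-finite latent coordinates", call. = FALSE)
  colnames(mu) <- paste0("z", seq_len(ncol(mu)) - 1L)
  structure(list(coords = mu, cell_ids = rownames(data)),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("latent_embedding: %d cells x %d dimensions\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}
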