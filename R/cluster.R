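#' Fit a k-component Gaussian mixture to a latent embedding
#'
#' Fits a full-covariance Gaussian mixture by EM (via \pkg{mclust}) to the
#' latent coordinates and returns the maximum-posterior component of each
#' cell together with the model's BIC, here on the "lower is better" scale
#' `BIC = -2 * logLik + p * log(N)` with `p` the number of free parameters.
#' EM is initialized from model-based hierarchical clustering, which makes
#' the fit deterministic for given data.
#'
#' @param embedding a `latent_embedding` from [embed_cells()], or a numeric
#'   matrix of coordinates.
#' @param k number of mixture components, `1 <= k <= N`.
#' @param seed integer seed (kept for interface stability; the fit itself is
#'   deterministic).
#' @param hc_init optional precomputed `mclust::hc()` initialization tree,
#'   reused across k by [select_clusters()] to avoid refitting it.
#' @param family mixture family to fit: `"VVV"` (default), `"VVV+prior"`
#'   (full covariance with mclust's conjugate-prior regularization) or
#'   `"EII+prior"` (regularized spherical); `"auto"` walks that ladder until
#'   a fit succeeds. The fallbacks exist for degenerate geometries such as
#'   zero-variance clusters of duplicated cells.
#' @return List with `labels` (N integers in `1..k`), `bic` (numeric),
#'   `family` (the family that produced the fit) and `model` (the fitted
#'   `Mclust` object).
#' @export
fit_gmm <- function(embedding, k, seed = 1L, hc_init = NULL, family = "auto") {
  coords <- if (inherits(embedding, "latent_embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  stopifnot(k >= 1L, k <= n)
  set.seed(seed)
  init <- if (is.null(hc_init)) NULL else list(hcPairs = hc_init)
  try_fit <- function(...) {
    f <- tryCatch(
      suppressWarnings(mclust::Mclust(coords, G = k, verbose = FALSE, ...)),
      error = function(e) NULL
    )
    if (is.null(f) || !is.finite(f$bic)) NULL else f
  }
  attempts <- list(
    "VVV" = function() try_fit(modelNames = "VVV", initialization = init),
    "VVV+prior" = function() try_fit(modelNames = "VVV",
                                     prior = mclust::priorControl()),
    "EII+prior" = function() try_fit(modelNames = "EII",
                                     prior = mclust::priorControl())
  )
  ladder <- if (identical(family, "auto")) names(attempts) else match.arg(family, names(attempts))
  fit <- NULL
  used <- NA_character_
  for (fam in ladder) {
    fit <- attempts[[fam]]()
    if (!is.null(fit)) {
      used <- fam
      break
    }
  }
  if (is.null(fit)) {
    stop(sprintf("degenerate Gaussian mixture fit at k = %d", k), call. = FALSE)
  }
  # mclust reports BIC as 2*logLik - p*log(N) (higher better); flip sign
  list(labels = as.integer(fit$classification), bic = -as.numeric(fit$bic),
       family = used, model = fit)
}

#' Select the number of clusters by BIC with a patience rule
#'
#' Scans k = 1, 2, 3, ... fitting a Gaussian mixture at each k, and stops
#' when the incumbent minimum BIC has not improved for `patience`
#' consecutive values of k, or when `max_clusters` is reached. Returns the
#' assignment of the k with minimum BIC; components that received no cells
#' are dropped and labels compacted to `1..K`. On equal BIC the smaller k
#' wins.
#'
#' @param embedding a `latent_embedding` or numeric coordinate matrix.
#' @param max_clusters largest k to consider (default `min(N - 1, 100)`).
#' @param patience number of consecutive non-improving k values after which
#'   the scan stops (default 10).
#' @param seed integer seed forwarded to [fit_gmm()].
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (N integers in `1..K`), `K`, `bic_trace` (data.frame of k and BIC in
#'   scan order; BIC is `NA` where the fit was degenerate), `patience` and
#'   `max_clusters`.
#' @export
select_clusters <- function(embedding, max_clusters = NULL, patience = 10L,
                            seed = 1L) {
  coords <- if (inherits(embedding, "latent_embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (is.null(max_clusters)) max_clusters <- min(n - 1L, 100L)
  max_clusters <- max(1L, min(as.integer(max_clusters), n))
  stopifnot(patience >= 1L)

  hc_init <- tryCatch(mclust::hc(coords, modelName = "VVV", use = "SVD"),
                      error = function(e) NULL)
  scan <- function(family) {
    best_bic <- Inf
    best_k <- NA_integer_
    best_labels <- NULL
    ks <- integer(0)
    bics <- numeric(0)
    fams <- character(0)
    for (k in seq_len(max_clusters)) {
      fit <- tryCatch(fit_gmm(coords, k, seed = seed, hc_init = hc_init,
                              family = family),
                      error = function(e) NULL)
      ks <- c(ks, k)
      bics <- c(bics, if (is.null(fit)) NA_real_ else fit$bic)
      fams <- c(fams, if (is.null(fit)) NA_character_ else fit$family)
      if (!is.null(fit) && fit$bic < best_bic) {  # strict improvement only
        best_bic <- fit$bic
        best_k <- k
        best_labels <- fit$labels
      }
      if (!is.na(best_k) && (k - best_k) >= patience) break
    }
    list(best_bic = best_bic, best_k = best_k, best_labels = best_labels,
         trace = data.frame(k = ks, bic = bics), families = fams)
  }

  ladder <- c("VVV", "VVV+prior", "EII+prior")
  res <- scan("auto")
  used <- unique(res$families[!is.na(res$families)])
  if (length(used) > 1L) {
    # BIC values are only comparable within one mixture family; if the
    # ladder mixed families across k (degenerate geometries), redo the scan
    # holding the most regularized family that was needed
    res <- scan(ladder[max(match(used, ladder))])
  }
  best_labels <- res$best_labels
  if (is.null(best_labels)) {
    stop("all Gaussian mixture fits were degenerate", call. = FALSE)
  }

  # drop empty components, compact labels to 1..K preserving order
  kept <- sort(unique(best_labels))
  labels <- match(best_labels, kept)
  structure(list(labels = as.integer(labels), K = length(kept),
                 bic_trace = res$trace,
                 patience = as.integer(patience),
                 max_clusters = as.integer(max_clusters),
                 best_bic = res$best_bic),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: %d cells in %d clusters (BIC %.1f; scanned k = 1..%d)\n",
    length(x$labels), x$K, x$best_bic, max(x$bic_trace$k)
  ))
  invisible(x)
}
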