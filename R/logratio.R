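#' Centred log-ratio transform
#'
#' Maps a vector of strictly positive proportions (or any positive vector —
#' the transform is invariant to the overall scale) to adjusted
#' log-proportions: component-wise logarithms minus their mean, so the
#' transformed vector always sums to zero. This removes the uninformative
#' "total amount" direction of compositional data and places relative
#' expression values in a Euclidean space where differences are log fold
#' changes. With base-2 logarithms a unit of z is a two-fold change.
#'
#' @param p A positive vector of length D >= 2, or a D x n matrix whose
#'   columns are transformed independently (e.g. posterior draws from
#'   [sample_posterior()]).
#' @param log_base Logarithm base (default 2).
#' @return A vector or matrix of the same shape; each vector/column sums
#'   to 0.
#' @examples
#' clr_transform(c(1 / 2, 1 / 4, 1 / 4))        # c(2/3, -1/3, -1/3)
#' clr_transform(10 * c(1 / 2, 1 / 4, 1 / 4))   # identical: scale-invariant
#' @export
clr_transform <- function(p, log_base = 2) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, ncol = 1L) else as.matrix(p)
  if (nrow(m) < 2L) abort("the transform needs at least two components (D >= 2)")
  if (anyNA(m) || any(m <= 0)) abort("all components must be strictly positive")
  lg <- log(m) / log(log_base)
  z <- sweep(lg, 2L, colMeans(lg))
  if (vec) drop(z) else z
}

#' Orthonormal basis of the sum-zero subspace
#'
#' Returns a D x (D-1) matrix whose columns are an orthonormal (Helmert)
#' basis of the hyperplane of vectors summing to zero. Projecting centred
#' log-ratio vectors onto it gives the (D-1)-dimensional isometric log-ratio
#' coordinates; the projection preserves Euclidean distances between
#' transformed vectors.
#'
#' @param D Number of components (>= 2).
#' @return A D x (D-1) matrix `V` with `t(V) %*% V = I` and `colSums(V) = 0`.
#' @export
ilr_basis <- function(D) {
  if (D < 2L) abort("D must be >= 2")
  V <- stats::contr.helmert(D)
  sweep(V, 2L, sqrt(colSums(V^2)), "/")
}

#' Isometric log-ratio coordinates
#'
#' Composition of [clr_transform()] with projection onto [ilr_basis()]. The
#' per-gene statistics of the pipeline are defined on the sum-zero vectors
#' themselves; this projection is provided for analyses that need linearly
#' independent coordinates.
#'
#' @inheritParams clr_transform
#' @return A (D-1)-vector, or (D-1) x n matrix for matrix input.
#' @export
ilr_transform <- function(p, log_base = 2) {
  z <- clr_transform(p, log_base = log_base)
  vec <- is.null(dim(z))
  m <- if (vec) matrix(z, ncol = 1L) else z
  out <- crossprod(ilr_basis(nrow(m)), m)
  if (vec) drop(out) else out
}

#' Closed-form moments of the transformed Dirichlet posterior
#'
#' For `q ~ Dirichlet(alpha)` the log-proportions have (natural-log) moments
#' `E[ln q_i] = psi(alpha_i) - psi(alpha0)` and
#' `Cov[ln q_i, ln q_j] = psi'(alpha_i) d_ij - psi'(alpha0)`, where `psi` and
#' `psi'` are the digamma and trigamma functions and `d_ij` the Kronecker
#' delta. Centring with `H = I - J/D` gives the moments of the sum-zero
#' vector z: the rank-one `-psi'(alpha0)` term is annihilated, leaving
#' `mean_z = H E[ln q]` and `cov_z = H diag(psi'(alpha)) H`, converted to the
#' requested log base. Because `psi'(x)` is roughly `1/x`, the off-diagonal
#' covariance decays inversely with both the total read count and the number
#' of genes: for thousands of genes the induced covariance is effectively
#' zero.
#'
#' @param params A `dirichlet_params` object (or a count vector, for which
#'   the default prior is applied).
#' @param log_base Logarithm base for the reported moments (default 2).
#' @return A list of class `clr_moments`: `mean` (sums to 0), `cov`
#'   (symmetric PSD, rows sum to 0), `log_base`.
#' @export
clr_moments <- function(params, log_base = 2) {
  if (!inherits(params, "dirichlet_params")) params <- posterior_alpha(params)
  alpha <- params$alpha
  D <- length(alpha)
  m_ln <- digamma(alpha) - digamma(params$alpha0)
  v_ln <- trigamma(alpha)
  mean_z <- m_ln - mean(m_ln)
  # H diag(v) H expanded: no D x D intermediates beyond the result itself
  cov_z <- diag(v_ln, nrow = D)
  cov_z <- cov_z - matrix(v_ln / D, D, D) - matrix(v_ln / D, D, D, byrow = TRUE) +
    mean(v_ln) / D
  lb2 <- log(log_base)^2
  structure(list(mean = mean_z / log(log_base), cov = cov_z / lb2, log_base = log_base),
            class = "clr_moments")
}

#' @export
print.clr_moments <- function(x, ...) {
  cat("Centred log-ratio moments (base", x$log_base, "log),", length(x$mean),
      "components\n")
  cat("  mean range:", paste(format(range(x$mean), digits = 4), collapse = " .. "), "\n")
  cat("  var  range:", paste(format(range(diag(x$cov)), digits = 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Sampling-variance envelope for a pair of technical replicates
#'
#' The diagnostic behind the question "is the difference between two
#' technical replicates explained by count sampling variation alone?". For
#' each gene the distribution of `z1 - z2` — one centred log-ratio draw from
#' each replicate's Dirichlet posterior — is summarised by its `probs`
#' quantile range (the expected difference envelope) together with the
#' observed difference of posterior median z between the replicates. A gene
#' is inside the envelope when the range covers zero, i.e. when sampling
#' variation accounts for the observed difference; with the default 1-99%
#' range about 98% of genes from a pure technical-replication process fall
#' inside, by construction of the quantile pair. Genes with low counts have
#' much wider envelopes than well-covered genes.
#'
#' @param counts_rep1,counts_rep2 Equal-length non-negative integer count
#'   vectors for the two replicates.
#' @param prior_mass Dirichlet prior mass per gene (default 0.5).
#' @param n_mc Paired posterior draws per replicate (default 2000).
#' @param probs Lower/upper quantiles of the envelope (default `c(0.01, 0.99)`).
#' @param log_base Logarithm base (default 2).
#' @param seed Optional integer seed.
#' @return A tibble with one row per gene: `gene`, `A` (median expression,
#'   pooled over both replicates' draws), `observed` (difference of posterior
#'   median z, replicate 1 minus replicate 2), `lo`, `hi` (envelope), and
#'   `inside`.
#' @export
sampling_variance_envelope <- function(counts_rep1, counts_rep2, prior_mass = 0.5,
                                       n_mc = 2000, probs = c(0.01, 0.99),
                                       log_base = 2, seed = NULL) {
  if (length(counts_rep1) != length(counts_rep2)) {
    abort("replicate count vectors must have equal length")
  }
  if (length(probs) != 2L || any(probs <= 0) || any(probs >= 1) || probs[1] >= probs[2]) {
    abort("probs must be an increasing pair inside (0, 1)")
  }
  genes <- names(counts_rep1)
  if (is.null(genes)) genes <- paste0("g", seq_along(counts_rep1))
  z1 <- clr_posterior_draws(counts_rep1, prior_mass, n_mc, seed, "envelope/rep1", log_base)
  z2 <- clr_posterior_draws(counts_rep2, prior_mass, n_mc, seed, "envelope/rep2", log_base)
  d <- z1 - z2
  qs <- row_quantiles(d, probs)
  obs <- row_medians(z1) - row_medians(z2)
  tibble::tibble(
    gene = genes,
    A = row_medians(cbind(z1, z2)),
    observed = obs,
    lo = qs[, 1],
    hi = qs[, 2],
    inside = qs[, 1] <= 0 & qs[, 2] >= 0
  )
}
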