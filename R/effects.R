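# The per-gene Monte-Carlo machinery: within-condition mixtures, the
# between-condition difference delta_A, the within-condition difference
# delta_W, the per-realization effect size delta_R = delta_A / delta_W, and
# the symmetric quantile-of-zero statistic zeta.

check_z_list <- function(z, what) {
  if (!is.list(z) || length(z) < 2L) abort(paste0(what, " needs a list of >= 2 replicate draw matrices"))
  z <- lapply(z, function(m) if (is.null(dim(m))) matrix(m, nrow = 1L) else as.matrix(m))
  dims <- vapply(z, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort(paste0(what, ": all replicates must have the same genes and the same n_mc"))
  }
  z
}

# pick z[[r[i]]][, i] for every MC index i
mixture_pick <- function(z, r) {
  out <- z[[1L]]
  for (j in seq_along(z)[-1L]) {
    sel <- r == j
    if (any(sel)) out[, sel] <- z[[j]][, sel, drop = FALSE]
  }
  out[, r == 1L] <- z[[1L]][, r == 1L, drop = FALSE]
  out
}

#' Within-condition mixture of replicate posteriors
#'
#' Pools the centred log-ratio posterior draws of a condition's replicates
#' into one distribution per gene, as if the replicates were components of an
#' equal-weight mixture: for each Monte-Carlo index one replicate is chosen
#' uniformly at random and its draw taken. The mixture carries both the
#' posterior (count-sampling) uncertainty of each replicate and the spread
#' between replicates.
#'
#' @param z A list (>= 2) of D x n_mc draw matrices, one per replicate of a
#'   single condition (see [clr_transform()]).
#' @param seed Optional integer seed for the replicate choices.
#' @return A D x n_mc matrix of mixture draws.
#' @export
within_mixture <- function(z, seed = NULL) {
  z <- check_z_list(z, "within_mixture")
  n_mc <- ncol(z[[1L]])
  r <- with_stream(seed, "mixture", sample.int(length(z), n_mc, replace = TRUE))
  mixture_pick(z, r)
}

#' Between-condition difference draws (delta_A)
#'
#' Per Monte-Carlo index, the difference between one draw from each
#' condition's within-condition mixture: first condition minus second. Its
#' per-gene median is the reported between-condition log fold change M.
#'
#' @param mix1,mix2 D x n_mc mixture matrices from [within_mixture()] for the
#'   two conditions (first = numerator of the fold change).
#' @return A D x n_mc matrix of difference draws.
#' @export
between_difference <- function(mix1, mix2) {
  if (!identical(dim(mix1), dim(mix2))) abort("mixture matrices must have identical dimensions")
  mix1 - mix2
}

# one within-condition difference draw matrix for a list of replicates
condition_within_diff <- function(z, n_mc, seed, tag) {
  k <- length(z)
  if (k == 2L) return(z[[1L]] - z[[2L]])
  pair <- with_stream(seed, tag, {
    a <- sample.int(k, n_mc, replace = TRUE)
    b <- sample.int(k - 1L, n_mc, replace = TRUE)
    list(a = a, b = b + (b >= a))
  })
  mixture_pick(z, pair$a) - mixture_pick(z, pair$b)
}

#' Within-condition difference draws (delta_W)
#'
#' Per Monte-Carlo index and condition, two distinct replicates are chosen
#' uniformly at random and their draws subtracted; delta_W is the absolute
#' difference of greatest magnitude across the two conditions. The max
#' operator makes it a deliberately conservative surrogate for the pooled
#' within-condition dispersion. Realizations are strictly positive with
#' probability one; an exact floating-point zero (possible only for
#' degenerate constant input) is re-drawn once and, if it persists, the gene
#' is flagged in the `"degenerate"` attribute.
#'
#' @param z1,z2 Lists (>= 2 each) of D x n_mc replicate draw matrices for the
#'   two conditions.
#' @param seed Optional integer seed for the pair choices.
#' @return A D x n_mc matrix of positive draws, with a logical per-gene
#'   attribute `degenerate`.
#' @export
within_difference <- function(z1, z2, seed = NULL) {
  z1 <- check_z_list(z1, "within_difference")
  z2 <- check_z_list(z2, "within_difference")
  if (!identical(dim(z1[[1L]]), dim(z2[[1L]]))) {
    abort("the two conditions must have the same genes and the same n_mc")
  }
  n_mc <- ncol(z1[[1L]])
  dw <- pmax(abs(condition_within_diff(z1, n_mc, seed, "pairs1")),
             abs(condition_within_diff(z2, n_mc, seed, "pairs2")))
  if (any(dw == 0)) {
    retry <- pmax(abs(condition_within_diff(z1, n_mc, seed, "pairs1/retry")),
                  abs(condition_within_diff(z2, n_mc, seed, "pairs2/retry")))
    zero <- dw == 0
    dw[zero] <- retry[zero]
  }
  attr(dw, "degenerate") <- rowSums(dw == 0) > 0
  dw
}

#' Per-realization effect size (delta_R)
#'
#' The relative effect size is the ratio of a single realization of the
#' between-condition difference to the *same* Monte-Carlo index's
#' within-condition difference — never a ratio of summaries, because the
#' median of a ratio can differ substantially from the ratio of medians.
#'
#' @param delta_a,delta_w Paired draw matrices (or vectors) of equal shape.
#' @return `delta_a / delta_w`, element-wise.
#' @examples
#' effect_ratio(c(2, 4), c(1, 8))           # c(2, 0.5): median 1.25,
#' median(c(2, 4)) / median(c(1, 8))        # while the ratio of medians is 0.667
#' @export
effect_ratio <- function(delta_a, delta_w) {
  if (!identical(dim(delta_a), dim(delta_w)) || length(delta_a) != length(delta_w)) {
    abort("delta_a and delta_w must be paired draw-for-draw (equal shapes)")
  }
  delta_a / delta_w
}

#' Symmetric quantile of zero (zeta)
#'
#' For a distribution of between-condition difference draws, `F` is the
#' fraction of draws at or below zero and `zeta = min(F, 1 - F)`, so
#' `zeta` is in `[0, 0.5]`. Small values mean the difference distribution
#' rarely crosses zero — the sign of the change is unambiguous; 0.5 means
#' the distribution straddles zero evenly.
#'
#' @param delta_a A numeric vector of draws, or a D x n_mc matrix (one row of
#'   draws per gene).
#' @return A scalar, or a per-gene vector for matrix input.
#' @examples
#' zeta_stat(c(1, 2, 3, 4))      # 0: all one sign
#' zeta_stat(c(-1, -2, 1, 2))    # 0.5: symmetric about zero
#' @export
zeta_stat <- function(delta_a) {
  if (is.null(dim(delta_a))) {
    if (!length(delta_a)) abort("delta_a must be non-empty")
    f <- mean(delta_a <= 0)
  } else {
    f <- rowMeans(delta_a <= 0)
  }
  pmin(f, 1 - f)
}

#' Differential-expression decision rule
#'
#' A gene is called differential when the magnitude of its median effect size
#' `E` reaches `effect_cutoff` *and* its `zeta` is at most `zeta_cutoff`.
#' An effect cutoff of 1.5 is the minimum practical threshold; 2.0 is a
#' conservative choice. The zeta cutoff defaults to 0.01 (0.01 and 0.001
#' behave very similarly; larger values admit many genes whose
#' within-condition variation rivals the between-condition change).
#'
#' @param results A result tibble (from [tidy()] on a fit) with columns `E`
#'   and `zeta`.
#' @param effect_cutoff Positive effect-size threshold (default 1.5).
#' @param zeta_cutoff Positive zeta threshold (default 0.01).
#' @return A logical vector, one entry per row of `results`.
#' @export
call_differential <- function(results, effect_cutoff = 1.5, zeta_cutoff = 0.01) {
  if (!is.numeric(effect_cutoff) || effect_cutoff <= 0) abort("effect_cutoff must be positive")
  if (!is.numeric(zeta_cutoff) || zeta_cutoff <= 0) abort("zeta_cutoff must be positive")
  results <- tibble::as_tibble(results)
  if (!all(c("E", "zeta") %in% names(results))) abort("results must have columns E and zeta")
  abs(results$E) >= effect_cutoff & results$zeta <= zeta_cutoff
}

quantile_label <- function(p) {
  pc <- 100 * p
  if (isTRUE(all.equal(pc, round(pc)))) sprintf("q%02d", as.integer(round(pc)))
  else paste0("q", format(pc, trim = TRUE))
}

#' Fit the Dirichlet Monte-Carlo differential expression model
#'
#' Runs the full pipeline on a two-condition count table: per-sample
#' Dirichlet posterior draws of transcript proportions, centred log-ratio
#' transform, within-condition mixtures, the between- (`delta_A`), within-
#' (`delta_W`) and relative (`delta_R`) difference distributions, their
#' robust (median and quantile) summaries, the zeta statistic, and the
#' differential call. All summaries are medians, never means. Given a seed
#' the result is fully deterministic, and invariant to permutations of the
#' gene rows and sample columns.
#'
#' The first condition label appearing in the design is the numerator:
#' positive `M`/`E` means higher expression in that condition. Exchanging the
#' two groups negates `M` and `E` realization-for-realization and leaves
#' `W`, `zeta` and `A` unchanged.
#'
#' @param counts A count tibble ([read_counts()]), data frame (first column
#'   gene ids) or integer matrix with gene rownames; genes in rows, samples
#'   in columns.
#' @param design A design tibble ([read_design()]), named label vector, or
#'   unnamed label vector in column order; exactly two conditions with >= 2
#'   samples each.
#' @param n_mc Monte-Carlo instances per sample (default 128; raise it when
#'   tight zeta resolution matters — zeta granularity is `1/n_mc`).
#' @param prior_mass Dirichlet prior mass per gene (default 0.5, the Jeffreys
#'   multinomial prior).
#' @param log_base Logarithm base for all expression values (default 2: units
#'   are two-fold changes).
#' @param effect_cutoff Effect-size threshold for the call (default 1.5).
#' @param zeta_cutoff Zeta threshold for the call (default 0.01).
#' @param conservative Use the conservative effect cutoff 2.0 instead of
#'   `effect_cutoff`.
#' @param quantiles Extra quantiles (besides the median) reported for the
#'   `delta_A`, `delta_W` and `delta_R` distributions; `NULL` for none.
#' @param seed Integer seed making the fit reproducible; `NULL` draws one
#'   from the session RNG (recorded in the fit).
#' @param drop_zero_genes Drop genes with zero counts in every sample instead
#'   of retaining them (they are always flagged via `all_zero`; the prior
#'   keeps their posterior proper, and a zero may mean "not expressed" or
#'   merely "below the detection depth").
#' @return An object of class `ddex`; see [tidy.ddex()] for the per-gene
#'   table and [glance.ddex()] for the one-row summary.
#' @examples
#' cts <- tibble::tibble(
#'   gene = paste0("g", 1:6),
#'   a1 = c(120L, 40L, 5L, 300L, 0L, 80L),
#'   a2 = c(110L, 36L, 8L, 280L, 0L, 90L),
#'   b1 = c(30L, 42L, 6L, 290L, 0L, 85L),
#'   b2 = c(25L, 38L, 4L, 310L, 0L, 78L)
#' )
#' fit <- ddex(cts, c("A", "A", "B", "B"), n_mc = 64, seed = 1)
#' tidy(fit)
#' @export
ddex <- function(counts, design, n_mc = 128, prior_mass = 0.5, log_base = 2,
                 effect_cutoff = 1.5, zeta_cutoff = 0.01, conservative = FALSE,
                 quantiles = c(0.01, 0.99), seed = NULL, drop_zero_genes = FALSE) {
  counts <- validate_counts(counts)
  design <- validate_design(design, counts)
  if (!is.numeric(n_mc) || n_mc < 1) abort("n_mc must be >= 1")
  n_mc <- as.integer(n_mc)
  effect_eff <- if (isTRUE(conservative)) 2.0 else effect_cutoff
  if (effect_eff <= 0 || zeta_cutoff <= 0) abort("cutoffs must be positive")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  seed <- as.integer(seed)

  parts <- count_parts(counts)
  all_zero <- unname(rowSums(parts$mat) == 0)
  keep <- if (isTRUE(drop_zero_genes)) !all_zero else rep(TRUE, length(parts$genes))
  if (sum(keep) < 2L) abort("fewer than two genes left to analyse")
  mat <- parts$mat[keep, , drop = FALSE]
  genes <- parts$genes[keep]

  # work in sorted-gene order so results do not depend on input row order
  ord <- order(genes)
  mat <- mat[ord, , drop = FALSE]
  genes_s <- genes[ord]

  lev <- unique(design$condition)
  samp <- lapply(lev, function(l) sort(design$sample[design$condition == l]))
  names(samp) <- lev

  z <- lapply(setNames(nm = design$sample), function(sid) {
    clr_posterior_draws(mat[, sid], prior_mass, n_mc, seed,
                        paste0("posterior/", sid), log_base)
  })

  mix <- lapply(lev, function(l) {
    within_mixture(z[samp[[l]]], seed = substream_seed(seed, paste0("mixture/", condition_tag(samp[[l]]))))
  })
  dA <- between_difference(mix[[1L]], mix[[2L]])
  dW <- within_difference(z[samp[[1L]]], z[samp[[2L]]],
                          seed = substream_seed(seed, paste0(
                            "within/", condition_tag(design$sample))))
  degenerate <- attr(dW, "degenerate")
  dR <- effect_ratio(dA, unclass(dW))

  res <- tibble::tibble(gene = genes_s)
  for (sid in unlist(samp)) res[[paste0("med_", sid)]] <- row_medians(z[[sid]])
  res[[paste0("med_", lev[1L])]] <- row_medians(mix[[1L]])
  res[[paste0("med_", lev[2L])]] <- row_medians(mix[[2L]])
  res$A <- row_medians(cbind(mix[[1L]], mix[[2L]]))
  res$M <- row_medians(dA)
  res$E <- row_medians(dR)
  res$W <- row_medians(dW)
  res$zeta <- zeta_stat(dA)
  if (!is.null(quantiles) && length(quantiles)) {
    for (nm in c("M", "E", "W")) {
      src <- switch(nm, M = dA, E = dR, W = dW)
      qs <- row_quantiles(src, quantiles)
      for (j in seq_along(quantiles)) {
        res[[paste0(nm, "_", quantile_label(quantiles[j]))]] <- qs[, j]
      }
    }
  }
  if (any(degenerate)) {
    res$E[degenerate] <- 0
    res$zeta[degenerate] <- 0.5
  }
  res$all_zero <- all_zero[keep][ord]
  res$degenerate <- degenerate
  res$called <- call_differential(res, effect_eff, zeta_cutoff) & !degenerate

  # restore the caller's gene order
  res <- res[match(genes, genes_s), ]

  structure(list(
    results = res,
    conditions = lev,
    design = design,
    config = list(n_mc = n_mc, prior_mass = prior_mass, log_base = log_base,
                  effect_cutoff = effect_eff, zeta_cutoff = zeta_cutoff,
                  quantiles = quantiles %||% numeric(0), seed = seed,
                  drop_zero_genes = isTRUE(drop_zero_genes))
  ), class = "ddex")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ddex <- function(x, ...) {
  g <- glance(x)
  cat("Dirichlet Monte-Carlo differential expression fit\n")
  cat(sprintf("  %d genes x %d samples (%s vs %s), n_mc = %d, prior = %g, seed = %d\n",
              g$n_genes, g$n_samples, x$conditions[1], x$conditions[2],
              g$n_mc, x$config$prior_mass, g$seed))
  cat(sprintf("  called differential: %d (|E| >= %g and zeta <= %g)\n",
              g$n_called, x$config$effect_cutoff, x$config$zeta_cutoff))
  invisible(x)
}

#' Tidy a differential expression fit
#'
#' @param x A `ddex` object.
#' @param ... Unused.
#' @return The per-gene result tibble: per-sample and per-condition median
#'   expression (`med_*`), overall median expression `A`, median
#'   between-condition difference `M`, median effect size `E`, median
#'   within-condition difference `W`, `zeta`, requested extra quantiles, the
#'   `all_zero`/`degenerate` flags and the boolean `called`.
#' @export
tidy.ddex <- function(x, ...) x$results

#' One-row summary of a differential expression fit
#'
#' @param x A `ddex` object.
#' @param ... Unused.
#' @return A one-row tibble: gene/sample counts, conditions, n_mc, cutoffs,
#'   number of genes called, seed.
#' @export
glance.ddex <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_samples = nrow(x$design),
    condition_1 = x$conditions[1],
    condition_2 = x$conditions[2],
    n_mc = x$config$n_mc,
    effect_cutoff = x$config$effect_cutoff,
    zeta_cutoff = x$config$zeta_cutoff,
    n_called = sum(x$results$called),
    seed = x$config$seed
  )
}
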