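# Synthetic data: a heavy-tailed count backbone standing in for a deeply
# sequenced bacterial transcriptome, spike-in genes with known fold
# differences, Dirichlet technical replicates, and the true/false-positive
# harness built from them.

#' Generate a heavy-tailed synthetic count backbone
#'
#' One sample's worth of per-gene read counts: log-normal expression
#' intensities (heavy-tailed, like a real transcriptome where a handful of
#' genes dominate the library) scaled to the requested sequencing depth by a
#' single multinomial draw, plus a small fraction of genes forced to zero
#' (real backbones of ~5400 coding sequences carry some tens of zero-read
#' genes).
#'
#' @param n_genes Number of genes (>= 100).
#' @param depth Total read count (>= 10 * n_genes).
#' @param meanlog,sdlog Log-normal intensity parameters (defaults 0 and 2;
#'   `sdlog = 2` gives a max/median count ratio well above 50 at thousands of
#'   genes).
#' @param zero_fraction Fraction of genes forced to zero intensity
#'   (default 0.01).
#' @param seed Optional integer seed.
#' @return A named integer vector (`bg0001`, ...) summing to `depth`.
#' @export
make_backbone <- function(n_genes, depth, meanlog = 0, sdlog = 2,
                          zero_fraction = 0.01, seed = NULL) {
  if (n_genes < 100) abort("n_genes must be >= 100")
  if (depth < 10 * n_genes) abort("depth must be at least 10 * n_genes")
  if (zero_fraction < 0 || zero_fraction >= 1) abort("zero_fraction must be in [0, 1)")
  counts <- with_stream(seed, "backbone", {
    lam <- rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
    n_zero <- round(zero_fraction * n_genes)
    if (n_zero > 0) lam[sample.int(n_genes, n_zero)] <- 0
    as.vector(rmultinom(1L, size = depth, prob = lam / sum(lam)))
  })
  setNames(as.integer(counts), sprintf("bg%05d", seq_len(n_genes)))
}

#' Append spike-in genes with known fold differences
#'
#' Builds the two condition templates of the spike-in design: two sets of
#' genes with the given base counts are appended to the backbone; set 1 is
#' multiplied by the fold difference in condition 1 and set 2 in condition 2
#' (a symmetric design, so both directions of change are represented). The
#' default base counts are 1..1024 in two-fold increments (11 genes per set,
#' 22 spiked genes). Fold-multiplied counts are rounded half-to-even, so a
#' fold of 1.1 at base count 1 stays at 1 — a designed hard case at the
#' method's low-count floor.
#'
#' @param backbone Named non-negative integer vector (see [make_backbone()]).
#' @param fold Positive fold difference(s), recycled over `base_counts`
#'   (typical range 1.1 to 10).
#' @param base_counts Base counts of the spiked genes (default `2^(0:10)`).
#' @return A list of class `spike_in`: `template` (tibble with `gene`,
#'   `cond1`, `cond2` counts) and `truth` (tibble with `gene`, `spiked`,
#'   `set`, `base_count`, `fold`, `boosted_in`).
#' @export
spike_in <- function(backbone, fold, base_counts = 2^(0:10)) {
  if (any(fold <= 0)) abort("fold must be positive")
  if (any(base_counts < 1)) abort("base_counts must be >= 1")
  fold <- rep_len(fold, length(base_counts))
  if (is.null(names(backbone))) names(backbone) <- sprintf("bg%05d", seq_along(backbone))
  nb <- length(base_counts)
  s1 <- sprintf("spike1_%04d", base_counts)
  s2 <- sprintf("spike2_%04d", base_counts)
  boosted <- as.integer(round(base_counts * fold))
  template <- tibble::tibble(
    gene = c(names(backbone), s1, s2),
    cond1 = c(as.integer(backbone), boosted, as.integer(base_counts)),
    cond2 = c(as.integer(backbone), as.integer(base_counts), boosted)
  )
  truth <- tibble::tibble(
    gene = template$gene,
    spiked = c(rep(FALSE, length(backbone)), rep(TRUE, 2L * nb)),
    set = c(rep(NA_integer_, length(backbone)), rep(1:2, each = nb)),
    base_count = c(rep(NA_real_, length(backbone)), rep(base_counts, 2L)),
    fold = c(rep(NA_real_, length(backbone)), rep(fold, 2L)),
    boosted_in = c(rep(NA_character_, length(backbone)),
                   rep(c("cond1", "cond2"), each = nb))
  )
  structure(list(template = template, truth = truth), class = "spike_in")
}

#' Simulate a technical replicate of a count vector
#'
#' Models repeat measurement of the same library. Two variance models are
#' offered: `"multinomial"` draws a proportion vector from the Dirichlet
#' posterior of the template and then resamples reads multinomially at the
#' requested depth (Dirichlet-multinomial: proportion uncertainty plus
#' counting noise — the model of a resequenced library); `"dirichlet"`
#' scales a single Dirichlet draw to the depth and rounds (pure proportion
#' resampling, the variance model the spike-in harness uses for its
#' replicates).
#'
#' @param counts Non-negative integer template vector.
#' @param depth Total reads of the replicate (default: same as the template).
#' @param prior_mass Dirichlet prior mass per gene (default 0.5).
#' @param method `"multinomial"` (Dirichlet-multinomial) or `"dirichlet"`.
#' @param seed Optional integer seed; the same seed reproduces the replicate.
#' @return A named integer vector of the same length.
#' @export
technical_replicate <- function(counts, depth = sum(counts), prior_mass = 0.5,
                                method = c("multinomial", "dirichlet"), seed = NULL) {
  method <- match.arg(method)
  if (!length(counts)) abort("counts must be non-empty")
  if (depth < 1) abort("depth must be >= 1")
  rep <- with_stream(seed, paste0("techrep/", method), {
    g <- rgamma(length(counts), shape = counts + prior_mass)
    p <- g / sum(g)
    if (method == "multinomial") as.vector(rmultinom(1L, size = depth, prob = p))
    else as.integer(round(depth * p))
  })
  setNames(as.integer(rep), names(counts))
}

#' Simulate a complete two-condition spike-in experiment
#'
#' Composes [make_backbone()], [spike_in()] and [technical_replicate()] into
#' a ready-to-fit dataset: a backbone plus 22 spiked genes, with
#' `n_replicates` technical replicates per condition drawn at the template
#' depth.
#'
#' @inheritParams make_backbone
#' @inheritParams spike_in
#' @param n_replicates Technical replicates per condition (default 2).
#' @param replicate_method Variance model for the replicates (see
#'   [technical_replicate()]); the harness default is `"dirichlet"`.
#' @param prior_mass Dirichlet prior mass used by the replicate sampler.
#' @param seed Optional integer seed.
#' @return A list: `counts` (tibble, `gene` + one column per sample named
#'   `<cond>_rep<i>`), `design` (tibble), `truth` (tibble as in
#'   [spike_in()]).
#' @export
simulate_experiment <- function(n_genes = 5358, depth = 1e6, fold = 2,
                                base_counts = 2^(0:10), n_replicates = 2,
                                replicate_method = c("dirichlet", "multinomial"),
                                prior_mass = 0.5, meanlog = 0, sdlog = 2,
                                zero_fraction = 0.01, seed = NULL) {
  replicate_method <- match.arg(replicate_method)
  bb <- make_backbone(n_genes, depth, meanlog, sdlog, zero_fraction,
                      seed = if (is.null(seed)) NULL else substream_seed(seed, "sim/backbone"))
  sp <- spike_in(bb, fold, base_counts)
  templates <- list(cond1 = setNames(sp$template$cond1, sp$template$gene),
                    cond2 = setNames(sp$template$cond2, sp$template$gene))
  counts <- tibble::tibble(gene = sp$template$gene)
  design <- tibble::tibble(sample = character(0), condition = character(0))
  for (cond in names(templates)) {
    for (r in seq_len(n_replicates)) {
      sid <- paste0(cond, "_rep", r)
      counts[[sid]] <- technical_replicate(
        templates[[cond]], depth = sum(templates[[cond]]), prior_mass = prior_mass,
        method = replicate_method,
        seed = if (is.null(seed)) NULL else substream_seed(seed, paste0("sim/", sid)))
      design <- dplyr::bind_rows(design, tibble::tibble(sample = sid, condition = cond))
    }
  }
  list(counts = counts, design = design, truth = sp$truth)
}

#' Expected false positives per trial from a per-gene rate
#'
#' Converts a per-gene false-positive rate into the expected number of
#' false-positive identifications in one trial: `rate * n_genes`. A rate of
#' 0.0002 on a 5358-gene dataset corresponds to about one false positive per
#' trial.
#'
#' @param rate Per-gene false-positive rate.
#' @param n_genes Number of (null) genes per trial.
#' @return Expected false positives per trial.
#' @export
expected_false_positives <- function(rate, n_genes) rate * n_genes

#' Spike-in true/false-positive harness
#'
#' The full simulation study: for each trial a fresh backbone is spiked with
#' 22 known differential genes, technical replicates are drawn for two
#' conditions, the pipeline is fitted, and the calls are scored against the
#' truth at one or more effect cutoffs (a stricter cutoff can only remove
#' calls, so counts are nested by construction). Folds are cycled across
#' trials.
#'
#' @param trials Number of simulation trials (default 100).
#' @param folds Fold differences cycled over trials (default
#'   `c(1.1, 1.5, 2, 5, 10)`).
#' @param base_counts Spike-in base counts (default `2^(0:10)`).
#' @param n_genes,depth Backbone size and depth (defaults 5358 and 1e6).
#' @param n_mc Monte-Carlo instances per sample for each fit (default 1000;
#'   the zeta cutoff of 0.01 needs resolution well below 1/n_mc).
#' @param prior_mass,zeta_cutoff,replicate_method,seed As elsewhere.
#' @param effect_cutoffs Effect cutoffs scored per trial (default
#'   `c(1.5, 2)`).
#' @return An object of class `ddex_harness`: `calls` (one row per trial x
#'   cutoff: `fp`, `fp_rate`, `tp`, ...), `spikes` (per-spiked-gene call
#'   records) and `config`. See [tidy.ddex_harness()] and
#'   [glance.ddex_harness()].
#' @export
run_harness <- function(trials = 100, folds = c(1.1, 1.5, 2, 5, 10),
                        base_counts = 2^(0:10), n_genes = 5358, depth = 1e6,
                        n_mc = 1000, prior_mass = 0.5, effect_cutoffs = c(1.5, 2),
                        zeta_cutoff = 0.01,
                        replicate_method = c("dirichlet", "multinomial"),
                        seed = NULL) {
  if (trials < 1) abort("trials must be >= 1")
  replicate_method <- match.arg(replicate_method)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  calls <- vector("list", trials)
  spikes <- vector("list", trials)
  for (i in seq_len(trials)) {
    fold <- folds[(i - 1L) %% length(folds) + 1L]
    sim <- simulate_experiment(n_genes = n_genes, depth = depth, fold = fold,
                               base_counts = base_counts,
                               replicate_method = replicate_method,
                               prior_mass = prior_mass,
                               seed = substream_seed(seed, paste0("harness/trial/", i)))
    fit <- ddex(sim$counts, sim$design, n_mc = n_mc, prior_mass = prior_mass,
                effect_cutoff = min(effect_cutoffs), zeta_cutoff = zeta_cutoff,
                quantiles = NULL,
                seed = substream_seed(seed, paste0("harness/fit/", i)))
    res <- fit$results
    truth <- sim$truth
    null_genes <- !truth$spiked
    calls[[i]] <- purrr::map_dfr(effect_cutoffs, function(ec) {
      called <- call_differential(res, ec, zeta_cutoff)
      tibble::tibble(
        trial = i, fold = fold, effect_cutoff = ec,
        n_null = sum(null_genes), fp = sum(called & null_genes),
        fp_rate = sum(called & null_genes) / sum(null_genes),
        n_spiked = sum(truth$spiked), tp = sum(called & truth$spiked)
      )
    })
    spikes[[i]] <- purrr::map_dfr(effect_cutoffs, function(ec) {
      called <- call_differential(res, ec, zeta_cutoff)
      tibble::tibble(
        trial = i, fold = fold, effect_cutoff = ec,
        gene = truth$gene[truth$spiked],
        base_count = truth$base_count[truth$spiked],
        called = called[truth$spiked]
      )
    })
  }
  structure(list(
    calls = dplyr::bind_rows(calls),
    spikes = dplyr::bind_rows(spikes),
    config = list(trials = trials, folds = folds, base_counts = base_counts,
                  n_genes = n_genes, depth = depth, n_mc = n_mc,
                  prior_mass = prior_mass, effect_cutoffs = effect_cutoffs,
                  zeta_cutoff = zeta_cutoff, replicate_method = replicate_method,
                  seed = seed)
  ), class = "ddex_harness")
}

#' @export
print.ddex_harness <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Spike-in harness: %d trials, %d genes, depth %g\n",
              x$config$trials, x$config$n_genes, x$config$depth))
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  effect >= %-4g mean FP/trial = %.3f (per-gene rate %.2e), overall TPR = %.3f\n",
                g$effect_cutoff[i], g$mean_fp[i], g$mean_fp_rate[i], g$tpr[i]))
  }
  invisible(x)
}

#' True-positive rates of a harness run
#'
#' @param x A `ddex_harness` object.
#' @param ... Unused.
#' @return A tibble with the true-positive rate per (fold, base count,
#'   effect cutoff) across the trials that used that fold.
#' @export
tidy.ddex_harness <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$spikes, .data$fold, .data$base_count, .data$effect_cutoff),
    n_trials = dplyr::n_distinct(.data$trial),
    tpr = mean(.data$called),
    .groups = "drop"
  )
}

#' One-row-per-cutoff summary of a harness run
#'
#' @param x A `ddex_harness` object.
#' @param ... Unused.
#' @return A tibble with, per effect cutoff: mean false positives per trial,
#'   mean per-gene false-positive rate, and the overall true-positive rate.
#' @export
glance.ddex_harness <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$calls, .data$effect_cutoff),
    trials = dplyr::n(),
    mean_fp = mean(.data$fp),
    mean_fp_rate = mean(.data$fp_rate),
    tpr = sum(.data$tp) / sum(.data$n_spiked),
    .groups = "drop"
  )
}
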