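# MA and MW diagnostic plots. Every plot has a TSV twin of exactly the data
# drawn, so results are testable without touching pixels.

plot_data <- function(results, type = c("MW", "MA")) {
  type <- match.arg(type)
  results <- tibble::as_tibble(results)
  need <- c("gene", if (type == "MW") "W" else "A", "M", "called")
  missing <- setdiff(need, names(results))
  if (length(missing)) abort(paste0("results lack required columns: ", paste(missing, collapse = ", ")))
  dplyr::select(results, dplyr::all_of(need))
}

#' MA / MW plot of a differential expression result
#'
#' `type = "MA"` is the Bland-Altman view: median between-condition
#' difference `M` against overall median expression `A` (whose across-gene
#' mean is ~0 by the sum-zero transform). `type = "MW"` plots `M` against the
#' maximum within-condition difference `W`, separating between-condition
#' change from within-condition dispersion: the dashed lines are the
#' within/between equivalence diagonals `|M| = W` and the solid lines the
#' `|M| = 2 W` threshold. Called genes are highlighted; those that also pass
#' the conservative effect cutoff of 2 form a second tier.
#'
#' @param object A `ddex` fit or a result tibble.
#' @param type `"MW"` (default) or `"MA"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddex <- function(object, type = c("MW", "MA"), ...) {
  results <- if (inherits(object, "ddex")) object$results else tibble::as_tibble(object)
  type <- match.arg(type)
  dat <- plot_data(results, type)
  tier <- rep("background", nrow(dat))
  tier[dat$called] <- "called"
  if ("E" %in% names(results)) tier[dat$called & abs(results$E) >= 2] <- "called (conservative)"
  dat$tier <- factor(tier, levels = c("background", "called", "called (conservative)"))
  xvar <- if (type == "MW") "W" else "A"
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data[[xvar]], y = .data$M))
  if (type == "MW") {
    p <- p +
      ggplot2::geom_abline(slope = c(1, -1), intercept = 0, linetype = "dashed", colour = "grey55") +
      ggplot2::geom_abline(slope = c(2, -2), intercept = 0, colour = "grey55")
  }
  p <- p + ggplot2::geom_point(data = dat[dat$tier == "background", ],
                               colour = "grey40", alpha = 0.35, size = 0.8)
  if (any(dat$tier != "background")) {
    p <- p +
      ggplot2::geom_point(data = dat[dat$tier != "background", ],
                          ggplot2::aes(colour = .data$tier), size = 1.2) +
      ggplot2::scale_colour_manual(values = c("called" = "red", "called (conservative)" = "orange"),
                                   name = NULL)
  }
  p +
    ggplot2::labs(
      x = if (type == "MW") "W (max within-condition difference)" else "A (median expression)",
      y = "M (median between-condition difference)",
      title = if (type == "MW") "MW plot" else "MA (Bland-Altman) plot"
    ) +
    ggplot2::theme_minimal()
}

#' Render a plot to file together with its TSV twin
#'
#' Writes the figure (format from the file extension: png, pdf or svg) and a
#' TSV holding exactly the plotted columns (`gene`, `W` or `A`, `M`,
#' `called`), so downstream checks can assert on data rather than pixels.
#'
#' @param x A `ddex` fit or result tibble.
#' @param type `"MW"` or `"MA"`.
#' @param file Image path, or `NULL` to skip rendering.
#' @param tsv TSV path (default: `file` with a `.tsv` extension).
#' @param width,height Figure size in inches.
#' @return The ggplot, invisibly.
#' @export
ddex_plot <- function(x, type = c("MW", "MA"), file = NULL, tsv = NULL,
                      width = 6, height = 5) {
  type <- match.arg(type)
  results <- if (inherits(x, "ddex")) x$results else tibble::as_tibble(x)
  if (!nrow(results)) abort("no genes to plot")
  if (is.null(tsv) && !is.null(file)) tsv <- paste0(sub("\\.[A-Za-z]+$", "", file), ".tsv")
  p <- autoplot.ddex(x, type = type)
  if (!is.null(tsv)) readr::write_tsv(plot_data(results, type), tsv)
  if (!is.null(file)) suppressMessages(ggplot2::ggsave(file, p, width = width, height = height, dpi = 150))
  invisible(p)
}

#' Plot a sampling-variance envelope table
#'
#' Shows the width of the expected technical-replicate difference envelope
#' against median expression, with the observed per-gene replicate
#' differences overlaid; genes outside the envelope (sampling variation does
#' not explain their difference) are highlighted.
#'
#' @param env A tibble from [sampling_variance_envelope()].
#' @return A ggplot object.
#' @export
plot_envelope <- function(env) {
  env <- tibble::as_tibble(env)
  need <- c("A", "observed", "lo", "hi", "inside")
  if (!all(need %in% names(env))) abort("env must come from sampling_variance_envelope()")
  centred_lo <- env$lo - (env$lo + env$hi) / 2
  centred_hi <- env$hi - (env$lo + env$hi) / 2
  dat <- dplyr::mutate(env, env_lo = centred_lo, env_hi = centred_hi)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$A)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_lo, ymax = .data$env_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed, colour = .data$inside),
                        size = 0.8, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30", `FALSE` = "red"),
                                 name = "inside envelope") +
    ggplot2::labs(x = "A (median expression)",
                  y = "between-replicate difference",
                  title = "Sampling-variance envelope") +
    ggplot2::theme_minimal()
}
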