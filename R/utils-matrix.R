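# Row-wise summaries used throughout; quantiles are always linear
# interpolation between order statistics (quantile type 7) so results are
# reproducible across implementations.

row_medians <- function(m) {
  if (is.null(dim(m))) return(median(m))
  row_medians_cpp(m)
}

row_quantiles <- function(m, probs) {
  q <- apply(m, 1L, quantile, probs = probs, names = FALSE, type = 7)
  if (length(probs) == 1L) matrix(q, ncol = 1L) else t(q)
}
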