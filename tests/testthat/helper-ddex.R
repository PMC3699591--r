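# small fixtures, built in code

tiny_counts <- function() {
  tibble::tibble(
    gene = c("gA", "gB", "gC"),
    s1 = c(10L, 0L, 100L),
    s2 = c(0L, 0L, 90L),
    s3 = c(5L, 0L, 80L),
    s4 = c(7L, 0L, 120L)
  )
}

tiny_design <- function() {
  tibble::tibble(sample = paste0("s", 1:4), condition = c("A", "A", "B", "B"))
}

write_tiny_tsv <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# constant-draw matrices for the effect-machinery examples
const_draws <- function(value, n_genes = 1, n_mc = 100) {
  matrix(value, nrow = n_genes, ncol = n_mc)
}
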