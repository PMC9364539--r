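# Small programmatic fixtures shared across test files.

make_meta <- function(n, strains = 2, weeks = 2) {
  # crossed layout: strain cycles fastest, diet flips every `strains`
  # samples, week every 2 * strains, so no factor pair is aliased
  i <- seq_len(n) - 1L
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             strain = sprintf("CC%03d", i %% strains + 1L),
             diet = c("HP", "HS")[(i %/% strains) %% 2L + 1L],
             week = sprintf("W%d", (i %/% (2L * strains)) %% weeks + 1L),
             stringsAsFactors = FALSE)
}

make_toy_dataset <- function(values, symbols = NULL, meta = NULL) {
  values <- as.matrix(values)
  if (is.null(symbols)) symbols <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(meta)) meta <- make_meta(ncol(values))
  expression_dataset(values, sprintf("TC%03d", seq_len(nrow(values))),
                     symbols, meta)
}

# bimodal intensity fixture: expressed genes high and spread across samples,
# unexpressed genes low -- the regime the TC-ID filter is designed for
make_bimodal_dataset <- function(n_expr = 30, n_unexpr = 20, n_samp = 12,
                                 seed = 42) {
  set.seed(seed)
  hi <- matrix(rnorm(n_expr * n_samp, 8, 1), n_expr, n_samp)
  lo <- matrix(rnorm(n_unexpr * n_samp, 2, 0.3), n_unexpr, n_samp)
  make_toy_dataset(rbind(hi, lo), meta = make_meta(n_samp))
}

write_tsv_trio <- function(dataset, phenotypes, dir = tempfile()) {
  write_dataset(dataset, dir, phenotypes)
}
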