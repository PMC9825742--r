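# Shared fixtures: small amplitude files and configs built in code.

write_amp_csv <- function(path, ch1, ch2 = NULL, header = TRUE) {
  df <- data.frame(`Ch1 Amplitude` = ch1, check.names = FALSE)
  if (!is.null(ch2)) df[["Ch2 Amplitude"]] <- ch2
  utils::write.csv(df, path, row.names = FALSE)
  if (!header) {
    lines <- readLines(path)
    writeLines(lines[-1], path)
  }
  path
}

write_sheet_csv <- function(path, wells, samples = paste0("s", seq_along(wells)),
                            target_types = "Ch1Unknown", targets = "GENE",
                            extra = NULL) {
  df <- data.frame(Well = wells, Sample = samples, TargetType = target_types,
                   Target = targets, stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# two-cloud sample with known membership, no rain
two_cloud <- function(n_neg, n_pos, neg_mean = 2000, neg_sd = 120,
                      pos_mean = 8000, pos_sd = 180, seed = 1) {
  set.seed(seed)
  list(amps = c(rnorm(n_neg, neg_mean, neg_sd), rnorm(n_pos, pos_mean, pos_sd)),
       truth = rep(c("negative", "positive"), c(n_neg, n_pos)))
}

# small-well config used by fast tests (fits are still Gaussian mixtures,
# just on fewer droplets than a production well)
fast_config <- function(...) calling_config(min_droplets = 500L, ...)
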