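# Poisson occupancy quantification: positive/total droplet counts ->
# copies per droplet (lambda) -> copies/microlitre, with Wilson-score
# confidence intervals on the positive fraction propagated through the
# monotone transform.

#' Estimate mean copies per droplet (lambda)
#'
#' Under random partitioning, the number of target copies per droplet is
#' Poisson distributed, so the fraction of empty droplets is `exp(-lambda)`
#' and `lambda = -ln(1 - k/n)` for `k` positive droplets out of `n`.
#'
#' @param k_positive Count of positive droplets.
#' @param n_total Count of retained droplets (destroyed droplets excluded
#'   from both `k` and `n`).
#' @return Copies per droplet (dimensionless); exactly 0 when `k_positive`
#'   is 0.
#' @export
estimate_lambda <- function(k_positive, n_total) {
  stopifnot(length(k_positive) == 1L, length(n_total) == 1L,
            k_positive >= 0, n_total >= 1)
  if (k_positive > n_total)
    stop("k_positive exceeds n_total")
  if (k_positive == n_total)
    stop("all droplets positive; concentration not estimable")
  if (k_positive == 0) return(0)
  -log1p(-(k_positive / n_total))
}

#' Convert lambda to concentration in copies per microlitre
#'
#' @param lambda Copies per droplet.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85, the
#'   Bio-Rad QX200 partition volume).
#' @return Concentration in copies/µL: `lambda / (droplet_volume_nl * 1e-3)`.
#' @export
lambda_to_concentration <- function(lambda, droplet_volume_nl = 0.85) {
  stopifnot(lambda >= 0)
  if (droplet_volume_nl <= 0) stop("droplet volume must be positive")
  lambda / (droplet_volume_nl * 1e-3)
}

#' Confidence interval for the concentration
#'
#' Wilson score bounds on the positive fraction `p = k/n` (no continuity
#' correction), mapped through the monotone transform
#' `-ln(1 - p) / volume`. The interval always contains the point estimate.
#'
#' @param k Positive droplet count (`k < n`).
#' @param n Retained droplet count.
#' @param droplet_volume_nl Droplet volume in nanolitres.
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(low, high)` in copies/µL; `low` is 0 when
#'   `k` is 0.
#' @export
concentration_interval <- function(k, n, droplet_volume_nl = 0.85,
                                   level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (k >= n) stop("all droplets positive; concentration not estimable")
  ci_p <- stats::prop.test(k, n, conf.level = level, correct = FALSE)$conf.int
  bounds <- -log1p(-ci_p) / (droplet_volume_nl * 1e-3)
  if (k == 0) bounds[1] <- 0
  c(low = bounds[1], high = bounds[2])
}

#' Quantify one channel from droplet counts
#'
#' Convenience wrapper combining [estimate_lambda()],
#' [lambda_to_concentration()] and [concentration_interval()]. Saturation
#' (`k == n`, lambda not estimable) and undefined counts yield a flagged
#' result with `NA` estimates rather than an error, so a single failed well
#' cannot abort a plate.
#'
#' @param k_positive Positive droplet count (may be `NA`).
#' @param n_total Retained droplet count.
#' @param droplet_volume_nl Droplet volume in nanolitres.
#' @param level Confidence level.
#' @return An object of class `well_quant`: `k_positive`, `n_total`,
#'   `lambda`, `concentration`, `ci_low`, `ci_high`, `droplet_volume_nl`,
#'   `qc_flags`.
#' @export
quantify_channel <- function(k_positive, n_total, droplet_volume_nl = 0.85,
                             level = 0.95) {
  out <- list(k_positive = suppressWarnings(as.integer(k_positive)),
              n_total = suppressWarnings(as.integer(n_total)),
              lambda = NA_real_, concentration = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_,
              droplet_volume_nl = droplet_volume_nl,
              qc_flags = character())
  if (is.na(k_positive) || is.na(n_total) || n_total < 1) {
    out$qc_flags <- "not_quantified"
    return(structure(out, class = "well_quant"))
  }
  if (k_positive == n_total) {
    out$qc_flags <- "saturated"
    return(structure(out, class = "well_quant"))
  }
  out$lambda <- estimate_lambda(k_positive, n_total)
  out$concentration <- lambda_to_concentration(out$lambda, droplet_volume_nl)
  ci <- concentration_interval(k_positive, n_total, droplet_volume_nl, level)
  out$ci_low <- unname(ci["low"])
  out$ci_high <- unname(ci["high"])
  structure(out, class = "well_quant")
}

#' @export
print.well_quant <- function(x, ...) {
  cat(sprintf("<well_quant: %s/%s positive, lambda %s, %s copies/uL [%s, %s]>\n",
              x$k_positive, x$n_total,
              signif(x$lambda, 4), signif(x$concentration, 6),
              signif(x$ci_low, 6), signif(x$ci_high, 6)))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}
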