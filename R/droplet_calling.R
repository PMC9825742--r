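# Per-well, per-channel droplet calling: robust removal of destroyed
# droplets, Gaussian mixture fit with BIC model selection, threshold
# placement, and labeling.

#' Calling configuration
#'
#' Collects the free parameters of the stepwise calling procedure. Defaults
#' are chosen for Bio-Rad QX-style two-cloud amplitude data and are recorded
#' in every run manifest for auditability.
#'
#' @param low_outlier_rule Method for destroyed-droplet removal; only
#'   `"median_mad"` is implemented: droplets below
#'   `median - low_outlier_k * MAD` of the lower half of the amplitude
#'   distribution are removed.
#' @param low_outlier_k Multiplier for the MAD in the low-outlier cut.
#' @param max_components Maximum number of mixture components tried (BIC
#'   selects among `1:max_components`).
#' @param min_droplets QC floor on retained droplets: below it the channel is
#'   flagged `low_droplet_count` and no threshold is fitted. The well is
#'   still reported (never silently excluded).
#' @param threshold_rule One of `"mean_plus_k_sd"` (default: negative-cloud
#'   mean plus `k_sd` standard deviations), `"quantile_of_negative"`
#'   (Gaussian quantile `negative_quantile` of the negative component), or
#'   `"component_intersection"` (equal-density point between the extreme
#'   components).
#' @param k_sd Multiplier for `"mean_plus_k_sd"`.
#' @param negative_quantile Probability for `"quantile_of_negative"`.
#' @param rng_seed Integer seed fixed before every mixture fit so results are
#'   reproducible without user action.
#' @param reference_control Optional well id of a methylation-positive (IVD)
#'   control well, recorded in outputs for provenance.
#' @return An object of class `calling_config`.
#' @export
calling_config <- function(low_outlier_rule = "median_mad",
                           low_outlier_k = 5,
                           max_components = 2L,
                           min_droplets = 8000L,
                           threshold_rule = c("mean_plus_k_sd",
                                              "quantile_of_negative",
                                              "component_intersection"),
                           k_sd = 5,
                           negative_quantile = 0.995,
                           rng_seed = 1L,
                           reference_control = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  low_outlier_rule <- match.arg(low_outlier_rule, "median_mad")
  stopifnot(max_components >= 1L, min_droplets >= 1L,
            k_sd > 0, low_outlier_k > 0,
            negative_quantile > 0, negative_quantile < 1)
  structure(list(low_outlier_rule = low_outlier_rule,
                 low_outlier_k = low_outlier_k,
                 max_components = as.integer(max_components),
                 min_droplets = as.integer(min_droplets),
                 threshold_rule = threshold_rule,
                 k_sd = k_sd,
                 negative_quantile = negative_quantile,
                 rng_seed = as.integer(rng_seed),
                 reference_control = reference_control),
            class = "calling_config")
}

#' Remove destroyed (extremely low amplitude) droplets
#'
#' Destroyed droplets present as a sparse tail far below the negative cloud.
#' The cut is `median - k * MAD` computed on the lower half of the amplitude
#' distribution (values at or below the overall median), which is insensitive
#' to the positive cloud. With zero spread (MAD = 0) nothing is removed and
#' the flag `zero_spread` is attached.
#'
#' @param amplitudes Numeric vector of amplitudes.
#' @param config A [calling_config()].
#' @return List with `retained_idx`, `removed_idx` (a partition of the input
#'   indices), `cutoff` and `qc_flags`.
#' @export
filter_low_droplets <- function(amplitudes, config = calling_config()) {
  stopifnot(length(amplitudes) >= 1L)
  flags <- character()
  lower <- amplitudes[amplitudes <= stats::median(amplitudes)]
  s <- stats::mad(lower)
  if (s == 0) {
    flags <- "zero_spread"
    cutoff <- -Inf
  } else {
    cutoff <- stats::median(lower) - config$low_outlier_k * s
  }
  removed <- which(amplitudes < cutoff)
  if (length(removed) == length(amplitudes))
    stop("well unusable: all droplets removed as low outliers")
  list(retained_idx = setdiff(seq_along(amplitudes), removed),
       removed_idx = removed, cutoff = cutoff, qc_flags = flags)
}

#' Fit a Gaussian mixture to droplet amplitudes
#'
#' Fits univariate Gaussian mixtures with 1 to `max_components` components
#' (equal- and unequal-variance parameterizations) and keeps the
#' BIC-optimal model. Components are reported in ascending-mean order; the
#' lowest-mean component is interpreted as the negative cloud.
#'
#' @param amplitudes Numeric amplitudes (after low-outlier filtering).
#' @param config A [calling_config()]; `rng_seed` is set before the fit, and
#'   the fit refuses to run on fewer than `min_droplets` droplets.
#' @return An object of class `mixture_fit` with `n_components`, `weights`,
#'   `means`, `sds`, `bic` and `converged`.
#' @export
fit_amplitude_mixture <- function(amplitudes, config = calling_config()) {
  if (length(amplitudes) < config$min_droplets)
    stop(sprintf("too few droplets for mixture fit: %d < min_droplets = %d",
                 length(amplitudes), config$min_droplets))
  set.seed(config$rng_seed)
  mc <- tryCatch(
    Mclust(amplitudes, G = seq_len(config$max_components),
           modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) e)
  if (inherits(mc, "error") || is.null(mc))
    stop("mixture fit failed for all candidate component counts (1..",
         config$max_components, "): ",
         if (inherits(mc, "error")) conditionMessage(mc) else "no model selected")
  p <- mc$parameters
  means <- as.numeric(p$mean)
  sds <- sqrt(as.numeric(p$variance$sigmasq))
  if (length(sds) == 1L) sds <- rep(sds, length(means))
  weights <- as.numeric(p$pro)
  if (is.null(weights)) weights <- 1
  ord <- order(means)
  structure(list(n_components = length(means),
                 weights = weights[ord] / sum(weights),
                 means = means[ord],
                 sds = sds[ord],
                 bic = as.numeric(mc$bic),
                 model_name = mc$modelName,
                 converged = TRUE),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: %d component(s), model %s, BIC %.1f>\n",
              x$n_components, x$model_name, x$bic))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

# Equal-density point of two weighted Gaussians, searched between the means.
intersect_components <- function(w1, m1, s1, w2, m2, s2) {
  f <- function(x) (log(w1) + stats::dnorm(x, m1, s1, log = TRUE)) -
                   (log(w2) + stats::dnorm(x, m2, s2, log = TRUE))
  out <- tryCatch(stats::uniroot(f, lower = m1, upper = m2, tol = 1e-8)$root,
                  error = function(e) NA_real_)
  out
}

#' Select the positive-droplet threshold from a mixture fit
#'
#' With a single fitted component the well is treated as target-free and the
#' threshold is placed in the far upper tail of the (negative) component —
#' `mean + k_sd * sd`, or its `negative_quantile` Gaussian quantile under the
#' quantile rule — so a genuinely empty well yields ~0 positives even when
#' that value exceeds the largest observed amplitude. With two or more
#' components the configured rule is applied to the lowest-mean (negative)
#' component and the threshold is guaranteed to lie strictly between the
#' lowest and highest component means, falling back to the equal-density
#' intersection and then the mid-point between means when the rule lands
#' outside that interval. Rain droplets are deliberately not modeled as a
#' component: they are split by the threshold (above: positive; below:
#' negative).
#'
#' @param fit A converged [fit_amplitude_mixture()] result.
#' @param amplitudes The amplitudes the fit was made on.
#' @param config A [calling_config()].
#' @return The threshold (amplitude units), or `NA` with attribute
#'   `qc_flags = "threshold_out_of_range"` when a multi-component threshold
#'   falls outside the observed amplitude range.
#' @export
select_threshold <- function(fit, amplitudes, config = calling_config()) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!isTRUE(fit$converged)) stop("mixture fit did not converge")
  m <- fit$means; s <- fit$sds; w <- fit$weights
  if (fit$n_components == 1L) {
    thr <- if (config$threshold_rule == "quantile_of_negative")
      stats::qnorm(config$negative_quantile, m, s)
    else m + config$k_sd * s
    return(thr)
  }
  lo <- 1L; hi <- fit$n_components
  thr <- switch(config$threshold_rule,
    mean_plus_k_sd = m[lo] + config$k_sd * s[lo],
    quantile_of_negative = stats::qnorm(config$negative_quantile, m[lo], s[lo]),
    component_intersection = intersect_components(w[lo], m[lo], s[lo],
                                                  w[hi], m[hi], s[hi]))
  if (!is.finite(thr) || thr <= m[lo] || thr >= m[hi]) {
    alt <- intersect_components(w[lo], m[lo], s[lo], w[hi], m[hi], s[hi])
    thr <- if (is.finite(alt) && alt > m[lo] && alt < m[hi]) alt
           else (m[lo] + m[hi]) / 2
  }
  if (thr < min(amplitudes) || thr > max(amplitudes))
    return(structure(NA_real_, qc_flags = "threshold_out_of_range"))
  thr
}

#' Label droplets against a threshold
#'
#' Strict inequality: amplitude > threshold is `positive`; amplitude equal to
#' the threshold is `negative` (ties go negative).
#'
#' @param amplitudes Numeric amplitudes.
#' @param threshold Finite threshold (amplitude units).
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify_droplets <- function(amplitudes, threshold) {
  stopifnot(is.finite(threshold))
  ifelse(amplitudes > threshold, "positive", "negative")
}

call_channel <- function(amplitudes, config) {
  out <- list(threshold = NA_real_,
              labels = rep(NA_character_, length(amplitudes)),
              n_positive = NA_integer_,
              n_total_retained = NA_integer_,
              fit = NULL, low_cutoff = NA_real_,
              threshold_source = "automatic",
              qc_flags = character())
  filt <- tryCatch(filter_low_droplets(amplitudes, config),
                   error = function(e) e)
  if (inherits(filt, "error")) {
    out$qc_flags <- "well_unusable"
    return(out)
  }
  out$qc_flags <- filt$qc_flags
  out$low_cutoff <- filt$cutoff
  out$labels[filt$removed_idx] <- "removed_low"
  ret <- filt$retained_idx
  out$n_total_retained <- length(ret)
  if (length(ret) < config$min_droplets) {
    out$qc_flags <- c(out$qc_flags, "low_droplet_count")
    return(out)
  }
  fit <- tryCatch(fit_amplitude_mixture(amplitudes[ret], config),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    out$qc_flags <- c(out$qc_flags, "mixture_fit_failed")
    return(out)
  }
  out$fit <- fit
  thr <- select_threshold(fit, amplitudes[ret], config)
  out$qc_flags <- c(out$qc_flags, attr(thr, "qc_flags"))
  if (!is.finite(thr)) return(out)
  out$threshold <- as.numeric(thr)
  out$labels[ret] <- classify_droplets(amplitudes[ret], out$threshold)
  out$n_positive <- sum(out$labels[ret] == "positive")
  out
}

#' Call positive droplets in one well
#'
#' Composes, independently per channel: low-outlier (destroyed droplet)
#' removal, Gaussian mixture fitting with BIC component selection, threshold
#' selection and droplet labeling. Stage failures never abort the well:
#' they leave the channel threshold undefined and attach a QC flag
#' (`low_droplet_count`, `zero_spread`, `threshold_out_of_range`,
#' `mixture_fit_failed`, `well_unusable`). Deterministic given
#' `config$rng_seed`.
#'
#' @param well A [droplet_well()].
#' @param config A [calling_config()].
#' @return An object of class `well_call`: `well_id`, `channels` (per
#'   channel: `threshold`, full-length `labels`, `n_positive`,
#'   `n_total_retained`, `fit`, `threshold_source`, `qc_flags`) and
#'   well-level `qc_flags`.
#' @export
call_well <- function(well, config = calling_config()) {
  stopifnot(inherits(well, "droplet_well"), inherits(config, "calling_config"))
  channels <- list(ch1 = call_channel(well$ch1_amplitude, config))
  if (!is.null(well$ch2_amplitude))
    channels$ch2 <- call_channel(well$ch2_amplitude, config)
  amps <- list(ch1 = well$ch1_amplitude)
  if (!is.null(well$ch2_amplitude)) amps$ch2 <- well$ch2_amplitude
  structure(list(well_id = well$well_id,
                 channels = channels,
                 amplitudes = amps,
                 config = config,
                 qc_flags = unique(c(well$qc_flags,
                                     unlist(lapply(channels, `[[`, "qc_flags"),
                                            use.names = FALSE)))),
            class = "well_call")
}

#' @export
print.well_call <- function(x, ...) {
  cat(sprintf("<well_call %s>\n", x$well_id))
  for (chn in names(x$channels)) {
    ch <- x$channels[[chn]]
    cat(sprintf("  %s: threshold %s (%s), %s/%s positive/retained\n", chn,
                if (is.na(ch$threshold)) "undefined" else sprintf("%.1f", ch$threshold),
                ch$threshold_source,
                ifelse(is.na(ch$n_positive), "?", ch$n_positive),
                ifelse(is.na(ch$n_total_retained), "?", ch$n_total_retained)))
  }
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Manually override the threshold of one channel
#'
#' Relabels the retained droplets of one channel against a user-supplied
#' threshold (the batch analogue of correcting a threshold after visual
#' inspection). Removal labels from the filtering stage are preserved and the
#' channel's `threshold_source` becomes `"manual"`.
#'
#' @param call A `well_call` from [call_well()].
#' @param channel `"ch1"` or `"ch2"` (or 1/2).
#' @param new_threshold Finite replacement threshold.
#' @return The updated `well_call`.
#' @export
override_threshold <- function(call, channel, new_threshold) {
  stopifnot(inherits(call, "well_call"), is.finite(new_threshold))
  if (is.numeric(channel)) channel <- paste0("ch", as.integer(channel))
  if (!channel %in% names(call$channels))
    stop("channel ", channel, " not present in well ", call$well_id)
  ch <- call$channels[[channel]]
  ret <- which(!(ch$labels %in% c("removed_low", "removed_outlier")))
  a <- call$amplitudes[[channel]]
  ch$labels[ret] <- classify_droplets(a[ret], new_threshold)
  ch$threshold <- as.numeric(new_threshold)
  ch$threshold_source <- "manual"
  ch$n_positive <- sum(ch$labels[ret] == "positive")
  call$channels[[channel]] <- ch
  call
}
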