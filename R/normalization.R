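# Normalization of methylation levels against an internal control:
# (target concentration / control concentration) * c, with c = 100 for a
# single-gene control and c = 400 for the 4Plex four-assay panel (four
# control copies per genome equivalent keep the values on the single-gene
# percent scale).

C_SINGLE_GENE <- 100
C_FOURPLEX <- 400

#' Normalize against a single-gene internal control
#'
#' @param ch1 Channel-1 (target) concentration, copies/µL.
#' @param ch2 Channel-2 (internal control) concentration, copies/µL; must be
#'   positive.
#' @return `(ch1 / ch2) * 100`, a percent-like methylation level.
#' @export
normalize_single_gene <- function(ch1, ch2) {
  stopifnot(ch1 >= 0)
  if (any(ch2 <= 0)) stop("control not detected; normalization undefined")
  (ch1 / ch2) * C_SINGLE_GENE
}

#' Normalize against the 4Plex control panel
#'
#' The 4Plex control amplifies four single-copy genes, so its concentration
#' is four control copies per genome equivalent; scaling by 400 puts the
#' value on the same percent scale as single-gene normalization.
#'
#' @inheritParams normalize_single_gene
#' @return `(ch1 / ch2) * 400`; exactly 4x [normalize_single_gene()] on the
#'   same inputs.
#' @export
normalize_fourplex <- function(ch1, ch2) {
  stopifnot(ch1 >= 0)
  if (any(ch2 <= 0)) stop("control not detected; normalization undefined")
  (ch1 / ch2) * C_FOURPLEX
}

#' Normalize a well's methylation level
#'
#' Dispatches on the control type. With `control_type = "none"` (no internal
#' control in channel 2) the normalized value is undefined and the raw
#' channel-1 concentration stands alone. A missing, saturated or
#' zero-concentration control yields a flagged result with an undefined
#' value rather than an error. Values above 100 are reported as computed
#' (copy-number aberrations can push target above control) with the QC note
#' `normalized_above_100`.
#'
#' @param ch1_quant A `well_quant` for channel 1 (target).
#' @param ch2_quant A `well_quant` for channel 2 (control), or `NULL`.
#' @param control_type `"single_gene"`, `"fourplex"` or `"none"`.
#' @return An object of class `normalized_result`: `value` (`NA` when
#'   undefined), `control_type`, `c_constant`, `ch1_concentration`,
#'   `ch2_concentration`, `qc_flags`.
#' @export
normalize_well <- function(ch1_quant, ch2_quant = NULL,
                           control_type = c("single_gene", "fourplex", "none")) {
  control_type <- match.arg(control_type)
  stopifnot(inherits(ch1_quant, "well_quant"))
  res <- list(value = NA_real_, control_type = control_type,
              c_constant = NA_real_,
              ch1_concentration = ch1_quant$concentration,
              ch2_concentration = NA_real_,
              qc_flags = character())
  if (control_type == "none")
    return(structure(res, class = "normalized_result"))
  if (is.null(ch2_quant))
    stop("control_type '", control_type,
         "' requires a channel-2 quantification (set control_type = 'none' ",
         "for single-channel runs)")
  stopifnot(inherits(ch2_quant, "well_quant"))
  res$ch2_concentration <- ch2_quant$concentration
  res$c_constant <- if (control_type == "single_gene") C_SINGLE_GENE else C_FOURPLEX
  bad_ch2 <- is.na(ch2_quant$concentration) || ch2_quant$concentration <= 0
  if (is.na(ch1_quant$concentration) || bad_ch2) {
    res$qc_flags <- c(if (is.na(ch1_quant$concentration)) "target_not_quantified",
                      if (bad_ch2) "control_not_detected",
                      ch2_quant$qc_flags)
    return(structure(res, class = "normalized_result"))
  }
  res$value <- if (control_type == "single_gene")
    normalize_single_gene(ch1_quant$concentration, ch2_quant$concentration)
  else
    normalize_fourplex(ch1_quant$concentration, ch2_quant$concentration)
  if (res$value > 100) res$qc_flags <- "normalized_above_100"
  structure(res, class = "normalized_result")
}

#' @export
print.normalized_result <- function(x, ...) {
  cat(sprintf("<normalized_result: %s (%s, c = %s)>\n",
              if (is.na(x$value)) "undefined" else sprintf("%.2f", x$value),
              x$control_type,
              if (is.na(x$c_constant)) "-" else x$c_constant))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}
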