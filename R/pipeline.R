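# Plate-level orchestration: directory of amplitude CSVs (+ optional sample
# sheet) -> calling -> quantification -> normalization -> results table,
# per-well label exports, run manifest and optional plots; plus batch
# threshold override with re-quantification.

results_row <- function(well, call, q1, q2, norm) {
  ch1 <- call$channels$ch1
  ch2 <- call$channels$ch2
  flags <- unique(c(call$qc_flags,
                    if (!is.null(q1)) q1$qc_flags,
                    if (!is.null(q2)) q2$qc_flags,
                    if (!is.null(norm)) norm$qc_flags))
  data.frame(
    well_id = well$well_id, sample = well$sample, target = well$target,
    ch1_threshold = ch1$threshold,
    ch1_positives = ch1$n_positive, ch1_total = ch1$n_total_retained,
    ch1_concentration = if (!is.null(q1)) q1$concentration else NA_real_,
    ch1_ci_low = if (!is.null(q1)) q1$ci_low else NA_real_,
    ch1_ci_high = if (!is.null(q1)) q1$ci_high else NA_real_,
    ch2_threshold = if (!is.null(ch2)) ch2$threshold else NA_real_,
    ch2_positives = if (!is.null(ch2)) ch2$n_positive else NA_integer_,
    ch2_total = if (!is.null(ch2)) ch2$n_total_retained else NA_integer_,
    ch2_concentration = if (!is.null(q2)) q2$concentration else NA_real_,
    ch2_ci_low = if (!is.null(q2)) q2$ci_low else NA_real_,
    ch2_ci_high = if (!is.null(q2)) q2$ci_high else NA_real_,
    normalized_value = if (!is.null(norm)) norm$value else NA_real_,
    control_type = if (!is.null(norm)) norm$control_type else "none",
    c_constant = if (!is.null(norm)) norm$c_constant else NA_real_,
    qc_flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Run the full plate workflow
#'
#' Reads every amplitude CSV in `input_dir` (files matching
#' `*_Amplitude.csv`, or any `.csv` except the sample sheet when none
#' match), annotates wells from the optional sample sheet, then per well:
#' calls droplets per channel, quantifies via the Poisson model, and
#' normalizes channel 1 against channel 2 per `control_type`. A failing or
#' flagged well is recorded in the manifest and excluded from normalization
#' but never aborts the run. `ch2 = FALSE` (no internal control present)
#' forces `control_type = "none"`.
#'
#' @param input_dir Directory of per-well amplitude CSVs.
#' @param out_dir Output directory; receives `results.csv`,
#'   `labels/<well>_labels.csv`, `manifest.json` and (optionally)
#'   `plots/<well>.<pdf|png>`.
#' @param sample_sheet Optional path to a sample sheet CSV.
#' @param config A [calling_config()].
#' @param ch2 Logical: is channel 2 an internal control to be analyzed?
#' @param control_type `"single_gene"`, `"fourplex"` or `"none"`.
#' @param droplet_volume_nl Droplet volume in nanolitres.
#' @param level Confidence level for concentration intervals.
#' @param plots Logical: emit per-well figures?
#' @param plot_format `"pdf"` or `"png"`.
#' @return Invisibly, a list with `results` (data.frame), `calls` (list of
#'   `well_call`), `manifest`, and the output paths.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         sample_sheet = NULL,
                         config = calling_config(),
                         ch2 = TRUE,
                         control_type = c("fourplex", "single_gene", "none"),
                         droplet_volume_nl = 0.85,
                         level = 0.95,
                         plots = FALSE,
                         plot_format = c("pdf", "png")) {
  control_type <- match.arg(control_type)
  plot_format <- match.arg(plot_format)
  if (!isTRUE(ch2)) control_type <- "none"
  files <- list.files(input_dir, pattern = "_Amplitude\\.csv$",
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0L) {
    files <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
    if (!is.null(sample_sheet))
      files <- files[normalizePath(files) != normalizePath(sample_sheet)]
  }
  if (length(files) == 0L) stop("no amplitude CSV files found in ", input_dir)
  files <- sort(files)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
  if (plots) dir.create(file.path(out_dir, "plots"), showWarnings = FALSE)

  sheet <- if (!is.null(sample_sheet)) read_sample_sheet(sample_sheet)
  manifest_wells <- list()
  rows <- list(); calls <- list()
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  for (f in files) {
    well <- tryCatch(read_amplitude_file(f), error = function(e) e)
    if (inherits(well, "error")) {
      wid <- parse_well_id(f)$well_id
      warning("well ", wid, " failed: ", conditionMessage(well), call. = FALSE)
      manifest_wells[[wid]] <- list(file = basename(f), status = "failed",
                                    error = conditionMessage(well))
      next
    }
    well <- annotate_wells(list(well), sheet)[[1]]
    if ("no_sheet_entry" %in% well$qc_flags)
      warning("well ", well$well_id, " has no sample sheet entry", call. = FALSE)
    call <- call_well(well, config)
    calls[[well$well_id]] <- call
    q1 <- quantify_channel(call$channels$ch1$n_positive,
                           call$channels$ch1$n_total_retained,
                           droplet_volume_nl, level)
    q2 <- if (!is.null(call$channels$ch2))
      quantify_channel(call$channels$ch2$n_positive,
                       call$channels$ch2$n_total_retained,
                       droplet_volume_nl, level)
    norm <- if (control_type != "none" && !is.null(q2))
      normalize_well(q1, q2, control_type)
    else normalize_well(q1, control_type = "none")
    rows[[well$well_id]] <- results_row(well, call, q1, q2, norm)
    write_well_labels(call, well,
                      file.path(out_dir, "labels",
                                paste0(well$well_id, "_labels.csv")))
    if (plots)
      render_well_plot(call, well,
                       file.path(out_dir, "plots",
                                 paste0(well$well_id, ".", plot_format)))
    status <- if (length(call$qc_flags)) "flagged" else "ok"
    if (length(call$qc_flags))
      warning("well ", well$well_id, " flagged: ",
              paste(call$qc_flags, collapse = ", "), call. = FALSE)
    manifest_wells[[well$well_id]] <- list(file = basename(f), status = status,
                                           qc_flags = as.list(call$qc_flags))
  }
  if (length(rows) == 0L) stop("no well could be processed in ", input_dir)
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results_path <- file.path(out_dir, "results.csv")
  write_results(results, results_path)

  manifest <- list(
    input_dir = input_dir,
    sample_sheet = if (!is.null(sample_sheet)) sample_sheet else NA,
    software = "dropcall",
    version = as.character(utils::packageVersion("dropcall")),
    config = unclass(config),
    ch2 = isTRUE(ch2), control_type = control_type,
    droplet_volume_nl = droplet_volume_nl, level = level,
    plots = isTRUE(plots),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    wells = manifest_wells,
    overrides = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(results = results, calls = calls, manifest = manifest,
                 results_path = results_path, manifest_path = manifest_path,
                 out_dir = out_dir))
}

#' Apply a batch of manual threshold overrides to a finished run
#'
#' The batch analogue of correcting thresholds after visual inspection:
#' reads the label exports of a previous [run_pipeline()] run, relabels the
#' retained droplets of each (well, channel) in the override table against
#' the supplied threshold, re-quantifies and re-normalizes the affected
#' wells only, and rewrites `results.csv`, the affected label exports and
#' the manifest (which records the override provenance).
#'
#' @param results_dir Output directory of a prior [run_pipeline()] run.
#' @param overrides Path to a CSV with columns `Well`, `Channel` (`ch1` /
#'   `ch2` or 1/2), `Threshold`, or an equivalent data.frame. An empty table
#'   leaves the results unchanged.
#' @return Invisibly, the updated results data.frame.
#' @export
apply_override_file <- function(results_dir, overrides) {
  if (!is.data.frame(overrides)) {
    overrides <- utils::read.csv(overrides, stringsAsFactors = FALSE)
  }
  missing <- setdiff(c("Well", "Channel", "Threshold"), names(overrides))
  if (length(missing))
    stop("override table is missing column(s): ", paste(missing, collapse = ", "))
  results_path <- file.path(results_dir, "results.csv")
  manifest_path <- file.path(results_dir, "manifest.json")
  if (!file.exists(results_path) || !file.exists(manifest_path))
    stop(results_dir, " does not contain a prior run (results.csv/manifest.json)")
  results <- read_results(results_path)
  manifest <- jsonlite::read_json(manifest_path)
  if (nrow(overrides) == 0L) return(invisible(results))

  unknown <- setdiff(unique(overrides$Well), results$well_id)
  if (length(unknown))
    stop("override(s) for unknown well(s): ", paste(unknown, collapse = ", "))
  droplet_volume_nl <- manifest$droplet_volume_nl
  level <- manifest$level
  control_type <- manifest$control_type

  for (i in seq_len(nrow(overrides))) {
    wid <- overrides$Well[i]
    chn <- overrides$Channel[i]
    if (is.numeric(chn) || grepl("^[12]$", chn)) chn <- paste0("ch", chn)
    thr <- as.numeric(overrides$Threshold[i])
    if (!is.finite(thr)) stop("non-finite override threshold for well ", wid)
    lab_path <- file.path(results_dir, "labels", paste0(wid, "_labels.csv"))
    if (!file.exists(lab_path)) stop("no label export for well ", wid)
    lab <- read_well_labels(lab_path)
    if (!chn %in% lab$channel)
      stop("channel ", chn, " not present in well ", wid)
    sel <- lab$channel == chn
    ret <- sel & lab$retained
    lab$label[ret] <- classify_droplets(lab$amplitude[ret], thr)
    lab$threshold[sel] <- thr
    lab$threshold_source[sel] <- "manual"
    utils::write.csv(lab, lab_path, row.names = FALSE, na = "")

    r <- which(results$well_id == wid)
    k <- sum(lab$label[ret] == "positive")
    n <- sum(ret)
    q <- quantify_channel(k, n, droplet_volume_nl, level)
    results[[paste0(chn, "_threshold")]][r] <- round(thr, 4)
    results[[paste0(chn, "_positives")]][r] <- k
    results[[paste0(chn, "_total")]][r] <- n
    results[[paste0(chn, "_concentration")]][r] <- q$concentration
    results[[paste0(chn, "_ci_low")]][r] <- q$ci_low
    results[[paste0(chn, "_ci_high")]][r] <- q$ci_high
    # re-normalize from the (updated) per-channel concentrations
    if (control_type != "none") {
      c1 <- results$ch1_concentration[r]
      c2 <- results$ch2_concentration[r]
      results$normalized_value[r] <-
        if (!is.na(c1) && !is.na(c2) && c2 > 0) {
          if (control_type == "single_gene") normalize_single_gene(c1, c2)
          else normalize_fourplex(c1, c2)
        } else NA_real_
    }
    manifest$overrides[[length(manifest$overrides) + 1L]] <-
      list(well = wid, channel = chn, threshold = thr,
           applied = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  }
  write_results(results, results_path)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(read_results(results_path))
}

#' Plot one well's droplets and fitted threshold
#'
#' Per channel: an amplitude scatter (droplet index vs amplitude, positives
#' highlighted, threshold as a horizontal line) next to an amplitude
#' histogram with the fitted mixture density overlaid. A channel without a
#' defined threshold is drawn without the line and watermarked
#' "no threshold".
#'
#' @param call A `well_call` from [call_well()].
#' @param well The corresponding [droplet_well()].
#' @param out_path Output figure path; the extension picks the device
#'   (`.pdf` or `.png`).
#' @return `out_path`, invisibly.
#' @export
render_well_plot <- function(call, well, out_path) {
  stopifnot(inherits(call, "well_call"), inherits(well, "droplet_well"))
  amps <- list(ch1 = well$ch1_amplitude, ch2 = well$ch2_amplitude)
  panels <- list()
  for (chn in names(call$channels)) {
    ch <- call$channels[[chn]]
    a <- amps[[chn]]
    if (!any(!(ch$labels %in% c("removed_low", "removed_outlier"))))
      stop("no retained droplets to plot for ", chn)
    df <- data.frame(idx = seq_along(a), amplitude = a,
                     label = ifelse(is.na(ch$labels), "unlabeled", ch$labels))
    p1 <- ggplot2::ggplot(df, ggplot2::aes(x = idx, y = amplitude,
                                           colour = label)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(
        positive = "#1b9e77", negative = "#7570b3",
        removed_low = "#d95f02", removed_outlier = "#e7298a",
        unlabeled = "grey60")) +
      ggplot2::labs(title = sprintf("%s %s", call$well_id, chn),
                    x = "droplet index", y = "amplitude") +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(legend.position = "bottom")
    p2 <- ggplot2::ggplot(df, ggplot2::aes(x = amplitude)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              bins = 120, fill = "grey75") +
      ggplot2::labs(x = "amplitude", y = "density") +
      ggplot2::theme_minimal(base_size = 9)
    if (!is.null(ch$fit)) {
      fit <- ch$fit
      grid <- seq(min(a), max(a), length.out = 400)
      dens <- rowSums(vapply(seq_len(fit$n_components), function(j)
        fit$weights[j] * stats::dnorm(grid, fit$means[j], fit$sds[j]),
        numeric(length(grid))))
      p2 <- p2 + ggplot2::geom_line(
        data = data.frame(amplitude = grid, density = dens),
        ggplot2::aes(x = amplitude, y = density), colour = "black")
    }
    if (is.finite(ch$threshold)) {
      p1 <- p1 + ggplot2::geom_hline(yintercept = ch$threshold,
                                     linetype = "dashed")
      p2 <- p2 + ggplot2::geom_vline(xintercept = ch$threshold,
                                     linetype = "dashed")
    } else {
      p1 <- p1 + ggplot2::annotate("text", x = mean(df$idx),
                                   y = mean(range(df$amplitude)),
                                   label = "no threshold", size = 6,
                                   colour = "grey40", alpha = 0.8)
    }
    panels <- c(panels, list(p1, p2))
  }
  fig <- patchwork::wrap_plots(panels, ncol = 2)
  ggplot2::ggsave(out_path, fig, width = 9,
                  height = 3.2 * length(call$channels), dpi = 150)
  invisible(out_path)
}
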