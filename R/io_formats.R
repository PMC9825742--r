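# Reading/writing the Bio-Rad amplitude CSV dialect, QuantaSoft-style sample
# sheets, and the plate-level results table.

#' Construct a droplet well
#'
#' A `droplet_well` holds the raw per-droplet fluorescence amplitudes of one
#' plate well: channel 1 carries the (methylation) target assay, channel 2 an
#' optional internal control. Rows are paired per droplet.
#'
#' @param well_id Plate-well label, e.g. `"A01"`.
#' @param ch1 Numeric vector of channel-1 amplitudes (arbitrary fluorescence
#'   units), one element per droplet.
#' @param ch2 Optional numeric vector of channel-2 amplitudes; must have the
#'   same length as `ch1`.
#' @param qc_flags Character vector of QC flags attached at construction.
#' @return An object of class `droplet_well` with fields `well_id`,
#'   `ch1_amplitude`, `ch2_amplitude` (`NULL` if absent), `n_droplets`,
#'   `sample`, `target`, `target_type` and `qc_flags`.
#' @export
droplet_well <- function(well_id, ch1, ch2 = NULL, qc_flags = character()) {
  ch1 <- as.numeric(ch1)
  if (length(ch1) < 1L) stop("no droplets")
  if (!all(is.finite(ch1))) stop("channel 1 amplitudes must all be finite")
  if (!is.null(ch2)) {
    ch2 <- as.numeric(ch2)
    if (length(ch2) != length(ch1))
      stop("channel 2 must have one amplitude per droplet (lengths differ)")
    if (!all(is.finite(ch2))) stop("channel 2 amplitudes must all be finite")
  }
  structure(
    list(well_id = as.character(well_id),
         ch1_amplitude = ch1,
         ch2_amplitude = ch2,
         n_droplets = length(ch1),
         sample = "", target = "", target_type = "",
         qc_flags = unique(as.character(qc_flags))),
    class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("<droplet_well %s: %d droplets, %s>\n", x$well_id, x$n_droplets,
              if (is.null(x$ch2_amplitude)) "1 channel" else "2 channels"))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

# Bio-Rad export convention: "<experiment>_<WELL>_Amplitude.csv".
parse_well_id <- function(filename) {
  base <- basename(filename)
  m <- regmatches(base,
                  regexec("_([A-Ha-h](?:0[1-9]|1[0-2]))_Amplitude\\.csv$",
                          base, ignore.case = TRUE))[[1]]
  if (length(m) == 2L)
    list(well_id = toupper(m[2]), parsed = TRUE)
  else
    list(well_id = tools::file_path_sans_ext(base), parsed = FALSE)
}

#' Read a per-well amplitude CSV
#'
#' Parses a well-specific amplitude file as exported by the Bio-Rad QX ddPCR
#' system: a comma-separated table with one row per droplet and one column per
#' fluorescence channel, with or without the `"Ch1 Amplitude","Ch2 Amplitude"`
#' header (presence is detected by attempting a numeric parse of the first
#' row). The well label is taken from the trailing `_<WELL>_Amplitude.csv`
#' token of the filename; when the filename does not follow that convention
#' the file stem is used and the flag `well_id_unparsed` attached.
#'
#' @param path Path to the CSV file.
#' @return A [droplet_well()]; single-column files yield a well with channel 2
#'   absent.
#' @export
read_amplitude_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(trimws(first[1]))) stop("no droplets in ", path)
  fields <- trimws(sub("^\ufeff", "", strsplit(first[1], ",", fixed = TRUE)[[1]]))
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.csv(path, header = has_header, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no droplets in ", path)
  names(df) <- trimws(sub("^\ufeff", "", names(df)))
  # Prefer the named amplitude columns when present (newer QuantaSoft exports
  # append extra columns such as "Cluster"); otherwise take the leading ones.
  amp_cols <- grep("^Ch[12] Amplitude$", names(df), value = TRUE)
  cols <- if (has_header && length(amp_cols) >= 1L) sort(amp_cols)
          else names(df)[seq_len(min(2L, ncol(df)))]
  amps <- lapply(cols, function(cn) {
    v <- df[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric amplitude value '%s' in column '%s', row %d of %s",
                   as.character(v[bad[1]]), cn, bad[1], basename(path)))
    num
  })
  id <- parse_well_id(path)
  droplet_well(id$well_id, amps[[1]],
               ch2 = if (length(amps) >= 2L) amps[[2]],
               qc_flags = if (id$parsed) character() else "well_id_unparsed")
}

sheet_columns <- c("Well", "Sample", "TargetType", "Target")

#' Read a QuantaSoft-style sample sheet
#'
#' The sheet must provide the four columns `Well`, `Sample`, `TargetType`
#' and `Target` (names matched exactly after stripping whitespace and
#' byte-order marks); any additional columns are dropped.
#'
#' @param path Path to the sample sheet CSV.
#' @return A data.frame with exactly the four required columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- trimws(sub("^\ufeff", "", names(df)))
  missing <- setdiff(sheet_columns, names(df))
  if (length(missing))
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  df[, sheet_columns, drop = FALSE]
}

#' Annotate wells with sample-sheet metadata
#'
#' Attaches sample/target annotation from a sample sheet to a list of wells.
#' Wells without a matching sheet row keep placeholder (empty) annotation and
#' are flagged `no_sheet_entry`; when no sheet is given at all, every well
#' keeps placeholders without the flag. Droplet amplitudes are never touched.
#'
#' @param wells List of [droplet_well()] objects.
#' @param sheet A data.frame from [read_sample_sheet()], or `NULL`.
#' @return The list of wells with `sample`, `target`, `target_type` filled in.
#' @export
annotate_wells <- function(wells, sheet = NULL) {
  stopifnot(is.list(wells), all(vapply(wells, inherits, TRUE, "droplet_well")))
  if (is.null(sheet)) return(wells)
  ids <- vapply(wells, `[[`, "", "well_id")
  dup <- unique(sheet$Well[duplicated(sheet$Well)])
  dup <- intersect(dup, ids)
  if (length(dup))
    stop("duplicate sample sheet rows for well(s): ", paste(dup, collapse = ", "))
  lapply(wells, function(w) {
    i <- match(w$well_id, sheet$Well)
    if (is.na(i)) {
      w$qc_flags <- unique(c(w$qc_flags, "no_sheet_entry"))
    } else {
      w$sample <- sheet$Sample[i]
      w$target <- sheet$Target[i]
      w$target_type <- sheet$TargetType[i]
    }
    w
  })
}

# Column layout of the plate results table. Counts are integer, floats are
# written with 4 decimal places so that write -> read -> write is a fixed
# point (byte-identical files).
results_count_cols <- c("ch1_positives", "ch1_total", "ch2_positives", "ch2_total")
results_float_cols <- c("ch1_threshold", "ch1_concentration", "ch1_ci_low",
                        "ch1_ci_high", "ch2_threshold", "ch2_concentration",
                        "ch2_ci_low", "ch2_ci_high", "normalized_value",
                        "c_constant")
results_char_cols  <- c("well_id", "sample", "target", "control_type", "qc_flags")
results_all_cols   <- c("well_id", "sample", "target",
                        "ch1_threshold", "ch1_positives", "ch1_total",
                        "ch1_concentration", "ch1_ci_low", "ch1_ci_high",
                        "ch2_threshold", "ch2_positives", "ch2_total",
                        "ch2_concentration", "ch2_ci_low", "ch2_ci_high",
                        "normalized_value", "control_type", "c_constant",
                        "qc_flags")

#' Write the plate results table to CSV
#'
#' One row per well; counts are written as integers, concentrations,
#' thresholds and normalized values with 4 decimal places, and missing values
#' as empty cells (e.g. `normalized_value` for wells with `control_type`
#' `"none"`). [read_results()] reproduces the written table exactly.
#'
#' @param results Data.frame of results rows (as produced by [run_pipeline()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop("results must contain at least one row")
  out <- results[, results_all_cols, drop = FALSE]
  for (cn in results_float_cols)
    out[[cn]] <- ifelse(is.na(out[[cn]]), NA_character_,
                        sprintf("%.4f", as.numeric(out[[cn]])))
  for (cn in results_count_cols)
    out[[cn]] <- ifelse(is.na(out[[cn]]), NA_character_,
                        sprintf("%d", as.integer(out[[cn]])))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to a results CSV.
#' @return Data.frame with typed columns (integer counts, numeric floats).
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(results_all_cols, names(df))
  if (length(missing))
    stop("results file is missing column(s): ", paste(missing, collapse = ", "))
  for (cn in results_float_cols) df[[cn]] <- as.numeric(ifelse(df[[cn]] == "", NA, df[[cn]]))
  for (cn in results_count_cols) df[[cn]] <- as.integer(ifelse(df[[cn]] == "", NA, df[[cn]]))
  df
}

#' Write the per-well droplet label export
#'
#' One row per droplet and channel: index, amplitude, label
#' (`positive`/`negative`/`removed_low`/`removed_outlier`, `NA` when no
#' threshold could be set), retained flag, threshold and threshold source.
#'
#' @param call A `well_call` from [call_well()].
#' @param well The [droplet_well()] the call was made on.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_well_labels <- function(call, well, path) {
  stopifnot(inherits(call, "well_call"), inherits(well, "droplet_well"))
  amps <- list(ch1 = well$ch1_amplitude, ch2 = well$ch2_amplitude)
  rows <- lapply(names(call$channels), function(chn) {
    ch <- call$channels[[chn]]
    data.frame(well_id = well$well_id,
               droplet_index = seq_along(amps[[chn]]),
               channel = chn,
               amplitude = amps[[chn]],
               label = ch$labels,
               retained = !(ch$labels %in% c("removed_low", "removed_outlier")),
               threshold = ch$threshold,
               threshold_source = ch$threshold_source,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

read_well_labels <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$label[df$label == ""] <- NA_character_
  df$retained <- as.logical(df$retained)
  df$threshold <- as.numeric(df$threshold)
  df
}
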