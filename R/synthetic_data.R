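# Simulation of ddPCR wells and plates with known ground truth: Gaussian
# negative/positive amplitude clouds, uniform "rain" between the clouds,
# destroyed droplets near zero amplitude, and well-wide baseline shifts.

#' Configuration of a simulated well
#'
#' Defaults emulate a typical Bio-Rad QX-style methylation well: 20,000
#' droplets, negative cloud at 2000 +/- 120 and positive cloud at
#' 8000 +/- 180 arbitrary fluorescence units on both channels (a two-cloud
#' geometry, about 33 negative-cloud standard deviations of separation),
#' target occupancy 0.1 copies per droplet against an internal control at
#' 0.2, and no rain, destroyed droplets or baseline shift unless requested.
#'
#' @param n_droplets Number of droplets in the well.
#' @param lambda_ch1 True mean copies per droplet, channel 1 (target).
#' @param lambda_ch2 True mean copies per droplet, channel 2 (internal
#'   control), or `NULL` for a single-channel well.
#' @param neg_mean,neg_sd,pos_mean,pos_sd Amplitude cloud parameters
#'   (arbitrary fluorescence units), recycled across channels.
#' @param rain_fraction Fraction of *occupied* droplets whose amplitude is
#'   drawn uniformly between the cloud means instead of from the positive
#'   cloud.
#' @param destroyed_fraction Fraction of all droplets replaced by destroyed
#'   droplets (amplitude uniform in [0, 100], both channels; physically a
#'   ruptured droplet is ruined in every channel).
#' @param baseline_shift Constant added to every amplitude of the well.
#' @param seed Integer seed; the simulated well is fully reproducible from
#'   it.
#' @return An object of class `sim_well_config`.
#' @export
sim_well_config <- function(n_droplets = 20000L,
                            lambda_ch1 = 0.1,
                            lambda_ch2 = 0.2,
                            neg_mean = 2000, neg_sd = 120,
                            pos_mean = 8000, pos_sd = 180,
                            rain_fraction = 0,
                            destroyed_fraction = 0,
                            baseline_shift = 0,
                            seed = 1L) {
  stopifnot(n_droplets >= 1L, lambda_ch1 >= 0,
            is.null(lambda_ch2) || lambda_ch2 >= 0,
            pos_mean > neg_mean, neg_sd > 0, pos_sd > 0,
            rain_fraction >= 0, rain_fraction < 1,
            destroyed_fraction >= 0, destroyed_fraction < 1)
  structure(list(n_droplets = as.integer(n_droplets),
                 lambda_ch1 = lambda_ch1, lambda_ch2 = lambda_ch2,
                 neg_mean = neg_mean, neg_sd = neg_sd,
                 pos_mean = pos_mean, pos_sd = pos_sd,
                 rain_fraction = rain_fraction,
                 destroyed_fraction = destroyed_fraction,
                 baseline_shift = baseline_shift,
                 seed = as.integer(seed)),
            class = "sim_well_config")
}

sim_channel <- function(n, lambda, cfg) {
  occupied <- stats::runif(n) < (1 - exp(-lambda))
  amp <- stats::rnorm(n, cfg$neg_mean, cfg$neg_sd)
  n_occ <- sum(occupied)
  if (n_occ > 0) {
    amp[occupied] <- stats::rnorm(n_occ, cfg$pos_mean, cfg$pos_sd)
    if (cfg$rain_fraction > 0) {
      rain <- which(occupied)[stats::runif(n_occ) < cfg$rain_fraction]
      amp[rain] <- stats::runif(length(rain), cfg$neg_mean, cfg$pos_mean)
    }
  }
  list(occupied = occupied, amplitude = amp)
}

#' Simulate one ddPCR well with ground truth
#'
#' Each droplet's occupancy is an independent Bernoulli draw with
#' probability `1 - exp(-lambda)` (the Poisson occupancy model); occupied
#' droplets sample from the positive cloud, empty droplets from the negative
#' cloud. A `rain_fraction` of occupied droplets instead take amplitudes
#' uniform between the cloud means; a `destroyed_fraction` of all droplets
#' are overwritten with near-zero amplitudes in every channel; the
#' `baseline_shift` is added last to every amplitude.
#'
#' @param config A [sim_well_config()].
#' @param well_id Well label for the emitted [droplet_well()].
#' @return A list with `well` (a [droplet_well()]) and `truth` (class
#'   `sim_truth`): per-channel occupancy labels and true positive counts,
#'   destroyed-droplet indices, and the generating config.
#' @export
simulate_well <- function(config = sim_well_config(), well_id = "A01") {
  stopifnot(inherits(config, "sim_well_config"))
  set.seed(config$seed)
  n <- config$n_droplets
  ch1 <- sim_channel(n, config$lambda_ch1, config)
  ch2 <- if (!is.null(config$lambda_ch2)) sim_channel(n, config$lambda_ch2, config)
  destroyed <- integer(0)
  if (config$destroyed_fraction > 0) {
    destroyed <- which(stats::runif(n) < config$destroyed_fraction)
    if (length(destroyed)) {
      ch1$amplitude[destroyed] <- stats::runif(length(destroyed), 0, 100)
      if (!is.null(ch2)) ch2$amplitude[destroyed] <- stats::runif(length(destroyed), 0, 100)
    }
  }
  ch1$amplitude <- ch1$amplitude + config$baseline_shift
  if (!is.null(ch2)) ch2$amplitude <- ch2$amplitude + config$baseline_shift
  well <- droplet_well(well_id, ch1$amplitude, ch2 = ch2$amplitude)
  truth <- structure(list(
    well_id = well_id,
    occupied_ch1 = ch1$occupied,
    occupied_ch2 = if (!is.null(ch2)) ch2$occupied,
    true_positive_ch1 = sum(ch1$occupied),
    true_positive_ch2 = if (!is.null(ch2)) sum(ch2$occupied) else NA_integer_,
    destroyed_idx = destroyed,
    config = config), class = "sim_truth")
  list(well = well, truth = truth)
}

#' Simulate a plate and write it in the Bio-Rad CSV dialect
#'
#' Writes one `<prefix>_<WELL>_Amplitude.csv` per well (readable by
#' [read_amplitude_file()]), a matching sample sheet
#' (`<prefix>_sample_sheet.csv`) and a ground-truth table
#' (`<prefix>_truth.csv`) keyed by well id.
#'
#' @param configs Named list mapping well ids (e.g. `"A01"`) to
#'   [sim_well_config()] objects.
#' @param out_dir Output directory (created if needed).
#' @param prefix Filename prefix for the emitted files.
#' @return Invisibly, a list with `amplitude_files`, `sample_sheet`,
#'   `truth_file` and the truth data.frame.
#' @export
simulate_plate <- function(configs, out_dir, prefix = "sim") {
  stopifnot(is.list(configs), length(configs) >= 1L)
  ids <- names(configs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("configs must be a named list keyed by well id")
  if (anyDuplicated(ids))
    stop("duplicate well id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- ids[!grepl("^[A-H](0[1-9]|1[0-2])$", ids)]
  if (length(bad)) stop("invalid plate well label(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  truth_rows <- list()
  for (id in ids) {
    sim <- simulate_well(configs[[id]], well_id = id)
    path <- file.path(out_dir, sprintf("%s_%s_Amplitude.csv", prefix, id))
    df <- data.frame(`Ch1 Amplitude` = sim$well$ch1_amplitude, check.names = FALSE)
    if (!is.null(sim$well$ch2_amplitude))
      df[["Ch2 Amplitude"]] <- sim$well$ch2_amplitude
    utils::write.csv(df, path, row.names = FALSE)
    files <- c(files, path)
    cfg <- configs[[id]]
    for (chn in c("ch1", "ch2")) {
      lam <- cfg[[paste0("lambda_", chn)]]
      if (is.null(lam)) next
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        well_id = id, channel = chn, true_lambda = lam,
        true_positive_count = if (chn == "ch1") sim$truth$true_positive_ch1
                              else sim$truth$true_positive_ch2,
        n_droplets = cfg$n_droplets,
        neg_mean = cfg$neg_mean, neg_sd = cfg$neg_sd,
        pos_mean = cfg$pos_mean, pos_sd = cfg$pos_sd,
        rain_fraction = cfg$rain_fraction,
        destroyed_fraction = cfg$destroyed_fraction,
        baseline_shift = cfg$baseline_shift, seed = cfg$seed,
        stringsAsFactors = FALSE)
    }
  }
  sheet <- data.frame(Well = ids,
                      Sample = paste0("synthetic_", ids),
                      TargetType = "Ch1Unknown",
                      Target = "synthetic_target",
                      stringsAsFactors = FALSE)
  sheet_path <- file.path(out_dir, paste0(prefix, "_sample_sheet.csv"))
  utils::write.csv(sheet, sheet_path, row.names = FALSE)
  truth <- do.call(rbind, truth_rows)
  truth_path <- file.path(out_dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(list(amplitude_files = files, sample_sheet = sheet_path,
                 truth_file = truth_path, truth = truth))
}
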