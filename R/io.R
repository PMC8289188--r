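#' Read a kinetic plate CSV with well metadata
#'
#' The kinetics file has a `time_h` column and one column per well; the
#' sidecar metadata table maps each well to its condition
#' (`well, protein_conc_uM, pom_id, pom_conc_uM, replicate`). Rows with
#' non-finite values are dropped per trace with a logged count.
#'
#' @param path Path to the kinetics CSV.
#' @param metadata_path Path to the well-metadata CSV.
#' @return A list of [kinetic_trace()] objects, one per well column.
#' @export
read_kinetic_csv <- function(path, metadata_path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(d))
    stop("kinetics CSV must contain a 'time_h' column", call. = FALSE)
  meta <- utils::read.csv(metadata_path, check.names = FALSE)
  need <- c("well", "protein_conc_uM", "pom_id", "pom_conc_uM", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(diff(d$time_h) <= 0))
    stop("time_h must be strictly increasing", call. = FALSE)
  wells <- setdiff(names(d), "time_h")
  lapply(wells, function(w) {
    row <- meta[meta$well == w, , drop = FALSE]
    if (nrow(row) != 1L)
      stop(sprintf("well '%s' has no (unique) metadata entry", w),
           call. = FALSE)
    y <- d[[w]]
    ok <- is.finite(y) & is.finite(d$time_h)
    if (any(!ok))
      warning(sprintf("well '%s': dropped %d non-finite row(s)",
                      w, sum(!ok)), call. = FALSE)
    kinetic_trace(d$time_h[ok], y[ok],
                  protein_conc = row$protein_conc_uM,
                  pom_id = as.character(row$pom_id),
                  pom_conc = row$pom_conc_uM,
                  replicate = row$replicate)
  })
}

#' Write a kinetic panel to CSV plus metadata sidecar
#'
#' Inverse of [read_kinetic_csv()]: all traces must share a time grid.
#'
#' @param traces List of [kinetic_trace()] objects.
#' @param path Output kinetics CSV path.
#' @param metadata_path Output metadata CSV path.
#' @return Invisibly, the well names used.
#' @export
write_kinetic_csv <- function(traces, path, metadata_path) {
  grids <- lapply(traces, function(tr) tr$times)
  if (!all(vapply(grids, identical, logical(1), grids[[1]])))
    stop("all traces must share one time grid to be written as a plate",
         call. = FALSE)
  wells <- sprintf("W%02d", seq_along(traces))
  d <- data.frame(time_h = grids[[1]])
  for (i in seq_along(traces)) d[[wells[i]]] <- traces[[i]]$signal
  utils::write.csv(d, path, row.names = FALSE)
  meta <- data.frame(
    well = wells,
    protein_conc_uM = vapply(traces, function(tr) tr$protein_conc, numeric(1)),
    pom_id = vapply(traces, function(tr) tr$pom_id, character(1)),
    pom_conc_uM = vapply(traces, function(tr) tr$pom_conc, numeric(1)),
    replicate = vapply(traces, function(tr) as.integer(tr$replicate),
                       integer(1)))
  utils::write.csv(meta, metadata_path, row.names = FALSE)
  invisible(wells)
}

#' Read a titration CSV (`conc_uM`, `signal`)
#' @param path CSV path.
#' @return data.frame with `conc_uM` and `signal`.
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("conc_uM", "signal") %in% names(d)))
    stop("titration CSV needs columns conc_uM, signal", call. = FALSE)
  d
}

#' Read a quenching CSV (`Q_M`, `F`)
#' @param path CSV path.
#' @return data.frame with `Q_M` and `F`.
#' @export
read_quenching_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("Q_M", "F") %in% names(d)))
    stop("quenching CSV needs columns Q_M, F", call. = FALSE)
  d
}

#' Read a spectrum CSV (`wavelength_nm` plus one column per repeat)
#' @param path CSV path.
#' @return A [spectrum_data()]; repeats attached when the file has more
#'   than one value column.
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(d))
    stop("spectrum CSV needs a wavelength_nm column", call. = FALSE)
  vals <- d[setdiff(names(d), "wavelength_nm")]
  if (ncol(vals) == 0L)
    stop("spectrum CSV has no value columns", call. = FALSE)
  if (ncol(vals) == 1L) spectrum_data(d$wavelength_nm, vals[[1]])
  else spectrum_data(d$wavelength_nm, repeats = as.matrix(vals))
}

#' Read an AFM heights CSV (`height_nm`, optional condition columns)
#' @param path CSV path.
#' @return Numeric vector of heights in nm.
#' @export
read_heights_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"height_nm" %in% names(d))
    stop("heights CSV needs a height_nm column", call. = FALSE)
  d$height_nm
}

.known_config_keys <- c(
  "kinetics_csv", "metadata_csv", "simulate", "reference_condition",
  "protein_conc", "ratios", "time_end_h", "time_step_h", "noise_fraction",
  "n_replicates", "rate_model", "plateau_model", "parameterization",
  "depletion", "smoothing_window", "bootstrap_n", "seed", "output_dir")

#' Build and validate an analysis configuration
#'
#' Accepts either a YAML file path or a named list of options; every key
#' is validated against the known option set before any computation.
#' Defaults mirror the aggregation assay design (75 uM protein, ratios
#' 0-10, 150 h at 10-minute sampling).
#'
#' @param config A named list or a path to a YAML file.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop("unknown config option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- list(
    kinetics_csv = NULL, metadata_csv = NULL, simulate = TRUE,
    reference_condition = "none", protein_conc = 75,
    ratios = c(0, 0.5, 1, 2, 4, 8, 10), time_end_h = 150,
    time_step_h = 1 / 6, noise_fraction = 0.02, n_replicates = 3L,
    rate_model = default_rate_model(),
    plateau_model = default_plateau_model(),
    parameterization = "rate", depletion = FALSE,
    smoothing_window = 9L, bootstrap_n = 0L, seed = 1L,
    output_dir = "amypom-output")
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("seed must be an integer", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$kinetics_csv) || is.null(cfg$metadata_csv))
      stop("input file missing: kinetics_csv and metadata_csv are required ",
           "when simulate is FALSE", call. = FALSE)
    for (p in c(cfg$kinetics_csv, cfg$metadata_csv))
      if (!file.exists(p))
        stop("input file missing or not found: ", p, call. = FALSE)
  }
  cfg$parameterization <- match.arg(cfg$parameterization, c("rate", "scale"))
  structure(cfg, class = c("analysis_config", "list"))
}
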