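# File formats: the native scan JSON dialect (lossless round-trip), optional
# mzML import, and study configuration.

#' Write / read a run in the native scan JSON dialect
#'
#' The dialect is `{"scans": [{"time": s, "polarity": "+"|"-", "mz": [...],
#' "intensity": [...]}, ...]}` -- human-diffable and lossless, including scans
#' that carry no peaks.
#'
#' @param run A scan-level run tibble (see [generate_run()]).
#' @param path JSON file path.
#' @return `write_run()` returns `path` invisibly; `read_run()` the run
#'   tibble of class `ms_run`.
#' @export
write_run <- function(run, path) {
  grid <- scan_grid(run)
  scans <- lapply(seq_len(nrow(grid)), function(i) {
    rows <- run$scan == grid$scan[i]
    list(time = grid$time[i], polarity = grid$polarity[i],
         mz = run$mz[rows], intensity = run$intensity[rows])
  })
  jsonlite::write_json(list(scans = scans), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (is.null(x$scans) || length(x$scans) == 0) {
    stop("no scans in ", path, call. = FALSE)
  }
  assemble_run(
    time = vapply(x$scans, `[[`, numeric(1), "time"),
    polarity = vapply(x$scans, `[[`, character(1), "polarity"),
    mz = lapply(x$scans, function(s) as.numeric(s$mz %||% numeric())),
    intensity = lapply(x$scans, function(s)
      as.numeric(s$intensity %||% numeric()))
  )
}

assemble_run <- function(time, polarity, mz, intensity) {
  n_peaks <- lengths(mz)
  stopifnot(identical(n_peaks, lengths(intensity)))
  bad <- vapply(mz, is.unsorted, logical(1), strictly = TRUE)
  if (any(bad)) {
    stop("m/z not strictly increasing in scan(s) ",
         paste(utils::head(which(bad), 3), collapse = ", "), call. = FALSE)
  }
  run <- tibble::tibble(
    scan = rep(seq_along(time), n_peaks),
    time = rep(time, n_peaks),
    polarity = rep(polarity, n_peaks),
    mz = unlist(mz, use.names = FALSE) %||% numeric(),
    intensity = unlist(intensity, use.names = FALSE) %||% numeric()
  )
  attr(run, "scans") <- tibble::tibble(scan = seq_along(time), time = time,
                                       polarity = polarity)
  class(run) <- c("ms_run", class(run))
  run
}

#' Import centroided scans from an mzML file
#'
#' Maps scan start times, polarity and centroid arrays into the native run
#' representation. Profile-mode spectra are rejected; centroid the data
#' upstream first. Requires the `mzR` package.
#'
#' @param path mzML file path.
#' @return A run tibble of class `ms_run`.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML import needs the 'mzR' package", call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (nrow(hd) == 0) stop("no scans in ", path, call. = FALSE)
  if (!is.null(hd$centroided) && any(!is.na(hd$centroided) & !hd$centroided)) {
    stop("profile-mode spectra in ", path,
         "; only centroided mzML is supported", call. = FALSE)
  }
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  pol <- if (!is.null(hd$polarity)) {
    ifelse(hd$polarity >= 0, "+", "-")
  } else rep("+", nrow(hd))
  assemble_run(
    time = hd$retentionTime,
    polarity = pol,
    mz = lapply(pk, function(m) m[, 1]),
    intensity = lapply(pk, function(m) m[, 2])
  )
}

#' Instrument profiles
#'
#' Abundance threshold, acquisition window and polarity for the two supported
#' instrument profiles: `"synapt"` (Q-TOF: threshold 2e3, 50-750 Th,
#' negative, 5 pulses averaged) and `"orbitrap"` (threshold 1.5e4, 67-1000
#' Th, positive, 3 pulses averaged).
#'
#' @param name `"synapt"` or `"orbitrap"`.
#' @return A list: `threshold`, `mz_range`, `polarity`, `k_pulses`.
#' @export
instrument_profile <- function(name = c("synapt", "orbitrap")) {
  switch(match.arg(name),
    synapt = list(name = "synapt", threshold = 2e3, mz_range = c(50, 750),
                  polarity = "-", k_pulses = 5L),
    orbitrap = list(name = "orbitrap", threshold = 1.5e4,
                    mz_range = c(67, 1000), polarity = "+", k_pulses = 3L)
  )
}

#' Pipeline configuration
#'
#' All thresholds default to the processing protocol this package implements:
#' instrument abundance threshold, IS normalization, 3x blank filter, 80%
#' prevalence, 80% QC-missingness, 20% sample-missingness outlier rule,
#' half-minimum imputation, 30% QC-RSD cut, glog + autoscaling, volcano
#' p < 0.05 with FC > 2 or < 0.5, VIP > 1.8, 10 ppm annotation.
#'
#' @param instrument `"synapt"` or `"orbitrap"`.
#' @param k_pulses Pulses averaged per sample (profile default).
#' @param is_mz Internal standard m/z.
#' @param seed Integer seed driving pulse selection.
#' @param ... Override any of the remaining thresholds (see details in the
#'   returned list).
#' @return A list of class `study_config`.
#' @export
study_config <- function(instrument = "synapt", k_pulses = NULL,
                         is_mz = 183.0879, seed = 1, ...) {
  prof <- instrument_profile(instrument)
  cfg <- list(
    instrument = prof$name,
    instrument_threshold = prof$threshold,
    mz_range = prof$mz_range,
    polarity = prof$polarity,
    k_pulses = k_pulses %||% prof$k_pulses,
    is_mz = is_mz,
    is_tol_ppm = 10,
    min_scans = 3,
    min_height = NULL,
    is_window = 0.2,
    align_ppm = 10,
    mz_bin_ppm = 10,
    blank_factor = 3,
    blank_per_sample = FALSE,
    prevalence_min = 0.8,
    qc_max_missing = 0.8,
    sample_max_missing = 0.2,
    max_rsd = 0.30,
    glog_lambda = "auto",
    p_cut = 0.05,
    fc_hi = 2,
    fc_lo = 0.5,
    vip_cut = 1.8,
    n_components = 2,
    n_ortho = 1,
    annotation_tol_ppm = 10,
    seed = seed
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "study_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields not present in the file keep their [study_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(study_config, x)
}
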