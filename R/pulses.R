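# Chronogram extraction and pulse-level processing of one acquisition run.

# Full scan grid for a run: prefer the "scans" attribute (lossless even when
# some scans carry no peaks), otherwise derive it from the peak rows.
scan_grid <- function(run) {
  g <- attr(run, "scans")
  if (is.null(g)) {
    g <- dplyr::distinct(tibble::as_tibble(run[c("scan", "time", "polarity")]))
    g <- dplyr::arrange(g, .data$scan)
  }
  g
}

new_chronogram <- function(grid, intensity, kind, target_mz = NULL,
                           tol_ppm = NULL) {
  out <- tibble::tibble(scan = grid$scan, time = grid$time,
                        intensity = intensity)
  attr(out, "kind") <- kind
  attr(out, "target_mz") <- target_mz
  attr(out, "tol_ppm") <- tol_ppm
  class(out) <- c("chronogram", class(out))
  out
}

#' Total ion chronogram
#'
#' Per-scan sum of all peak intensities. In a pulsed acquisition the TIC
#' appears as a train of discrete pulses rather than a continuous trace.
#'
#' @param run A scan-level run tibble (`scan`, `time`, `polarity`, `mz`,
#'   `intensity`), e.g. from [generate_run()] or [read_run()].
#' @return A tibble (`scan`, `time`, `intensity`) of class `chronogram`.
#' @export
compute_tic <- function(run) {
  grid <- scan_grid(run)
  if (nrow(grid) == 0) stop("empty run", call. = FALSE)
  if (length(unique(grid$polarity)) > 1) {
    stop("run mixes polarities; split before computing a TIC", call. = FALSE)
  }
  s <- tapply(run$intensity, factor(run$scan, levels = grid$scan), sum,
              default = 0)
  new_chronogram(grid, as.numeric(s), "TIC")
}

#' Extracted ion chronogram
#'
#' Per-scan sum of intensities within a ppm window of a target m/z; zero where
#' the target is absent.
#'
#' @inheritParams compute_tic
#' @param target_mz Target m/z, Th.
#' @param tol_ppm Half-window in ppm.
#' @return A `chronogram` tibble.
#' @export
extract_eic <- function(run, target_mz, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  grid <- scan_grid(run)
  if (nrow(grid) == 0) stop("empty run", call. = FALSE)
  tol <- tol_ppm * 1e-6 * target_mz
  hit <- abs(run$mz - target_mz) <= tol
  s <- tapply(run$intensity[hit], factor(run$scan[hit], levels = grid$scan),
              sum, default = 0)
  new_chronogram(grid, as.numeric(s), "EIC", target_mz, tol_ppm)
}

#' Detect pulses on a chronogram
#'
#' Threshold-crossing segmentation: maximal contiguous runs of scans with
#' intensity at or above `min_height`, kept if at least `min_scans` long.
#' Pulses in a pulsed-spray acquisition are well separated, so no
#' derivative-based peak picking is needed. Area is the trapezoidal integral
#' over the segment (zero baseline); the apex is the argmax, earliest scan on
#' ties.
#'
#' @param chron A `chronogram` tibble.
#' @param min_height Detection threshold, counts. Default: 1% of the
#'   chronogram maximum (pulses rise orders of magnitude above the noise
#'   floor in this acquisition mode).
#' @param min_scans Minimum scans per pulse.
#' @return A tibble with one row per pulse: `pulse`, `start_index`,
#'   `end_index`, `apex_index` (0-based scan indices), `scan_count`, `area`
#'   (counts*s), `start_time`, `end_time`, `width` (s), `apex_intensity`.
#' @export
detect_pulses <- function(chron, min_height = NULL, min_scans = 3) {
  if (nrow(chron) == 0) return(empty_pulses())
  if (is.null(min_height)) {
    min_height <- 0.01 * max(chron$intensity)
    if (min_height <= 0) return(empty_pulses())  # flat-zero chronogram
  }
  stopifnot(min_height > 0, min_scans >= 1)
  above <- chron$intensity >= min_height
  if (!any(above)) return(empty_pulses())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- which(r$values & r$lengths >= min_scans)
  if (!length(seg)) return(empty_pulses())
  out <- lapply(seq_along(seg), function(j) {
    i0 <- starts[seg[j]]; i1 <- ends[seg[j]]
    idx <- i0:i1
    y <- chron$intensity[idx]; t <- chron$time[idx]
    apex <- idx[which.max(y)]
    tibble::tibble(
      pulse = j,
      start_index = i0 - 1L, end_index = i1 - 1L, apex_index = apex - 1L,
      scan_count = i1 - i0 + 1L,
      area = trapezoid(t, y),
      start_time = t[1], end_time = t[length(t)],
      width = t[length(t)] - t[1],
      apex_intensity = max(y)
    )
  })
  dplyr::bind_rows(out)
}

empty_pulses <- function() {
  tibble::tibble(pulse = integer(), start_index = integer(),
                 end_index = integer(), apex_index = integer(),
                 scan_count = integer(), area = numeric(),
                 start_time = numeric(), end_time = numeric(),
                 width = numeric(), apex_intensity = numeric())
}

trapezoid <- function(t, y) {
  if (length(t) < 2) return(0)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Integrate a chronogram over detected pulse bounds
#'
#' Used to measure the internal standard's per-pulse EIC area over pulse
#' bounds detected on the TIC.
#'
#' Detected bounds are padded by `pad` scans toward baseline (without crossing
#' a neighbouring pulse) so the envelope tails below the detection threshold
#' are counted.
#'
#' @param chron A `chronogram` (typically the IS EIC).
#' @param pulses Pulse table from [detect_pulses()].
#' @param pad Scans of baseline padding on each side (default 2).
#' @return `pulses` with an added `is_area` column.
#' @export
integrate_pulses <- function(chron, pulses, pad = 2L) {
  n <- nrow(chron)
  pulses$is_area <- vapply(seq_len(nrow(pulses)), function(i) {
    lo <- pulses$start_index[i] + 1L - pad
    hi <- pulses$end_index[i] + 1L + pad
    if (i > 1) lo <- max(lo, pulses$end_index[i - 1] + 2L)
    if (i < nrow(pulses)) hi <- min(hi, pulses$start_index[i + 1])
    idx <- max(1L, lo):min(n, hi)
    trapezoid(chron$time[idx], chron$intensity[idx])
  }, numeric(1))
  pulses
}

#' Internal-standard window rejection of outlier pulses
#'
#' Flags pulses whose IS EIC area falls outside a window of +/- `window`
#' around the median area of all candidate pulses (inclusive bounds; the
#' median is computed once, not recomputed after removals).
#'
#' @param pulses Pulse table with an `is_area` column (see
#'   [integrate_pulses()]), or a bare numeric vector of areas.
#' @param window Half-width of the acceptance interval as a fraction of the
#'   median (default 0.2, i.e. +/-20%).
#' @return The pulse table with a logical `kept` column (for a numeric input,
#'   the logical vector itself).
#' @export
reject_outlier_pulses <- function(pulses, window = 0.2) {
  areas <- if (is.data.frame(pulses)) pulses$is_area else pulses
  if (length(areas) == 0) stop("no pulses to QC", call. = FALSE)
  m <- median(areas)
  kept <- areas >= (1 - window) * m & areas <= (1 + window) * m
  if (!is.data.frame(pulses)) return(kept)
  pulses$kept <- kept
  attr(pulses, "is_median") <- m
  pulses
}

#' Random selection of pulses for the representative spectrum
#'
#' Uniform subset of size `k` without replacement from the kept pulses,
#' returned in time order; deterministic under `seed`. A handful of pulses
#' suffices for a representative spectrum, which is what makes the method
#' usable on extremely small sample volumes.
#'
#' @param kept Pulse table (rows already restricted to kept pulses).
#' @param k Number of pulses to select (3 or 5 in the motivating profiles).
#' @param seed Integer seed.
#' @return `k` rows of `kept`, time-ordered.
#' @export
select_pulses <- function(kept, k, seed = 1) {
  if (k > nrow(kept)) {
    stop("insufficient usable pulses: need ", k, ", have ", nrow(kept),
         "; replicate flagged as failed", call. = FALSE)
  }
  idx <- withr::with_seed(seed, sort(sample.int(nrow(kept), k)))
  kept[idx, ]
}

# Single-linkage 1-D clustering: break sorted m/z where the gap between
# neighbours exceeds the ppm tolerance. Returns cluster ids per input element.
cluster_mz <- function(mz, tol_ppm) {
  ord <- order(mz)
  s <- mz[ord]
  gap <- diff(s) > tol_ppm * 1e-6 * (head(s, -1) + tail(s, -1)) / 2
  cl_sorted <- cumsum(c(1L, as.integer(gap)))
  cl <- integer(length(mz))
  cl[ord] <- cl_sorted
  cl
}

#' Assemble the representative spectrum from selected pulses
#'
#' Pools every scan inside the selected pulses, clusters peaks by m/z within
#' `mz_bin_ppm` (single linkage), takes the intensity-weighted mean m/z and
#' the mean intensity over all pooled scans (a scan without the peak counts as
#' zero), then removes peaks below the instrument abundance threshold.
#'
#' @param run A scan-level run tibble.
#' @param selected Pulse rows from [select_pulses()].
#' @param mz_bin_ppm Peak clustering tolerance, ppm.
#' @param instrument_threshold Minimum reported abundance, counts (2e3 or
#'   1.5e4 depending on instrument profile; see [instrument_profile()]).
#' @param sample_id Optional label stored on the result.
#' @return A tibble (`mz`, `intensity`) of class `rep_spectrum`, with the
#'   pulses used, pooled scan count and threshold as attributes.
#' @export
representative_spectrum <- function(run, selected, mz_bin_ppm = 10,
                                    instrument_threshold = 2e3,
                                    sample_id = NULL) {
  if (nrow(selected) == 0) stop("no pulses selected", call. = FALSE)
  grid <- scan_grid(run)
  scan_idx <- unlist(lapply(seq_len(nrow(selected)), function(i) {
    grid$scan[(selected$start_index[i] + 1L):(selected$end_index[i] + 1L)]
  }))
  n_scans <- length(scan_idx)
  peaks <- run[run$scan %in% scan_idx, c("mz", "intensity")]
  if (nrow(peaks) == 0) {
    out <- tibble::tibble(mz = numeric(), intensity = numeric())
  } else {
    cl <- cluster_mz(peaks$mz, mz_bin_ppm)
    out <- tibble::as_tibble(peaks) |>
      dplyr::mutate(cl = cl) |>
      dplyr::group_by(.data$cl) |>
      dplyr::summarise(
        mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
        intensity = sum(.data$intensity) / n_scans,
        .groups = "drop"
      ) |>
      dplyr::filter(.data$intensity >= instrument_threshold) |>
      dplyr::arrange(.data$mz) |>
      dplyr::select("mz", "intensity")
  }
  attr(out, "sample_id") <- sample_id
  attr(out, "pulses_used") <- selected
  attr(out, "n_scans") <- n_scans
  attr(out, "instrument_threshold") <- instrument_threshold
  class(out) <- c("rep_spectrum", class(out))
  out
}

#' Process one run into its representative spectrum
#'
#' The full per-run stage: TIC pulse detection, IS EIC integration per pulse,
#' +/-20%-of-median IS window rejection, seeded random selection of `k`
#' pulses, spectrum averaging and abundance thresholding.
#'
#' @inheritParams representative_spectrum
#' @param is_mz Internal standard m/z, Th.
#' @param k Pulses to select.
#' @param min_height,min_scans Pulse detection settings (see
#'   [detect_pulses()]).
#' @param is_tol_ppm IS EIC extraction tolerance, ppm.
#' @param window IS rejection window fraction.
#' @param seed Integer seed for pulse selection.
#' @return A list: `spectrum` (`rep_spectrum` or `NULL` if the replicate
#'   failed QC), `pulses` (per-pulse table with `kept`/`selected` flags) and
#'   `counts` (detected / kept / rejected / selected).
#' @export
process_run <- function(run, is_mz, k = 5, min_height = NULL, min_scans = 3,
                        is_tol_ppm = 10, window = 0.2, mz_bin_ppm = 10,
                        instrument_threshold = 2e3, sample_id = NULL,
                        seed = 1) {
  tic <- compute_tic(run)
  pulses <- detect_pulses(tic, min_height = min_height,
                          min_scans = min_scans)
  if (nrow(pulses) == 0) {
    return(list(spectrum = NULL, pulses = pulses,
                counts = c(detected = 0L, kept = 0L, rejected = 0L,
                           selected = 0L)))
  }
  eic <- extract_eic(run, is_mz, tol_ppm = is_tol_ppm)
  pulses <- integrate_pulses(eic, pulses)
  pulses <- reject_outlier_pulses(pulses, window = window)
  kept <- pulses[pulses$kept, ]
  spectrum <- NULL
  pulses$selected <- FALSE
  if (nrow(kept) >= k) {
    sel <- select_pulses(kept, k, seed = seed)
    pulses$selected <- pulses$pulse %in% sel$pulse
    spectrum <- representative_spectrum(
      run, sel, mz_bin_ppm = mz_bin_ppm,
      instrument_threshold = instrument_threshold, sample_id = sample_id
    )
  }
  list(
    spectrum = spectrum,
    pulses = pulses,
    counts = c(detected = nrow(pulses), kept = nrow(kept),
               rejected = sum(!pulses$kept),
               selected = sum(pulses$selected))
  )
}
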