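# Feature table assembly and the filter cascade: IS normalization, blank,
# prevalence, QC-missingness, sample-outlier and RSD-QC filters, half-minimum
# imputation. Missing values are NA throughout; every operation appends to an
# append-only provenance log carried on the table.

meta_cols <- c("run_id", "sample_id", "role", "group")

new_feature_table <- function(data, features, filters = list()) {
  stopifnot(all(meta_cols %in% names(data)))
  out <- tibble::as_tibble(data)
  attr(out, "features") <- features
  attr(out, "filters") <- filters
  class(out) <- c("feature_table", setdiff(class(out), "feature_table"))
  out
}

#' @export
print.feature_table <- function(x, ...) {
  f <- features_of(x)
  cat(sprintf(
    "<feature_table> %d runs (%d samples, %d QC, %d blank) x %d features; %d filter step(s)\n",
    nrow(x), sum(x$role == "sample"), sum(x$role == "QC"),
    sum(x$role == "blank"), nrow(f), length(attr(x, "filters"))))
  NextMethod()
}

#' Feature metadata of a feature table
#'
#' @param table A `feature_table`.
#' @return Tibble with `feature` (column key) and `mz`.
#' @export
features_of <- function(table) attr(table, "features")

#' Provenance log of applied filters
#'
#' @param table A `feature_table`.
#' @return List of steps, each `list(filter =, params =)`, in application
#'   order.
#' @export
applied_filters <- function(table) attr(table, "filters")

ft_matrix <- function(table) {
  f <- features_of(table)
  m <- as.matrix(table[, f$feature, drop = FALSE])
  rownames(m) <- table$run_id
  m
}

log_step <- function(table, filter, params) {
  filters <- c(attr(table, "filters"), list(list(filter = filter,
                                                 params = params)))
  attr(table, "filters") <- filters
  table
}

drop_features <- function(table, drop_keys) {
  f <- features_of(table)
  keep <- !(f$feature %in% drop_keys)
  out <- table[, c(meta_cols, f$feature[keep]), drop = FALSE]
  new_feature_table(out, f[keep, ], attr(table, "filters"))
}

#' Align representative spectra into a feature table
#'
#' Single-linkage clustering of peak m/z across all spectra within a ppm
#' tolerance. The feature m/z is the intensity-weighted mean of its member
#' peaks; each run contributes at most one value per feature (peaks of the
#' same run falling in one cluster are summed); absence is `NA`.
#'
#' @param spectra Named list of [representative_spectrum()] tibbles; names are
#'   run ids matching `metadata$run_id`.
#' @param metadata Tibble with `run_id`, `sample_id`, `role`
#'   (sample/QC/blank) and `group`; e.g. the schedule from
#'   [make_run_order()].
#' @param tol_ppm Alignment tolerance, ppm.
#' @return A `feature_table`: one row per run, metadata columns followed by
#'   feature columns keyed by m/z (4 decimals), feature metadata and an empty
#'   provenance log as attributes.
#' @export
align_features <- function(spectra, metadata, tol_ppm = 10) {
  stopifnot(length(spectra) >= 1, !is.null(names(spectra)))
  pool <- dplyr::bind_rows(
    lapply(names(spectra), function(id) {
      s <- spectra[[id]]
      tibble::tibble(run_id = id, mz = s$mz, intensity = s$intensity)
    })
  )
  metadata <- tibble::as_tibble(metadata)[, meta_cols]
  metadata <- metadata[metadata$run_id %in% names(spectra), ]
  if (nrow(pool) == 0) {
    return(new_feature_table(metadata, tibble::tibble(feature = character(),
                                                      mz = numeric())))
  }
  pool$cl <- cluster_mz(pool$mz, tol_ppm)
  fmeta <- pool |>
    dplyr::group_by(.data$cl) |>
    dplyr::summarise(mz = sum(.data$mz * .data$intensity) /
                       sum(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$mz)
  fmeta$feature <- make.unique(sprintf("%.4f", fmeta$mz), sep = "_")
  vals <- pool |>
    dplyr::group_by(.data$run_id, .data$cl) |>
    dplyr::summarise(value = sum(.data$intensity), .groups = "drop") |>
    dplyr::left_join(fmeta[c("cl", "feature")], by = "cl") |>
    dplyr::select("run_id", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  data <- dplyr::left_join(metadata, vals, by = "run_id")
  # runs with no peaks at all still need the feature columns
  for (k in setdiff(fmeta$feature, names(data))) data[[k]] <- NA_real_
  data <- data[, c(meta_cols, fmeta$feature)]
  new_feature_table(data, fmeta[c("feature", "mz")])
}

#' Normalize all features to the internal standard
#'
#' Divides each run's values by that run's IS feature value, then removes the
#' IS feature from the table. Fails if the IS is missing in any run (a failed
#' replicate).
#'
#' @param table A `feature_table`.
#' @param is_mz IS m/z, Th.
#' @param tol_ppm Tolerance for locating the IS feature.
#' @return The normalized `feature_table` (IS column removed).
#' @export
normalize_to_is <- function(table, is_mz, tol_ppm = 10) {
  f <- features_of(table)
  d_ppm <- abs(f$mz - is_mz) / is_mz * 1e6
  if (!any(d_ppm <= tol_ppm)) {
    stop("IS feature not found at m/z ", is_mz, call. = FALSE)
  }
  key <- f$feature[which.min(d_ppm)]
  is_vals <- table[[key]]
  if (anyNA(is_vals) || any(is_vals <= 0)) {
    stop("IS missing or non-positive in run(s): ",
         paste(table$run_id[is.na(is_vals) | is_vals <= 0], collapse = ", "),
         call. = FALSE)
  }
  out <- table
  for (k in f$feature) out[[k]] <- out[[k]] / is_vals
  out <- new_feature_table(out, f, attr(table, "filters"))
  out <- drop_features(out, key)
  log_step(out, "normalize_to_is", list(is_mz = is_mz, tol_ppm = tol_ppm))
}

bio_rows <- function(table) table$role == "sample"

#' Blank filter
#'
#' Removes a feature when the mean abundance over biological samples is below
#' `factor` times its mean abundance in the blank runs (blank absence counts
#' as zero, so features absent from the blank are kept).
#'
#' @param table A `feature_table` with at least one blank run.
#' @param factor Blank multiple (default 3).
#' @param per_sample If `TRUE`, instead censor individual sample values below
#'   `factor` times the blank mean to missing (the per-sample reading of the
#'   rule); the feature itself is then only removed if all sample values are
#'   censored.
#' @return Filtered `feature_table`.
#' @export
blank_filter <- function(table, factor = 3, per_sample = FALSE) {
  if (!any(table$role == "blank")) stop("no blank run present", call. = FALSE)
  m <- ft_matrix(table)
  blank_mean <- colMeans(ifelse(is.na(m[table$role == "blank", , drop = FALSE]),
                                0, m[table$role == "blank", , drop = FALSE]))
  if (!per_sample) {
    samp_mean <- colMeans(m[bio_rows(table), , drop = FALSE], na.rm = TRUE)
    samp_mean[is.nan(samp_mean)] <- 0
    drop <- samp_mean < factor * blank_mean
    out <- drop_features(table, features_of(table)$feature[drop])
  } else {
    f <- features_of(table)
    out <- table
    for (j in seq_along(f$feature)) {
      k <- f$feature[j]
      censor <- bio_rows(out) & !is.na(out[[k]]) & out[[k]] < factor * blank_mean[j]
      out[[k]][censor] <- NA_real_
    }
    all_gone <- vapply(f$feature,
                       function(k) all(is.na(out[[k]][bio_rows(out)])),
                       logical(1))
    out <- new_feature_table(out, f, attr(table, "filters"))
    out <- drop_features(out, f$feature[all_gone])
  }
  log_step(out, "blank_filter",
           list(factor = factor, per_sample = per_sample))
}

#' Prevalence filter
#'
#' Keeps a feature only if it is detected (non-missing) in at least
#' `min_fraction` of the biological samples (inclusive boundary: 16/20
#' qualifies at 0.8).
#'
#' @param table A `feature_table`.
#' @param min_fraction Minimum detection fraction (default 0.8).
#' @return Filtered `feature_table`.
#' @export
prevalence_filter <- function(table, min_fraction = 0.8) {
  m <- ft_matrix(table)[bio_rows(table), , drop = FALSE]
  frac <- colMeans(!is.na(m))
  out <- drop_features(table,
                       features_of(table)$feature[frac < min_fraction])
  log_step(out, "prevalence_filter", list(min_fraction = min_fraction))
}

#' QC missingness filter
#'
#' Removes features missing in at least `max_missing` of the QC runs, or not
#' detected in any QC.
#'
#' @param table A `feature_table` with at least one QC run.
#' @param max_missing Missing-fraction threshold (default 0.8, inclusive).
#' @return Filtered `feature_table`.
#' @export
qc_feature_filter <- function(table, max_missing = 0.8) {
  qc <- table$role == "QC"
  if (!any(qc)) stop("no QC run present", call. = FALSE)
  m <- ft_matrix(table)[qc, , drop = FALSE]
  miss <- colMeans(is.na(m))
  out <- drop_features(table, features_of(table)$feature[miss >= max_missing])
  log_step(out, "qc_feature_filter", list(max_missing = max_missing))
}

#' Sample outlier removal by missingness
#'
#' Drops biological samples whose missing fraction over the currently
#' retained features is strictly greater than `max_missing` (a sample missing
#' exactly 20% stays).
#'
#' @param table A `feature_table`.
#' @param max_missing Missing-fraction threshold (default 0.2, strict).
#' @return Filtered `feature_table`.
#' @export
sample_outlier_filter <- function(table, max_missing = 0.2) {
  m <- ft_matrix(table)
  miss <- rowMeans(is.na(m))
  drop <- bio_rows(table) & miss > max_missing
  out <- new_feature_table(table[!drop, , drop = FALSE], features_of(table),
                           attr(table, "filters"))
  log_step(out, "sample_outlier_filter", list(max_missing = max_missing))
}

#' Half-minimum imputation
#'
#' Replaces every missing entry by half the minimum positive value of the
#' whole table.
#'
#' @param table A `feature_table` with at least one positive value.
#' @return Imputed `feature_table` (no missing entries remain).
#' @export
impute_half_min <- function(table) {
  f <- features_of(table)
  m <- ft_matrix(table)
  pos <- m[!is.na(m) & m > 0]
  if (!length(pos)) stop("no positive values to impute from", call. = FALSE)
  fill <- min(pos) / 2
  out <- table
  for (k in f$feature) out[[k]][is.na(out[[k]])] <- fill
  out <- new_feature_table(out, f, attr(table, "filters"))
  log_step(out, "impute_half_min", list(fill = fill))
}

qc_rsd <- function(table) {
  qc <- table$role == "QC"
  if (sum(qc) < 2) stop("need at least 2 QC runs", call. = FALSE)
  m <- ft_matrix(table)[qc, , drop = FALSE]
  apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    sd(x) / mean(x)
  })
}

#' Technical-precision filter on QC relative SD
#'
#' Per-feature RSD over QC runs (sample SD over mean); features with RSD
#' strictly above `max_rsd` are removed.
#'
#' @param table A `feature_table` with at least 2 QC runs.
#' @param max_rsd RSD threshold (default 0.30).
#' @return Filtered `feature_table`.
#' @export
rsd_qc_filter <- function(table, max_rsd = 0.30) {
  rsd <- qc_rsd(table)
  drop <- !is.na(rsd) & rsd > max_rsd
  out <- drop_features(table, features_of(table)$feature[drop])
  log_step(out, "rsd_qc_filter", list(max_rsd = max_rsd))
}

#' Median QC RSD of the table
#'
#' The median over retained features of the per-feature QC RSD: the standard
#' single-number summary of platform technical precision.
#'
#' @param table A `feature_table` with at least 2 QC runs.
#' @return A fraction (e.g. 0.128 for 12.8%).
#' @export
median_rsd_qc <- function(table) {
  median(qc_rsd(table), na.rm = TRUE)
}

#' Replay a provenance log on a table
#'
#' Re-applies the logged filter cascade to a (typically unfiltered) table;
#' replaying the log of a filtered table on its own unfiltered ancestor
#' reproduces it exactly.
#'
#' @param table A `feature_table`.
#' @param filters A log from [applied_filters()].
#' @return The filtered `feature_table`.
#' @export
replay_filters <- function(table, filters) {
  for (st in filters) {
    table <- switch(st$filter,
      normalize_to_is = normalize_to_is(table, st$params$is_mz,
                                        st$params$tol_ppm),
      blank_filter = blank_filter(table, st$params$factor,
                                  st$params$per_sample),
      prevalence_filter = prevalence_filter(table, st$params$min_fraction),
      qc_feature_filter = qc_feature_filter(table, st$params$max_missing),
      sample_outlier_filter = sample_outlier_filter(table,
                                                    st$params$max_missing),
      impute_half_min = impute_half_min(table),
      rsd_qc_filter = rsd_qc_filter(table, st$params$max_rsd),
      stop("unknown filter in log: ", st$filter, call. = FALSE)
    )
  }
  table
}

#' Write / read a feature table as CSV plus JSON sidecar
#'
#' The CSV holds one row per run (metadata columns then feature columns named
#' by m/z to 4 decimals); the sidecar (`<path>.json`) holds full-precision
#' feature m/z and the provenance log.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `path` invisibly; `read_feature_table()` returns the
#'   `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(unclass(table)), path, na = "")
  side <- list(features = features_of(table),
               filters = applied_filters(table))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          na = c("", "NA"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    features <- tibble::as_tibble(side$features)
    filters <- lapply(
      jsonlite::read_json(sidecar, simplifyVector = FALSE)$filters,
      function(st) list(filter = st$filter, params = st$params)
    )
  } else {
    keys <- setdiff(names(data), meta_cols)
    features <- tibble::tibble(feature = keys,
                               mz = as.numeric(sub("_.*$", "", keys)))
    filters <- list()
  }
  new_feature_table(data, features, filters)
}
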