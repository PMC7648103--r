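# Synthetic pulsed direct-infusion MS studies with known ground truth.
#
# The generator emulates a pulsed nanoelectrospray acquisition: a ~0.8 Hz
# train of spray pulses, each spanning 6-7 analyzer scans, with an
# isotope-labeled internal standard (IS) spiked into every run. Pulse-to-pulse
# spray efficiency is common-mode: one per-pulse multiplier scales every
# species in that pulse, which is what makes IS-based pulse QC meaningful.

# Deterministic sub-seed per run, derived from the study seed. Kept < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed %% 100000L) * 20011 + as.double(i) * 7919) %%
               2147483647)
}

#' Acquisition settings for the synthetic pulse train
#'
#' Defaults emulate the acquisition this pipeline targets: pulses at 0.8 Hz,
#' 6-7 scans per pulse (0.7 s pulse support at a 0.1 s scan period), 8.9%
#' pulse-width variation, 10% pulse-to-pulse ion-yield variation, and
#' occasional outlier pulses (1.5x yield with probability 0.1).
#'
#' @param pulse_rate Pulses per second.
#' @param scan_period Seconds between scans.
#' @param pulse_width Mean above-baseline pulse duration, seconds.
#' @param pulse_width_cv Relative SD of pulse width.
#' @param n_pulses Number of pulses per run.
#' @param mz_range Acquisition m/z window, Th.
#' @param noise_sd SD of additive Gaussian intensity noise, counts.
#' @param amplitude_cv Relative SD of the common-mode per-pulse ion yield.
#' @param outlier_pulse_prob Probability that a pulse is an outlier.
#' @param outlier_pulse_scale Yield multiplier for outlier pulses.
#' @param polarity `"+"` or `"-"`.
#' @return A list of class `acq_config`.
#' @export
acquisition_config <- function(pulse_rate = 0.8,
                               scan_period = 0.1,
                               pulse_width = 0.7,
                               pulse_width_cv = 0.089,
                               n_pulses = 40,
                               mz_range = c(50, 750),
                               noise_sd = 30,
                               amplitude_cv = 0.10,
                               outlier_pulse_prob = 0.1,
                               outlier_pulse_scale = 1.5,
                               polarity = "-") {
  stopifnot(pulse_rate > 0, scan_period > 0, pulse_width > 0,
            pulse_width_cv >= 0, n_pulses >= 1,
            length(mz_range) == 2, mz_range[1] < mz_range[2],
            noise_sd >= 0, amplitude_cv >= 0,
            outlier_pulse_prob >= 0, outlier_pulse_prob <= 1,
            outlier_pulse_scale > 0, polarity %in% c("+", "-"))
  structure(as.list(environment()), class = "acq_config")
}

#' Two-group study design
#'
#' @param n_per_group Biological samples per group.
#' @param groups Two group labels; the second is the "positive"
#'   (stimulated / post-challenge) class.
#' @param n_qc Pooled-QC injections (placed as a leading triplicate, then in
#'   triplicates every `qc_interval` samples while injections remain).
#' @param n_blank Method-blank runs, placed first.
#' @param replicates_per_sample Technical replicates per sample.
#' @param qc_interval Samples between QC triplicates.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_per_group = 10, groups = c("Pre", "Post"),
                         n_qc = 3, n_blank = 1, replicates_per_sample = 1,
                         qc_interval = 6) {
  stopifnot(n_per_group >= 1, length(groups) == 2, !anyDuplicated(groups),
            n_qc >= 0, n_blank >= 0, replicates_per_sample >= 1,
            qc_interval >= 1)
  structure(as.list(environment()), class = "study_design")
}

#' Generate a synthetic metabolite panel
#'
#' Draws feature m/z values over the acquisition window (minimum spacing well
#' above the alignment tolerance) and log-normal base abundances. Exactly
#' `n_differential` features carry a planted fold change: half up-regulated
#' (`fc`) and half down-regulated (`1/fc`) in the second group.
#'
#' @param n_features Total features.
#' @param n_differential Features with a planted effect.
#' @param fc Planted fold change (> 0; two-sided interpretation).
#' @param abundance_log_mean,abundance_log_sd Log-scale location and SD of
#'   base abundances (natural log of counts).
#' @param detection_probability Per-run probability that a feature ionizes at
#'   all. The default 1 leaves missingness to the realistic mechanism --
#'   left-censoring at the instrument abundance threshold; lower it to add
#'   abundance-independent dropout.
#' @param mz_range m/z window for feature positions, Th.
#' @param is_mz,is_area Internal-standard m/z (Th) and nominal per-pulse EIC
#'   area (counts).
#' @param seed Integer seed.
#' @return A list of class `metabolite_panel` with a `features` tibble
#'   (`feature_id`, `mz`, `base_abundance`, `group_fold_change`,
#'   `detection_probability`, `differential`) plus `is_mz` and `is_area`.
#' @export
generate_panel <- function(n_features = 100, n_differential = 10, fc = 5,
                           abundance_log_mean = log(5e4),
                           abundance_log_sd = 1,
                           detection_probability = 1,
                           mz_range = c(50, 750),
                           is_mz = 183.0879, is_area = 2e4,
                           seed = 1) {
  stopifnot(n_features >= 1, n_differential >= 0,
            n_differential <= n_features, fc > 0,
            detection_probability > 0, detection_probability <= 1)
  withr::with_seed(seed, {
    # rejection-sample m/z until all gaps (and the IS gap) exceed 0.5 Th
    repeat {
      mz <- sort(runif(n_features, mz_range[1] + 1, mz_range[2] - 1))
      if (all(diff(c(mz, is_mz)[order(c(mz, is_mz))]) > 0.5)) break
    }
    base <- rlnorm(n_features, abundance_log_mean, abundance_log_sd)
    diff_idx <- if (n_differential > 0) {
      sort(sample.int(n_features, n_differential))
    } else integer()
    gfc <- rep(1, n_features)
    if (n_differential > 0) {
      n_up <- ceiling(n_differential / 2)
      gfc[diff_idx[seq_len(n_up)]] <- fc
      if (n_differential > n_up) {
        gfc[diff_idx[(n_up + 1):n_differential]] <- 1 / fc
      }
    }
    features <- tibble::tibble(
      feature_id = sprintf("F%03d", seq_len(n_features)),
      mz = mz,
      base_abundance = base,
      group_fold_change = gfc,
      detection_probability = detection_probability,
      differential = seq_len(n_features) %in% diff_idx
    )
  })
  structure(list(features = features, is_mz = is_mz, is_area = is_area),
            class = "metabolite_panel")
}

# Unit-area truncated-Gaussian pulse envelope evaluated at scan times.
# Support is |t - center| <= width/2 with sigma = width/6 (+/-3 sigma, so the
# envelope is ~1% of peak at the edges); it integrates to 1 over its support,
# so a pulse's EIC area equals the species' abundance times the common-mode
# pulse multiplier.
pulse_envelope <- function(scan_time, center, width) {
  sigma <- width / 6
  idx <- which(abs(scan_time - center) <= width / 2)
  g <- exp(-(scan_time[idx] - center)^2 / (2 * sigma^2))
  norm <- sigma * sqrt(2 * pi) * (2 * stats::pnorm(3) - 1)
  list(idx = idx, value = g / norm)
}

#' Simulate one pulsed acquisition run
#'
#' Places Gaussian-envelope pulses at the configured rate, with widths jittered
#' at `pulse_width_cv` and a common-mode per-pulse yield multiplier (log-normal,
#' median 1) shared by every feature and the IS. Outlier pulses are scaled by
#' `outlier_pulse_scale`. Features drop out of a run with probability
#' `1 - detection_probability`; additive Gaussian noise and a sparse background
#' are superimposed.
#'
#' @param panel A [generate_panel()] object.
#' @param sample_abundances Per-feature abundances for this run (counts), in
#'   panel feature order. All zeros gives a method blank (IS + noise only).
#' @param acq An [acquisition_config()].
#' @param seed Integer seed.
#' @return A tibble of scan-level peaks (`scan`, `time`, `polarity`, `mz`,
#'   `intensity`) of class `ms_run`, with the per-pulse ground truth
#'   (`pulse_truth` attribute: center, width, multiplier, outlier flag).
#' @export
generate_run <- function(panel, sample_abundances, acq = acquisition_config(),
                         seed = 1) {
  feats <- panel$features
  stopifnot(length(sample_abundances) == nrow(feats))
  withr::with_seed(seed, {
    duration <- acq$n_pulses / acq$pulse_rate
    scan_time <- seq(0, duration, by = acq$scan_period)
    n_scans <- length(scan_time)
    centers <- (seq_len(acq$n_pulses) - 0.5) / acq$pulse_rate
    widths <- rnorm(acq$n_pulses, acq$pulse_width,
                    acq$pulse_width_cv * acq$pulse_width)
    widths <- pmax(widths, 3 * acq$scan_period)
    sdlog <- sqrt(log(1 + acq$amplitude_cv^2))
    mult <- rlnorm(acq$n_pulses, 0, sdlog)
    outlier <- runif(acq$n_pulses) < acq$outlier_pulse_prob
    mult[outlier] <- mult[outlier] * acq$outlier_pulse_scale

    env <- numeric(n_scans)
    for (i in seq_len(acq$n_pulses)) {
      pe <- pulse_envelope(scan_time, centers[i], widths[i])
      env[pe$idx] <- env[pe$idx] + mult[i] * pe$value
    }
    active <- which(env > 0)

    present <- runif(nrow(feats)) < feats$detection_probability
    abund <- sample_abundances * present
    # per-run mass calibration offset, ~2 ppm
    cal <- 1 + rnorm(1, 0, 2e-6)
    species_mz <- c(feats$mz, panel$is_mz) * cal
    species_abund <- c(abund, panel$is_area)

    keep <- species_abund > 0
    m <- outer(species_abund[keep], env[active])
    if (acq$noise_sd > 0) {
      m <- pmax(m + rnorm(length(m), 0, acq$noise_sd), 0)
    }
    signal <- tibble::tibble(
      scan = rep(active, each = sum(keep)),
      mz = rep(species_mz[keep], times = length(active)),
      intensity = as.vector(m)
    )
    peaks <- signal[signal$intensity > 0, ]
    if (acq$noise_sd > 0) {
      n_bg <- 10L
      bg <- tibble::tibble(
        scan = rep(seq_len(n_scans), each = n_bg),
        mz = runif(n_scans * n_bg, acq$mz_range[1], acq$mz_range[2]),
        intensity = abs(rnorm(n_scans * n_bg, 0, acq$noise_sd))
      )
      peaks <- dplyr::bind_rows(peaks, bg)
    }
    peaks <- dplyr::arrange(peaks, .data$scan, .data$mz)
    run <- tibble::tibble(
      scan = peaks$scan,
      time = scan_time[peaks$scan],
      polarity = acq$polarity,
      mz = peaks$mz,
      intensity = peaks$intensity
    )
  })
  attr(run, "scans") <- tibble::tibble(
    scan = seq_len(n_scans), time = scan_time, polarity = acq$polarity
  )
  attr(run, "pulse_truth") <- tibble::tibble(
    pulse = seq_len(acq$n_pulses), center = centers, width = widths,
    multiplier = mult, outlier = outlier
  )
  attr(run, "is_mz") <- panel$is_mz
  class(run) <- c("ms_run", class(run))
  run
}

#' Generate the full synthetic study
#'
#' Draws per-sample feature abundances log-normally (mean-preserving) around
#' group means -- the second group's mean is `base_abundance *
#' group_fold_change` -- simulates every run in the randomized schedule from
#' [make_run_order()], builds pooled-QC runs from the mean of all sample
#' abundance vectors, and blank runs with zero feature signal. All randomness
#' derives from `seed` via documented per-run sub-seeds.
#'
#' @param design A [study_design()].
#' @param panel A [generate_panel()] object.
#' @param acq An [acquisition_config()].
#' @param between_sample_cv Biological coefficient of variation.
#' @param seed Integer seed.
#' @return A list of class `pulse_study`: `runs` (named list of [generate_run()]
#'   tibbles), `schedule` (run-order tibble), `truth` (per-sample true
#'   abundances, planted differential set), plus `panel`, `design`, `acq`.
#' @export
generate_study <- function(design = study_design(), panel = generate_panel(),
                           acq = acquisition_config(),
                           between_sample_cv = 0.2, seed = 1) {
  feats <- panel$features
  schedule <- make_run_order(design, seed = derive_seed(seed, 0L))
  sample_ids <- unique(schedule$sample_id[schedule$role == "sample"])
  sample_meta <- dplyr::distinct(
    schedule[schedule$role == "sample", c("sample_id", "group")]
  )
  sdlog <- sqrt(log(1 + between_sample_cv^2))
  abund <- withr::with_seed(derive_seed(seed, 1L), {
    vapply(seq_len(nrow(sample_meta)), function(i) {
      g2 <- sample_meta$group[i] == design$groups[2]
      mean_f <- feats$base_abundance *
        (if (g2) feats$group_fold_change else 1)
      mean_f * rlnorm(nrow(feats), -sdlog^2 / 2, sdlog)
    }, numeric(nrow(feats)))
  })
  colnames(abund) <- sample_meta$sample_id
  qc_abund <- rowMeans(abund)

  runs <- vector("list", nrow(schedule))
  names(runs) <- schedule$run_id
  for (i in seq_len(nrow(schedule))) {
    a <- switch(schedule$role[i],
      sample = abund[, schedule$sample_id[i]],
      QC = qc_abund,
      blank = numeric(nrow(feats))
    )
    runs[[i]] <- generate_run(panel, a, acq, seed = derive_seed(seed, i + 1L))
  }
  truth <- list(
    differential = feats$feature_id[feats$differential],
    differential_mz = feats$mz[feats$differential],
    sample_abundances = tibble::as_tibble(abund) |>
      dplyr::mutate(feature_id = feats$feature_id, .before = 1),
    qc_abundances = qc_abund,
    seed = seed
  )
  structure(list(runs = runs, schedule = schedule, truth = truth,
                 panel = panel, design = design, acq = acq),
            class = "pulse_study")
}

#' Randomized run order for a two-group study
#'
#' Blanks are run first, then a leading pooled-QC triplicate, then sample
#' segments in which the two groups are interleaved pairwise with the pair
#' order randomized; further QC triplicates are inserted after every
#' `qc_interval` samples while QC injections remain. Deterministic under
#' `seed`.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A tibble with `position`, `run_id`, `sample_id`, `role`, `group`.
#' @export
make_run_order <- function(design, seed = 1) {
  g <- design$groups
  ids <- lapply(1:2, function(k) {
    sprintf("%s_%02d", g[k], seq_len(design$n_per_group))
  })
  pairs <- withr::with_seed(seed, {
    ord <- sample.int(design$n_per_group)
    first <- sample(1:2, 1)  # one orientation: strict A,B,A,B or B,A,B,A
    lapply(seq_len(design$n_per_group), function(i) {
      c(ids[[first]][ord[i]], ids[[3 - first]][ord[i]])
    })
  })
  samples <- rep(unlist(pairs), each = design$replicates_per_sample)

  qc_left <- design$n_qc
  take_qc <- function(k) {
    k <- min(k, qc_left)
    qc_left <<- qc_left - k
    rep("QC", k)
  }
  roles <- c(rep("blank", design$n_blank), take_qc(3L))
  sample_pos <- 0L
  for (s in samples) {
    roles <- c(roles, s)
    sample_pos <- sample_pos + 1L
    if (sample_pos %% (design$qc_interval * design$replicates_per_sample) == 0L
        && qc_left > 0L) {
      roles <- c(roles, take_qc(3L))
    }
  }
  if (qc_left > 0L) roles <- c(roles, take_qc(qc_left))

  role <- ifelse(roles %in% c("blank", "QC"), roles, "sample")
  sample_id <- ifelse(role == "sample", roles, role)
  # unique ids for repeated QC/blank injections
  run_id <- make.unique(ifelse(role == "sample", roles,
                               paste0(roles, "_run")), sep = "_")
  group <- dplyr::case_when(
    role != "sample" ~ NA_character_,
    startsWith(sample_id, g[1]) ~ g[1],
    TRUE ~ g[2]
  )
  tibble::tibble(position = seq_along(roles), run_id = run_id,
                 sample_id = sample_id, role = role, group = group)
}

#' Serialize the study ground truth to JSON
#'
#' Stores the planted differential set, per-sample true abundances, the panel
#' and the study seed; [read_ground_truth()] round-trips it.
#'
#' @param study A [generate_study()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(study, path) {
  payload <- list(
    seed = study$truth$seed,
    differential = study$truth$differential,
    differential_mz = study$truth$differential_mz,
    panel = list(features = study$panel$features,
                 is_mz = study$panel$is_mz, is_area = study$panel$is_area),
    sample_abundances = study$truth$sample_abundances,
    qc_abundances = study$truth$qc_abundances,
    schedule = study$schedule
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$panel$features <- tibble::as_tibble(x$panel$features)
  x$sample_abundances <- tibble::as_tibble(x$sample_abundances)
  x$schedule <- tibble::as_tibble(x$schedule)
  x
}
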