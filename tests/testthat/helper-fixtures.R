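# Shared fixture builders. All synthetic, built in code at test time.

# Feature table from a bare matrix (rows = runs, cols = features).
toy_table <- function(values, roles, groups = NULL, mzs = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  p <- ncol(values)
  mzs <- mzs %||% (100 + seq_len(p))
  keys <- sprintf("%.4f", mzs)
  groups <- groups %||% ifelse(roles == "sample",
                               rep(c("Pre", "Post"), length.out = n), NA)
  groups[roles != "sample"] <- NA
  data <- tibble::tibble(
    run_id = sprintf("run_%02d", seq_len(n)),
    sample_id = sprintf("S%02d", seq_len(n)),
    role = roles,
    group = groups
  )
  for (j in seq_len(p)) data[[keys[j]]] <- values[, j]
  pulsedms:::new_feature_table(
    data, tibble::tibble(feature = keys, mz = mzs)
  )
}

# Scan-level run from per-scan peak lists.
toy_run <- function(time, mz, intensity, polarity = "-") {
  pulsedms:::assemble_run(
    time = time,
    polarity = rep(polarity, length(time)),
    mz = mz,
    intensity = intensity
  )
}

# Random feature table with missingness, for oracle-equivalence checks.
random_table <- function(n_sample = 8, n_qc = 3, n_blank = 1, p = 12,
                         miss_prob = 0.15) {
  n <- n_sample + n_qc + n_blank
  m <- matrix(rlnorm(n * p, log(10), 1), n, p)
  m[matrix(runif(n * p) < miss_prob, n, p)] <- NA
  roles <- c(rep("sample", n_sample), rep("QC", n_qc), rep("blank", n_blank))
  toy_table(m, roles)
}

# Match selected feature m/z against planted differential m/z (ppm window).
recovery_counts <- function(selected_mz, truth_mz, tol_ppm = 20) {
  hit <- vapply(truth_mz, function(m) {
    any(abs(selected_mz - m) / m * 1e6 < tol_ppm)
  }, logical(1))
  false_pos <- if (length(selected_mz)) {
    sum(!vapply(selected_mz, function(m) {
      any(abs(truth_mz - m) / m * 1e6 < tol_ppm)
    }, logical(1)))
  } else 0L
  list(recovered = sum(hit), n_truth = length(truth_mz),
       false_pos = false_pos)
}

`%||%` <- rlang::`%||%`

# All permutations of 1..n (n small), as a list of integer vectors.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}
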