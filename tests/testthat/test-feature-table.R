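make_spectrum <- function(mz, intensity) {
  out <- tibble::tibble(mz = mz, intensity = intensity)
  class(out) <- c("rep_spectrum", class(out))
  out
}

meta_for <- function(ids, roles, groups = NA) {
  tibble::tibble(run_id = ids, sample_id = ids, role = roles, group = groups)
}

test_that("alignment clusters peaks across samples within tolerance", {
  s1 <- make_spectrum(c(200.0000, 300.0), c(10, 5))
  s2 <- make_spectrum(c(200.0010, 300.0), c(20, 5))
  ft <- align_features(list(a = s1, b = s2),
                       meta_for(c("a", "b"), c("sample", "sample"),
                                c("Pre", "Post")),
                       tol_ppm = 10)
  # 200.0000 and 200.0010 are 5 ppm apart -> one feature
  expect_equal(nrow(features_of(ft)), 2)
  expect_false(anyNA(pulsedms:::ft_matrix(ft)))
  # intensity-weighted mean m/z
  expect_equal(features_of(ft)$mz[1],
               (200.0000 * 10 + 200.0010 * 20) / 30, tolerance = 1e-9)

  # disjoint spectra give block-diagonal missingness
  s3 <- make_spectrum(c(500.0, 600.0), c(1, 1))
  ft2 <- align_features(list(a = s1, c = s3),
                        meta_for(c("a", "c"), c("sample", "sample"),
                                 c("Pre", "Post")),
                        tol_ppm = 10)
  m <- pulsedms:::ft_matrix(ft2)
  expect_equal(sum(is.na(m)), 4)
  expect_false(anyNA(m[1, 1:2]))
  expect_false(anyNA(m[2, 3:4]))
})

test_that("IS normalization divides per run and removes the IS feature", {
  v <- rbind(c(10, 4, 2), c(30, 9, 3), c(20, 8, 4))
  ft <- toy_table(v, roles = rep("sample", 3), mzs = c(150, 250, 183.0879))
  out <- normalize_to_is(ft, 183.0879)
  expect_equal(nrow(features_of(out)), 2)
  expect_equal(unname(pulsedms:::ft_matrix(out)[, 1]), c(5, 10, 5))
  # scale invariance: 10x raw scale, same ratios
  ft10 <- toy_table(v * 10, roles = rep("sample", 3),
                    mzs = c(150, 250, 183.0879))
  expect_equal(pulsedms:::ft_matrix(normalize_to_is(ft10, 183.0879)),
               pulsedms:::ft_matrix(out))
  # IS missing in a run is a failed replicate
  v2 <- v; v2[2, 3] <- NA
  ft_bad <- toy_table(v2, roles = rep("sample", 3),
                      mzs = c(150, 250, 183.0879))
  expect_error(normalize_to_is(ft_bad, 183.0879), "IS missing")
})

test_that("blank filter compares sample means to 3x blank", {
  # feature 1: samples mean 10 vs blank 5 -> removed; feature 2: 100 vs 5 kept;
  # feature 3: absent from blank -> kept
  v <- rbind(c(10, 100, 7), c(10, 100, 7), c(5, 5, NA))
  ft <- toy_table(v, roles = c("sample", "sample", "blank"))
  out <- blank_filter(ft, factor = 3)
  expect_identical(features_of(out)$mz, c(102, 103))
  expect_error(blank_filter(toy_table(v[1:2, ], rep("sample", 2))),
               "no blank")
  # blank zero everywhere removes nothing
  v0 <- rbind(c(10, 1, 2), c(10, 1, 2), c(0, 0, 0))
  expect_equal(nrow(features_of(
    blank_filter(toy_table(v0, c("sample", "sample", "blank"))))), 3)
})

test_that("prevalence filter keeps features at or above 80% detection", {
  n <- 20
  v <- matrix(1, n, 3)
  v[1:4, 1] <- NA   # 16/20 present -> kept (inclusive boundary)
  v[1:5, 2] <- NA   # 15/20 -> removed
  ft <- toy_table(v, roles = rep("sample", n))
  out <- prevalence_filter(ft, 0.8)
  expect_identical(features_of(out)$mz, c(101, 103))
})

test_that("QC missingness filter follows the 80%-or-absent rule", {
  v <- rbind(
    c(1, NA, NA), c(1, NA, 1), c(1, NA, 1),          # QCs
    c(1, 1, 1), c(1, 1, 1)                           # samples
  )
  ft <- toy_table(v, roles = c("QC", "QC", "QC", "sample", "sample"))
  out <- qc_feature_filter(ft, 0.8)
  # feature 1: 3/3 kept; feature 2: 0/3 removed; feature 3: missing 1/3 kept
  expect_identical(features_of(out)$mz, c(101, 103))
  v2 <- rbind(c(1, NA, 1), c(1, NA, 1), c(1, 1, 1), c(1, 1, 1))
  ft2 <- toy_table(v2, roles = c("QC", "QC", "QC", "sample"))
  # missing 2/3 (66% < 80%) -> kept
  expect_equal(nrow(features_of(qc_feature_filter(ft2, 0.8))), 3)
  expect_error(qc_feature_filter(toy_table(v2, rep("sample", 4))), "no QC")
})

test_that("sample outlier rule is strictly greater than 20% missing", {
  v <- matrix(1, 4, 10)
  v[1, 1:2] <- NA       # exactly 20% missing -> kept
  v[2, 1:3] <- NA       # 30% missing -> removed
  ft <- toy_table(v, roles = rep("sample", 4))
  out <- sample_outlier_filter(ft, 0.2)
  expect_equal(sum(out$role == "sample"), 3)
  expect_false("S02" %in% out$sample_id)
})

test_that("half-minimum imputation uses the global minimum positive value", {
  v <- rbind(c(4, NA, 8), c(10, 6, NA))
  ft <- toy_table(v, roles = rep("sample", 2))
  out <- impute_half_min(ft)
  m <- pulsedms:::ft_matrix(out)
  expect_equal(sum(is.na(m)), 0)
  expect_equal(unname(m[1, 2]), 2)
  expect_equal(unname(m[2, 3]), 2)
  # table without missing values is unchanged
  ft2 <- toy_table(rbind(c(1, 2), c(3, 4)), rep("sample", 2))
  expect_equal(pulsedms:::ft_matrix(impute_half_min(ft2)),
               pulsedms:::ft_matrix(ft2))
  expect_error(impute_half_min(toy_table(matrix(NA_real_, 2, 2),
                                         rep("sample", 2))), "no positive")
})

test_that("QC RSD filter and median RSD follow sd/mean with n-1", {
  v <- rbind(c(10, 10, 10), c(20, 11, 10), c(30, 12, 10),
             c(5, 5, 5))
  ft <- toy_table(v, roles = c("QC", "QC", "QC", "sample"))
  # per-feature QC RSDs: 0.5 (removed), ~0.091 (kept), 0 (kept)
  out <- rsd_qc_filter(ft, 0.30)
  expect_identical(features_of(out)$mz, c(102, 103))
  expect_equal(median_rsd_qc(out), median(c(sd(10:12) / 11, 0)),
               tolerance = 1e-12)
  expect_error(median_rsd_qc(toy_table(v, c("QC", rep("sample", 3)))),
               "at least 2 QC")
})

test_that("each filter is idempotent", {
  withr::with_seed(31, {
    ft <- random_table()
    filters <- list(
      function(x) blank_filter(x),
      function(x) prevalence_filter(x, 0.6),
      function(x) qc_feature_filter(x),
      function(x) sample_outlier_filter(x, 0.3),
      function(x) impute_half_min(x),
      function(x) rsd_qc_filter(x, 0.5)
    )
    for (f in filters) {
      once <- f(ft)
      twice <- f(once)
      expect_equal(pulsedms:::ft_matrix(twice), pulsedms:::ft_matrix(once))
      expect_identical(twice$run_id, once$run_id)
    }
  })
})

test_that("filters match a brute-force oracle on random tables", {
  withr::with_seed(32, {
    for (i in 1:100) {
      ft <- random_table(n_sample = sample(4:10, 1), p = sample(5:15, 1))
      m <- pulsedms:::ft_matrix(ft)
      roles <- ft$role
      f <- features_of(ft)

      # blank oracle
      keep <- logical(ncol(m))
      for (j in seq_len(ncol(m))) {
        b <- m[roles == "blank", j]; b[is.na(b)] <- 0
        s <- m[roles == "sample", j]
        sm <- if (all(is.na(s))) 0 else mean(s, na.rm = TRUE)
        keep[j] <- sm >= 3 * mean(b)
      }
      expect_identical(features_of(blank_filter(ft))$feature,
                       f$feature[keep])

      # prevalence oracle
      keep <- vapply(seq_len(ncol(m)), function(j) {
        mean(!is.na(m[roles == "sample", j])) >= 0.8
      }, logical(1))
      expect_identical(features_of(prevalence_filter(ft))$feature,
                       f$feature[keep])

      # QC-missingness oracle
      keep <- vapply(seq_len(ncol(m)), function(j) {
        mean(is.na(m[roles == "QC", j])) < 0.8
      }, logical(1))
      expect_identical(features_of(qc_feature_filter(ft))$feature,
                       f$feature[keep])

      # sample-outlier oracle
      drop <- roles == "sample" & rowMeans(is.na(m)) > 0.2
      expect_identical(sample_outlier_filter(ft)$run_id, ft$run_id[!drop])

      # RSD oracle
      keep <- vapply(seq_len(ncol(m)), function(j) {
        q <- m[roles == "QC", j]; q <- q[!is.na(q)]
        if (length(q) < 2) return(TRUE)
        sd(q) / mean(q) <= 0.3
      }, logical(1))
      expect_identical(features_of(rsd_qc_filter(ft))$feature,
                       f$feature[keep])
    }
  })
})

test_that("provenance log replays to the identical table", {
  withr::with_seed(33, {
    raw <- random_table(n_sample = 10, p = 14)
    ft <- raw |>
      blank_filter() |>
      prevalence_filter(0.6) |>
      qc_feature_filter() |>
      sample_outlier_filter(0.3) |>
      impute_half_min() |>
      rsd_qc_filter(0.5)
    replayed <- replay_filters(raw, applied_filters(ft))
    expect_equal(pulsedms:::ft_matrix(replayed), pulsedms:::ft_matrix(ft))
    expect_identical(replayed$run_id, ft$run_id)
  })
})

test_that("filter order is interchangeable on complete tables, divergences reported otherwise", {
  steps <- list(
    blank = function(x) blank_filter(x),
    prevalence = function(x) prevalence_filter(x),
    qc = function(x) qc_feature_filter(x),
    rsd = function(x) rsd_qc_filter(x)
  )
  orders <- combinat_perms(4)

  run_orders <- function(ft) {
    lapply(orders, function(ord) {
      out <- ft
      for (k in ord) out <- steps[[k]](out)
      sort(features_of(out)$feature)
    })
  }

  # no missing values: every order retains the same feature set
  withr::with_seed(34, {
    v <- matrix(rlnorm(14 * 12, log(10), 0.6), 14, 12)
    ft <- toy_table(v, roles = c(rep("sample", 10), "QC", "QC", "QC",
                                 "blank"))
    sets <- run_orders(ft)
    expect_true(all(vapply(sets, identical, logical(1), sets[[1]])))
  })

  # with missingness, orders may diverge; the harness reports, not hides
  withr::with_seed(35, {
    ft <- random_table(n_sample = 10, p = 12, miss_prob = 0.25)
    sets <- run_orders(ft)
    n_distinct <- length(unique(sets))
    report <- tibble::tibble(order = vapply(orders, paste, character(1),
                                            collapse = ">"),
                             retained = vapply(sets, length, integer(1)))
    expect_equal(nrow(report), 24)
    expect_gte(n_distinct, 1)
  })
})

test_that("feature table CSV + sidecar round-trips", {
  withr::with_seed(36, {
    ft <- impute_half_min(random_table())
    path <- withr::local_tempfile(fileext = ".csv")
    write_feature_table(ft, path)
    back <- read_feature_table(path)
    expect_equal(pulsedms:::ft_matrix(back), pulsedms:::ft_matrix(ft),
                 tolerance = 1e-12)
    expect_equal(features_of(back)$mz, features_of(ft)$mz)
    expect_equal(length(applied_filters(back)), length(applied_filters(ft)))
  })
})
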