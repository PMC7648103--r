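test_that("glog limits, identity and monotonicity", {
  x <- matrix(c(1, 2, 4, 8), 2, 2)
  expect_equal(glog_transform(x, lambda = 0), log2(x), ignore_attr = TRUE)
  # x = lambda: glog(x) = log2(x (1 + sqrt(2)) / 2)
  expect_equal(glog_transform(matrix(3), lambda = 3)[1, 1],
               log2(3 * (1 + sqrt(2)) / 2))
  withr::with_seed(40, {
    xs <- sort(rlnorm(50, 0, 2))
    g <- glog_transform(matrix(xs, nrow = 1), lambda = 0.5)
    expect_true(all(diff(as.vector(g)) > 0))
  })
  expect_error(glog_transform(matrix(c(1, -1), 1)), "non-positive")
  # lambda = "auto" uses the minimum positive value
  g <- glog_transform(matrix(c(2, 8), 1), lambda = "auto")
  expect_equal(attr(g, "glog_lambda"), 2)
})

test_that("autoscaling yields exact column moments and is idempotent", {
  expect_equal(as.vector(autoscale(matrix(c(1, 3), 2, 1))),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  withr::with_seed(41, {
    x <- matrix(rnorm(60, 5, 3), 10, 6)
    z <- autoscale(x)
    expect_lt(max(abs(colMeans(z))), 1e-10)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
    z2 <- autoscale(z)
    expect_equal(unclass(z2), unclass(z), tolerance = 1e-10,
                 ignore_attr = TRUE)
  })
  expect_error(autoscale(cbind(1:5, rep(2, 5))), "constant")
})

test_that("Welch test matches the closed form and handles degeneracy", {
  a <- c(1, 2); b <- c(3, 5)
  got <- welch_t_test(a, b)
  # hand-computed Welch statistic and Welch-Satterthwaite df
  se2 <- var(a) / 2 + var(b) / 2
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  df_manual <- se2^2 / ((var(a) / 2)^2 / 1 + (var(b) / 2)^2 / 1)
  expect_equal(got$statistic, t_manual, tolerance = 1e-12)
  expect_equal(got$df, df_manual, tolerance = 1e-12)
  expect_equal(got$p_value,
               2 * stats::pt(-abs(t_manual), df_manual), tolerance = 1e-12)

  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_lt(welch_t_test(c(1, 2, 3), c(101, 102.2, 103.1))$p_value, 1e-3)
  # exactly constant equal groups: limit p = 1
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p_value, 1)
})

test_that("fold change is the group-mean ratio on raw abundances", {
  v <- rbind(c(5, 10), c(5, 10), c(10, 10), c(10, 10))
  ft <- toy_table(v, roles = rep("sample", 4),
                  groups = c("Pre", "Pre", "Post", "Post"))
  fc <- fold_change(ft)
  expect_equal(unname(fc), c(2, 1))
  ft0 <- toy_table(rbind(c(0, 1), c(0, 1), c(1, 1), c(1, 1)),
                   roles = rep("sample", 4),
                   groups = c("Pre", "Pre", "Post", "Post"))
  expect_error(fold_change(ft0), "zero group-1 mean")
})

test_that("planted fold changes are estimated within expected error", {
  # 5x effect, 10% noise, n = 10/group: estimate within [4, 6] nearly always
  withr::with_seed(42, {
    n_rep <- 200
    est <- vapply(seq_len(n_rep), function(i) {
      pre <- 100 * rlnorm(10, 0, sqrt(log(1.01)))
      post <- 500 * rlnorm(10, 0, sqrt(log(1.01)))
      mean(post) / mean(pre)
    }, numeric(1))
    expect_gte(mean(est >= 4 & est <= 6), 0.95)
  })
})

test_that("volcano selection applies strict thresholds", {
  v <- tibble::tibble(feature = c("a", "b", "c", "d"),
                      p_value = c(0.04, 0.04, 0.05, 0.01),
                      fc = c(3, 1.5, 3, 0.4))
  expect_identical(volcano_select(v), c("a", "d"))
})

test_that("PLS-DA separates constructed classes with orthogonal scores", {
  withr::with_seed(43, {
    n <- 20; p <- 10
    y <- rep(c("U", "S"), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[y == "S", 1:4] <- X[y == "S", 1:4] + 4
    colnames(X) <- paste0("V", 1:p)
    fit <- plsda_fit(autoscale(X), y, n_components = 2)
    t1 <- fit$scores[, 1]
    expect_true(max(t1[y == "U"]) < min(t1[y == "S"]) ||
                  min(t1[y == "U"]) > max(t1[y == "S"]))
    expect_lt(abs(sum(fit$scores[, 1] * fit$scores[, 2])), 1e-8)
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-8)
  })
})

test_that("y-orthogonal data carries no explainable y-variance", {
  withr::with_seed(44, {
    n <- 16; p <- 6
    y <- rep(c("A", "B"), each = n / 2)
    yc <- ifelse(y == "B", 1, -1)
    X <- matrix(rnorm(n * p), n, p)
    X <- X - yc %*% t(crossprod(X, yc)) / sum(yc^2)  # project y out
    X <- X + matrix(rnorm(n * p, 0, 1e-8), n, p)
    fit <- plsda_fit(X, y, n_components = 1)
    ssy <- fit$y_loadings^2 * colSums(fit$scores^2)
    expect_lt(sum(ssy) / sum((yc - mean(yc))^2), 1e-6)
  })
})

test_that("VIP identifies informative features and normalizes correctly", {
  withr::with_seed(45, {
    n <- 20; p <- 12
    y <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[, 5] <- ifelse(y == "B", 1, -1) + rnorm(n, 0, 0.1)
    fit <- plsda_fit(autoscale(X), y, n_components = 2)
    expect_equal(which.max(fit$vip), 5, ignore_attr = TRUE)
    # identical columns: all weights equal, VIP = 1 everywhere
    Xeq <- matrix(rep(ifelse(y == "B", 1, -1) + rnorm(n, 0, 0.2), 4), n, 4)
    fit_eq <- plsda_fit(Xeq, y, n_components = 1)
    expect_equal(unname(fit_eq$vip), rep(1, 4), tolerance = 1e-10)
  })
})

test_that("VIP and scores agree with an independent PLS implementation", {
  withr::with_seed(46, {
    n <- 20; p <- 15
    y <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[y == "B", 1:3] <- X[y == "B", 1:3] + 2
    colnames(X) <- paste0("V", 1:p)
    Z <- autoscale(X)
    fit <- plsda_fit(Z, y, n_components = 2)
    mo <- mixOmics::plsda(Z, factor(y), ncomp = 2, scale = FALSE)
    expect_gt(abs(cor(fit$scores[, 1], mo$variates$X[, 1])), 1 - 1e-8)
    expect_equal(unname(fit$vip), unname(mixOmics::vip(mo)[, 2]),
                 tolerance = 1e-6)
  })
})

test_that("discriminant selection intersects volcano and VIP with strict cutoff", {
  vip <- c(a = 2.5, b = 1.8, c = 1.9, d = 0.2)
  expect_identical(select_significant(c("a", "b", "c"), vip), c("a", "c"))
  expect_identical(select_significant(character(), vip), character())
})

test_that("orthogonal signal correction removes a y-orthogonal confounder", {
  withr::with_seed(47, {
    n <- 20; p <- 8
    y <- rep(c("A", "B"), each = n / 2)
    yc <- ifelse(y == "B", 1, -1); yc <- yc - mean(yc)
    a <- rnorm(p)
    X0 <- yc %*% t(a)                          # pure predictive structure
    t_conf <- rnorm(n)
    t_conf <- t_conf - yc * sum(t_conf * yc) / sum(yc^2)
    b <- rnorm(p); b <- b - a * sum(a * b) / sum(a^2)
    X1 <- X0 + 3 * t_conf %*% t(b)             # plus orthogonal confounder

    plain <- plsda_fit(X0 + matrix(rnorm(n * p, 0, 1e-9), n, p), y, 1)
    op <- oplsda_fit(X1, y, n_ortho = 1)
    s_ref <- plain$scores[, 1] / sqrt(sum(plain$scores[, 1]^2))
    s_op <- op$scores[, 1] / sqrt(sum(op$scores[, 1]^2))
    expect_lt(min(sum((s_ref - s_op)^2), sum((s_ref + s_op)^2)), 1e-6)

    # no orthogonal structure: oPLS predictive component = plain PLS comp 1
    op0 <- oplsda_fit(X0 + matrix(rnorm(n * p, 0, 1e-9), n, p), y,
                      n_ortho = 1)
    c1 <- cor(op0$scores[, 1], plain$scores[, 1])
    expect_gt(abs(c1), 1 - 1e-6)

    # predicted y correlates with the class coding on separable data
    expect_gt(cor(op$fitted, yc), 0.99)
  })
})

test_that("leave-one-out CV refits per fold and scores classifications", {
  withr::with_seed(48, {
    n <- 20; p <- 6
    y <- rep(c("U", "S"), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[y == "S", ] <- X[y == "S", ] + 5
    cv <- loo_cv(X, y, type = "oplsda")
    expect_equal(cv$accuracy, 1)
    expect_equal(cv$sensitivity, 1)
    expect_equal(cv$specificity, 1)
    expect_identical(cv$positive, "S")

    # n = 4: exactly 4 held-out predictions
    cv4 <- loo_cv(X[c(1, 2, 11, 12), ], y[c(1, 2, 11, 12)], type = "plsda",
                  n_components = 1)
    expect_equal(nrow(cv4$predictions), 4)

    # permuted labels: near-chance accuracy on average
    accs <- vapply(1:20, function(i) {
      yp <- sample(y)
      loo_cv(X[, 1:3], yp, type = "plsda", n_components = 1)$accuracy
    }, numeric(1))
    expect_gt(mean(accs), 0.2)
    expect_lt(mean(accs), 0.8)
  })
})

test_that("PLS-DA and oPLS-DA give identical LOO predictions without orthogonal structure", {
  withr::with_seed(49, {
    n <- 12; p <- 5
    y <- rep(c("A", "B"), each = n / 2)
    yc <- ifelse(y == "B", 1, -1)
    X <- yc %*% t(rnorm(p)) + matrix(rnorm(n * p, 0, 1e-6), n, p)
    cv_pls <- loo_cv(X, y, type = "plsda", n_components = 1)
    cv_opls <- loo_cv(X, y, type = "oplsda", n_ortho = 1)
    expect_identical(cv_pls$predictions$predicted,
                     cv_opls$predictions$predicted)
  })
})

test_that("PCA conserves variance with a fixed sign convention", {
  # 2-D data on a line: PC1 explains everything
  x <- cbind(1:10, 2 * (1:10))
  pc <- pca_fit(scale(x, scale = FALSE))
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)

  withr::with_seed(50, {
    X <- autoscale(matrix(rnorm(80), 10, 8))
    pc <- pca_fit(X)
    expect_equal(sum(pc$variance), sum(apply(X, 2, var)), tolerance = 1e-10)
    # reconstruction at full rank
    expect_lt(max(abs(pc$scores %*% t(pc$loadings) - X)), 1e-8)
    # largest-magnitude loading of each component is positive
    for (j in seq_len(ncol(pc$loadings))) {
      v <- pc$loadings[, j]
      expect_gte(v[which.max(abs(v))], 0)
    }
  })
})

test_that("correlation map and anchor correlations behave as Pearson r", {
  withr::with_seed(51, {
    x <- rnorm(12)
    X <- cbind(a = x, b = -x, c = rnorm(12))
    cm <- pearson_correlation_map(X)
    expect_equal(unname(diag(cm)), rep(1, 3))
    expect_equal(cm, t(cm))
    expect_equal(cm["a", "b"], -1)
    expect_true(all(cm >= -1 & cm <= 1))
    expect_error(pearson_correlation_map(cbind(x, rep(1, 12))), "constant")

    # anchor with 5 negatively scaled copies + 10% noise: |r| > 0.8
    anchor <- rnorm(20, 0, 1)
    copies <- sapply(1:5, function(i) {
      -runif(1, 0.5, 2) * anchor + rnorm(20, 0, 0.1)
    })
    Xa <- cbind(anchor = anchor, copies)
    r <- correlation_to_anchor(Xa, "anchor")
    expect_true(all(abs(r[-1]) > 0.8))
    expect_true(all(r[-1] < 0))
  })
})

test_that("tidy and glance methods summarize fitted models", {
  withr::with_seed(52, {
    y <- rep(c("A", "B"), each = 6)
    X <- matrix(rnorm(12 * 4), 12, 4)
    X[y == "B", 1] <- X[y == "B", 1] + 3
    colnames(X) <- paste0("V", 1:4)
    fit <- plsda_fit(autoscale(X), y, 2)
    td <- tidy(fit)
    expect_s3_class(td, "tbl_df")
    expect_identical(td$feature, paste0("V", 1:4))
    gl <- glance(fit)
    expect_equal(gl$n_components, 2)
    cv <- loo_cv(X, y, type = "plsda", n_components = 1)
    expect_s3_class(glance(cv), "tbl_df")
  })
})
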