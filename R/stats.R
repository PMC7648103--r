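# Statistical stage: variance stabilization, scaling, univariate testing and
# fold changes, PLS-DA / oPLS-DA with VIP scores, leave-one-out CV, PCA and
# Pearson correlation.
#
# Convention mirrored from the upstream processing split: fold changes are
# computed on un-transformed IS-normalized abundances (post-imputation);
# p-values, multivariate models and correlations on the glog-transformed,
# autoscaled matrix.

# Biological-sample matrix and class labels from a feature table.
sample_matrix <- function(table) {
  rows <- table$role == "sample"
  m <- ft_matrix(table)[rows, , drop = FALSE]
  rownames(m) <- table$sample_id[rows]
  attr(m, "group") <- table$group[rows]
  m
}

#' Generalized log transform
#'
#' `x -> log2((x + sqrt(x^2 + lambda^2)) / 2)`, a variance-stabilizing map
#' that is smooth through small values and tends to `log2(x)` as
#' `lambda -> 0`.
#'
#' @param x A numeric matrix (samples x features) or a `feature_table` with
#'   no missing values; all values must be positive.
#' @param lambda Transform parameter in abundance units, or `"auto"` (the
#'   minimum positive value of the data).
#' @param base Logarithm base (default 2).
#' @return Same shape as `x`; the lambda used is attached as attribute
#'   `glog_lambda`.
#' @export
glog_transform <- function(x, lambda = "auto", base = 2) {
  if (inherits(x, "feature_table")) {
    f <- features_of(x)
    m <- ft_matrix(x)
    g <- glog_transform(m, lambda = lambda, base = base)
    out <- x
    for (j in seq_along(f$feature)) out[[f$feature[j]]] <- g[, j]
    out <- new_feature_table(out, f, attr(x, "filters"))
    attr(out, "glog_lambda") <- attr(g, "glog_lambda")
    return(out)
  }
  m <- as.matrix(x)
  if (anyNA(m)) stop("missing values present; impute first", call. = FALSE)
  if (any(m <= 0)) stop("non-positive values present", call. = FALSE)
  if (identical(lambda, "auto")) lambda <- min(m)
  stopifnot(is.numeric(lambda), lambda >= 0)
  out <- log((m + sqrt(m^2 + lambda^2)) / 2, base = base)
  attr(out, "glog_lambda") <- lambda
  out
}

#' Autoscale (unit-variance scale) a matrix
#'
#' Centers each feature column to mean 0 and scales to standard deviation 1
#' (n-1 denominator).
#'
#' @param x Numeric matrix, samples x features.
#' @return Scaled matrix with `scaled:center` / `scaled:scale` attributes.
#' @export
autoscale <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(utils::head(colnames(m)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  scale(m)
}

#' Welch's unequal-variance t-test
#'
#' Two-tailed p-value with Welch-Satterthwaite degrees of freedom, via
#' [stats::t.test()]. Zero-variance degenerate groups fall back to the exact
#' limit (p = 1 for equal means, p = 0 otherwise).
#'
#' @param group_a,group_b Numeric vectors (each length >= 2).
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  res <- tryCatch(t.test(group_a, group_b, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    p <- if (isTRUE(all.equal(mean(group_a), mean(group_b)))) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf, df = NA_real_,
                p_value = p))
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Per-feature fold change between groups
#'
#' `mean(group2) / mean(group1)` per feature, on un-transformed IS-normalized
#' abundances after imputation.
#'
#' @param table A `feature_table` (post-imputation).
#' @param group1,group2 Group labels; default to the first and second labels
#'   in table order (so the ratio reads second/first, stimulated over
#'   unstimulated).
#' @return Named numeric vector of ratios (names = feature keys).
#' @export
fold_change <- function(table, group1 = NULL, group2 = NULL) {
  m <- sample_matrix(table)
  g <- attr(m, "group")
  lv <- unique(g)
  group1 <- group1 %||% lv[1]
  group2 <- group2 %||% lv[2]
  m1 <- colMeans(m[g == group1, , drop = FALSE])
  m2 <- colMeans(m[g == group2, , drop = FALSE])
  if (any(m1 == 0)) stop("zero group-1 mean for some feature", call. = FALSE)
  m2 / m1
}

#' Volcano table: fold change plus Welch p-value per feature
#'
#' Fold changes come from the raw (IS-normalized, imputed) table; p-values
#' from Welch's t-test on the glog-transformed, autoscaled matrix.
#'
#' @inheritParams fold_change
#' @param lambda Passed to [glog_transform()].
#' @param p_cut,fc_hi,fc_lo Selection thresholds recorded in `passes`
#'   (strict inequalities).
#' @return A tibble (`feature`, `mz`, `fc`, `p_value`, `passes`) of class
#'   `volcano_result`.
#' @export
volcano_table <- function(table, group1 = NULL, group2 = NULL,
                          lambda = "auto", p_cut = 0.05, fc_hi = 2,
                          fc_lo = 0.5) {
  m <- sample_matrix(table)
  g <- attr(m, "group")
  lv <- unique(g)
  group1 <- group1 %||% lv[1]
  group2 <- group2 %||% lv[2]
  fc <- fold_change(table, group1, group2)
  z <- autoscale(glog_transform(m, lambda = lambda))
  p <- apply(z, 2, function(col) {
    welch_t_test(col[g == group1], col[g == group2])$p_value
  })
  f <- features_of(table)
  out <- tibble::tibble(
    feature = f$feature, mz = f$mz, fc = unname(fc), p_value = unname(p),
    passes = p < p_cut & (fc > fc_hi | fc < fc_lo)
  )
  attr(out, "cuts") <- c(p_cut = p_cut, fc_hi = fc_hi, fc_lo = fc_lo)
  attr(out, "groups") <- c(group1, group2)
  class(out) <- c("volcano_result", class(out))
  out
}

#' Features passing the volcano criteria
#'
#' Strict thresholds: `p < p_cut` and (`fc > fc_hi` or `fc < fc_lo`).
#'
#' @param volcano A [volcano_table()] result.
#' @param p_cut,fc_hi,fc_lo Thresholds.
#' @return Character vector of feature keys.
#' @export
volcano_select <- function(volcano, p_cut = 0.05, fc_hi = 2, fc_lo = 0.5) {
  volcano$feature[volcano$p_value < p_cut &
                    (volcano$fc > fc_hi | volcano$fc < fc_lo)]
}

# ---- PLS ----

code_y <- function(y) {
  lv <- if (is.factor(y)) levels(droplevels(y)) else unique(y)
  if (length(lv) != 2) stop("need exactly two classes", call. = FALSE)
  list(levels = lv, coded = ifelse(y == lv[2], 1, -1))
}

# NIPALS PLS1 on (X, centered y): deterministic, one pass per component.
nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- X; yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop("rank deficiency: no y-covariance left at component ", a,
           call. = FALSE)
    }
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  list(weights = W, loadings = P, scores = Tm, y_loadings = q)
}

#' Fit a PLS-DA model
#'
#' PLS1 via NIPALS on the (autoscaled) matrix against +/-1-coded class
#' labels, with deflation per component; deterministic. The second class
#' label codes as +1.
#'
#' @param X Numeric matrix, samples x features (glog + autoscaled).
#' @param y Two-class labels, length `nrow(X)`.
#' @param n_components Number of latent components (default 2).
#' @return A `pls_model`: scores `T`, weights `W`, loadings `P`, y-loadings
#'   `q`, per-feature `vip`, fitted values and the class decision threshold
#'   (midpoint of class-mean fitted values).
#' @export
plsda_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  cy <- code_y(y)
  y_center <- mean(cy$coded)
  fit <- nipals_pls1(X, cy$coded - y_center, n_components)
  rotation <- fit$weights %*%
    solve(crossprod(fit$loadings, fit$weights))
  coef <- rotation %*% fit$y_loadings
  fitted <- drop(X %*% coef) + y_center
  thr <- mean(c(mean(fitted[cy$coded == 1]), mean(fitted[cy$coded == -1])))
  model <- structure(list(
    type = "plsda", n_components = n_components,
    scores = fit$scores, weights = fit$weights, loadings = fit$loadings,
    y_loadings = fit$y_loadings, coefficients = coef,
    y_center = y_center, y_levels = cy$levels,
    fitted = fitted, class_threshold = thr,
    features = colnames(X) %||% paste0("V", seq_len(ncol(X)))
  ), class = "pls_model")
  model$vip <- vip_scores(model)
  model
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm weight
#' vectors and `SSY_a = q_a^2 t_a' t_a`, the y-variance captured by component
#' a. Squared VIPs average to 1 over features.
#'
#' @param model A fitted `pls_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  p <- nrow(model$weights)
  w2 <- sweep(model$weights^2, 2,
              colSums(model$weights^2), "/")
  vip <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  names(vip) <- model$features
  vip
}

#' Final discriminant feature list
#'
#' Intersection of the volcano-passing features with those whose PLS-DA VIP
#' score strictly exceeds the cutoff.
#'
#' @param volcano_features Character vector from [volcano_select()].
#' @param vip Named VIP vector from [vip_scores()].
#' @param vip_cut VIP cutoff (default 1.8, strict).
#' @return Character vector of feature keys.
#' @export
select_significant <- function(volcano_features, vip, vip_cut = 1.8) {
  intersect(volcano_features, names(vip)[vip > vip_cut])
}

#' Fit an orthogonal PLS-DA model
#'
#' Orthogonal signal correction: `n_ortho` components of X-variation
#' orthogonal to y are estimated and removed, then a one-component PLS model
#' is fitted on the filtered matrix. Class prediction thresholds the
#' predicted y at the midpoint of the training class means.
#'
#' @inheritParams plsda_fit
#' @param n_ortho Number of orthogonal components removed (default 1).
#' @return A `pls_model` (type `"oplsda"`) with the orthogonal weights and
#'   loadings (`W_ortho`, `P_ortho`, `T_ortho`) alongside the predictive fit.
#' @export
oplsda_fit <- function(X, y, n_ortho = 1) {
  X <- as.matrix(X)
  cy <- code_y(y)
  yc <- cy$coded - mean(cy$coded)
  Xf <- X
  p <- ncol(X)
  Wo <- Po <- matrix(0, p, n_ortho)
  To <- matrix(0, nrow(X), n_ortho)
  for (a in seq_len(n_ortho)) {
    w <- crossprod(Xf, yc); w <- w / sqrt(sum(w^2))
    t_p <- Xf %*% w
    p_p <- crossprod(Xf, t_p) / sum(t_p^2)
    w_o <- p_p - drop(crossprod(w, p_p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10) {
      # no y-orthogonal structure left; keep zero component
      Wo[, a] <- 0; Po[, a] <- 0
      next
    }
    w_o <- w_o / nw
    t_o <- Xf %*% w_o
    p_o <- crossprod(Xf, t_o) / sum(t_o^2)
    Xf <- Xf - t_o %*% t(p_o)
    Wo[, a] <- w_o; Po[, a] <- p_o; To[, a] <- t_o
  }
  core <- plsda_fit(Xf, y, n_components = 1)
  core$type <- "oplsda"
  core$n_ortho <- n_ortho
  core$W_ortho <- Wo
  core$P_ortho <- Po
  core$T_ortho <- To
  core
}

#' Predict classes from a fitted (o)PLS-DA model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix on the same feature scale as the training X.
#' @param ... Unused.
#' @return A tibble with `y_pred` (predicted y value) and `class`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  m <- as.matrix(newdata)
  if (identical(object$type, "oplsda")) {
    for (a in seq_len(object$n_ortho)) {
      w_o <- object$W_ortho[, a]
      if (all(w_o == 0)) next
      t_o <- m %*% w_o
      m <- m - t_o %*% t(object$P_ortho[, a])
    }
  }
  y_pred <- drop(m %*% object$coefficients) + object$y_center
  tibble::tibble(
    y_pred = y_pred,
    class = object$y_levels[(y_pred > object$class_threshold) + 1L]
  )
}

#' Leave-one-out cross-validated classification
#'
#' Each sample is predicted by a model refitted on the remaining n-1 samples,
#' with the autoscaling parameters re-estimated inside each training fold.
#'
#' @param X Numeric matrix, samples x features, on the transformed but
#'   UN-scaled scale (e.g. glog output): scaling happens per fold.
#' @param y Two-class labels.
#' @param type `"plsda"` or `"oplsda"`.
#' @param n_components,n_ortho Model size.
#' @param positive Label of the positive class for sensitivity; defaults to
#'   the second unique label (the stimulated / post-challenge group).
#' @return A list of class `cv_result`: per-sample `predictions`,
#'   `confusion` counts, `sensitivity`, `specificity`, `accuracy`.
#' @export
loo_cv <- function(X, y, type = c("oplsda", "plsda"), n_components = 2,
                   n_ortho = 1, positive = NULL) {
  type <- match.arg(type)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  lv <- unique(y)
  positive <- positive %||% lv[2]
  pred <- character(n)
  for (i in seq_len(n)) {
    if (length(unique(y[-i])) < 2) {
      stop("training fold with a single class", call. = FALSE)
    }
    ctr <- colMeans(X[-i, , drop = FALSE])
    scl <- apply(X[-i, , drop = FALSE], 2, sd)
    scl[scl == 0] <- 1
    Xtr <- scale(X[-i, , drop = FALSE], center = ctr, scale = scl)
    xte <- (X[i, ] - ctr) / scl
    fit <- if (type == "plsda") {
      plsda_fit(Xtr, y[-i], n_components = n_components)
    } else {
      oplsda_fit(Xtr, y[-i], n_ortho = n_ortho)
    }
    pred[i] <- predict(fit, matrix(xte, nrow = 1))$class
  }
  tp <- sum(pred == positive & y == positive)
  fn <- sum(pred != positive & y == positive)
  tn <- sum(pred != positive & y != positive)
  fp <- sum(pred == positive & y != positive)
  structure(list(
    predictions = tibble::tibble(sample = rownames(X) %||%
                                   as.character(seq_len(n)),
                                 truth = y, predicted = pred),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / n,
    positive = positive, type = type
  ), class = "cv_result")
}

#' Principal component analysis of an autoscaled matrix
#'
#' Thin wrapper over [stats::prcomp()] (no further centering or scaling) with
#' a deterministic sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param X Autoscaled matrix, samples x features.
#' @return A list of class `pca_result`: `scores`, `loadings`, `variance`
#'   (per component), `explained` (proportions).
#' @export
pca_fit <- function(X) {
  X <- as.matrix(X)
  pr <- prcomp(X, center = FALSE, scale. = FALSE)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, "*")
  loadings <- sweep(pr$rotation, 2, flip, "*")
  vars <- pr$sdev^2
  structure(list(scores = scores, loadings = loadings, variance = vars,
                 explained = vars / sum(vars)), class = "pca_result")
}

#' Pearson correlation map of selected features
#'
#' @param X Transformed + autoscaled matrix restricted to the features of
#'   interest (samples x features).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation_map <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("constant feature present", call. = FALSE)
  cor(X)
}

#' Correlation of every feature to an anchor feature
#'
#' @inheritParams pearson_correlation_map
#' @param anchor_feature Column name or index of the anchor.
#' @return Named vector of Pearson r against the anchor.
#' @export
correlation_to_anchor <- function(X, anchor_feature) {
  cm <- pearson_correlation_map(X)
  cm[, anchor_feature]
}

# ---- broom-style methods ----

#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(
    feature = x$features,
    vip = unname(x$vip),
    weight_1 = x$weights[, 1],
    loading_1 = x$loadings[, 1]
  )
}

#' @export
glance.pls_model <- function(x, ...) {
  ssy <- x$y_loadings^2 * colSums(x$scores^2)
  tibble::tibble(
    type = x$type,
    n_components = x$n_components,
    n_samples = nrow(x$scores),
    n_features = length(x$features),
    ssy_explained = sum(ssy)
  )
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    accuracy = x$accuracy
  )
}
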