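#' Gaussian GLM coefficient table
#'
#' Ordinary least squares with intercept (a generalized linear model with
#' Gaussian error), returning the coefficient table with two-sided t tests.
#' A rank-deficient design is an error naming the aliased columns.
#'
#' @param data A data frame holding response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`
#'   (t on n - p - 1 df), `p_value`, plus the fitted model in the
#'   `"fit"` attribute.
#' @export
gaussian_glm <- function(data, response, predictors) {
  data <- as.data.frame(data)
  stopifnot(all(c(response, predictors) %in% names(data)))
  if (nrow(data) <= length(predictors) + 1) {
    stop("need more observations than model parameters", call. = FALSE)
  }
  fml <- if (length(predictors) == 0) {
    stats::as.formula(paste(response, "~ 1"))
  } else {
    stats::reformulate(predictors, response = response)
  }
  fit <- glm(fml, data = data, family = gaussian())
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  s <- summary(fit)$coefficients
  out <- tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std_error = unname(s[, 2]),
    statistic = unname(s[, 3]), p_value = unname(s[, 4])
  )
  attr(out, "fit") <- fit
  out
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} from regressing predictor j on the others.
#' Perfect collinearity is reported as `Inf` with a flag rather than an
#' error.
#'
#' @param data A data frame.
#' @param predictors Character vector of (numeric) predictor columns.
#' @return A tibble with `predictor`, `vif`, `aliased`.
#' @export
vif_table <- function(data, predictors) {
  data <- as.data.frame(data)[, predictors, drop = FALSE]
  if (length(predictors) < 2) stop("need at least two predictors", call. = FALSE)
  out <- purrr::map_dfr(predictors, function(v) {
    fit <- lm(stats::reformulate(setdiff(predictors, v), response = v),
              data = data)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    aliased <- r2 > 1 - 1e-10
    tibble::tibble(predictor = v,
                   vif = if (aliased) Inf else 1 / (1 - r2),
                   aliased = aliased)
  })
  if (any(out$aliased)) {
    warning("perfectly collinear predictors: ",
            paste(out$predictor[out$aliased], collapse = ", "), call. = FALSE)
  }
  out
}

#' Linear discriminant analysis with resubstitution classification
#'
#' Fisher discriminants from the pooled within-group covariance
#' (via [MASS::lda()]), classifying by nearest group in discriminant space.
#' Priors are equal by default: with heavily unbalanced group sizes,
#' proportional priors let the prior dominate the resubstitution table.
#' Classification success is resubstitution unless `cv = TRUE`, which
#' switches to leave-one-out cross-validation.
#'
#' @param data A data frame.
#' @param predictors Character vector of numeric predictor columns.
#' @param group Name of the grouping column.
#' @param prior `"equal"` or `"proportional"`.
#' @param cv Leave-one-out cross-validated classification instead of
#'   resubstitution.
#' @return An `ems_lda` list: `fit` (the lda object), `confusion`
#'   (observed x predicted table), `percent_correct` (tibble per group),
#'   `total_correct` (percent), `n_axes`.
#' @export
lda_classify <- function(data, predictors, group,
                         prior = c("equal", "proportional"), cv = FALSE) {
  prior <- match.arg(prior)
  data <- as.data.frame(data)
  g <- factor(data[[group]])
  X <- data[, predictors, drop = FALSE]
  sizes <- table(g)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) {
    warning("groups with a single member: ",
            paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  pr <- if (prior == "equal") rep(1 / nlevels(g), nlevels(g)) else
    as.numeric(sizes) / length(g)
  fit <- MASS::lda(x = X, grouping = g, prior = pr)
  pred <- if (cv) {
    MASS::lda(x = X, grouping = g, prior = pr, CV = TRUE)$class
  } else {
    predict(fit, X)$class
  }
  confusion <- table(observed = g, predicted = pred)
  per_group <- diag(confusion) / rowSums(confusion) * 100
  structure(list(
    fit = fit,
    confusion = confusion,
    percent_correct = tibble::tibble(group = names(per_group),
                                     n = as.integer(rowSums(confusion)),
                                     correct_pct = unname(per_group)),
    total_correct = 100 * sum(diag(confusion)) / length(g),
    n_axes = ncol(fit$scaling),
    cv = cv, prior = prior
  ), class = "ems_lda")
}

#' @export
print.ems_lda <- function(x, ...) {
  cat(sprintf("<ems_lda> %d discriminant axes, %s classification success %.1f%%\n",
              x$n_axes, if (x$cv) "leave-one-out" else "resubstitution",
              x$total_correct))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.ems_lda <- function(x, ...) x$percent_correct

#' @export
glance.ems_lda <- function(x, ...) {
  tibble::tibble(total_correct = x$total_correct, n_axes = x$n_axes,
                 cv = x$cv, prior = x$prior)
}

# Wilks' lambda = det(W) / det(W + B) for numeric predictors X and groups g.
wilks_lambda <- function(X, g) {
  X <- as.matrix(X)
  g <- factor(g)
  centred_total <- scale(X, scale = FALSE)
  Tm <- crossprod(centred_total)
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    xi <- X[g == lev, , drop = FALSE]
    W <- W + crossprod(scale(xi, scale = FALSE))
  }
  det(W) / det(Tm)
}

#' Greedy forward selection on Wilks' lambda
#'
#' At each step adds the predictor that minimizes Wilks' lambda of the
#' expanded discriminant model, admitting it only if the partial-F test of
#' the lambda ratio has p below `p_enter`; stops when no candidate
#' qualifies. The partial F for adding one variable to a p-variable model
#' with g groups and n observations is
#' \eqn{F = \frac{n - g - p}{g - 1}\,\frac{1 - \Lambda_{p+1}/\Lambda_p}
#' {\Lambda_{p+1}/\Lambda_p}} on \eqn{(g - 1, n - g - p)} df.
#'
#' @param data A data frame.
#' @param predictors Candidate predictor columns (numeric).
#' @param group Grouping column.
#' @param p_enter Admission threshold (default 0.05).
#' @return A tibble of selected predictors in order: `step`, `term`,
#'   `wilks`, `F_partial`, `p_value`. Zero rows when nothing qualifies.
#' @export
greedy_wilks <- function(data, predictors, group, p_enter = 0.05) {
  data <- as.data.frame(data)
  g <- factor(data[[group]])
  n <- length(g); ng <- nlevels(g)
  selected <- character(0)
  lambda_prev <- 1
  rows <- list()
  repeat {
    candidates <- setdiff(predictors, selected)
    if (length(candidates) == 0) break
    if (n - ng - length(selected) < 1) break
    lams <- vapply(candidates, function(v) {
      wilks_lambda(data[, c(selected, v), drop = FALSE], g)
    }, numeric(1))
    best <- candidates[which.min(lams)]
    lambda_new <- min(lams)
    ratio <- lambda_new / lambda_prev
    df2 <- n - ng - length(selected)
    Fp <- (df2 / (ng - 1)) * (1 - ratio) / ratio
    pv <- pf(Fp, ng - 1, df2, lower.tail = FALSE)
    if (!is.finite(pv) || pv >= p_enter) break
    selected <- c(selected, best)
    rows[[length(rows) + 1]] <- tibble::tibble(
      step = length(selected), term = best, wilks = lambda_new,
      F_partial = Fp, p_value = pv)
    lambda_prev <- lambda_new
  }
  if (length(rows) == 0) {
    tibble::tibble(step = integer(), term = character(), wilks = numeric(),
                   F_partial = numeric(), p_value = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' MANOVA with Wilks' lambda
#'
#' Tests for overall group differences in a set of numeric variables using
#' Wilks' lambda with Rao's F approximation (via [stats::manova()]).
#'
#' @param data A data frame.
#' @param variables Numeric response columns.
#' @param group Grouping column.
#' @return A one-row tibble: `wilks`, `statistic` (approximate F), `df1`,
#'   `df2`, `p_value`.
#' @export
manova_wilks <- function(data, variables, group) {
  data <- as.data.frame(data)
  g <- factor(data[[group]])
  Y <- as.matrix(data[, variables, drop = FALSE])
  if (ncol(Y) == 1) {
    # univariate case: Wilks' lambda is SSW/SST and Rao's F is the ANOVA F
    a <- stats::anova(lm(Y[, 1] ~ g))
    return(tibble::tibble(
      wilks = a[2, "Sum Sq"] / sum(a[, "Sum Sq"]),
      statistic = a[1, "F value"], df1 = a[1, "Df"], df2 = a[2, "Df"],
      p_value = a[1, "Pr(>F)"]))
  }
  fit <- manova(Y ~ g)
  s <- summary(fit, test = "Wilks")$stats
  tibble::tibble(wilks = s[1, "Wilks"], statistic = s[1, "approx F"],
                 df1 = s[1, "num Df"], df2 = s[1, "den Df"],
                 p_value = s[1, "Pr(>F)"])
}

#' Permutation chi-square test for a contingency table
#'
#' Pearson chi-square statistic with a Monte-Carlo p-value from random
#' tables holding both margins fixed (Patefield sampler, [stats::r2dtable()]),
#' with the add-one correction \eqn{p = (\#\{sim \ge obs\} + 1)/(B + 1)}.
#' All-zero rows or columns are dropped with a warning.
#'
#' @param tab A matrix (or table) of non-negative integer counts.
#' @param n_perm Number of random tables (at least 999).
#' @param seed Integer seed.
#' @return A one-row tibble: `chi2`, `df`, `p_perm`, `p_asymptotic`,
#'   `n_perm`.
#' @export
contingency_chi2_perm <- function(tab, n_perm = 9999, seed = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (n_perm < 999) stop("n_perm must be at least 999", call. = FALSE)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero rows/columns from the contingency table",
            call. = FALSE)
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  E <- outer(rs, cs) / n
  chi2 <- sum((tab - E)^2 / E)
  set.seed(seed)
  sims <- vapply(r2dtable(n_perm, rs, cs),
                 function(x) sum((x - E)^2 / E), numeric(1))
  tibble::tibble(
    chi2 = chi2,
    df = (nrow(tab) - 1) * (ncol(tab) - 1),
    p_perm = (sum(sims >= chi2 - 1e-12) + 1) / (n_perm + 1),
    p_asymptotic = pchisq(chi2, (nrow(tab) - 1) * (ncol(tab) - 1),
                          lower.tail = FALSE),
    n_perm = n_perm
  )
}

#' Univariate association tests
#'
#' Thin tidy wrappers over the standard tests: Spearman or Pearson
#' correlation ([stats::cor.test()]) and Kruskal-Wallis
#' ([stats::kruskal.test()], tie-corrected H with a chi-square p on k - 1
#' df).
#'
#' @param x Numeric vector.
#' @param y Numeric vector (correlations) or grouping vector
#'   (Kruskal-Wallis).
#' @param method `"spearman"`, `"pearson"` or `"kruskal_wallis"`.
#' @return A one-row tibble: `method`, `statistic` (correlation or H),
#'   `p_value`.
#' @export
univariate_assoc <- function(x, y,
                             method = c("spearman", "pearson",
                                        "kruskal_wallis")) {
  method <- match.arg(method)
  if (method == "kruskal_wallis") {
    g <- factor(y)
    if (nlevels(g) < 2) stop("Kruskal-Wallis needs at least two groups",
                             call. = FALSE)
    t <- kruskal.test(x, g)
    return(tibble::tibble(method = method,
                          statistic = unname(t$statistic),
                          p_value = t$p.value))
  }
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(tibble::tibble(method = method, statistic = NA_real_,
                          p_value = NA_real_))
  }
  t <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(method = method, statistic = unname(t$estimate),
                 p_value = t$p.value)
}
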