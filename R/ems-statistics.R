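#' Embedded absences (coherence statistic, Abs)
#'
#' Counts the 0-cells lying strictly inside occupied ranges of the ordinated
#' matrix: for every species, the gaps between its first and last occupied
#' site, and (by default) likewise for every site's range across the species
#' ordering. All-zero rows or columns have no range and contribute nothing.
#'
#' @param m_ordinated An incidence matrix already ordinated by CA axis 1
#'   (see [ordinate()]).
#' @param scope `"both"` (species and site ranges, the Leibold-Mikkelson
#'   convention) or `"species_only"`.
#' @return Non-negative integer count.
#' @export
embedded_absences <- function(m_ordinated, scope = c("both", "species_only")) {
  scope <- match.arg(scope)
  m <- unclass(as_incidence(m_ordinated))
  cpp_count_abs(m, scope == "species_only")
}

#' Fill species ranges
#'
#' Sets every embedded absence within each species' (column) range to 1, so
#' each species occupies a contiguous run of sites; this is the "range
#' perspective" matrix on which replacements are counted. Idempotent.
#'
#' @inheritParams embedded_absences
#' @return The range-filled incidence matrix.
#' @export
fill_ranges <- function(m_ordinated) {
  x <- unclass(m_ordinated)
  storage.mode(x) <- "integer"
  out <- cpp_fill_ranges(x)
  dimnames(out) <- dimnames(m_ordinated)
  if (inherits(m_ordinated, "incidence_matrix")) {
    class(out) <- class(m_ordinated)
  }
  out
}

#' Species replacements (turnover statistic, Rep)
#'
#' On the range-filled matrix, counts over all unordered site pairs and
#' unordered species pairs the configurations in which one species occupies
#' the first site but not the second while the other occupies the second but
#' not the first.
#'
#' @inheritParams embedded_absences
#' @param fill Fill species ranges first (the range perspective, default).
#' @return Non-negative count.
#' @export
replacements <- function(m_ordinated, fill = TRUE) {
  m <- unclass(as_incidence(m_ordinated))
  if (fill) m <- cpp_fill_ranges(m)
  cpp_count_rep(m)
}

#' Boundary clumping: Morisita's dispersion index
#'
#' Collects both range boundaries of every species (the first and last
#' occupied site; single-site species contribute both boundaries at that
#' site) and measures their aggregation across sites with Morisita's
#' dispersion index \eqn{I = n \sum_i f_i (f_i - 1) / (F (F - 1))}, where
#' \eqn{f_i} is the number of boundaries at site \eqn{i} and \eqn{F} their
#' total. \eqn{I = 1} indicates randomly placed boundaries, \eqn{I > 1}
#' clumped and \eqn{I < 1} hyperdispersed boundaries. Significance against 1
#' uses the standard Morisita chi-square statistic
#' \eqn{\chi^2 = I(F-1) + n - F} on \eqn{n - 1} degrees of freedom; the
#' reported p-value is two-sided (twice the smaller tail, capped at 1).
#'
#' @inheritParams embedded_absences
#' @return A list with `morisita_index`, `p_clumping`, `chi2`, `df`,
#'   `n_boundaries`.
#' @export
boundary_clumping <- function(m_ordinated) {
  m <- unclass(as_incidence(m_ordinated))
  n <- nrow(m)
  occupied <- colSums(m) > 0
  if (sum(occupied) < 1) stop("no occupied species ranges", call. = FALSE)
  firsts <- apply(m[, occupied, drop = FALSE], 2, function(col) which(col > 0)[1])
  lasts <- apply(m[, occupied, drop = FALSE], 2, function(col) max(which(col > 0)))
  f <- tabulate(c(firsts, lasts), nbins = n)
  FF <- sum(f)
  if (FF < 2) stop("fewer than two range boundaries; Morisita index undefined",
                   call. = FALSE)
  I <- n * sum(f * (f - 1)) / (FF * (FF - 1))
  chi2 <- I * (FF - 1) + n - FF
  df <- n - 1
  p <- min(1, 2 * min(pchisq(chi2, df), pchisq(chi2, df, lower.tail = FALSE)))
  list(morisita_index = I, p_clumping = p, chi2 = chi2, df = df,
       n_boundaries = FF)
}

#' Permutation test of an observed statistic against a null distribution
#'
#' Standardized effect size \eqn{z = (obs - mean_{null}) / sd_{null}} and a
#' two-tailed add-one permutation p-value,
#' \eqn{p = 2 \min(\#\{sim \le obs\} + 1, \#\{sim \ge obs\} + 1)/(n_{sim}+1)},
#' capped at 1. A degenerate null (zero spread) leaves z undefined and flags
#' the result; the p-value is still reported from the empirical distribution.
#'
#' @param observed Observed statistic.
#' @param sims Numeric vector of the statistic under the null model.
#' @return A list with `z`, `p`, `null_mean`, `null_sd`, `degenerate`.
#' @export
perm_test <- function(observed, sims) {
  sims <- sims[is.finite(sims)]
  if (length(sims) == 0) stop("empty null distribution", call. = FALSE)
  mu <- mean(sims)
  sdev <- sd(sims)
  degenerate <- !is.finite(sdev) || sdev == 0
  z <- if (!degenerate) (observed - mu) / sdev else
    if (observed == mu) 0 else NA_real_
  p <- min(1, 2 * min(sum(sims <= observed) + 1, sum(sims >= observed) + 1) /
             (length(sims) + 1))
  list(z = z, p = p, null_mean = mu, null_sd = if (degenerate) 0 else sdev,
       degenerate = degenerate)
}

#' Null-model test of an EMS statistic
#'
#' Re-ordinates every replicate of a null ensemble (empty species columns in
#' a replicate are dropped first; they have no range), measures the requested
#' statistic, and compares the observed value against the resulting null
#' distribution with [perm_test()].
#'
#' @param observed Observed statistic from the ordinated source matrix.
#' @param ensemble A [build_ensemble()] result.
#' @param statistic `"abs"` (embedded absences) or `"rep"` (replacements).
#' @param scope Coherence scope passed to [embedded_absences()].
#' @param reordinate Re-ordinate each replicate before measuring (the
#'   standard EMS convention); `FALSE` keeps each replicate's own ordering
#'   for sensitivity analysis.
#' @return A list as from [perm_test()] plus `sims`.
#' @export
null_test <- function(observed, ensemble, statistic = c("abs", "rep"),
                      scope = "both", reordinate = TRUE) {
  statistic <- match.arg(statistic)
  sims <- vapply(ensemble$matrices, function(mm) {
    mo <- if (reordinate) ordinate_replicate(mm) else mm
    if (statistic == "abs") {
      cpp_count_abs(mo, scope == "species_only")
    } else {
      cpp_count_rep(cpp_fill_ranges(mo))
    }
  }, numeric(1))
  out <- perm_test(observed, sims)
  out$sims <- sims
  out
}

#' Metacommunity types
#'
#' The ten labels of the EMS decision tree.
#' @return Character vector of labels.
#' @export
metacommunity_types <- function() {
  c("checkerboard", "random", "nested", "quasi_nested",
    "evenly_spaced", "quasi_evenly_spaced",
    "gleasonian", "quasi_gleasonian",
    "clementsian", "quasi_clementsian")
}

#' Classify a metacommunity from its three elements
#'
#' Implements the EMS decision tree. Coherence direction follows the raw
#' Z-score on embedded absences: *more* embedded absences than the null
#' (z > 0, significant) is negative coherence (checkerboard); *fewer*
#' (z < 0, significant) is positive coherence. Nonsignificant coherence is
#' random. Under positive coherence, significantly negative turnover is
#' nested, significantly positive turnover splits into evenly spaced /
#' Gleasonian / Clementsian by boundary clumping, and nonsignificant
#' turnover yields the quasi analogues (quasi-nested when the observed
#' replacement count falls below its null mean).
#'
#' @param coherence,turnover Lists with elements `p`, `observed`,
#'   `null_mean` (as assembled by [ems_analyze()], or hand-built).
#' @param clumping List with `morisita_index` and `p_clumping`
#'   (see [boundary_clumping()]).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return A single label from [metacommunity_types()].
#' @export
classify_metacommunity <- function(coherence, turnover, clumping,
                                   alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single probability strictly between 0 and 1",
         call. = FALSE)
  }
  if (coherence$p >= alpha) return("random")
  if (coherence$observed > coherence$null_mean) return("checkerboard")
  clump_label <- function(prefix) {
    if (clumping$p_clumping < alpha && clumping$morisita_index > 1) {
      paste0(prefix, "clementsian")
    } else if (clumping$p_clumping < alpha && clumping$morisita_index < 1) {
      paste0(prefix, "evenly_spaced")
    } else {
      paste0(prefix, "gleasonian")
    }
  }
  if (turnover$p < alpha) {
    if (turnover$observed < turnover$null_mean) return("nested")
    return(clump_label(""))
  }
  if (turnover$observed < turnover$null_mean) return("quasi_nested")
  clump_label("quasi_")
}

#' Full EMS analysis of one incidence matrix
#'
#' Validates and ordinates the matrix, computes embedded absences (Abs),
#' replacements on the range-filled matrix (Rep) and Morisita boundary
#' clumping, tests Abs and Rep against the chosen permutation null model,
#' and classifies the metacommunity type.
#'
#' @param m An [incidence_matrix()].
#' @param null_model `"r1"` (fixed-proportional) or `"quasiswap"`
#'   (fixed-fixed).
#' @param n_sim Number of null replicates (default 999).
#' @param seed Integer seed (mandatory).
#' @param alpha Significance level for the decision tree.
#' @param scope Coherence scope, `"both"` or `"species_only"`.
#' @param fill Count replacements on the range-filled matrix (default).
#' @param reordinate Re-ordinate each null replicate (default).
#' @param thin,burnin Quasiswap chain controls, see [build_ensemble()].
#' @return An `ems_result` list: observed statistics, null means/SDs,
#'   Z-scores, p-values, Morisita index and its test, the assigned `mtype`,
#'   and provenance (`null_model`, `n_sim`, `seed`, `alpha`, dimensions,
#'   fill). Use [tidy()] / [glance()] for tabular views.
#' @examples
#' m <- simulate_metacommunity("clementsian", 20, 40, seed = 7)
#' res <- ems_analyze(m, n_sim = 99, seed = 7)
#' res$mtype
#' @export
ems_analyze <- function(m, null_model = c("r1", "quasiswap"), n_sim = 999,
                        seed, alpha = 0.05, scope = c("both", "species_only"),
                        fill = TRUE, reordinate = TRUE, thin = NULL,
                        burnin = NULL) {
  null_model <- match.arg(null_model)
  scope <- match.arg(scope)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  m <- validate_for_ems(m)
  ord <- ca_axis1(m)
  mo <- ordinate(m, ord)
  abs_obs <- embedded_absences(mo, scope = scope)
  rep_obs <- replacements(mo, fill = fill)
  clump <- boundary_clumping(mo)
  ens <- build_ensemble(m, model = null_model, n_sim = n_sim, seed = seed,
                        thin = thin, burnin = burnin)
  sims <- measure_ensemble(ens, scope = scope, fill = fill,
                           reordinate = reordinate)
  coh <- perm_test(abs_obs, sims$abs)
  turn <- perm_test(rep_obs, sims$rep)
  mtype <- classify_metacommunity(
    coherence = list(p = coh$p, observed = abs_obs, null_mean = coh$null_mean),
    turnover = list(p = turn$p, observed = rep_obs, null_mean = turn$null_mean),
    clumping = clump, alpha = alpha)
  structure(list(
    n_sites = nrow(m), n_species = ncol(m), fill = matrix_fill(m),
    abs_observed = abs_obs, rep_observed = rep_obs,
    abs_null_mean = coh$null_mean, abs_null_sd = coh$null_sd,
    rep_null_mean = turn$null_mean, rep_null_sd = turn$null_sd,
    z_coherence = coh$z, z_turnover = turn$z,
    p_coherence = coh$p, p_turnover = turn$p,
    degenerate_null = coh$degenerate || turn$degenerate,
    morisita_index = clump$morisita_index, p_clumping = clump$p_clumping,
    mtype = mtype, eigenvalue_axis1 = ord$eigenvalue_axis1,
    null_model = null_model, n_sim = n_sim, seed = seed, alpha = alpha,
    scope = scope, tie_break = "stable_input_order",
    morisita_df = clump$df,
    ordination = ord, ordinated = mo
  ), class = "ems_result")
}

# Measure Abs and Rep over every ensemble replicate in one pass.
measure_ensemble <- function(ensemble, scope = "both", fill = TRUE,
                             reordinate = TRUE) {
  species_only <- identical(scope, "species_only")
  n <- length(ensemble$matrices)
  abs_sims <- rep_sims <- numeric(n)
  for (k in seq_len(n)) {
    mo <- if (reordinate) ordinate_replicate(ensemble$matrices[[k]]) else
      ensemble$matrices[[k]]
    abs_sims[k] <- cpp_count_abs(mo, species_only)
    rep_sims[k] <- cpp_count_rep(if (fill) cpp_fill_ranges(mo) else mo)
  }
  list(abs = abs_sims, rep = rep_sims)
}

#' @export
print.ems_result <- function(x, ...) {
  cat(sprintf("<ems_result> %d sites x %d species (fill %.3f), %s null, %d sims\n",
              x$n_sites, x$n_species, x$fill, x$null_model, x$n_sim))
  cat(sprintf("  coherence: Abs = %g (null %.1f +/- %.2f), z = %.2f, p = %.4f\n",
              x$abs_observed, x$abs_null_mean, x$abs_null_sd,
              x$z_coherence, x$p_coherence))
  cat(sprintf("  turnover : Rep = %g (null %.1f +/- %.2f), z = %.2f, p = %.4f\n",
              x$rep_observed, x$rep_null_mean, x$rep_null_sd,
              x$z_turnover, x$p_turnover))
  cat(sprintf("  clumping : Morisita I = %.3f, p = %.4f\n",
              x$morisita_index, x$p_clumping))
  cat(sprintf("  type     : %s\n", x$mtype))
  invisible(x)
}

#' Tidy the three elements of an EMS result
#'
#' @param x An `ems_result`.
#' @param ... Unused.
#' @return A tibble with one row per element (coherence, turnover,
#'   boundary_clumping): observed statistic, null mean/sd, z, p.
#' @export
tidy.ems_result <- function(x, ...) {
  tibble::tibble(
    element = c("coherence", "turnover", "boundary_clumping"),
    statistic = c("Abs", "Rep", "morisita_index"),
    observed = c(x$abs_observed, x$rep_observed, x$morisita_index),
    null_mean = c(x$abs_null_mean, x$rep_null_mean, NA_real_),
    null_sd = c(x$abs_null_sd, x$rep_null_sd, NA_real_),
    z = c(x$z_coherence, x$z_turnover, NA_real_),
    p = c(x$p_coherence, x$p_turnover, x$p_clumping)
  )
}

#' One-row summary of an EMS result
#'
#' @param x An `ems_result`.
#' @param ... Unused.
#' @return A one-row tibble mirroring the per-metacommunity results schema.
#' @export
glance.ems_result <- function(x, ...) {
  tibble::tibble(
    n_sites = x$n_sites, n_species = x$n_species, fill = x$fill,
    abs_observed = x$abs_observed, rep_observed = x$rep_observed,
    z_coherence = x$z_coherence, z_turnover = x$z_turnover,
    p_coherence = x$p_coherence, p_turnover = x$p_turnover,
    morisita = x$morisita_index, p_clumping = x$p_clumping,
    mtype = x$mtype, null_model = x$null_model, n_sim = x$n_sim,
    seed = x$seed
  )
}
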