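#' First axis of reciprocal averaging (correspondence analysis)
#'
#' Ordinates a binary incidence matrix along the first non-trivial
#' correspondence-analysis axis, the gradient on which all EMS statistics
#' are computed. Site and species scores satisfy the reciprocal-averaging
#' fixed point: each site's score is proportional to the mean score of the
#' species it holds, and vice versa.
#'
#' The decomposition is the SVD of the standardized correspondence residuals
#' \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}} with \eqn{P} the matrix of
#' cell proportions and \eqn{r, c} its margins; scores are the standard
#' coordinates \eqn{D_r^{-1/2} u_1} and \eqn{D_c^{-1/2} v_1}. The axis sign
#' is arbitrary and is fixed so the first site's score is non-positive.
#'
#' @param m A validated [incidence_matrix()] with no empty rows or columns.
#' @param n_axes Number of axes to retain for diagnostics; only axis 1 is
#'   consumed by the EMS statistics.
#' @return An object of class `ems_ordination`: a list with `site_scores`,
#'   `species_scores` (named, axis 1), `site_order`, `species_order`
#'   (permutations sorting scores ascending, ties kept in input order),
#'   `eigenvalue_axis1`, and `axes` (a list of per-axis score matrices).
#' @examples
#' m <- simulate_metacommunity("clementsian", 20, 30, seed = 1)
#' o <- ca_axis1(m)
#' head(o$site_order)
#' @export
ca_axis1 <- function(m, n_axes = 1L) {
  m <- as_incidence(m)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("matrix has empty rows or columns; run validate_for_ems() first",
         call. = FALSE)
  }
  n <- sum(m)
  P <- unclass(m) / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - tcrossprod(r, cc)) / sqrt(tcrossprod(r, cc))
  # Eigendecomposition of the smaller cross-product; singular values of S
  # are bounded by 1, with the trivial axis already removed by centring.
  if (nrow(S) <= ncol(S)) {
    e <- eigen(tcrossprod(S), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    U <- e$vectors
    k <- min(n_axes, length(lam))
    V <- crossprod(S, U[, seq_len(k), drop = FALSE])
    V <- sweep(V, 2, sqrt(pmax(lam[seq_len(k)], .Machine$double.eps)), "/")
  } else {
    e <- eigen(crossprod(S), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    V <- e$vectors
    k <- min(n_axes, length(lam))
    U <- S %*% V[, seq_len(k), drop = FALSE]
    U <- sweep(U, 2, sqrt(pmax(lam[seq_len(k)], .Machine$double.eps)), "/")
  }
  if (lam[1] < 1e-12) {
    stop("no compositional gradient: first correspondence eigenvalue is zero",
         call. = FALSE)
  }
  site_axes <- sweep(U[, seq_len(k), drop = FALSE], 1, sqrt(r), "/")
  species_axes <- sweep(V[, seq_len(k), drop = FALSE], 1, sqrt(cc), "/")
  # Deterministic sign: first site's axis-1 score <= 0.
  for (a in seq_len(k)) {
    if (site_axes[1, a] > 0) {
      site_axes[, a] <- -site_axes[, a]
      species_axes[, a] <- -species_axes[, a]
    }
  }
  site_scores <- setNames(site_axes[, 1], rownames(m))
  species_scores <- setNames(species_axes[, 1], colnames(m))
  # Ordering treats scores equal to 12 significant digits as ties, so that
  # numerically identical sites (e.g. duplicated compositions) keep their
  # input order regardless of last-bit eigenvector noise.
  structure(list(
    site_scores = site_scores,
    species_scores = species_scores,
    site_order = order(signif(site_scores, 12)),
    species_order = order(signif(species_scores, 12)),
    eigenvalue_axis1 = lam[1],
    eigenvalues = lam[seq_len(k)],
    site_axes = site_axes,
    species_axes = species_axes
  ), class = "ems_ordination")
}

#' @export
print.ems_ordination <- function(x, ...) {
  cat(sprintf("<ems_ordination> axis-1 eigenvalue %.4f; %d sites, %d species\n",
              x$eigenvalue_axis1, length(x$site_scores), length(x$species_scores)))
  invisible(x)
}

#' Apply an ordination to an incidence matrix
#'
#' Permutes rows and columns by ascending axis-1 scores (ties keep the input
#' order, so the permutation is a stable sort). The result is the ordinated
#' matrix on which embedded absences, replacements and boundary clumping are
#' counted.
#'
#' @param m The incidence matrix the ordination was computed from.
#' @param o An [ca_axis1()] result; computed from `m` when missing.
#' @return The ordinated [incidence_matrix()].
#' @export
ordinate <- function(m, o = NULL) {
  m <- as_incidence(m)
  o <- o %||% ca_axis1(m)
  if (length(o$site_order) != nrow(m) || length(o$species_order) != ncol(m)) {
    stop("ordination dimensions do not match the matrix", call. = FALSE)
  }
  m[o$site_order, o$species_order, drop = FALSE]
}

#' Tidy site and species scores of an ordination
#'
#' @param x An `ems_ordination`.
#' @param ... Unused.
#' @return A tibble with one row per site and species: `id`, `role`,
#'   `score`, `rank`.
#' @export
tidy.ems_ordination <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(id = names(x$site_scores), role = "site",
                   score = unname(x$site_scores),
                   rank = rank(x$site_scores, ties.method = "first")),
    tibble::tibble(id = names(x$species_scores), role = "species",
                   score = unname(x$species_scores),
                   rank = rank(x$species_scores, ties.method = "first"))
  )
}

# Internal: axis-1 site/species orders for a (possibly null-replicate)
# matrix, dropping empty columns (they have no range and would otherwise
# need an arbitrary position). Returns the matrix already ordinated.
# Falls back to the input ordering if the gradient degenerates.
ordinate_replicate <- function(m) {
  keep <- colSums(m) > 0
  if (!all(keep)) m <- m[, keep, drop = FALSE]
  o <- tryCatch(ca_axis1(m), error = function(e) NULL)
  if (is.null(o)) return(m)
  m[o$site_order, o$species_order, drop = FALSE]
}
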