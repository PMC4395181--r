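#' Gower distance on metacommunity trait variables
#'
#' Computes the Gower distance across metacommunities from a mixed trait
#' table: the per-variable contribution is |x - y| / range for continuous
#' variables and a 0/1 mismatch for categorical ones, and the distance is
#' the average contribution over the selected variables. Missing values are
#' handled by pairwise deletion with re-averaging. The computation is
#' delegated to [cluster::daisy()].
#'
#' Body size is log10-transformed before range normalization by default:
#' across metacommunities it spans orders of magnitude (bacteria to fish),
#' and an untransformed range would let the largest organisms dominate the
#' variable's contribution.
#'
#' @param traits A data frame with one row per metacommunity, containing the
#'   columns named in `variables`. Character columns are treated as
#'   categorical.
#' @param variables Trait columns entering the distance; default the five
#'   metacommunity-level descriptors.
#' @param log_body_size Apply log10 to `body_size` first.
#' @return A `dist` object (lower triangle), labelled by `traits$id` when
#'   present.
#' @export
gower_distance <- function(traits,
                           variables = c("body_size", "trophic_group",
                                         "ecosystem", "life_form", "dispersal"),
                           log_body_size = TRUE) {
  traits <- as.data.frame(traits)
  missing_vars <- setdiff(variables, names(traits))
  if (length(missing_vars) > 0) {
    stop("trait table lacks variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(traits) < 2) stop("need at least two metacommunities", call. = FALSE)
  x <- traits[, variables, drop = FALSE]
  for (v in variables) {
    if (is.character(x[[v]]) || is.logical(x[[v]])) x[[v]] <- factor(x[[v]])
  }
  if (log_body_size && "body_size" %in% variables) {
    if (any(x$body_size <= 0, na.rm = TRUE)) {
      stop("body_size must be positive for the log transform", call. = FALSE)
    }
    x$body_size <- log10(x$body_size)
  }
  num <- vapply(x, is.numeric, logical(1))
  for (v in variables[num]) {
    if (diff(range(x[[v]], na.rm = TRUE)) == 0) {
      stop(sprintf("continuous variable '%s' has zero range", v), call. = FALSE)
    }
  }
  if (anyNA(x)) {
    warning("missing trait values: using pairwise deletion with re-averaging",
            call. = FALSE)
  }
  d <- cluster::daisy(x, metric = "gower", warnBin = FALSE)
  attr(d, "Labels") <- if (!is.null(traits$id)) as.character(traits$id) else
    rownames(traits)
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Eigendecomposition of the double-centred \eqn{-d^2/2} matrix (classical
#' metric scaling, via [stats::cmdscale()]). Axes with non-positive
#' eigenvalues are dropped without correction; `variance_explained` is
#' normalized over the retained (positive-eigenvalue) axes.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param n_axes Maximum number of axes to return (default all positive).
#' @return An object of class `ems_pcoa`: list with `coordinates` (tibble,
#'   one row per object, columns `PCoA1..k`), `eigenvalues` (positive ones),
#'   `all_eigenvalues`, and `variance_explained`.
#' @export
pcoa_traits <- function(d, n_axes = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- which(eig > tol)
  k <- length(pos)
  if (!is.null(n_axes)) k <- min(k, n_axes)
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PCoA", seq_len(k))
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  coords <- tibble::as_tibble(pts)
  coords <- dplyr::bind_cols(tibble::tibble(id = labels), coords)
  structure(list(
    coordinates = coords,
    eigenvalues = eig[pos],
    all_eigenvalues = eig,
    variance_explained = eig[pos] / sum(eig[pos])
  ), class = "ems_pcoa")
}

#' @export
print.ems_pcoa <- function(x, ...) {
  cat(sprintf("<ems_pcoa> %d objects, %d positive axes; axis-1 variance %.1f%%\n",
              nrow(x$coordinates), length(x$eigenvalues),
              100 * x$variance_explained[1]))
  invisible(x)
}

#' @export
tidy.ems_pcoa <- function(x, ...) {
  tibble::tibble(
    axis = paste0("PCoA", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    variance_explained = x$variance_explained
  )
}

#' Plot the first two principal coordinates
#'
#' @param object An `ems_pcoa`.
#' @param colour Optional vector (recycled) mapped to point colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ems_pcoa <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) stop("need at least two positive axes to plot", call. = FALSE)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PCoA1, .data$PCoA2)) +
    ggplot2::labs(
      x = sprintf("PCoA1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PCoA2 (%.1f%%)", 100 * object$variance_explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
}
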