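#' Multiple-site beta-diversity partition
#'
#' Partitions total multiple-site Sorensen dissimilarity into its turnover
#' (Simpson) and nestedness-resultant components. With \eqn{S_i} the
#' richness of site \eqn{i}, \eqn{S_T} the pooled richness and \eqn{b_{ij}}
#' the number of species present at site \eqn{i} but not \eqn{j}:
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
#'   {\sum_i S_i - S_T + \sum_{i<j}\min(b_{ij},b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum_{i<j}\min(b_{ij},b_{ji}) +
#'   \sum_{i<j}\max(b_{ij},b_{ji})}
#'   {2(\sum_i S_i - S_T) + \sum_{i<j}\min + \sum_{i<j}\max}}
#' and \eqn{\beta_{SNE} = \beta_{SOR} - \beta_{SIM}}. The identity
#' \eqn{\beta_{SOR} = \beta_{SIM} + \beta_{SNE}} holds by construction.
#'
#' @param m An [incidence_matrix()] with at least two sites and no empty
#'   site rows (clean with [validate_for_ems()] first).
#' @return A one-row tibble with `beta_sor`, `beta_sim`, `beta_sne`.
#' @examples
#' m <- simulate_metacommunity("gleasonian", 20, 40, seed = 3)
#' multisite_beta(validate_for_ems(m))
#' @export
multisite_beta <- function(m) {
  m <- as_incidence(m)
  if (nrow(m) < 2) stop("need at least two sites", call. = FALSE)
  if (ncol(m) < 1) stop("need at least one species", call. = FALSE)
  Si <- rowSums(m)
  if (any(Si == 0)) {
    stop("matrix has empty sites; remove them with validate_for_ems()",
         call. = FALSE)
  }
  ST <- sum(colSums(m) > 0)
  shared <- tcrossprod(unclass(m))
  b <- matrix(Si, nrow(m), nrow(m)) - shared        # b[i, j] = in i, not in j
  bt <- t(b)
  up <- upper.tri(b)
  sum_min <- sum(pmin(b[up], bt[up]))
  sum_max <- sum(pmax(b[up], bt[up]))
  a_term <- sum(Si) - ST
  beta_sim <- if (sum_min == 0) 0 else sum_min / (a_term + sum_min)
  denom_sor <- 2 * a_term + sum_min + sum_max
  beta_sor <- if (denom_sor == 0) 0 else (sum_min + sum_max) / denom_sor
  tibble::tibble(beta_sor = beta_sor, beta_sim = beta_sim,
                 beta_sne = beta_sor - beta_sim)
}
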