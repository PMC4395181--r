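#' Batch EMS + beta-diversity analysis
#'
#' Runs the full per-metacommunity stage over a collection of incidence
#' matrices: EMS analysis ([ems_analyze()]) and the multiple-site
#' beta-diversity partition ([multisite_beta()]), one result row per
#' matrix. Inputs may be a named list of matrices or a directory of
#' delimited files (`.csv`/`.tsv`; file names become dataset ids). Failing
#' datasets are logged and skipped, not fatal.
#'
#' Each dataset gets its own RNG substream derived from the master seed and
#' the dataset id, so adding or removing a dataset never changes the
#' others' results.
#'
#' @param x Named list of [incidence_matrix()] objects (or coercibles), or
#'   a directory path.
#' @param null_model,n_sim,alpha,scope Passed to [ems_analyze()].
#' @param seed Master integer seed (mandatory).
#' @param coerce Passed to [read_incidence()] for directory input.
#' @return An `ems_batch` tibble: `id`, the [glance()] columns of each EMS
#'   result, and `beta_sor`, `beta_sim`, `beta_sne`. Failures are kept in
#'   the `"failures"` attribute (tibble of id + message).
#' @export
run_ems_batch <- function(x, null_model = "r1", n_sim = 999, seed,
                          alpha = 0.05, scope = "both", coerce = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    files <- list.files(x, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
    files <- files[basename(files) != "manifest.csv"]
    if (length(files) == 0) stop("no matrix files found in ", x, call. = FALSE)
    x <- setNames(as.list(files), sub("\\.[^.]+$", "", basename(files)))
  }
  if (length(x) == 0) stop("empty input set", call. = FALSE)
  ids <- names(x) %||% paste0("dataset_", seq_along(x))
  if (is.null(names(x))) names(x) <- ids
  rows <- list(); fails <- list()
  for (id in ids) {
    res <- tryCatch({
      m <- x[[id]]
      if (is.character(m)) m <- read_incidence(m, coerce = coerce)
      m <- validate_for_ems(m)
      r <- ems_analyze(m, null_model = null_model, n_sim = n_sim,
                       seed = dataset_seed(seed, id), alpha = alpha,
                       scope = scope)
      dplyr::bind_cols(tibble::tibble(id = id), glance(r), multisite_beta(m))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble::tibble(id = id,
                                                   message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(rows) == 0) stop("all datasets failed", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble::tibble(id = character(), message = character())
  attr(out, "master_seed") <- seed
  class(out) <- c("ems_batch", class(out))
  if (nrow(attr(out, "failures")) > 0) {
    warning(sprintf("%d dataset(s) failed and were skipped",
                    nrow(attr(out, "failures"))), call. = FALSE)
  }
  out
}

#' Plot a batch of EMS results in Z-score space
#'
#' Scatter of turnover Z-score against coherence Z-score, point size scaled
#' by the Morisita boundary-clumping index and coloured by assigned type;
#' dashed lines mark the +/-1.96 significance bounds. More embedded absences
#' than the null pushes the coherence Z-score positive, so positively
#' coherent metacommunities sit left of the dashed line at -1.96.
#'
#' @param object An `ems_batch` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ems_batch <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$z_coherence, .data$z_turnover,
                               size = .data$morisita, colour = .data$mtype)) +
    ggplot2::geom_vline(xintercept = c(-1.96, 1.96), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "coherence Z-score (embedded absences)",
                  y = "turnover Z-score (replacements)",
                  size = "Morisita index", colour = "type") +
    ggplot2::theme_minimal()
}

#' Plot an ordinated incidence matrix
#'
#' Presence-absence heatmap of a (typically ordinated) incidence matrix,
#' sites on the vertical axis in matrix order.
#'
#' @param m An [incidence_matrix()].
#' @return A ggplot.
#' @export
plot_incidence <- function(m) {
  m <- as_incidence(m)
  df <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "site") |>
    tidyr::pivot_longer(-"site", names_to = "species", values_to = "presence")
  df$site <- factor(df$site, levels = rev(rownames(m)))
  df$species <- factor(df$species, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$species, .data$site,
                                   fill = factor(.data$presence))) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey20"),
                               guide = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "species (axis-1 order)", y = "sites (axis-1 order)")
}

#' Cross-metacommunity comparative analysis
#'
#' The second stage of the pipeline: relates per-metacommunity EMS outcomes
#' to metacommunity traits. Traits are summarized by Gower distance and
#' principal coordinates; the predictor set is the nine-variable design
#' (number of sites, matrix fill, multiple-site Simpson index, PCoA1-4,
#' basin area, latitude). Fits Gaussian GLMs for the coherence Z-score, the
#' turnover Z-score and the Morisita index; computes VIFs; runs a full and
#' a greedy-Wilks-reduced linear discriminant analysis of metacommunity
#' type; a MANOVA across types; and, when a `taxon` column is present, a
#' permutation chi-square of taxon against type plus Kruskal-Wallis checks
#' of the three elements across taxa.
#'
#' @param results An `ems_batch` tibble (or any tibble with `id`,
#'   `n_sites`, `fill`, `beta_sim`, `z_coherence`, `z_turnover`,
#'   `morisita`, `mtype`).
#' @param traits Trait table with `id`, the five trait variables,
#'   `basin_area`, `latitude` and optionally `taxon`.
#' @param exclude Character vector of metacommunity ids to drop (e.g.
#'   flagged outliers); never automatic.
#' @param n_axes Number of principal coordinates in the predictor set.
#' @param n_perm,seed Contingency-test permutations and seed.
#' @param lda_prior Priors for the discriminant analyses.
#' @param cv Cross-validated classification success instead of
#'   resubstitution.
#' @param p_enter Admission threshold for [greedy_wilks()].
#' @return An `ems_comparative` list of tidy components: `data` (the merged
#'   analysis table), `glm_coherence`, `glm_turnover`, `glm_clumping`,
#'   `vif`, `pcoa`, `lda_full`, `wilks_selection`, `lda_reduced`, `manova`,
#'   and (with taxa) `taxon_type_test`, `taxon_type_table`,
#'   `kruskal_by_taxon`.
#' @export
run_comparative <- function(results, traits, exclude = NULL, n_axes = 4,
                            n_perm = 9999, seed = 1,
                            lda_prior = "equal", cv = FALSE,
                            p_enter = 0.05) {
  results <- tibble::as_tibble(results)
  traits <- tibble::as_tibble(traits)
  stopifnot("id" %in% names(results), "id" %in% names(traits))
  if (!is.null(exclude)) {
    missing_ids <- setdiff(exclude, c(results$id, traits$id))
    if (length(missing_ids) > 0) {
      stop("excluded ids not present: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    results <- dplyr::filter(results, !.data$id %in% exclude)
  }
  unmatched <- setdiff(results$id, traits$id)
  if (length(unmatched) > 0) {
    stop("no trait record for: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  dat <- dplyr::inner_join(results, traits, by = "id",
                           suffix = c("", ".trait"))
  d <- gower_distance(dat)
  pc <- pcoa_traits(d, n_axes = n_axes)
  got <- ncol(pc$coordinates) - 1
  if (got < n_axes) {
    warning(sprintf("only %d positive principal coordinates available", got),
            call. = FALSE)
  }
  dat <- dplyr::left_join(dat, pc$coordinates, by = "id")
  dat$simpson_multi <- dat$beta_sim
  predictors <- c("n_sites", "fill", "simpson_multi",
                  paste0("PCoA", seq_len(got)), "basin_area", "latitude")
  out <- list(
    data = dat,
    pcoa = pc,
    glm_coherence = gaussian_glm(dat, "z_coherence", predictors),
    glm_turnover = gaussian_glm(dat, "z_turnover", predictors),
    glm_clumping = gaussian_glm(dat, "morisita", predictors),
    vif = vif_table(dat, predictors),
    lda_full = lda_classify(dat, predictors, "mtype", prior = lda_prior,
                            cv = cv),
    wilks_selection = greedy_wilks(dat, predictors, "mtype",
                                   p_enter = p_enter),
    manova = manova_wilks(dat, predictors, "mtype"),
    predictors = predictors, exclude = exclude
  )
  if (nrow(out$wilks_selection) > 0) {
    out$lda_reduced <- lda_classify(dat, out$wilks_selection$term, "mtype",
                                    prior = lda_prior, cv = cv)
  }
  if ("taxon" %in% names(dat)) {
    tab <- table(dat$taxon, dat$mtype)
    out$taxon_type_table <- tab
    out$taxon_type_test <- contingency_chi2_perm(tab, n_perm = n_perm,
                                                 seed = seed)
    out$kruskal_by_taxon <- purrr::map_dfr(
      c("z_coherence", "z_turnover", "morisita"),
      function(v) dplyr::mutate(
        univariate_assoc(dat[[v]], dat$taxon, "kruskal_wallis"),
        response = v, .before = 1))
  }
  class(out) <- "ems_comparative"
  out
}

#' @export
print.ems_comparative <- function(x, ...) {
  cat(sprintf("<ems_comparative> %d metacommunities, %d predictors\n",
              nrow(x$data), length(x$predictors)))
  cat(sprintf("  DFA (full): %.1f%% correct; MANOVA Wilks = %.3f, F = %.3f, p = %.4f\n",
              x$lda_full$total_correct, x$manova$wilks, x$manova$statistic,
              x$manova$p_value))
  if (nrow(x$wilks_selection) > 0) {
    cat("  greedy Wilks selection:",
        paste(x$wilks_selection$term, collapse = ", "), "\n")
  } else {
    cat("  greedy Wilks selection: (none admitted)\n")
  }
  if (!is.null(x$taxon_type_test)) {
    cat(sprintf("  taxon x type: chi2 = %.2f, permutation p = %.3f\n",
                x$taxon_type_test$chi2, x$taxon_type_test$p_perm))
  }
  invisible(x)
}

#' Write batch results as one CSV row per metacommunity
#'
#' @param results An `ems_batch` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_csv(tibble::as_tibble(results), path)
  invisible(path)
}
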