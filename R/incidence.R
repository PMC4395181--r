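#' Construct a binary site-by-species incidence matrix
#'
#' The raw unit of analysis: a binary matrix with sites as rows and species
#' as columns, carrying unique site and species identifiers. All analysis
#' functions in the package operate on this class.
#'
#' @param x A numeric or integer matrix (or object coercible to one) with
#'   values in `{0, 1}`. Row and column names are used as site and species
#'   identifiers when present.
#' @param site_ids,species_ids Optional character vectors overriding the
#'   dimnames of `x`. Defaults are taken from `rownames(x)`/`colnames(x)`,
#'   or generated (`site_1`, ..., `sp_1`, ...) when absent.
#' @param coerce If `TRUE`, positive abundances are coerced to 1. If `FALSE`
#'   (default), any cell outside `{0, 1}` is an error.
#'
#' @return An `incidence_matrix`: an integer matrix with dimnames and class
#'   attribute.
#' @examples
#' m <- incidence_matrix(matrix(c(1, 0, 1, 1, 1, 0), nrow = 3))
#' dim(m)
#' @export
incidence_matrix <- function(x, site_ids = NULL, species_ids = NULL,
                             coerce = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    stop("incidence matrix cells must be numeric 0/1 values", call. = FALSE)
  }
  if (anyNA(x)) stop("incidence matrix contains missing cells", call. = FALSE)
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad) > 0) {
    if (coerce) {
      if (any(x < 0)) stop("negative abundances cannot be coerced to presence",
                           call. = FALSE)
      x <- (x > 0) + 0L
    } else {
      ij <- arrayInd(bad[1], dim(x))
      stop(sprintf(
        "non-binary cell %s at row %d, column %d (use coerce = TRUE for abundances)",
        format(x[bad[1]]), ij[1], ij[2]), call. = FALSE)
    }
  }
  storage.mode(x) <- "integer"
  site_ids <- site_ids %||% rownames(x) %||% paste0("site_", seq_len(nrow(x)))
  species_ids <- species_ids %||% colnames(x) %||% paste0("sp_", seq_len(ncol(x)))
  if (length(site_ids) != nrow(x) || length(species_ids) != ncol(x)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(site_ids)) {
    stop("duplicated site identifiers: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(species_ids)) {
    stop("duplicated species identifiers: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(x) <- list(as.character(site_ids), as.character(species_ids))
  class(x) <- c("incidence_matrix", "matrix", "array")
  x
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d sites x %d species, fill %.3f\n",
              nrow(x), ncol(x), matrix_fill(x)))
  y <- unclass(x)
  print(y[seq_len(min(10, nrow(y))), seq_len(min(10, ncol(y))), drop = FALSE])
  if (nrow(x) > 10 || ncol(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
`[.incidence_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("incidence_matrix", "matrix", "array")
  out
}

#' Proportion of presences in an incidence matrix
#'
#' @param m An incidence matrix (or plain binary matrix).
#' @return Matrix fill, the proportion of 1s.
#' @export
matrix_fill <- function(m) {
  sum(m) / length(m)
}

#' Read an incidence matrix from delimited text
#'
#' Expects one header row of species identifiers and one leading column of
#' site identifiers; all remaining cells must parse as 0/1 (or positive
#' abundances with `coerce = TRUE`).
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` is comma, anything else is tab).
#' @param coerce Coerce positive abundances to presence.
#' @return An [incidence_matrix()].
#' @export
read_incidence <- function(path, delim = NULL, coerce = FALSE) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2) stop("expected a site-identifier column plus species columns",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  cells <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(cells)) {
    j <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("column '%s' does not parse as numeric", names(df)[j + 1]),
         call. = FALSE)
  }
  incidence_matrix(cells, site_ids = ids, species_ids = colnames(cells),
                   coerce = coerce)
}

#' Write an incidence matrix as delimited text
#'
#' @param m An incidence matrix.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(m, path, delim = ",") {
  df <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "site")
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Clean an incidence matrix for EMS analysis
#'
#' Removes all-zero rows (empty sites) and all-zero columns (unobserved
#' species), which carry no ordination information. Fewer than 15 remaining
#' sites triggers a warning, mirroring the dataset-selection rule of
#' comparative EMS studies; fewer than 3 sites or 3 species is an error
#' because the ordination degenerates.
#'
#' @param m An [incidence_matrix()].
#' @return The cleaned incidence matrix.
#' @export
validate_for_ems <- function(m) {
  m <- as_incidence(m)
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 3 || ncol(m) < 3) {
    stop(sprintf(
      "matrix degenerate after removing empty margins (%d sites x %d species); need >= 3 of each",
      nrow(m), ncol(m)), call. = FALSE)
  }
  if (nrow(m) < 15) {
    warning(sprintf("fewer than 15 sites (%d); metacommunity-type inference may be unreliable",
                    nrow(m)), call. = FALSE)
  }
  m
}

# Internal: accept plain binary matrices anywhere an incidence_matrix is
# expected.
as_incidence <- function(m) {
  if (inherits(m, "incidence_matrix")) return(m)
  incidence_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
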