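#' One draw from the fixed-proportional ("r1") null model
#'
#' Row sums (site richness) are preserved exactly; within each row the
#' occupied columns are drawn without replacement with selection weights
#' proportional to the source matrix's species occurrence frequencies
#' (column sums). Sampling is sequential with renormalization, i.e. the
#' semantics of [base::sample()] with a `prob` argument.
#'
#' @param m A validated [incidence_matrix()].
#' @param seed Optional integer seed (uses the current RNG state when `NULL`).
#' @return An incidence matrix with the same dimensions and row sums as `m`.
#' @export
r1_matrix <- function(m, seed = NULL) {
  m <- as_incidence(m)
  if (!is.null(seed)) set.seed(seed)
  w <- colSums(m)
  out <- r1_draw(unclass(m), w)
  dimnames(out) <- dimnames(m)
  class(out) <- class(m)
  out
}

# Internal unwrapped draw used inside ensembles.
r1_draw <- function(m, w) {
  nc <- ncol(m)
  rs <- rowSums(m)
  out <- matrix(0L, nrow(m), nc)
  for (i in seq_len(nrow(m))) {
    k <- rs[i]
    if (k == nc) {
      out[i, ] <- 1L
    } else if (k > 0) {
      out[i, sample.int(nc, k, replace = FALSE, prob = w)] <- 1L
    }
  }
  out
}

#' One draw from the fixed-fixed ("quasiswap") null model
#'
#' Both row and column sums are preserved exactly. The draw is produced by
#' (a) constructing an independent matrix with the source margins by the
#' Gale-Ryser greedy construction and (b) running a 2x2 checkerboard swap
#' chain, whose stationary distribution is uniform over the margin class,
#' for `burnin` attempted updates (candidate 2x2 submatrices, swapped when
#' they form a checkerboard).
#'
#' @param m A validated [incidence_matrix()].
#' @param seed Optional integer seed.
#' @param burnin Attempted swap updates before the matrix is returned;
#'   default `100 * sum(m)`.
#' @return An incidence matrix with both margins equal to those of `m`.
#' @export
quasiswap_matrix <- function(m, seed = NULL, burnin = NULL) {
  m <- as_incidence(m)
  if (!is.null(seed)) set.seed(seed)
  burnin <- burnin %||% (100 * sum(m))
  start <- gale_ryser_fill(rowSums(m), colSums(m))
  out <- cpp_swap_chain(start, burnin)
  dimnames(out) <- dimnames(m)
  class(out) <- class(m)
  out
}

# Gale-Ryser greedy construction of a binary matrix with the given margins.
# Rows are processed in decreasing row-sum order; each row's presences go to
# the columns with the largest remaining demand (ties by column index).
# Always succeeds when the margins are realizable, in particular when they
# come from an observed binary matrix.
gale_ryser_fill <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs)
  out <- matrix(0L, nr, nc)
  demand <- as.numeric(cs)
  for (i in order(rs, decreasing = TRUE)) {
    k <- rs[i]
    if (k == 0) next
    pick <- order(demand, decreasing = TRUE)[seq_len(k)]
    out[i, pick] <- 1L
    demand[pick] <- demand[pick] - 1
  }
  if (any(demand != 0)) stop("margins are not realizable", call. = FALSE)
  out
}

#' Build a null ensemble of randomized incidence matrices
#'
#' For `model = "r1"` the replicates are independent draws with per-replicate
#' RNG substreams derived from `seed` by counter, so individual members are
#' reproducible in isolation. For `model = "quasiswap"` the replicates are
#' successive states of one swap chain separated by `thin` attempted swap
#' updates after a burn-in of `100 * sum(m)` attempted updates.
#'
#' @param m A validated [incidence_matrix()].
#' @param model `"r1"` or `"quasiswap"`.
#' @param n_sim Number of replicates; at least 19 (999 is the conventional
#'   choice, 99 a fallback for very large matrices).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param thin Attempted swap updates between successive quasiswap samples;
#'   default `10 * sum(m)`.
#' @param burnin Attempted swap updates before the first quasiswap sample;
#'   default `100 * sum(m)`.
#' @return A `null_ensemble`: list with `matrices` (list of plain integer
#'   matrices), `model`, `n_sim`, `seed`, `thin`.
#' @export
build_ensemble <- function(m, model = c("r1", "quasiswap"), n_sim = 999,
                           seed, thin = NULL, burnin = NULL) {
  model <- match.arg(model)
  m <- as_incidence(m)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_sim < 19) {
    stop("n_sim must be at least 19 for a meaningful permutation test",
         call. = FALSE)
  }
  src <- unclass(m)
  mats <- vector("list", n_sim)
  if (model == "r1") {
    w <- colSums(src)
    for (k in seq_len(n_sim)) {
      set.seed(substream_seed(seed, k))
      mats[[k]] <- r1_draw(src, w)
    }
  } else {
    thin <- thin %||% (10 * sum(src))
    burnin <- burnin %||% (100 * sum(src))
    set.seed(substream_seed(seed, 0L))
    state <- gale_ryser_fill(rowSums(src), colSums(src))
    state <- cpp_swap_chain(state, burnin)
    for (k in seq_len(n_sim)) {
      state <- cpp_swap_chain(state, thin)
      mats[[k]] <- state
    }
  }
  structure(list(matrices = mats, model = model, n_sim = n_sim, seed = seed,
                 thin = if (model == "quasiswap") thin else NA_integer_,
                 dim = dim(src)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s, %d matrices of %d x %d (seed %d)\n",
              x$model, x$n_sim, x$dim[1], x$dim[2], x$seed))
  invisible(x)
}

# Deterministic 32-bit substream seed from a master seed and a counter, so
# parallel or partial evaluation reproduces individual replicates.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}

# Deterministic per-dataset seed from a master seed and a dataset id, so
# adding a dataset to a batch never changes the others' results.
dataset_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}
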