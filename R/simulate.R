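#' Simulate an incidence matrix with a canonical metacommunity structure
#'
#' Generates a binary site-by-species matrix whose species ranges follow one
#' of the six idealized structures along a latent gradient given by the site
#' index, optionally degraded by independent cell-flip noise. At `noise = 0`
#' each structure satisfies its defining property exactly:
#'
#' * `nested` - ranges all share the first site as a common endpoint, with
#'   lengths spread to hit the target fill, so every species-poor site holds
#'   a subset of every richer site.
#' * `clementsian` - species are partitioned into blocks; all species in a
#'   block share an identical contiguous range, and block ranges tile the
#'   gradient.
#' * `gleasonian` - contiguous ranges with independently placed random
#'   endpoints: one endpoint is uniform over sites and the other is the
#'   first endpoint plus a random-direction offset reflected at the gradient
#'   edges, which keeps each boundary's marginal distribution exactly
#'   uniform while offset lengths control fill.
#' * `evenly_spaced` - contiguous equal-length ranges with boundaries on a
#'   deterministic regular lattice (hyperdispersed boundaries).
#' * `checkerboard` - species come in mutually exclusive pairs occupying
#'   complementary halves of a shared random site set.
#' * `random` - independent Bernoulli(fill) cells.
#'
#' @param structure One of `"nested"`, `"clementsian"`, `"gleasonian"`,
#'   `"evenly_spaced"`, `"checkerboard"`, `"random"`.
#' @param n_sites Number of sites (local communities); at least 15 mirrors
#'   the dataset-selection convention, smaller values are allowed for toy
#'   examples.
#' @param n_species Number of species.
#' @param fill Target matrix fill (proportion of presences), in (0, 1);
#'   structures constrain the feasible range and error outside it.
#' @param noise Independent cell-flip probability in \[0, 0.5).
#' @param seed Optional integer seed.
#' @param n_blocks Number of Clementsian blocks; default `round(1 / fill)`.
#' @return An [incidence_matrix()] with attributes `structure` and
#'   `generator_params`.
#' @examples
#' m <- simulate_metacommunity("nested", 20, 40, fill = 0.25, seed = 1)
#' matrix_fill(m)
#' @export
simulate_metacommunity <- function(structure = c("nested", "clementsian",
                                                 "gleasonian", "evenly_spaced",
                                                 "checkerboard", "random"),
                                   n_sites = 30, n_species = 60, fill = 0.25,
                                   noise = 0, seed = NULL, n_blocks = NULL) {
  structure <- match.arg(structure)
  stopifnot(n_sites >= 3, n_species >= 2)
  if (fill <= 0 || fill >= 1) stop("fill must be in (0, 1)", call. = FALSE)
  if (noise < 0 || noise >= 0.5) stop("noise must be in [0, 0.5)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  S <- n_sites; P <- n_species
  m <- switch(structure,
    nested = gen_nested(S, P, fill),
    clementsian = gen_clementsian(S, P, fill, n_blocks),
    gleasonian = gen_gleasonian(S, P, fill),
    evenly_spaced = gen_evenly_spaced(S, P, fill),
    checkerboard = gen_checkerboard(S, P, fill),
    random = matrix(rbinom(S * P, 1, fill), S, P)
  )
  if (noise > 0) {
    flip <- matrix(runif(S * P) < noise, S, P)
    m <- abs(m - flip)
  }
  out <- incidence_matrix(m,
                          site_ids = sprintf("site_%02d", seq_len(S)),
                          species_ids = sprintf("sp_%03d", seq_len(P)))
  attr(out, "structure") <- structure
  attr(out, "generator_params") <- list(n_sites = S, n_species = P,
                                        fill = fill, noise = noise,
                                        seed = seed)
  out
}

# Lengths spread evenly over 1..Lmax (so the realized fill is tight around
# the target), randomly assigned to species.
spread_lengths <- function(P, Lmin, Lmax) {
  sample(round(seq(Lmin, Lmax, length.out = P)))
}

gen_nested <- function(S, P, fill) {
  if (fill <= 1 / S) {
    stop(sprintf("infeasible fill %.3f for nested structure; must exceed %.3f",
                 fill, 1 / S), call. = FALSE)
  }
  # Range lengths as quantiles of a power-law on 1..S with mean ~ fill * S,
  # so the subset chain spans the whole gradient (no empty sites) while the
  # realized fill stays tight around the target.
  a <- max(1 / fill - 1, 1e-6)
  lens <- pmax(1, round(S * ((seq_len(P) - 0.5) / P)^a))
  lens[P] <- S
  lens <- sample(lens)
  m <- matrix(0L, S, P)
  for (j in seq_len(P)) m[seq_len(lens[j]), j] <- 1L
  m
}

gen_clementsian <- function(S, P, fill, n_blocks = NULL) {
  len <- round(fill * S)
  if (len < 1 || len > S) {
    stop(sprintf("infeasible fill %.3f for clementsian structure; feasible range (%.3f, 1)",
                 fill, 1 / (2 * S)), call. = FALSE)
  }
  # enough blocks that the block ranges tile the gradient without gaps
  B <- n_blocks %||% max(2, ceiling(S / len))
  starts <- round(seq(1, S - len + 1, length.out = B))
  block_of <- sample(rep_len(seq_len(B), P))
  m <- matrix(0L, S, P)
  for (j in seq_len(P)) {
    s <- starts[block_of[j]]
    m[s:(s + len - 1), j] <- 1L
  }
  m
}

# Expected range length for each endpoint offset under the edge-reflected
# placement, averaged over the uniform first endpoint and both directions.
reflected_length_table <- function(S) {
  vapply(0:(S - 1), function(off) {
    lens <- vapply(seq_len(S), function(a) {
      up <- a + off; dn <- a - off
      up <- if (up > S) 2 * S + 1 - up else up
      dn <- if (dn < 1) 1 - dn + 1 else dn
      (abs(up - a) + abs(dn - a)) / 2 + 1
    }, numeric(1))
    mean(lens)
  }, numeric(1))
}

gen_gleasonian <- function(S, P, fill) {
  target <- fill * S
  elen <- reflected_length_table(S)   # elen[off + 1]
  # pick the largest offset whose stratified 1..offmax mix matches the target
  cand <- 1:(S - 1)
  err <- vapply(cand, function(omax) {
    offs <- round(seq(1, omax, length.out = P))
    abs(mean(elen[offs + 1]) - target)
  }, numeric(1))
  offmax <- cand[which.min(err)]
  if (min(err) > 0.1 * S) {
    stop(sprintf("infeasible fill %.3f for gleasonian structure on %d sites",
                 fill, S), call. = FALSE)
  }
  offs <- sample(round(seq(1, offmax, length.out = P)))
  m <- matrix(0L, S, P)
  for (j in seq_len(P)) {
    a <- sample.int(S, 1)
    b0 <- a + sample(c(-1, 1), 1) * offs[j]
    b <- if (b0 > S) 2 * S + 1 - b0 else if (b0 < 1) 1 - b0 + 1 else b0
    m[min(a, b):max(a, b), j] <- 1L
  }
  m
}

gen_evenly_spaced <- function(S, P, fill) {
  len <- round(fill * S)
  if (len < 1 || len > S) {
    stop(sprintf("infeasible fill %.3f for evenly spaced structure", fill),
         call. = FALSE)
  }
  starts <- round(seq(1, S - len + 1, length.out = P))
  m <- matrix(0L, S, P)
  for (j in seq_len(P)) m[starts[j]:(starts[j] + len - 1), j] <- 1L
  m
}

gen_checkerboard <- function(S, P, fill) {
  k <- round(fill * S)
  if (k < 1 || 2 * k > S) {
    stop(sprintf("infeasible fill %.3f for checkerboard structure; feasible range (%.3f, %.3f)",
                 fill, 1 / (2 * S), floor(S / 2) / S), call. = FALSE)
  }
  m <- matrix(0L, S, P)
  for (j in seq(1, P - 1, by = 2)) {
    pool <- sample.int(S, 2 * k)
    m[pool[seq_len(k)], j] <- 1L
    m[pool[(k + 1):(2 * k)], j + 1] <- 1L
  }
  if (P %% 2 == 1) m[sample.int(S, k), P] <- 1L
  m
}

#' Simulate a metacommunity trait table
#'
#' Generates per-metacommunity ecological descriptors with the statistical
#' shape of comparative freshwater metacommunity data: one continuous trait
#' (body size, log-uniform across nine orders of magnitude) and four
#' categorical traits, dataset characteristics (number of sites, matrix
#' fill), a multiple-site Simpson index, a log-uniform drainage basin area,
#' a boreal latitude range, and a taxonomic group label. Optional
#' group-dependent mean shifts on numeric columns plant a signal for testing
#' discriminant-analysis and MANOVA power.
#'
#' @param n Number of metacommunities (at least 12).
#' @param seed Optional integer seed.
#' @param groups Number of true groups (labels `group_1..k`), or a character
#'   vector of labels recycled over rows. `NULL` for no grouping (a single
#'   group).
#' @param shifts Named list: numeric column -> length-k vector of additive
#'   group means, e.g. `list(simpson_multi = c(-0.1, 0.1))`.
#' @return A tibble with columns `id`, `taxon`, `body_size`,
#'   `trophic_group`, `ecosystem`, `life_form`, `dispersal`, `n_sites`,
#'   `matrix_fill`, `simpson_multi`, `basin_area`, `latitude`, `group`.
#' @export
simulate_trait_table <- function(n, seed = NULL, groups = NULL,
                                 shifts = NULL) {
  if (n < 12) stop("need at least 12 metacommunities", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  group <- if (is.null(groups)) {
    rep("group_1", n)
  } else if (is.numeric(groups)) {
    sort(rep_len(paste0("group_", seq_len(groups)), n))
  } else {
    sort(rep_len(as.character(groups), n))
  }
  tab <- tibble::tibble(
    id = sprintf("mc_%02d", seq_len(n)),
    taxon = sample(c("algae", "bacteria", "invertebrates", "macrophytes",
                     "vertebrates"), n, replace = TRUE),
    body_size = 10^runif(n, -6, 3),
    trophic_group = sample(c("decomposer", "producer", "omnivore", "predator"),
                           n, replace = TRUE),
    ecosystem = sample(c("lentic", "lotic"), n, replace = TRUE),
    life_form = sample(c("rooted", "benthic", "pelagic"), n, replace = TRUE),
    dispersal = sample(c("passive", "active"), n, replace = TRUE),
    n_sites = sample(15:60, n, replace = TRUE),
    matrix_fill = runif(n, 0.15, 0.35),
    simpson_multi = runif(n, 0.6, 0.95),
    basin_area = 10^runif(n, 2, 5),
    latitude = runif(n, 59, 70),
    group = group
  )
  if (!is.null(shifts)) {
    k <- length(unique(group))
    for (col in names(shifts)) {
      if (!col %in% names(tab) || !is.numeric(tab[[col]])) {
        stop("shifts must name numeric trait columns", call. = FALSE)
      }
      delta <- rep_len(shifts[[col]], k)
      tab[[col]] <- tab[[col]] + delta[match(group, sort(unique(group)))]
    }
  }
  tab
}
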