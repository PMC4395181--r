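# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (literal scans, exhaustive enumeration)
# rather than sharing any code path with the package.

# Embedded absences: literal scan of every column and row range.
oracle_abs <- function(m, species_only = FALSE) {
  gaps <- 0
  for (j in seq_len(ncol(m))) {
    idx <- which(m[, j] == 1)
    if (length(idx) > 0) {
      gaps <- gaps + sum(m[min(idx):max(idx), j] == 0)
    }
  }
  if (!species_only) {
    for (i in seq_len(nrow(m))) {
      idx <- which(m[i, ] == 1)
      if (length(idx) > 0) {
        gaps <- gaps + sum(m[i, min(idx):max(idx)] == 0)
      }
    }
  }
  gaps
}

# Literal per-column range fill.
oracle_fill <- function(m) {
  for (j in seq_len(ncol(m))) {
    idx <- which(m[, j] == 1)
    if (length(idx) > 0) m[min(idx):max(idx), j] <- 1
  }
  m
}

# Replacements: literal enumeration of all site-pair x species-pair
# configurations on the (filled) matrix.
oracle_rep <- function(m, fill = TRUE) {
  if (fill) m <- oracle_fill(m)
  count <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr - 1)) for (k in (i + 1):nr) {
    for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
      ab <- (m[i, a] == 1 && m[k, a] == 0 && m[i, b] == 0 && m[k, b] == 1)
      ba <- (m[i, a] == 0 && m[k, a] == 1 && m[i, b] == 1 && m[k, b] == 0)
      if (ab || ba) count <- count + 1
    }
  }
  count
}

# First correspondence axis by direct SVD of the standardized residuals.
oracle_ca_scores <- function(m) {
  n <- sum(m)
  P <- m / n
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  list(site = sv$u[, 1] / sqrt(r), species = sv$v[, 1] / sqrt(cc),
       eig = sv$d[1]^2)
}

# Probability of each k-subset under sequential weighted sampling without
# replacement (summing ordered-draw probabilities over all orderings).
oracle_subset_probs <- function(w, k) {
  n <- length(w)
  subsets <- utils::combn(n, k)
  perm_all <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perm_all(v[-i]))
    }))
  }
  probs <- apply(subsets, 2, function(s) {
    perms <- perm_all(s)
    sum(apply(perms, 1, function(p) {
      rem <- sum(w)
      pr <- 1
      for (j in p) {
        pr <- pr * w[j] / rem
        rem <- rem - w[j]
      }
      pr
    }))
  })
  list(subsets = subsets, probs = probs)
}

# Per-column inclusion probabilities implied by oracle_subset_probs.
oracle_inclusion_probs <- function(w, k) {
  o <- oracle_subset_probs(w, k)
  vapply(seq_along(w), function(j) {
    sum(o$probs[apply(o$subsets, 2, function(s) j %in% s)])
  }, numeric(1))
}

# Exhaustive enumeration of binary matrices with the given margins.
# Returns a character vector of matrix keys (row-major 0/1 strings).
oracle_margin_class <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs)
  out <- character(0)
  row_options <- function(k) {
    if (k == 0) return(matrix(0L, 1, nc))
    ch <- utils::combn(nc, k)
    t(apply(ch, 2, function(idx) { v <- integer(nc); v[idx] <- 1L; v }))
  }
  recurse <- function(i, rem_cs, acc) {
    if (i > nr) {
      if (all(rem_cs == 0)) out[[length(out) + 1]] <<- paste(acc, collapse = "")
      return(invisible())
    }
    opts <- row_options(rs[i])
    for (r in seq_len(nrow(opts))) {
      v <- opts[r, ]
      new_cs <- rem_cs - v
      if (any(new_cs < 0)) next
      if (any(new_cs > nr - i)) next
      recurse(i + 1, new_cs, c(acc, v))
    }
  }
  recurse(1, cs, integer(0))
  out
}

mat_key <- function(m) paste(t(m), collapse = "")

# Random binary matrix with no empty rows or columns.
rand_incidence <- function(nr, nc, p = 0.4) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Closed-form pairwise dissimilarities for a two-site matrix.
oracle_pairwise_sor_sim <- function(m) {
  a <- sum(m[1, ] == 1 & m[2, ] == 1)
  b <- sum(m[1, ] == 1 & m[2, ] == 0)
  c <- sum(m[1, ] == 0 & m[2, ] == 1)
  list(sor = if (2 * a + b + c == 0) 0 else (b + c) / (2 * a + b + c),
       sim = if (a + min(b, c) == 0) 0 else min(b, c) / (a + min(b, c)))
}
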