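test_that("embedded absences match the literal gap-count oracle", {
  # hand case: column pattern 1,0,0,1 carries two column gaps
  m <- matrix(0L, 4, 3)
  m[, 1] <- c(1L, 0L, 0L, 1L)
  m[, 2] <- 1L
  m[c(1, 2), 3] <- 1L
  expect_equal(embedded_absences(m, scope = "species_only"), 2)
  expect_equal(embedded_absences(m), oracle_abs(m))

  # perfectly banded matrix has no gaps by construction
  band <- unclass(simulate_metacommunity("evenly_spaced", 15, 20,
                                         fill = 0.3, seed = 1))
  expect_equal(embedded_absences(band, scope = "species_only"), 0)

  set.seed(8)
  for (k in 1:100) {
    mm <- matrix(rbinom(80, 1, runif(1, 0.2, 0.7)), 8, 10)
    expect_equal(embedded_absences(mm), oracle_abs(mm))
    expect_equal(embedded_absences(mm, scope = "species_only"),
                 oracle_abs(mm, species_only = TRUE))
  }
})

test_that("range filling is idempotent and removes exactly the column gaps", {
  col <- matrix(c(1L, 0L, 1L), 3, 1)
  expect_equal(as.vector(unclass(fill_ranges(col))), c(1L, 1L, 1L))
  set.seed(9)
  for (k in 1:50) {
    mm <- matrix(rbinom(60, 1, 0.4), 6, 10)
    f1 <- fill_ranges(mm)
    expect_equal(unclass(fill_ranges(f1)), unclass(f1))
    expect_equal(unclass(f1), oracle_fill(mm))
    expect_equal(embedded_absences(f1, scope = "species_only"), 0)
  }
})

test_that("replacements match the quadruple-loop oracle and the limit cases", {
  cb <- matrix(c(1L, 0L, 0L, 1L), 2, 2)      # A at site 1, B at site 2
  expect_equal(replacements(cb), 1)

  nested <- unclass(simulate_metacommunity("nested", 12, 15, fill = 0.3,
                                           seed = 2))
  nested <- nested[order(rowSums(nested), decreasing = TRUE), ]
  expect_equal(replacements(nested), 0)

  set.seed(10)
  for (k in 1:60) {
    mm <- matrix(rbinom(63, 1, runif(1, 0.25, 0.6)), 7, 9)
    expect_equal(replacements(mm), oracle_rep(mm))
    expect_equal(replacements(mm, fill = FALSE), oracle_rep(mm, fill = FALSE))
  }
})

test_that("Morisita boundary clumping detects the canonical patterns", {
  # all species share one range: maximal clumping
  m <- matrix(0L, 10, 8)
  m[3:6, ] <- 1L
  bc <- boundary_clumping(m)
  expect_gt(bc$morisita_index, 1)
  expect_lt(bc$p_clumping, 0.05)

  # boundaries spread as evenly as possible: index at most 1
  me <- matrix(0L, 10, 5)
  for (j in 1:5) me[(2 * j - 1):(2 * j), j] <- 1L
  expect_lte(boundary_clumping(me)$morisita_index, 1)

  # single-site species contribute both boundaries at that site
  ms <- matrix(0L, 6, 3)
  ms[2, 1] <- 1L; ms[2, 2] <- 1L; ms[5, 3] <- 1L
  expect_equal(boundary_clumping(ms)$n_boundaries, 6)

  expect_error(boundary_clumping(matrix(0L, 4, 2)), "occupied")
})

test_that("generated Gleasonian boundaries are Morisita-neutral on average", {
  # oracle: Monte-Carlo expectation of I under uniform boundary placement
  set.seed(3)
  n_rep <- 300
  oracle_I <- replicate(n_rep, {
    f <- tabulate(sample.int(30, 120, replace = TRUE), 30)
    30 * sum(f * (f - 1)) / (120 * 119)
  })
  gen_I <- vapply(seq_len(n_rep), function(k) {
    m <- simulate_metacommunity("gleasonian", 30, 60, fill = 0.25, seed = k)
    boundary_clumping(m)$morisita_index   # true gradient order
  }, numeric(1))
  sem <- sqrt(var(oracle_I) / n_rep + var(gen_I) / n_rep)
  expect_lt(abs(mean(gen_I) - mean(oracle_I)), 4 * sem)
})

test_that("permutation test follows the add-one two-tailed contract", {
  same <- perm_test(5, rep(5, 999))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  below <- perm_test(0, seq_len(999))
  expect_equal(below$p, 2 / 1000)
  expect_lt(below$z, 0)

  mid <- perm_test(500, seq_len(999))
  expect_equal(mid$p, 1)
})

test_that("|z| > 1.96 and permutation p < 0.05 agree on gaussian nulls", {
  # scaled-down screen; 1000 trials in the acceptance suite
  set.seed(21)
  agree <- vapply(1:200, function(i) {
    sims <- rnorm(999)
    obs <- rnorm(1)
    t <- perm_test(obs, sims)
    (abs(t$z) > 1.96) == (t$p < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("the decision tree covers the full truth table", {
  coh <- function(dir, sig) list(p = if (sig) 0.01 else 0.4,
                                 observed = if (dir == "more") 120 else 80,
                                 null_mean = 100)
  turn <- function(dir, sig) list(p = if (sig) 0.01 else 0.4,
                                  observed = if (dir == "more") 60 else 40,
                                  null_mean = 50)
  clump <- function(dir) list(
    morisita_index = switch(dir, over = 3, under = 0.3, none = 1.05),
    p_clumping = if (dir == "none") 0.6 else 0.01)

  # nonsignificant coherence is always random
  for (td in c("more", "less")) for (cd in c("over", "under", "none")) {
    expect_equal(classify_metacommunity(coh("less", FALSE), turn(td, TRUE),
                                        clump(cd)), "random")
  }
  # significantly MORE embedded absences than null: checkerboard
  expect_equal(classify_metacommunity(coh("more", TRUE), turn("more", TRUE),
                                      clump("over")), "checkerboard")
  # positive coherence, significant negative turnover: nested
  expect_equal(classify_metacommunity(coh("less", TRUE), turn("less", TRUE),
                                      clump("over")), "nested")
  # positive coherence, significant positive turnover: split by clumping
  expect_equal(classify_metacommunity(coh("less", TRUE), turn("more", TRUE),
                                      clump("over")), "clementsian")
  expect_equal(classify_metacommunity(coh("less", TRUE), turn("more", TRUE),
                                      clump("under")), "evenly_spaced")
  expect_equal(classify_metacommunity(coh("less", TRUE), turn("more", TRUE),
                                      clump("none")), "gleasonian")
  # nonsignificant turnover: quasi structures
  expect_equal(classify_metacommunity(coh("less", TRUE), turn("less", FALSE),
                                      clump("over")), "quasi_nested")
  expect_equal(classify_metacommunity(coh("less", TRUE), turn("more", FALSE),
                                      clump("over")), "quasi_clementsian")
  expect_equal(classify_metacommunity(coh("less", TRUE), turn("more", FALSE),
                                      clump("under")), "quasi_evenly_spaced")
  expect_equal(classify_metacommunity(coh("less", TRUE), turn("more", FALSE),
                                      clump("none")), "quasi_gleasonian")

  expect_error(classify_metacommunity(coh("less", TRUE), turn("more", TRUE),
                                      clump("over"), alpha = 1.5), "alpha")
  expect_true(all(vapply(
    list(classify_metacommunity(coh("less", TRUE), turn("more", FALSE),
                                clump("none"))),
    function(x) x %in% metacommunity_types(), logical(1))))
})

test_that("the full analysis is deterministic and self-consistent", {
  m <- simulate_metacommunity("clementsian", 20, 40, seed = 4)
  r1 <- ems_analyze(m, n_sim = 99, seed = 11)
  r2 <- ems_analyze(m, n_sim = 99, seed = 11)
  expect_equal(glance(r1), glance(r2))
  expect_equal(r1$z_coherence,
               (r1$abs_observed - r1$abs_null_mean) / r1$abs_null_sd)
  expect_equal(r1$z_turnover,
               (r1$rep_observed - r1$rep_null_mean) / r1$rep_null_sd)
  expect_true(all(c(r1$p_coherence, r1$p_turnover, r1$p_clumping) >= 0))
  expect_true(all(c(r1$p_coherence, r1$p_turnover, r1$p_clumping) <= 1))
  expect_equal(r1$mtype, classify_metacommunity(
    list(p = r1$p_coherence, observed = r1$abs_observed,
         null_mean = r1$abs_null_mean),
    list(p = r1$p_turnover, observed = r1$rep_observed,
         null_mean = r1$rep_null_mean),
    list(morisita_index = r1$morisita_index, p_clumping = r1$p_clumping),
    alpha = r1$alpha))
  td <- tidy(r1)
  expect_equal(nrow(td), 3)
  expect_equal(td$observed[1], r1$abs_observed)
})

test_that("r1 and quasiswap Z-scores point the same way on a synthetic ensemble", {
  set.seed(30)
  zs <- t(vapply(1:10, function(k) {
    s <- c("nested", "clementsian", "gleasonian", "evenly_spaced", "random")[
      (k %% 5) + 1]
    m <- simulate_metacommunity(s, 18, 30, fill = 0.28, seed = k)
    a <- suppressWarnings(ems_analyze(m, "r1", n_sim = 49, seed = 100 + k))
    b <- suppressWarnings(ems_analyze(m, "quasiswap", n_sim = 49,
                                      seed = 100 + k))
    c(a$z_coherence, b$z_coherence, a$z_turnover, b$z_turnover)
  }, numeric(4)))
  expect_gt(cor(zs[, 1], zs[, 2]), 0)
  expect_gt(cor(zs[, 3], zs[, 4]), 0)
})
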