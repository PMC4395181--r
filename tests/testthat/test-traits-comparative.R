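toy_traits <- function() {
  tibble::tibble(
    id = paste0("m", 1:5),
    body_size = c(1, 10, 100, 1000, 10000),
    trophic_group = c("producer", "producer", "predator", "omnivore",
                      "decomposer"),
    ecosystem = c("lentic", "lotic", "lotic", "lentic", "lentic"),
    life_form = c("rooted", "benthic", "pelagic", "benthic", "rooted"),
    dispersal = c("passive", "active", "active", "passive", "passive")
  )
}

test_that("Gower distance equals the literal per-variable average", {
  tr <- toy_traits()
  d <- as.matrix(gower_distance(tr, log_body_size = FALSE))
  # independent literal evaluation
  rng <- diff(range(tr$body_size))
  for (i in 1:4) for (j in (i + 1):5) {
    contrib <- c(abs(tr$body_size[i] - tr$body_size[j]) / rng,
                 tr$trophic_group[i] != tr$trophic_group[j],
                 tr$ecosystem[i] != tr$ecosystem[j],
                 tr$life_form[i] != tr$life_form[j],
                 tr$dispersal[i] != tr$dispersal[j])
    expect_equal(d[i, j], mean(contrib), tolerance = 1e-12)
  }
  expect_true(all(diag(d) == 0))

  # identical records are at distance zero; full disagreement at distance one
  tr2 <- tr
  tr2$body_size <- c(1, 1, 1, 1, 10)  # rows 1 and 2 identical but body size
  tr2$trophic_group[2] <- tr2$trophic_group[1]
  tr2$ecosystem[2] <- tr2$ecosystem[1]
  tr2$life_form[2] <- tr2$life_form[1]
  tr2$dispersal[2] <- tr2$dispersal[1]
  d2 <- as.matrix(gower_distance(tr2, log_body_size = FALSE))
  expect_equal(d2[1, 2], 0)

  opp <- tibble::tibble(
    id = c("a", "b"), body_size = c(1, 100),
    trophic_group = c("producer", "predator"),
    ecosystem = c("lentic", "lotic"), life_form = c("rooted", "pelagic"),
    dispersal = c("passive", "active"))
  expect_equal(as.matrix(gower_distance(opp, log_body_size = FALSE))[1, 2], 1)

  # body size enters on the log10 scale by default
  dl <- as.matrix(gower_distance(tr))
  expect_equal(dl[1, 2],
               mean(c(1 / 4, 0, 1, 1, 1)), tolerance = 1e-12)
})

test_that("PCoA reconstructs Euclidean configurations and normalizes variance", {
  # points on a line: one positive eigenvalue, coordinates isometric
  x <- c(0, 1, 3, 7)
  d <- dist(x)
  pc <- pcoa_traits(d)
  expect_equal(length(pc$eigenvalues), 1)
  got <- dist(pc$coordinates$PCoA1)
  expect_equal(as.vector(got), as.vector(d), tolerance = 1e-8)

  set.seed(20)
  pts <- matrix(rnorm(30), 10, 3)
  d3 <- dist(pts)
  pc3 <- pcoa_traits(d3)
  rec <- dist(as.matrix(pc3$coordinates[, -1]))
  expect_equal(as.vector(rec), as.vector(d3), tolerance = 1e-8)
  expect_equal(sum(pc3$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pc3$eigenvalues) <= 1e-8))

  expect_error(pcoa_traits(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ordination of traits is invariant to record order up to sign", {
  tr <- simulate_trait_table(20, seed = 31)
  d1 <- gower_distance(tr)
  pc1 <- pcoa_traits(d1, n_axes = 3)
  perm <- sample(20)
  tr2 <- tr[perm, ]
  pc2 <- pcoa_traits(gower_distance(tr2), n_axes = 3)
  m1 <- as.matrix(pc1$coordinates[, -1])[perm, ]
  m2 <- as.matrix(pc2$coordinates[, -1])
  for (a in 1:3) {
    expect_equal(abs(cor(m1[, a], m2[, a])), 1, tolerance = 1e-6)
  }
})

test_that("the Gaussian GLM equals the normal-equations oracle", {
  set.seed(22)
  n <- 40
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dat$y <- 2 + 1.5 * dat$x1 - 0.7 * dat$x2
  exact <- gaussian_glm(dat, "y", c("x1", "x2", "x3"))
  expect_equal(exact$estimate, c(2, 1.5, -0.7, 0), tolerance = 1e-10,
               ignore_attr = TRUE)

  dat$y <- dat$y + rnorm(n)
  fit <- gaussian_glm(dat, "y", c("x1", "x2", "x3"))
  X <- cbind(1, as.matrix(dat[, c("x1", "x2", "x3")]))
  beta <- solve(crossprod(X), crossprod(X, dat$y))
  expect_equal(fit$estimate, as.vector(beta), tolerance = 1e-10)

  fit0 <- gaussian_glm(dat, "y", character(0))
  expect_equal(fit0$estimate, mean(dat$y))

  dat$x4 <- dat$x1
  expect_error(gaussian_glm(dat, "y", c("x1", "x2", "x3", "x4")),
               "rank-deficient")
})

test_that("VIF matches the closed form and flags collinearity", {
  set.seed(23)
  n <- 200
  x1 <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x1))                       # exactly orthogonal part
  x2 <- 0.9 * scale(x1)[, 1] + sqrt(1 - 0.81) * scale(e)[, 1]
  dat <- data.frame(x1 = scale(x1)[, 1], x2 = x2)
  r <- cor(dat$x1, dat$x2)
  v <- vif_table(dat, c("x1", "x2"))
  expect_equal(v$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-8)

  orth <- data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(vif_table(orth, c("a", "b"))$vif, c(1, 1))

  dat$x3 <- dat$x1
  expect_warning(v3 <- vif_table(dat, c("x1", "x2", "x3")), "collinear")
  expect_true(any(is.infinite(v3$vif)))

  skip_if_not_installed("car")
  set.seed(24)
  big <- as.data.frame(matrix(rnorm(300), 60, 5))
  big$y <- rnorm(60)
  ours <- vif_table(big, paste0("V", 1:5))$vif
  theirs <- car::vif(lm(y ~ ., data = big))
  expect_equal(ours, unname(theirs), tolerance = 1e-10)
})

test_that("LDA separates separable groups and respects its rank bound", {
  set.seed(25)
  n <- 30
  dat <- data.frame(
    x = c(rnorm(n), rnorm(n) + 10, rnorm(n) - 10),
    y = c(rnorm(n), rnorm(n) + 10, rnorm(n) + 10),
    g = rep(c("a", "b", "c"), each = n))
  fit <- lda_classify(dat, c("x", "y"), "g")
  expect_equal(fit$total_correct, 100)
  expect_lte(fit$n_axes, 2)
  expect_equal(unname(rowSums(fit$confusion)), rep(n, 3))
  expect_equal(glance(fit)$total_correct, 100)

  # indistinguishable groups classify near chance with equal priors
  set.seed(26)
  rates <- vapply(1:20, function(k) {
    d0 <- data.frame(x = rnorm(60), y = rnorm(60),
                     g = rep(c("a", "b", "c"), each = 20))
    lda_classify(d0, c("x", "y"), "g")$total_correct
  }, numeric(1))
  expect_lt(abs(mean(rates) - 100 / 3), 12)

  dat1 <- dat; dat1$g[1] <- "solo"; dat1 <- dat1[c(1, 31:90), ]
  expect_warning(lda_classify(dat1, c("x", "y"), "g"), "single member")
})

test_that("greedy Wilks selection matches a per-step exhaustive oracle", {
  set.seed(27)
  n <- 60
  g <- rep(c("a", "b", "c"), each = n / 3)
  dat <- data.frame(
    x1 = rnorm(n) + 3 * (g == "b") - 3 * (g == "c"),
    x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n) + (g == "b"), g = g)
  sel <- greedy_wilks(dat, paste0("x", 1:4), "g")
  expect_gt(nrow(sel), 0)
  expect_equal(sel$term[1], "x1")

  # oracle: at each step pick the minimal Wilks lambda via stats::manova
  oracle_lambda <- function(vars) {
    if (length(vars) == 1) {
      a <- anova(lm(dat[[vars]] ~ g))
      a[2, "Sum Sq"] / sum(a[, "Sum Sq"])
    } else {
      summary(manova(as.matrix(dat[vars]) ~ g), test = "Wilks")$stats[1, "Wilks"]
    }
  }
  chosen <- character(0)
  for (s in seq_len(nrow(sel))) {
    cand <- setdiff(paste0("x", 1:4), chosen)
    lams <- vapply(cand, function(v) oracle_lambda(c(chosen, v)), numeric(1))
    expect_equal(sel$term[s], cand[which.min(lams)])
    expect_equal(sel$wilks[s], min(lams), tolerance = 1e-10)
    chosen <- c(chosen, sel$term[s])
  }

  # planted single informative predictor is found first in most seeds
  hits <- vapply(1:20, function(k) {
    set.seed(300 + k)
    d <- data.frame(x1 = rnorm(45), x2 = rnorm(45), x3 = rnorm(45),
                    g = rep(c("a", "b", "c"), each = 15))
    d$x2 <- d$x2 + 2.5 * (d$g == "b")
    s <- greedy_wilks(d, c("x1", "x2", "x3"), "g")
    nrow(s) > 0 && s$term[1] == "x2"
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # pure noise is rejected most of the time at p_enter = 0.05
  empty <- vapply(1:40, function(k) {
    set.seed(600 + k)
    d <- data.frame(x1 = rnorm(36), x2 = rnorm(36),
                    g = rep(c("a", "b", "c"), each = 12))
    nrow(greedy_wilks(d, c("x1", "x2"), "g")) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.8)
})

test_that("MANOVA reduces to one-way ANOVA in the univariate two-group case", {
  set.seed(28)
  d <- data.frame(x = rnorm(30), g = rep(c("a", "b"), each = 15))
  mw <- manova_wilks(d, "x", "g")
  a <- anova(lm(x ~ g, data = d))
  expect_equal(mw$statistic, a[1, "F value"], tolerance = 1e-10)
  expect_gt(mw$wilks, 0)
  expect_lte(mw$wilks, 1)

  d3 <- data.frame(x = rnorm(45), y = rnorm(45),
                   g = rep(c("a", "b", "c"), each = 15))
  m3 <- manova_wilks(d3, c("x", "y"), "g")
  expect_true(m3$wilks > 0 && m3$wilks <= 1)
})

test_that("permutation chi-square matches the formula and the null table", {
  flat <- matrix(10, 2, 2)
  r0 <- contingency_chi2_perm(flat, n_perm = 999, seed = 1)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_perm, 1)

  set.seed(29)
  for (k in 1:10) {
    tab <- matrix(rpois(9, 8), 3, 3)
    r <- contingency_chi2_perm(tab, n_perm = 999, seed = k)
    expect_equal(r$chi2,
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE)$statistic)),
                 tolerance = 1e-10)
  }

  # permutation p approaches the asymptotic p on a large balanced table
  big <- matrix(c(60, 40, 35, 65), 2, 2)
  rb <- contingency_chi2_perm(big, n_perm = 19999, seed = 2)
  expect_lt(abs(rb$p_perm - rb$p_asymptotic), 0.01)

  withzero <- rbind(matrix(5, 2, 3), 0)
  expect_warning(contingency_chi2_perm(withzero, n_perm = 999, seed = 1),
                 "all-zero")
  expect_error(contingency_chi2_perm(matrix(0.5, 2, 2)), "integers")
})

test_that("univariate association wrappers behave on canonical inputs", {
  x <- 1:20
  expect_equal(univariate_assoc(x, x^3, "spearman")$statistic, 1)
  expect_equal(univariate_assoc(x, x, "pearson")$statistic, 1)
  kw <- univariate_assoc(c(rnorm(10), rnorm(10) + 5),
                         rep(c("a", "b"), each = 10), "kruskal_wallis")
  expect_lt(kw$p_value, 0.01)
  expect_warning(r <- univariate_assoc(rep(1, 5), rnorm(5), "pearson"),
                 "constant")
  expect_true(is.na(r$statistic))
})
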