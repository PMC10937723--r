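test_that("SRH reduces to Kruskal-Wallis when one factor is constant", {
  set.seed(101)
  for (rep in 1:5) {
    y <- rnorm(40) + rep(c(0, 0.5, 1, 0.2), each = 10)
    a <- rep(letters[1:4], each = 10)
    res <- scheirer_ray_hare(y, a, rep("z", 40))
    kw <- stats::kruskal.test(y, factor(a))
    expect_equal(res$H[res$term == "A"], unname(kw$statistic),
                 tolerance = 1e-10)
    expect_equal(res$p_value[res$term == "A"], kw$p.value, tolerance = 1e-10)
  }
  expect_error(scheirer_ray_hare(1:4, rep("a", 4), rep("b", 4)),
               ">= 2 levels")
})

test_that("SRH is invariant under monotone transforms and detects shifts", {
  set.seed(102)
  y <- rnorm(60)
  a <- sample(c("i", "m"), 60, TRUE)
  b <- sample(c("t", "n"), 60, TRUE)
  r1 <- scheirer_ray_hare(y, a, b)
  r2 <- scheirer_ray_hare(exp(3 * y), a, b)   # strictly monotone
  expect_equal(r1$H, r2$H, tolerance = 1e-12)
  # ties: denominator differs from n(n+1)/12, no-tie case matches it
  n <- 60
  expect_equal(attr(r1, "ms_total"), n * (n + 1) / 12)

  # strong additive shift on A at n = 200 -> tiny p
  y2 <- rnorm(200) + ifelse(a2 <- sample(c("i", "m"), 200, TRUE) == "i", 2, 0)
  b2 <- sample(c("t", "n"), 200, TRUE)
  r3 <- scheirer_ray_hare(y2, a2, b2)
  expect_lt(r3$p_value[r3$term == "A"], 0.001)
  # empty cell rejected
  expect_error(scheirer_ray_hare(1:6, c("a", "a", "a", "b", "b", "b"),
                                 c("x", "x", "x", "y", "y", "y")),
               "empty cell")
})

test_that("pairwise Wilcoxon: exact extreme p and identity correction", {
  res <- pairwise_wilcoxon(c(1, 2, 3, 10, 11, 12),
                           rep(c("lo", "hi"), each = 3))
  # exact enumeration oracle: all C(6,3) = 20 assignments; the observed
  # complete separation is one of two most extreme -> two-sided p = 2/20
  splits <- utils::combn(6, 3)
  vals <- c(1, 2, 3, 10, 11, 12)
  obs_w <- sum(rank(vals)[4:6]) # hi group rank sum
  stats_all <- apply(splits, 2, function(ix) sum(rank(vals)[ix]))
  center <- mean(stats_all)
  p_exact <- mean(abs(stats_all - center) >= abs(obs_w - center))
  expect_equal(res$p_raw, p_exact)
  # single pair: correction is the identity
  expect_equal(res$p_adj, res$p_raw)

  # Bonferroni caps at 1 and multiplies by the comparison count
  set.seed(103)
  y <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  r3 <- pairwise_wilcoxon(y, g)
  expect_equal(r3$p_adj, pmin(1, r3$p_raw * 3))
  expect_error(pairwise_wilcoxon(y, rep("a", 30)), ">= 2 groups")
})

test_that("Mantel: self-correlation, exhaustive enumeration, relabeling", {
  set.seed(104)
  n <- 5
  m1 <- matrix(0, n, n); m1[upper.tri(m1)] <- runif(10); m1 <- m1 + t(m1)
  m2 <- matrix(0, n, n); m2[upper.tri(m2)] <- runif(10); m2 <- m2 + t(m2)
  expect_equal(mantel_test(m1, m1, n_perm = 9, seed = 1)$r, 1)

  got <- mantel_test(m1, m2, exhaustive = TRUE)
  # independent oracle: enumerate the 120 label permutations directly
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == n), ]
  ut <- upper.tri(m1)
  r_obs <- cor(m1[ut], m2[ut])
  r_all <- apply(perms, 1, function(idx) cor(m1[idx, idx][ut], m2[ut]))
  expect_equal(nrow(perms), 120)
  expect_equal(got$p_value, mean(r_all >= r_obs))

  # invariance under identical relabeling of both matrices
  idx <- sample(n)
  a <- mantel_test(m1, m2, n_perm = 99, seed = 7)
  b <- mantel_test(m1[idx, idx], m2[idx, idx], n_perm = 99, seed = 7)
  expect_equal(a$r, b$r, tolerance = 1e-12)

  dimnames(m1) <- list(letters[1:n], letters[1:n])
  dimnames(m2) <- list(LETTERS[1:n], LETTERS[1:n])
  expect_error(mantel_test(m1, m2), "labels differ")
})

test_that("Mantel agrees with vegan on a fixed instance", {
  set.seed(105)
  n <- 12
  m1 <- matrix(0, n, n); m1[upper.tri(m1)] <- runif(n * (n - 1) / 2)
  m1 <- m1 + t(m1)
  m2 <- m1 + matrix(rnorm(n * n, sd = 0.1), n, n)
  m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  got <- mantel_test(m1, m2, n_perm = 999, seed = 9)
  ref <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                       permutations = 999)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(got$p_value - ref$signif), 0.03)
})

test_that("distance decay recovers noiseless parameters and handles b = 0", {
  set.seed(106)
  n <- 20
  lab <- sprintf("p%02d", 1:n)
  d <- matrix(0, n, n); d[upper.tri(d)] <- runif(n * (n - 1) / 2, 50, 15000)
  d <- d + t(d); dimnames(d) <- list(lab, lab)
  s <- 0.9 * exp(-5e-4 * d); diag(s) <- 1; dimnames(s) <- dimnames(d)
  fit <- fit_distance_decay(s, d)
  expect_equal(fit$a, 0.9, tolerance = 1e-6)
  expect_equal(fit$b, 5e-4, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$decay_rate_per_1000km, 1 - exp(-0.5), tolerance = 1e-5)

  flat <- matrix(0.7, n, n); diag(flat) <- 1; dimnames(flat) <- dimnames(d)
  fit0 <- fit_distance_decay(flat, d)
  expect_equal(fit0$decay_rate_per_1000km, 0, tolerance = 1e-6)

  # power-law alternative exposed
  s2 <- 5 * d^(-0.4); diag(s2) <- 1; dimnames(s2) <- dimnames(d)
  fitp <- fit_distance_decay(s2, d, form = "power")
  expect_equal(fitp$b, 0.4, tolerance = 1e-6)
  expect_error(fit_distance_decay(s * 0, d), "all similarities")
})

test_that("GLMM with negligible random effect matches the fixed-effect GLM", {
  set.seed(107)
  n <- 1500  # large n so a spurious region-variance estimate vanishes
  tropical <- runif(n) < 0.5
  island <- runif(n) < 0.4
  region <- rep(sprintf("r%02d", 1:10), length.out = n)
  mu <- exp(1 + 0.8 * tropical + 0.5 * island)
  y <- MASS::rnegbin(n, mu = mu, theta = 3)
  fit <- fit_count_glmm(y, tropical, island, region, family = "negbin")
  ref <- MASS::glm.nb(y ~ tropical + island)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ref))), 1e-3)
  expect_equal(fit$theta, ref$theta, tolerance = 0.05)
  # AIC identity holds: 2 * params - 2 * loglik
  n_par <- nrow(fit$coefficients) + 2  # + RE variance + theta
  expect_equal(fit$aic, 2 * n_par - 2 * fit$loglik, tolerance = 1e-8)
  expect_error(fit_count_glmm(c(1.5, 2), TRUE, TRUE, c("a", "b")),
               "integers|regions")
})
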