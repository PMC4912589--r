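test_that("transition back-transformation matches the closed form", {
  expect_equal(transition_row(c(0, 0, 0)), rep(0.25, 4))
  expect_equal(transition_row(c(log(2), 0)), c(0.5, 0.25, 0.25))
  # saturation without overflow: all mass on the huge coefficient
  expect_equal(transition_row(c(800, -800, -800)), c(1, 0, 0, 0))
  set.seed(4)
  for (k in 2:4) for (i in 1:200) {
    psi <- transition_row(rnorm(k - 1, 0, 10))
    expect_true(all(psi >= 0))
    expect_lt(abs(sum(psi) - 1), 1e-12)
  }
})

test_that("age-linear survival follows the inverse logit", {
  expect_equal(survival_prob(0, 0, 3), 0.5)
  expect_equal(survival_prob(0, log(3), 1), 0.75)
  expect_gt(survival_prob(-1, 0.4, 7), survival_prob(-1, 0.4, 1))
  expect_error(survival_prob(0, 0, 8), "age")
})

test_that("derived transition rows always sum to one", {
  set.seed(9)
  for (i in 1:25) {
    tb <- par_to_tables(random_par())
    for (a in 1:7)
      expect_equal(rowSums(tb$psi[, , a]), rep(1, 4), tolerance = 1e-12)
    expect_true(all(tb$phi > 0 & tb$phi < 1))
  }
})

test_that("forward likelihood agrees with exhaustive path enumeration", {
  set.seed(21)
  histories <- c(all_valid_histories(3), list(c(1L, 0L, 3L, 0L), c(1L, 1L, 1L, 1L),
                                              c(1L, 0L, 0L, 4L), c(1L, 2L, 2L, 4L)))
  for (i in 1:20) {
    tb <- par_to_tables(random_par())
    for (h in histories)
      expect_equal(forward_loglik(h, tb), enum_loglik(h, tb),
                   tolerance = 1e-10)
  }
})

test_that("forward likelihood handles the analytic corner cases", {
  tb <- par_to_tables(random_par())
  expect_equal(forward_loglik(1L, tb), 0)  # marked on the final occasion
  tb$p <- rep(1, 4)
  expect_equal(forward_loglik(c(1L, 1L), tb),
               log(tb$phi[1, 1] * tb$psi[1, 1, 1]))
  # impossible observation (backward move) yields -Inf with a warning
  expect_warning(ll <- forward_loglik(c(1L, 3L, 1L), tb), "impossible")
  expect_identical(ll, -Inf)
})

test_that("compiled likelihood equals the R forward algorithm on real sets", {
  cfg <- study_config(years = 1:12, cohorts = setNames(rep(60L, 4L), 1:4))
  ch <- simulate_population(default_truth(), cfg, seed = 6)
  j0 <- match(ch$cohort_year, ch$years)
  set.seed(31)
  for (rep in 1:5) {
    par <- random_par()
    tb <- par_to_tables(par)
    ll_r <- sum(vapply(seq_len(nrow(ch$obs)), function(i)
      forward_loglik(ch$obs[i, j0[i]:ncol(ch$obs)], tb), 0))
    expect_equal(loglik_capthist(ch, par), ll_r, tolerance = 1e-8)
  }
})

test_that("log prior combines Normal coefficients and Uniform detection", {
  lay <- par_layout()
  par0 <- c(rep(0, 47), rep(0.5, 4))
  lp0 <- log_prior(par0, lay)
  expect_equal(lp0, sum(dnorm(rep(0, 47), 0, sqrt(1000), log = TRUE)))
  # one coefficient at one prior SD costs exactly 1/2
  par1 <- par0; par1[1] <- sqrt(1000)
  expect_equal(lp0 - log_prior(par1, lay), 0.5)
  # detection outside the unit interval is impossible
  par2 <- par0; par2[lay$idx_p[1]] <- 1.5
  expect_identical(log_prior(par2, lay), -Inf)
})

test_that("Gelman-Rubin statistic matches the PSRF formula", {
  set.seed(8)
  one <- rnorm(100)
  # identical chains: B = 0, Rhat = sqrt((n-1)/n)
  r <- gelman_rubin(c(one, one), chain = rep(1:2, each = 100))
  expect_equal(as.numeric(r), sqrt(99 / 100), tolerance = 1e-12)
  # same-distribution chains: about 1
  r2 <- gelman_rubin(rnorm(2000), chain = rep(1:2, each = 1000))
  expect_lt(abs(as.numeric(r2) - 1), 0.05)
  # far-separated chains: far above the 1.1 flag
  x <- c(rnorm(100, 0), rnorm(100, 10))
  r3 <- gelman_rubin(x, chain = rep(1:2, each = 100))
  expect_gt(as.numeric(r3), 3)
  expect_error(gelman_rubin(one, chain = rep(1, 100)), "2 chains")
})

test_that("posterior summaries report means and central 95% intervals", {
  n <- 1000
  phi <- array(0.7, c(n, 4, 7)); p <- matrix(0.5, n, 4)
  psi <- array(0, c(n, 4, 4, 7))
  psi[, 1, 1, ] <- 0.6; psi[, 1, 3, ] <- 0.4
  psi[, 2, 2, ] <- 1; psi[, 3, 3, ] <- 1; psi[, 4, 4, ] <- 1
  psi[, 1, 1, 1] <- (1:n) / n; psi[, 1, 3, 1] <- 1 - (1:n) / n
  fit <- draws_from_tables(phi, psi, p)
  s <- summarize_posterior(fit)
  expect_true(all(s$mean >= 0 & s$mean <= 1))
  expect_true(all(s$lo95 <= s$mean & s$mean <= s$hi95))
  row <- s[s$parameter == "psi_P_to_P_a1", ]
  expect_equal(row$mean, mean((1:n) / n))
  expect_lt(abs(row$lo95 - 0.025), 0.002)
  expect_lt(abs(row$hi95 - 0.975), 0.002)
  # constant draws collapse to a width-zero interval
  row2 <- s[s$parameter == "phi_P_a3", ]
  expect_equal(c(row2$lo95, row2$hi95), c(0.7, 0.7))
})

test_that("credible differences follow the strict below-zero tie policy", {
  d <- credible_difference(c(1, 2, 3), c(0, 1, 2))
  expect_equal(d$p_below, 0)
  expect_true(d$credible)
  expect_equal(credible_difference(1:4, 1:4)$p_below, 0)  # ties not below
  d3 <- credible_difference(c(0.1, -0.2, 0.3, 0.4), rep(0, 4))
  expect_equal(d3$p_below, 0.25)
  expect_false(d3$credible)
  expect_error(credible_difference(1:3, 1:4), "aligned")
})

test_that("the sampler is deterministic and concentrates on degenerate data", {
  # all birds always seen with parents: remain-with-parents posterior ~ 1
  obs <- matrix(1L, 40, 6)
  ch <- capthist_set(sprintf("x%d", 1:40), rep(1L, 40), obs, years = 1:6)
  mc <- mcmc_config(n_chains = 2, n_iter = 800, n_burnin = 300, thin = 5,
                    seed = 14)
  fit1 <- sample_posterior(ch, mc)
  fit2 <- sample_posterior(ch, mc)
  expect_identical(fit1$par, fit2$par)
  expect_equal(nrow(fit1$par), 2 * (800 - 300) %/% 5)
  stay <- fit1$tables$psi[, 1, 1, 2]
  expect_gt(mean(stay), 0.85)
  p1 <- fit1$tables$p[, 1]
  expect_gt(mean(p1), 0.85)
})

test_that("the age-constant variant ties transitions across ages", {
  cfg <- study_config(years = 1:8, cohorts = setNames(rep(40L, 2L), 1:2))
  ch <- simulate_population(default_truth(), cfg, seed = 4)
  fit <- sample_posterior(ch, mcmc_config(n_chains = 1, n_iter = 400,
                                          n_burnin = 200, thin = 5, seed = 2),
                          variant = "age_constant")
  expect_equal(ncol(fit$par), 18L)
  for (a in 2:7)
    expect_equal(fit$tables$psi[, , , a], fit$tables$psi[, , , 2])
})
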