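test_that("strategy specifications are range-checked", {
  expect_error(strategy_spec(0), "1..7")
  expect_error(strategy_spec(8), "1..7")
  expect_error(strategy_spec(3, -1), "0..5")
  expect_error(strategy_spec(3, 6), "0..5")
  s <- strategy_spec(3, 5)  # sibling years saturating in the 7+ class
  expect_equal(s$sibling_years, 5L)
})

test_that("forced tables route the family phases deterministically", {
  tb <- truth_tables()
  # leave parents at age 1, no sibling years: everyone to ind/nonbreeder
  f10 <- forced_transition_tables(tb, strategy_spec(1, 0))
  expect_equal(f10[1, 3, 1], 1)
  expect_true(all(f10[1, 3, ] == 1))
  # leave parents at 7: remain with probability 1 through ages 1-6
  f70 <- forced_transition_tables(tb, strategy_spec(7, 0))
  for (a in 1:6) expect_equal(f70[1, 1, a], 1)
  expect_equal(f70[1, 3, 7], 1)
  # leave at 2, two sibling years: P->S at age 2, stay S at 3, S->INB at 4
  f22 <- forced_transition_tables(tb, strategy_spec(2, 2))
  expect_equal(f22[1, 1, 1], 1)
  expect_equal(f22[1, 2, 2], 1)
  expect_equal(f22[2, 2, 3], 1)
  expect_equal(f22[2, 3, 4], 1)
  # observed independent breeding probabilities are retained
  expect_equal(f22[3, 4, ], tb$psi[3, 4, ])
  # no breeding out of forced family phases by default
  expect_equal(sum(f22[1:2, 4, ]), 0)
  # conservation for every strategy and age
  for (i in seq_len(nrow(valid_strategies()))) {
    vs <- valid_strategies()[i, ]
    f <- forced_transition_tables(tb, strategy_spec(vs$leave_parents_age,
                                                    vs$sibling_years))
    for (a in 1:7) expect_equal(rowSums(f[, , a]), rep(1, 4))
  }
  # the optional sibling-breeding shortcut restores the observed rate
  fb <- forced_transition_tables(tb, strategy_spec(2, 2),
                                 allow_sibling_breeding = TRUE)
  expect_equal(fb[2, 4, 3], tb$psi[2, 4, 3])
  expect_equal(rowSums(fb[, , 3]), rep(1, 4))
})

test_that("a wild type that already equals the forced strategy is a fixed point", {
  # deterministic observed tables identical to strategy (2, 0)
  phi <- matrix(0.8, 4, 7)
  psi <- forced_transition_tables(truth_tables(), strategy_spec(2, 0))
  tb <- list(phi = phi, psi = psi, p = rep(1, 4))
  n <- 10
  phiA <- array(rep(phi, each = n), c(n, 4, 7))
  psiA <- array(rep(psi, each = n), c(n, 4, 4, 7))
  fit <- draws_from_tables(phiA, psiA, matrix(1, n, 4))
  wt <- wildtype_fitness(fit)
  st <- strategy_fitness(fit, strategy_spec(2, 0))
  expect_equal(st$lambda, wt$lambda, tolerance = 1e-12)
  om <- fitness_difference(wt, st, strategy_spec(2, 0))
  expect_equal(om$omega, rep(0, n))
  expect_equal(om$p_below, 0)  # ties count as not-below
})

test_that("omega bookkeeping counts draws below zero", {
  wt <- structure(list(lambda = c(0.9, 0.92, 0.91, 0.88)),
                  class = "fitness_posterior")
  st <- structure(list(lambda = c(0.91, 0.90, 0.88, 0.90)),
                  class = "fitness_posterior")
  om <- fitness_difference(wt, st, strategy_spec(1, 0))
  expect_equal(om$omega, c(-0.01, 0.02, 0.03, -0.02))
  expect_equal(om$p_below, 0.5)
  expect_false(om$credible)
  st2 <- structure(list(lambda = wt$lambda + 0.01), class = "fitness_posterior")
  om2 <- fitness_difference(wt, st2, strategy_spec(1, 0))
  expect_equal(om2$p_below, 1)
  expect_true(om2$credible)
  bad <- structure(list(lambda = 1:3), class = "fitness_posterior")
  expect_error(fitness_difference(wt, bad, strategy_spec(1, 0)), "aligned")
})

test_that("the strategy grid enumerates every valid combination once", {
  vs <- valid_strategies()
  # per departure age p, sibling years run 0..(8 - p)
  expect_equal(nrow(vs), sum(9 - (1:7)))
  expect_false(any(duplicated(vs)))
  fit <- jitter_draws(30, truth_tables(), sd = 0.05, seed = 2)
  sub <- vs[vs$leave_parents_age >= 6, ]
  g <- strategy_grid(fit, sub)
  expect_equal(nrow(g), nrow(sub))
  expect_true(all(g$P >= 0 & g$P <= 1))
  expect_equal(g$credible, g$P < 0.05 | g$P > 0.95)
  # evaluation order does not matter
  g2 <- strategy_grid(fit, sub[rev(seq_len(nrow(sub))), ])
  key <- function(d) d[order(d$leave_parents_age, d$sibling_years), ]
  expect_equal(key(g2), key(g), ignore_attr = TRUE)
})

test_that("early forced departure is credibly worse when family survival dominates", {
  # survival with parents/siblings far above independent survival at young
  # ages; modest breeding advantage for independents
  base <- truth_tables()
  base$phi[1, ] <- 0.90
  base$phi[2, ] <- 0.88
  base$phi[3, ] <- plogis(qlogis(0.5) + 0.25 * (1:7 - 1))
  fit <- jitter_draws(200, base, sd = 0.08, seed = 3)
  wt <- wildtype_fitness(fit)
  for (st in list(strategy_spec(1, 0), strategy_spec(2, 0))) {
    om <- fitness_difference(wt, strategy_fitness(fit, st), st)
    expect_lt(om$p_below, 0.05)
    expect_true(om$credible)
  }
  # shifting all wild-type draws up pushes every P towards zero
  wt_up <- wt; wt_up$lambda <- wt$lambda + 0.05
  st <- strategy_spec(4, 1)
  om0 <- fitness_difference(wt, strategy_fitness(fit, st), st)
  om1 <- fitness_difference(wt_up, strategy_fitness(fit, st), st)
  expect_lte(om1$p_below, om0$p_below)
})

test_that("consecutive-age posterior correlations are reported faithfully", {
  set.seed(6)
  fit <- jitter_draws(300, truth_tables(), sd = 0.1, seed = 6)
  rep_ <- monitor_draw_correlations(fit)
  # independent jitter: no strong correlations anywhere
  expect_true(all(abs(rep_$r) < 0.5))
  expect_false(any(rep_$flagged))
  # direct recomputation for one entry
  row <- rep_[rep_$quantity == "phi" & rep_$from_state == "P" &
                rep_$age == 2, ]
  expect_equal(row$r, cor(fit$tables$phi[, 1, 2], fit$tables$phi[, 1, 3]))
  # duplicated columns across ages are flagged at r = 1
  fit$tables$phi[, 1, 4] <- fit$tables$phi[, 1, 3]
  rep2 <- monitor_draw_correlations(fit)
  row2 <- rep2[rep2$quantity == "phi" & rep2$from_state == "P" &
                 rep2$age == 3, ]
  expect_equal(row2$r, 1)
  expect_true(row2$flagged)
})
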