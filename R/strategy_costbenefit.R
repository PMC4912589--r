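#' Specify a forced family-departure strategy
#'
#' A strategy forces the family phases of the life history: the bird stays
#' with its parents through age class `leave_parents_age`, departing (with
#' probability 1) on the transition out of that age; it then stays with
#' siblings for `sibling_years` years (0 = directly to
#' independent/nonbreeder).  Once independent, the observed age-specific
#' breeding probabilities apply.  Sibling years that would extend past age
#' class 7+ saturate there: the bird keeps sibling-state survival within the
#' 7+ class, so `sibling_years` is capped at `8 - leave_parents_age`.
#'
#' @param leave_parents_age Integer 1..7.
#' @param sibling_years Integer `0..(8 - leave_parents_age)`.
#' @return A list of class `strategy_spec`.
#' @export
strategy_spec <- function(leave_parents_age, sibling_years = 0L) {
  p <- as.integer(leave_parents_age); s <- as.integer(sibling_years)
  if (length(p) != 1L || is.na(p) || p < 1L || p > MAX_AGE)
    stop("leave_parents_age must be a single integer in 1..7")
  if (length(s) != 1L || is.na(s) || s < 0L || s > MAX_AGE + 1L - p)
    stop(sprintf("sibling_years must lie in 0..%d for leave_parents_age %d",
                 MAX_AGE + 1L - p, p))
  structure(list(leave_parents_age = p, sibling_years = s),
            class = "strategy_spec")
}

#' All valid forced strategies
#'
#' @return Data frame of `leave_parents_age` and `sibling_years`
#'   combinations, ordered by departure age then sibling years.
#' @export
valid_strategies <- function() {
  out <- do.call(rbind, lapply(1:MAX_AGE, function(p)
    data.frame(leave_parents_age = p,
               sibling_years = 0:(MAX_AGE + 1L - p))))
  out[order(out$leave_parents_age, out$sibling_years), , drop = FALSE]
}

#' Forced transition tables for one strategy
#'
#' Replaces the family-phase transition rows of one posterior draw with the
#' deterministic strategy: remain with parents (probability 1) before the
#' forced departure age and leave at it; remain with siblings through the
#' forced sibling years, then move to independent/nonbreeder.  The
#' independent/nonbreeder row keeps the observed age-specific breeding
#' probability, and all survival values stay observed.  By default birds
#' cannot breed out of a forced family phase (they must pass through
#' independence first); `allow_sibling_breeding = TRUE` restores the
#' observed sibling-to-breeder shortcut during forced sibling years.
#'
#' @param tables One draw's probability tables (`phi`, `psi`, `p`).
#' @param strategy A [strategy_spec()].
#' @param allow_sibling_breeding Allow the observed direct
#'   sibling-to-breeder transition during forced sibling years?
#' @return A 4 x 4 x 7 transition array with every row summing to 1.
#' @export
forced_transition_tables <- function(tables, strategy,
                                     allow_sibling_breeding = FALSE) {
  stopifnot(inherits(strategy, "strategy_spec"))
  p_age <- strategy$leave_parents_age
  s_yrs <- strategy$sibling_years
  leave_sib_age <- p_age + s_yrs   # transition out of this age leaves siblings
  psi <- array(0, dim = c(4L, 4L, 7L))
  for (a in 1:MAX_AGE) {
    # with parents
    if (a < p_age) {
      psi[1L, 1L, a] <- 1
    } else if (s_yrs > 0L) {
      psi[1L, 2L, a] <- 1
    } else {
      psi[1L, 3L, a] <- 1
    }
    # with siblings
    breed <- if (allow_sibling_breeding) tables$psi[2L, 4L, a] else 0
    if (a < leave_sib_age) {
      psi[2L, 2L, a] <- 1 - breed
    } else {
      psi[2L, 3L, a] <- 1 - breed
    }
    psi[2L, 4L, a] <- breed
    # independent/nonbreeder: observed breeding probability
    b <- tables$psi[3L, 4L, a]
    psi[3L, 3L, a] <- 1 - b
    psi[3L, 4L, a] <- b
    psi[4L, 4L, a] <- 1
  }
  psi
}

#' Forced-strategy fitness posterior
#'
#' Per-draw dominant eigenvalue of the projection matrix built from the
#' forced transition tables of `strategy` with the draw's observed survival
#' and breeding probabilities.
#'
#' @param fit An `msfit`.
#' @param strategy A [strategy_spec()].
#' @param ... Passed to [forced_transition_tables()].
#' @return A `fitness_posterior`.
#' @export
strategy_fitness <- function(fit, strategy, ...) {
  wildtype_fitness(fit, strategy = strategy, ...)
}

#' Fitness difference between wild type and a forced strategy
#'
#' Per aligned posterior draw, `omega = lambda_wt - lambda_s`.  `p_below`
#' is the proportion of omega draws strictly below zero (ties count as
#' not-below); the difference is credible when `p_below < 0.05` or
#' `> 0.95`.  Small `p_below` means the forced strategy is credibly worse
#' than the wild type.
#'
#' @param wildtype,simulated `fitness_posterior` objects computed from the
#'   same draws in the same order.
#' @param strategy The [strategy_spec()] the comparison belongs to.
#' @return An object of class `omega_result`: `strategy`, per-draw
#'   `omega`, `mean`, `lo95`, `hi95`, `p_below`, `credible`.
#' @export
fitness_difference <- function(wildtype, simulated, strategy) {
  if (length(wildtype$lambda) != length(simulated$lambda))
    stop("wild-type and strategy posteriors must have aligned draws")
  d <- credible_difference(wildtype$lambda, simulated$lambda)
  structure(list(strategy = strategy, omega = wildtype$lambda - simulated$lambda,
                 mean = d$mean, lo95 = d$lo95, hi95 = d$hi95,
                 p_below = d$p_below, credible = d$credible),
            class = "omega_result")
}

#' @export
print.omega_result <- function(x, ...) {
  cat(sprintf(
    "omega (leave parents %d, siblings %d): mean %.4f [%.4f, %.4f], P = %.3f%s\n",
    x$strategy$leave_parents_age, x$strategy$sibling_years,
    x$mean, x$lo95, x$hi95, x$p_below,
    if (x$credible) " (credible)" else ""))
  invisible(x)
}

#' Cost-benefit grid over all forced strategies
#'
#' Computes the wild-type fitness posterior once, then for every valid
#' `(leave_parents_age, sibling_years)` combination the forced-strategy
#' fitness and the posterior of the difference `omega`.
#'
#' @param fit An `msfit`.
#' @param strategies Data frame of strategies (default [valid_strategies()]).
#' @param ... Passed to [forced_transition_tables()].
#' @return Data frame with one row per strategy: `leave_parents_age`,
#'   `sibling_years`, `omega_mean`, `omega_lo95`, `omega_hi95`, `P`
#'   (proportion of omega draws below zero), `credible`.  The wild-type
#'   fitness posterior is attached as attribute `wildtype`.
#' @export
strategy_grid <- function(fit, strategies = valid_strategies(), ...) {
  wt <- wildtype_fitness(fit)
  rows <- lapply(seq_len(nrow(strategies)), function(i) {
    st <- strategy_spec(strategies$leave_parents_age[i],
                        strategies$sibling_years[i])
    om <- fitness_difference(wt, strategy_fitness(fit, st, ...), st)
    data.frame(leave_parents_age = st$leave_parents_age,
               sibling_years = st$sibling_years,
               omega_mean = om$mean, omega_lo95 = om$lo95,
               omega_hi95 = om$hi95, P = om$p_below,
               credible = om$credible)
  })
  out <- do.call(rbind, rows)
  attr(out, "wildtype") <- wt
  out
}

#' Posterior correlations between consecutive-age parameters
#'
#' For each state, the correlation across posterior draws between each
#' derived probability at age `a` and the same quantity at age `a + 1`
#' (survival, and each transition destination).  Strong negative
#' correlations between neighbouring ages would warn that year-on-year
#' cost-benefit contrasts lean on anti-correlated estimates.
#'
#' @param fit An `msfit`.
#' @param flag_threshold Absolute correlation above which a pair is flagged.
#' @return Data frame with `quantity`, `from_state`, `age`, `age_next`,
#'   `r`, `flagged`.
#' @export
monitor_draw_correlations <- function(fit, flag_threshold = 0.9) {
  tb <- fit$tables
  rows <- list()
  add <- function(quantity, state, a, x, y) {
    r <- suppressWarnings(cor(x, y))
    if (is.na(r)) r <- 0   # degenerate (constant) draws
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, from_state = STATE_ABB[state],
      age = a, age_next = a + 1L, r = r,
      flagged = abs(r) > flag_threshold)
  }
  for (s in 1:4) for (a in 1:6)
    add("phi", s, a, tb$phi[, s, a], tb$phi[, s, a + 1L])
  for (s in 1:3) {
    for (d in DEST_SETS[[as.character(s)]]) for (a in 1:6)
      add(sprintf("psi_to_%s", STATE_ABB[d]), s, a,
          tb$psi[, s, d, a], tb$psi[, s, d, a + 1L])
  }
  do.call(rbind, rows)
}
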