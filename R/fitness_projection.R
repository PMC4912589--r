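# Stage space of the projection model: (age class 1..7) x (with parents,
# with siblings, independent/nonbreeder).  Breeders are not a stage: a bird
# entering the breeding state contributes one recruit and is lost to
# population growth.
N_STAGE_STATES <- 3L
N_STAGES <- MAX_AGE * N_STAGE_STATES

stage_index <- function(age, state) (state - 1L) * MAX_AGE + age

stage_names <- function() {
  as.vector(vapply(1:N_STAGE_STATES, function(s)
    sprintf("%s_a%d", STATE_ABB[s], 1:MAX_AGE), character(MAX_AGE)))
}

#' Build the age-by-state projection matrix from one posterior draw
#'
#' Stages are the 21 combinations of age class (1-7+) and living nonbreeder
#' state (with parents, with siblings, independent/nonbreeder).  A bird in
#' stage `(a, s)` survives with `phi[s, a]` and moves to stage
#' `(min(a + 1, 7), s')` with weight `phi[s, a] * psi[s, s', a]`.
#' Transitions to the breeder state are breeding probabilities: they add a
#' fecundity entry `phi[s, a] * psi[s, 4, a]` into stage (age 1, with
#' parents), after which the breeder is lost to population growth.
#'
#' @param tables Probability tables for one draw: list of `phi` (4 x 7),
#'   `psi` (4 x 4 x 7), `p` (ignored here).
#' @param strategy Optional [strategy_spec()]; when given, the forced
#'   transition tables of [forced_transition_tables()] replace the observed
#'   ones (survival stays observed).
#' @param ... Passed to [forced_transition_tables()] (e.g.
#'   `allow_sibling_breeding`).
#' @return A 21 x 21 nonnegative matrix `A` with `A[to, from]` entries.
#' @export
build_projection_matrix <- function(tables, strategy = NULL, ...) {
  phi <- tables$phi
  psi <- if (is.null(strategy)) tables$psi
         else forced_transition_tables(tables, strategy, ...)
  for (a in 1:MAX_AGE)
    if (any(rowSums(psi[, , a]) > 1 + 1e-8))
      stop("transition rows must not exceed probability 1")
  A <- matrix(0, N_STAGES, N_STAGES, dimnames = list(stage_names(),
                                                     stage_names()))
  recruit <- stage_index(1L, 1L)
  for (a in 1:MAX_AGE) {
    a_next <- min(a + 1L, MAX_AGE)
    for (s in 1:N_STAGE_STATES) {
      from <- stage_index(a, s)
      for (s2 in s:N_STAGE_STATES) {
        w <- phi[s, a] * psi[s, s2, a]
        if (w > 0) {
          to <- stage_index(a_next, s2)
          A[to, from] <- A[to, from] + w
        }
      }
      fec <- phi[s, a] * psi[s, 4L, a]
      A[recruit, from] <- A[recruit, from] + fec
    }
  }
  A
}

#' Dominant eigenvalue (spectral radius) of a nonnegative matrix
#'
#' Shifted power iteration: iterates `v <- (M + I) v` (the unit shift makes
#' the iteration aperiodic without moving the Perron eigenvector) with L1
#' normalization until the eigenvalue estimate stabilizes.  For a
#' nonnegative matrix the spectral radius is a real, nonnegative eigenvalue.
#'
#' @param M Square nonnegative matrix.
#' @param tol Convergence tolerance on successive eigenvalue estimates.
#' @param max_iter Iteration cap.
#' @return The dominant eigenvalue as a single number.
#' @export
dominant_eigenvalue <- function(M, tol = 1e-13, max_iter = 100000L) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  if (any(M < 0)) stop("matrix must be nonnegative")
  n <- nrow(M)
  Ms <- M + diag(n)
  v <- rep(1 / n, n)
  lam <- NA_real_
  stable <- 0L
  for (k in seq_len(max_iter)) {
    w <- Ms %*% v
    s <- sum(w)
    if (s == 0) return(0)          # nilpotent-with-shift cannot happen; guard
    lam_new <- s                   # since sum(v) == 1, s = v' Ms v direction
    v <- as.vector(w) / s
    if (is.finite(lam) && abs(lam_new - lam) < tol * max(1, lam_new)) {
      stable <- stable + 1L
      if (stable >= 5L) { lam <- lam_new; break }
    } else stable <- 0L
    lam <- lam_new
  }
  max(lam - 1, 0)
}

#' Posterior distribution of wild-type fitness
#'
#' Computes, for every posterior draw, the dominant eigenvalue of the
#' age-by-state projection matrix built from that draw's probability tables.
#'
#' @param fit An `msfit` (from [sample_posterior()] or
#'   [draws_from_tables()]).
#' @param strategy Optional [strategy_spec()] producing the forced-strategy
#'   fitness instead of the wild type.
#' @param ... Passed to [build_projection_matrix()].
#' @return An object of class `fitness_posterior`: per-draw `lambda`,
#'   posterior `mean`, `lo95`, `hi95`, and the `strategy` (NULL = wild
#'   type).
#' @export
wildtype_fitness <- function(fit, strategy = NULL, ...) {
  tb <- fit$tables
  n <- dim(tb$phi)[1]
  lambda <- numeric(n)
  for (i in seq_len(n)) {
    draw <- list(phi = tb$phi[i, , ], psi = tb$psi[i, , , ], p = tb$p[i, ])
    lambda[i] <- dominant_eigenvalue(
      build_projection_matrix(draw, strategy = strategy, ...))
  }
  qs <- quantile(lambda, c(0.025, 0.975), names = FALSE)
  structure(list(lambda = lambda, mean = mean(lambda),
                 lo95 = qs[1L], hi95 = qs[2L], strategy = strategy),
            class = "fitness_posterior")
}

#' @export
print.fitness_posterior <- function(x, ...) {
  lab <- if (is.null(x$strategy)) "wild type"
         else sprintf("leave parents at %d, %d sibling year(s)",
                      x$strategy$leave_parents_age, x$strategy$sibling_years)
  cat(sprintf("fitness posterior (%s): mean %.4f, 95%% CRI [%.4f, %.4f], %d draws\n",
              lab, x$mean, x$lo95, x$hi95, length(x$lambda)))
  invisible(x)
}
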