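STATE_ABB <- c("P", "S", "INB", "IB")

# Allowed destination sets (reference category last, as the final
# back-transformed transition).
DEST_SETS <- list(`1` = c(1L, 2L, 3L, 4L), `2` = c(2L, 3L, 4L),
                  `3` = c(3L, 4L), `4` = 4L)

#' Age-linear survival on the logit scale
#'
#' @param alpha,beta Logit intercept and per-age-class slope.
#' @param age Age class(es) in 1..7.
#' @return Survival probability `plogis(alpha + beta * age)`.
#' @export
survival_prob <- function(alpha, beta, age) {
  stopifnot(all(age >= 1), all(age <= MAX_AGE))
  stats::plogis(alpha + beta * age)
}

#' Multinomial-logit back-transformation of one transition row
#'
#' Maps `k - 1` unconstrained coefficients to `k` destination probabilities:
#' `psi_i = exp(eta_i) / (1 + sum_j exp(eta_j))` for the parameterized
#' destinations, and the final (reference) destination takes the remaining
#' mass `1 - sum(psi_i)`.  Computed with a log-sum-exp guard so large
#' coefficients never produce negative mass.
#'
#' @param eta Numeric vector of `k - 1` coefficients.
#' @return Probability vector of length `k` summing to 1; the reference
#'   destination is last.
#' @examples
#' transition_row(c(0, 0, 0))   # uniform over 4 destinations
#' transition_row(c(log(2), 0)) # (0.5, 0.25, 0.25)
#' @export
transition_row <- function(eta) {
  w <- c(eta, 0)
  w <- exp(w - max(w))
  w / sum(w)
}

#' Parameter layout of the multistate model
#'
#' The unconstrained parameter vector concatenates survival logit intercepts
#' and slopes for the four states, multinomial-logit transition coefficients
#' (from parents: ages 1-7; from siblings and from independent/nonbreeder:
#' ages 2-7; reference destination = the last allowed state), and the four
#' resighting probabilities on the probability scale.
#'
#' @param variant `"age_specific"` (default) or `"age_constant"` transitions.
#' @return A list with parameter `names`, index vectors per component, the
#'   sampler `blocks`, and an `eta_map` table (from, age, dest per eta
#'   entry).
#' @export
par_layout <- function(variant = c("age_specific", "age_constant")) {
  variant <- match.arg(variant)
  nm <- c(paste0("alpha_", STATE_ABB), paste0("beta_", STATE_ABB))
  eta_map <- NULL
  add_eta <- function(from, ages) {
    dests <- DEST_SETS[[as.character(from)]]
    free <- dests[-length(dests)]
    expand.grid(dest = free, age = ages, from = from)[, c("from", "age", "dest")]
  }
  if (variant == "age_specific") {
    eta_map <- rbind(add_eta(1L, 1:7), add_eta(2L, 2:7), add_eta(3L, 2:7))
  } else {
    eta_map <- rbind(add_eta(1L, NA), add_eta(2L, NA), add_eta(3L, NA))
  }
  eta_nm <- with(eta_map, ifelse(is.na(age),
                                 sprintf("eta_%s_to_%s", STATE_ABB[from], STATE_ABB[dest]),
                                 sprintf("eta_%s_a%d_to_%s", STATE_ABB[from], age, STATE_ABB[dest])))
  nm <- c(nm, eta_nm, paste0("p_", STATE_ABB))
  n_eta <- nrow(eta_map)
  idx_alpha <- 1:4
  idx_beta <- 5:8
  idx_eta <- 8L + seq_len(n_eta)
  idx_p <- 8L + n_eta + 1:4
  blocks <- c(list(survival = c(idx_alpha, idx_beta)),
              lapply(split(idx_eta, eta_map$from),
                     function(ix) ix),
              list(detection = idx_p))
  names(blocks) <- c("survival", paste0("trans_from_", STATE_ABB[1:3]),
                     "detection")
  list(variant = variant, names = nm, n_par = length(nm),
       idx_alpha = idx_alpha, idx_beta = idx_beta, idx_eta = idx_eta,
       idx_p = idx_p, eta_map = eta_map, blocks = blocks)
}

# Expand an age-constant parameter vector to the canonical age-specific
# layout consumed by the C++ kernel and par_to_tables().
expand_age_constant <- function(par) {
  out <- numeric(51)
  out[1:8] <- par[1:8]
  out[8 + rep(seq(0, 18, by = 3), each = 3) + rep(1:3, 7)] <- rep(par[9:11], 7)
  out[29 + rep(seq(0, 10, by = 2), each = 2) + rep(1:2, 6)] <- rep(par[12:13], 6)
  out[42:47] <- par[14]
  out[48:51] <- par[15:18]
  out
}

#' Derived probability tables from one parameter vector
#'
#' @param par Unconstrained parameter vector in the [par_layout()] order.
#' @param variant Model variant the vector belongs to.
#' @return List with `phi` (4 x 7 survival), `psi` (4 x 4 x 7 transitions,
#'   rows summing to 1), and `p` (length-4 resighting).
#' @export
par_to_tables <- function(par, variant = "age_specific") {
  if (variant == "age_constant") par <- expand_age_constant(par)
  phi <- outer(1:4, 1:7, function(s, a)
    stats::plogis(par[s] + par[s + 4L] * a))
  psi <- array(0, dim = c(4L, 4L, 7L))
  for (a in 1:7) {
    psi[1L, , a] <- transition_row(par[8L + (a - 1L) * 3L + 1:3])
    aa <- max(a, 2L)  # age-1 rows of unreachable states reuse age 2
    psi[2L, 2:4, a] <- transition_row(par[29L + (aa - 2L) * 2L + 1:2])
    psi[3L, 3:4, a] <- transition_row(par[41L + (aa - 1L)])
    psi[4L, 4L, a] <- 1
  }
  list(phi = phi, psi = psi, p = par[48:51])
}

#' Forward-algorithm log-likelihood of one capture history
#'
#' Marginalizes the latent state sequence (four living states plus dead) by
#' the hidden-Markov forward recursion, conditioning on first capture:
#' alive, with parents, detected, at the cohort year.  Emission is
#' `p[s]` for seeing a living bird in its state, `1 - p[s]` for missing it,
#' and 1 for never seeing a dead bird.
#'
#' @param obs Integer vector of observation codes for one bird, starting at
#'   (or before, padded with zeros) the marking occasion; the first nonzero
#'   entry must be state 1.
#' @param tables Probability tables from [par_to_tables()] (or a
#'   `truth_params`-derived equivalent: list of `phi`, `psi`, `p`).
#' @param id Individual label used in warnings.
#' @return Log-likelihood contribution; `-Inf` (with a warning) when the
#'   observations are impossible under the state graph.
#' @export
forward_loglik <- function(obs, tables, id = "?") {
  obs <- as.integer(obs)
  first <- match(TRUE, obs != 0L)
  if (is.na(first)) stop("history contains no sighting")
  if (obs[first] != STATE_PARENTS)
    stop("first sighting must be state 1 (with parents)")
  obs <- obs[first:length(obs)]
  L <- length(obs)
  if (L == 1L) return(0)
  phi <- tables$phi; psi <- tables$psi; p <- tables$p
  alpha <- c(1, 0, 0, 0, 0)
  ll <- 0
  for (t in 2:L) {
    age <- min(t - 1L, MAX_AGE)
    M <- matrix(0, 5, 5)
    M[1:4, 1:4] <- phi[, age] * psi[, , age]
    M[1:4, 5] <- 1 - phi[, age]
    M[5, 5] <- 1
    a_new <- as.numeric(alpha %*% M)
    o <- obs[t]
    if (o > 0L) {
      alpha <- numeric(5)
      alpha[o] <- a_new[o] * p[o]
    } else {
      alpha <- a_new * c(1 - p, 1)
    }
    cc <- sum(alpha)
    if (cc <= 0) {
      warning(sprintf("individual %s: observations impossible under the state graph", id))
      return(-Inf)
    }
    ll <- ll + log(cc)
    alpha <- alpha / cc
  }
  ll
}

# Collapse a capthist_set to unique trimmed histories with multiplicities,
# the form consumed by the C++ kernel.
prepare_histories <- function(ch) {
  stopifnot(inherits(ch, "capthist_set"))
  n <- nrow(ch$obs)
  j0 <- match(ch$cohort_year, ch$years)
  maxL <- max(ncol(ch$obs) - j0 + 1L)
  trimmed <- matrix(-1L, n, maxL)
  len <- integer(n)
  for (i in seq_len(n)) {
    v <- ch$obs[i, j0[i]:ncol(ch$obs)]
    len[i] <- length(v)
    trimmed[i, seq_along(v)] <- v
  }
  key <- apply(trimmed, 1L, paste0, collapse = ",")
  ux <- !duplicated(key)
  count <- as.numeric(table(factor(key, levels = key[ux])))
  list(obs = trimmed[ux, , drop = FALSE], len = len[ux], count = count)
}

#' Total log-likelihood of a capture-history set
#'
#' Fast path used by the sampler: unique histories are collapsed with
#' multiplicities and evaluated by a compiled forward recursion.  Agrees
#' with summing [forward_loglik()] over individuals.
#'
#' @param ch A `capthist_set` (or a prepared object from the sampler).
#' @param par Canonical (age-specific layout) parameter vector.
#' @return Total log-likelihood.
#' @export
loglik_capthist <- function(ch, par) {
  prep <- if (inherits(ch, "capthist_set")) prepare_histories(ch) else ch
  cpp_forward_loglik(par, prep$obs, prep$len, prep$count)
}

#' Log prior density
#'
#' Independent Normal(0, `prior_sd`) on every survival and transition
#' coefficient; Uniform(0, 1) on each resighting probability.  The default
#' `prior_sd = sqrt(1000)` is a vague prior on the logit scale.
#'
#' @param par Parameter vector.
#' @param layout A [par_layout()].
#' @param prior_sd Standard deviation of the Normal priors.
#' @return Log prior density (`-Inf` when a resighting probability leaves
#'   the unit interval).
#' @export
log_prior <- function(par, layout, prior_sd = sqrt(1000)) {
  p <- par[layout$idx_p]
  if (any(p < 0 | p > 1)) return(-Inf)
  coef <- par[c(layout$idx_alpha, layout$idx_beta, layout$idx_eta)]
  sum(stats::dnorm(coef, 0, prior_sd, log = TRUE))
}

#' MCMC configuration
#'
#' Defaults are a desk-scale protocol (3 chains of 30,000 iterations,
#' burn-in 10,000, thinning 10).  The full-scale protocol used for
#' publication-grade runs of such models is 450,000 iterations with a
#' burn-in of 90,000 and thinning 10.
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burnin Burn-in iterations discarded (adaptation happens here).
#' @param thin Thinning interval for retained draws.
#' @param seed Base RNG seed; chain `k` uses `seed + k - 1`.
#' @param target_accept Target acceptance rate of the adaptive blocks.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 30000L, n_burnin = 10000L,
                        thin = 10L, seed = 1L, target_accept = 0.25) {
  stopifnot(n_iter > n_burnin, thin >= 1L, n_chains >= 1L)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), target_accept = target_accept),
            class = "mcmc_config")
}

draw_init <- function(layout) {
  par <- numeric(layout$n_par)
  ncoef <- layout$n_par - 4L
  par[seq_len(ncoef)] <- rnorm(ncoef, 0, 0.1)
  par[layout$idx_p] <- runif(4L, 0.3, 0.9)
  par
}

#' Sample the posterior by adaptive block Metropolis
#'
#' Random-walk Metropolis in five blocks (survival coefficients, transition
#' coefficients per from-state, resighting probabilities) over the
#' marginalized forward log-likelihood.  During burn-in each block adapts a
#' global scale (Robbins-Monro towards `target_accept`) and a per-coordinate
#' spread estimated online from the chain, then both are frozen.  Fully
#' reproducible given `mcmc$seed`.
#'
#' @param histories A `capthist_set`.
#' @param mcmc An [mcmc_config()].
#' @param prior_sd Normal prior scale for coefficients (see [log_prior()]).
#' @param variant `"age_specific"` (default) or `"age_constant"`
#'   transitions.
#' @return An object of class `msfit`: retained parameter draws (`par`,
#'   with `chain` and `iter` tags), per-draw derived probability tables
#'   (`tables$phi`, `tables$psi`, `tables$p`), block acceptance rates, and
#'   the layout.
#' @export
sample_posterior <- function(histories, mcmc = mcmc_config(),
                             prior_sd = sqrt(1000),
                             variant = c("age_specific", "age_constant")) {
  variant <- match.arg(variant)
  layout <- par_layout(variant)
  prep <- prepare_histories(histories)
  post <- function(par) {
    lp <- log_prior(par, layout, prior_sd)
    if (!is.finite(lp)) return(-Inf)
    cpar <- if (variant == "age_constant") expand_age_constant(par) else par
    lp + cpp_forward_loglik(cpar, prep$obs, prep$len, prep$count)
  }
  blocks <- layout$blocks
  nb <- length(blocks)
  n_keep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin

  all_par <- vector("list", mcmc$n_chains)
  all_chain <- vector("list", mcmc$n_chains)
  all_iter <- vector("list", mcmc$n_chains)
  acc_rates <- matrix(NA_real_, mcmc$n_chains, nb,
                      dimnames = list(NULL, names(blocks)))

  for (chain in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + chain - 1L)
    par <- draw_init(layout)
    lp <- post(par)
    tries <- 0L
    while (!is.finite(lp) && tries < 100L) {
      par <- draw_init(layout); lp <- post(par); tries <- tries + 1L
    }
    if (!is.finite(lp)) stop("could not find finite starting values")

    # per-block adaptation state: global log-scale (Robbins-Monro) plus a
    # running covariance whose Cholesky factor shapes the proposal once
    # enough burn-in samples have accrued (Haario-style adaptive Metropolis)
    log_scale <- rep(log(0.2), nb)
    dims <- lengths(blocks)
    run_mean <- par
    run_cov <- lapply(dims, function(d) diag(1e-4, d))
    chol_prop <- lapply(dims, function(d) diag(0.1, d))
    n_seen <- 1L
    acc_count <- numeric(nb)
    prop_count <- numeric(nb)
    kept <- matrix(NA_real_, n_keep, layout$n_par,
                   dimnames = list(NULL, layout$names))
    k <- 0L

    for (it in seq_len(mcmc$n_iter)) {
      for (b in seq_len(nb)) {
        ix <- blocks[[b]]
        prop <- par
        prop[ix] <- par[ix] + exp(log_scale[b]) *
          as.vector(crossprod(chol_prop[[b]], rnorm(dims[b])))
        lp_prop <- post(prop)
        lr <- lp_prop - lp
        a_prob <- if (is.finite(lr)) min(1, exp(lr)) else 0
        if (runif(1L) < a_prob) {
          par <- prop; lp <- lp_prop
          acc_count[b] <- acc_count[b] + 1
        }
        prop_count[b] <- prop_count[b] + 1
        if (it <= mcmc$n_burnin) {
          gam <- 1 / max(10, it)^0.6
          log_scale[b] <- log_scale[b] + gam * (a_prob - mcmc$target_accept)
        }
      }
      if (it <= mcmc$n_burnin) {
        n_seen <- n_seen + 1L
        d <- par - run_mean
        run_mean <- run_mean + d / n_seen
        for (b in seq_len(nb)) {
          ix <- blocks[[b]]
          run_cov[[b]] <- run_cov[[b]] * ((n_seen - 2) / (n_seen - 1)) +
            tcrossprod(d[ix]) / n_seen
        }
        # refresh proposal shapes periodically once moderately informed
        if (it %% 200L == 0L && n_seen > 10L * max(dims)) {
          for (b in seq_len(nb)) {
            sig <- run_cov[[b]] + diag(1e-8, dims[b])
            ch <- tryCatch(chol(sig), error = function(e) NULL)
            if (!is.null(ch)) chol_prop[[b]] <- ch / sqrt(dims[b])
          }
        }
      } else if ((it - mcmc$n_burnin) %% mcmc$thin == 0L) {
        k <- k + 1L
        kept[k, ] <- par
      }
    }
    all_par[[chain]] <- kept
    all_chain[[chain]] <- rep(chain, n_keep)
    all_iter[[chain]] <- mcmc$n_burnin + seq_len(n_keep) * mcmc$thin
    acc_rates[chain, ] <- acc_count / prop_count
  }

  par_mat <- do.call(rbind, all_par)
  fit <- structure(
    list(par = par_mat, chain = unlist(all_chain), iter = unlist(all_iter),
         layout = layout, variant = variant, mcmc = mcmc,
         prior_sd = prior_sd, accept = acc_rates,
         tables = tables_from_draws(par_mat, variant)),
    class = "msfit")
  fit
}

# Per-draw derived probability tables for a matrix of parameter draws.
tables_from_draws <- function(par_mat, variant) {
  n <- nrow(par_mat)
  phi <- array(NA_real_, c(n, 4L, 7L))
  psi <- array(NA_real_, c(n, 4L, 4L, 7L))
  p <- matrix(NA_real_, n, 4L, dimnames = list(NULL, paste0("p_", STATE_ABB)))
  for (i in seq_len(n)) {
    tb <- par_to_tables(par_mat[i, ], variant)
    phi[i, , ] <- tb$phi
    psi[i, , , ] <- tb$psi
    p[i, ] <- tb$p
  }
  list(phi = phi, psi = psi, p = p)
}

#' @export
print.msfit <- function(x, ...) {
  cat(sprintf("msfit: %d draws (%d chains), %d parameters, %s transitions\n",
              nrow(x$par), length(unique(x$chain)), ncol(x$par), x$variant))
  cat("block acceptance rates (mean over chains):\n")
  print(round(colMeans(x$accept), 3))
  invisible(x)
}

#' Construct an `msfit`-compatible draws object from probability tables
#'
#' Useful for feeding externally constructed posteriors (or designed
#' scenarios) into the fitness and cost-benefit machinery.
#'
#' @param phi `n x 4 x 7` survival array.
#' @param psi `n x 4 x 4 x 7` transition array.
#' @param p `n x 4` resighting matrix.
#' @param chain Optional chain labels (default all 1).
#' @return An object of class `msfit` with `tables` populated (no raw
#'   parameter draws).
#' @export
draws_from_tables <- function(phi, psi, p, chain = NULL) {
  n <- dim(phi)[1]
  stopifnot(identical(dim(phi), c(n, 4L, 7L)),
            identical(dim(psi), c(n, 4L, 4L, 7L)),
            identical(dim(p), c(n, 4L)))
  if (is.null(chain)) chain <- rep(1L, n)
  structure(list(par = NULL, chain = chain, iter = seq_len(n),
                 layout = NULL, variant = "tables", mcmc = NULL,
                 accept = NULL, tables = list(phi = phi, psi = psi, p = p)),
            class = "msfit")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free PSRF: with `m` chains of length `n`, within-chain
#' variance `W`, between-chain variance `B` of the chain means,
#' `Rhat = sqrt(((n - 1)/n + B/(n W)) )` per scalar parameter.
#'
#' @param x An `msfit` (uses the raw parameter draws), or a numeric matrix
#'   of draws (rows) by scalar parameters (columns), or a numeric vector.
#' @param chain Chain labels per row (taken from the `msfit` when omitted).
#' @return Named numeric vector of R-hat values, with attribute `flagged`
#'   naming parameters exceeding 1.1.
#' @export
gelman_rubin <- function(x, chain = NULL) {
  if (inherits(x, "msfit")) {
    if (is.null(x$par)) stop("draws object carries no raw parameter draws")
    chain <- x$chain
    x <- x$par
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  chains <- unique(chain)
  m <- length(chains)
  if (m < 2L) stop("Gelman-Rubin requires at least 2 chains")
  n <- sum(chain == chains[1L])
  if (n < 10L) stop("need at least 10 retained draws per chain")
  if (!all(vapply(chains, function(cc) sum(chain == cc), 0L) == n))
    stop("chains must have equal lengths")
  rhat <- apply(x, 2L, function(v) {
    means <- tapply(v, chain, mean)
    vars <- tapply(v, chain, var)
    W <- mean(vars)
    B_over_n <- var(means)       # = B/n in the usual notation
    if (W <= 0) return(1)
    vhat <- (n - 1) / n * W + B_over_n
    sqrt(vhat / W)
  })
  names(rhat) <- colnames(x)
  attr(rhat, "flagged") <- names(rhat)[rhat > 1.1]
  rhat
}

# Long-form matrix of every derived probability, one column per scalar.
derived_matrix <- function(fit) {
  tb <- fit$tables
  n <- dim(tb$phi)[1]
  cols <- list()
  for (s in 1:4) for (a in 1:7)
    cols[[sprintf("phi_%s_a%d", STATE_ABB[s], a)]] <- tb$phi[, s, a]
  for (s in 1:3) {
    dests <- DEST_SETS[[as.character(s)]]
    for (d in dests) for (a in 1:7)
      cols[[sprintf("psi_%s_to_%s_a%d", STATE_ABB[s], STATE_ABB[d], a)]] <-
        tb$psi[, s, d, a]
  }
  for (s in 1:4) cols[[paste0("p_", STATE_ABB[s])]] <- tb$p[, s]
  do.call(cbind, cols)
}

#' Posterior summaries of every derived probability
#'
#' @param fit An `msfit`.
#' @param rhat Attach Gelman-Rubin diagnostics (needs >= 2 chains of raw
#'   draws)?
#' @return Data frame with columns `parameter`, `mean`, `lo95`, `hi95`
#'   (central 95\% credible interval) and, when available, `Rhat`.
#' @export
summarize_posterior <- function(fit, rhat = FALSE) {
  dm <- derived_matrix(fit)
  qs <- apply(dm, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(parameter = colnames(dm), mean = colMeans(dm),
                    lo95 = qs[1L, ], hi95 = qs[2L, ], row.names = NULL)
  if (rhat) {
    rh <- gelman_rubin(dm, chain = fit$chain)
    out$Rhat <- as.numeric(rh)
  }
  out
}

#' Posterior distribution of a difference, with credibility test
#'
#' Computes per-draw differences `a - b`, their posterior mean and central
#' 95\% credible interval, and `p_below`, the proportion of differences
#' strictly below zero (ties count as not-below).  The difference is deemed
#' credible when `p_below < 0.05` or `p_below > 0.95`.
#'
#' @param a,b Aligned numeric vectors of posterior draws.
#' @return List with `mean`, `lo95`, `hi95`, `p_below`, `credible`.
#' @export
credible_difference <- function(a, b) {
  if (length(a) != length(b)) stop("draw vectors must be aligned")
  d <- a - b
  qs <- quantile(d, c(0.025, 0.975), names = FALSE)
  p_below <- mean(d < 0)
  list(mean = mean(d), lo95 = qs[1L], hi95 = qs[2L],
       p_below = p_below, credible = p_below < 0.05 || p_below > 0.95)
}
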