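# Independent oracles and fixture builders shared across tests.

# Exhaustive path-enumeration likelihood for one trimmed history (first
# entry = state 1 at first capture): sums the joint probability of the
# observations over every latent state sequence in {1..4, dead}^(L-1).
# Deliberately brute force and structured nothing like the forward pass.
enum_loglik <- function(obs, tables) {
  L <- length(obs)
  if (L == 1L) return(0)
  phi <- tables$phi; psi <- tables$psi; p <- tables$p
  paths <- as.matrix(expand.grid(rep(list(1:5), L - 1L)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    states <- c(1L, paths[r, ])
    pr <- 1
    for (t in 2:L) {
      a <- min(t - 1L, 7L)
      s_prev <- states[t - 1L]; s_cur <- states[t]
      step <- if (s_prev == 5L) {
        if (s_cur == 5L) 1 else 0
      } else if (s_cur == 5L) {
        1 - phi[s_prev, a]
      } else {
        phi[s_prev, a] * psi[s_prev, s_cur, a]
      }
      emit <- if (obs[t] == 0L) {
        if (s_cur == 5L) 1 else 1 - p[s_cur]
      } else {
        if (s_cur == obs[t]) p[s_cur] else 0
      }
      pr <- pr * step * emit
      if (pr == 0) break
    }
    total <- total + pr
  }
  log(total)
}

# Random valid parameter vector in the canonical age-specific layout.
random_par <- function(coef_sd = 0.8) {
  c(rnorm(8, 0, coef_sd), rnorm(39, 0, coef_sd), runif(4, 0.2, 0.95))
}

# All valid trimmed observation vectors of a given length: first entry 1,
# later entries 0 or a code no smaller than any earlier nonzero code.
all_valid_histories <- function(len) {
  if (len == 1L) return(list(1L))
  tails <- expand.grid(rep(list(0:4), len - 1L))
  keep <- apply(tails, 1L, function(v) {
    seen <- c(1L, v[v != 0])
    all(diff(seen) >= 0L)
  })
  lapply(which(keep), function(r) c(1L, as.integer(tails[r, ])))
}

# Six hand-checkable histories for the descriptive summaries.
#   id  obs (from marking)        parent  sibling  ever_breeder
#   d1  1 1 3 4                   2       0        TRUE
#   d2  1 0 1 3 0                 3       0        FALSE
#   d3  1 2 2 3 0                 1       2        FALSE
#   d4  1 2 0 2 4                 1       3        TRUE
#   d5  1 0 0 0 0                 1       0        FALSE
#   d6  1 1 1 1 2                 4       1        FALSE
descriptives_fixture <- function() {
  obs <- rbind(
    c(1, 1, 3, 4, 0),
    c(1, 0, 1, 3, 0),
    c(1, 2, 2, 3, 0),
    c(1, 2, 0, 2, 4),
    c(1, 0, 0, 0, 0),
    c(1, 1, 1, 1, 2))
  capthist_set(paste0("d", 1:6), rep(1L, 6L), obs, years = 1:5)
}

# Small synthetic posterior: independent logit-normal jitter around a set
# of base tables, as draws_from_tables() input.
jitter_draws <- function(n, base, sd = 0.05, seed = 1) {
  set.seed(seed)
  jit <- function(x) plogis(qlogis(pmin(pmax(x, 1e-6), 1 - 1e-6)) +
                              rnorm(length(x), 0, sd))
  phi <- array(NA_real_, c(n, 4, 7))
  psi <- array(0, c(n, 4, 4, 7))
  p <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    phi[i, , ] <- jit(base$phi)
    p[i, ] <- jit(base$p)
    for (a in 1:7) for (s in 1:3) {
      dests <- which(base$psi[s, , a] > 0)
      w <- jit(base$psi[s, dests, a])
      psi[i, s, dests, a] <- w / sum(w)
    }
    psi[i, 4, 4, ] <- 1
  }
  draws_from_tables(phi, psi, p)
}

truth_tables <- function(truth = default_truth()) {
  list(phi = truth_phi(truth), psi = truth$psi, p = truth$p)
}
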