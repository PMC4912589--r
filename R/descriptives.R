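# Duration of the leading run of `state` in a trimmed observation vector,
# bridging unseen winters (0) that are flanked by the same state; trailing
# unseen winters never extend a run.  Returns the duration and the index
# just past the run.
run_duration <- function(v, state, start) {
  n <- length(v)
  last <- 0L
  i <- start
  while (i <= n) {
    if (v[i] == state) last <- i
    else if (v[i] != 0L) break
    i <- i + 1L
  }
  if (last == 0L) list(duration = 0L, next_idx = start)
  else list(duration = last - start + 1L, next_idx = last + 1L)
}

#' Family-association durations per individual
#'
#' The parent-association duration is the number of winters from marking
#' through the last winter assigned "with parents" before any other seen
#' state; unseen winters bridged by later "with parents" sightings count
#' towards it, while trailing unseen winters do not.  The sibling duration
#' is computed the same way over the "with siblings" run that follows the
#' parent phase.
#'
#' @param ch A `capthist_set`.
#' @return Object of class `duration_summary`: per-individual data frame
#'   (`id`, `parent_years`, `sibling_years`, `ever_breeder`), histogram of
#'   parent durations, fraction of parent durations of three years or
#'   less, and means with standard errors stratified by ever-breeder
#'   status (see [breeding_summary()]).
#' @examples
#' ch <- capthist_set("g1", 1L, matrix(c(1L, 0L, 1L, 3L), 1), validate = FALSE)
#' association_durations(ch)$individuals$parent_years  # 3: gap bridged
#' @export
association_durations <- function(ch) {
  stopifnot(inherits(ch, "capthist_set"))
  n <- nrow(ch$obs)
  j0 <- match(ch$cohort_year, ch$years)
  parent_years <- integer(n)
  sibling_years <- integer(n)
  for (i in seq_len(n)) {
    v <- ch$obs[i, j0[i]:ncol(ch$obs)]
    pr <- run_duration(v, STATE_PARENTS, 1L)
    parent_years[i] <- pr$duration
    # find the first seen state after the parent phase; a sibling run must
    # open it for any sibling years to accrue
    k <- pr$next_idx
    while (k <= length(v) && v[k] == 0L) k <- k + 1L
    if (k <= length(v) && v[k] == STATE_SIBLINGS)
      sibling_years[i] <- run_duration(v, STATE_SIBLINGS, k)$duration
  }
  ever_breeder <- apply(ch$obs == STATE_IND_B, 1L, any)
  ind <- data.frame(id = ch$id, parent_years = parent_years,
                    sibling_years = sibling_years,
                    ever_breeder = ever_breeder)
  hist_parent <- table(factor(parent_years, levels = 1:max(1, parent_years)))
  structure(list(
    individuals = ind,
    parent_histogram = hist_parent,
    frac_parent_le3 = mean(parent_years <= 3L),
    frac_sibling_le3 = if (any(sibling_years > 0L))
      mean(sibling_years[sibling_years > 0L] <= 3L) else NA_real_
  ), class = "duration_summary")
}

#' @export
print.duration_summary <- function(x, ...) {
  cat(sprintf("association durations for %d individuals\n",
              nrow(x$individuals)))
  cat(sprintf("  mean parent association: %.2f years (%.0f%% lasted <= 3)\n",
              mean(x$individuals$parent_years), 100 * x$frac_parent_le3))
  cat(sprintf("  birds with any sibling association: %d (%.0f%%)\n",
              sum(x$individuals$sibling_years > 0),
              100 * mean(x$individuals$sibling_years > 0)))
  invisible(x)
}

mean_se <- function(x) {
  c(mean = mean(x), se = if (length(x) > 1L) sd(x) / sqrt(length(x))
                         else NA_real_, n = length(x))
}

#' Breeding summary and durations stratified by breeder status
#'
#' An "ever-breeder" is any bird observed at least once in the
#' independent/breeder state.
#'
#' @param ch A `capthist_set`.
#' @return List: `n`, `n_breeders`, `prop_breeders`, and a data frame
#'   `durations` of mean and standard error of parent and sibling
#'   association years among ever-breeders and never-breeders.
#' @export
breeding_summary <- function(ch) {
  d <- association_durations(ch)$individuals
  strat <- function(sub) {
    pm <- mean_se(sub$parent_years); sm <- mean_se(sub$sibling_years)
    data.frame(parent_mean = pm["mean"], parent_se = pm["se"],
               sibling_mean = sm["mean"], sibling_se = sm["se"],
               n = nrow(sub), row.names = NULL)
  }
  breeders <- d[d$ever_breeder, , drop = FALSE]
  nonbreeders <- d[!d$ever_breeder, , drop = FALSE]
  durations <- rbind(
    cbind(group = "ever_breeder", strat(breeders)),
    cbind(group = "never_breeder", strat(nonbreeders)))
  list(n = nrow(d), n_breeders = nrow(breeders),
       prop_breeders = nrow(breeders) / nrow(d),
       durations = durations)
}
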