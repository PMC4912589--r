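#' famcr: multistate capture-recapture and fitness cost-benefit models
#'
#' Tools for analysing long-term family associations in marked bird
#' populations: a Bayesian multistate capture-recapture model over winter
#' encounter histories, matrix-projection fitness from its posterior, and a
#' cost-benefit simulator of forced family-departure strategies.
#'
#' @section Observable states:
#' Annual winter observations are coded
#' \describe{
#'   \item{0}{not seen}
#'   \item{1}{seen, with parents}
#'   \item{2}{seen, with at least one sibling (post-parents)}
#'   \item{3}{seen, independent/nonbreeder}
#'   \item{4}{seen, independent/breeder}
#' }
#' The latent process adds an unobservable dead state (internally 5).
#' Birds are marked in their first winter, always with at least one parent,
#' so every history opens in state 1, and birds never return to an earlier
#' state (state codes of an individual are non-decreasing through life).
#'
#' @docType package
#' @name famcr-package
#' @useDynLib famcr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif dnorm plogis quantile sd var cor setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Observable state codes; latent-only dead state.
STATE_PARENTS  <- 1L
STATE_SIBLINGS <- 2L
STATE_IND_NB   <- 3L
STATE_IND_B    <- 4L
STATE_DEAD     <- 5L
N_OBS_STATES   <- 4L
MAX_AGE        <- 7L   # terminal pooled "7+" age class

#' Map years since marking to age class
#'
#' Birds are marked at age 1 in their first winter; ages of 7 and above are
#' pooled into a single terminal class.
#'
#' @param year Integer vector of study years (same unit as `cohort_year`).
#' @param cohort_year Year of marking (age 1).
#' @return Integer age classes in `1:7`.
#' @examples
#' age_class(1983:1995, 1983)
#' @export
age_class <- function(year, cohort_year) {
  a <- as.integer(year) - as.integer(cohort_year) + 1L
  if (any(a < 1L)) stop("year precedes cohort_year")
  pmin(a, MAX_AGE)
}

#' Construct a set of capture histories
#'
#' The container is a list of parallel components: individual ids, cohort
#' (marking) years, and an integer observation matrix with one column per
#' study year and codes 0-4.
#'
#' @param id Character vector of individual identifiers.
#' @param cohort_year Integer vector, year each bird was marked (at age 1).
#' @param obs Integer matrix, one row per bird, one column per study year,
#'   entries in 0:4.
#' @param years Integer vector of study years labelling the columns of
#'   `obs`; defaults to `1:ncol(obs)`.
#' @param validate Check invariants (first sighting in state 1 at the cohort
#'   year, non-decreasing nonzero states, zeros before marking)?
#' @return An object of class `capthist_set`.
#' @export
capthist_set <- function(id, cohort_year, obs, years = NULL, validate = TRUE) {
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  if (is.null(years)) years <- seq_len(ncol(obs))
  years <- as.integer(years)
  if (length(id) != nrow(obs) || length(cohort_year) != nrow(obs))
    stop("id, cohort_year and rows of obs must align")
  if (length(years) != ncol(obs))
    stop("years must label the columns of obs")
  x <- structure(
    list(id = as.character(id), cohort_year = as.integer(cohort_year),
         obs = obs, years = years),
    class = "capthist_set")
  if (validate) validate_capthist(x)
  x
}

#' @export
print.capthist_set <- function(x, ...) {
  cat(sprintf("capthist_set: %d individuals, %d occasions (%d-%d)\n",
              nrow(x$obs), ncol(x$obs), min(x$years), max(x$years)))
  tab <- table(factor(x$obs, levels = 0:4))
  cat("observation codes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.capthist_set <- function(x) nrow(x$obs)

#' Validate capture-history invariants
#'
#' @param x A `capthist_set`.
#' @return Invisibly `x`; stops with an informative error naming the first
#'   offending individual otherwise.
#' @export
validate_capthist <- function(x) {
  obs <- x$obs
  if (any(is.na(obs)) || any(obs < 0L | obs > 4L))
    stop("observation codes must be integers in 0..4")
  for (i in seq_len(nrow(obs))) {
    j0 <- match(x$cohort_year[i], x$years)
    if (is.na(j0))
      stop(sprintf("individual %s: cohort year %d outside study years",
                   x$id[i], x$cohort_year[i]))
    if (j0 > 1L && any(obs[i, seq_len(j0 - 1L)] != 0L))
      stop(sprintf("individual %s: nonzero observation before marking",
                   x$id[i]))
    if (obs[i, j0] != STATE_PARENTS)
      stop(sprintf(
        "individual %s: first observation must be state 1 (with parents)",
        x$id[i]))
    seen <- obs[i, obs[i, ] != 0L]
    if (any(diff(seen) < 0L))
      stop(sprintf("individual %s: return to an earlier state", x$id[i]))
  }
  invisible(x)
}

#' Read capture histories from delimited text
#'
#' Expects a header `id,cohort_year,y<year>,...` with one column per study
#' year holding codes 0-4.
#'
#' @param path Path to a CSV file written by [write_capture_histories()] or
#'   of the same layout.
#' @return A validated [capthist_set()].
#' @export
read_capture_histories <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("id", "cohort_year")))
    stop("expected header: id, cohort_year, then one column per study year")
  years <- sub("^y", "", names(df)[-(1:2)])
  if (any(!grepl("^-?[0-9]+$", years)))
    stop("year columns must be named y<integer>")
  obs_chr <- as.matrix(df[, -(1:2), drop = FALSE])
  bad <- which(matrix(!(obs_chr %in% as.character(0:4)), nrow = nrow(df)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("malformed state code %s at row %d, column %s",
                 obs_chr[bad[1, 1], bad[1, 2]], bad[1, 1],
                 names(df)[-(1:2)][bad[1, 2]]))
  obs <- matrix(as.integer(obs_chr), nrow = nrow(df))
  capthist_set(df$id, as.integer(df$cohort_year), obs,
               years = as.integer(years))
}

#' Write capture histories to delimited text
#'
#' @param x A `capthist_set`.
#' @param path Output file path.
#' @return Invisibly `path`. Round-trips exactly through
#'   [read_capture_histories()].
#' @export
write_capture_histories <- function(x, path) {
  stopifnot(inherits(x, "capthist_set"))
  df <- data.frame(id = x$id, cohort_year = x$cohort_year,
                   x$obs, check.names = FALSE)
  names(df) <- c("id", "cohort_year", paste0("y", x$years))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export histories in MARK-style .inp format
#'
#' Writes each history as a contiguous string of codes 0-4 followed by a
#' frequency of 1, for cross-checking in external multistate software.
#'
#' @param x A `capthist_set`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_mark_inp <- function(x, path) {
  stopifnot(inherits(x, "capthist_set"))
  lines <- paste0(apply(x$obs, 1L, paste0, collapse = ""), " 1;")
  writeLines(lines, path)
  invisible(path)
}

#' Modal state of within-winter sightings
#'
#' When repeated sightings of one bird within a winter disagree, the annual
#' state is the most frequent sighting state.  Ties are broken by the fixed
#' precedence 1 > 2 > 4 > 3: family states over independent ones, and
#' breeder over nonbreeder, so the more informative state wins.
#'
#' @param states Integer vector of seen-state codes (1-4), one winter's
#'   sightings of one bird.  Must be non-empty; callers encode winters with
#'   no sightings as 0 themselves.
#' @return A single state code.
#' @examples
#' modal_state(c(1, 1, 3))  # 1
#' modal_state(c(2, 3))     # 2 (tie: family state preferred)
#' @export
modal_state <- function(states) {
  states <- as.integer(states)
  if (length(states) == 0L)
    stop("no within-winter sightings: encode unseen winters as 0")
  if (any(states < 1L | states > 4L))
    stop("sighting states must be in 1..4")
  counts <- tabulate(states, nbins = 4L)
  precedence <- c(1L, 2L, 4L, 3L)
  best <- precedence[which.max(counts[precedence])]
  best
}
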