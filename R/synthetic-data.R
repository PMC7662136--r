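# Synthetic inputs: an ACS-like child population, state school-closure
# durations, and the bundled published death table and expectancy anchors,
# so the whole pipeline runs with no external download.

# Approximate 2018 state resident-population shares (50 states + DC),
# normalised at use.  Any 51-vector can be substituted via population_spec().
state_population_weights <- c(
  AL = 4.90, AK = 0.74, AZ = 7.17, AR = 3.01, CA = 39.56, CO = 5.70,
  CT = 3.57, DE = 0.97, DC = 0.70, FL = 21.30, GA = 10.52, HI = 1.42,
  ID = 1.75, IL = 12.74, IN = 6.69, IA = 3.16, KS = 2.91, KY = 4.47,
  LA = 4.66, ME = 1.34, MD = 6.04, MA = 6.90, MI = 9.99, MN = 5.61,
  MS = 2.99, MO = 6.13, MT = 1.06, NE = 1.93, NV = 3.03, NH = 1.36,
  NJ = 8.91, NM = 2.10, NY = 19.54, NC = 10.38, ND = 0.76, OH = 11.69,
  OK = 3.94, OR = 4.19, PA = 12.81, RI = 1.06, SC = 5.08, SD = 0.88,
  TN = 6.77, TX = 28.70, UT = 3.16, VT = 0.63, VA = 8.52, WA = 7.54,
  WV = 1.81, WI = 5.81, WY = 0.58
)

#' Bundled state population shares
#'
#' The fixed 51-element share vector (50 states plus DC, normalised to sum
#' to 1) used by [generate_population()] to spread child counts across
#' states.
#'
#' @return Named numeric vector summing to 1.
#' @export
builtin_state_shares <- function() {
  state_population_weights / sum(state_population_weights)
}

#' Specification of the synthetic child population
#'
#' Defaults reproduce the modelled US public primary-school population of
#' 2020: 24.2 million children aged 5-11 (11.4M White, 4.3M Hispanic, 3.6M
#' Black, 4.9M Other), a male fraction of 0.512, school closures of median
#' 54.0 days (IQR 48-62.5) across 51 jurisdictions, and a baseline final
#' educational attainment of mean 13.7 (SD 2.1) years.  The attainment
#' moments are carried for reporting; the YLL model is a pure decrement
#' model and does not consume them.
#'
#' @param total_children Total child count; must match `sum(race_counts)`
#'   within rounding.
#' @param race_counts Named counts for White, Hispanic, Black, Other.
#' @param male_fraction Fraction of boys, in (0, 1).
#' @param n_states Number of jurisdictions.
#' @param closure_median,closure_iqr Target median and quartiles (days) of
#'   state school-closure durations.
#' @param attainment_mean,attainment_sd Baseline attainment moments, years.
#' @param state_shares Optional share vector of length `n_states`
#'   (normalised internally); defaults to [builtin_state_shares()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(total_children = 24.2e6,
                            race_counts = c(White = 11.4e6, Hispanic = 4.3e6,
                                            Black = 3.6e6, Other = 4.9e6),
                            male_fraction = 0.512,
                            n_states = 51,
                            closure_median = 54,
                            closure_iqr = c(48, 62.5),
                            attainment_mean = 13.7,
                            attainment_sd = 2.1,
                            state_shares = NULL) {
  if (male_fraction <= 0 || male_fraction >= 1) {
    stop("`male_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (any(race_counts < 0)) stop("race counts must be non-negative",
                                 call. = FALSE)
  if (abs(sum(race_counts) - total_children) > length(race_counts)) {
    stop("race counts must sum to `total_children` within rounding",
         call. = FALSE)
  }
  if (!(closure_iqr[1] <= closure_median && closure_median <= closure_iqr[2])) {
    stop("closure IQR must bracket the median", call. = FALSE)
  }
  if (is.null(state_shares)) {
    shares <- builtin_state_shares()
    if (n_states != length(shares)) {
      stop("supply `state_shares` when `n_states` is not 51", call. = FALSE)
    }
  } else {
    if (length(state_shares) != n_states || any(state_shares < 0)) {
      stop("`state_shares` must be a non-negative vector of length `n_states`",
           call. = FALSE)
    }
    shares <- state_shares / sum(state_shares)
    if (is.null(names(shares))) {
      names(shares) <- sprintf("S%02d", seq_len(n_states))
    }
  }
  structure(list(total_children = total_children, race_counts = race_counts,
                 male_fraction = male_fraction, n_states = n_states,
                 closure_median = closure_median, closure_iqr = closure_iqr,
                 attainment_mean = attainment_mean,
                 attainment_sd = attainment_sd,
                 state_shares = shares),
            class = "population_spec")
}

#' Generate the synthetic child population
#'
#' Counts are allocated across states (population-share weights), sexes
#' (`male_fraction`), races (spec counts) and single-year ages 5-11
#' (uniform).  Within each race the cell counts are rounded by the largest
#' -remainder method, so every race total -- and hence the grand total --
#' matches the specification exactly.  The allocation is deterministic; the
#' `seed` argument is accepted for interface symmetry with the other
#' generators.
#'
#' @param spec A [population_spec()].
#' @param seed Ignored (allocation is deterministic).
#' @return Data frame with columns `state`, `sex`, `race`, `age`, `count`.
#' @export
#' @examples
#' pop <- generate_population(population_spec())
#' sum(pop$count)  # 24,200,000 exactly
generate_population <- function(spec = population_spec(), seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  states <- names(spec$state_shares)
  cells <- expand.grid(state = states, sex = c("male", "female"),
                       age = 5:11, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  sex_frac <- ifelse(cells$sex == "male", spec$male_fraction,
                     1 - spec$male_fraction)
  w <- spec$state_shares[cells$state] * sex_frac / 7
  out <- lapply(names(spec$race_counts), function(race) {
    counts <- largest_remainder(w, spec$race_counts[[race]])
    data.frame(state = cells$state, sex = cells$sex, race = race,
               age = cells$age, count = counts,
               stringsAsFactors = FALSE)
  })
  pop <- do.call(rbind, out)
  rownames(pop) <- NULL
  pop
}

# Integer allocation of `total` across weights `w` (largest remainder).
largest_remainder <- function(w, total) {
  target <- w / sum(w) * total
  counts <- floor(target)
  short <- as.integer(round(total - sum(counts)))
  if (short > 0) {
    top <- order(target - counts, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Generate per-state school-closure durations
#'
#' A four-parameter scaled beta distribution is calibrated so its quartiles
#' match the specified median and IQR; the states then receive the rounded
#' distribution quantiles at evenly spaced probability points (a stratified
#' systematic sample), randomly assigned to state labels.  Stratification
#' guarantees that the sample median and IQR match the published targets
#' for every seed.  A degenerate spec (IQR collapsed onto the median)
#' yields identical durations for all states.
#'
#' @param spec A [population_spec()].
#' @param seed Optional integer seed controlling the state assignment.
#' @return Data frame with columns `state`, `closure_days` (integer days).
#' @export
generate_closure_days <- function(spec = population_spec(), seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  states <- names(spec$state_shares)
  n <- spec$n_states
  if (spec$closure_iqr[1] == spec$closure_median &&
      spec$closure_iqr[2] == spec$closure_median) {
    days <- rep(as.integer(round(spec$closure_median)), n)
  } else {
    cal <- calibrate_closure_beta(spec$closure_median, spec$closure_iqr)
    p <- (seq_len(n) - 0.5) / n
    days <- as.integer(round(cal$lower +
                               (cal$upper - cal$lower) *
                                 stats::qbeta(p, cal$alpha, cal$beta)))
    perm <- with_substream(seed, "closure-days", sample.int(n))
    days <- days[perm]
  }
  data.frame(state = states, closure_days = days, stringsAsFactors = FALSE)
}

# Fit (lower, upper, alpha, beta) of a scaled beta to three target
# quartiles by least squares on a log parameterisation.
calibrate_closure_beta <- function(med, iqr) {
  targets <- c(iqr[1], med, iqr[2])
  objective <- function(par) {
    lower <- par[1]
    width <- exp(par[2])
    a <- exp(par[3]); b <- exp(par[4])
    qs <- lower + width * stats::qbeta(c(0.25, 0.5, 0.75), a, b)
    sum((qs - targets)^2)
  }
  fit <- stats::optim(c(iqr[1] - (med - iqr[1]), log(4 * (iqr[2] - iqr[1])),
                        log(2), log(3)),
                      objective, control = list(maxit = 10000,
                                                reltol = 1e-14))
  fit <- stats::optim(fit$par, objective,
                      control = list(maxit = 10000, reltol = 1e-14))
  list(lower = fit$par[1], upper = fit$par[1] + exp(fit$par[2]),
       alpha = exp(fit$par[3]), beta = exp(fit$par[4]))
}

#' The bundled published age-band death table
#'
#' Returns the table of US COVID-19 deaths through early June 2020 by sex
#' and 10-year age band (midpoint labels 0, 1, 10, ..., 85), with the
#' reported annual death probability, band life expectancy, and printed YLL
#' (thousands) per band.  The running text of the source gives the total
#' through May 30, 2020 while its table is titled through June 3, 2020; the
#' bundled data follow the printed table, whose deaths sum to the quoted
#' 88,241.
#'
#' @return A [death_band_table()].
#' @export
builtin_death_table <- function() {
  path <- system.file("extdata", "covid_deaths_by_age_2020.csv",
                      package = "schoolyll", mustWork = TRUE)
  read_death_bands(path)
}

#' Life-expectancy anchors from the bundled death table
#'
#' The published table's life-expectancy column provides 11 `(age, e(age))`
#' anchors per sex (76.0 years at age 0 for males, 81.0 for females, down
#' to 5.9 and 7.0 at age 85), from which
#' [life_table_from_anchors()] reconstructs full single-year tables.
#'
#' @return Named list (`male`, `female`) of anchor data frames.
#' @export
builtin_expectancy_anchors <- function() {
  tbl <- builtin_death_table()
  lapply(stats::setNames(c("male", "female"), c("male", "female")),
         function(s) {
           rows <- tbl$sex == s
           data.frame(age = tbl$midpoint_age[rows], ex = tbl$ex[rows])
         })
}

#' Default sex-specific life tables
#'
#' Convenience wrapper reconstructing the male and female life tables from
#' the bundled expectancy anchors.
#'
#' @inheritParams life_table_from_anchors
#' @return Named list (`male`, `female`) of [life_table()]s.
#' @export
builtin_life_tables <- function(method = "piecewise", omega = 100) {
  anchors <- builtin_expectancy_anchors()
  list(male = life_table_from_anchors(anchors$male, sex = "male",
                                      method = method, omega = omega),
       female = life_table_from_anchors(anchors$female, sex = "female",
                                        method = method, omega = omega))
}
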