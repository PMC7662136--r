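# Scenario assembly: closed-schools (direct + education-mediated YLL)
# versus the open-schools counterfactual, and the full model run.

#' Open-schools counterfactual YLL draws
#'
#' Elementwise product of the undercount-corrected direct-YLL draws with
#' fresh mortality-ratio draws from a PERT distribution.  The default
#' triple (minimum 1, mode 1.93, maximum 2.85) spans the published range of
#' school-closure mortality effects: 1 if young children do not measurably
#' influence spread, 2.85 from the largest published closure-effect
#' estimate, with the mode the average of the two published ratios.
#'
#' @param closed_direct Draws of corrected direct YLL, person-years.
#' @param ratio A [pert_params()] triple for the school-opening mortality
#'   ratio.
#' @param seed Optional integer seed (isolated substream, independent of
#'   the undercount draws).
#' @return Vector of open-scenario YLL draws, paired with `closed_direct`.
#' @export
open_scenario_yll <- function(closed_direct,
                              ratio = pert_params(1, 1.93, 2.85),
                              seed = NULL) {
  if (!is.numeric(closed_direct) || length(closed_direct) == 0) {
    stop("`closed_direct` must be a non-empty numeric vector", call. = FALSE)
  }
  ratios <- with_substream(seed, "mortality-ratio",
                           sample_pert(length(closed_direct), ratio))
  closed_direct * ratios
}

#' Compare the closed- and open-schools scenarios
#'
#' The headline decision quantity: the probability, over paired Monte Carlo
#' draws, that total YLL under school closure (corrected direct plus
#' education-mediated) exceeds total YLL under schools remaining open --
#' algebraically, `P(education > closed_direct * (ratio - 1))`.
#'
#' @param closed_direct,education,open_total Paired draw vectors of equal
#'   length, person-years.
#' @param level Credible-interval mass for the summaries.
#' @return A list of class `scenario_comparison`: `probability`, and
#'   [summarize_draws()] objects `closed` (direct + education) and `open`.
#' @export
compare_scenarios <- function(closed_direct, education, open_total,
                              level = 0.95) {
  if (length(closed_direct) != length(education) ||
      length(education) != length(open_total)) {
    stop("scenario draw vectors must be paired (equal length)",
         call. = FALSE)
  }
  closed_total <- closed_direct + education
  structure(list(probability = prob_greater(closed_total, open_total),
                 closed = summarize_draws(closed_total, level),
                 open = summarize_draws(open_total, level)),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("P(closed-schools YLL > open-schools YLL) = %.3f\n",
              x$probability))
  cat("  closed: "); print(x$closed)
  cat("  open:   "); print(x$open)
  invisible(x)
}

#' Run the full closure-versus-open model
#'
#' Orchestrates every stage: synthetic inputs (unless supplied), direct YLL
#' from the death table with undercount correction, education-mediated YLL
#' per discount rate, the open-schools counterfactual, and the exceedance
#' probabilities.  All randomness descends from `seed` through labelled
#' substreams, so stages are individually reproducible.  Direct-YLL draws
#' are shared between the closed and open scenarios within a draw (paired
#' comparison) unless `paired = FALSE`, in which case the open scenario
#' receives independent undercount draws.  Direct YLL is not discounted --
#' the deaths occurred in 2020 -- so only the education component responds
#' to the discount rate.
#'
#' @param n_draws Monte Carlo draws used throughout.
#' @param seed Integer master seed.
#' @param discount_rates Annual discount rates for the education pathway.
#' @param spec [population_spec()] used when `pop` or `closures` are NULL.
#' @param pop,closures Optional population and closure tables (see
#'   [population_education_yll()]).
#' @param death_table A [death_band_table()]; default the bundled published
#'   table.
#' @param tables Optional named list of life tables; default reconstructed
#'   from the bundled anchors.
#' @param effect,mort_effect,undercount,mortality_ratio Model parameters.
#' @param horizon Oldest age contributing education life-years.
#' @param ci_level Credible-interval mass.
#' @param paired Share direct-YLL draws between scenarios (default TRUE).
#' @return An object of class `school_closure_model`: per-rate education
#'   summaries, direct/open/incremental summaries, exceedance
#'   probabilities, and the underlying draws.
#' @export
#' @examples
#' \donttest{
#' m <- run_full_model(n_draws = 500, seed = 1)
#' print(m)
#' }
run_full_model <- function(n_draws = 1e4, seed = 1,
                           discount_rates = c(0, 0.005, 0.03),
                           spec = population_spec(),
                           pop = NULL, closures = NULL,
                           death_table = builtin_death_table(),
                           tables = NULL,
                           effect = attainment_effect(),
                           mort_effect = education_mortality_effect(),
                           undercount = pert_params(1, 1.22, 2.44),
                           mortality_ratio = pert_params(1, 1.93, 2.85),
                           horizon = 85, ci_level = 0.95, paired = TRUE) {
  n_draws <- check_count(n_draws, "n_draws")
  if (is.null(pop)) pop <- generate_population(spec)
  if (is.null(closures)) closures <- generate_closure_days(spec, seed = seed)
  if (is.null(tables)) tables <- builtin_life_tables()

  base <- yll_from_deaths(death_table, tables = tables)
  closed_direct <- corrected_direct_yll(base$total, undercount,
                                        n = n_draws, seed = seed)
  open_base <- if (paired) closed_direct else {
    corrected_direct_yll(base$total, undercount, n = n_draws,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  }
  open_total <- open_scenario_yll(open_base, mortality_ratio, seed = seed)

  params <- draw_model_params(effect, mort_effect, n = n_draws, seed = seed)
  education <- lapply(discount_rates, function(rate) {
    population_education_yll(pop, closures, tables, rate = rate,
                             horizon = horizon, draws = params)
  })
  names(education) <- format_rate(discount_rates)

  comparisons <- lapply(education, function(edu) {
    compare_scenarios(closed_direct, edu, open_total, level = ci_level)
  })

  structure(list(
    summaries = list(
      education = lapply(education, summarize_draws, level = ci_level),
      closed_direct = summarize_draws(closed_direct, level = ci_level),
      open = summarize_draws(open_total, level = ci_level),
      incremental = summarize_draws(open_total - open_base,
                                    level = ci_level),
      closed_total = lapply(comparisons, `[[`, "closed")
    ),
    probabilities = vapply(comparisons, `[[`, 0, "probability"),
    draws = list(closed_direct = closed_direct, open = open_total,
                 education = education),
    inputs = list(n_draws = n_draws, seed = seed,
                  discount_rates = discount_rates,
                  base_direct_yll = base$total, horizon = horizon,
                  ci_level = ci_level, paired = paired,
                  total_deaths = total_deaths(death_table),
                  children = sum(pop$count),
                  effect = effect, mort_effect = mort_effect,
                  undercount = undercount,
                  mortality_ratio = mortality_ratio)),
    class = "school_closure_model")
}

format_rate <- function(rates) sprintf("%g%%", 100 * rates)

#' @export
print.school_closure_model <- function(x, ...) {
  inp <- x$inputs
  cat(sprintf("School-closure YLL model: %s draws, seed %s\n",
              format(inp$n_draws, big.mark = ","),
              if (is.null(inp$seed)) "none" else inp$seed))
  cat(sprintf("  %s recorded deaths -> %s person-years direct YLL\n",
              format(inp$total_deaths, big.mark = ","),
              format(round(inp$base_direct_yll), big.mark = ",")))
  fmt <- function(s) sprintf("%5.2f M (%g%% CI, %.2f-%.2f M)",
                             s$median / 1e6, 100 * s$level,
                             s$ci_low / 1e6, s$ci_high / 1e6)
  cat("  corrected direct YLL:  ", fmt(x$summaries$closed_direct), "\n")
  cat("  open-schools YLL:      ", fmt(x$summaries$open), "\n")
  cat("  incremental (open):    ", fmt(x$summaries$incremental), "\n")
  cat("  education YLL by discount rate:\n")
  for (nm in names(x$summaries$education)) {
    cat(sprintf("    %-5s %s   P(closed > open) = %.3f\n", nm,
                fmt(x$summaries$education[[nm]]), x$probabilities[[nm]]))
  }
  invisible(x)
}

#' Tabular summary of a model run
#'
#' @param object A `school_closure_model`.
#' @param ... Unused.
#' @return Data frame with one row per reported quantity: `quantity`,
#'   `discount_rate`, `median`, `ci_low`, `ci_high`, `probability`.
#' @export
summary.school_closure_model <- function(object, ...) {
  s <- object$summaries
  rates <- object$inputs$discount_rates
  row <- function(quantity, rate, ds, prob = NA_real_) {
    data.frame(quantity = quantity, discount_rate = rate,
               median = ds$median, ci_low = ds$ci_low,
               ci_high = ds$ci_high, probability = prob)
  }
  out <- rbind(
    row("closed_direct_yll", 0, s$closed_direct),
    row("open_yll", 0, s$open),
    row("incremental_open_yll", 0, s$incremental))
  for (i in seq_along(rates)) {
    nm <- names(s$education)[i]
    out <- rbind(out,
                 row("education_yll", rates[i], s$education[[nm]]),
                 row("closed_total_yll", rates[i], s$closed_total[[nm]],
                     object$probabilities[[nm]]))
  }
  rownames(out) <- NULL
  out
}

#' Write a model report to disk
#'
#' Writes `summary.csv` (the [summary.school_closure_model()] table) and
#' `report.json` (summaries, probabilities and inputs) into `dir`.
#'
#' @param x A `school_closure_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_model_report <- function(x, dir) {
  stopifnot(inherits(x, "school_closure_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "summary.csv")
  utils::write.csv(summary(x), csv, row.names = FALSE)
  json <- file.path(dir, "report.json")
  strip <- function(obj) {
    if (inherits(obj, "draw_summary")) return(unclass(obj))
    if (is.list(obj)) return(lapply(obj, strip))
    obj
  }
  payload <- list(
    summaries = strip(x$summaries),
    probabilities = as.list(x$probabilities),
    inputs = x$inputs[c("n_draws", "seed", "discount_rates",
                        "base_direct_yll", "horizon", "ci_level",
                        "paired", "total_deaths", "children")])
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' Density plot of scenario YLL distributions
#'
#' Mirrors the distributional summary figure of the analysis: probability
#' densities of total YLL under the closed-schools scenario at each
#' discount rate and under the open-schools counterfactual.  Requires
#' ggplot2.
#'
#' @param x A `school_closure_model`.
#' @return A ggplot object.
#' @export
plot_yll_distributions <- function(x) {
  stopifnot(inherits(x, "school_closure_model"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- x$draws
  frames <- lapply(names(d$education), function(nm) {
    data.frame(scenario = sprintf("closed (discount %s)", nm),
               yll = (d$closed_direct + d$education[[nm]]) / 1e6)
  })
  frames <- c(frames, list(data.frame(scenario = "open",
                                      yll = d$open / 1e6)))
  df <- do.call(rbind, frames)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$yll, fill = .data$scenario)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "Years of life lost (millions)", y = "Density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
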