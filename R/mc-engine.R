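# Seeded Monte Carlo primitives shared by every model stage.

#' PERT distribution parameters
#'
#' A PERT distribution is a beta distribution rescaled to \[`minimum`,
#' `maximum`\] and parameterised by its most likely (modal) value.  With the
#' classic shape of 4 the mode receives roughly four-fold the probability
#' weight of the extremes, which is why the family is the conventional choice
#' for expert-elicited three-point estimates such as the death-undercount
#' ratio and the school-opening mortality ratio used in this model.
#'
#' @param minimum Smallest attainable value.
#' @param mode Most likely value; `minimum <= mode <= maximum`.
#' @param maximum Largest attainable value.
#' @param shape Modal weight (dimensionless, > 0); 4 is the classic PERT.
#'
#' @return An object of class `pert_params`.
#' @seealso [sample_pert()]
#' @export
#' @examples
#' pert_params(1, 1.22, 2.44)
pert_params <- function(minimum, mode, maximum, shape = 4) {
  stopifnot(is.numeric(minimum), is.numeric(mode), is.numeric(maximum),
            length(minimum) == 1, length(mode) == 1, length(maximum) == 1)
  if (!(minimum <= mode && mode <= maximum)) {
    stop("PERT triple must satisfy minimum <= mode <= maximum", call. = FALSE)
  }
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0) {
    stop("PERT `shape` must be a positive number", call. = FALSE)
  }
  structure(list(minimum = minimum, mode = mode, maximum = maximum,
                 shape = shape),
            class = "pert_params")
}

#' @export
print.pert_params <- function(x, ...) {
  cat(sprintf("PERT(min = %g, mode = %g, max = %g, shape = %g); mean = %.4f\n",
              x$minimum, x$mode, x$maximum, x$shape, pert_mean(x)))
  invisible(x)
}

#' Closed-form mean of a PERT distribution
#'
#' `(minimum + shape * mode + maximum) / (shape + 2)`, the classical
#' three-point estimate.  Used as an independent check on sampled moments.
#'
#' @param params A [pert_params()] object.
#' @return The distribution mean.
#' @export
pert_mean <- function(params) {
  stopifnot(inherits(params, "pert_params"))
  (params$minimum + params$shape * params$mode + params$maximum) /
    (params$shape + 2)
}

#' Draw from a PERT distribution
#'
#' Implemented as a scaled beta with
#' `alpha = 1 + shape (mode - min) / (max - min)` and
#' `beta  = 1 + shape (max - mode) / (max - min)`.  The degenerate triple
#' `min = mode = max` returns a constant vector.
#'
#' @param n Number of draws (>= 1).
#' @param params A [pert_params()] object.
#' @param seed Optional integer; when given, draws come from an isolated,
#'   reproducible substream and the caller's RNG state is left untouched.
#'
#' @return Numeric vector of `n` draws, all within `[minimum, maximum]`.
#' @export
#' @examples
#' mean(sample_pert(1e4, pert_params(1, 1.22, 2.44), seed = 1))
sample_pert <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "pert_params"))
  n <- check_count(n, "n")
  with_substream(seed, "pert", {
    width <- params$maximum - params$minimum
    if (width == 0) {
      rep(params$mode, n)
    } else {
      a <- 1 + params$shape * (params$mode - params$minimum) / width
      b <- 1 + params$shape * (params$maximum - params$mode) / width
      params$minimum + width * stats::rbeta(n, a, b)
    }
  })
}

#' Truncated-normal parameters
#'
#' @param mean Location of the untruncated normal.
#' @param sd Standard deviation of the untruncated normal (>= 0).
#' @param lower,upper Truncation bounds; `lower < upper`.  With `sd = 0` the
#'   point mass at `mean` must lie inside the bounds.
#'
#' @return An object of class `trunc_normal_params`.
#' @export
trunc_normal_params <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1,
            length(sd) == 1)
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (!(lower < upper)) stop("`lower` must be below `upper`", call. = FALSE)
  if (sd == 0 && (mean < lower || mean > upper)) {
    stop("zero-variance distribution has its mean outside [lower, upper]",
         call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "trunc_normal_params")
}

#' Draw from a truncated normal
#'
#' Exact inverse-CDF sampling: uniforms on the truncated probability range
#' pushed through [stats::qnorm()].  `sd = 0` returns constant draws.
#'
#' @inheritParams sample_pert
#' @param params A [trunc_normal_params()] object.
#' @return Numeric vector of `n` draws within `[lower, upper]`.
#' @export
sample_trunc_normal <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "trunc_normal_params"))
  n <- check_count(n, "n")
  with_substream(seed, "truncnorm", {
    if (params$sd == 0) {
      rep(params$mean, n)
    } else {
      p_lo <- stats::pnorm(params$lower, params$mean, params$sd)
      p_hi <- stats::pnorm(params$upper, params$mean, params$sd)
      stats::qnorm(stats::runif(n, p_lo, p_hi), params$mean, params$sd)
    }
  })
}

#' Summarise Monte Carlo draws
#'
#' Median and equal-tailed credible interval at quantiles `(1 - level) / 2`
#' and `1 - (1 - level) / 2`.  Equal-tailed (not highest-posterior-density)
#' intervals are used throughout so that interval level is a free parameter.
#'
#' @param draws Non-empty numeric vector.
#' @param level Interval mass, in (0, 1); default 0.95.
#' @return A `draw_summary` list: `median`, `ci_low`, `ci_high`, `level`,
#'   `n`.
#' @export
#' @examples
#' summarize_draws(rnorm(1000), level = 0.95)
summarize_draws <- function(draws, level = 0.95) {
  if (!is.numeric(draws) || length(draws) == 0) {
    stop("`draws` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(draws, c(alpha, 0.5, 1 - alpha), names = FALSE)
  structure(list(median = qs[2], ci_low = qs[1], ci_high = qs[3],
                 level = level, n = length(draws)),
            class = "draw_summary")
}

#' @export
print.draw_summary <- function(x, ...) {
  cat(sprintf("median %.4g (%g%% CI, %.4g-%.4g) over %d draws\n",
              x$median, 100 * x$level, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Exceedance probability over paired draws
#'
#' Fraction of paired Monte Carlo draws where `a` strictly exceeds `b`.
#'
#' @param a,b Numeric vectors of equal length (paired draws).
#' @return A fraction in \[0, 1\].
#' @export
prob_greater <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("`a` and `b` must be numeric", call. = FALSE)
  }
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length (paired draws)", call. = FALSE)
  }
  if (length(a) == 0) stop("empty draw vectors", call. = FALSE)
  mean(a > b)
}

# --- seed substreams -------------------------------------------------------

# One master seed spawns labelled substreams so that the draw sequence of one
# parameter never depends on how many draws another parameter consumed.
substream_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer(((seed %% 2147483647) * 69069 + h) %% 2147483646 + 1)
}

# Evaluate `expr` under the substream RNG, restoring the caller's RNG state.
# A NULL seed means "use the ambient RNG stream".
with_substream <- function(seed, label, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

check_count <- function(n, name) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 ||
      n != floor(n)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  as.integer(n)
}
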