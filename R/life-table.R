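# Period life tables: construction, remaining (and discounted) life
# expectancy, and proportional scaling of annual death probabilities.

#' Construct a period life table
#'
#' A period life table carries the annual death probability `q(x)` for each
#' integer age `x = 0, ..., omega`, with the terminal `q(omega) = 1` closing
#' the table.  Remaining life expectancy is computed on construction as the
#' curtate expectation plus a half year for within-year survival:
#' `e(x) = sum_{t >= 1} S(x + t) / S(x) + 0.5` where
#' `S(x) = prod_{k < x} (1 - q(k))`.
#'
#' @param age Integer ages `0:omega`, contiguous.
#' @param qx Annual death probabilities in \[0, 1\], aligned with `age`;
#'   `qx` at the terminal age must equal 1.
#' @param sex `"male"` or `"female"`.
#' @param race Race/ethnicity label; `"All"` denotes the table not
#'   conditioned on race.
#'
#' @return An object of class `life_table` with elements `age`, `qx`, `ex`,
#'   `sex`, `race`, `omega`.
#' @export
#' @examples
#' lt <- life_table(0:3, c(0.1, 0.2, 0.5, 1), sex = "male")
#' remaining_life(lt, 0)
life_table <- function(age, qx, sex = c("male", "female"), race = "All") {
  sex <- match.arg(sex)
  if (!is.numeric(age) || !identical(as.integer(age), seq.int(0L, length.out = length(age)))) {
    stop("`age` must be the contiguous integer sequence 0:omega", call. = FALSE)
  }
  if (!is.numeric(qx) || length(qx) != length(age)) {
    stop("`qx` must be numeric and aligned with `age`", call. = FALSE)
  }
  if (anyNA(qx) || any(qx < 0) || any(qx > 1)) {
    stop("all `qx` must lie in [0, 1]", call. = FALSE)
  }
  if (qx[length(qx)] != 1) {
    stop("terminal death probability q(omega) must equal 1", call. = FALSE)
  }
  structure(list(age = as.integer(age), qx = as.numeric(qx),
                 ex = curtate_expectancy(qx),
                 sex = sex, race = race,
                 omega = length(qx) - 1L),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> %s, %s; ages 0-%d; e(0) = %.2f years\n",
              x$sex, x$race, x$omega, x$ex[1]))
  invisible(x)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  data.frame(age = x$age, sex = x$sex, race = x$race, qx = x$qx, ex = x$ex)
}

# e(x) for every age via the backward recursion
# f(x) = (1 - q(x)) (1 + f(x + 1)), f at omega = 0; e = f + 0.5.
curtate_expectancy <- function(qx) {
  n <- length(qx)
  e <- numeric(n)
  f <- 0
  if (n > 1) {
    for (x in (n - 1):1) {
      f <- (1 - qx[x]) * (1 + f)
      e[x] <- f
    }
  }
  e + 0.5
}

#' Remaining life expectancy at an age
#'
#' @param lt A [life_table()].
#' @param age Integer age within `0:omega`.
#' @return `e(age)` in years.
#' @export
remaining_life <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  if (!is.numeric(age) || length(age) != 1 || age != floor(age) ||
      age < 0 || age > lt$omega) {
    stop(sprintf("`age` must be an integer within 0-%d", lt$omega),
         call. = FALSE)
  }
  lt$ex[age + 1]
}

#' Scale annual death probabilities by a hazard multiplier
#'
#' Applies `q'(x) = min(1, q(x) * multiplier)` for all `x >= from_age`,
#' leaving younger ages untouched, and recomputes expectancies.  This is the
#' mechanism through which an education-derived relative risk acts on the
#' life course: losing `L` years of attainment at relative risk `RR` per
#' year multiplies annual mortality by `RR^-L` (see
#' [hazard_multiplier()]).  The terminal `q(omega) = 1` is preserved even
#' for multipliers below 1 (the closed table end is a grid convention, not a
#' mortality rate).
#'
#' For the annual probabilities (q below ~0.1) and multipliers (below ~1.5)
#' arising in this model, proportional scaling of `q` differs from scaling
#' the continuous hazard by under 1%.
#'
#' @param lt A [life_table()].
#' @param multiplier Positive hazard multiplier.
#' @param from_age First age (years) at which the multiplier applies.
#' @return A new `life_table`.
#' @export
adjust_hazard <- function(lt, multiplier, from_age = 0) {
  stopifnot(inherits(lt, "life_table"))
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0) {
    stop("`multiplier` must be a positive number", call. = FALSE)
  }
  qx <- lt$qx
  idx <- lt$age >= from_age
  qx[idx] <- pmin(1, qx[idx] * multiplier)
  qx[length(qx)] <- 1
  life_table(lt$age, qx, sex = lt$sex, race = lt$race)
}

#' Discounted remaining life expectancy
#'
#' Expected present value of future life years at `age`:
#' `0.5 + sum_t S(age + t) / S(age) * (1 + rate)^-t`, the immediate half
#' year being undiscounted.  `horizon` caps the ages over which life-years
#' are counted (years lived beyond `horizon` do not accrue); the model's
#' education pathway uses `horizon = 85`, the maximum age of death assumed
#' in the direct-mortality accounting, so that both arms of the comparison
#' count the same life span.
#'
#' @param lt A [life_table()].
#' @param age Integer age within `0:omega`.
#' @param rate Annual discount rate (>= 0); 0 reproduces
#'   [remaining_life()] exactly (when `horizon` is unlimited).
#' @param horizon Oldest age contributing life-years; `Inf` for the full
#'   table.
#' @return Discounted years of remaining life.
#' @export
discounted_remaining_life <- function(lt, age, rate = 0, horizon = Inf) {
  stopifnot(inherits(lt, "life_table"))
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0) {
    stop("`rate` must be a non-negative annual fraction", call. = FALSE)
  }
  if (!is.numeric(age) || length(age) != 1 || age != floor(age) ||
      age < 0 || age > lt$omega) {
    stop(sprintf("`age` must be an integer within 0-%d", lt$omega),
         call. = FALSE)
  }
  t_max <- min(lt$omega, horizon) - age
  if (t_max < 1) return(0.5)
  v <- 1 / (1 + rate)
  surv <- cumprod(1 - lt$qx[(age + 1):(age + t_max)])  # S(age+t)/S(age)
  0.5 + sum(surv * v^seq_len(t_max))
}

#' Build a life table from printed life-expectancy anchors
#'
#' Reconstructs a full single-year table from a handful of
#' `(age, e(age))` anchor pairs, such as the life-expectancy column of a
#' published age-band table, so the model needs no external life-table
#' download.
#'
#' Two methods are available.  `"piecewise"` (default) assumes a constant
#' annual death probability within each inter-anchor segment and solves each
#' segment so that every anchor expectancy is reproduced exactly (to
#' numerical tolerance); above the last anchor the hazard grows
#' geometrically at rate `tail_growth` per year (a Gompertz tail) with its
#' level calibrated so the terminal anchor holds.  `"gompertz-makeham"` fits
#' the three-parameter hazard `mu(x) = A + B exp(theta x)` to all anchors by
#' least squares; it is smooth but cannot capture infant mortality, so
#' residuals at the printed anchors can reach ~0.4 years (fitted parameters
#' are returned in the `gm_params` attribute).
#'
#' @param anchors Data frame with numeric columns `age` (strictly
#'   increasing, starting at 0, at least 4 rows) and `ex` (strictly
#'   decreasing beyond age 1).
#' @param sex,race Passed to [life_table()].
#' @param method `"piecewise"` or `"gompertz-makeham"`.
#' @param omega Terminal age of the reconstructed table.
#' @param tail_growth Annual geometric hazard growth above the last anchor
#'   (piecewise method); 0.09 is a typical old-age Gompertz slope.
#' @return A [life_table()]; for `"gompertz-makeham"` with attribute
#'   `gm_params` (`A`, `B`, `theta`).
#' @export
#' @examples
#' anc <- builtin_expectancy_anchors()$male
#' lt <- life_table_from_anchors(anc, sex = "male")
#' remaining_life(lt, 0)  # 76.0, the printed anchor
life_table_from_anchors <- function(anchors, sex = c("male", "female"),
                                    race = "All",
                                    method = c("piecewise",
                                               "gompertz-makeham"),
                                    omega = 100, tail_growth = 0.09) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  anchors <- validate_anchors(anchors)
  if (max(anchors$age) >= omega) {
    stop("`omega` must exceed the last anchor age", call. = FALSE)
  }
  if (method == "piecewise") {
    qx <- anchors_piecewise_qx(anchors, omega, tail_growth)
    life_table(0:omega, qx, sex = sex, race = race)
  } else {
    fit <- fit_gompertz_makeham(anchors, omega)
    lt <- life_table(0:omega, fit$qx, sex = sex, race = race)
    attr(lt, "gm_params") <- fit$params
    lt
  }
}

validate_anchors <- function(anchors) {
  if (!is.data.frame(anchors) || !all(c("age", "ex") %in% names(anchors))) {
    stop("`anchors` must be a data frame with columns `age` and `ex`",
         call. = FALSE)
  }
  anchors <- anchors[order(anchors$age), c("age", "ex")]
  if (nrow(anchors) < 4) {
    stop("at least 4 anchors are required", call. = FALSE)
  }
  if (anchors$age[1] != 0) {
    stop("anchors must include age 0", call. = FALSE)
  }
  if (any(diff(anchors$age) <= 0)) {
    stop("anchor ages must be strictly increasing", call. = FALSE)
  }
  adult <- anchors$ex[anchors$age >= 1]
  if (any(diff(adult) >= 0)) {
    stop("anchor expectancies must be strictly decreasing beyond age 1",
         call. = FALSE)
  }
  anchors
}

# Constant q within each inter-anchor segment, solved backwards from the
# last anchor so every anchor e(x) is hit exactly; Gompertz tail above.
anchors_piecewise_qx <- function(anchors, omega, tail_growth) {
  qx <- numeric(omega + 1)
  qx[omega + 1] <- 1
  a_last <- max(anchors$age)
  e_last <- anchors$ex[anchors$age == a_last]
  n_tail <- omega - a_last
  tail_ex <- function(q_base) {
    qt <- pmin(1, q_base * exp(tail_growth * (0:n_tail)))
    qt[n_tail + 1] <- 1
    curtate_expectancy(qt)[1]
  }
  if (tail_ex(1e-10) < e_last) {
    stop("terminal anchor expectancy is unattainable by the tail model; ",
         "increase `omega`", call. = FALSE)
  }
  q_base <- stats::uniroot(function(z) tail_ex(z) - e_last,
                           c(1e-10, 0.99), tol = 1e-13)$root
  qx[(a_last + 1):(omega + 1)] <-
    pmin(1, q_base * exp(tail_growth * (0:n_tail)))
  qx[omega + 1] <- 1
  # segments, youngest last; f = e - 0.5 satisfies f(x) = (1-q)(1+f(x+1))
  f <- anchors$ex - 0.5
  for (i in rev(seq_len(nrow(anchors) - 1))) {
    a0 <- anchors$age[i]
    a1 <- anchors$age[i + 1]
    gap <- function(q_seg) {
      fx <- f[i + 1]
      for (x in seq_len(a1 - a0)) fx <- (1 - q_seg) * (1 + fx)
      fx - f[i]
    }
    g0 <- gap(0)
    if (g0 < -1e-9) {
      stop(sprintf(paste0("anchors at ages %d and %d imply expectancy ",
                          "falling faster than one year per year"),
                   a0, a1), call. = FALSE)
    }
    q_seg <- if (g0 <= 1e-12) 0 else {
      stats::uniroot(gap, c(0, 0.999999), tol = 1e-14)$root
    }
    qx[(a0 + 1):a1] <- q_seg
  }
  qx
}

# Least-squares Gompertz-Makeham fit on anchor expectancies.
# Hazard mu(x) = A + B exp(theta x); discretised annual probability
# q(x) = 1 - exp(-A - B exp(theta x) (exp(theta) - 1) / theta).
fit_gompertz_makeham <- function(anchors, omega) {
  qx_of <- function(par) {
    A <- exp(par[1]); B <- exp(par[2]); theta <- par[3]
    x <- 0:omega
    hx <- A + B * exp(theta * x) * (exp(theta) - 1) / theta
    q <- 1 - exp(-hx)
    q[omega + 1] <- 1
    q
  }
  objective <- function(par) {
    e <- curtate_expectancy(qx_of(par))
    sum((e[anchors$age + 1] - anchors$ex)^2)
  }
  fit <- stats::optim(c(log(5e-4), log(3e-5), 0.095), objective,
                      control = list(maxit = 5000, reltol = 1e-12))
  fit <- stats::optim(fit$par, objective,
                      control = list(maxit = 5000, reltol = 1e-14))
  list(qx = qx_of(fit$par),
       params = c(A = exp(fit$par[1]), B = exp(fit$par[2]),
                  theta = fit$par[3]))
}

#' Extract expectancy anchors from a life table
#'
#' Inverse of [life_table_from_anchors()]: reads `e(x)` at the requested
#' ages, so that reconstruct-then-extract is a fixed point within fit
#' tolerance.
#'
#' @param lt A [life_table()].
#' @param ages Integer ages at which to read anchors.
#' @return Data frame with columns `age`, `ex`.
#' @export
extract_anchors <- function(lt, ages) {
  stopifnot(inherits(lt, "life_table"))
  data.frame(age = as.integer(ages),
             ex = vapply(ages, function(a) remaining_life(lt, a), 0))
}
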