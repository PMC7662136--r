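# Independent oracles and small fixtures built in code.

# Expected (discounted) remaining life by exhaustive enumeration over all
# death-age outcomes: a person dying during age-year k has lived k - age
# complete years past `age` (each discounted at its calendar offset) plus
# the half-year convention.  Deliberately written as an outcome-tree sum,
# independent of the survival recursion used by the package.
oracle_expectancy <- function(qx, age = 0, rate = 0, horizon = Inf) {
  omega <- length(qx) - 1
  v <- 1 / (1 + rate)
  total <- 0
  surv <- 1
  for (k in age:omega) {
    p_die <- surv * qx[k + 1]
    t_max <- min(k - age, horizon - age)
    yrs <- if (t_max >= 1) sum(v^seq_len(t_max)) else 0
    total <- total + p_die * (yrs + 0.5)
    surv <- surv * (1 - qx[k + 1])
  }
  total
}

# A small four-age toy table (ages 0-3, terminal q = 1).
toy_qx <- c(0.1, 0.25, 0.5, 1)
toy_table <- function(qx = toy_qx, sex = "male") {
  life_table(seq_along(qx) - 1L, qx, sex = sex)
}

# A toy table wide enough to hold a primary-school-aged child.
child_toy_table <- function(sex = "male") {
  qx <- c(rep(0.001, 5), rep(0.002, 7), 0.3, 0.6, 1)
  life_table(0:14, qx, sex = sex)
}

printed_anchor_ages <- c(0, 1, 10, 20, 30, 40, 50, 60, 70, 80, 85)
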