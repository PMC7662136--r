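test_that("life-table construction enforces its invariants", {
  expect_error(life_table(0:2, c(0.1, 0.2, 0.9)), "terminal")
  expect_error(life_table(0:2, c(0.1, 1.2, 1)), "\\[0, 1\\]")
  expect_error(life_table(c(0, 2, 3), c(0.1, 0.2, 1)), "contiguous")
  lt <- toy_table()
  expect_s3_class(lt, "life_table")
  expect_true(all(diff(cumprod(1 - lt$qx)) <= 0))  # survival non-increasing
})

test_that("expectancy matches hand-checkable cases", {
  # immediate death with the half-year credit
  expect_equal(remaining_life(life_table(0L, 1, sex = "male"), 0), 0.5)
  # constant q = 1/2: e(0) -> sum of 0.5^t + 0.5 = 1.5
  qx <- c(rep(0.5, 60), 1)
  expect_equal(remaining_life(life_table(0:60, qx, sex = "male"), 0), 1.5,
               tolerance = 1e-9)
})

test_that("expectancy equals the exhaustive death-age enumeration oracle", {
  set.seed(31)
  for (i in 1:20) {
    qx <- c(runif(3), 1)
    lt <- toy_table(qx)
    for (age in 0:3) {
      expect_equal(remaining_life(lt, age), oracle_expectancy(qx, age),
                   tolerance = 1e-12)
    }
  }
})

test_that("anchor reconstruction reproduces every printed expectancy", {
  anchors <- builtin_expectancy_anchors()
  for (sex in c("male", "female")) {
    lt <- life_table_from_anchors(anchors[[sex]], sex = sex)
    for (i in seq_len(nrow(anchors[[sex]]))) {
      expect_equal(remaining_life(lt, anchors[[sex]]$age[i]),
                   anchors[[sex]]$ex[i], tolerance = 0.2)
    }
  }
  expect_equal(remaining_life(
    life_table_from_anchors(anchors$female, sex = "female"), 0),
    81.0, tolerance = 0.2)
})

test_that("anchor validation rejects malformed input", {
  bad <- data.frame(age = c(0, 10, 20, 30), ex = c(70, 60, 62, 40))
  expect_error(life_table_from_anchors(bad, sex = "male"),
               "strictly decreasing")
  expect_error(life_table_from_anchors(
    data.frame(age = c(0, 10, 20), ex = c(70, 60, 50)), sex = "male"),
    "at least 4")
})

test_that("Gompertz-Makeham fitting recovers known parameters within 1%", {
  true <- c(A = 4e-4, B = 3e-5, theta = 0.10)
  x <- 0:100
  hx <- true["A"] + true["B"] * exp(true["theta"] * x) *
    (exp(true["theta"]) - 1) / true["theta"]
  qx <- 1 - exp(-hx)
  qx[101] <- 1
  lt_true <- life_table(x, qx, sex = "male")
  anchors <- extract_anchors(lt_true, printed_anchor_ages)
  fit <- life_table_from_anchors(anchors, sex = "male",
                                 method = "gompertz-makeham")
  recovered <- attr(fit, "gm_params")
  expect_equal(unname(recovered["A"]), unname(true["A"]), tolerance = 0.01)
  expect_equal(unname(recovered["B"]), unname(true["B"]), tolerance = 0.01)
  expect_equal(unname(recovered["theta"]), unname(true["theta"]),
               tolerance = 0.01)
})

test_that("reconstruct-then-extract is a fixed point at the anchors", {
  anchors <- builtin_expectancy_anchors()$male
  lt <- life_table_from_anchors(anchors, sex = "male")
  again <- extract_anchors(lt, anchors$age)
  expect_equal(again$ex, anchors$ex, tolerance = 1e-6)
})

test_that("remaining life obeys its structural bounds", {
  lt <- life_table_from_anchors(builtin_expectancy_anchors()$male,
                                sex = "male")
  expect_equal(remaining_life(lt, lt$omega), 0.5)
  # cannot gain more than one year of expectancy per year survived
  expect_true(all(diff(lt$ex) >= -1 - 1e-12))
  expect_error(remaining_life(lt, 101), "within")
})

test_that("hazard adjustment is the identity at multiplier 1", {
  lt <- toy_table()
  expect_equal(adjust_hazard(lt, 1)$ex, lt$ex, tolerance = 1e-14)
})

test_that("hazard adjustment matches the oracle and is monotone", {
  qx <- toy_qx
  lt <- toy_table(qx)
  for (m in c(1.05, 1.3333, 2)) {
    adj <- adjust_hazard(lt, m, from_age = 1)
    q2 <- qx
    q2[2:4] <- pmin(1, q2[2:4] * m)
    q2[4] <- 1
    for (age in 0:3) {
      expect_equal(remaining_life(adj, age), oracle_expectancy(q2, age),
                   tolerance = 1e-12)
    }
  }
  # strictly lower expectancy wherever survival is still at stake
  # (the terminal age has e = 0.5 under any multiplier)
  e1 <- adjust_hazard(lt, 1.1, from_age = 1)$ex
  e2 <- adjust_hazard(lt, 1.4, from_age = 1)$ex
  expect_true(all(e2[2:3] < e1[2:3]))
  expect_true(remaining_life(adjust_hazard(lt, 1.4, from_age = 1), 1) <
                remaining_life(lt, 1))
  expect_error(adjust_hazard(lt, -1), "positive")
})

test_that("discounting reduces to closed forms and is monotone in rate", {
  lt <- life_table_from_anchors(builtin_expectancy_anchors()$male,
                                sex = "male")
  # discount-free limit
  expect_equal(discounted_remaining_life(lt, 8, rate = 0),
               remaining_life(lt, 8), tolerance = 1e-12)
  # certain survival for T years: an annuity plus the half year
  T <- 20
  certain <- life_table(0:T, c(rep(0, T), 1), sex = "male")
  r <- 0.03
  v <- 1 / (1 + r)
  expect_equal(discounted_remaining_life(certain, 0, rate = r),
               v * (1 - v^T) / (1 - v) + 0.5, tolerance = 1e-12)
  # only the immediate half-year survives extreme discounting
  expect_equal(discounted_remaining_life(lt, 8, rate = 1e6), 0.5,
               tolerance = 1e-5)
  rates <- c(0, 0.005, 0.03, 0.1)
  vals <- vapply(rates, function(r) discounted_remaining_life(lt, 8, r), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(discounted_remaining_life(lt, 8, rate = -0.01),
               "non-negative")
})

test_that("the accounting horizon caps counted life-years", {
  qx <- toy_qx
  lt <- toy_table(qx)
  expect_equal(discounted_remaining_life(lt, 1, rate = 0, horizon = 1), 0.5)
  for (h in 1:3) {
    expect_equal(discounted_remaining_life(lt, 0, rate = 0.02, horizon = h),
                 oracle_expectancy(qx, 0, rate = 0.02, horizon = h),
                 tolerance = 1e-12)
  }
})
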