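rules <- fuzzy_rules()

test_that("fuzzify produces at most two active terms summing to one", {
  u <- fuzzy_universe(-3, 3)
  # peaks
  expect_equal(unname(fuzzify(0, u)["ZO"]), 1)
  expect_equal(sum(fuzzify(0, u)), 1)
  # midway between PS and PM centers (1 and 2)
  mu <- fuzzify(1.5, u)
  expect_equal(unname(mu[c("PS", "PM")]), c(0.5, 0.5))
  expect_equal(sum(mu > 0), 2)
  # clipping beyond the bounds
  expect_equal(unname(fuzzify(10, u)["PB"]), 1)
  expect_equal(unname(fuzzify(-10, u)["NB"]), 1)
  set.seed(3)
  for (x in runif(50, -4, 4)) {
    mu <- fuzzify(x, u)
    expect_lte(sum(mu > 0), 2)
    expect_equal(sum(mu), 1)
    expect_true(all(mu >= 0 & mu <= 1))
  }
  expect_error(fuzzy_universe(1, 1), "lower < upper")
})

test_that("the shipped rule table is a complete 7x7 quad-output grid", {
  expect_s3_class(rules, "fuzzy_rules")
  expect_named(rules, c("dKp", "dKi", "dKd", "lambda"))
  for (ch in rules) {
    expect_equal(dim(ch), c(7, 7))
    expect_true(all(ch %in% 1:7))
  }
  labs <- c("NB", "NM", "NS", "ZO", "PS", "PM", "PB")
  # spot checks against the expert rule base
  expect_equal(labs[rules$dKp["ZO", "ZO"]], "ZO")
  expect_equal(labs[rules$dKi["ZO", "ZO"]], "PS")
  expect_equal(labs[rules$dKd["ZO", "ZO"]], "NS")
  expect_equal(labs[rules$lambda["ZO", "ZO"]], "NB")
  expect_equal(labs[c(rules$dKp["NB", "NB"], rules$dKi["NB", "NB"],
                      rules$dKd["NB", "NB"], rules$lambda["NB", "NB"])],
               c("PB", "NB", "PS", "PB"))
})

test_that("inference fires single rules at centers and splits at midpoints", {
  ue <- fuzzy_universe(-3, 3)
  uec <- fuzzy_universe(-1.5, 1.5)
  # both inputs at ZO centers: only the ZO/ZO rule fires
  st <- fuzzy_infer(fuzzify(0, ue), fuzzify(0, uec), rules)
  expect_equal(unname(st$dKp["ZO"]), 1)
  expect_equal(sum(st$dKp > 0), 1)
  expect_equal(unname(st$dKi["PS"]), 1)
  expect_equal(unname(st$dKd["NS"]), 1)
  expect_equal(unname(st$lambda["NB"]), 1)
  # both at NB centers
  st <- fuzzy_infer(fuzzify(-3, ue), fuzzify(-1.5, uec), rules)
  expect_equal(unname(st$dKp["PB"]), 1)
  expect_equal(unname(st$lambda["PB"]), 1)
  # e midway NB/NM with ec at NB center: two rules at strength 0.5
  st <- fuzzy_infer(fuzzify(-2.5, ue), fuzzify(-1.5, uec), rules)
  # cells (NB, NB) -> dKp PB and (NB, NM) -> dKp PB aggregate by max
  expect_equal(unname(st$dKp["PB"]), 0.5)
  # lambda outputs PB (from e=NB) and PM (from e=NM), each at 0.5
  expect_equal(unname(st$lambda[c("PM", "PB")]), c(0.5, 0.5))
})

test_that("centroid defuzzification respects symmetry and bounds", {
  u <- fuzzy_universe(-5, 5)
  one_hot <- function(k) { s <- numeric(7); s[k] <- 1; s }
  expect_equal(defuzzify(one_hot(4), u), 0, tolerance = 1e-12)
  # equal-strength symmetric pair NS + PS
  s <- numeric(7); s[3] <- 0.6; s[5] <- 0.6
  expect_equal(defuzzify(s, u), 0, tolerance = 1e-12)
  # full-strength PB: centroid of the edge triangle, one third in from the
  # bound (half-triangle within the universe)
  pb <- defuzzify(one_hot(7), u)
  expect_gt(pb, 0)
  expect_lt(pb, 5)
  expect_equal(pb, 5 - (10 / 6) / 3, tolerance = 0.01)
  # all-zero membership: midpoint with a warning
  expect_warning(z <- defuzzify(numeric(7), u), "midpoint")
  expect_equal(z, 0)
  # outputs always inside the universe
  set.seed(11)
  for (i in 1:50) {
    s <- runif(7) * rbinom(7, 1, 0.4)
    if (all(s == 0)) s[sample(7, 1)] <- runif(1, 0.1, 1)
    v <- defuzzify(s, u)
    expect_gte(v, -5)
    expect_lte(v, 5)
  }
})

test_that("lambda mapping anchors NB at 0, PB at 1 and ZO at 1/2", {
  u <- fuzzy_universe(0, 1)
  one_hot <- function(k) { s <- numeric(7); s[k] <- 1; s }
  expect_equal(lambda_from_output(defuzzify(one_hot(1), u), u), 0)
  expect_equal(lambda_from_output(defuzzify(one_hot(7), u), u), 1)
  expect_equal(lambda_from_output(defuzzify(one_hot(4), u), u), 0.5,
               tolerance = 1e-12)
})

test_that("lambda response is non-increasing in e when ec is at ZO", {
  ue <- fuzzy_universe(-3, 3)
  uec <- fuzzy_universe(-1.5, 1.5)
  ulam <- fuzzy_universe(0, 1)
  lam_at <- function(e) {
    st <- fuzzy_infer(fuzzify(e, ue), fuzzify(0, uec), rules)
    lambda_from_output(defuzzify(st$lambda, ulam), ulam)
  }
  # exactly non-increasing across the term centers (the rule-table row)
  lam_centers <- sapply(ue$centers, lam_at)
  expect_true(all(diff(lam_centers) <= 1e-9))
  # on a fine grid, monotone up to the small centroid-clipping ripple of
  # Mamdani defuzzification between adjacent cells
  lam_fine <- sapply(seq(-3, 3, by = 0.25), lam_at)
  expect_true(all(diff(lam_fine) <= 0.02))
  # hot house (e < 0) drives more positive-pressure ventilation
  expect_gt(lam_fine[1], lam_fine[length(lam_fine)])
})

test_that("dKp channel is antisymmetric under joint input negation where the
           table is antisymmetric", {
  ue <- fuzzy_universe(-3, 3)
  uec <- fuzzy_universe(-1.5, 1.5)
  uu <- fuzzy_universe(-5, 5)
  # cell-wise antisymmetry check of the printed table: cell (i, j) vs
  # its mirror (8-i, 8-j) on the dKp channel
  mirror_anti <- outer(1:7, 1:7, Vectorize(function(i, j) {
    rules$dKp[i, j] + rules$dKp[8 - i, 8 - j] == 8
  }))
  # where the table itself is antisymmetric, crisp outputs negate
  for (i in 1:7) {
    for (j in 1:7) {
      if (!mirror_anti[i, j]) next
      e <- fuzzy_universe(-3, 3)$centers[j]
      ec <- fuzzy_universe(-1.5, 1.5)$centers[i]
      a <- defuzzify(fuzzy_infer(fuzzify(e, ue), fuzzify(ec, uec),
                                 rules)$dKp, uu)
      b <- defuzzify(fuzzy_infer(fuzzify(-e, ue), fuzzify(-ec, uec),
                                 rules)$dKp, uu)
      expect_equal(a, -b, tolerance = 1e-9)
    }
  }
})

test_that("controller step with fuzzy disabled reduces to the PID law", {
  ctrl <- house_controller(KP = 2, KI = 0.5, KD = 1, use_fuzzy = FALSE,
                           lambda_fixed = 0.3)
  st <- controller_state()
  # independent discrete PID recursion
  errs <- c(1.2, 0.8, 0.3, -0.2, -0.4)
  integ <- 0; eprev <- 0
  for (k in seq_along(errs)) {
    res <- controller_step(ctrl, Tset = 25, Ti = 25 - errs[k], st)
    st <- res$state
    integ <- integ + errs[k]
    ec <- if (k == 1) 0 else errs[k] - eprev
    expect_equal(res$u, 2 * errs[k] + 0.5 * integ + 1 * ec)
    expect_equal(res$lambda, 0.3)
    eprev <- errs[k]
  }
})

test_that("constant error grows the integral contribution linearly", {
  ctrl <- house_controller(KP = 1, KI = 2, KD = 5, use_fuzzy = FALSE)
  st <- controller_state()
  us <- numeric(6)
  for (k in 1:6) {
    res <- controller_step(ctrl, Tset = 26, Ti = 25.5, st)
    st <- res$state
    us[k] <- res$u
  }
  # after the first step ec = 0, so successive outputs differ by KI * e
  expect_equal(diff(us)[-1], rep(2 * 0.5, 4))
})

test_that("anti-windup clamps the integral term to the actuator span", {
  ctrl <- house_controller(KP = 1, KI = 2, KD = 1, use_fuzzy = FALSE)
  st <- controller_state()
  for (k in 1:500) {
    res <- controller_step(ctrl, Tset = 30, Ti = 20, st, u_span = 100)
    st <- res$state
  }
  expect_lte(abs(res$Ki * st$integral), 100 + 1e-9)
})

test_that("closed loop with plain PID matches a first-order-plant recursion", {
  # plant: x_{k+1} = a x_k + b u_k, setpoint step; oracle is the closed-form
  # recursion of the same discrete PID written independently
  a <- 0.9; b <- 0.05; Tset <- 1
  ctrl <- house_controller(KP = 3, KI = 0.4, KD = 1, use_fuzzy = FALSE)
  st <- controller_state()
  x <- 0
  xs <- numeric(40)
  for (k in 1:40) {
    res <- controller_step(ctrl, Tset, x, st)
    st <- res$state
    x <- a * x + b * res$u
    xs[k] <- x
  }
  # oracle recursion
  x2 <- 0; integ <- 0; eprev <- 0
  for (k in 1:40) {
    e <- Tset - x2
    integ <- integ + e
    ec <- if (k == 1) 0 else e - eprev
    u <- 3 * e + 0.4 * integ + 1 * ec
    eprev <- e
    x2 <- a * x2 + b * u
    expect_equal(xs[k], x2)
  }
  # and the loop actually converges to the setpoint
  expect_lt(abs(xs[40] - Tset), 0.05)
})
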