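## Surrogate-risk construction and penalized weighted hinge-loss fitting.

test_that("surrogate risk matches hand arithmetic", {
  w2 <- c(0, 1, 0)
  # two uncensored subjects with utilities 2 and 1 (time in state 2), pi = 0.5
  tr <- toy_trial(z = rbind(c(1, 0), c(-1, 0)), a = c(1, -1),
                  start2 = c(0, 0), end = c(2, 1), delta = c(1, 1))
  expect_equal(ipcw_utilities(tr, w2)$utility, c(2, 1))
  f <- function(Z) ifelse(Z[, 1] > 0, 0, 0.5)   # f = 0 for subj 1, 0.5 for subj 2
  expect_equal(surrogate_risk(f, tr, w2), 3.5)
  # hinge vanishes when every margin is >= 1
  fbig <- function(Z) ifelse(Z[, 1] > 0, 2, -2)
  expect_equal(surrogate_risk(fbig, tr, w2), 0)
  # zero utilities: risk 0 for any f
  w_none <- c(0.5, 0, 0)
  tr0 <- toy_trial(z = rbind(c(1, 0), c(-1, 0)), a = c(1, -1),
                   start2 = c(0, 0), end = c(3, 3), delta = c(1, 1))
  # both subjects spend all time in state 2 -> zero weight-1 time
  expect_equal(surrogate_risk(f, tr0, c(0.5, 0, 0)), 0)
})

test_that("fitted objective matches the dense grid-search oracle on small instances", {
  set.seed(42)
  gaps <- double(20)
  for (k in 1:20) {
    n <- sample(15:30, 1)
    tr <- simulate_trial(n, scenario = sample(1:2, 1), theta = -1,
                         seed = 1000 + k)
    if (length(unique(tr$a)) < 2) next
    lam <- runif(1, 0.05, 0.5)
    h <- censoring_hazard(tr); pi <- estimate_propensity(tr)
    fit <- owl_fit(tr, c(0, 1, 0), lam, h = h, pi = pi)
    cw <- owl_case_weights(tr, c(0, 1, 0), h, pi)
    oracle <- grid_search_objective(tr$z, as.double(tr$a), cw, lam)
    gaps[k] <- fit$objective - oracle
  }
  expect_true(all(gaps <= 1e-4))
})

test_that("the fitted rule recovers a constructed benefit boundary", {
  # 1-D signal: subjects with z1 > 0 benefit only under +1, z1 < 0 only under -1
  z <- rbind(c(0.5, 0), c(0.5, 0), c(-0.5, 0), c(-0.5, 0))
  a <- c(1, -1, -1, 1)
  # matched-arm subjects get utility 2, mismatched 0.1
  u_dur <- c(2, 0.1, 2, 0.1)
  tr <- toy_trial(z = z, a = a, start2 = rep(0, 4), end = u_dur,
                  delta = rep(1, 4))
  fit <- owl_fit(tr, c(0, 1, 0), lambda = 0.01)
  expect_gt(fit$coefs[1], 0)
  expect_equal(itr_assign(fit, rbind(c(0.5, 0), c(-0.5, 0))), c(1, -1))

  # heavy regularization shrinks the slope to ~0; intercept picks the
  # better single arm (here +1, the arm with more reachable utility)
  tr2 <- toy_trial(z = z, a = a, start2 = rep(0, 4),
                   end = c(2.5, 0.1, 0.5, 0.1), delta = rep(1, 4))
  fit2 <- owl_fit(tr2, c(0, 1, 0), lambda = 1e6)
  expect_lt(sqrt(sum(fit2$coefs^2)), 1e-3)
  expect_equal(unique(itr_assign(fit2, z)), 1)
})

test_that("all-zero utilities give the zero decision function with a warning", {
  tr0 <- toy_trial(z = rbind(c(1, 0), c(-1, 0)), a = c(1, -1),
                   start2 = c(NA, NA), end = c(3, 3), delta = c(1, 1))
  expect_warning(fit <- owl_fit(tr0, c(0, 1, 0), 0.1), "zero")
  expect_equal(fit$intercept, 0)
  expect_equal(fit$coefs, c(0, 0))
  expect_equal(unique(itr_assign(fit, rbind(c(1, 2), c(-3, 0)))), 1)  # sgn(0) = +1
})

test_that("sgn assigns +1 at zero and tracks the sign elsewhere", {
  expect_equal(sgn(c(0, -0.3, 2)), c(1, -1, 1))
  fit <- owl_fit(sim_fixture(n = 40, seed = 3), c(0, 1, 0), 0.2)
  z <- rbind(c(0.3, 0.3), c(-0.9, -0.9))
  expect_equal(itr_assign(fit, z), sgn(predict(fit, z)))
})

test_that("penalized objective is convex along random segments", {
  tr <- sim_fixture(n = 40, seed = 9)
  lam <- 0.1
  set.seed(10)
  for (k in 1:10) {
    th1 <- rnorm(3); th2 <- rnorm(3); t <- runif(1)
    thm <- t * th1 + (1 - t) * th2
    o1 <- linear_objective(th1[1], th1[-1], tr, c(0, 1, 0), lam)
    o2 <- linear_objective(th2[1], th2[-1], tr, c(0, 1, 0), lam)
    om <- linear_objective(thm[1], thm[-1], tr, c(0, 1, 0), lam)
    expect_lte(om, t * o1 + (1 - t) * o2 + 1e-12)
  }
})

test_that("gaussian-kernel decision functions evaluate and fit sensibly", {
  # kernel identity at a support point
  fit1 <- structure(
    list(kind = "gaussian_kernel", intercept = 0.25, coefs = NULL,
         alphas = 1, support = matrix(c(0.3, -0.2), 1), sigma = 1,
         lambda = 0.1, w = preference_weight(c(0, 1, 0)), pi = 0.5,
         objective = NA, diagnostics = list()),
    class = "owl_fit")
  expect_equal(predict(fit1, c(0.3, -0.2)), 1 + 0.25)

  # tiny sigma on the constructed 1-D boundary reproduces the linear rule's signs
  z <- rbind(c(0.5, 0), c(0.5, 0), c(-0.5, 0), c(-0.5, 0))
  a <- c(1, -1, -1, 1)
  tr <- toy_trial(z = z, a = a, start2 = rep(0, 4), end = c(2, 0.1, 2, 0.1),
                  delta = rep(1, 4))
  fl <- owl_fit(tr, c(0, 1, 0), 0.01)
  fk <- owl_fit(tr, c(0, 1, 0), 0.01, kernel = "gaussian", sigma = 0.05)
  test_pts <- rbind(c(0.5, 0), c(-0.5, 0))
  expect_equal(itr_assign(fk, test_pts), itr_assign(fl, test_pts))
  expect_equal(itr_assign(fk, test_pts), c(1, -1))

  # with a linear true boundary the kernel rule beats an intercept-only rule
  tr2 <- simulate_trial(200, scenario = 1, theta = -1.6, seed = 15)
  fk2 <- owl_fit(tr2, c(0, 1, 0), 1 / sqrt(200), kernel = "gaussian", sigma = 1)
  set.seed(16)
  zt <- matrix(runif(4000, -1, 1), 2000, 2)
  d_true <- sgn(optimal_decision(1, zt))
  mis_kernel <- mean(itr_assign(fk2, zt) != d_true)
  mis_const <- min(mean(d_true != 1), mean(d_true != -1))
  expect_lt(mis_kernel, mis_const)
})

test_that("lambda selection maximizes the jackknife value with ties to larger lambda", {
  tr <- sim_fixture(n = 25, seed = 19)
  # single-element grid returns it
  expect_equal(as.numeric(select_lambda(tr, c(0, 1, 0), grid = 0.3)), 0.3)
  # degenerate zero-utility data: every lambda ties; the largest is returned
  tr0 <- toy_trial(z = matrix(rnorm(12), 6, 2), a = rep(c(1, -1), 3),
                   start2 = rep(NA, 6), end = rep(3, 6), delta = rep(1, 6))
  sel <- suppressWarnings(select_lambda(tr0, c(0, 1, 0), grid = c(0.1, 0.5, 0.2)))
  expect_equal(as.numeric(sel), 0.5)
  # definitional post-condition on a real grid
  grid <- c(0.05, 0.2, 0.8)
  sel2 <- select_lambda(tr, c(0, 1, 0), grid = grid)
  crit <- attr(sel2, "criterion")
  expect_equal(max(crit$jk_value), crit$jk_value[crit$lambda == as.numeric(sel2)])
})

test_that("value + weighted 0-1 risk equals the total weighted mass exactly", {
  for (seed in c(4, 8)) {
    tr <- sim_fixture(n = 35, seed = seed)
    h <- censoring_hazard(tr); pi <- estimate_propensity(tr)
    w <- c(0, 1, 0)
    fit <- owl_fit(tr, w, 0.15, h = h, pi = pi)
    v <- estimate_value(tr, fit, w, h = h, pi = pi)
    r01 <- surrogate_risk(fit, tr, w, h = h, pi = pi, loss = "zero_one")
    u <- ipcw_utilities(tr, w, h)$utility
    denom <- ifelse(tr$a > 0, pi, 1 - pi)
    expect_equal(v + r01, mean(u / denom), tolerance = 1e-12)
  }
})
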