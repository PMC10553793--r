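#' Optimal decision function of the validation scenarios
#'
#' Four scenarios of a progressive illness-death trial generator, indexed by
#' the form of the optimal decision function `f*`:
#' Scenario 1: `z1 + z2` (linear); Scenario 2: `2 z1 - z2` (linear);
#' Scenario 3: `1 + z2 - exp(-z1)`; Scenario 4: `2 log(2 - z1 - z2) - 1.4`
#' (both nonlinear).  The optimal rule is `sgn(f*)` for both the
#' time-in-response weight `(0,1,0)` and the progression-free-time weight
#' `(1,1,0)`.
#'
#' @param scenario Integer 1-4.
#' @param z Covariate matrix with two columns (or a length-2 vector).
#' @return Numeric vector `f*(z)`.
#' @export
optimal_decision <- function(scenario, z) {
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 2)
  stopifnot(ncol(Z) == 2, scenario %in% 1:4)
  z1 <- Z[, 1]; z2 <- Z[, 2]
  switch(scenario,
         z1 + z2,
         2 * z1 - z2,
         1 + z2 - exp(-z1),
         {
           arg <- 2 - z1 - z2
           if (any(arg <= 0)) stop("scenario 4 undefined: 2 - z1 - z2 <= 0",
                                   call. = FALSE)
           2 * log(arg) - 1.4
         })
}

#' Transition intensities of the illness-death generator
#'
#' Constant (time-homogeneous) intensities given treatment and covariates:
#' `alpha12 = exp(-0.5 z1 + 0.5 z2 + a f*(z))` (initial -> response),
#' `alpha13 = exp(-0.5 z1 + 0.5 z2) / 4` (initial -> progression/death), and
#' `alpha23 = exp(-0.5 z1 + 0.5 z2 - a f*(z)) / 2` (response ->
#' progression/death).  Treatment `a = sgn(f*)` therefore both speeds entry
#' into, and slows exit from, the response state.
#'
#' @inheritParams optimal_decision
#' @param a Treatment, -1/+1 (scalar or vector matching rows of `z`).
#' @return A matrix with columns `a12`, `a13`, `a23`.
#' @export
transition_intensities <- function(scenario, a, z) {
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 2)
  base <- exp(-0.5 * Z[, 1] + 0.5 * Z[, 2])
  f <- optimal_decision(scenario, Z)
  cbind(a12 = base * exp(a * f), a13 = base / 4, a23 = base * exp(-a * f) / 2)
}

#' Simulate a randomized trial with a censored illness-death outcome
#'
#' Subjects have `Z ~ U(-1, 1)^2`, `P(A = 1) = pi`, and a progressive
#' illness-death trajectory 1 -> 2 -> 3 / 1 -> 3 generated from competing
#' exponentials with the scenario's intensities.  The censoring time is
#' `C ~ Exponential(rate = exp(theta))`, independent of everything; the
#' calibration values `theta = -1.6, -1, -0.4` yield roughly 28%, 43% and
#' 60% censoring at `tau = 3`.  Observation ends at `tilde_t = min(T, C)`
#' with `T = min(T*, tau)`; a subject alive at `tau` is an event
#' (administrative truncation), not a censoring.
#'
#' @param n Number of subjects.
#' @param scenario Integer 1-4.
#' @param theta Log censoring rate.
#' @param tau Study horizon (default 3).
#' @param pi Randomization probability of the +1 arm.
#' @param seed Optional integer seed.
#' @return An [ms_trial] with an attribute `latent`: a tibble with the
#'   uncensored event time `t_star`, the response-entry time `t12` (`Inf` if
#'   never), and the censoring time `c` of every subject, for use in
#'   generator-level diagnostics.
#' @export
simulate_trial <- function(n, scenario = 1, theta = -1.6, tau = 3, pi = 0.5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::runif(2 * n, -1, 1), n, 2,
              dimnames = list(NULL, c("z1", "z2")))
  a <- ifelse(stats::runif(n) < pi, 1L, -1L)
  al <- transition_intensities(scenario, a, z)
  r <- al[, "a12"] + al[, "a13"]
  t_leave1 <- stats::rexp(n, r)
  to2 <- stats::runif(n) < al[, "a12"] / r
  t12 <- ifelse(to2, t_leave1, Inf)
  t_star <- ifelse(to2, t_leave1 + stats::rexp(n, al[, "a23"]), t_leave1)
  cc <- stats::rexp(n, exp(theta))

  t_event <- pmin(t_star, tau)          # T = T* ^ tau
  tilde_t <- pmin(t_event, cc)
  delta <- as.integer(t_event <= cc)

  path_times <- vector("list", n); path_states <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- 0; ss <- 1L
    if (t12[i] <= tilde_t[i]) { tt <- c(tt, t12[i]); ss <- c(ss, 2L) }
    if (delta[i] == 1L && t_star[i] <= tilde_t[i]) {
      tt <- c(tt, t_star[i]); ss <- c(ss, 3L)
    }
    path_times[[i]] <- tt; path_states[[i]] <- ss
  }

  trial <- structure(
    list(id = seq_len(n), z = z, a = a, tilde_t = tilde_t, delta = delta,
         path_times = path_times, path_states = path_states,
         tau = tau, n_states = 3L, absorbing = 3L),
    class = "ms_trial")
  attr(trial, "latent") <- tibble::tibble(t_star = t_star, t12 = t12, c = cc)
  attr(trial, "scenario") <- scenario
  attr(trial, "theta") <- theta
  trial
}

#' Expected restricted state-occupation times of the illness-death model
#'
#' For constant intensities the occupation probabilities are available in
#' closed form: with `r = a12 + a13`,
#' `E[time in state 1 up to tau] = (1 - exp(-r tau)) / r` and
#' `E[time in state 2 up to tau] = a12/(r - a23) * ((1 - exp(-a23 tau))/a23 -
#' (1 - exp(-r tau))/r)`, with the continuous limit used when `r = a23`.
#'
#' @param a12,a13,a23 Positive intensity vectors.
#' @param tau Horizon.
#' @return A matrix with columns `e1`, `e2`.
#' @export
expected_occupation <- function(a12, a13, a23, tau) {
  r <- a12 + a13
  e1 <- (1 - exp(-r * tau)) / r
  gap <- r - a23
  near <- abs(gap) < 1e-8
  e2 <- ifelse(near,
               a12 * (1 - (1 + r * tau) * exp(-r * tau)) / r^2,
               a12 / gap * ((1 - exp(-a23 * tau)) / a23 - e1))
  cbind(e1 = e1, e2 = e2)
}

#' Precomputed quadrature grid for a scenario
#'
#' Tensor Gauss-Legendre nodes over `Z ~ U(-1,1)^2` with the per-arm
#' closed-form occupation times evaluated once; pass as `quad` to
#' [true_value()] / [evaluate_rule()] to avoid recomputation across
#' replications.
#'
#' @inheritParams true_value
#' @return A list with nodes `z`, quadrature weights `wq`, occupation-time
#'   matrices `occ_plus` / `occ_minus` and the optimal decision values
#'   `f_star` at the nodes.
#' @export
scenario_quadrature <- function(scenario, tau, n_nodes = 64) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  zg <- as.matrix(expand.grid(z1 = gl$x, z2 = gl$x))
  wq <- as.vector(outer(gl$w, gl$w)) / 4        # U(-1,1)^2 density = 1/4
  occ <- lapply(c(`1` = 1, `-1` = -1), function(a) {
    al <- transition_intensities(scenario, a, zg)
    expected_occupation(al[, "a12"], al[, "a13"], al[, "a23"], tau)
  })
  list(z = zg, wq = wq, occ_plus = occ[[1]], occ_minus = occ[[2]],
       f_star = optimal_decision(scenario, zg))
}

#' True value of a rule under the generator, by quadrature
#'
#' Computes `V_w(d) = E_Z[w1 e1(d(Z), Z) + w2 e2(d(Z), Z)]` exactly (up to
#' tensor Gauss-Legendre quadrature over `Z ~ U(-1,1)^2`) using the
#' closed-form occupation times.  `d` may be an `owl_fit`, a function, a
#' fixed rule +1/-1, or the string `"optimal"` for `sgn(f*)`.
#'
#' @param d Rule, as in [itr_assign()], or `"optimal"`.
#' @param scenario Integer 1-4.
#' @param w Preference weight vector of length 3 (weight on the absorbing
#'   state must be 0: occupation of state 3 is unbounded in time).
#' @param tau Horizon.
#' @param n_nodes One-dimensional quadrature size (total nodes `n_nodes^2`).
#' @param quad Optional precomputed [scenario_quadrature()] object.
#' @return A single number.
#' @export
true_value <- function(d, scenario, w, tau = 3, n_nodes = 64, quad = NULL) {
  w <- as_pref(w, 3L)
  if (unclass(w)[3] != 0) {
    stop("true_value requires zero weight on the absorbing state", call. = FALSE)
  }
  q <- quad %||% scenario_quadrature(scenario, tau, n_nodes)
  assn <- if (identical(d, "optimal")) sgn(q$f_star) else itr_assign(d, q$z)
  e <- q$occ_minus
  plus <- assn == 1
  e[plus, ] <- q$occ_plus[plus, ]
  sum(q$wq * (unclass(w)[1] * e[, "e1"] + unclass(w)[2] * e[, "e2"]))
}

#' Value ratio and misclassification of a fitted rule
#'
#' The value ratio is `V_w(d) / V_w(d*)` computed by quadrature; the
#' misclassification rate is the fraction of a fresh test draw of covariates
#' on which the rule disagrees with the optimal rule `sgn(f*)`.
#'
#' @inheritParams true_value
#' @param n_test Test-set size for the misclassification rate.
#' @param seed Optional seed for the test draw.
#' @return A one-row tibble: `value`, `value_opt`, `value_ratio`,
#'   `misclassification`.
#' @export
evaluate_rule <- function(d, scenario, w, tau = 3, n_test = 10000,
                          seed = NULL, quad = NULL) {
  q <- quad %||% scenario_quadrature(scenario, tau)
  v <- true_value(d, scenario, w, tau, quad = q)
  v_opt <- true_value("optimal", scenario, w, tau, quad = q)
  if (!is.null(seed)) set.seed(seed)
  zt <- matrix(stats::runif(2 * n_test, -1, 1), n_test, 2)
  mis <- mean(itr_assign(d, zt) != sgn(optimal_decision(scenario, zt)))
  tibble::tibble(value = v, value_opt = v_opt, value_ratio = v / v_opt,
                 misclassification = mis)
}

#' Run the simulation study over a grid of scenarios and sample sizes
#'
#' For each cell (scenario, theta, n) and each replication: simulate a
#' training trial, fit the linear-class rule with `lambda = 1/sqrt(n)`
#' (unless overridden), compute the plug-in value of the fitted rule with
#' its influence-function standard error, the true value of the fitted rule
#' by quadrature, the value ratio and misclassification, and optionally the
#' jackknife value.  Reported per cell: mean percent error of the plug-in
#' (and jackknife) value estimator, Monte Carlo SD of the estimates (MCSD),
#' average standard error (ASE), empirical coverage of the 95% interval
#' (CP), mean value ratio, mean misclassification and the censoring rate.
#'
#' @param cells A data frame with columns `scenario`, `theta`, `n` (one row
#'   per cell), or vectors `scenarios`, `thetas`, `ns` crossed.
#' @param n_reps Replications per cell.
#' @param seed Master seed; per-replication seeds are derived as
#'   `seed + 7919 * cell_index + rep` so any replication can be reproduced
#'   in isolation.
#' @param w Preference weight (default time in response, `c(0, 1, 0)`).
#' @param tau Horizon.
#' @param lambda Function of `n` giving the penalty (default `1/sqrt(n)`).
#' @param jackknife Also compute the jackknife value per replication
#'   (an n-fold refit; substantially slower).
#' @param level Confidence level for the coverage metric.
#' @return A tibble with one row per cell and the metric columns described
#'   above, plus `n_failed` (replications excluded due to fit failures).
#' @export
run_study <- function(cells, n_reps = 100, seed = 1, w = c(0, 1, 0), tau = 3,
                      lambda = function(n) 1 / sqrt(n), jackknife = FALSE,
                      level = 0.95) {
  stopifnot(is.data.frame(cells),
            all(c("scenario", "theta", "n") %in% names(cells)))
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    scn <- cells$scenario[ci]; th <- cells$theta[ci]; n <- cells$n[ci]
    quad <- scenario_quadrature(scn, tau)
    lam <- lambda(n)
    rep_rows <- vector("list", n_reps)
    n_failed <- 0L
    for (b in seq_len(n_reps)) {
      rep_seed <- (seed + 7919L * ci + b) %% .Machine$integer.max
      res <- tryCatch({
        trial <- simulate_trial(n, scn, th, tau, seed = rep_seed)
        h <- censoring_hazard(trial)
        pi <- estimate_propensity(trial)
        fit <- owl_fit(trial, w, lam, h = h, pi = pi)
        iv <- influence_values(trial, fit, w, h = h, pi = pi)
        v_hat <- attr(iv, "v_hat"); se <- attr(iv, "se")
        v_true <- true_value(fit, scn, w, tau, quad = quad)
        set.seed(rep_seed + 1L)
        zt <- matrix(stats::runif(2 * 10000, -1, 1), 10000, 2)
        mis <- mean(itr_assign(fit, zt) != sgn(optimal_decision(scn, zt)))
        v_opt <- true_value("optimal", scn, w, tau, quad = quad)
        row <- tibble::tibble(
          v_hat = v_hat, se = se, v_true = v_true,
          covered = abs(v_hat - v_true) <= zcrit * se,
          value_ratio = v_true / v_opt, misclassification = mis,
          cens = mean(trial$delta == 0))
        if (jackknife) {
          row$v_jk <- jackknife_value(trial, w, lam, h = h, pi = pi)
          row$covered_jk <- abs(row$v_jk - v_true) <= zcrit * se
        }
        row
      }, error = function(e) NULL)
      if (is.null(res)) n_failed <- n_failed + 1L else rep_rows[[b]] <- res
    }
    reps <- dplyr::bind_rows(rep_rows)
    cell <- tibble::tibble(
      scenario = scn, theta = th, n = n,
      n_reps = nrow(reps), n_failed = n_failed,
      cens_rate = mean(reps$cens),
      pct_error_plugin = mean(100 * (reps$v_hat - reps$v_true) / reps$v_true),
      mcsd = stats::sd(reps$v_hat),
      ase = mean(reps$se),
      cp = mean(reps$covered),
      value_ratio = mean(reps$value_ratio),
      misclassification = mean(reps$misclassification))
    if (jackknife) {
      cell$pct_error_jackknife <-
        mean(100 * (reps$v_jk - reps$v_true) / reps$v_true)
      cell$mcsd_jackknife <- stats::sd(reps$v_jk)
      cell$cp_jackknife <- mean(reps$covered_jk)
    }
    out[[ci]] <- cell
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("mstowl_study", class(res))
  res
}

#' @export
autoplot.mstowl_study <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data$value_ratio,
                               colour = factor(.data$theta))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~scenario, labeller = ggplot2::label_both) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "training sample size", y = "mean value ratio",
                  colour = expression(theta))
}
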