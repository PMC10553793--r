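#' Plug-in value estimate of a treatment rule
#'
#' The value of a rule `d` is the expected preference-weighted utility if
#' every patient were treated according to `d`.  It is estimated by the
#' inverse-probability-weighted average
#' \deqn{\hat{\mathcal V}_{n,w}(d) = \frac1n \sum_i U_{i,w}
#'   \frac{I(A_i = d(Z_i))}{A_i\hat\pi + (1-A_i)/2},}
#' where `U_{i,w}` is the IPCW-weighted utility.  `d` may be a fitted
#' `owl_fit`, a function of the covariate matrix, or a fixed one-size-fits-all
#' rule `+1` / `-1`.
#'
#' @param trial An [ms_trial].
#' @param d Rule (see [itr_assign()]).
#' @param w Preference weight vector.
#' @param h Censoring hazard; defaults to the Nelson-Aalen estimate.
#' @param pi Propensity; defaults to the sample estimate.
#' @return A single number.
#' @export
estimate_value <- function(trial, d, w, h = censoring_hazard(trial),
                           pi = estimate_propensity(trial)) {
  w <- as_pref(w, trial$n_states)
  u <- subject_utilities(trial, unclass(w), h)
  mean(value_summands(trial, d, u, pi))
}

## g_i = U_i I(A_i = d(Z_i)) / denom_i
value_summands <- function(trial, d, u, pi) {
  assn <- itr_assign(d, trial$z)
  denom <- ifelse(trial$a > 0, pi, 1 - pi)
  u * (trial$a == assn) / denom
}

#' Jackknife (leave-one-out) value estimate of the fitted rule
#'
#' The plug-in value of a rule evaluated on its own training data is
#' optimistic.  The jackknife estimator refits the rule `n` times, leaving
#' out one subject at a time, and evaluates each subject's value summand
#' under the rule fitted without that subject.  Each leave-one-out refit
#' recomputes the censoring hazard and propensity on its own n-1 subjects;
#' the evaluation summand uses the full-sample hazard and propensity.
#'
#' @inheritParams owl_fit
#' @return A single number.
#' @export
jackknife_value <- function(trial, w, lambda, kernel = "linear", sigma = NULL,
                            h = censoring_hazard(trial),
                            pi = estimate_propensity(trial),
                            control = owl_control()) {
  n <- length(trial$id)
  stopifnot(n >= 3)
  w <- as_pref(w, trial$n_states)
  u <- subject_utilities(trial, unclass(w), h)
  denom <- ifelse(trial$a > 0, pi, 1 - pi)
  s <- vapply(seq_len(n), function(i) {
    sub <- trial_subset(trial, setdiff(seq_len(n), i))
    fit_i <- tryCatch(
      owl_fit(sub, w, lambda, kernel = kernel, sigma = sigma,
              control = control),
      error = function(e) stop("leave-one-out refit failed at subject ",
                               trial$id[i], ": ", conditionMessage(e),
                               call. = FALSE))
    di <- itr_assign(fit_i, trial$z[i, , drop = FALSE])
    u[i] * (trial$a[i] == di) / denom[i]
  }, double(1))
  mean(s)
}

#' Influence-function values and standard error for a value estimate
#'
#' Linearizes the plug-in value estimator: the per-subject influence value
#' has three parts, (a) the centered inverse-probability summand
#' `g_i - V_hat`, (b) a censoring-martingale correction accounting for the
#' estimation of the Nelson-Aalen censoring hazard,
#' `int_0^tau rho_hat(u) / ybar(u) dM_i^C(u)`, and (c) a propensity
#' correction `-c_pi (I(A_i = 1) - pi_hat)` accounting for the estimation of
#' `pi`.  The variance estimate is `sigma2 = mean(psi^2)` and the standard
#' error of the value is `sqrt(sigma2 / n)`.
#'
#' @inheritParams estimate_value
#' @param pi_known If `TRUE`, treats the propensity as known (drops the
#'   propensity correction); used mainly in reduction tests.
#' @return A tibble with one row per subject: `id`, `g` (raw summand) and
#'   `psi` (influence value).  Attributes: `v_hat`, `sigma2`, `se`.
#' @export
influence_values <- function(trial, d, w, h = censoring_hazard(trial),
                             pi = estimate_propensity(trial),
                             pi_known = FALSE) {
  w <- as_pref(w, trial$n_states)
  n <- length(trial$id)
  u <- subject_utilities(trial, unclass(w), h)
  g <- value_summands(trial, d, u, pi)
  v_hat <- mean(g)

  psi <- g - v_hat

  if (nrow(h) > 0) {
    assn <- itr_assign(d, trial$z)
    denom <- ifelse(trial$a > 0, pi, 1 - pi)
    kappa <- (trial$a == assn) / denom
    uk <- h$time
    ybar <- h$n_risk / n
    dLam <- h$increment
    # rho(u_k) = mean_j I(tilde_t_j >= u_k) kappa_j * tail_j(u_k)
    tails <- subject_tail_integrals(trial, unclass(w), h, uk)
    at_risk <- outer(trial$tilde_t, uk, ">=")
    rho <- colMeans(tails * kappa * at_risk)
    # dM_i^C(u) = dN_i^C(u) - Y_i(u) dLambda_hat(u)
    ratio <- rho / ybar
    drift <- cumsum(ratio * dLam)
    k_i <- findInterval(trial$tilde_t, uk)           # jumps with u_k <= tilde_t_i
    mart <- -c(0, drift)[k_i + 1L]
    cens_at <- ifelse(trial$delta == 0L, findInterval(trial$tilde_t, uk), 0L)
    jump_part <- ifelse(cens_at > 0, ratio[pmax(cens_at, 1L)], 0)
    psi <- psi + jump_part + mart
  }

  if (!pi_known) {
    denom <- ifelse(trial$a > 0, pi, 1 - pi)
    c_pi <- mean(g * trial$a / denom)
    psi <- psi - c_pi * ((trial$a == 1L) - pi)
  }

  sigma2 <- mean(psi^2)
  out <- tibble::tibble(id = trial$id, g = g, psi = psi)
  attr(out, "v_hat") <- v_hat
  attr(out, "sigma2") <- sigma2
  attr(out, "se") <- sqrt(sigma2 / n)
  out
}

#' Value estimate with influence-function confidence interval
#'
#' @inheritParams influence_values
#' @param level Confidence level for the pointwise normal interval.
#' @return A one-row tibble: `v_hat`, `se`, `ci_low`, `ci_high`.
#' @export
value_inference <- function(trial, d, w, h = censoring_hazard(trial),
                            pi = estimate_propensity(trial),
                            pi_known = FALSE, level = 0.95) {
  iv <- influence_values(trial, d, w, h = h, pi = pi, pi_known = pi_known)
  v <- attr(iv, "v_hat"); se <- attr(iv, "se")
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(v_hat = v, se = se, ci_low = v - z * se, ci_high = v + z * se)
}

#' Covariance matrix of several value estimates
#'
#' For a list of (rule, weight) pairs, returns the influence-function
#' covariance estimate `Omega_hat` with entries
#' `omega_{l,l'} = n^{-1} sum_i psi_{i,l} psi_{i,l'}` (diagonal entries are
#' the variance estimates `sigma2_l`).  The matrix is symmetrized and, if
#' its smallest eigenvalue falls below `-1e-10`, projected onto the positive
#' semidefinite cone by eigenvalue truncation.
#'
#' @param trial An [ms_trial].
#' @param entries List of `list(d = rule, w = weight)` pairs; rules may mix
#'   fitted and fixed (+1 / -1) rules.
#' @inheritParams influence_values
#' @return A symmetric matrix with attributes `estimates` (the value
#'   estimates, in order) and `n`.
#' @export
value_covariance <- function(trial, entries, h = censoring_hazard(trial),
                             pi = estimate_propensity(trial),
                             pi_known = FALSE) {
  stopifnot(length(entries) >= 1)
  n <- length(trial$id)
  psis <- matrix(0, n, length(entries))
  ests <- double(length(entries))
  for (l in seq_along(entries)) {
    e <- entries[[l]]
    iv <- influence_values(trial, e$d, e$w, h = h, pi = pi, pi_known = pi_known)
    psis[, l] <- iv$psi
    ests[l] <- attr(iv, "v_hat")
  }
  omega <- crossprod(psis) / n
  omega <- (omega + t(omega)) / 2
  ev <- eigen(omega, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    omega <- ev$vectors %*% diag(pmax(ev$values, 0), nrow(omega)) %*% t(ev$vectors)
    omega <- (omega + t(omega)) / 2
  }
  attr(omega, "estimates") <- ests
  attr(omega, "n") <- n
  omega
}

#' Simultaneous confidence intervals via Gaussian multiplier simulation
#'
#' Given `M` estimates with influence covariance `Omega_hat`, draws `B`
#' vectors `G_b ~ N(0, Omega_hat)`, scales componentwise by
#' `Q = diag(1/sigma_l)`, and takes the `1 - alpha` empirical percentile
#' `c_alpha` of `max_l |(Q G_b)_l|`.  The simultaneous intervals are
#' `estimate_l +/- c_alpha * sigma_l / sqrt(n)`; the critical value always
#' dominates the pointwise normal quantile (up to Monte Carlo error).
#' Contrasts (e.g. differences against fixed rules) are handled by passing a
#' contrast matrix `L`: intervals are formed for `L %*% estimates` with
#' covariance `L Omega L'`.
#'
#' @param estimates Numeric vector of value estimates (ignored if `omega`
#'   carries an `estimates` attribute and `estimates` is missing).
#' @param omega Covariance matrix from [value_covariance()].
#' @param n Sample size the estimates were computed from.
#' @param alpha One minus the joint coverage level.
#' @param B Number of multiplier draws (at least 100; default 1000).
#' @param seed Optional integer seed for the draws.
#' @param L Optional contrast matrix (rows = reported quantities).
#' @param labels Optional row labels.
#' @return A `simultaneous_band`: a tibble with columns `label`, `estimate`,
#'   `se`, `low`, `high`, and attributes `c_alpha`, `alpha`, `B`, `seed`.
#' @export
simultaneous_band <- function(estimates = attr(omega, "estimates"), omega,
                              n = attr(omega, "n"), alpha = 0.05, B = 1000,
                              seed = NULL, L = NULL, labels = NULL) {
  stopifnot(B >= 100, alpha > 0, alpha < 1)
  force(n); force(estimates)
  omega <- as.matrix(omega)
  ev <- eigen((omega + t(omega)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("omega is not positive semidefinite", call. = FALSE)
  if (!is.null(L)) {
    L <- as.matrix(L)
    stopifnot(ncol(L) == nrow(omega))
    estimates <- as.vector(L %*% estimates)
    omega <- L %*% omega %*% t(L)
    omega <- (omega + t(omega)) / 2
  }
  M <- nrow(omega)
  sig <- sqrt(pmax(diag(omega), 0))
  # components with zero variance (e.g. a contrast of identical rules) carry
  # no randomness: they are excluded from the max-norm and get width-0 bands
  live <- sig > 1e-12
  if (!any(live)) stop("all components are degenerate (zero variance)", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  # Cholesky with diagonal jitter for semidefinite Omega
  R <- tryCatch(chol(omega), error = function(e) chol(omega + diag(1e-10, M)))
  G <- matrix(stats::rnorm(B * M), B, M) %*% R
  scaled <- abs(sweep(G[, live, drop = FALSE], 2, sig[live], "/"))
  maxstat <- apply(scaled, 1, max)
  c_alpha <- unname(stats::quantile(maxstat, 1 - alpha, type = 1))
  half <- c_alpha * sig / sqrt(n)
  out <- tibble::tibble(
    label = labels %||% paste0("par", seq_len(M)),
    estimate = estimates, se = sig / sqrt(n),
    low = estimates - half, high = estimates + half)
  structure(out, class = c("simultaneous_band", class(out)),
            c_alpha = c_alpha, alpha = alpha, B = B, seed = seed)
}

#' @export
print.simultaneous_band <- function(x, ...) {
  cat("<simultaneous_band> ", nrow(x), " parameter(s), c_alpha = ",
      format(attr(x, "c_alpha"), digits = 4), " (alpha = ", attr(x, "alpha"),
      ", B = ", attr(x, "B"), ")\n", sep = "")
  NextMethod()
}

#' Fit rules for a set of preference weights and report values with
#' simultaneous intervals
#'
#' For each preference weight, fits the linear-class rule, then reports the
#' estimated value of the fitted rule, and its differences against the fixed
#' rules `d = +1` and `d = -1`, with pointwise and simultaneous confidence
#' intervals over all reported parameters (3 per weight).  Inference uses
#' the influence-function covariance; interval half-widths use the
#' multiplier critical value from [simultaneous_band()].  Standard errors
#' are only available for the linear decision class.
#'
#' @inheritParams owl_fit
#' @param weights List of preference weight vectors.
#' @param lambda Penalty; a single value (default `1/sqrt(n)`) used for all
#'   weights, or a vector with one entry per weight.
#' @param alpha One minus the joint coverage level.
#' @param B Multiplier draws.
#' @param seed Optional seed for the multiplier draws.
#' @param jackknife If `TRUE`, adds the jackknife value of each fitted rule.
#' @return A tibble with one row per reported parameter: `w`, `parameter`,
#'   `estimate`, `se`, pointwise `pw_low`/`pw_high` and simultaneous
#'   `sim_low`/`sim_high` bounds; attributes `c_alpha`, `fits`.
#' @export
itr_value_report <- function(trial, weights, lambda = NULL, alpha = 0.05,
                             B = 1000, seed = NULL, jackknife = FALSE,
                             control = owl_control()) {
  stopifnot(inherits(trial, "ms_trial"), length(weights) >= 1)
  n <- length(trial$id)
  if (is.null(lambda)) lambda <- 1 / sqrt(n)
  lambda <- rep_len(lambda, length(weights))
  h <- censoring_hazard(trial)
  pi <- estimate_propensity(trial)

  fits <- purrr::map2(weights, lambda, function(w, l) {
    fit <- owl_fit(trial, w, l, kernel = "linear", h = h, pi = pi,
                   control = control)
    fv <- abs(predict(fit, trial$z))
    if (mean(fv < 1e-6) > 0.01) {
      warning("more than 1% of |f(Z_i)| are below 1e-6; ",
              "near-boundary decision values can distort inference",
              call. = FALSE)
    }
    fit
  })

  entries <- list(); labels <- character(0); wlab <- character(0)
  for (m in seq_along(weights)) {
    wm <- weights[[m]]
    entries <- c(entries,
                 list(list(d = fits[[m]], w = wm),
                      list(d = 1, w = wm),
                      list(d = -1, w = wm)))
  }
  omega <- value_covariance(trial, entries, h = h, pi = pi)
  ests <- attr(omega, "estimates")

  # per weight: value of fitted rule, and contrasts vs the fixed rules
  Lrows <- list(); lab <- character(0); wl <- character(0)
  for (m in seq_along(weights)) {
    base <- 3 * (m - 1)
    e1 <- e2 <- e3 <- rep(0, length(ests))
    e1[base + 1] <- 1
    e2[base + 1] <- 1; e2[base + 2] <- -1
    e3[base + 1] <- 1; e3[base + 3] <- -1
    Lrows <- c(Lrows, list(e1, e2, e3))
    lab <- c(lab, "V(d_hat)", "V(d_hat) - V(+1)", "V(d_hat) - V(-1)")
    wl <- c(wl, rep(paste0("(", paste(weights[[m]], collapse = ","), ")"), 3))
  }
  L <- do.call(rbind, Lrows)
  band <- simultaneous_band(omega = omega, alpha = alpha, B = B, seed = seed,
                            L = L, labels = lab)
  z <- stats::qnorm(1 - alpha / 2)
  out <- tibble::tibble(
    w = wl, parameter = band$label, estimate = band$estimate, se = band$se,
    pw_low = band$estimate - z * band$se, pw_high = band$estimate + z * band$se,
    sim_low = band$low, sim_high = band$high)
  if (jackknife) {
    jk <- vapply(seq_along(weights), function(m) {
      jackknife_value(trial, weights[[m]], lambda[m], control = control)
    }, double(1))
    out$jackknife <- NA_real_
    out$jackknife[out$parameter == "V(d_hat)"] <- jk
  }
  attr(out, "c_alpha") <- attr(band, "c_alpha")
  attr(out, "fits") <- fits
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
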