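#' Preference weights over health states
#'
#' A preference weight `w` is a vector of length `S` with entries in `[0, 1]`
#' whose sum is strictly between 0 and `S`.  It encodes how a patient values
#' time spent in each state: `w = c(0, 1, 0)` counts only time in state 2
#' (e.g., tumor response), `w = c(1, 1, 0)` counts progression-free time,
#' and `w = c(0.5, 1, 0)` is a quality-adjusted lifetime in which time in the
#' initial state is discounted by half.
#'
#' @param w Numeric vector of state weights.
#' @return The validated weight vector, classed `preference_weight`.
#' @export
preference_weight <- function(w) {
  w <- as.double(w)
  if (any(w < 0) || any(w > 1)) {
    stop("preference weights must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(w)
  if (s <= 0 || s >= length(w)) {
    stop("preference weights must have 0 < sum(w) < S", call. = FALSE)
  }
  structure(w, class = "preference_weight")
}

as_pref <- function(w, n_states) {
  w <- preference_weight(unclass(w))
  if (length(w) != n_states) {
    stop("preference weight has length ", length(w), " but the trial has ",
         n_states, " states", call. = FALSE)
  }
  w
}

#' Benefit trajectory of one subject
#'
#' The benefit process is `Y_w(t) = w[X(t)]`, the preference weight of the
#' state occupied at time `t`; it is a piecewise-constant step function.  For
#' a subject that reached an absorbing state before `tau` the trajectory
#' continues at the absorbing state's weight through `tau`; for a censored
#' subject it is only defined up to `tilde_t`.
#'
#' @param path A [state_path].
#' @param w A [preference_weight] (length = number of states).
#' @param tau Positive horizon.
#' @return A tibble with columns `start`, `end`, `level`: the value of
#'   `Y_w` on each interval of `[0, min(tilde_t or tau)]`.
#' @export
benefit_trajectory <- function(path, w, tau) {
  stopifnot(inherits(path, "state_path"), tau > 0)
  w <- preference_weight(unclass(w))
  if (any(path$states > length(w))) {
    stop("state outside 1..", length(w), call. = FALSE)
  }
  upper <- if (path$delta == 1L) tau else min(path$tilde_t, tau)
  breaks <- sort(unique(c(path$times[path$times < upper], upper)))
  starts <- breaks[-length(breaks)]
  ends <- breaks[-1]
  st <- path$states[findInterval((starts + ends) / 2, path$times)]
  tibble::tibble(start = starts, end = ends, level = w[st])
}

#' Utility of a fully observed trajectory
#'
#' The utility is the Lebesgue integral `int_0^tau Y_w(t) dt`, i.e. the
#' preference-weighted sum of restricted state-occupation times up to `tau`.
#' Requires an uncensored path (`delta = 1`); for censored subjects use
#' [ipcw_utility()].
#'
#' @inheritParams benefit_trajectory
#' @return A non-negative number in `[0, tau * max(w)]`.
#' @export
raw_utility <- function(path, w, tau) {
  stopifnot(inherits(path, "state_path"))
  if (path$delta != 1L) {
    stop("raw_utility requires an uncensored path (delta = 1); use ipcw_utility",
         call. = FALSE)
  }
  traj <- benefit_trajectory(path, w, tau)
  sum((traj$end - traj$start) * traj$level)
}

## Piecewise-constant IPCW-weighted integrand for one subject.
##
## The estimand contribution is  int_0^tau Y_w(t) I(C >= T ^ t)
## exp{Lambda_hat((tilde_t ^ t)-)} dt.  The indicator I(C >= T ^ t) is not
## directly observable but reduces to observables by cases:
##   * delta = 1 (T <= C):  for t <= T,  T^t = t <= T <= C so I = 1;
##     for t > T, T^t = T <= C so I = 1.  Hence I = 1 for ALL t in [0, tau].
##   * delta = 0 (C < T):   for t <= C,  T^t = t <= C so I = 1;
##     for t > C (= tilde_t), T^t = min(T, t) > C so I = 0.
##     Hence the contribution region is t in [0, tilde_t].
## The integrand is therefore piecewise constant on the common refinement of
## the path breakpoints, the hazard jump times below tilde_t, tilde_t itself
## and tau, and the integral is an exact breakpoint sum (single points carry
## no Lebesgue mass).
##
## Returns breaks b_0 < ... < b_K and levels l_1..l_K on the intervals.
ipcw_integrand <- function(times, states, tilde_t, delta, w, hjump, hcum, tau) {
  upper <- if (delta == 1L) tau else min(tilde_t, tau)
  if (upper <= 0) return(list(breaks = c(0, 0), levels = 0))
  b <- c(times[times < upper], hjump[hjump < min(tilde_t, upper)], upper)
  if (tilde_t < upper) b <- c(b, tilde_t)
  b <- sort(unique(c(0, b)))
  mids <- (b[-length(b)] + b[-1]) / 2
  st <- states[findInterval(mids, times)]
  s <- pmin(tilde_t, mids)
  # left limit Lambda_hat(s-): count of jumps strictly below s
  k <- findInterval(s, hjump, left.open = TRUE)
  lev <- w[st] * exp(c(0, hcum)[k + 1L])
  list(breaks = b, levels = lev)
}

#' IPCW-weighted utility of one (possibly censored) record
#'
#' Estimates a subject's utility contribution under right censoring by
#' weighting the observed benefit process with the reciprocal of the
#' estimated censoring survival, `exp{Lambda_hat((tilde_t ^ t)-)}`.
#' Uncensored subjects contribute on all of `[0, tau]`; censored subjects
#' contribute on `[0, tilde_t]` only.  With no censoring in the dataset the
#' result equals [raw_utility()].
#'
#' @param path A [state_path].
#' @param w A [preference_weight].
#' @param h A [censoring_hazard] estimated from the same dataset.
#' @param tau Positive horizon.
#' @return A non-negative number.
#' @export
ipcw_utility <- function(path, w, h, tau) {
  stopifnot(inherits(path, "state_path"), inherits(h, "censoring_hazard"))
  w <- preference_weight(unclass(w))
  if (any(path$states > length(w))) {
    stop("state outside 1..", length(w), call. = FALSE)
  }
  pc <- ipcw_integrand(path$times, path$states, path$tilde_t, path$delta,
                       unclass(w), h$time, h$cum_hazard, tau)
  sum(diff(pc$breaks) * pc$levels)
}

#' Per-subject IPCW utilities for a whole trial
#'
#' @param trial An [ms_trial].
#' @param w A preference weight vector (length = number of states).
#' @param h A [censoring_hazard]; defaults to the Nelson-Aalen estimate from
#'   `trial`.
#' @return A tibble with columns `id` and `utility`.
#' @export
ipcw_utilities <- function(trial, w, h = censoring_hazard(trial)) {
  stopifnot(inherits(trial, "ms_trial"))
  w <- as_pref(w, trial$n_states)
  u <- subject_utilities(trial, unclass(w), h)
  tibble::tibble(id = trial$id, utility = u)
}

## vectorized over subjects; returns plain numeric vector
subject_utilities <- function(trial, w, h) {
  n <- length(trial$id)
  hj <- h$time; hc <- h$cum_hazard; tau <- trial$tau
  vapply(seq_len(n), function(i) {
    pc <- ipcw_integrand(trial$path_times[[i]], trial$path_states[[i]],
                         trial$tilde_t[i], trial$delta[i], w, hj, hc, tau)
    sum(diff(pc$breaks) * pc$levels)
  }, double(1))
}

## Tail integrals of each subject's IPCW integrand, evaluated at a grid u:
## M[i, k] = int_{u_k}^{tau} (subject i's integrand)(t) dt.
## The integrand is piecewise constant, so the tail integral is piecewise
## linear in u with kinks at the subject's breakpoints.
subject_tail_integrals <- function(trial, w, h, u) {
  n <- length(trial$id)
  hj <- h$time; hc <- h$cum_hazard; tau <- trial$tau
  out <- matrix(0, n, length(u))
  if (length(u) == 0) return(out)
  for (i in seq_len(n)) {
    pc <- ipcw_integrand(trial$path_times[[i]], trial$path_states[[i]],
                         trial$tilde_t[i], trial$delta[i], w, hj, hc, tau)
    b <- pc$breaks
    tail_at_b <- rev(c(0, cumsum(rev(pc$levels * diff(b)))))
    out[i, ] <- stats::approx(b, tail_at_b, xout = pmin(pmax(u, b[1]), b[length(b)]),
                              method = "linear", ties = "ordered")$y
  }
  out
}
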