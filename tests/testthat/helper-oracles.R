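## Shared fixtures and independent oracles used across the test files.

## Build a small trial from per-subject specs; each subject sits in state 2
## from time `start2` until death/censoring, so w = (0,1,0) utilities are
## transparent.  `death` = NA means censored at `end`.
toy_trial <- function(z, a, start2, end, delta, tau = 3) {
  n <- length(a)
  rows <- lapply(seq_len(n), function(i) {
    if (!is.na(start2[i]) && start2[i] == 0) {
      tt <- 0; ss <- 2
    } else {
      tt <- 0; ss <- 1
      if (!is.na(start2[i]) && start2[i] <= end[i]) { tt <- c(tt, start2[i]); ss <- c(ss, 2) }
    }
    if (delta[i] == 1 && end[i] < tau) { tt <- c(tt, end[i]); ss <- c(ss, 3) }
    tibble::tibble(id = i, z1 = z[i, 1], z2 = z[i, 2], a = a[i],
                   entry_time = tt, state = ss, tilde_t = end[i],
                   delta = delta[i])
  })
  ms_trial(dplyr::bind_rows(rows), tau = tau, n_states = 3)
}

## Dense iterated grid search over (b0, beta): an optimizer that shares no
## code with the package solver.  Returns the best objective value found.
grid_search_objective <- function(Z, y, cw, lambda, rounds = 8, m = 21,
                                  half_width = 6) {
  p <- ncol(Z)
  n <- length(y)
  ctr <- rep(0, p + 1)
  width <- 2 * half_width
  best <- Inf
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p + 1), function(j) {
      seq(ctr[j] - width / 2, ctr[j] + width / 2, length.out = m)
    })
    G <- as.matrix(expand.grid(grids))
    FV <- G[, 1] + tcrossprod(G[, -1, drop = FALSE], Z)   # grid x n
    hinge <- pmax(1 - sweep(FV, 2, y, "*"), 0)
    obj <- as.vector(hinge %*% (cw / n)) +
      lambda * rowSums(G[, -1, drop = FALSE]^2)
    i <- which.min(obj)
    ctr <- G[i, ]; best <- obj[i]
    width <- width * 4 / m
  }
  best
}

## Case weights exactly as owl_fit builds them.
owl_case_weights <- function(trial, w, h = censoring_hazard(trial),
                             pi = estimate_propensity(trial)) {
  u <- ipcw_utilities(trial, w, h)$utility
  denom <- ifelse(trial$a > 0, pi, 1 - pi)
  u / denom
}

## Penalized objective of a linear decision function, computed from public
## API pieces only.
linear_objective <- function(b0, beta, trial, w, lambda,
                             h = censoring_hazard(trial),
                             pi = estimate_propensity(trial)) {
  f <- function(Z) b0 + as.vector(Z %*% beta)
  surrogate_risk(f, trial, w, h = h, pi = pi) + lambda * sum(beta^2)
}

## Deterministic small simulated trial reused by several files.
sim_fixture <- function(n = 60, scenario = 1, theta = -1.6, seed = 123) {
  simulate_trial(n, scenario, theta, seed = seed)
}
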