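#' Assemble a multistate trial dataset from a long-format table
#'
#' A trial dataset holds, for each subject, baseline covariates `z1..zp`, a
#' binary treatment `a` coded -1/+1, and the right-censored multistate
#' trajectory: the ordered state-entry records `(entry_time, state)`, the end
#' of observation `tilde_t` (the minimum of the event time `T` and the
#' censoring time `C`), and the event indicator `delta` (1 if `T <= C`).
#' Trajectories are right-continuous step functions: a subject occupies the
#' state of its most recent entry.  The event time is `T = min(T*, tau)`,
#' where `T*` is the arrival time at an absorbing state, so a subject still
#' under observation at the horizon `tau` has `tilde_t = tau`, `delta = 1`
#' (administrative truncation at `tau` is not censoring).
#'
#' @param data A data frame in long format with one row per state entry and
#'   columns `id`, the covariate columns, `a`, `entry_time`, `state`,
#'   `tilde_t`, `delta`.  `tilde_t` and `delta` must be constant within `id`.
#' @param tau Positive analysis horizon, in study time units.
#' @param n_states Number of states `S`; defaults to the largest state
#'   observed.
#' @param covariates Character vector naming the covariate columns; defaults
#'   to every column whose name starts with `"z"`.
#' @param absorbing States with no outgoing transitions; defaults to
#'   `n_states` (the final state of a progressive model).
#' @param validate Set `FALSE` to skip invariant checks (used internally by
#'   the simulator, which generates valid data by construction).
#'
#' @return An object of class `ms_trial`.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   id = c(1, 1, 1, 2), z1 = 0.2, z2 = -0.1,
#'   a = c(1, 1, 1, -1),
#'   entry_time = c(0, 1, 2.5, 0), state = c(1, 2, 3, 1),
#'   tilde_t = c(2.5, 2.5, 2.5, 1.4), delta = c(1, 1, 1, 0)
#' )
#' ms_trial(tbl, tau = 3)
ms_trial <- function(data, tau, n_states = NULL, covariates = NULL,
                     absorbing = NULL, validate = TRUE) {
  stopifnot(is.data.frame(data), is.numeric(tau), length(tau) == 1L, tau > 0)
  required <- c("id", "a", "entry_time", "state", "tilde_t", "delta")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- setdiff(grep("^z", names(data), value = TRUE), required)
  }
  if (length(covariates) == 0) {
    stop("schema error: no covariate columns found (expected names starting with 'z')",
         call. = FALSE)
  }

  data <- dplyr::arrange(data, .data$id, .data$entry_time)
  ids <- unique(data$id)
  idx <- split(seq_len(nrow(data)), factor(data$id, levels = ids))

  first <- vapply(idx, `[`, integer(1), 1L)
  z <- as.matrix(data[first, covariates, drop = FALSE])
  storage.mode(z) <- "double"
  a <- as.integer(data$a[first])
  tilde_t <- as.double(data$tilde_t[first])
  delta <- as.integer(data$delta[first])
  path_times <- lapply(idx, function(i) as.double(data$entry_time[i]))
  path_states <- lapply(idx, function(i) as.integer(data$state[i]))

  if (is.null(n_states)) n_states <- max(data$state)
  if (is.null(absorbing)) absorbing <- n_states

  out <- structure(
    list(id = ids, z = z, a = a, tilde_t = tilde_t, delta = delta,
         path_times = path_times, path_states = path_states,
         tau = tau, n_states = as.integer(n_states),
         absorbing = as.integer(absorbing)),
    class = "ms_trial")
  if (validate) validate_ms_trial(out, data, idx)
  out
}

validate_ms_trial <- function(x, data = NULL, idx = NULL) {
  n <- length(x$id)
  if (n < 1) stop("validation error: empty dataset", call. = FALSE)
  if (!all(x$a %in% c(-1L, 1L))) {
    bad <- x$id[!(x$a %in% c(-1L, 1L))][1]
    stop("validation error: treatment must be -1/+1 (subject ", bad, ")",
         call. = FALSE)
  }
  if (any(!is.finite(x$z))) {
    bad <- x$id[rowSums(!is.finite(x$z)) > 0][1]
    stop("validation error: non-finite covariate (subject ", bad, ")", call. = FALSE)
  }
  if (any(x$tilde_t < 0) || any(x$tilde_t > x$tau + 1e-12)) {
    bad <- x$id[x$tilde_t < 0 | x$tilde_t > x$tau + 1e-12][1]
    stop("validation error: tilde_t outside [0, tau] (subject ", bad, ")",
         call. = FALSE)
  }
  if (!all(x$delta %in% c(0L, 1L))) {
    stop("validation error: delta must be 0/1", call. = FALSE)
  }
  if (!is.null(data) && !is.null(idx)) {
    for (nm in c("a", "tilde_t", "delta")) {
      ok <- vapply(idx, function(i) length(unique(data[[nm]][i])) == 1L, logical(1))
      if (!all(ok)) {
        stop("validation error: '", nm, "' varies within subject ",
             x$id[!ok][1], call. = FALSE)
      }
    }
  }
  for (i in seq_len(n)) {
    tt <- x$path_times[[i]]; ss <- x$path_states[[i]]
    if (tt[1] != 0) {
      stop("validation error: first entry must be at time 0 (subject ", x$id[i], ")",
           call. = FALSE)
    }
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      stop("validation error: entry times not strictly increasing (subject ",
           x$id[i], ")", call. = FALSE)
    }
    if (any(ss < 1L | ss > x$n_states)) {
      stop("validation error: state outside 1..", x$n_states, " (subject ",
           x$id[i], ")", call. = FALSE)
    }
    if (any(tt > x$tilde_t[i] + 1e-12)) {
      stop("validation error: entry time after tilde_t (subject ", x$id[i], ")",
           call. = FALSE)
    }
    k <- which(ss %in% x$absorbing)
    if (length(k) > 0 && min(k) < length(ss)) {
      stop("validation error: transition out of an absorbing state (subject ",
           x$id[i], ")", call. = FALSE)
    }
  }
  if (length(unique(x$a)) < 2 && n >= 2) {
    warning("only one treatment arm present; estimation functions will fail",
            call. = FALSE)
  }
  invisible(x)
}

#' @export
print.ms_trial <- function(x, ...) {
  cat("<ms_trial> ", length(x$id), " subjects, ", ncol(x$z), " covariate(s), ",
      x$n_states, " states, tau = ", format(x$tau), "\n", sep = "")
  cat("  treated (+1): ", sum(x$a == 1), ";  censored: ", sum(x$delta == 0),
      " (", sprintf("%.1f%%", 100 * mean(x$delta == 0)), ")\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.ms_trial <- function(x, ...) {
  n_rows <- lengths(x$path_times)
  rep_i <- rep(seq_along(x$id), n_rows)
  zt <- tibble::as_tibble(x$z[rep_i, , drop = FALSE])
  dplyr::bind_cols(
    tibble::tibble(id = x$id[rep_i]),
    zt,
    tibble::tibble(
      a = x$a[rep_i],
      entry_time = unlist(x$path_times),
      state = unlist(x$path_states),
      tilde_t = x$tilde_t[rep_i],
      delta = x$delta[rep_i]))
}

#' Read / write a multistate trial as a long-format CSV
#'
#' The file dialect is comma-separated with a header row, UTF-8, one row per
#' state entry, columns `id, z1..zp, a, entry_time, state, tilde_t, delta`,
#' times as decimal reals in study time units.
#'
#' @param file Path to a CSV file.
#' @inheritParams ms_trial
#' @return `read_ms_trial()` returns an [ms_trial]; `write_ms_trial()`
#'   returns `trial` invisibly.
#' @export
read_ms_trial <- function(file, tau, n_states = NULL, covariates = NULL,
                          absorbing = NULL) {
  tbl <- readr::read_csv(file, show_col_types = FALSE)
  ms_trial(tbl, tau = tau, n_states = n_states, covariates = covariates,
           absorbing = absorbing)
}

#' @rdname read_ms_trial
#' @param trial An [ms_trial].
#' @export
write_ms_trial <- function(trial, file) {
  readr::write_csv(as_tibble.ms_trial(trial), file)
  invisible(trial)
}

#' Estimated propensity of assignment to the +1 arm
#'
#' In a two-arm randomized trial the propensity is a constant
#' `pi0 = P(A = 1)`, estimated by the sample fraction assigned to the +1 arm.
#' The estimate is used in the inverse-probability denominators even when the
#' randomization ratio is known, which typically improves efficiency.
#'
#' @param trial An [ms_trial].
#' @return A single number in (0, 1).
#' @export
estimate_propensity <- function(trial) {
  stopifnot(inherits(trial, "ms_trial"))
  p <- mean(trial$a == 1L)
  if (p <= 0 || p >= 1) {
    stop("positivity error: both treatment arms must be present", call. = FALSE)
  }
  p
}

## fast subset used by the jackknife; keeps ids and tau
trial_subset <- function(trial, keep) {
  structure(
    list(id = trial$id[keep], z = trial$z[keep, , drop = FALSE],
         a = trial$a[keep], tilde_t = trial$tilde_t[keep],
         delta = trial$delta[keep],
         path_times = trial$path_times[keep],
         path_states = trial$path_states[keep],
         tau = trial$tau, n_states = trial$n_states,
         absorbing = trial$absorbing),
    class = "ms_trial")
}

#' Extract one subject's observed trajectory
#'
#' @param trial An [ms_trial].
#' @param i Subject position (row index), 1..n.
#' @return A `state_path` list with fields `times`, `states`, `tilde_t`,
#'   `delta`.
#' @export
subject_path <- function(trial, i) {
  state_path(trial$path_times[[i]], trial$path_states[[i]],
             trial$tilde_t[i], trial$delta[i])
}

#' Construct a single censored multistate trajectory
#'
#' @param times Strictly increasing entry times, starting at 0.
#' @param states States entered at `times`, integers in `1..S`.
#' @param tilde_t End of observation, `min(T, C)`.
#' @param delta Event indicator `I(T <= C)`.
#' @return A `state_path` object.
#' @export
state_path <- function(times, states, tilde_t, delta) {
  stopifnot(length(times) == length(states), times[1] == 0,
            all(diff(times) > 0), tilde_t >= max(times) - 1e-12,
            delta %in% c(0, 1))
  structure(list(times = as.double(times), states = as.integer(states),
                 tilde_t = as.double(tilde_t), delta = as.integer(delta)),
            class = "state_path")
}
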