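#' Nelson-Aalen estimator of the censoring cumulative hazard
#'
#' Treats censoring as the "event" of interest: the counting process is
#' `N_i(t) = (1 - delta_i) I(tilde_t_i <= t)` and the at-risk process is
#' `Y_i(t) = I(tilde_t_i >= t)`, so subjects whose event occurs at `u` are
#' still in the risk set for censorings at `u`.  The estimator is the step
#' function `Lambda_hat(t) = sum_{u <= t} (# censored at u) / (# at risk at u)`.
#'
#' @param trial An [ms_trial], or a data frame with columns `tilde_t`, `delta`.
#' @return A `censoring_hazard` object: a tibble with one row per censoring
#'   time (`time`, `n_risk`, `n_censored`, `increment`, `cum_hazard`), and
#'   attribute `n` (sample size).  With no censored subjects the table is
#'   empty and the hazard is identically zero.
#' @export
#' @examples
#' h <- censoring_hazard(data.frame(tilde_t = c(1, 2, 3), delta = c(1, 0, 1)))
#' cumhaz(h, c(1.5, 2, 2.5))   # 0, 0.5, 0.5
censoring_hazard <- function(trial) {
  if (inherits(trial, "ms_trial")) {
    tt <- trial$tilde_t; dd <- trial$delta
  } else {
    tt <- trial$tilde_t; dd <- trial$delta
    stopifnot(!is.null(tt), !is.null(dd))
  }
  n <- length(tt)
  ct <- sort(unique(tt[dd == 0]))
  if (length(ct) == 0) {
    tab <- tibble::tibble(time = double(), n_risk = integer(),
                          n_censored = integer(), increment = double(),
                          cum_hazard = double())
  } else {
    n_cens <- vapply(ct, function(u) sum(tt == u & dd == 0), double(1))
    n_risk <- vapply(ct, function(u) sum(tt >= u), double(1))
    inc <- n_cens / n_risk
    tab <- tibble::tibble(time = ct, n_risk = as.integer(n_risk),
                          n_censored = as.integer(n_cens), increment = inc,
                          cum_hazard = cumsum(inc))
  }
  structure(tab, class = c("censoring_hazard", class(tab)), n = n)
}

#' Evaluate a censoring cumulative hazard
#'
#' @param h A `censoring_hazard`.
#' @param t Vector of times, `t >= 0`.
#' @param side `"right"` for the cadlag value `Lambda_hat(t)`, `"left"` for
#'   the left limit `Lambda_hat(t-)` (excludes a jump exactly at `t`).
#' @return Numeric vector of cumulative-hazard values.
#' @export
cumhaz <- function(h, t, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(h, "censoring_hazard"))
  if (nrow(h) == 0) return(rep(0, length(t)))
  k <- findInterval(t, h$time, left.open = (side == "left"))
  c(0, h$cum_hazard)[k + 1L]
}

#' Inverse-probability-of-censoring weight at a time point
#'
#' Returns `1 / S_C_hat(s-) = exp(Lambda_hat(s-))`, the reciprocal of the
#' estimated censoring survival just before `s`.  The left limit is the
#' standard convention: a subject's weight at its own censoring time must not
#' include its own censoring jump.
#'
#' @inheritParams cumhaz
#' @param s Vector of times, `s >= 0`.
#' @return Numeric weights, all `>= 1`.
#' @export
ipcw_weight <- function(h, s) {
  exp(cumhaz(h, s, side = "left"))
}

#' @export
print.censoring_hazard <- function(x, ...) {
  cat("<censoring_hazard> Nelson-Aalen, ", nrow(x), " jump(s), n = ",
      attr(x, "n"), "\n", sep = "")
  if (nrow(x) > 0) NextMethod()
  invisible(x)
}

#' Export / import the censoring hazard as a two-column table
#'
#' For reproducibility logs: the step function is fully determined by its
#' jump times and cumulative values.
#'
#' @param h A `censoring_hazard`.
#' @param file CSV path.
#' @export
write_censoring_hazard <- function(h, file) {
  readr::write_csv(tibble::tibble(jump_time = h$time, cum_hazard = h$cum_hazard),
                   file)
  invisible(h)
}

#' @rdname write_censoring_hazard
#' @param n Sample size the hazard was computed from (stored as attribute).
#' @export
read_censoring_hazard <- function(file, n = NA_integer_) {
  tab <- readr::read_csv(file, show_col_types = FALSE)
  inc <- diff(c(0, tab$cum_hazard))
  out <- tibble::tibble(time = tab$jump_time, n_risk = NA_integer_,
                        n_censored = NA_integer_, increment = inc,
                        cum_hazard = tab$cum_hazard)
  structure(out, class = c("censoring_hazard", class(out)), n = n)
}

#' @export
autoplot.censoring_hazard <- function(object, ...) {
  df <- tibble::tibble(
    time = c(0, rep(object$time, each = 2)),
    cum_hazard = c(0, 0, rep(object$cum_hazard, each = 2)[seq_len(2 * nrow(object) - 1)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cum_hazard)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = expression(hat(Lambda)[C](t)),
                  title = "Nelson-Aalen censoring cumulative hazard")
}
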