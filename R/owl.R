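#' Fit an outcome-weighted-learning treatment rule
#'
#' Estimates the decision function `f` minimizing the penalized empirical
#' surrogate risk
#' \deqn{\frac1n \sum_i U_{i,w}\,\phi(A_i f(Z_i)) / \{A_i\hat\pi + (1-A_i)/2\}
#'   + \lambda \|f\|^2,}
#' where `U_{i,w}` is the subject's IPCW-weighted utility, `phi(x) =
#' max(0, 1 - x)` is the hinge loss, and the norm is the Euclidean norm of
#' the slope for the linear class or the RKHS norm for the Gaussian-kernel
#' class.  The treatment rule is `d(z) = sgn(f(z))` with `sgn(0) = +1`.
#' The intercept is not penalized (standard support-vector convention).
#'
#' The convex objective is minimized in the primal by smoothed-hinge
#' (Huber) continuation with BFGS, followed by an exact line search over the
#' intercept, where the objective is piecewise linear.  The solve is
#' deterministic (zero initialization, no randomness).
#'
#' @param trial An [ms_trial].
#' @param w Preference weight vector (length = number of states).
#' @param lambda Positive ridge penalty; the reference choice in the
#'   validation studies is `1/sqrt(n)`.
#' @param kernel `"linear"` or `"gaussian"`.
#' @param sigma Gaussian kernel scale (`k(z1, z2) = exp(-sigma ||z1 - z2||^2)`);
#'   required for `kernel = "gaussian"`.
#' @param h Censoring hazard; defaults to the Nelson-Aalen estimate.
#' @param pi Propensity `P(A = 1)` used in the weights; defaults to the
#'   sample estimate (recommended even when the randomization ratio is known).
#' @param control List of solver settings, see [owl_control()].
#' @return An object of class `owl_fit` with elements `kind`, `intercept`,
#'   `coefs` (linear) or `alphas`/`support`/`sigma` (kernel), `lambda`, `w`,
#'   `pi`, `objective`, `surrogate_risk`, and `diagnostics`.
#' @export
#' @examples
#' trial <- simulate_trial(n = 100, scenario = 1, theta = -1.6, seed = 1)
#' fit <- owl_fit(trial, w = c(0, 1, 0), lambda = 1 / sqrt(100))
#' tidy(fit)
#' itr_assign(fit, rbind(c(0.5, 0.5), c(-0.5, -0.5)))
owl_fit <- function(trial, w, lambda, kernel = c("linear", "gaussian"),
                    sigma = NULL, h = censoring_hazard(trial),
                    pi = estimate_propensity(trial), control = owl_control()) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(trial, "ms_trial"), lambda > 0, pi > 0, pi < 1)
  w <- as_pref(w, trial$n_states)
  u <- subject_utilities(trial, unclass(w), h)
  y <- as.double(trial$a)
  denom <- ifelse(y > 0, pi, 1 - pi)
  cw <- u / denom                       # fixed non-negative case weights
  Z <- trial$z
  n <- length(y)

  if (all(cw <= 0)) {
    warning("all case weights are zero; returning the zero decision function",
            call. = FALSE)
    fit <- zero_owl_fit(kernel, Z, sigma, lambda, w, pi)
    fit$surrogate_risk <- 0
    fit$objective <- 0
    return(fit)
  }

  if (kernel == "linear") {
    sol <- solve_weighted_hinge_linear(Z, y, cw, lambda, control)
    fit <- structure(
      list(kind = "linear", intercept = sol$b0, coefs = sol$beta,
           alphas = NULL, support = NULL, sigma = NULL,
           lambda = lambda, w = w, pi = pi,
           objective = sol$objective,
           diagnostics = sol$diagnostics),
      class = "owl_fit")
  } else {
    if (is.null(sigma) || sigma <= 0) {
      stop("kernel = 'gaussian' requires a positive sigma", call. = FALSE)
    }
    sol <- solve_weighted_hinge_kernel(Z, y, cw, lambda, sigma, control)
    fit <- structure(
      list(kind = "gaussian_kernel", intercept = sol$b0, coefs = NULL,
           alphas = sol$alpha, support = Z, sigma = sigma,
           lambda = lambda, w = w, pi = pi,
           objective = sol$objective,
           diagnostics = sol$diagnostics),
      class = "owl_fit")
  }
  fit$surrogate_risk <- mean(cw * pmax(0, 1 - y * predict(fit, Z)))
  fit
}

#' Solver settings for [owl_fit()]
#'
#' @param deltas Decreasing Huber smoothing widths for the hinge
#'   continuation; the final width bounds the smoothing error of the
#'   objective by `delta/2 * mean(case weight)`.
#' @param maxit BFGS iteration cap per continuation stage.
#' @param reltol BFGS relative convergence tolerance.
#' @export
owl_control <- function(deltas = c(1e-1, 1e-3, 1e-5, 1e-7),
                        maxit = 1000L, reltol = 1e-14) {
  list(deltas = deltas, maxit = maxit, reltol = reltol)
}

huber_hinge <- function(x, d) {
  ifelse(x >= 1, 0, ifelse(x <= 1 - d, 1 - x - d / 2, (1 - x)^2 / (2 * d)))
}
huber_hinge_grad <- function(x, d) {
  ifelse(x >= 1, 0, ifelse(x <= 1 - d, -1, -(1 - x) / d))
}

## exact minimization over the intercept given the rest of f: the weighted
## hinge sum is piecewise linear and convex in b0, with kinks at y_i - s_i;
## ties in the optimum are broken toward the smallest evaluated candidate.
polish_intercept <- function(s, y, cw) {
  kinks <- sort(unique(y * (1 - y * s)))
  cand <- unique(c(kinks, (kinks[-1] + kinks[-length(kinks)]) / 2))
  vals <- vapply(cand, function(b0) sum(cw * pmax(0, 1 - y * (b0 + s))), double(1))
  cand[which.min(vals)]
}

solve_weighted_hinge_linear <- function(Z, y, cw, lambda, control) {
  n <- length(y); p <- ncol(Z)
  th <- rep(0, p + 1)
  conv <- 0L
  for (d in control$deltas) {
    fn <- function(th) {
      f <- th[1] + as.vector(Z %*% th[-1])
      mean(cw * huber_hinge(y * f, d)) + lambda * sum(th[-1]^2)
    }
    gr <- function(th) {
      f <- th[1] + as.vector(Z %*% th[-1])
      g <- cw * huber_hinge_grad(y * f, d) * y / n
      c(sum(g), as.vector(crossprod(Z, g)) + 2 * lambda * th[-1])
    }
    o <- stats::optim(th, fn, gr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
    th <- o$par; conv <- o$convergence
  }
  beta <- th[-1]
  s <- as.vector(Z %*% beta)
  b0 <- polish_intercept(s, y, cw / n)
  obj <- mean(cw * pmax(0, 1 - y * (b0 + s))) + lambda * sum(beta^2)
  list(b0 = b0, beta = beta, objective = obj,
       diagnostics = list(convergence = conv,
                          n_positive_weight = sum(cw > 0)))
}

gaussian_kernel_matrix <- function(X, Y, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-sigma * pmax(d2, 0))
}

solve_weighted_hinge_kernel <- function(Z, y, cw, lambda, sigma, control) {
  n <- length(y)
  K <- gaussian_kernel_matrix(Z, Z, sigma)
  th <- rep(0, n + 1)                    # (b0, alpha)
  conv <- 0L
  for (d in control$deltas) {
    fn <- function(th) {
      f <- th[1] + as.vector(K %*% th[-1])
      mean(cw * huber_hinge(y * f, d)) + lambda * sum(th[-1] * (K %*% th[-1]))
    }
    gr <- function(th) {
      a <- th[-1]
      f <- th[1] + as.vector(K %*% a)
      g <- cw * huber_hinge_grad(y * f, d) * y / n
      c(sum(g), as.vector(K %*% g) + 2 * lambda * as.vector(K %*% a))
    }
    o <- stats::optim(th, fn, gr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
    th <- o$par; conv <- o$convergence
  }
  alpha <- th[-1]
  s <- as.vector(K %*% alpha)
  b0 <- polish_intercept(s, y, cw / n)
  obj <- mean(cw * pmax(0, 1 - y * (b0 + s))) + lambda * sum(alpha * (K %*% alpha))
  list(b0 = b0, alpha = alpha, objective = obj,
       diagnostics = list(convergence = conv,
                          n_positive_weight = sum(cw > 0)))
}

zero_owl_fit <- function(kernel, Z, sigma, lambda, w, pi) {
  if (kernel == "linear") {
    structure(list(kind = "linear", intercept = 0, coefs = rep(0, ncol(Z)),
                   alphas = NULL, support = NULL, sigma = NULL,
                   lambda = lambda, w = w, pi = pi, objective = 0,
                   diagnostics = list(convergence = 0L, n_positive_weight = 0L)),
              class = "owl_fit")
  } else {
    structure(list(kind = "gaussian_kernel", intercept = 0, coefs = NULL,
                   alphas = rep(0, nrow(Z)), support = Z, sigma = sigma,
                   lambda = lambda, w = w, pi = pi, objective = 0,
                   diagnostics = list(convergence = 0L, n_positive_weight = 0L)),
              class = "owl_fit")
  }
}

#' Evaluate a fitted decision function
#'
#' @param object An `owl_fit`.
#' @param newdata Covariate matrix (rows = subjects) or vector (one subject).
#' @param type `"link"` for `f(z)`, `"treatment"` for `sgn(f(z))`.
#' @param ... Unused.
#' @return Numeric vector of decision values or -1/+1 assignments.
#' @export
predict.owl_fit <- function(object, newdata, type = c("link", "treatment"), ...) {
  type <- match.arg(type)
  Z <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  f <- if (object$kind == "linear") {
    object$intercept + as.vector(Z %*% object$coefs)
  } else {
    object$intercept +
      as.vector(gaussian_kernel_matrix(Z, object$support, object$sigma) %*% object$alphas)
  }
  if (type == "link") f else sgn(f)
}

#' Sign convention of the treatment rule
#'
#' `sgn(x) = +1` for `x >= 0` and `-1` for `x < 0`; ties at zero assign the
#' +1 arm.
#'
#' @param x Numeric vector.
#' @return Vector of -1/+1.
#' @export
sgn <- function(x) ifelse(x >= 0, 1, -1)

#' Treatment assignment for new patients
#'
#' @param f An `owl_fit`, a function `z -> f(z)` applied to covariate rows,
#'   or a fixed rule given as scalar `+1` or `-1`.
#' @param z Covariate matrix or single covariate vector.
#' @return Vector of -1/+1 assignments (`sgn(f(z))`, with `sgn(0) = +1`).
#' @export
itr_assign <- function(f, z) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  sgn(rule_values(f, Z))
}

## decision-function values for the rule argument conventions used throughout
rule_values <- function(f, Z) {
  if (inherits(f, "owl_fit")) return(predict(f, Z, type = "link"))
  if (is.function(f)) return(as.double(f(Z)))
  if (is.numeric(f) && length(f) == 1 && f %in% c(-1, 1)) {
    return(rep(as.double(f), nrow(Z)))
  }
  stop("rule must be an owl_fit, a function of z, or a fixed +1/-1", call. = FALSE)
}

#' Empirical surrogate (hinge) or 0-1 risk of a decision function
#'
#' The surrogate risk is `(1/n) sum_i U_i phi(A_i f(Z_i)) / denom_i` with
#' `phi` the hinge loss; with `loss = "zero_one"` the hinge is replaced by
#' `I(A_i f(Z_i) < 0)`, i.e. the weighted misallocation risk.  The 0-1 risk
#' and the estimated value of `sgn(f)` always sum to the total weighted mass
#' `(1/n) sum_i U_i / denom_i`.
#'
#' @param f Rule as in [itr_assign()].
#' @inheritParams owl_fit
#' @param loss `"hinge"` or `"zero_one"`.
#' @return A non-negative number.
#' @export
surrogate_risk <- function(f, trial, w, h = censoring_hazard(trial),
                           pi = estimate_propensity(trial),
                           loss = c("hinge", "zero_one")) {
  loss <- match.arg(loss)
  w <- as_pref(w, trial$n_states)
  u <- subject_utilities(trial, unclass(w), h)
  y <- as.double(trial$a)
  denom <- ifelse(y > 0, pi, 1 - pi)
  fv <- rule_values(f, trial$z)
  m <- y * fv
  l <- if (loss == "hinge") pmax(0, 1 - m) else as.double(y != sgn(fv))
  mean(u * l / denom)
}

#' Select the ridge penalty by leave-one-out cross-validated value
#'
#' Evaluates each candidate `lambda` by the jackknife (leave-one-out) value
#' estimator and returns the candidate with the largest cross-validated
#' value; ties are broken toward the larger penalty (more regularization).
#' The reference candidate set is
#' `c(0.001, 0.005, 0.01, 0.1, 0.25, 0.5, 1, 2.5, 5, 10, 20, 50, 100) / sqrt(n)`.
#'
#' @inheritParams owl_fit
#' @param grid Positive candidate penalties.
#' @return The selected penalty, with the per-candidate jackknife values in
#'   attribute `"criterion"`.
#' @export
select_lambda <- function(trial, w, grid = lambda_grid(length(trial$id)),
                          kernel = "linear", sigma = NULL,
                          h = censoring_hazard(trial),
                          pi = estimate_propensity(trial)) {
  stopifnot(length(grid) >= 1, all(grid > 0))
  crit <- vapply(grid, function(l) {
    jackknife_value(trial, w, lambda = l, kernel = kernel, sigma = sigma)
  }, double(1))
  best <- max(grid[crit >= max(crit) - 1e-12])
  structure(best, criterion = tibble::tibble(lambda = grid, jk_value = crit))
}

#' @rdname select_lambda
#' @param n Training sample size.
#' @export
lambda_grid <- function(n) {
  c(0.001, 0.005, 0.01, 0.1, 0.25, 0.5, 1, 2.5, 5, 10, 20, 50, 100) / sqrt(n)
}

#' @export
print.owl_fit <- function(x, ...) {
  cat("<owl_fit> ", x$kind, " decision function, lambda = ",
      format(x$lambda, digits = 4), "\n", sep = "")
  if (x$kind == "linear") {
    cat("  f(z) = ", format(x$intercept, digits = 4), " + z' [",
        paste(format(x$coefs, digits = 4), collapse = ", "), "]\n", sep = "")
  } else {
    cat("  ", length(x$alphas), " kernel sections, sigma = ", x$sigma, "\n",
        sep = "")
  }
  cat("  penalized objective: ", format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.owl_fit <- function(x, ...) {
  if (x$kind == "linear") {
    tibble::tibble(term = c("(Intercept)", paste0("z", seq_along(x$coefs))),
                   estimate = c(x$intercept, x$coefs))
  } else {
    tibble::tibble(term = c("(Intercept)", paste0("alpha", seq_along(x$alphas))),
                   estimate = c(x$intercept, x$alphas))
  }
}

#' @export
glance.owl_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, lambda = x$lambda,
                 objective = x$objective, surrogate_risk = x$surrogate_risk,
                 n_positive_weight = x$diagnostics$n_positive_weight,
                 convergence = x$diagnostics$convergence)
}

#' @export
autoplot.owl_fit <- function(object, trial = NULL, grid_n = 101, ...) {
  if (object$kind == "linear" && length(object$coefs) != 2 ||
      object$kind != "linear" && ncol(object$support) != 2) {
    stop("autoplot.owl_fit supports two covariates only", call. = FALSE)
  }
  g <- seq(-1, 1, length.out = grid_n)
  df <- tidyr::expand_grid(z1 = g, z2 = g)
  df$f <- predict(object, as.matrix(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z1, y = .data$z2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(sgn(.data$f)))) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$f), breaks = 0,
                          colour = "black") +
    ggplot2::scale_fill_manual(values = c(`-1` = "#fddbc7", `1` = "#d1e5f0"),
                               name = "assigned arm") +
    ggplot2::labs(x = "z1", y = "z2", title = "Estimated treatment rule")
  if (!is.null(trial)) {
    pts <- tibble::tibble(z1 = trial$z[, 1], z2 = trial$z[, 2],
                          a = factor(trial$a))
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(shape = .data$a), alpha = 0.6)
  }
  p
}
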