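## RHS / Jacobian evaluation and time integration.

check_rhs_domain <- function(x) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop_hpt("hormone state must be finite", class = "hpt_domain_error")
  }
  if (x[3] <= 0 || x[4] <= 0) {
    stop_hpt("FT4 and FT3 must be strictly positive (feedback terms divide ",
             "by FT4*FT3)", class = "hpt_domain_error")
  }
  invisible(x)
}

#' Evaluate a variant's right-hand side
#'
#' Returns the four time derivatives (dTRH/dt, dTSH/dt, dFT4/dt, dFT3/dt)
#' of the chosen system variant at a state and parameter set.
#'
#' @param variant a variant id or \code{hpt_system} object.
#' @param state a strictly positive hormone state (see [hpt_state()]).
#' @param params a parameter set (see [hpt_parameters()]); defaults to
#'   the variant's baseline.
#' @return a named numeric vector of derivatives, in model-time units.
#' @examples
#' hpt_rhs("sys1", hpt_state(1, 1, 1, 1))
#' @export
hpt_rhs <- function(variant, state, params = hpt_default_parameters(variant)) {
  v <- hpt_system(variant)
  x <- as_hpt_state(state)
  check_rhs_domain(x)
  p <- validate_params(params)
  d <- v$rhs(unclass(x), p)
  names(d) <- HPT_HORMONES
  d
}

#' Analytic Jacobian of a variant's right-hand side
#'
#' The 4x4 matrix of partial derivatives of the derivatives with respect
#' to (TRH, TSH, FT4, FT3), evaluated analytically.  Row i is the
#' gradient of the i-th equation.
#'
#' @inheritParams hpt_rhs
#' @return a 4x4 numeric matrix with columns named after the hormones.
#' @examples
#' hpt_jacobian("sys1", hpt_state(1, 1, 1, 1))
#' @export
hpt_jacobian <- function(variant, state,
                         params = hpt_default_parameters(variant)) {
  v <- hpt_system(variant)
  x <- as_hpt_state(state)
  check_rhs_domain(x)
  p <- validate_params(params)
  v$jac(unclass(x), p)
}

#' Integrate a variant to steady state
#'
#' Integrates the ODE system with a stiff-capable solver
#' (\code{deSolve::lsoda}) from a positive initial state, reporting the
#' trajectory on a dense output grid (every 0.5 time units) and
#' truncating it at the first time point where the max-norm of the
#' right-hand side falls below \code{tol}.
#'
#' @inheritParams hpt_rhs
#' @param initial_state strictly positive starting concentrations.
#' @param t_max integration horizon in model time units.
#' @param tol convergence tolerance on the max-norm of the derivatives.
#' @return an object of class \code{hpt_trajectory}: a list with the
#'   time/state table (\code{$data}), \code{$converged},
#'   \code{$final_residual}, \code{$variant_id} and \code{$parameters}.
#' @examples
#' tr <- hpt_integrate("sys1", initial_state = hpt_state(2, 0.5, 1, 3))
#' tail(tr$data, 1)
#' @export
hpt_integrate <- function(variant, params = hpt_default_parameters(variant),
                          initial_state = hpt_state(1, 1, 1, 1),
                          t_max = 200, tol = 1e-9) {
  v <- hpt_system(variant)
  x0 <- as_hpt_state(initial_state)
  validate_state(x0)
  p <- validate_params(params)
  stopifnot(t_max > 0, tol > 0)

  deriv <- function(t, y, parms) {
    if (y[3] <= 0 || y[4] <= 0) {
      stop_hpt("state left the positive orthant at t = ", format(t),
               class = "hpt_integration_error")
    }
    list(v$rhs(y, p))
  }
  times <- seq(0, t_max, by = 0.5)
  out <- deSolve::ode(y = unclass(x0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(out)
  names(out) <- c("time", HPT_HORMONES)

  bad <- which(apply(out[HPT_HORMONES], 1L, function(r) any(r <= 0)))
  if (length(bad)) {
    stop_hpt("state left the positive orthant at t = ", out$time[bad[1L]],
             class = "hpt_integration_error")
  }
  res <- apply(out[HPT_HORMONES], 1L,
               function(r) max(abs(v$rhs(as.numeric(r), p))))
  hit <- which(res < tol)
  converged <- length(hit) > 0L
  if (converged) out <- out[seq_len(max(2L, hit[1L])), , drop = FALSE]
  structure(
    list(data = out,
         variant_id = v$id,
         parameters = p,
         converged = converged,
         final_residual = res[if (converged) max(2L, hit[1L]) else length(res)]),
    class = "hpt_trajectory")
}

#' @export
print.hpt_trajectory <- function(x, ...) {
  n <- nrow(x$data)
  cat("<hpt_trajectory> ", x$variant_id, ": ", n, " points over t = [0, ",
      x$data$time[n], "]\n", sep = "")
  cat("  converged: ", x$converged,
      "  final residual: ", format(x$final_residual, digits = 3), "\n", sep = "")
  cat("  final state:\n")
  print(round(unlist(x$data[n, HPT_HORMONES]), 6))
  invisible(x)
}
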