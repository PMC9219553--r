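## Equilibrium solutions: damped Newton root finding, closed forms, and
## the printed polynomial solutions, cross-checked against one another.

#' Solve for a positive equilibrium
#'
#' Finds a positive root of the variant's right-hand side with a damped
#' Newton iteration.  Steps are projected back into the positive orthant
#' by step-halving line search, and each accepted step must reduce the
#' residual max-norm.  At the solution the Jacobian eigenvalues are
#' computed and the equilibrium is flagged stable when every real part
#' lies below \code{-stability_margin} (the margin guards against calling
#' a numerically-zero eigenvalue stable).
#'
#' @inheritParams hpt_rhs
#' @param guess optional positive starting state; defaults to all ones.
#' @param tol residual tolerance (max-norm of the right-hand side).
#' @param step_tol relative step-size tolerance.
#' @param stability_margin eigenvalue real-part margin for stability.
#' @param max_iter maximum Newton iterations.
#' @param restarts number of time-integration restarts allowed when the
#'   damped iteration stalls far from a root: the trajectory is followed
#'   for a stretch of model time (the studied equilibria are attracting)
#'   and the Newton iteration resumes from where it lands.
#' @return an object of class \code{hpt_equilibrium} with elements
#'   \code{variant_id}, \code{parameters}, \code{state},
#'   \code{residual}, \code{eigenvalues} (complex), \code{stable} and
#'   \code{method}.
#' @examples
#' eq <- hpt_equilibrium("sys1")
#' eq$state[["FT3"]]   # sqrt(2)
#' @export
hpt_equilibrium <- function(variant, params = hpt_default_parameters(variant),
                            guess = NULL, tol = 1e-10, step_tol = 1e-12,
                            stability_margin = 1e-8, max_iter = 100L,
                            restarts = 2L) {
  v <- hpt_system(variant)
  p <- validate_params(params)
  x <- if (is.null(guess)) rep(1, 4) else as.numeric(as_hpt_state(guess))
  if (any(x <= 0)) {
    stop_hpt("initial guess must be strictly positive", class = "hpt_domain_error")
  }

  newton_pass <- function(x) {
    f <- v$rhs(x, p)
    nf <- max(abs(f))
    for (it in seq_len(max_iter)) {
      if (nf < tol) break
      J <- v$jac(x, p)
      dx <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(dx)) break
      step <- 1
      accepted <- FALSE
      for (h in 1:60) {
        xn <- x + step * dx
        if (all(xn > 0)) {
          fn <- v$rhs(xn, p)
          nfn <- max(abs(fn))
          if (nfn < nf || nfn < tol) {
            x <- xn; f <- fn; nf <- nfn; accepted <- TRUE
            break
          }
        }
        step <- step / 2
      }
      if (!accepted || max(abs(step * dx)) < step_tol * max(1, max(abs(x)))) break
    }
    list(x = x, nf = nf)
  }

  res <- newton_pass(x)
  for (r in seq_len(restarts)) {
    if (res$nf < tol) break
    # Stalled away from a root: ride the (attracting) flow for a while
    # and resume the iteration from where the trajectory lands.
    deriv <- function(t, y, parms) {
      if (y[3] <= 0 || y[4] <= 0) stop("left positive orthant")
      list(v$rhs(y, p))
    }
    relaxed <- tryCatch(
      deSolve::ode(y = res$x, times = c(0, 50 * r), func = deriv,
                   parms = NULL, method = "lsoda",
                   rtol = 1e-10, atol = 1e-12),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(relaxed)) break
    xr <- as.numeric(relaxed[nrow(relaxed), -1L])
    if (any(!is.finite(xr)) || any(xr <= 0)) break
    res <- newton_pass(xr)
  }
  x <- res$x
  nf <- res$nf
  if (nf >= tol) {
    stop_hpt("Newton iteration for ", v$id, " did not reach residual ", tol,
             " (final residual ", format(nf, digits = 3),
             "); consider a continuation warm start from nearby parameters",
             class = "hpt_convergence_error")
  }
  if (any(x <= 0)) {
    stop_hpt("root finding reached a non-positive state for ", v$id,
             class = "hpt_domain_error")
  }
  J <- v$jac(x, p)
  ev <- eigen(J, only.values = TRUE)$values
  names(x) <- HPT_HORMONES
  structure(
    list(variant_id = v$id,
         parameters = p,
         state = structure(x, class = "hpt_state"),
         residual = nf,
         eigenvalues = ev,
         stable = all(Re(ev) < -stability_margin),
         method = "root-find"),
    class = "hpt_equilibrium")
}

#' Closed-form equilibrium FT3
#'
#' Evaluates the analytic equilibrium FT3 level for the variants that
#' admit one (sys1, sys1mod, sys4, sys6, sys8, sys12).  For sys1/sys12
#' this is the square root of a rational function of the rate constants;
#' for sys4/sys6 the positive root of a quadratic in which the FT4
#' production and elimination constants cancel (the algebra is laid out
#' in the package vignette); for sys8 a cube root; for sys1mod a seventh
#' root.
#'
#' @inheritParams hpt_rhs
#' @return the positive equilibrium FT3 level (model units).
#' @examples
#' hpt_analytic_ft3("sys4", hpt_parameters(FT3_const = 0.5))  # 2.4142
#' @export
hpt_analytic_ft3 <- function(variant,
                             params = hpt_default_parameters(variant)) {
  v <- hpt_system(variant)
  if (is.null(v$analytic_ft3)) {
    has <- names(Filter(function(w) !is.null(w$analytic_ft3), .hpt_registry))
    stop_hpt("no closed-form FT3 solution for ", v$id,
             "; available for: ", paste(has, collapse = ", "),
             class = "hpt_unsupported_error")
  }
  p <- validate_params(params)
  v$analytic_ft3(p)
}

#' Polynomial-root equilibrium FT3
#'
#' For sys2, sys3, sys5, sys7, sys9 and sys10 the equilibrium FT3 is the
#' admissible positive real root of a univariate quartic obtained by
#' eliminating TRH, TSH and FT4 from the equilibrium conditions.  The
#' printed quartics hold with all non-free constants at 1 (k32 and a3
#' free; additionally FT3_const/FT4_const for sys3; only a3 free with
#' k32 = 1 for sys9/sys10); outside that validity the function refuses
#' and points to [hpt_equilibrium()].
#'
#' The elimination squares an intermediate equation, so the quartic
#' carries spurious positive roots: the admissible root is identified by
#' back-substituting the full state (TRH, TSH, FT4) and requiring the
#' four equilibrium conditions to vanish.
#'
#' @inheritParams hpt_rhs
#' @param return_all if \code{TRUE}, also return the quartic
#'   coefficients and all candidate roots.
#' @return the admissible positive root (FT3, model units), or a list
#'   when \code{return_all} is set.
#' @examples
#' hpt_polynomial_ft3("sys9")   # exactly 2 at the baseline
#' @export
hpt_polynomial_ft3 <- function(variant,
                               params = hpt_default_parameters(variant),
                               return_all = FALSE) {
  v <- hpt_system(variant)
  if (is.null(v$polynomial_ft3)) {
    has <- names(Filter(function(w) !is.null(w$polynomial_ft3), .hpt_registry))
    stop_hpt("no polynomial FT3 solution for ", v$id,
             "; available for: ", paste(has, collapse = ", "),
             class = "hpt_unsupported_error")
  }
  p <- validate_params(params)
  coefs <- v$polynomial_ft3(p)          # ascending order
  roots <- polyroot(coefs)
  pos <- Re(roots[abs(Im(roots)) < 1e-8 & Re(roots) > 0])
  if (!length(pos)) {
    stop_hpt("no positive real root of the FT3 polynomial for ", v$id,
             class = "hpt_solver_error")
  }
  cand <- vapply(pos, function(z) {
    st <- v$reconstruct(z, p)
    if (any(!is.finite(st)) || any(st <= 0)) return(Inf)
    max(abs(v$rhs(as.numeric(st), p)))
  }, numeric(1))
  admissible <- which(cand < 1e-8 * (1 + max(pos)))
  if (!length(admissible)) {
    stop_hpt("no positive real root reconstructs a positive equilibrium ",
             "state for ", v$id, class = "hpt_solver_error")
  }
  z <- pos[admissible[which.min(cand[admissible])]]
  if (return_all) {
    list(ft3 = z, coefficients = coefs, positive_roots = sort(pos),
         residuals = cand[order(pos)])
  } else z
}

#' Cross-check the equilibrium solution methods
#'
#' Compares the Newton root-finder's FT3 against whichever closed-form
#' or polynomial solution the variant carries (within its validity).
#' Reports rather than raises on disagreement.
#'
#' @inheritParams hpt_rhs
#' @param tol pass threshold on the maximum pairwise FT3 discrepancy.
#' @return a list with \code{pass}, the per-method \code{ft3} values and
#'   \code{max_discrepancy}.
#' @examples
#' hpt_crosscheck("sys1")
#' @export
hpt_crosscheck <- function(variant, params = hpt_default_parameters(variant),
                           tol = 1e-7) {
  v <- hpt_system(variant)
  if (is.null(v$analytic_ft3) && is.null(v$polynomial_ft3)) {
    stop_hpt(v$id, " has neither a closed-form nor a polynomial FT3 ",
             "solution to check against", class = "hpt_unsupported_error")
  }
  p <- validate_params(params)
  ft3 <- c(`root-find` = unname(hpt_equilibrium(v, p)$state["FT3"]))
  if (!is.null(v$analytic_ft3)) {
    ft3["analytic"] <- hpt_analytic_ft3(v, p)
  }
  if (!is.null(v$polynomial_ft3)) {
    poly <- tryCatch(hpt_polynomial_ft3(v, p), hpt_poly_validity_error = function(e) NULL)
    if (!is.null(poly)) ft3["polynomial"] <- poly
  }
  disc <- if (length(ft3) > 1L) max(dist(ft3)) else NA_real_
  list(pass = isTRUE(disc < tol), ft3 = ft3, max_discrepancy = disc)
}

#' @export
print.hpt_equilibrium <- function(x, ...) {
  cat("<hpt_equilibrium> ", x$variant_id, " (", x$method, ")\n", sep = "")
  print(round(unclass(x$state), 6))
  cat("  residual: ", format(x$residual, digits = 3),
      "   stable: ", x$stable, "\n", sep = "")
  cat("  eigenvalue real parts: ",
      paste(format(sort(Re(x$eigenvalues), decreasing = TRUE), digits = 4),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
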