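## Natural-parameter continuation of the equilibrium branch, stability
## assessment along the branch, and homeostasis classification.

#' Sweep a parameter and continue the equilibrium branch
#'
#' Computes the positive equilibrium over an increasing parameter grid,
#' warm-starting each Newton solve from the previous grid point's
#' solution (natural-parameter continuation).  Jacobian eigenvalues are
#' recorded at every point and the FT3 branch is classified as
#' \code{"preserved"} (relative span below \code{epsilon}; perfect
#' homeostasis) or \code{"adapted"} otherwise.
#'
#' @inheritParams hpt_rhs
#' @param param name of the swept constant (typically \code{"k32"}).
#' @param from,to sweep interval; \code{to} must exceed \code{from}.
#'   The lower bound must be positive, except for pure production
#'   constants (\code{k43}, \code{k42}, \code{drug3}, \code{drug4})
#'   where zero simply switches the term off.
#' @param n number of grid points (at least 2).
#' @param epsilon homeostasis threshold on the relative FT3 span; the
#'   default 1e-6 sits many orders of magnitude between exact analytic
#'   invariance (~1e-10) and genuine adaptation (~1e-1).
#' @param stability_margin eigenvalue real-part margin.
#' @return an object of class \code{hpt_sweep}: the grid, a data frame
#'   \code{branch} (equilibrium state, residual, leading eigenvalue real
#'   part and stability flag per point), the complex eigenvalue matrix,
#'   \code{ft3_relative_span}, \code{classification} and
#'   \code{all_stable}.
#' @examples
#' sw <- hpt_sweep("sys1", param = "k32", from = 0.3, to = 3, n = 25)
#' sw$classification
#' @export
hpt_sweep <- function(variant, params = hpt_default_parameters(variant),
                      param = "k32", from = 0.3, to = 3, n = 100,
                      epsilon = 1e-6, stability_margin = 1e-8) {
  v <- hpt_system(variant)
  p <- validate_params(params)
  if (!param %in% v$required) {
    stop_hpt(param, " is not a constant of ", v$id, "; its constants are: ",
             paste(v$required, collapse = ", "), class = "hpt_param_error")
  }
  if (!(to > from)) {
    stop_hpt("sweep interval is degenerate: 'to' (", to,
             ") must exceed 'from' (", from, ")", class = "hpt_usage_error")
  }
  lo_ok <- if (param %in% HPT_ZERO_OK_PARAMS) from >= 0 else from > 0
  if (!lo_ok) {
    stop_hpt("lower sweep bound for ", param, " must be ",
             if (param %in% HPT_ZERO_OK_PARAMS) ">= 0" else "> 0",
             class = "hpt_usage_error")
  }
  if (n < 2L) stop_hpt("n must be at least 2", class = "hpt_usage_error")

  grid <- seq(from, to, length.out = n)
  states <- matrix(NA_real_, n, 4, dimnames = list(NULL, HPT_HORMONES))
  resid <- numeric(n)
  eig <- matrix(NA_complex_, n, 4)
  guess <- NULL
  for (i in seq_len(n)) {
    pi_ <- p
    pi_[param] <- grid[i]
    eqi <- tryCatch(
      hpt_equilibrium(v, pi_, guess = guess,
                      stability_margin = stability_margin),
      error = function(e) {
        stop_hpt("continuation failed at ", param, " = ", grid[i],
                 if (i > 1L) paste0(" (last success at ", param, " = ",
                                    grid[i - 1L], ")"),
                 ": ", conditionMessage(e),
                 class = "hpt_continuation_error")
      })
    states[i, ] <- eqi$state
    resid[i] <- eqi$residual
    eig[i, ] <- eqi$eigenvalues
    guess <- eqi$state
  }
  max_re <- apply(Re(eig), 1L, max)
  stable <- max_re < -stability_margin
  ft3 <- states[, "FT3"]
  span <- (max(ft3) - min(ft3)) / min(ft3)
  structure(
    list(variant_id = v$id,
         swept_parameter = param,
         parameters = p,
         grid = grid,
         branch = data.frame(param_value = grid, states,
                             residual = resid, max_re_eigenvalue = max_re,
                             stable = stable),
         eigenvalues = eig,
         ft3_relative_span = span,
         classification = if (span < epsilon) "preserved" else "adapted",
         all_stable = all(stable),
         epsilon = epsilon,
         stability_margin = stability_margin),
    class = "hpt_sweep")
}

#' Assess stability along a sweep
#'
#' @param sweep an [hpt_sweep()] result.
#' @param margin eigenvalue real-part margin; a point passes when its
#'   leading eigenvalue real part is below \code{-margin}.
#' @return a list with \code{all_stable} and a data frame
#'   \code{failures} of grid points whose leading eigenvalue real part
#'   does not clear the margin.
#' @export
hpt_assess_stability <- function(sweep, margin = sweep$stability_margin) {
  stopifnot(inherits(sweep, "hpt_sweep"))
  ok <- sweep$branch$max_re_eigenvalue < -margin
  list(all_stable = all(ok),
       failures = sweep$branch[!ok, c("param_value", "max_re_eigenvalue")])
}

#' Classify FT3 homeostasis over a sweep
#'
#' \code{"preserved"} when the relative FT3 span over the branch is
#' below \code{epsilon} (the equilibrium FT3 is insensitive to the swept
#' constant), \code{"adapted"} when the level shifts with it.
#'
#' @param sweep an [hpt_sweep()] result.
#' @param epsilon positive homeostasis threshold.
#' @return a list with \code{classification} and
#'   \code{ft3_relative_span}.
#' @export
hpt_classify_homeostasis <- function(sweep, epsilon = 1e-6) {
  stopifnot(inherits(sweep, "hpt_sweep"), epsilon > 0)
  list(classification = if (sweep$ft3_relative_span < epsilon) "preserved"
       else "adapted",
       ft3_relative_span = sweep$ft3_relative_span)
}

#' @export
print.hpt_sweep <- function(x, ...) {
  cat("<hpt_sweep> ", x$variant_id, ": ", x$swept_parameter, " in [",
      min(x$grid), ", ", max(x$grid), "], ", length(x$grid), " points\n",
      sep = "")
  cat("  FT3 relative span: ", format(x$ft3_relative_span, digits = 4),
      "  ->  ", x$classification, "\n", sep = "")
  cat("  all stable: ", x$all_stable, "\n", sep = "")
  invisible(x)
}
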