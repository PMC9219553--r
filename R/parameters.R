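## Parameter handling.  All model constants are dimensionless and live in a
## single flat named vector shared by every system variant; a variant only
## reads the constants it declares in its `required` field.

HPT_PARAM_NAMES <- c(
  "s1",                       # central input signal to TRH production
  "a1", "a2", "a3", "a4",     # elimination rate constants (TRH, TSH, FT4, FT3)
  "k134",                     # FT4.FT3 -> TRH negative feedback constant
  "k21",                      # TRH -> TSH feedforward
  "c2",                       # pituitary secretory capacity
  "k234",                     # FT4.FT3 -> TSH negative feedback constant
  "k32",                      # TSH -> FT4 production
  "k423",                     # TSH.FT4 -> FT3 production
  "k43",                      # FT4 -> FT3 peripheral deiodinase conversion
  "k42",                      # TSH -> FT3 de novo thyroidal production
  "k13",                      # FT3const.FT4 -> TRH feedback (clamped FT3)
  "k14",                      # FT3 -> TRH feedback (FT4 influence clamped)
  "k23",                      # FT3const.FT4 -> TSH feedback (clamped FT3)
  "k24",                      # FT3 -> TSH feedback (FT4 influence clamped)
  "FT3_const",                # clamped FT3 feedback level
  "FT4_const",                # clamped FT4 feedback level
  "drug3",                    # external FT3 production rate (T3 drug)
  "drug4",                    # external FT4 production rate (T4 drug)
  "ptTSH"                     # seasonal modulator of TRH production
)

## Constants that appear in a denominator somewhere must stay strictly
## positive; pure production constants may be zero (switched off).
HPT_DENOM_PARAMS <- c("k134", "k234", "k13", "k14", "k23", "k24",
                      "FT3_const", "FT4_const")
HPT_ELIM_PARAMS <- c("a1", "a2", "a3", "a4")
HPT_ZERO_OK_PARAMS <- c("k43", "k42", "drug3", "drug4")

hpt_base_defaults <- function() {
  p <- rep(1, length(HPT_PARAM_NAMES))
  names(p) <- HPT_PARAM_NAMES
  p[c("k43", "k42", "drug3", "drug4")] <- 0
  p
}

#' Construct a model parameter set
#'
#' Returns the full named vector of dimensionless rate and feedback
#' constants used by the HPT model family.  Every constant defaults to 1
#' except the optional production terms \code{k43}, \code{k42},
#' \code{drug3} and \code{drug4}, which default to 0 (switched off).
#'
#' @param ... named parameter overrides, e.g. \code{k32 = 0.5}.
#' @param base an existing parameter vector to start from instead of the
#'   all-ones baseline.
#' @return a named numeric vector of class \code{hpt_params}.
#' @examples
#' hpt_parameters(k32 = 2, FT3_const = 0.5)
#' @export
hpt_parameters <- function(..., base = NULL) {
  p <- if (is.null(base)) hpt_base_defaults() else unclass(as_hpt_params(base))
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) &&
      (is.list(over[[1L]]) || (is.numeric(over[[1L]]) && !is.null(names(over[[1L]]))))) {
    over <- as.list(over[[1L]])
  }
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(nm == "")) {
      stop_hpt("parameter overrides must be named", class = "hpt_param_error")
    }
    bad <- setdiff(nm, HPT_PARAM_NAMES)
    if (length(bad)) {
      stop_hpt("unknown parameter(s): ", paste(bad, collapse = ", "),
               "; valid names are: ", paste(HPT_PARAM_NAMES, collapse = ", "),
               class = "hpt_param_error")
    }
    p[nm] <- vapply(over, as.numeric, numeric(1))
  }
  structure(p, class = "hpt_params")
}

as_hpt_params <- function(p) {
  if (inherits(p, "hpt_params")) return(p)
  if (is.list(p)) return(do.call(hpt_parameters, p))
  if (is.numeric(p) && !is.null(names(p))) return(hpt_parameters(p))
  stop_hpt("cannot interpret object as parameter set", class = "hpt_param_error")
}

validate_params <- function(p) {
  p <- as_hpt_params(p)
  if (anyNA(p) || any(!is.finite(p))) {
    stop_hpt("parameters must be finite", class = "hpt_param_error")
  }
  if (any(p[HPT_ELIM_PARAMS] <= 0)) {
    stop_hpt("elimination constants a1..a4 must be > 0",
             class = "hpt_param_error")
  }
  if (any(p < 0)) {
    stop_hpt("production/feedback constants must be >= 0 (offending: ",
             paste(names(p)[p < 0], collapse = ", "), ")",
             class = "hpt_param_error")
  }
  if (any(p[HPT_DENOM_PARAMS] <= 0)) {
    stop_hpt("constants appearing in a denominator must be > 0 (offending: ",
             paste(intersect(HPT_DENOM_PARAMS, names(p)[p <= 0]),
                   collapse = ", "), ")",
             class = "hpt_param_error")
  }
  invisible(p)
}

#' Default parameters for a system variant
#'
#' The all-ones baseline used throughout the model analysis, with
#' variant-specific extras: variants that include peripheral T4-to-T3
#' conversion get \code{k43 = 1}, variants with de novo thyroidal FT3
#' production get \code{k42 = 1}, and the drug variant starts with both
#' external production rates at 0.
#'
#' @param id a registered variant identifier, e.g. \code{"sys1"}.
#' @return a parameter vector of class \code{hpt_params}.
#' @examples
#' hpt_default_parameters("sys10")
#' @export
hpt_default_parameters <- function(id) {
  v <- hpt_system(id)
  p <- hpt_base_defaults()
  p[names(v$default_extras)] <- v$default_extras
  structure(p, class = "hpt_params")
}

#' @export
print.hpt_params <- function(x, ...) {
  cat("<hpt_params> (dimensionless)\n")
  print(unclass(x), ...)
  invisible(x)
}
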