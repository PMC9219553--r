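HPT_HORMONES <- c("TRH", "TSH", "FT4", "FT3")

#' Construct a hormone state
#'
#' A state is the vector of the four circulating hormone concentrations
#' (TRH, TSH, FT4, FT3) in dimensionless model units.  All four must be
#' strictly positive: the feedback terms contain \code{1/(FT4*FT3)}
#' factors that blow up at zero.
#'
#' @param TRH,TSH,FT4,FT3 strictly positive concentrations.
#' @return a named numeric vector of class \code{hpt_state}.
#' @examples
#' hpt_state(1, 1, 1, 1)
#' @export
hpt_state <- function(TRH = 1, TSH = 1, FT4 = 1, FT3 = 1) {
  x <- c(TRH = as.numeric(TRH), TSH = as.numeric(TSH),
         FT4 = as.numeric(FT4), FT3 = as.numeric(FT3))
  validate_state(x)
  structure(x, class = "hpt_state")
}

as_hpt_state <- function(x) {
  if (inherits(x, "hpt_state")) return(x)
  x <- as.numeric(x)
  if (length(x) != 4L) {
    stop_hpt("a hormone state has exactly 4 components (TRH, TSH, FT4, FT3)",
             class = "hpt_state_error")
  }
  names(x) <- HPT_HORMONES
  structure(x, class = "hpt_state")
}

validate_state <- function(x, strict = TRUE) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop_hpt("hormone concentrations must be finite", class = "hpt_state_error")
  }
  if (strict && any(x <= 0)) {
    stop_hpt("hormone concentrations must be strictly positive (offending: ",
             paste(HPT_HORMONES[x <= 0], collapse = ", "), ")",
             class = "hpt_state_error")
  }
  invisible(x)
}

#' @export
print.hpt_state <- function(x, ...) {
  cat("<hpt_state>\n")
  print(unclass(x), ...)
  invisible(x)
}
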