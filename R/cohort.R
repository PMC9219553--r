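## Synthetic cohort generator: per-subject parameter draws from a
## scenario's stated intervals, equilibrium FT3/FT4 on the percent-change
## scale, plus optional Gaussian measurement noise.  Stands in, at the
## level of normalized percent-change structure, for the kind of clinical
## cohort the scenario emulates; it is synthetic model output, not data.

#' Generate a synthetic cohort table
#'
#' Draws one k32 value per subject (uniform over the scenario's swept
#' interval) together with the scenario's range parameters, computes the
#' model equilibrium, and reports FT4/FT3 as percent change from the
#' scenario's euthyroid reference configuration.  Independent Gaussian
#' noise (standard deviation \code{noise_sd}, percent scale) is added to
#' the hormone columns.  Deterministic given \code{seed}.
#'
#' @param n_subjects number of rows to generate.
#' @param scenario a registered scenario name (see [hpt_scenario_spec()]).
#' @param noise_sd non-negative noise standard deviation on the percent
#'   scale.
#' @param seed RNG seed.
#' @return a data frame with columns \code{subject_id},
#'   \code{k32_percent} (100 * k32 relative to the reference k32),
#'   \code{FT3_percent} and \code{FT4_percent}.
#' @examples
#' head(hpt_cohort_fixture(5, "hypothyroid_onset", noise_sd = 0, seed = 7))
#' @export
hpt_cohort_fixture <- function(n_subjects, scenario = "hypothyroid_onset",
                               noise_sd = 0, seed = 1L) {
  if (n_subjects < 1L) {
    stop_hpt("n_subjects must be at least 1", class = "hpt_usage_error")
  }
  if (noise_sd < 0) {
    stop_hpt("noise_sd must be non-negative", class = "hpt_usage_error")
  }
  spec <- hpt_scenario_spec(scenario)
  base <- hpt_default_parameters(spec$variant_id)
  k32_ref <- spec$reference[["k32"]] %||% 1

  with_preserved_seed(seed, {
    rows <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      ov <- spec$fixed
      for (nm in names(spec$ranges)) {
        rg <- spec$ranges[[nm]]
        ov[[nm]] <- stats::runif(1, rg[1], rg[2])
      }
      if (!is.null(spec$levels)) {
        for (nm in names(spec$levels)) {
          ov[[nm]] <- sample(spec$levels[[nm]], 1)
        }
      }
      k32 <- stats::runif(1, spec$sweep[1], spec$sweep[2])
      p <- hpt_parameters(ov, base = base)
      p["k32"] <- k32
      eq <- hpt_equilibrium(spec$variant_id, p)
      pref <- hpt_parameters(spec$reference, base = hpt_parameters(ov, base = base))
      eqr <- hpt_equilibrium(spec$variant_id, pref)
      rows[[s]] <- data.frame(
        subject_id = s,
        k32_percent = 100 * k32 / k32_ref,
        FT3_percent = normalize_percent(eq$state[["FT3"]], eqr$state[["FT3"]]),
        FT4_percent = normalize_percent(eq$state[["FT4"]], eqr$state[["FT4"]]))
    }
    tab <- do.call(rbind, rows)
    if (noise_sd > 0) {
      tab$FT3_percent <- tab$FT3_percent + stats::rnorm(n_subjects, 0, noise_sd)
      tab$FT4_percent <- tab$FT4_percent + stats::rnorm(n_subjects, 0, noise_sd)
    }
    rownames(tab) <- NULL
    tab
  })
}
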