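## Named scenario experiments: parameter-range envelope runs over a k32
## sweep, the normalization used for cross-model comparison, and the
## protection flag that operationalizes "FT3 is protected".

.hpt_scenarios <- list(
  hypothyroid_onset = list(
    variant_id = "sys10", sweep = c(0.4, 1.1),
    ranges = list(k423 = c(0.2, 0.3), k43 = c(0.7, 0.8), k42 = c(0.1, 0.2)),
    fixed = list(), levels = NULL,
    reference = list(k32 = 1), n_samples = 200,
    description = "Declining FT4 production at the onset of autoimmune thyroiditis"),
  ntis = list(
    variant_id = "sys10", sweep = c(0.8, 1.2),
    ranges = list(k423 = c(0.2, 0.3), k43 = c(0.1, 0.4), k42 = c(0.1, 0.2),
                  s1 = c(0.2, 0.8), c2 = c(0.2, 0.8)),
    fixed = list(), levels = NULL,
    ## normalization reference is the healthy parameterization, not the
    ## diseased draws: the clinical comparison normalizes against a
    ## euthyroid sample
    reference = list(k32 = 1, k423 = 0.25, k43 = 0.75, k42 = 0.15,
                     s1 = 1, c2 = 1),
    n_samples = 200,
    description = "Non-thyroidal illness: multiple rate constants depressed at once"),
  drug = list(
    variant_id = "sys11", sweep = c(0.3, 3),
    ranges = list(), fixed = list(drug3 = 0.5, drug4 = 0), levels = NULL,
    reference = list(k32 = 1), n_samples = 1,
    description = "Constant external T3 administration in the presence of an intact thyroid"),
  seasonality = list(
    variant_id = "sys12", sweep = c(0.3, 3),
    ranges = list(), fixed = list(),
    levels = list(ptTSH = c(0.5, 1, 1.5)),
    reference = list(k32 = 1, ptTSH = 1), n_samples = 3,
    description = "Seasonal modulation of the central TRH drive"),
  peripheral_conversion = list(
    variant_id = "sys9", sweep = c(0.3, 3),
    ranges = list(k43 = c(0, 1)), fixed = list(k423 = 0.5, k42 = 0),
    levels = NULL, reference = list(k32 = 1), n_samples = 200,
    description = "Varying peripheral deiodinase T4-to-T3 conversion"),
  denovo_t3 = list(
    variant_id = "sys10", sweep = c(0.3, 3),
    ranges = list(k43 = c(0, 1)), fixed = list(k423 = 0.5, k42 = 1),
    levels = NULL, reference = list(k32 = 1), n_samples = 200,
    description = "De novo thyroidal FT3 secretion switched on alongside conversion")
)

#' Build a scenario specification
#'
#' Retrieves one of the registered scenarios and optionally overrides
#' its fields.  A scenario sweeps \code{k32} over an interval while the
#' remaining constants are either fixed, drawn once per sample from
#' stated intervals (uniform, seeded), or stepped through a fixed list
#' of levels (seasonality).  The \code{reference} overrides define the
#' euthyroid configuration against which percent changes are computed.
#'
#' @param name one of \code{"hypothyroid_onset"}, \code{"ntis"},
#'   \code{"drug"}, \code{"seasonality"}, \code{"peripheral_conversion"},
#'   \code{"denovo_t3"}.
#' @param sweep length-2 numeric, the swept k32 interval.
#' @param n_grid number of k32 grid points.
#' @param ranges named list of \code{c(lo, hi)} sampling intervals.
#' @param fixed named list of constant parameter overrides.
#' @param reference named list defining the normalization reference
#'   configuration (applied on top of each sample's parameters).
#' @param n_samples number of parameter draws for the envelope.
#' @param seed RNG seed used for the range draws.
#' @return an object of class \code{hpt_scenario_spec}.
#' @examples
#' hpt_scenario_spec("ntis", n_samples = 50)
#' @export
hpt_scenario_spec <- function(name, sweep = NULL, n_grid = 25, ranges = NULL,
                              fixed = NULL, reference = NULL,
                              n_samples = NULL, seed = 1L) {
  if (!name %in% names(.hpt_scenarios)) {
    stop_hpt("unknown scenario ", deparse(name), "; registered: ",
             paste(names(.hpt_scenarios), collapse = ", "),
             class = "hpt_lookup_error")
  }
  sc <- .hpt_scenarios[[name]]
  spec <- list(name = name,
               variant_id = sc$variant_id,
               sweep = sweep %||% sc$sweep,
               n_grid = n_grid,
               ranges = ranges %||% sc$ranges,
               fixed = fixed %||% sc$fixed,
               levels = sc$levels,
               reference = reference %||% sc$reference,
               n_samples = n_samples %||% sc$n_samples,
               seed = as.integer(seed),
               description = sc$description)
  validate_scenario_spec(spec)
  structure(spec, class = "hpt_scenario_spec")
}

validate_scenario_spec <- function(spec) {
  stopifnot(length(spec$sweep) == 2L, spec$sweep[2] > spec$sweep[1],
            spec$sweep[1] > 0, spec$n_grid >= 2L, spec$n_samples >= 1L)
  if (!is.null(spec$levels)) {
    len <- unique(lengths(spec$levels))
    if (length(len) != 1L || spec$n_samples != len) {
      stop_hpt("n_samples must equal the number of scenario levels (", len,
               ")", class = "hpt_usage_error")
    }
  }
  for (nm in names(spec$ranges)) {
    rg <- spec$ranges[[nm]]
    if (length(rg) != 2L || rg[1] > rg[2]) {
      stop_hpt("range for ", nm, " must be c(lo, hi) with lo <= hi",
               class = "hpt_usage_error")
    }
    lo_ok <- if (nm %in% HPT_ZERO_OK_PARAMS) rg[1] >= 0 else rg[1] > 0
    if (!lo_ok) {
      stop_hpt("range lower bound for ", nm, " must be ",
               if (nm %in% HPT_ZERO_OK_PARAMS) ">= 0" else "> 0",
               class = "hpt_usage_error")
    }
  }
  invisible(spec)
}

## Draw one sample's parameter overrides (uniform within each range).
draw_sample_overrides <- function(spec, i) {
  ov <- spec$fixed
  for (nm in names(spec$ranges)) {
    rg <- spec$ranges[[nm]]
    ov[[nm]] <- stats::runif(1, rg[1], rg[2])
  }
  if (!is.null(spec$levels)) {
    for (nm in names(spec$levels)) ov[[nm]] <- spec$levels[[nm]][i]
  }
  ov
}

#' Run a scenario experiment
#'
#' For each of \code{n_samples} seeded parameter draws the equilibrium
#' branch is continued over the k32 grid; FT3 and FT4 are recorded both
#' raw and as percent change from the sample's reference configuration
#' (its own parameters with the scenario's \code{reference} overrides
#' applied, typically k32 = 1).  Envelopes are pointwise min / median /
#' max across samples.  \code{ft3_protected} compares the median percent
#' declines at the low-k32 end: FT3 is protected when it declines less
#' (in percent of its reference) than FT4 does.
#'
#' @param spec an [hpt_scenario_spec()], or a scenario name.
#' @param ... passed to [hpt_scenario_spec()] when \code{spec} is a name.
#' @return an object of class \code{hpt_scenario}.
#' @examples
#' res <- hpt_run_scenario("hypothyroid_onset", n_samples = 20)
#' res$ft3_protected
#' @export
hpt_run_scenario <- function(spec, ...) {
  if (is.character(spec)) spec <- hpt_scenario_spec(spec, ...)
  stopifnot(inherits(spec, "hpt_scenario_spec"))
  base <- hpt_default_parameters(spec$variant_id)
  grid <- seq(spec$sweep[1], spec$sweep[2], length.out = spec$n_grid)

  run_one <- function(ov) {
    p <- hpt_parameters(ov, base = base)
    guess <- NULL
    ft3 <- ft4 <- numeric(length(grid))
    for (i in seq_along(grid)) {
      p["k32"] <- grid[i]
      eq <- hpt_equilibrium(spec$variant_id, p, guess = guess)
      ft3[i] <- eq$state[["FT3"]]; ft4[i] <- eq$state[["FT4"]]
      guess <- eq$state
    }
    pref <- hpt_parameters(spec$reference,
                           base = hpt_parameters(ov, base = base))
    eqr <- hpt_equilibrium(spec$variant_id, pref)
    list(ft3 = ft3, ft4 = ft4,
         ft3_pct = normalize_percent(ft3, eqr$state[["FT3"]]),
         ft4_pct = normalize_percent(ft4, eqr$state[["FT4"]]))
  }

  samples <- with_preserved_seed(spec$seed, {
    out <- vector("list", spec$n_samples)
    for (s in seq_len(spec$n_samples)) {
      ov <- draw_sample_overrides(spec, s)
      out[[s]] <- tryCatch(run_one(ov), error = function(e) {
        warning("scenario sample ", s, " dropped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    }
    out
  })
  kept <- Filter(Negate(is.null), samples)
  if (length(kept) < 0.8 * spec$n_samples) {
    stop_hpt("more than 20% of scenario samples failed (",
             spec$n_samples - length(kept), " of ", spec$n_samples, ")",
             class = "hpt_scenario_error")
  }

  env <- function(field) {
    m <- do.call(rbind, lapply(kept, `[[`, field))
    data.frame(k32 = grid,
               min = apply(m, 2, min),
               median = apply(m, 2, stats::median),
               max = apply(m, 2, max))
  }
  ft3_env <- env("ft3"); ft4_env <- env("ft4")
  ft3_pct <- env("ft3_pct"); ft4_pct <- env("ft4_pct")
  decline_ft3 <- -ft3_pct$median[1L]
  decline_ft4 <- -ft4_pct$median[1L]
  structure(
    list(spec = spec,
         k32_grid = grid,
         n_used = length(kept),
         ft3_envelope = ft3_env, ft4_envelope = ft4_env,
         normalized_ft3 = ft3_pct, normalized_ft4 = ft4_pct,
         ft3_decline_low = decline_ft3, ft4_decline_low = decline_ft4,
         ft3_protected = decline_ft3 < decline_ft4),
    class = "hpt_scenario")
}

#' Peripheral conversion experiment
#'
#' Equilibria of sys9 along a grid of the peripheral conversion constant
#' k43 (with k32 = 1, k423 = 0.5, k42 = 0 and all other constants 1):
#' increasing extra-thyroidal T4-to-T3 conversion raises FT3 while FT4
#' falls, disjoining the two hormones.
#'
#' @param k43_lo,k43_hi sweep interval, \code{0 <= k43_lo < k43_hi}.
#' @param n number of grid points.
#' @return a data frame with columns \code{k43}, \code{TRH}, \code{TSH},
#'   \code{FT4}, \code{FT3}.
#' @examples
#' head(hpt_peripheral_conversion(0, 1, 11))
#' @export
hpt_peripheral_conversion <- function(k43_lo = 0, k43_hi = 1, n = 50) {
  if (!(k43_lo >= 0 && k43_hi > k43_lo)) {
    stop_hpt("need 0 <= k43_lo < k43_hi", class = "hpt_usage_error")
  }
  if (n < 2L) stop_hpt("n must be at least 2", class = "hpt_usage_error")
  p <- hpt_parameters(k423 = 0.5, k42 = 0,
                      base = hpt_default_parameters("sys9"))
  grid <- seq(k43_lo, k43_hi, length.out = n)
  states <- matrix(NA_real_, n, 4, dimnames = list(NULL, HPT_HORMONES))
  guess <- NULL
  for (i in seq_len(n)) {
    p["k43"] <- grid[i]
    eq <- hpt_equilibrium("sys9", p, guess = guess)
    states[i, ] <- eq$state
    guess <- eq$state
  }
  data.frame(k43 = grid, states)
}

#' Percent change relative to a reference
#'
#' @param values numeric vector.
#' @param reference strictly positive reference level.
#' @return \code{100 * (values - reference) / reference}.
#' @examples
#' normalize_percent(c(1.5, 0.5), 1)
#' @export
normalize_percent <- function(values, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    stop_hpt("reference must be a single positive number",
             class = "hpt_domain_error")
  }
  100 * (values - reference) / reference
}

#' Centre a vector on its mean
#'
#' @param values non-empty numeric vector.
#' @return \code{values - mean(values)}.
#' @examples
#' mean_center(c(1, 2, 3))
#' @export
mean_center <- function(values) {
  if (!length(values)) {
    stop_hpt("cannot mean-centre an empty vector", class = "hpt_domain_error")
  }
  values - mean(values)
}

#' @export
print.hpt_scenario_spec <- function(x, ...) {
  cat("<hpt_scenario_spec> ", x$name, " (", x$variant_id, ")\n  ",
      x$description, "\n", sep = "")
  cat("  k32 in [", x$sweep[1], ", ", x$sweep[2], "], ", x$n_grid,
      " points; ", x$n_samples, " samples; seed ", x$seed, "\n", sep = "")
  for (nm in names(x$ranges)) {
    cat("  ", nm, " ~ U(", x$ranges[[nm]][1], ", ", x$ranges[[nm]][2], ")\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.hpt_scenario <- function(x, ...) {
  cat("<hpt_scenario> ", x$spec$name, " (", x$spec$variant_id, "), ",
      x$n_used, " samples\n", sep = "")
  cat("  FT3 decline at low k32: ", round(x$ft3_decline_low, 2),
      "%   FT4 decline: ", round(x$ft4_decline_low, 2), "%\n", sep = "")
  cat("  ft3_protected: ", x$ft3_protected, "\n", sep = "")
  invisible(x)
}
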