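#' Scenario specification for one-way sensitivity analysis
#'
#' A labelled set of parameter overrides. Only the four macro parameters
#' varied by the deterministic sensitivity design may be overridden:
#' `discount_rate`, `gdp_growth`, `inflation`, `unemployment`. An override
#' is either an absolute value (e.g. `discount_rate = 0.01`) or a relative
#' change given as a percent string: `"-100%"` sets the parameter to zero,
#' `"+100%"` doubles it.
#'
#' @param label Scenario label.
#' @param overrides Named list of overrides.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("d = 1", list(discount_rate = 0.01))
#' scenario_spec("g +100; i +100",
#'               list(gdp_growth = "+100%", inflation = "+100%"))
#' @export
scenario_spec <- function(label, overrides = list()) {
  allowed <- c("discount_rate", "gdp_growth", "inflation", "unemployment")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad))
    stop("unknown scenario parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(label = label, overrides = overrides),
            class = "scenario_spec")
}

#' The built-in eight-scenario sensitivity set
#'
#' The standard one-way design: discount rate at 1% and 5%, GDP growth and
#' inflation jointly at -100% and +100%, unemployment at -100% and +100%,
#' plus the two combined crisis/boom scenarios.
#'
#' @return A named list of eight `scenario_spec` objects
#'   (`"1"` through `"8"`).
#' @export
table4_scenarios <- function() {
  list(
    "1" = scenario_spec("g -100; i -100",
                        list(gdp_growth = "-100%", inflation = "-100%")),
    "2" = scenario_spec("g +100; i +100",
                        list(gdp_growth = "+100%", inflation = "+100%")),
    "3" = scenario_spec("d = 1", list(discount_rate = 0.01)),
    "4" = scenario_spec("d = 5", list(discount_rate = 0.05)),
    "5" = scenario_spec("U -100", list(unemployment = "-100%")),
    "6" = scenario_spec("U +100", list(unemployment = "+100%")),
    "7" = scenario_spec("g -100; i -100; U +100",
                        list(gdp_growth = "-100%", inflation = "-100%",
                             unemployment = "+100%")),
    "8" = scenario_spec("g +100; i +100; U -100",
                        list(gdp_growth = "+100%", inflation = "+100%",
                             unemployment = "-100%")))
}

#' Apply a scenario specification to macro parameters
#'
#' Returns a copy of `base` with the overrides applied; untouched fields
#' are unchanged. Percent strings are relative to the base value.
#'
#' @param base A `macro_params`.
#' @param spec A `scenario_spec`.
#' @return A `macro_params`.
#' @export
apply_scenario <- function(base, spec) {
  stopifnot(inherits(base, "macro_params"), inherits(spec, "scenario_spec"))
  out <- unclass(base)
  for (nm in names(spec$overrides)) {
    v <- spec$overrides[[nm]]
    if (is.character(v)) {
      pct <- suppressWarnings(as.numeric(sub("%$", "", v)))
      if (is.na(pct))
        stop("cannot parse relative override: ", v, call. = FALSE)
      v <- out[[nm]] * (1 + pct / 100)
    }
    out[[nm]] <- v
  }
  do.call(macro_params, out[setdiff(names(out), character(0))])
}

#' Re-weight profiles for a changed unemployment rate
#'
#' The sensitivity design varies the unemployment rate; the age profiles
#' must respond. Unemployment-benefit participation is scaled by
#' `U_new/U_base`; employment-conditional components — Social Security
#' contributions, income tax and the public-wage participation — are
#' scaled by `(1-U_new)/(1-U_base)`. Participation probabilities are
#' clipped to `[0, 1]`; consumption-tax profiles are unchanged.
#'
#' @param transfers A `transfer_profile_set`.
#' @param taxes A `tax_profile_set`.
#' @param U_new New unemployment rate in `[0, 1)`.
#' @param U_base Base unemployment rate in `(0, 1)`.
#' @param include_taxes Also re-scale the employment-conditional tax
#'   profiles (default `TRUE`).
#' @return `list(transfers = , taxes = )` with adjusted sets.
#' @export
adjust_unemployment <- function(transfers, taxes, U_new, U_base,
                                include_taxes = TRUE) {
  if (U_new < 0 || U_new >= 1 || U_base < 0 || U_base >= 1)
    stop("unemployment rates must lie in [0, 1)", call. = FALSE)
  if (U_base == 0 && U_new > 0)
    stop("cannot scale unemployment up from a zero base", call. = FALSE)
  u_ratio <- if (U_base == 0) 1 else U_new / U_base
  e_ratio <- (1 - U_new) / (1 - U_base)
  scale_part <- function(p, s)
    age_profile(pmin(pmax(as.numeric(p) * s, 0), 1),
                kind = "participation")
  transfers$unemp_part <- scale_part(transfers$unemp_part, u_ratio)
  transfers$wages_part <- scale_part(transfers$wages_part, e_ratio)
  if (include_taxes) {
    taxes$ss <- age_profile(as.numeric(taxes$ss) * e_ratio)
    taxes$income <- age_profile(as.numeric(taxes$income) * e_ratio)
  }
  list(transfers = transfers, taxes = taxes)
}

#' Fiscal result for an individual conceived through assisted reproduction
#'
#' The expected lifetime flows of an ART-conceived individual are the
#' natural flows scaled by the live-birth probability and the probability
#' of pregnancy under the funding policy, with the expected treatment cost
#' paid upfront at `t = 0`. The break-even age is read off the resulting
#' cumulative curve.
#'
#' @param taxes,transfers Calibrated `age_profile` totals (from
#'   [sum_taxes()] / [sum_transfers()]).
#' @param art An `art_params`.
#' @param params A `macro_params`.
#' @return A `fiscal_result` whose `nfc` equals the policy's net
#'   contribution (expected NFC minus expected cost).
#' @export
art_fiscal_result <- function(taxes, transfers, art, params) {
  stopifnot(inherits(art, "art_params"))
  pp <- preg_prob_within(art$success_prob, art$funded_cycles)
  s <- art$live_birth_prob * pp
  cost <- expected_capped_cost(art$cycle_cost, art$success_prob,
                               art$funded_cycles)
  npv(age_profile(as.numeric(taxes) * s),
      age_profile(as.numeric(transfers) * s),
      upfront_cost = cost, params = params)
}

#' Run the one-way deterministic sensitivity analysis
#'
#' Re-runs the full pipeline — macro override, unemployment re-weighting,
#' projection, discounting, ART adjustment — for each scenario. The
#' calibrated real profiles are fixed; scenarios vary only the macro
#' parameters (and, through the unemployment rate, the
#' employment-conditional weights).
#'
#' @param base_params Base-case `macro_params`.
#' @param transfers,taxes Calibrated profile sets.
#' @param art An `art_params` (technique and funding policy under study).
#' @param specs List of `scenario_spec` (default [table4_scenarios()]).
#' @return A data frame of class `scenario_results` with one row per
#'   scenario: `label`, `expected_nfc`, `net_contribution`,
#'   `break_even_age`, `roi`, `expected_cost`, `nfc_natural`.
#' @export
run_sensitivity <- function(base_params, transfers, taxes, art,
                            specs = table4_scenarios()) {
  if (length(specs) == 0) stop("no scenarios given", call. = FALSE)
  rows <- lapply(specs, function(spec) {
    params <- apply_scenario(base_params, spec)
    adj <- adjust_unemployment(transfers, taxes, params$unemployment,
                               base_params$unemployment)
    tax_tot <- sum_taxes(adj$taxes)
    tra_tot <- sum_transfers(adj$transfers)
    natural <- npv(tax_tot, tra_tot, 0, params)
    outcome <- evaluate_art(art, natural$nfc)
    fr <- art_fiscal_result(tax_tot, tra_tot, art, params)
    data.frame(label = spec$label, expected_nfc = outcome$expected_nfc,
               net_contribution = outcome$net_contribution,
               break_even_age = fr$break_even_age, roi = outcome$roi,
               expected_cost = outcome$expected_cost,
               nfc_natural = natural$nfc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("scenario_results", class(out))
  out
}

#' Tornado-diagram summary of scenario ROI spans
#'
#' Orders scenarios by the magnitude of their return-on-investment
#' departure from the base case, ready for horizontal-bar rendering.
#'
#' @param results A `scenario_results` data frame.
#' @param base The base-case row: anything with elements `roi` (e.g. an
#'   `art_outcome` or a single `scenario_results` row).
#' @return A data frame `label, roi_low, roi_high, span` sorted by
#'   descending `span` (`|roi - base roi|`).
#' @export
tornado <- function(results, base) {
  base_roi <- base$roi
  span <- abs(results$roi - base_roi)
  out <- data.frame(label = results$label,
                    roi_low = pmin(results$roi, base_roi),
                    roi_high = pmax(results$roi, base_roi),
                    span = span, stringsAsFactors = FALSE)
  out[order(-out$span), , drop = FALSE]
}
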