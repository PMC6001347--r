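#' Macroeconomic parameters
#'
#' The macro assumptions under which real base-year age profiles are
#' projected and discounted. Defaults are the base case: a 3.5% annual
#' discount rate, 4.08% GDP growth, 3.5% inflation, a 10.61% unemployment
#' rate (relative to the over-16 population), retirement at 65 and a life
#' expectancy at birth of 78 years, base year 2006.
#'
#' `growth_scheme` selects how real flows are projected to age `t`:
#' * `"real_only"` (default): flow × `(1+g)^t`, discounted at `r` — flows
#'   and the discount rate are both real, so inflation cancels out of the
#'   base case. This is the only scheme consistent with the calibrated
#'   lifetime totals and the qualitative sensitivity pattern (see the
#'   methods vignette);
#' * `"nominal_product"`: flow × `((1+g)(1+i))^t`, discounted at a nominal
#'   rate `r`.
#'
#' @param discount_rate Annual discount rate `r` (fraction).
#' @param gdp_growth Annual GDP growth rate `g` (fraction).
#' @param inflation Annual inflation rate `i` (fraction).
#' @param unemployment Unemployment rate `U` (fraction of the over-16
#'   population).
#' @param retirement_age Retirement age in years.
#' @param life_expectancy Life expectancy at birth `N` in years; the model
#'   horizon is ages `0..N`.
#' @param base_year Calendar base year (year of birth).
#' @param growth_scheme `"nominal_product"` or `"real_only"`.
#' @return An object of class `macro_params`.
#' @examples
#' macro_params()                      # base case
#' macro_params(discount_rate = 0.01)  # low-discount scenario
#' @export
macro_params <- function(discount_rate = 0.035, gdp_growth = 0.0408,
                         inflation = 0.035, unemployment = 0.1061,
                         retirement_age = 65, life_expectancy = 78,
                         base_year = 2006,
                         growth_scheme = c("real_only", "nominal_product")) {
  growth_scheme <- match.arg(growth_scheme)
  if (discount_rate < 0 || gdp_growth < 0 || inflation < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (unemployment < 0 || unemployment >= 1)
    stop("unemployment must lie in [0, 1)", call. = FALSE)
  if (retirement_age <= 0 || retirement_age >= life_expectancy)
    stop("retirement_age must lie in (0, life_expectancy)", call. = FALSE)
  structure(list(discount_rate = discount_rate, gdp_growth = gdp_growth,
                 inflation = inflation, unemployment = unemployment,
                 retirement_age = retirement_age,
                 life_expectancy = as.integer(life_expectancy),
                 base_year = as.integer(base_year),
                 growth_scheme = growth_scheme),
            class = "macro_params")
}

#' @export
print.macro_params <- function(x, ...) {
  cat("<macro_params>\n")
  cat(sprintf("  r = %.4f, g = %.4f, i = %.4f, U = %.4f\n",
              x$discount_rate, x$gdp_growth, x$inflation, x$unemployment))
  cat(sprintf("  retirement %d, horizon 0..%d, base year %d, scheme %s\n",
              x$retirement_age, x$life_expectancy, x$base_year,
              x$growth_scheme))
  invisible(x)
}

#' Growth projection factor at age t
#'
#' The factor applied to a real base-year flow to obtain the nominal flow
#' at age `t`. Under the default scheme this is `((1+g)(1+i))^t`; under
#' `"real_only"` it is `(1+g)^t`. At `t = 0` (birth year) it is 1: base-year
#' flows are neither grown nor discounted.
#'
#' @param t Age in years (vectorised, `t >= 0`).
#' @param params A `macro_params`.
#' @return Dimensionless factor(s).
#' @export
growth_factor <- function(t, params) {
  stopifnot(all(t >= 0))
  base <- if (params$growth_scheme == "nominal_product")
    (1 + params$gdp_growth) * (1 + params$inflation)
  else 1 + params$gdp_growth
  base^t
}

#' Discount factor at age t
#'
#' `(1 + r)^(-t)` with the annual discount rate `r`.
#'
#' @inheritParams growth_factor
#' @return Dimensionless factor(s).
#' @export
discount_factor <- function(t, params) {
  stopifnot(all(t >= 0))
  (1 + params$discount_rate)^(-t)
}

#' Present value of an age profile
#'
#' Sums the profile over ages 0..N after applying the growth projection and
#' the discount factor: `sum_t profile[t] * growth_factor(t) *
#' discount_factor(t)`.
#'
#' @param profile An `age_profile` of real base-year amounts on ages 0..N.
#' @param params A `macro_params`.
#' @return Present value in base-year euros.
#' @export
present_value <- function(profile, params) {
  t <- profile_ages(profile)
  sum(as.numeric(profile) * growth_factor(t, params) *
        discount_factor(t, params))
}

#' Lifetime net present value and cumulative fiscal position
#'
#' The engine of the model: discounts lifetime taxes and transfers,
#' subtracts the upfront treatment cost `K0` paid once at `t = 0`
#' (undiscounted), and accumulates the per-age discounted net flow into the
#' cumulative net position of the treasury.
#'
#' @param taxes,transfers `age_profile` objects on a shared axis (real
#'   base-year expected amounts).
#' @param upfront_cost Upfront cost `K0` in euros at `t = 0` (default 0).
#' @param params A `macro_params`.
#' @return A `fiscal_result`: list with `pv_taxes`, `pv_transfers`, `nfc`
#'   (`pv_taxes - pv_transfers - upfront_cost`), `cumulative` (an
#'   `age_profile`-shaped signed series; `cumulative[N]` equals `nfc`) and
#'   `break_even_age`.
#' @export
npv <- function(taxes, transfers, upfront_cost = 0, params) {
  check_same_axis(taxes, transfers, what = "tax and transfer profiles")
  if (upfront_cost < 0)
    stop("upfront_cost must be non-negative", call. = FALSE)
  t <- profile_ages(taxes)
  w <- growth_factor(t, params) * discount_factor(t, params)
  net <- (as.numeric(taxes) - as.numeric(transfers)) * w
  cumulative <- cumsum(net) - upfront_cost
  res <- structure(list(pv_taxes = sum(as.numeric(taxes) * w),
                        pv_transfers = sum(as.numeric(transfers) * w),
                        nfc = sum(net) - upfront_cost,
                        upfront_cost = upfront_cost,
                        cumulative = stats::setNames(cumulative, t),
                        break_even_age = NA_integer_),
                   class = "fiscal_result")
  res$break_even_age <- break_even_age(res)
  res
}

#' @export
print.fiscal_result <- function(x, ...) {
  cat("<fiscal_result>\n")
  cat(sprintf("  PV taxes      %14.2f\n", x$pv_taxes))
  cat(sprintf("  PV transfers  %14.2f\n", x$pv_transfers))
  cat(sprintf("  upfront cost  %14.2f\n", x$upfront_cost))
  cat(sprintf("  NFC           %14.2f\n", x$nfc))
  cat(sprintf("  break-even age %s\n",
              if (is.na(x$break_even_age)) "none" else x$break_even_age))
  invisible(x)
}

#' Break-even age of a cumulative fiscal position
#'
#' The first age at which the cumulative discounted net position (taxes
#' minus transfers, minus the upfront treatment cost) reaches zero — the
#' age at which accrued state expenses and revenues balance. The model is
#' annual, so the age is an integer; the post-retirement re-descent of the
#' curve does not retract a crossing. Returns `NA` if the curve never
#' reaches zero.
#'
#' @param result A `fiscal_result`.
#' @return Integer age, or `NA` if the position never turns non-negative.
#' @export
break_even_age <- function(result) {
  stopifnot(inherits(result, "fiscal_result"))
  idx <- which(result$cumulative >= 0)
  if (length(idx) == 0L) return(NA_integer_)
  as.integer(names(result$cumulative)[idx[1L]])
}
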