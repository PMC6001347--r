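#' Age profiles
#'
#' An `age_profile` is the atomic series of the model: one value per single
#' year of age on a contiguous axis `0..N`. Two flavours exist:
#'
#' * `"amount"` — euros per year in base-year prices (non-negative, finite);
#' * `"participation"` — the probability of belonging to the paying or
#'   receiving group at that age (in `[0, 1]`).
#'
#' All profile construction happens in real base-year euros; growth,
#' inflation and discounting are applied only by the lifecycle functions.
#'
#' @param values Numeric vector of length `N + 1`, one value per age `0..N`.
#' @param kind `"amount"` or `"participation"`.
#' @param ages Integer ages; must be contiguous and start at 0. Defaults to
#'   `0:(length(values) - 1)`.
#' @return An object of class `age_profile`: a numeric vector with
#'   attributes `ages` and `kind`.
#' @examples
#' age_profile(rep(100, 79))
#' age_profile(rep(0.5, 79), kind = "participation")
#' @export
age_profile <- function(values, kind = c("amount", "participation"),
                        ages = seq_along(values) - 1L) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  ages <- as.integer(ages)
  if (length(values) != length(ages))
    stop("`values` and `ages` must have the same length", call. = FALSE)
  if (length(ages) == 0L || ages[1L] != 0L || !all(diff(ages) == 1L))
    stop("ages must be contiguous integers starting at 0", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("profile values must be finite and non-missing", call. = FALSE)
  if (kind == "participation") {
    if (any(values < 0 | values > 1))
      stop("participation values must lie in [0, 1]", call. = FALSE)
  } else {
    if (any(values < 0))
      stop("amount values must be non-negative", call. = FALSE)
  }
  structure(values, ages = ages, kind = kind, class = "age_profile")
}

#' @export
print.age_profile <- function(x, ...) {
  ages <- attr(x, "ages")
  cat(sprintf("<age_profile: %s, ages %d..%d>\n",
              attr(x, "kind"), ages[1L], ages[length(ages)]))
  print(stats::setNames(as.numeric(x), ages), ...)
  invisible(x)
}

profile_ages <- function(x) attr(x, "ages")

max_age <- function(x) {
  a <- attr(x, "ages")
  a[length(a)]
}

is_age_profile <- function(x) inherits(x, "age_profile")

check_same_axis <- function(..., what = "profiles") {
  ps <- list(...)
  n <- vapply(ps, length, integer(1))
  if (length(unique(n)) != 1L)
    stop(sprintf("%s must share the same age axis", what), call. = FALSE)
  invisible(TRUE)
}

#' Expand age-group means onto a single-year age axis
#'
#' Statistical sources often report per-capita amounts by age band (for
#' example healthcare expenditure for the bands 0-4, 5-14, 15-44, 45-64,
#' 65-74, over 74). This imputes the band mean to every single year of age
#' inside the band; ages covered by no band get 0. Bands are closed
#' intervals; an open-ended final band should be closed at `N`.
#'
#' @param group_means A data frame with columns `age_lo`, `age_hi`,
#'   `amount` (one row per band), or a list of length-3 vectors
#'   `c(age_lo, age_hi, amount)`.
#' @param N Last age of the axis (life expectancy in years).
#' @return An `age_profile` of kind `"amount"` on ages `0..N`.
#' @examples
#' expand_group_profile(data.frame(age_lo = c(0, 5), age_hi = c(4, 14),
#'                                 amount = c(50, 20)), N = 78)
#' @export
expand_group_profile <- function(group_means, N) {
  if (is.list(group_means) && !is.data.frame(group_means))
    group_means <- do.call(rbind.data.frame,
                           lapply(group_means, function(g)
                             stats::setNames(as.list(g),
                                             c("age_lo", "age_hi", "amount"))))
  stopifnot(is.data.frame(group_means),
            all(c("age_lo", "age_hi", "amount") %in% names(group_means)))
  N <- as.integer(N)
  lo <- as.integer(group_means$age_lo)
  hi <- as.integer(group_means$age_hi)
  if (any(lo > hi))
    stop("invalid group: age_lo > age_hi", call. = FALSE)
  if (any(lo < 0L | hi > N))
    stop("group outside the age axis [0, N]", call. = FALSE)
  covered <- rep(FALSE, N + 1L)
  values <- numeric(N + 1L)
  ord <- order(lo)
  for (j in ord) {
    idx <- (lo[j]:hi[j]) + 1L
    if (any(covered[idx]))
      stop("overlapping age groups", call. = FALSE)
    covered[idx] <- TRUE
    values[idx] <- group_means$amount[j]
  }
  age_profile(values)
}

#' Impute a flat per-capita amount from a starting age
#'
#' Used for taxes only available as national aggregates with no age
#' distribution (VAT from age 17, miscellaneous taxes from age 18):
#' `aggregate / population` at every age at or above `start_age`, 0 below.
#'
#' @param aggregate Total amount in euros.
#' @param population Denominator count; must be positive.
#' @param start_age First age at which the per-capita amount applies.
#' @param N Last age of the axis.
#' @return An `age_profile` of kind `"amount"`.
#' @export
per_capita_profile <- function(aggregate, population, start_age, N) {
  if (population <= 0)
    stop("population must be positive", call. = FALSE)
  N <- as.integer(N)
  start_age <- as.integer(start_age)
  if (start_age < 0L || start_age > N)
    stop("start_age must lie in [0, N]", call. = FALSE)
  values <- numeric(N + 1L)
  values[(start_age:N) + 1L] <- aggregate / population
  age_profile(values)
}

#' Weight an amount profile by a participation profile
#'
#' Element-wise product turning a conditional per-recipient amount into an
#' expected per-capita amount: the average transfer (or tax) at each age
#' times the probability of belonging to the recipient (or payer) group at
#' that age.
#'
#' @param amount An `age_profile` of kind `"amount"`.
#' @param participation An `age_profile` of kind `"participation"` on the
#'   same age axis.
#' @return An `age_profile` of kind `"amount"`; never exceeds `amount`.
#' @export
weight_by_participation <- function(amount, participation) {
  check_same_axis(amount, participation)
  p <- as.numeric(participation)
  if (any(p < 0 | p > 1))
    stop("participation values must lie in [0, 1]", call. = FALSE)
  age_profile(as.numeric(amount) * p)
}

transfer_components <- c("education", "healthcare", "wages", "pensions",
                         "unemp")
tax_components <- c("ss", "income", "corporate", "nonresident", "alcohol",
                    "tobacco", "fuel", "vat", "other")

#' Transfer profile set
#'
#' Bundles the five state-to-individual transfer components — education,
#' healthcare, salaries of governmental employees, pensions and unemployment
#' benefits — each as an amount profile plus a participation profile on a
#' shared age axis. Healthcare and pensions are supplied as expected
#' per-capita amounts (group averages already fold in participation), so
#' their participation defaults to 1 at every age.
#'
#' @param education_amount,education_part,healthcare_amount,healthcare_part,wages_amount,wages_part,pensions_amount,pensions_part,unemp_amount,unemp_part
#'   `age_profile` objects on a common axis; `healthcare_part` and
#'   `pensions_part` may be omitted (default: participation 1 at all ages).
#' @return An object of class `transfer_profile_set`.
#' @export
transfer_profile_set <- function(education_amount, education_part,
                                 healthcare_amount, healthcare_part = NULL,
                                 wages_amount, wages_part,
                                 pensions_amount, pensions_part = NULL,
                                 unemp_amount, unemp_part) {
  N <- max_age(education_amount)
  ones <- age_profile(rep(1, N + 1L), kind = "participation")
  if (is.null(healthcare_part)) healthcare_part <- ones
  if (is.null(pensions_part)) pensions_part <- ones
  x <- list(education_amount = education_amount,
            education_part = education_part,
            healthcare_amount = healthcare_amount,
            healthcare_part = healthcare_part,
            wages_amount = wages_amount, wages_part = wages_part,
            pensions_amount = pensions_amount, pensions_part = pensions_part,
            unemp_amount = unemp_amount, unemp_part = unemp_part)
  stopifnot(all(vapply(x, is_age_profile, logical(1))))
  do.call(check_same_axis, c(x, list(what = "transfer profiles")))
  for (nm in grep("_part$", names(x), value = TRUE))
    if (attr(x[[nm]], "kind") != "participation")
      stop(nm, " must be a participation profile", call. = FALSE)
  structure(x, class = "transfer_profile_set")
}

#' Tax profile set
#'
#' Bundles the nine individual-to-state tax components as expected
#' (participation-weighted) per-age amounts on a shared axis: Social
#' Security contributions, income tax, corporate tax, non-resident income
#' tax, alcohol and tobacco excises, the hydrocarbon (petrol/diesel) tax,
#' VAT, and other taxes. Per-capita imputations start at fixed ages: the
#' fuel tax at 13 (driver's licence census), VAT at 17, other taxes at 18 —
#' the constructor enforces zeros below those ages.
#'
#' @param ss,income,corporate,nonresident,alcohol,tobacco,fuel,vat,other
#'   `age_profile` objects of kind `"amount"` on a common axis.
#' @return An object of class `tax_profile_set`.
#' @export
tax_profile_set <- function(ss, income, corporate, nonresident, alcohol,
                            tobacco, fuel, vat, other) {
  x <- list(ss = ss, income = income, corporate = corporate,
            nonresident = nonresident, alcohol = alcohol, tobacco = tobacco,
            fuel = fuel, vat = vat, other = other)
  stopifnot(all(vapply(x, is_age_profile, logical(1))))
  do.call(check_same_axis, c(x, list(what = "tax profiles")))
  starts <- c(fuel = 13L, vat = 17L, other = 18L)
  for (nm in names(starts)) {
    s <- starts[[nm]]
    if (s > 0L && any(as.numeric(x[[nm]])[seq_len(s)] != 0))
      stop(sprintf("%s tax must be zero below age %d", nm, s), call. = FALSE)
  }
  structure(x, class = "tax_profile_set")
}

#' Total expected transfers per age
#'
#' The per-age sum over the five transfer components of amount times
#' participation: the expected euros the state spends on an average
#' individual at each age.
#'
#' @param ts A `transfer_profile_set`.
#' @return An `age_profile` of kind `"amount"`.
#' @export
sum_transfers <- function(ts) {
  stopifnot(inherits(ts, "transfer_profile_set"))
  total <- Reduce(`+`, lapply(transfer_components, function(cmp)
    as.numeric(ts[[paste0(cmp, "_amount")]]) *
      as.numeric(ts[[paste0(cmp, "_part")]])))
  age_profile(total)
}

#' Total expected taxes per age
#'
#' The per-age sum over the nine tax components (already expected amounts).
#'
#' @param ts A `tax_profile_set`.
#' @return An `age_profile` of kind `"amount"`.
#' @export
sum_taxes <- function(ts) {
  stopifnot(inherits(ts, "tax_profile_set"))
  age_profile(Reduce(`+`, lapply(ts[tax_components], as.numeric)))
}
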