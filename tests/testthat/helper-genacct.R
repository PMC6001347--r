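# shared fixture builders; everything is generated in code

flat_profile <- function(value, N = 78, kind = "amount")
  age_profile(rep(value, N + 1), kind = kind)

# tiny but complete profile sets on a short axis for unit tests
toy_transfers <- function(N = 9) {
  amt <- function(v) age_profile(v)
  prt <- function(v) age_profile(v, kind = "participation")
  zeros <- rep(0, N + 1)
  transfer_profile_set(
    education_amount = amt(c(0, 0, 3000, 3000, 3000, rep(0, N - 4))),
    education_part = prt(c(0, 0, 1, 1, 0.5, rep(0, N - 4))),
    healthcare_amount = amt(rep(100, N + 1)),
    wages_amount = amt(c(rep(0, 5), rep(20000, N - 4))),
    wages_part = prt(c(rep(0, 5), rep(0.05, N - 4))),
    pensions_amount = amt(c(rep(50, 5), rep(0, N - 4))),
    unemp_amount = amt(c(rep(0, 5), rep(5000, N - 4))),
    unemp_part = prt(c(rep(0, 5), rep(0.1, N - 4))))
}

toy_taxes <- function(N = 19, fill = 100) {
  amt <- function(start) {
    v <- rep(0, N + 1)
    v[(start:N) + 1] <- fill
    age_profile(v)
  }
  tax_profile_set(ss = amt(16), income = amt(16), corporate = amt(18),
                  nonresident = amt(15), alcohol = amt(16),
                  tobacco = amt(16), fuel = amt(13), vat = amt(17),
                  other = amt(18))
}

# random valid profile sets (seeded by caller) used in property tests
random_transfers <- function(N = 78) {
  amt <- function() age_profile(runif(N + 1, 0, 1000))
  prt <- function() age_profile(runif(N + 1), kind = "participation")
  transfer_profile_set(
    education_amount = amt(), education_part = prt(),
    healthcare_amount = amt(), healthcare_part = prt(),
    wages_amount = amt(), wages_part = prt(),
    pensions_amount = amt(), pensions_part = prt(),
    unemp_amount = amt(), unemp_part = prt())
}

random_taxes <- function(N = 78) {
  amt <- function(start = 0) {
    v <- runif(N + 1, 0, 500)
    if (start > 0) v[seq_len(start)] <- 0
    age_profile(v)
  }
  tax_profile_set(ss = amt(), income = amt(), corporate = amt(),
                  nonresident = amt(), alcohol = amt(), tobacco = amt(),
                  fuel = amt(13), vat = amt(17), other = amt(18))
}

scale_transfer_amounts <- function(ts, alpha) {
  for (nm in grep("_amount$", names(ts), value = TRUE))
    ts[[nm]] <- age_profile(as.numeric(ts[[nm]]) * alpha)
  ts
}

scale_tax_amounts <- function(ts, alpha) {
  for (nm in setdiff(names(ts), character(0)))
    ts[[nm]] <- age_profile(as.numeric(ts[[nm]]) * alpha)
  ts
}
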