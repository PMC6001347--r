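test_that("age_profile enforces its invariants", {
  p <- age_profile(rep(1, 79))
  expect_s3_class(p, "age_profile")
  expect_identical(attr(p, "ages"), 0:78)
  expect_error(age_profile(c(1, 2), ages = c(1, 2)), "starting at 0")
  expect_error(age_profile(c(1, NA)), "finite")
  expect_error(age_profile(c(1, -2)), "non-negative")
  expect_error(age_profile(c(0.5, 1.2), kind = "participation"), "\\[0, 1\\]")
})

test_that("expand_group_profile imputes band means to member ages", {
  p <- expand_group_profile(data.frame(age_lo = 0, age_hi = 78,
                                       amount = 100), N = 78)
  expect_equal(as.numeric(p), rep(100, 79))

  p <- expand_group_profile(data.frame(age_lo = c(0, 5), age_hi = c(4, 14),
                                       amount = c(50, 20)), N = 78)
  expect_equal(as.numeric(p), c(rep(50, 5), rep(20, 10), rep(0, 64)))

  expect_error(expand_group_profile(
    data.frame(age_lo = c(0, 8), age_hi = c(10, 20), amount = c(5, 7)),
    N = 78), "overlap")
  expect_error(expand_group_profile(
    data.frame(age_lo = 70, age_hi = 80, amount = 5), N = 78), "outside")
  expect_error(expand_group_profile(
    data.frame(age_lo = 10, age_hi = 5, amount = 5), N = 78), "age_lo")
})

test_that("expand_group_profile value at each age equals its unique group",
{
  set.seed(42)
  for (rep in 1:5) {
    # random partition of 0..N into bands
    cuts <- sort(sample(1:77, sample(3:8, 1)))
    lo <- c(0, cuts)
    hi <- c(cuts - 1, 78)
    amounts <- runif(length(lo), 0, 100)
    p <- expand_group_profile(data.frame(age_lo = lo, age_hi = hi,
                                         amount = amounts), N = 78)
    for (a in 0:78) {
      g <- which(lo <= a & a <= hi)
      expect_length(g, 1)
      expect_identical(as.numeric(p)[a + 1], amounts[g])
    }
  }
})

test_that("per_capita_profile divides and applies the start age", {
  p <- per_capita_profile(1000, 10, start_age = 17, N = 78)
  expect_equal(as.numeric(p), c(rep(0, 17), rep(100, 62)))
  expect_equal(as.numeric(per_capita_profile(0, 5, 0, 78)), rep(0, 79))
  p <- per_capita_profile(500, 4, start_age = 78, N = 78)
  expect_equal(as.numeric(p), c(rep(0, 78), 125))
  expect_error(per_capita_profile(100, 0, 0, 78), "positive")
  expect_error(per_capita_profile(100, 10, 80, 78), "\\[0, N\\]")
})

test_that("weight_by_participation is an element-wise product, bounded", {
  amount <- flat_profile(200, N = 9)
  expect_equal(as.numeric(weight_by_participation(
    amount, flat_profile(0.5, 9, "participation"))), rep(100, 10))
  expect_equal(as.numeric(weight_by_participation(
    amount, flat_profile(0, 9, "participation"))), rep(0, 10))
  expect_equal(as.numeric(weight_by_participation(
    amount, flat_profile(1, 9, "participation"))), as.numeric(amount))

  set.seed(7)
  a <- age_profile(runif(10, 0, 100))
  p <- age_profile(runif(10), kind = "participation")
  expect_true(all(as.numeric(weight_by_participation(a, p)) <=
                    as.numeric(a)))
  expect_error(weight_by_participation(amount, flat_profile(0.5, 19,
                                                            "participation")),
               "same age axis")
})

test_that("sum_transfers matches a brute-force per-age loop", {
  ts <- toy_transfers(N = 9)
  got <- as.numeric(sum_transfers(ts))
  # independent loop oracle over components and ages
  want <- vapply(1:10, function(i) {
    tot <- 0
    for (cmp in c("education", "healthcare", "wages", "pensions", "unemp"))
      tot <- tot + as.numeric(ts[[paste0(cmp, "_amount")]])[i] *
        as.numeric(ts[[paste0(cmp, "_part")]])[i]
    tot
  }, numeric(1))
  expect_equal(got, want)

  set.seed(11)
  ts <- random_transfers()
  got <- as.numeric(sum_transfers(ts))
  want <- rowSums(vapply(
    c("education", "healthcare", "wages", "pensions", "unemp"),
    function(cmp) as.numeric(ts[[paste0(cmp, "_amount")]]) *
      as.numeric(ts[[paste0(cmp, "_part")]]), numeric(79)))
  expect_equal(got, unname(want))
})

test_that("sum_taxes matches a brute-force per-age loop", {
  expect_equal(as.numeric(sum_taxes(toy_taxes(19, fill = 0))), rep(0, 20))
  # single nonzero component is the identity
  tt <- toy_taxes(19, fill = 0)
  v <- rep(0, 20); v[18:20] <- 250
  tt$vat <- age_profile(v)
  expect_equal(as.numeric(sum_taxes(tt)), v)

  set.seed(12)
  ts <- random_taxes()
  want <- rep(0, 79)
  for (nm in c("ss", "income", "corporate", "nonresident", "alcohol",
               "tobacco", "fuel", "vat", "other"))
    want <- want + as.numeric(ts[[nm]])
  expect_equal(as.numeric(sum_taxes(ts)), want)
})

test_that("sum_transfers and sum_taxes are linear in the amounts", {
  set.seed(13)
  tr <- random_transfers()
  tx <- random_taxes()
  base_tr <- as.numeric(sum_transfers(tr))
  base_tx <- as.numeric(sum_taxes(tx))
  for (alpha in c(0, 0.5, 2)) {
    expect_equal(as.numeric(sum_transfers(scale_transfer_amounts(tr, alpha))),
                 alpha * base_tr)
    expect_equal(as.numeric(sum_taxes(scale_tax_amounts(tx, alpha))),
                 alpha * base_tx)
  }
})

test_that("profile set constructors validate structure", {
  tt <- toy_taxes(19)
  v <- rep(100, 20)  # nonzero below start age 17
  expect_error(tax_profile_set(ss = tt$ss, income = tt$income,
                               corporate = tt$corporate,
                               nonresident = tt$nonresident,
                               alcohol = tt$alcohol, tobacco = tt$tobacco,
                               fuel = tt$fuel, vat = age_profile(v),
                               other = tt$other),
               "zero below age 17")
  ts <- toy_transfers(9)
  expect_error(transfer_profile_set(
    education_amount = ts$education_amount,
    education_part = ts$education_part,
    healthcare_amount = flat_profile(1, N = 19),
    wages_amount = ts$wages_amount, wages_part = ts$wages_part,
    pensions_amount = ts$pensions_amount,
    unemp_amount = ts$unemp_amount, unemp_part = ts$unemp_part),
    "same age axis")
  # healthcare participation defaults to universal coverage
  expect_equal(as.numeric(ts$healthcare_part), rep(1, 10))
})
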