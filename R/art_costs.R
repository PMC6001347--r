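#' Assisted reproduction treatment parameters
#'
#' Characterises a treatment technique by its per-cycle cost, per-cycle
#' pregnancy probability, the number of cycles the state funds, and the
#' probability that an achieved pregnancy results in a live birth.
#'
#' Cycles to the first success are geometric, so the expected number of
#' cycles is `1/p` and the expected cost of achieving a pregnancy is `c/p`.
#' Either the per-cycle cost or the cost per pregnancy may be given (the
#' other is derived), and either the per-cycle success probability or the
#' expected cycle count.
#'
#' @param technique `"ivf"` or `"ai"` (label only).
#' @param cycle_cost Cost per treatment cycle in euros; derived from
#'   `cost_per_pregnancy * success_prob` when omitted.
#' @param cost_per_pregnancy Expected cost of achieving one pregnancy;
#'   derived as `cycle_cost / success_prob` when omitted.
#' @param success_prob Per-cycle pregnancy probability in (0, 1]; derived
#'   as `1 / cycles_needed` when `cycles_needed` is given instead.
#' @param cycles_needed Expected cycles to pregnancy (`1/success_prob`).
#' @param funded_cycles Cycles paid by the state: a positive integer cap or
#'   `Inf` for unlimited funding.
#' @param live_birth_prob Probability that a pregnancy ends in a live birth
#'   (default 0.75).
#' @return An object of class `art_params`.
#' @seealso [ivf_params()], [ai_params()] for the shipped defaults.
#' @export
art_params <- function(technique = c("ivf", "ai"), cycle_cost = NULL,
                       cost_per_pregnancy = NULL, success_prob = NULL,
                       cycles_needed = NULL, funded_cycles = Inf,
                       live_birth_prob = 0.75) {
  technique <- match.arg(technique)
  if (is.null(success_prob)) {
    if (is.null(cycles_needed))
      stop("give success_prob or cycles_needed", call. = FALSE)
    success_prob <- 1 / cycles_needed
  }
  if (success_prob <= 0 || success_prob > 1)
    stop("success_prob must lie in (0, 1]", call. = FALSE)
  if (is.null(cycle_cost)) {
    if (is.null(cost_per_pregnancy))
      stop("give cycle_cost or cost_per_pregnancy", call. = FALSE)
    cycle_cost <- cost_per_pregnancy * success_prob
  }
  if (cycle_cost < 0) stop("cycle_cost must be non-negative", call. = FALSE)
  if (live_birth_prob <= 0 || live_birth_prob > 1)
    stop("live_birth_prob must lie in (0, 1]", call. = FALSE)
  if (is.finite(funded_cycles) &&
      (funded_cycles < 1 || funded_cycles != round(funded_cycles)))
    stop("funded_cycles must be a positive integer or Inf", call. = FALSE)
  structure(list(technique = technique, cycle_cost = cycle_cost,
                 success_prob = success_prob, funded_cycles = funded_cycles,
                 live_birth_prob = live_birth_prob),
            class = "art_params")
}

#' Shipped IVF parameters
#'
#' Per-cycle success rate 28.7%; the per-cycle cost is back-solved from the
#' expected cost per pregnancy of 4,173 euros (2006 prices) as
#' `4173 * 0.287`.
#'
#' @inheritParams art_params
#' @return An `art_params` for IVF.
#' @export
ivf_params <- function(funded_cycles = Inf, live_birth_prob = 0.75) {
  art_params("ivf", cost_per_pregnancy = 4173, success_prob = 0.287,
             funded_cycles = funded_cycles, live_birth_prob = live_birth_prob)
}

#' Shipped AI parameters
#'
#' The per-cycle success probability is recovered from the expected cycle
#' count of 6.53 as `1/6.53`; the per-cycle cost is back-solved from the
#' expected cost per pregnancy of 3,629 euros as `3629 / 6.53`.
#'
#' @inheritParams art_params
#' @return An `art_params` for AI.
#' @export
ai_params <- function(funded_cycles = Inf, live_birth_prob = 0.75) {
  art_params("ai", cost_per_pregnancy = 3629, cycles_needed = 6.53,
             funded_cycles = funded_cycles, live_birth_prob = live_birth_prob)
}

#' Expected treatment cycles to pregnancy
#'
#' Mean of the geometric distribution of cycles to the first success:
#' `1/p`.
#'
#' @param p Per-cycle pregnancy probability in (0, 1].
#' @return Expected number of cycles.
#' @examples
#' expected_cycles(0.287)   # 3.48 cycles
#' @export
expected_cycles <- function(p) {
  if (any(p <= 0 | p > 1))
    stop("success probability must lie in (0, 1]", call. = FALSE)
  1 / p
}

#' Expected cost of achieving one pregnancy
#'
#' `c / p`: per-cycle cost times expected cycles under unlimited funding.
#'
#' @param c Cost per cycle in euros.
#' @param p Per-cycle pregnancy probability in (0, 1].
#' @return Euros.
#' @export
cost_per_pregnancy <- function(c, p) {
  if (any(p <= 0 | p > 1))
    stop("success probability must lie in (0, 1]", call. = FALSE)
  if (any(c < 0)) stop("cycle cost must be non-negative", call. = FALSE)
  c / p
}

#' Expected state expenditure under a capped funding policy
#'
#' If the state pays at most `k` cycles, cycle `j` (0-based) is paid only
#' if the first `j` cycles all failed, so the expected outlay is
#' `c * sum_{j=0}^{k-1} (1-p)^j = (c/p) * (1 - (1-p)^k)`. Cycles paid for
#' couples who never conceive within the cap are included. `k = Inf`
#' recovers the full cost per pregnancy `c/p`.
#'
#' @param c Cost per cycle in euros.
#' @param p Per-cycle pregnancy probability in (0, 1].
#' @param k Funded-cycle cap: positive integer or `Inf`.
#' @return Euros; this is the upfront cost `K0` of the lifecycle model.
#' @examples
#' expected_capped_cost(4173 * 0.287, 0.287, 3)   # about 2660 euros
#' @export
expected_capped_cost <- function(c, p, k) {
  if (any(p <= 0 | p > 1))
    stop("success probability must lie in (0, 1]", call. = FALSE)
  if (any(c < 0)) stop("cycle cost must be non-negative", call. = FALSE)
  if (any(is.finite(k) & (k < 1 | k != round(k))))
    stop("k must be a positive integer or Inf", call. = FALSE)
  ifelse(is.finite(k), (c / p) * (1 - (1 - p)^k), c / p)
}

#' Probability of achieving a pregnancy within the funded cycles
#'
#' `1 - (1-p)^k`; 1 under unlimited funding.
#'
#' @inheritParams expected_capped_cost
#' @return Probability in (0, 1].
#' @export
preg_prob_within <- function(p, k) {
  if (any(p <= 0 | p > 1))
    stop("success probability must lie in (0, 1]", call. = FALSE)
  if (any(is.finite(k) & (k < 1 | k != round(k))))
    stop("k must be a positive integer or Inf", call. = FALSE)
  ifelse(is.finite(k), 1 - (1 - p)^k, 1)
}

#' Live-birth-adjusted expected net fiscal contribution
#'
#' The NFC of a naturally conceived individual scaled by the probability
#' that treatment yields a pregnancy under the funding policy and by the
#' probability that the pregnancy ends in a live birth.
#'
#' @param nfc_natural Lifetime NFC of a (naturally conceived) individual in
#'   euros, excluding treatment cost.
#' @param lambda Live-birth probability in `[0, 1]`.
#' @param preg_prob Probability of pregnancy under the policy in `[0, 1]`.
#' @return Expected NFC in euros.
#' @examples
#' expected_nfc(94510, 0.75, 1)   # 70882.5
#' @export
expected_nfc <- function(nfc_natural, lambda, preg_prob) {
  if (any(lambda < 0 | lambda > 1) || any(preg_prob < 0 | preg_prob > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  nfc_natural * lambda * preg_prob
}

#' Evaluate an assisted-reproduction funding policy
#'
#' Composes the cycle, cost and live-birth arithmetic into a single outcome:
#' expected cycles, cost per pregnancy, the expected state expenditure
#' under the funding policy (the `K0` of the lifecycle model), the
#' pregnancy probability under the policy, the expected NFC, the net
#' contribution (expected NFC minus expected cost), and the return on
#' investment in euros returned per euro invested.
#'
#' @param art An `art_params`.
#' @param nfc_natural Lifetime NFC of a naturally conceived individual in
#'   euros (treatment cost excluded).
#' @return An object of class `art_outcome`: list with `technique`,
#'   `funded_cycles`, `expected_cycles`, `cost_per_pregnancy`,
#'   `expected_cost`, `preg_prob`, `expected_nfc`, `net_contribution`,
#'   `roi`.
#' @examples
#' evaluate_art(ivf_params(), 94510)
#' evaluate_art(ai_params(funded_cycles = 3), 94510)
#' @export
evaluate_art <- function(art, nfc_natural) {
  stopifnot(inherits(art, "art_params"))
  cost <- expected_capped_cost(art$cycle_cost, art$success_prob,
                               art$funded_cycles)
  if (cost == 0)
    stop("expected cost is zero: return on investment undefined",
         call. = FALSE)
  pp <- preg_prob_within(art$success_prob, art$funded_cycles)
  enfc <- expected_nfc(nfc_natural, art$live_birth_prob, pp)
  net <- enfc - cost
  structure(list(technique = art$technique,
                 funded_cycles = art$funded_cycles,
                 expected_cycles = expected_cycles(art$success_prob),
                 cost_per_pregnancy = cost_per_pregnancy(art$cycle_cost,
                                                         art$success_prob),
                 expected_cost = cost, preg_prob = pp, expected_nfc = enfc,
                 net_contribution = net, roi = net / cost),
            class = "art_outcome")
}

#' @export
print.art_outcome <- function(x, ...) {
  cat(sprintf("<art_outcome: %s, funded cycles %s>\n", toupper(x$technique),
              if (is.finite(x$funded_cycles)) x$funded_cycles
              else "unlimited"))
  cat(sprintf("  expected cycles     %8.2f\n", x$expected_cycles))
  cat(sprintf("  cost per pregnancy  %12.2f\n", x$cost_per_pregnancy))
  cat(sprintf("  expected cost (K0)  %12.2f\n", x$expected_cost))
  cat(sprintf("  pregnancy prob.     %8.4f\n", x$preg_prob))
  cat(sprintf("  expected NFC        %12.2f\n", x$expected_nfc))
  cat(sprintf("  net contribution    %12.2f\n", x$net_contribution))
  cat(sprintf("  ROI (EUR per EUR)   %8.2f\n", x$roi))
  invisible(x)
}

#' Half-up rounding for euro display
#'
#' Tables round euro amounts half-up to whole euros (R's `round()` is
#' half-even). Internal arithmetic is never pre-rounded.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
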