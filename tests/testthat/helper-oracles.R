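# Independent oracles used across the suite. These re-derive the target
# quantities from first principles (combinatorial enumeration, direct
# formulas) so they share no code with the implementation paths they check.

# Hypergeometric point probability of cell a given the table margins,
# via binomial coefficients.
hyper_point_prob <- function(a, row1, row2, col1) {
  choose(row1, a) * choose(row2, col1 - a) / choose(row1 + row2, col1)
}

# Support of cell a for fixed margins.
hyper_support <- function(row1, row2, col1) {
  max(0, col1 - row2):min(row1, col1)
}

# Fisher exact p by exhaustive enumeration of all tables with the observed
# margins. One-sided: tail at least as extreme in the observed direction;
# two-sided: sum of point probabilities <= the observed one (with a tiny
# relative tolerance for ties, as in the conventional definition).
fisher_oracle <- function(a, b, c, d, side = c("two_sided", "one_sided")) {
  side <- match.arg(side)
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  support <- hyper_support(row1, row2, col1)
  probs <- vapply(support, hyper_point_prob, numeric(1), row1, row2, col1)
  p_obs <- probs[support == a]
  if (side == "two_sided") {
    return(min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
  }
  expected_a <- row1 * col1 / (row1 + row2)
  if (a <= expected_a) {
    min(1, sum(probs[support <= a]))
  } else {
    min(1, sum(probs[support >= a]))
  }
}

# Conditional hypergeometric moments of cell a for one stratum, computed by
# summing over the enumerated support.
mh_moments_oracle <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  support <- hyper_support(row1, row2, col1)
  probs <- vapply(support, hyper_point_prob, numeric(1), row1, row2, col1)
  e <- sum(support * probs)
  list(e = e, v = sum(support^2 * probs) - e^2)
}

# Closed-form Pearson chi-square statistic for a 2x2 table.
chi2_formula <- function(a, b, c, d, correction = FALSE) {
  n <- a + b + c + d
  num <- if (correction) {
    (max(0, abs(a * d - b * c) - n / 2))^2
  } else {
    (a * d - b * c)^2
  }
  n * num / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Random non-degenerate fourfold table with N <= nmax.
random_fourfold <- function(nmax = 60) {
  repeat {
    counts <- as.integer(rmultinom(1, sample(8:nmax, 1), rep(1 / 4, 4)))
    t <- fourfold_table(counts[1], counts[2], counts[3], counts[4])
    m <- as.matrix(t)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(t)
  }
}

# Random valid chain-probability vector for one arm.
random_chain_probs <- function() {
  p <- runif(length(levoCEA:::prob_params))
  names(p) <- levoCEA:::prob_params
  as.list(p)
}

# Exhaustive 16-pathway enumeration of one arm's expectations, written
# independently of the package's tree code: loops over the four indicator
# bits, multiplies the chain factors, adds stay increments, and prices the
# pathway by explicit catalogue lookups.
enumeration_oracle <- function(p, los_base_icu, los_base_ward,
                               icu_inc, ward_inc,
                               profiles, catalogue, upfront) {
  price <- function(q) {
    sum(vapply(names(q), function(code) {
      q[[code]] * catalogue$unit_cost[catalogue$code == code]
    }, numeric(1)))
  }
  cost <- icu <- ward <- eff <- 0
  for (noaf in c(0, 1)) for (lco in c(0, 1)) {
    for (rf in c(0, 1)) for (mv in c(0, 1)) {
      pp <- (if (noaf) p$noaf else 1 - p$noaf)
      pl <- if (noaf) p$lco_given_noaf else p$lco_given_no_noaf
      pp <- pp * (if (lco) pl else 1 - pl)
      pr <- if (lco) p$rf_given_lco else p$rf_given_no_lco
      pp <- pp * (if (rf) pr else 1 - pr)
      pm <- if (lco) p$mv_given_lco else p$mv_given_no_lco
      pp <- pp * (if (mv) pm else 1 - pm)
      icu_i <- los_base_icu + noaf * icu_inc[["noaf"]] +
        lco * icu_inc[["lco"]] + rf * icu_inc[["rf"]] + mv * icu_inc[["mv"]]
      ward_i <- los_base_ward + noaf * ward_inc[["noaf"]] +
        lco * ward_inc[["lco"]] + rf * ward_inc[["rf"]] +
        mv * ward_inc[["mv"]]
      cost_i <- price(profiles$base) +
        (if (upfront) price(profiles$upfront_intervention) else 0) +
        icu_i * price(profiles$per_icu_day) +
        ward_i * price(profiles$per_ward_day) +
        noaf * price(profiles$noaf) + lco * price(profiles$lco) +
        rf * price(profiles$rf) + mv * price(profiles$mv)
      cost <- cost + pp * cost_i
      icu <- icu + pp * icu_i
      ward <- ward + pp * ward_i
      if (!noaf && !lco && !rf && !mv) eff <- eff + pp
    }
  }
  list(cost = cost, icu = icu, ward = ward, eff = 100 * eff)
}

# 99% binomial concentration half-width for a proportion estimate.
binom99_halfwidth <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)
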