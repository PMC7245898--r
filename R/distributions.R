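#' Parameter distribution specifications
#'
#' Constructors for the distribution families of the probabilistic
#' sensitivity analysis:
#'
#' * `dist_beta(events, non_events)`: transition probabilities, defined by
#'   the occurrence and non-occurrence counts of the event; mean
#'   `events / (events + non_events)`. When either count is zero the
#'   Jeffreys adjustment (+1/2 to both shapes) is applied at sampling time
#'   so the distribution is proper.
#' * `dist_gamma(mean, bound_fraction)`: cost parameters; the shape is set
#'   so the central 95% interval spans `mean * (1 +/- bound_fraction)`
#'   (default 10% around the mean).
#' * `dist_unif(lower, upper)`: resource-use quantities.
#' * `dist_fixed(value)`: degenerate, always `value`.
#'
#' @param events,non_events Non-negative beta counts with a positive sum.
#' @param mean Positive gamma mean.
#' @param bound_fraction Half-width of the central 95% interval as a
#'   fraction of the mean.
#' @param lower,upper Uniform bounds, `lower <= upper`.
#' @param value Fixed value.
#' @return Object of class `dist_spec`.
#' @name dist_spec
NULL

new_dist <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_beta <- function(events, non_events) {
  if (events < 0 || non_events < 0 || events + non_events <= 0) {
    abort_levo("beta counts must be >= 0 with a positive sum",
               "levoCEA_validation_error")
  }
  new_dist("beta", events = events, non_events = non_events)
}

#' @rdname dist_spec
#' @export
dist_gamma <- function(mean, bound_fraction = 0.10) {
  if (!is.finite(mean) || mean <= 0) {
    abort_levo("gamma mean must be > 0", "levoCEA_validation_error")
  }
  if (bound_fraction <= 0 || bound_fraction >= 1) {
    abort_levo("gamma bound_fraction must be in (0, 1)",
               "levoCEA_validation_error")
  }
  new_dist("gamma", mean = mean, bound_fraction = bound_fraction)
}

#' @rdname dist_spec
#' @export
dist_unif <- function(lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower > upper) {
    abort_levo("uniform bounds must be finite with lower <= upper",
               "levoCEA_validation_error")
  }
  new_dist("uniform", lower = lower, upper = upper)
}

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) {
  if (!is.finite(value)) {
    abort_levo("fixed value must be finite", "levoCEA_validation_error")
  }
  new_dist("fixed", value = value)
}

# Gamma shape such that the central 95% interval spans mean*(1 +/- bound);
# the quantile ratio depends on the shape only, so one solve per bound.
gamma_shape_cache <- new.env(parent = emptyenv())

gamma_shape_for_bound <- function(bound) {
  key <- format(bound, digits = 12)
  if (!is.null(gamma_shape_cache[[key]])) {
    return(gamma_shape_cache[[key]])
  }
  shape <- uniroot(
    function(s) (qgamma(0.975, s) - qgamma(0.025, s)) / (2 * s) - bound,
    interval = c(1, 1e7), tol = 1e-10
  )$root
  gamma_shape_cache[[key]] <- shape
  shape
}

#' Sample from a distribution specification
#'
#' Draws from the current RNG stream. Beta draws lie in \[0, 1\] with mean
#' `events / (events + non_events)`; gamma draws are positive with the
#' configured mean; uniform draws lie in `[lower, upper]`; fixed "draws"
#' are constant (no RNG consumed).
#'
#' @param spec A [dist_spec] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    beta = {
      r <- spec$events
      s <- spec$non_events
      if (r == 0 || s == 0) {  # Jeffreys adjustment for empty cells
        r <- r + 0.5
        s <- s + 0.5
      }
      rbeta(n, r, s)
    },
    gamma = {
      shape <- gamma_shape_for_bound(spec$bound_fraction)
      rgamma(n, shape = shape, scale = spec$mean / shape)
    },
    uniform = if (spec$lower == spec$upper) {
      rep(spec$lower, n)
    } else {
      runif(n, spec$lower, spec$upper)
    },
    fixed = rep(spec$value, n)
  )
}
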