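## Population-level rescue probability.
##
## The declining wild-type population is treated deterministically,
## N(t) = N0 exp(s(n,0) t), and successfully establishing mutations form an
## inhomogeneous Poisson process with intensity u n P_est lambda_0 N(t)
## (at most one mutation per cell division). Rescue is the event that this
## process has at least one point; its time integral is available in closed
## form, which also yields the distribution of the (rescue-conditioned)
## time of the first successful mutation.

#' Assemble a rescue setting
#'
#' Combines a fitness model, a replication mode and the mutational input.
#' The analytic quantities depend on `u` and `N0` only through their
#' product, so either the pair or the product `uN0` may be given. The
#' establishment probability is computed from the branching solver unless
#' supplied.
#'
#' @param model A [fitness_model()]; `s(n, 0)` must be negative (the
#'   wild-type population must decline).
#' @param mode `"regular"` or `"random"`.
#' @param u Per-locus per-replication mutation probability (optional if
#'   `uN0` is given).
#' @param N0 Initial wild-type population size (optional if `uN0` given).
#' @param uN0 Product of mutation rate and initial population size.
#' @param P_est Optional establishment probability; computed via
#'   [establishment_probability()] when `NULL`.
#' @return An object of class `rescue_setting`.
#' @examples
#' m <- fitness_model(4, "dominant", s_min = -0.1, s_max = 1.0)
#' s <- rescue_setting(m, "regular", uN0 = 0.1)
#' rescue_probability(s)
#' @export
rescue_setting <- function(model, mode = c("regular", "random"),
                           u = NULL, N0 = NULL, uN0 = NULL, P_est = NULL) {
  stopifnot(inherits(model, "fitness_model"))
  mode <- match.arg(mode)
  if (is.null(uN0)) {
    if (is.null(u) || is.null(N0)) {
      stop("supply either uN0 or both u and N0")
    }
    uN0 <- u * N0
  }
  stopifnot(uN0 >= 0)
  if (!is.null(u) && u < 0) stop("u must be nonnegative")
  if (!is.null(N0) && N0 <= 0) stop("N0 must be positive")
  if (model$s[1L] >= 0) {
    stop("rescue scenario requires a declining wild type: s(n,0) < 0")
  }
  if (is.null(P_est)) P_est <- establishment_probability(model, mode)
  stopifnot(P_est >= 0, P_est <= 1)
  structure(list(model = model, mode = mode, u = u, N0 = N0, uN0 = uN0,
                 P_est = P_est),
            class = "rescue_setting")
}

#' @export
print.rescue_setting <- function(x, ...) {
  cat("Rescue setting: n =", x$model$n, ",", x$model$kind, "fitness,",
      x$mode, "replication\n")
  cat("  uN0 =", x$uN0, ", P_est =", signif(x$P_est, 6),
      ", P_rescue =", signif(rescue_probability(x), 6), "\n")
  invisible(x)
}

#' Deterministic decay of the wild-type population
#'
#' @param setting A [rescue_setting()] (with `N0` set) or a list with
#'   components `model` and `N0`.
#' @param t Time(s) in mean-lifespan units, >= 0.
#' @return Population size(s) `N0 * exp(s(n,0) * t)`.
#' @export
wildtype_decay <- function(setting, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (is.null(setting$N0)) stop("wildtype_decay requires N0, not just uN0")
  setting$N0 * exp(setting$model$s[1L] * t)
}

## exponent of the rescue probability: u n N0 (1+s0)/|s0| P_est
rescue_exponent <- function(setting, t = Inf) {
  s0 <- setting$model$s[1L]
  n <- setting$model$n
  full <- setting$uN0 * n * (1 + s0) / abs(s0) * setting$P_est
  full * (1 - exp(s0 * t))
}

#' Probability of evolutionary rescue
#'
#' \deqn{P_{rescue} = 1 - \exp\!\left(-u n N_0
#'   \frac{1 + s(n,0)}{|s(n,0)|} P_{est}\right).}
#'
#' @param setting A [rescue_setting()].
#' @return A single probability.
#' @export
rescue_probability <- function(setting) {
  stopifnot(inherits(setting, "rescue_setting"))
  1 - exp(-rescue_exponent(setting))
}

#' Distribution of the time of the first successful rescue mutation
#'
#' Conditional on rescue, the arrival time `T` of the first mutation whose
#' lineage establishes has cdf
#' \deqn{P(T \le t) = \frac{1 - \exp(-u n P_{est} (1+s_0) N_0
#'   (1 - e^{s_0 t})/|s_0|)}{P_{rescue}}.}
#'
#' @param setting A [rescue_setting()] with positive rescue probability.
#' @param t Time(s) >= 0.
#' @return Conditional probabilities `P(T <= t | rescue)`.
#' @export
rescue_time_cdf <- function(setting, t) {
  stopifnot(inherits(setting, "rescue_setting"))
  if (any(t < 0)) stop("t must be nonnegative")
  pr <- rescue_probability(setting)
  if (pr == 0) stop("rescue probability is zero: rescue time is undefined")
  (1 - exp(-rescue_exponent(setting, t))) / pr
}

#' Conditional median time of the first successful rescue mutation
#'
#' Solves `P(T <= t) = 1/2` by root bracketing.
#'
#' @inheritParams rescue_time_cdf
#' @return The median rescue time.
#' @export
median_rescue_time <- function(setting) {
  stopifnot(inherits(setting, "rescue_setting"))
  pr <- rescue_probability(setting)
  if (pr == 0) stop("rescue probability is zero: rescue time is undefined")
  upper <- 1
  while (rescue_time_cdf(setting, upper) < 0.5) upper <- upper * 2
  stats::uniroot(function(t) rescue_time_cdf(setting, t) - 0.5,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Conditional mean time of the first successful rescue mutation
#'
#' Computes `E[T | rescue]` as the integral of the survival function
#' `1 - P(T <= t)` by adaptive quadrature.
#'
#' @inheritParams rescue_time_cdf
#' @return The mean rescue time in mean-lifespan units.
#' @export
mean_rescue_time <- function(setting) {
  stopifnot(inherits(setting, "rescue_setting"))
  pr <- rescue_probability(setting)
  if (pr == 0) stop("rescue probability is zero: rescue time is undefined")
  stats::integrate(function(t) 1 - rescue_time_cdf(setting, t),
                   lower = 0, upper = Inf, rel.tol = 1e-10)$value
}
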