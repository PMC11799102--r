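#' Dominant fitness function
#'
#' Net growth rate of a cell carrying `i` mutant plasmids out of `n` under the
#' dominant fitness function: a single copy of either allele confers the full
#' fitness effect, so every heterozygote (0 < i < n) has net growth rate
#' `s_max` while both homozygotes have `s_min`.
#'
#' @param n Plasmid copy number (integer >= 1).
#' @param i Number of mutant plasmid copies, 0 <= i <= n. Vectorised.
#' @param s_min Net growth rate of homozygote cells, must be negative.
#' @param s_max Net growth rate of heterozygote cells, must be positive.
#' @return Numeric vector of net growth rates (Malthusian fitnesses).
#' @examples
#' dominant_fitness(4, 0:4, s_min = -0.1, s_max = 1.0)
#' @export
dominant_fitness <- function(n, i, s_min, s_max) {
  check_copy_number(n)
  check_mutant_count(n, i)
  stopifnot(s_min < 0, s_max > 0)
  ifelse(i == 0L | i == n, s_min, s_max)
}

#' Peaked fitness function
#'
#' Net growth rate that linearly interpolates between a maximum `s_max` at an
#' exact half-and-half mixture of mutant and wild-type plasmids and a minimum
#' `s_min` for the two homozygotes:
#' \deqn{s(n,i) = s_{max} - \frac{2(s_{max}-s_{min})}{n}\left|i - n/2\right|.}
#' For odd `n` the balanced composition is a half-integer and no cell attains
#' `s_max` exactly; the formula is evaluated as printed, with no rounding.
#'
#' @inheritParams dominant_fitness
#' @return Numeric vector of net growth rates.
#' @examples
#' peaked_fitness(4, 0:4, s_min = -0.1, s_max = 1.0)
#' @export
peaked_fitness <- function(n, i, s_min, s_max) {
  check_copy_number(n)
  check_mutant_count(n, i)
  stopifnot(s_min < 0, s_max > 0)
  s_max - (2 * (s_max - s_min) / n) * abs(i - n / 2)
}

#' Construct a plasmid fitness model
#'
#' Bundles the copy number `n` with the per-type net growth rates
#' `s(n, i)`, `i = 0..n`, and the implied birth rates `lambda_i = 1 + s(n,i)`.
#' The death rate is fixed at `mu_i = 1` for every type, which sets the unit
#' of time to the mean cell lifespan; results for other death rates follow by
#' rescaling time (see [rescale_rates()]).
#'
#' Both homozygote types must decline (`s(n,0) < 0` and `s(n,n) < 0`) --- the
#' rescue scenario requires maintenance of both alleles --- and every birth
#' rate must be nonnegative (`s(n,i) > -1`). These constraints are enforced
#' for custom tables as well.
#'
#' @param n Plasmid copy number (integer >= 1).
#' @param kind One of `"dominant"`, `"peaked"`, `"custom"`.
#' @param s_min,s_max Homozygote and (maximum) heterozygote net growth rates;
#'   required for the built-in kinds, ignored when `kind = "custom"`.
#' @param table Numeric vector of length `n + 1` giving `s(n, i)` for
#'   `i = 0..n`; required when `kind = "custom"`.
#' @return An object of class `fitness_model` with components `n`, `kind`,
#'   `s_min`, `s_max`, `s` (length `n + 1`), `lambda` (birth rates) and
#'   `mu` (death rates, all 1).
#' @examples
#' m <- fitness_model(4, "dominant", s_min = -0.1, s_max = 1.0)
#' m$s
#' @export
fitness_model <- function(n, kind = c("dominant", "peaked", "custom"),
                          s_min = NULL, s_max = NULL, table = NULL) {
  check_copy_number(n)
  n <- as.integer(n)
  kind <- match.arg(kind)
  if (kind == "custom") {
    if (is.null(table)) {
      stop("kind = \"custom\" requires a fitness `table` of length n + 1")
    }
    if (length(table) != n + 1L || !is.numeric(table)) {
      stop("custom fitness table must be a numeric vector of length n + 1 (",
           n + 1L, "), got length ", length(table))
    }
    s <- as.numeric(table)
    s_min <- min(s[1L], s[n + 1L])
    s_max <- max(s)
  } else {
    if (is.null(s_min) || is.null(s_max)) {
      stop("s_min and s_max are required for kind = \"", kind, "\"")
    }
    if (s_min >= 0) stop("s_min must be negative (homozygotes must decline)")
    if (s_max <= 0) stop("s_max must be positive (heterozygote advantage)")
    s <- switch(kind,
      dominant = dominant_fitness(n, 0:n, s_min, s_max),
      peaked   = peaked_fitness(n, 0:n, s_min, s_max)
    )
  }
  if (s[1L] >= 0 || s[n + 1L] >= 0) {
    stop("homozygote fitnesses s(n,0) and s(n,n) must be negative")
  }
  if (any(s <= -1)) {
    stop("all net growth rates must exceed -1 so that birth rates ",
         "lambda_i = 1 + s(n,i) are nonnegative; offending types: ",
         paste(which(s <= -1) - 1L, collapse = ", "))
  }
  structure(
    list(n = n, kind = kind, s_min = s_min, s_max = s_max,
         s = s, lambda = 1 + s, mu = rep(1, n + 1L)),
    class = "fitness_model"
  )
}

#' @export
print.fitness_model <- function(x, ...) {
  cat("Plasmid fitness model (", x$kind, ")\n", sep = "")
  cat("  copy number n:", x$n, "\n")
  cat("  s(n, i), i = 0..n:", paste(signif(x$s, 4), collapse = " "), "\n")
  cat("  birth rates lambda_i = 1 + s(n,i); death rates mu_i = 1\n")
  invisible(x)
}

#' Probability that a cell reproduces before it dies
#'
#' For a type-`i` cell with birth rate `lambda_i = 1 + s(n, i)` and death
#' rate 1, the probability that the next event is a division rather than a
#' death is `rho_i = lambda_i / (lambda_i + 1)`. Under the dominant fitness
#' function this takes only the two values
#' `rho_hom = (1 + s_min) / (2 + s_min)` and
#' `rho_het = (1 + s_max) / (2 + s_max)`.
#'
#' @param model A [fitness_model()].
#' @param i Mutant-copy count(s), 0 <= i <= n; defaults to all types.
#' @return Numeric vector of reproduction probabilities in `[0, 1)`.
#' @examples
#' m <- fitness_model(4, "dominant", s_min = -0.1, s_max = 1.0)
#' reproduction_probability(m, 1)  # (1 + 1)/(2 + 1) = 2/3
#' @export
reproduction_probability <- function(model, i = 0:model$n) {
  stopifnot(inherits(model, "fitness_model"))
  check_mutant_count(model$n, i)
  lam <- model$lambda[i + 1L]
  lam / (lam + 1)
}

#' Rescale rates for a non-unit death rate
#'
#' The model fixes the death rate at `mu = 1`, making the unit of time the
#' mean cell lifespan. All probabilities (establishment, rescue) are
#' invariant under a common rescaling of all rates; only times change.
#' Given results computed at `mu = 1`, times for a death rate `mu != 1`
#' are obtained by dividing by `mu`. This helper performs that conversion.
#'
#' @param t Time (or times) measured in mean-lifespan units (`mu = 1`).
#' @param mu Actual death rate, > 0.
#' @return Times on the absolute scale implied by `mu`.
#' @export
rescale_rates <- function(t, mu) {
  stopifnot(is.numeric(mu), mu > 0)
  t / mu
}

check_copy_number <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || n < 1 || n != floor(n)) {
    stop("copy number n must be a single integer >= 1")
  }
  invisible(TRUE)
}

check_mutant_count <- function(n, i) {
  if (!is.numeric(i) || any(i < 0) || any(i > n) || any(i != floor(i))) {
    stop("mutant count i must be integer(s) in 0..n (n = ", n, ")")
  }
  invisible(TRUE)
}
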