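## Spectral analysis of the expected-progeny matrix.
##
## M has (i, j) entry the expected number of daughters with j mutant
## plasmids from a type-i parent: M = 2 R P in regular mode, with R the
## diagonal matrix of reproduction probabilities and P the hypergeometric
## segregation marginal. The eigenvalues of P are known in closed form,
## which yields the critical thresholds on heterozygote fitness and copy
## number; the leading left eigenvector of M gives the long-run cell-type
## distribution of an established (rescued) population.

#' Segregation marginal matrix
#'
#' The (n+1) x (n+1) row-stochastic matrix whose `(i, j)` entry is the
#' probability that a uniformly chosen daughter of a type-`i` parent has
#' `j` mutant plasmids. In regular mode this is the hypergeometric matrix
#' `C(2i, j) C(2(n-i), n-j) / C(2n, n)`.
#'
#' @param n Copy number.
#' @param mode `"regular"` or `"random"`.
#' @return An (n+1) x (n+1) matrix with dimnames `0..n`.
#' @export
segregation_marginal_matrix <- function(n, mode = c("regular", "random")) {
  pair_kernel(n, match.arg(mode))$marginal
}

#' Expected-progeny matrix
#'
#' `m_ij = rho_i * sum_k 2^{delta_jk} P(i -> {j, k})`, i.e. twice the
#' reproduction probability times the marginal daughter matrix.
#'
#' @param model A [fitness_model()].
#' @param mode `"regular"` or `"random"`.
#' @return An (n+1) x (n+1) matrix.
#' @examples
#' m <- fitness_model(2, "dominant", s_min = -0.1, s_max = 4)
#' progeny_matrix(m, "regular")
#' @export
progeny_matrix <- function(model, mode = c("regular", "random")) {
  stopifnot(inherits(model, "fitness_model"))
  mode <- match.arg(mode)
  rho <- reproduction_probability(model)
  2 * rho * segregation_marginal_matrix(model$n, mode)
}

#' Closed-form eigenvalues of the regular segregation marginal
#'
#' The eigenvalues of the hypergeometric matrix `P` are
#' `chi_i = 2^i C(n, i) / C(2n, i)`, `i = 0..n`, a nonincreasing sequence
#' with `chi_0 = chi_1 = 1` and `chi_2 = 2(n-1)/(2n-1)`.
#'
#' @param n Copy number >= 1.
#' @return Numeric vector of length `n + 1`.
#' @export
chi_eigenvalues <- function(n) {
  check_copy_number(n)
  i <- 0:n
  2^i * exp(lchoose(n, i) - lchoose(2 * n, i))
}

#' Leading eigenvalue of the expected-progeny matrix
#'
#' @inheritParams progeny_matrix
#' @return The largest (real) eigenvalue of `M`.
#' @export
leading_eigenvalue <- function(model, mode = c("regular", "random")) {
  M <- progeny_matrix(model, match.arg(mode))
  max(Re(eigen(M, only.values = TRUE)$values))
}

#' Critical heterozygote fitness for establishment
#'
#' The threshold on `s_max` above which establishment (and hence rescue)
#' has positive probability under the dominant fitness function:
#' `2/(2n-3)` for regular replication and `4n/(2n^2-3n-1)` for random
#' replication. The boundary itself is excluded (equality means certain
#' extinction). For `n < 2` no heterozygote class exists and the threshold
#' is `Inf`.
#'
#' @param n Copy number(s).
#' @param mode `"regular"` or `"random"`.
#' @return Threshold value(s) of `s_max` (possibly `Inf`).
#' @examples
#' critical_s_max(2, "regular")  # 2: division rate must exceed 3
#' @export
critical_s_max <- function(n, mode = c("regular", "random")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n), all(n >= 1), all(n == floor(n)))
  thr <- switch(mode,
    regular = 2 / (2 * n - 3),
    random  = 4 * n / (2 * n^2 - 3 * n - 1)
  )
  ifelse(n < 2, Inf, thr)
}

#' Minimal copy number permitting establishment
#'
#' Inverts the critical-fitness thresholds: establishment is possible if
#' and only if `n > 1/s_max + 3/2` (regular) or
#' `n > 1/s_max + 3/4 + sqrt((1/s_max + 3/4)^2 + 1/2)` (random). Returns
#' the smallest integer strictly satisfying the inequality.
#'
#' @param s_max Heterozygote fitness > 0.
#' @param mode `"regular"` or `"random"`.
#' @return The minimal copy number (integer).
#' @examples
#' critical_n(1, "regular")  # 3
#' critical_n(1, "random")   # 4
#' @export
critical_n <- function(s_max, mode = c("regular", "random")) {
  mode <- match.arg(mode)
  stopifnot(s_max > 0)
  bound <- switch(mode,
    regular = 1 / s_max + 3 / 2,
    random  = 1 / s_max + 3 / 4 + sqrt((1 / s_max + 3 / 4)^2 + 1 / 2)
  )
  as.integer(floor(bound) + 1)
}

#' Long-run distribution of cell types in an established population
#'
#' The left eigenvector of the expected-progeny matrix `M` for its
#' dominant eigenvalue, normalized to sum to 1, gives the long-run
#' proportions of cells with `0..n` mutant plasmids (homozygotes included:
#' they are constantly replenished by segregation). Defined only for
#' supercritical models; for subcritical ones the population goes extinct
#' with probability one and there is no stationary distribution.
#'
#' @inheritParams progeny_matrix
#' @return Named numeric vector of length `n + 1` summing to 1.
#' @export
stationary_type_distribution <- function(model, mode = c("regular", "random")) {
  mode <- match.arg(mode)
  M <- progeny_matrix(model, mode)
  e <- eigen(t(M))
  lead <- which.max(Re(e$values))
  if (Re(e$values[lead]) <= 1 + 1e-12) {
    stop("model is subcritical (leading eigenvalue <= 1): the population ",
         "goes extinct with probability one and there is no stationary ",
         "type distribution")
  }
  v <- Re(e$vectors[, lead])
  v <- abs(v) / sum(abs(v))
  names(v) <- 0:model$n
  v
}

#' Long-run growth rate of the rescued population
#'
#' Once established, the rescued population grows (in continuous time) at
#' rate `(1 + s_max)(2*chi - 1) - 1`, where `chi` is the largest
#' eigenvalue of the segregation marginal other than 1: `2(n-1)/(2n-1)`
#' for regular replication and `(n-1)(2n+1)/((n+1)(2n-1))` for random
#' replication. Derived for the dominant fitness function.
#'
#' @param n Copy number >= 2.
#' @param s_max Heterozygote fitness.
#' @param mode `"regular"` or `"random"`.
#' @return Net growth rate of the established population.
#' @examples
#' rescued_growth_rate(2, 1, "regular")  # -1/3: below threshold
#' @export
rescued_growth_rate <- function(n, s_max, mode = c("regular", "random")) {
  mode <- match.arg(mode)
  stopifnot(all(n >= 2), all(n == floor(n)))
  chi <- switch(mode,
    regular = 2 * (n - 1) / (2 * n - 1),
    random  = (n - 1) * (2 * n + 1) / ((n + 1) * (2 * n - 1))
  )
  (1 + s_max) * (2 * chi - 1) - 1
}

#' Heterozygote-fitness threshold of the balanced-composition model
#'
#' A simplified comparison model treats every heterozygote as an exact
#' half-and-half mixture, so the probability of a homozygote daughter is
#' `2^{1-n}`; its establishment threshold is `s_max > 1/(2^{n-2} - 1)`.
#' For `n > 3` this is strictly weaker than the regular-replication
#' threshold: ignoring unbalanced heterozygotes overestimates stability.
#'
#' @param n Copy number >= 3 (the denominator vanishes at `n = 2`).
#' @return The comparison threshold on `s_max`.
#' @export
half_and_half_threshold <- function(n) {
  stopifnot(is.numeric(n), all(n == floor(n)))
  if (any(n <= 2)) stop("half_and_half_threshold requires n >= 3")
  1 / (2^(n - 2) - 1)
}
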