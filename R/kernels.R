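## Division-outcome kernels for plasmid replication and segregation.
##
## A dividing cell with i mutant plasmids out of n replicates its plasmids up
## to 2n copies and segregates n into each daughter. Two replication modes
## are supported (after the classic taxonomy of copy-number control models):
##   regular -- every copy replicated exactly once (deterministic doubling),
##   random  -- copies drawn iteratively at random (Polya urn) up to 2n.
## Distributions over unordered daughter pairs {j, k} carry the doubling
## factor for j != k, so stored probabilities sum to 1.

# binomial coefficient with the combinatorial conventions the urn pmf needs:
# C(a, 0) = 1 for every a (including C(-1, 0) = 1); C(a, b) = 0 when b < 0
# or b > a >= 0. Computed in log space for numerical range.
binom_coef <- function(a, b) {
  out <- numeric(length(a <- rep_len(a, m <- max(length(a), length(b)))))
  b <- rep_len(b, m)
  out[b == 0] <- 1
  ok <- b > 0 & a >= b
  out[ok] <- exp(lchoose(a[ok], b[ok]))
  out
}

#' Regular-replication division kernel for one parent type
#'
#' Under regular replication every plasmid copy is duplicated, so a parent
#' with `i` mutant copies holds `2i` mutant among `2n` plasmids at division;
#' random segregation into halves makes the daughter mutant count
#' hypergeometric, and the unordered daughter pair `{j, k}` must satisfy
#' `j + k = 2i`.
#'
#' @param n Copy number.
#' @param i Parent mutant-copy count, 0 <= i <= n.
#' @return A data frame with columns `j`, `k` (`j <= k`) and `prob`;
#'   probabilities sum to 1 and include the factor 2 for `j != k`.
#' @examples
#' regular_pair_probs(2, 1)  # {1,1} w.p. 2/3, {0,2} w.p. 1/3
#' @export
regular_pair_probs <- function(n, i) {
  check_copy_number(n)
  check_mutant_count(n, i)
  stopifnot(length(i) == 1L)
  j <- max(0L, 2L * i - n):min(i, n)  # j <= k = 2i - j  =>  j <= i
  k <- 2L * i - j
  keep <- k <= n
  j <- j[keep]; k <- k[keep]
  p <- ifelse(j == k, 1, 2) *
    exp(lchoose(2 * i, j) + lchoose(2 * (n - i), n - j) - lchoose(2 * n, n))
  data.frame(j = j, k = k, prob = p)
}

#' Post-replication mutant-copy distribution under the Polya urn
#'
#' Random replication draws the next template uniformly from the current
#' pool until `2n` copies exist; starting from `i` mutant of `n` copies the
#' final mutant count `m` follows a Polya urn law with pmf
#' `C(2n-m-1, n-m+i) C(m-1, m-i) / C(2n-1, n)` on `m = 0..2n`.
#'
#' @param n Copy number.
#' @param i Initial mutant-copy count, 0 <= i <= n.
#' @return Numeric vector of length `2n + 1`, named by `m = 0..2n`.
#' @examples
#' polya_copy_pmf(2, 1)  # uniform 1/3 on m = 1, 2, 3
#' @export
polya_copy_pmf <- function(n, i) {
  check_copy_number(n)
  check_mutant_count(n, i)
  stopifnot(length(i) == 1L)
  m <- 0:(2L * n)
  p <- binom_coef(2 * n - m - 1, n - m + i) * binom_coef(m - 1, m - i) /
    exp(lchoose(2 * n - 1, n))
  names(p) <- m
  p
}

#' Random-replication division kernel for one parent type
#'
#' Composition of Polya-urn replication with the hypergeometric segregation
#' split: the unordered daughter pair `{j, k}` has probability
#' (doubled for `j != k`)
#' \deqn{\frac{\binom{j+k}{j}\binom{2n-j-k}{n-j}}{\binom{2n}{n}} \cdot
#'       \frac{\binom{2n-j-k-1}{n-j-k+i}\binom{j+k-1}{j+k-i}}{\binom{2n-1}{n}}.}
#'
#' @inheritParams regular_pair_probs
#' @return A data frame with columns `j`, `k` (`j <= k`) and `prob`.
#' @examples
#' random_pair_probs(2, 1)
#' @export
random_pair_probs <- function(n, i) {
  check_copy_number(n)
  check_mutant_count(n, i)
  stopifnot(length(i) == 1L)
  grid <- expand.grid(j = 0:n, k = 0:n)
  grid <- grid[grid$j <= grid$k, ]
  m <- grid$j + grid$k
  split <- binom_coef(m, grid$j) * binom_coef(2 * n - m, n - grid$j) /
    exp(lchoose(2 * n, n))
  urn <- binom_coef(2 * n - m - 1, n - m + i) * binom_coef(m - 1, m - i) /
    exp(lchoose(2 * n - 1, n))
  p <- ifelse(grid$j == grid$k, 1, 2) * split * urn
  keep <- p > 0
  out <- data.frame(j = grid$j[keep], k = grid$k[keep], prob = p[keep])
  out[order(out$j, out$k), , drop = FALSE]
}

#' Mutant-copy count after replication, given exactly one mutation
#'
#' Under random replication a mutation arising during plasmid replication
#' can itself be replicated within the same cell cycle. Conditional on
#' exactly one mutation occurring, the number `m` of mutant plasmids among
#' the `2n` products has pmf
#' \deqn{\frac{2n+(n-1)m}{n\,m\,(m+1)} \frac{\binom{n}{m}}{\binom{2n-1}{m}},
#'       \quad m = 1..n,}
#' with zero mass above `n`.
#'
#' @param n Copy number.
#' @return Numeric vector of length `n`, named by `m = 1..n`.
#' @examples
#' conditional_single_mutation_pmf(2)  # 5/6, 1/6
#' @export
conditional_single_mutation_pmf <- function(n) {
  check_copy_number(n)
  m <- seq_len(n)
  p <- (2 * n + (n - 1) * m) / (n * m * (m + 1)) *
    exp(lchoose(n, m) - lchoose(2 * n - 1, m))
  names(p) <- m
  p
}

#' Hypergeometric segregation split of m mutant plasmids
#'
#' Given `m` mutant plasmids among the `2n` post-replication copies, random
#' segregation into halves sends `j` mutants to one daughter and `k = m - j`
#' to the other with probability `C(m,j) C(2n-m, n-j) / C(2n, n)`, doubled
#' for unordered pairs with `j != k`.
#'
#' @param n Copy number.
#' @param m Post-replication mutant count, 0 <= m <= 2n.
#' @return A data frame with columns `j`, `k` (`j <= k`, `j + k = m`) and
#'   `prob`.
#' @examples
#' segregation_split_pmf(2, 2)  # {1,1}: 2/3, {0,2}: 1/3
#' @export
segregation_split_pmf <- function(n, m) {
  check_copy_number(n)
  if (length(m) != 1L || !is.numeric(m) || m < 0 || m > 2 * n ||
      m != floor(m)) {
    stop("m must be a single integer in 0..2n")
  }
  j <- max(0L, m - n):floor(m / 2)
  k <- m - j
  p <- ifelse(j == k, 1, 2) * binom_coef(m, j) *
    binom_coef(2 * n - m, n - j) / exp(lchoose(2 * n, n))
  data.frame(j = j, k = k, prob = p)
}

#' Head-start distribution of the first mutation under random replication
#'
#' The unordered daughter pair `{j, k}` produced by the division in which a
#' single mutation arises: the replication factor
#' ([conditional_single_mutation_pmf()]) composed with the segregation split
#' ([segregation_split_pmf()]). This is the launch state of the mutant
#' lineage under random replication (it may begin with several mutant
#' plasmids, possibly in two separate cells).
#'
#' @param n Copy number.
#' @return A data frame with columns `j`, `k` (`j <= k`) and `prob`,
#'   summing to 1.
#' @export
single_mutation_pair_pmf <- function(n) {
  repl <- conditional_single_mutation_pmf(n)
  out <- do.call(rbind, lapply(seq_len(n), function(m) {
    sp <- segregation_split_pmf(n, m)
    sp$prob <- sp$prob * repl[[m]]
    sp
  }))
  agg <- stats::aggregate(prob ~ j + k, data = out, FUN = sum)
  agg[order(agg$j, agg$k), , drop = FALSE]
}

#' Full division kernel for all parent types
#'
#' Computes the unordered daughter-pair distribution for every parent type
#' `i = 0..n` under the chosen replication mode, plus the marginal daughter
#' matrix whose `(i, j)` entry is the probability that a uniformly chosen
#' daughter of a type-`i` parent has `j` mutant plasmids. Kernels are cached
#' per `(n, mode)`.
#'
#' @param n Copy number.
#' @param mode `"regular"` or `"random"`.
#' @return An object of class `pair_kernel`: a list with `n`, `mode`,
#'   `pair_probs` (list of data frames indexed by parent type `i + 1`) and
#'   `marginal` ((n+1) x (n+1) row-stochastic matrix).
#' @examples
#' k <- pair_kernel(2, "regular")
#' k$marginal["1", "1"]  # 2/3: heterozygote daughters of a heterozygote
#' @export
pair_kernel <- function(n, mode = c("regular", "random")) {
  check_copy_number(n)
  mode <- match.arg(mode)
  key <- paste0(mode, ":", n)
  if (!is.null(cached <- .kernel_cache[[key]])) return(cached)
  pp <- lapply(0:n, function(i) {
    switch(mode,
      regular = regular_pair_probs(n, i),
      random  = random_pair_probs(n, i)
    )
  })
  marg <- matrix(0, n + 1L, n + 1L, dimnames = list(0:n, 0:n))
  for (i in 0:n) {
    d <- pp[[i + 1L]]
    for (r in seq_len(nrow(d))) {
      marg[i + 1L, d$j[r] + 1L] <- marg[i + 1L, d$j[r] + 1L] + d$prob[r] / 2
      marg[i + 1L, d$k[r] + 1L] <- marg[i + 1L, d$k[r] + 1L] + d$prob[r] / 2
    }
  }
  out <- structure(list(n = n, mode = mode, pair_probs = pp, marginal = marg),
                   class = "pair_kernel")
  .kernel_cache[[key]] <- out
  out
}

.kernel_cache <- new.env(parent = emptyenv())

#' @export
print.pair_kernel <- function(x, ...) {
  cat("Plasmid division kernel: n =", x$n, ", mode =", x$mode, "\n")
  cat("  pair distributions for parent types i = 0..", x$n,
      "; marginal daughter matrix ", x$n + 1, "x", x$n + 1, "\n", sep = "")
  invisible(x)
}

#' Tidy table of a division kernel
#'
#' @param kernel A [pair_kernel()].
#' @return A data frame with columns `n`, `mode`, `i`, `j`, `k`, `prob`.
#' @export
kernel_table <- function(kernel) {
  stopifnot(inherits(kernel, "pair_kernel"))
  do.call(rbind, lapply(0:kernel$n, function(i) {
    d <- kernel$pair_probs[[i + 1L]]
    data.frame(n = kernel$n, mode = kernel$mode, i = i,
               j = d$j, k = d$k, prob = d$prob)
  }))
}
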