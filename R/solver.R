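## Extinction-probability fixed point for multitype branching processes.
##
## Each type t dies before dividing with probability 1 - rho_t and otherwise
## produces an unordered daughter pair {j, k} from its division kernel. The
## extinction probabilities are the least fixed point of
##   f_t(z) = (1 - rho_t) + rho_t * sum_pairs P(t -> {j,k}) z_j z_k,
## reached by iterating from the zero vector. Plain sweeps converge
## monotonically but slow down near criticality, so after a warm-up the
## solver switches to Newton's method on z - f(z); for monotone convex
## systems of this kind Newton iterates started below the least fixed point
## converge to it monotonically, and quadratically away from the critical
## manifold.

least_fixed_point <- function(q0, rho, ei, ej, ek, p,
                              tol = 1e-12, max_iter = 1e5L,
                              warmup = 256L, newton = TRUE) {
  nt <- length(q0)
  stopifnot(length(rho) == nt, length(ei) == length(p),
            length(ej) == length(p), length(ek) == length(p))
  z <- numeric(nt)
  iter <- 0L
  monotone <- TRUE
  sweep_f <- function(z) {
    acc <- numeric(nt)
    s <- rowsum(p * z[ej] * z[ek], group = ei)
    acc[as.integer(rownames(s))] <- s[, 1L]
    q0 + rho * acc
  }
  residual <- Inf
  repeat {
    fz <- sweep_f(z)
    residual <- max(abs(fz - z))
    if (residual < tol || iter >= max_iter) break
    if (any(fz < z - 1e-13)) monotone <- FALSE
    if (newton && iter >= warmup) {
      ## Newton step on F(z) = z - f(z)
      jac <- jacobian_quadratic(z, rho, ei, ej, ek, p, nt)
      step <- tryCatch(solve(diag(nt) - jac, fz - z), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        znew <- z + step
        if (all(znew > -1e-10) && all(znew < 1 + 1e-8)) {
          z <- pmin(pmax(znew, 0), 1)
          iter <- iter + 1L
          next
        }
      }
    }
    z <- fz
    iter <- iter + 1L
  }
  if (residual >= tol) {
    stop("extinction fixed point did not converge within ", max_iter,
         " iterations (sup-norm residual ", signif(residual, 3), ")")
  }
  if (newton) {
    ## polish: near the critical manifold the fixed point is (almost) a
    ## double root and a residual criterion alone can leave an O(sqrt(tol))
    ## gap; continue Newton until the step itself is negligible
    for (extra in seq_len(200L)) {
      fz <- sweep_f(z)
      jac <- jacobian_quadratic(z, rho, ei, ej, ek, p, nt)
      step <- tryCatch(solve(diag(nt) - jac, fz - z), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      znew <- pmin(pmax(z + step, 0), 1)
      moved <- max(abs(znew - z))
      z <- znew
      iter <- iter + 1L
      if (moved < 1e-13) break
    }
    residual <- max(abs(sweep_f(z) - z))
  }
  list(Q = z, iterations = iter, residual = residual, monotone = monotone)
}

jacobian_quadratic <- function(z, rho, ei, ej, ek, p, nt) {
  vals <- c(rho[ei] * p * z[ek], rho[ei] * p * z[ej])
  cols <- c(ej, ek)
  rows <- c(ei, ei)
  idx <- rows + (cols - 1L) * nt
  s <- rowsum(vals, group = idx)
  jac <- numeric(nt * nt)
  jac[as.integer(rownames(s))] <- s[, 1L]
  matrix(jac, nt, nt)
}

## flatten a pair kernel into index/probability arrays (1-based type index)
kernel_entries <- function(kernel) {
  tab <- kernel_table(kernel)
  list(ei = tab$i + 1L, ej = tab$j + 1L, ek = tab$k + 1L, p = tab$prob)
}

#' Extinction probabilities of mutant-carrying cell lineages
#'
#' Solves the generating-function fixed point for the multitype branching
#' process in which a type-`i` cell (carrying `i` mutant plasmids) dies
#' before dividing with probability `1 - rho_i` and otherwise produces a
#' daughter pair from the division kernel of the chosen replication mode.
#' The least fixed point, approached by iteration from the zero vector,
#' gives the extinction probabilities `Q_0..Q_n`. Components within `1e-9`
#' of 1 are snapped to 1 so that the exact zero-establishment statements of
#' the critical-threshold theorems are reproduced stably.
#'
#' @param model A [fitness_model()].
#' @param mode `"regular"` or `"random"` replication.
#' @param tol Sup-norm fixed-point residual required for convergence.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @param method `"hybrid"` (monotone sweeps plus Newton polishing, the
#'   default) or `"iterate"` (plain monotone sweeps only).
#' @return An object of class `extinction_solution`: list with `model`,
#'   `mode`, `Q` (length `n + 1`), `P_est` (establishment probability for
#'   this mode), `iterations`, `residual`, `monotone`.
#' @examples
#' m <- fitness_model(2, "dominant", s_min = -0.1, s_max = 4)
#' extinction_probabilities(m, "regular")$Q  # c(1, 0.8, 1)
#' @export
extinction_probabilities <- function(model, mode = c("regular", "random"),
                                     tol = 1e-12, max_iter = 1e5L,
                                     method = c("hybrid", "iterate")) {
  stopifnot(inherits(model, "fitness_model"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  n <- model$n
  rho <- reproduction_probability(model)
  ker <- pair_kernel(n, mode)
  ## Standard extinction criterion: with no final classes, the process dies
  ## out with probability one iff the leading eigenvalue of the expected-
  ## progeny matrix M = 2 R P is <= 1, in which case Q = 1 exactly. This
  ## classifies the critical boundary itself (where the fixed point is a
  ## double root and iteration alone cannot resolve Q = 1 to full accuracy).
  if (method == "hybrid") {
    M <- 2 * rho * ker$marginal
    lead <- max(Re(eigen(M, only.values = TRUE)$values))
    if (lead <= 1 + 1e-12) {
      return(structure(
        list(model = model, mode = mode, Q = rep(1, n + 1L), P_est = 0,
             iterations = 0L, residual = 0, monotone = TRUE),
        class = "extinction_solution"
      ))
    }
  }
  ent <- kernel_entries(ker)
  sol <- least_fixed_point(1 - rho, rho, ent$ei, ent$ej, ent$ek, ent$p,
                           tol = tol, max_iter = max_iter,
                           newton = (method == "hybrid"))
  Q <- sol$Q
  Q[Q > 1 - 1e-9] <- 1
  pest <- switch(mode,
    regular = if (n >= 2) 1 - Q[2L] else 0,
    random  = if (n >= 2) {
      hs <- single_mutation_pair_pmf(n)
      1 - sum(hs$prob * Q[hs$j + 1L] * Q[hs$k + 1L])
    } else 0
  )
  if (pest < 1e-9) pest <- 0
  structure(
    list(model = model, mode = mode, Q = Q, P_est = pest,
         iterations = sol$iterations, residual = sol$residual,
         monotone = sol$monotone),
    class = "extinction_solution"
  )
}

#' @export
print.extinction_solution <- function(x, ...) {
  cat("Extinction probabilities (", x$mode, " replication, n = ",
      x$model$n, ")\n", sep = "")
  cat("  Q_i, i = 0..n:", paste(signif(x$Q, 6), collapse = " "), "\n")
  cat("  P_est =", signif(x$P_est, 6),
      " (", x$iterations, " iterations, residual ",
      signif(x$residual, 3), ")\n", sep = "")
  invisible(x)
}

#' Establishment probability of a new mutant plasmid allele
#'
#' Probability that the lineage founded by the cell in which a plasmid
#' mutation first appears survives indefinitely. Under regular replication
#' the mutation appears on a single plasmid in a single cell, so
#' `P_est = 1 - Q_1`. Under random replication the new mutant plasmid can
#' be re-replicated in the same cell cycle, so the lineage gets a head
#' start: `P_est = 1 - sum w(j,k) Q_j Q_k` with `w` the head-start
#' distribution of [single_mutation_pair_pmf()]. For `n = 1` there is no
#' heterozygote class and establishment is impossible.
#'
#' @inheritParams extinction_probabilities
#' @param ... Passed to [extinction_probabilities()].
#' @return A single probability.
#' @examples
#' m <- fitness_model(2, "dominant", s_min = -0.1, s_max = 4)
#' establishment_probability(m, "regular")  # 1/5
#' @export
establishment_probability <- function(model, mode = c("regular", "random"),
                                      ...) {
  mode <- match.arg(mode)
  extinction_probabilities(model, mode, ...)$P_est
}

#' @rdname establishment_probability
#' @export
establishment_regular <- function(model, ...) {
  establishment_probability(model, "regular", ...)
}

#' @rdname establishment_probability
#' @export
establishment_random <- function(model, ...) {
  establishment_probability(model, "random", ...)
}

#' Monte-Carlo estimate of the establishment probability
#'
#' Simulates `reps` independent mutant lineages, each begun from the cell
#' (or cells) produced by the division in which the mutation arises: a
#' single type-1 cell under regular replication, or a draw from the
#' head-start distribution under random replication. A lineage counts as
#' established when the number of living mutant-carrying cells reaches
#' `survival_threshold` before extinction. Used as an independent oracle
#' for the fixed-point establishment probabilities.
#'
#' @inheritParams extinction_probabilities
#' @param reps Number of replicate lineages (>= 1).
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param survival_threshold Living mutant-carrying cells at which a
#'   lineage is declared established.
#' @param event_cap Maximum cell lifetimes simulated per lineage;
#'   replicates hitting the cap are flagged, not silently counted.
#' @return List with `estimate`, `se` (binomial standard error), `reps`,
#'   `established`, `capped` (number of flagged replicates).
#' @export
monte_carlo_establishment <- function(model, mode = c("regular", "random"),
                                      reps, seed = NULL,
                                      survival_threshold = 500L,
                                      event_cap = 1e7) {
  stopifnot(inherits(model, "fitness_model"))
  mode <- match.arg(mode)
  if (length(reps) != 1L || !is.numeric(reps) || reps < 1) {
    stop("reps must be a positive integer")
  }
  reps <- as.integer(reps)
  if (!is.null(seed)) set.seed(seed)
  n <- model$n
  rho <- reproduction_probability(model)
  ker <- pair_kernel(n, mode)
  flat <- flatten_kernel(ker)
  ## initial cells per replicate: columns are the two daughter types
  ## produced by the mutation division (-1 = no mutant-carrying cell)
  if (mode == "regular") {
    starts <- matrix(c(rep(1L, reps), rep(-1L, reps)), ncol = 2L)
  } else {
    hs <- single_mutation_pair_pmf(n)
    pick <- sample.int(nrow(hs), reps, replace = TRUE, prob = hs$prob)
    starts <- cbind(ifelse(hs$j[pick] >= 1L, hs$j[pick], -1L),
                    ifelse(hs$k[pick] >= 1L, hs$k[pick], -1L))
    storage.mode(starts) <- "integer"
  }
  out <- cpp_mc_lineages(n, rho, flat$offsets, flat$j, flat$k, flat$cum,
                         starts, as.integer(survival_threshold),
                         as.numeric(event_cap))
  est <- mean(out == 1L)
  list(estimate = est, se = sqrt(est * (1 - est) / reps), reps = reps,
       established = sum(out == 1L), capped = sum(out == 2L))
}

## CSR-style flattening of a pair kernel for the C++ samplers:
## per parent type, cumulative pair probabilities with daughter types.
flatten_kernel <- function(kernel) {
  n <- kernel$n
  offs <- integer(n + 2L)
  jj <- integer(0); kk <- integer(0); cc <- numeric(0)
  for (i in 0:n) {
    d <- kernel$pair_probs[[i + 1L]]
    offs[i + 2L] <- offs[i + 1L] + nrow(d)
    jj <- c(jj, d$j); kk <- c(kk, d$k)
    cum <- cumsum(d$prob)
    cc <- c(cc, cum / cum[length(cum)])
  }
  list(offsets = offs, j = jj, k = kk, cum = cc)
}
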