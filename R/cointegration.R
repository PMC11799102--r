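## Plasmid cointegration (multimer formation) extension.
##
## Cell types track how the n allele-bearing backbone units are packaged
## into molecules: a type like (AA)(B)(AB) holds a dimer of two A units, an
## A+B heterodimer and a B monomer. An m-mer counts m times against the
## copy-number control total, so unit counts always sum to n. Fusion of two
## molecules concatenates their allele content (no resolution); division
## duplicates every molecule and splits the copies into two daughters with
## equal copy-number-control totals. Fitness is dominant-type and depends
## only on the alleles present, not their packaging.

## molecules are (a, b) unit-count pairs; a cell type is a 2 x L matrix of
## molecule columns, canonicalized by decreasing size then decreasing a.
type_canonical <- function(mat) {
  ord <- order(-colSums(mat), -mat[1L, ])
  mat[, ord, drop = FALSE]
}

type_key <- function(mat) {
  mat <- type_canonical(mat)
  paste(paste(mat[1L, ], mat[2L, ], sep = ","), collapse = "|")
}

key_to_mat <- function(key) {
  parts <- strsplit(strsplit(key, "|", fixed = TRUE)[[1L]], ",", fixed = TRUE)
  matrix(as.integer(unlist(parts)), nrow = 2L)
}

#' Format a cointegrate cell type
#'
#' Renders a cell type in the `(AA)(AB)(B)` notation: each parenthesized
#' group is one molecule, letters are the allele-bearing units it carries.
#'
#' @param mat A 2 x L matrix (rows: A units, B units; columns: molecules),
#'   or a canonical key string.
#' @return A single character string.
#' @export
format_cell_type <- function(mat) {
  if (is.character(mat)) mat <- key_to_mat(mat)
  mat <- type_canonical(mat)
  paste(vapply(seq_len(ncol(mat)), function(c) {
    paste0("(", strrep("A", mat[1L, c]), strrep("B", mat[2L, c]), ")")
  }, character(1)), collapse = "")
}

#' Parse a cointegrate cell type
#'
#' Inverse of [format_cell_type()]: reads `(AA)(B)(AB)`-style notation
#' into the canonical matrix representation.
#'
#' @param s A character string of parenthesized `A`/`B` groups.
#' @return A 2 x L matrix in canonical order.
#' @export
parse_cell_type <- function(s) {
  groups <- regmatches(s, gregexpr("\\(([AB]*)\\)", s))[[1L]]
  if (length(groups) == 0L) stop("cannot parse cell type: ", s)
  inner <- gsub("[()]", "", groups)
  if (any(nchar(inner) == 0L)) stop("empty molecule in cell type: ", s)
  mat <- vapply(inner, function(g) {
    ch <- strsplit(g, "")[[1L]]
    c(sum(ch == "A"), sum(ch == "B"))
  }, numeric(2))
  type_canonical(matrix(as.integer(mat), nrow = 2L))
}

#' Enumerate all cointegrate cell types for a copy number
#'
#' All multisets of nonempty allele-multiset molecules whose unit counts
#' sum to `n`, each in canonical form, duplicate-free.
#'
#' @param n Copy number, 1 <= n <= `cap`.
#' @param cap Resource cap on `n` (the state space grows combinatorially);
#'   raise explicitly for larger systems.
#' @return Character vector of canonical type labels (see
#'   [format_cell_type()]).
#' @examples
#' enumerate_cell_types(2)  # 6 types
#' @export
enumerate_cell_types <- function(n, cap = 8L) {
  check_copy_number(n)
  if (n > cap) {
    stop("n = ", n, " exceeds the state-space cap (", cap,
         "); pass a larger `cap` explicitly to override")
  }
  ## molecule kinds ordered: size ascending, A-count descending
  kinds <- do.call(cbind, lapply(seq_len(n), function(m) {
    rbind(m:0, 0:m)
  }))
  sizes <- colSums(kinds)
  recurse <- function(remaining, min_kind) {
    if (remaining == 0L) return(list(integer(0)))
    out <- list()
    for (k in seq(min_kind, ncol(kinds))) {
      if (sizes[k] <= remaining) {
        for (tail in recurse(remaining - sizes[k], k)) {
          out[[length(out) + 1L]] <- c(k, tail)
        }
      }
    }
    out
  }
  combos <- recurse(as.integer(n), 1L)
  vapply(combos, function(idx) {
    format_cell_type(kinds[, idx, drop = FALSE])
  }, character(1))
}

#' Fusion (cointegration) transition probabilities
#'
#' Conditional on a fusion occurring in a cell of the given type, two
#' molecules are chosen uniformly among all unordered pairs and
#' concatenated. Only fusion is modelled; cointegrates are never resolved.
#'
#' @param type A cell type (label string or 2 x L matrix).
#' @return A data frame with columns `type` (resulting label) and `prob`;
#'   empty (zero rows) for single-molecule types, where no further
#'   cointegration can occur.
#' @examples
#' fusion_transition_probs("(A)(A)(B)")  # (A)(AB): 2/3, (AA)(B): 1/3
#' @export
fusion_transition_probs <- function(type) {
  mat <- if (is.character(type)) parse_cell_type(type) else type_canonical(type)
  L <- ncol(mat)
  if (L < 2L) {
    return(data.frame(type = character(0), prob = numeric(0)))
  }
  acc <- new.env(parent = emptyenv())
  npairs <- L * (L - 1) / 2
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      fused <- mat[, i] + mat[, j]
      newmat <- cbind(mat[, -c(i, j), drop = FALSE], fused)
      lab <- format_cell_type(newmat)
      acc[[lab]] <- (if (is.null(acc[[lab]])) 0 else acc[[lab]]) + 1 / npairs
    }
  }
  labs <- ls(acc)
  data.frame(type = labs,
             prob = vapply(labs, function(l) acc[[l]], numeric(1)),
             row.names = NULL)
}

#' Division-outcome distribution for a cointegrate cell type
#'
#' Every molecule is duplicated and the 2L labelled copies are split
#' uniformly at random over all assortments in which each daughter's
#' copy-number-control total equals `n`; assortments violating the total
#' are impossible. The two daughters are unordered.
#'
#' @param type A cell type (label string or 2 x L matrix).
#' @return A data frame with columns `daughter1`, `daughter2` (labels,
#'   lexicographically ordered within a pair) and `prob`, summing to 1.
#' @examples
#' division_probs("(AAA)(B)")  # identical daughters with probability 1
#' @export
division_probs <- function(type) {
  mat <- if (is.character(type)) parse_cell_type(type) else type_canonical(type)
  n <- sum(mat)
  ## distinct molecule kinds with multiplicities
  keys <- paste(mat[1L, ], mat[2L, ], sep = ",")
  tab <- table(keys)
  kmat <- vapply(names(tab), function(k) {
    as.integer(strsplit(k, ",", fixed = TRUE)[[1L]])
  }, integer(2))
  kmat <- matrix(kmat, nrow = 2L)
  mult <- as.integer(tab)
  sizes <- colSums(kmat)
  K <- length(mult)
  acc <- new.env(parent = emptyenv())
  total <- 0
  dfs <- function(k, units, x, weight) {
    if (k > K) {
      if (units != n) return(invisible(NULL))
      d1 <- kmat[, rep(seq_len(K), x), drop = FALSE]
      d2 <- kmat[, rep(seq_len(K), 2L * mult - x), drop = FALSE]
      l1 <- format_cell_type(d1)
      l2 <- format_cell_type(d2)
      pairlab <- paste(sort(c(l1, l2)), collapse = "\r")
      acc[[pairlab]] <- (if (is.null(acc[[pairlab]])) 0
                         else acc[[pairlab]]) + weight
      total <<- total + weight
      return(invisible(NULL))
    }
    for (xk in 0:(2L * mult[k])) {
      u <- units + xk * sizes[k]
      if (u > n) break
      dfs(k + 1L, u, c(x, xk), weight * choose(2L * mult[k], xk))
    }
    invisible(NULL)
  }
  dfs(1L, 0L, integer(0), 1)
  labs <- ls(acc)
  parts <- strsplit(labs, "\r", fixed = TRUE)
  data.frame(
    daughter1 = vapply(parts, `[`, character(1), 1L),
    daughter2 = vapply(parts, `[`, character(1), 2L),
    prob = vapply(labs, function(l) acc[[l]], numeric(1)) / total,
    row.names = NULL
  )
}

#' Configuration of the cointegration model
#'
#' Regular replication, dominant fitness: a cell's net growth rate is
#' `s_max` when both alleles are present (in any packaging) and `s_min`
#' otherwise. `kappa` is the per-cell-cycle probability of one fusion
#' event (0 for single-molecule types); `Inf` denotes the limiting model
#' in which the mutation is immediately followed by fusion of all plasmids
#' into a single multimer.
#'
#' @param n Copy number >= 1.
#' @param s_min Homozygote net growth rate (< 0).
#' @param s_max Heterozygote net growth rate (> 0).
#' @param kappa Cointegration probability in `[0, 1]`, or `Inf`.
#' @return An object of class `cointegration_config`.
#' @export
cointegration_config <- function(n, s_min, s_max, kappa) {
  check_copy_number(n)
  stopifnot(s_min < 0, s_min > -1, s_max > 0)
  if (!(is.infinite(kappa) && kappa > 0) && (kappa < 0 || kappa > 1)) {
    stop("kappa must be in [0, 1] or Inf")
  }
  structure(list(n = as.integer(n), s_min = s_min, s_max = s_max,
                 kappa = kappa),
            class = "cointegration_config")
}

## dominant fitness from allele presence
cointegrate_rho <- function(mat, s_min, s_max) {
  s <- if (sum(mat[1L, ]) > 0L && sum(mat[2L, ]) > 0L) s_max else s_min
  (1 + s) / (2 + s)
}

#' Extinction probabilities for the cointegration model
#'
#' Least fixed point of the extinction recursion over the full cointegrate
#' type space: with probability `kappa_a` a fusion occurs (then division),
#' otherwise the cell divides directly; at most one fusion per cell cycle.
#'
#' @param config A [cointegration_config()] with finite `kappa`.
#' @param tol,max_iter Solver controls as in [extinction_probabilities()].
#' @param cap State-space cap passed to [enumerate_cell_types()].
#' @return A list with `types` (labels), `Q` (named extinction
#'   probabilities, snapped to 1 within 1e-9), `iterations`, `residual`.
#' @export
cointegrate_extinction <- function(config, tol = 1e-12, max_iter = 1e5L,
                                   cap = 8L) {
  stopifnot(inherits(config, "cointegration_config"))
  if (is.infinite(config$kappa)) {
    stop("kappa = Inf has no type-space recursion; use ",
         "kappa_infinity_establishment()")
  }
  types <- enumerate_cell_types(config$n, cap = cap)
  idx <- stats::setNames(seq_along(types), types)
  mats <- lapply(types, parse_cell_type)
  rho <- vapply(mats, cointegrate_rho, numeric(1),
                s_min = config$s_min, s_max = config$s_max)
  ## per-type effective division kernel:
  ## (1 - kappa_a) K_a + kappa_a sum_a' F(a, a') K_a'
  div <- lapply(types, division_probs)
  ei <- integer(0); ej <- integer(0); ek <- integer(0); p <- numeric(0)
  add <- function(a, kern, w) {
    if (w == 0 || nrow(kern) == 0L) return(invisible(NULL))
    ei <<- c(ei, rep(a, nrow(kern)))
    ej <<- c(ej, idx[kern$daughter1])
    ek <<- c(ek, idx[kern$daughter2])
    p <<- c(p, w * kern$prob)
    invisible(NULL)
  }
  for (a in seq_along(types)) {
    kap <- if (ncol(mats[[a]]) >= 2L) config$kappa else 0
    add(a, div[[a]], 1 - kap)
    if (kap > 0) {
      fus <- fusion_transition_probs(mats[[a]])
      for (r in seq_len(nrow(fus))) {
        add(a, div[[idx[fus$type[r]]]], kap * fus$prob[r])
      }
    }
  }
  names(ej) <- names(ek) <- NULL
  sol <- least_fixed_point(1 - rho, rho, ei, ej, ek, p,
                           tol = tol, max_iter = max_iter)
  Q <- sol$Q
  Q[Q > 1 - 1e-9] <- 1
  names(Q) <- types
  list(types = types, Q = Q, iterations = sol$iterations,
       residual = sol$residual)
}

#' Establishment probability under cointegration
#'
#' The mutation first appears in a cell with only monomers, so
#' `P_est = 1 - Q` of the all-monomer type with a single B allele,
#' `(A)^(n-1)(B)`. With `kappa = 0` this reduces exactly to the base
#' regular-replication model; with `kappa > 0` establishment is possible
#' for any positive `s_max` (no threshold effect); `kappa = Inf` gives the
#' theoretical maximum [kappa_infinity_establishment()].
#'
#' @inheritParams cointegrate_extinction
#' @param ... Passed to [cointegrate_extinction()].
#' @return A single probability.
#' @examples
#' cfg <- cointegration_config(2, s_min = -0.1, s_max = 4, kappa = 0)
#' cointegrate_establishment(cfg)  # = 1/5, the base-model value
#' @export
cointegrate_establishment <- function(config, ...) {
  stopifnot(inherits(config, "cointegration_config"))
  if (config$n < 2L) return(0)
  if (is.infinite(config$kappa)) return(kappa_infinity_establishment(config))
  sol <- cointegrate_extinction(config, ...)
  start <- format_cell_type(cbind(matrix(rep(c(1L, 0L), config$n - 1L),
                                         nrow = 2L),
                                  c(0L, 1L)))
  pest <- 1 - sol$Q[[start]]
  if (pest < 1e-9) pest <- 0
  pest
}

#' Establishment probability in the immediate-fusion limit
#'
#' With `kappa = Inf` the mutation is immediately followed by fusion of
#' all plasmids into one heterozygous multimer, whose daughters are always
#' identical to it: a single-type binary branching process with
#' reproduction probability `rho_het = (1 + s_max)/(2 + s_max)` and
#' extinction probability `(1 - rho_het)/rho_het`, giving
#' `P_est = s_max/(1 + s_max)` --- the theoretical maximum over all
#' `kappa`.
#'
#' @param config A [cointegration_config()] (only `s_max` is used).
#' @return A single probability.
#' @export
kappa_infinity_establishment <- function(config) {
  stopifnot(inherits(config, "cointegration_config"))
  if (config$n < 2L) return(0)
  rho <- (1 + config$s_max) / (2 + config$s_max)
  max(0, (2 * rho - 1) / rho)
}
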