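test_that("progeny matrix is 2 R P with the right rows", {
  m <- fitness_model(2, "dominant", s_min = -0.1, s_max = 4)
  M <- progeny_matrix(m, "regular")
  rho <- reproduction_probability(m)
  expect_equal(unname(rowSums(M)), unname(2 * rho), tolerance = 1e-12)
  expect_equal(unname(M[2L, ]), (5 / 6) * 2 * c(1 / 6, 2 / 3, 1 / 6),
               tolerance = 1e-12)
  for (mode in c("regular", "random")) {
    M4 <- progeny_matrix(dominant4(1), "regular")
    rho4 <- reproduction_probability(dominant4(1))
    expect_equal(M4[1L, ], c(2 * rho4[1L], 0, 0, 0, 0),
                 ignore_attr = TRUE)
    expect_equal(M4[5L, ], c(0, 0, 0, 0, 2 * rho4[5L]),
                 ignore_attr = TRUE)
    # M = 2 R P elementwise (regular factorization)
    P <- segregation_marginal_matrix(4, "regular")
    expect_equal(M4, 2 * rho4 * P, tolerance = 1e-12)
  }
})

test_that("chi eigenvalues match the dense eigensolver", {
  for (n in 2:10) {
    chi <- chi_eigenvalues(n)
    expect_equal(chi[1L], 1)
    expect_equal(chi[2L], 1)
    expect_true(all(diff(chi) <= 1e-14))
    P <- segregation_marginal_matrix(n, "regular")
    num <- sort(Re(eigen(P, only.values = TRUE)$values), decreasing = TRUE)
    expect_equal(num, sort(chi, decreasing = TRUE), tolerance = 1e-10)
  }
  expect_equal(chi_eigenvalues(4)[3L], 6 / 7)
})

test_that("critical fitness thresholds follow both theorems", {
  expect_equal(critical_s_max(2, "regular"), 2)
  expect_equal(critical_s_max(3, "random"), 1.5)
  expect_equal(critical_s_max(1, "regular"), Inf)
  n <- 2:10
  expect_true(all(critical_s_max(n, "random") > critical_s_max(n, "regular")))
  # threshold equivalence: leading eigenvalue crosses 1 exactly there
  for (nn in 2:10) {
    for (mode in c("regular", "random")) {
      f <- function(s) {
        leading_eigenvalue(fitness_model(nn, "dominant",
                                         s_min = -0.1, s_max = s), mode) - 1
      }
      root <- stats::uniroot(f, c(0.01, 12), tol = 1e-9)$root
      expect_equal(root, critical_s_max(nn, mode), tolerance = 1e-6)
    }
  }
})

test_that("critical copy numbers invert the thresholds", {
  expect_equal(critical_n(1, "regular"), 3L)
  expect_equal(critical_n(1, "random"), 4L)
  # consistency with the branching solver at s_max = 1
  for (mode in c("regular", "random")) {
    nc <- critical_n(1, mode)
    above <- fitness_model(nc, "dominant", s_min = -0.1, s_max = 1)
    below <- fitness_model(nc - 1L, "dominant", s_min = -0.1, s_max = 1)
    expect_gt(establishment_probability(above, mode), 0)
    expect_equal(establishment_probability(below, mode), 0)
  }
})

test_that("stationary type distribution is the leading left eigenvector", {
  m <- dominant4(1)
  # random + dominant: all heterozygote types equally abundant
  d <- stationary_type_distribution(m, "random")
  expect_equal(sum(d), 1)
  expect_equal(d[["1"]], d[["2"]])
  expect_equal(d[["2"]], d[["3"]])
  # relabelling symmetry for symmetric fitness functions
  for (kind in c("dominant", "peaked")) {
    for (mode in c("regular", "random")) {
      mm <- fitness_model(6, kind, s_min = -0.1, s_max = 2)
      dd <- stationary_type_distribution(mm, mode)
      expect_equal(unname(dd), rev(unname(dd)), tolerance = 1e-10)
      expect_true(all(dd >= 0))
    }
  }
  # subcritical: no stationary distribution (random + peaked at n = 4)
  mp <- fitness_model(4, "peaked", s_min = -0.1, s_max = 1)
  expect_error(stationary_type_distribution(mp, "random"), "subcritical")
})

test_that("random-mode interior block has constant column sums", {
  # the all-ones LEFT eigenvector of the heterozygote block: column sums
  # of B = M_interior / (2 rho_het) all equal (n-1)(2n+1)/((n+1)(2n-1))
  for (n in 2:10) {
    m <- fitness_model(n, "dominant", s_min = -0.1, s_max = 1)
    M <- progeny_matrix(m, "random")
    rho_het <- reproduction_probability(m, 1)
    B <- M[2:n, 2:n, drop = FALSE] / (2 * rho_het)
    expect_equal(unname(colSums(B)),
                 rep((n - 1) * (2 * n + 1) / ((n + 1) * (2 * n - 1)),
                     n - 1),
                 tolerance = 1e-12)
  }
})

test_that("leading eigenvalue of regular dominant M has closed form", {
  for (n in 2:8) {
    for (smax in c(0.5, 1, 3)) {
      m <- fitness_model(n, "dominant", s_min = -0.1, s_max = smax)
      rho <- reproduction_probability(m)
      lead <- leading_eigenvalue(m, "regular")
      expect_equal(lead,
                   max(2 * rho[1L],
                       2 * rho[2L] * 2 * (n - 1) / (2 * n - 1)),
                   tolerance = 1e-10)
    }
  }
})

test_that("rescued growth rate matches the mean-matrix eigenvalue", {
  expect_equal(rescued_growth_rate(2, 1, "regular"), -1 / 3)
  for (n in c(2, 4, 7)) {
    for (smax in c(0.5, 1, 3)) {
      for (mode in c("regular", "random")) {
        m <- fitness_model(n, "dominant", s_min = -0.1, s_max = smax)
        P <- segregation_marginal_matrix(n, mode)
        A <- diag(m$lambda) %*% (2 * P - diag(n + 1)) - diag(n + 1)
        num <- max(Re(eigen(A, only.values = TRUE)$values))
        got <- rescued_growth_rate(n, smax, mode)
        # closed form holds when the heterozygote branch dominates
        expect_equal(max(got, m$s_min), num, tolerance = 1e-10)
        # positive growth exactly above the critical fitness
        expect_equal(got > 0, smax > critical_s_max(n, mode))
      }
    }
  }
})

test_that("balanced-heterozygote comparison threshold is weaker for n > 3", {
  expect_equal(half_and_half_threshold(4), 1 / 3)
  expect_error(half_and_half_threshold(2), "n >= 3")
  for (n in 4:10) {
    expect_lt(half_and_half_threshold(n), critical_s_max(n, "regular"))
  }
  # n = 3 is the printed boundary case: 1 vs 2/3, inequality reversed
  expect_gt(half_and_half_threshold(3), critical_s_max(3, "regular"))
})

test_that("solver establishment vanishes exactly when M is subcritical", {
  for (n in c(2, 3, 5)) {
    for (mode in c("regular", "random")) {
      for (smax in c(0.3, 0.9, 1.8, 4)) {
        m <- fitness_model(n, "dominant", s_min = -0.1, s_max = smax)
        pest <- establishment_probability(m, mode)
        lead <- leading_eigenvalue(m, mode)
        expect_equal(pest > 0, lead > 1 + 1e-12)
      }
    }
  }
})
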