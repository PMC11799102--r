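# independent count of cointegrate cell types: coefficient of x^n in
# prod_m (1 - x^m)^-(m+1), since there are m + 1 allele compositions of an
# m-mer and types are multisets of molecules
count_types_gf <- function(n) {
  coefs <- c(1, rep(0, n))                       # polynomial in x, mod x^(n+1)
  for (m in seq_len(n)) {
    for (rep in seq_len(m + 1)) {                # (1 - x^m)^-1, m+1 times
      for (k in (m + 1):(n + 1)) {
        if (k - m >= 1) coefs[k] <- coefs[k] + coefs[k - m]
      }
    }
  }
  coefs[n + 1]
}

test_that("cell-type enumeration is complete and canonical", {
  expect_setequal(enumerate_cell_types(1), c("(A)", "(B)"))
  expect_setequal(enumerate_cell_types(2),
                  c("(A)(A)", "(A)(B)", "(B)(B)", "(AA)", "(AB)", "(BB)"))
  for (n in 1:6) {
    types <- enumerate_cell_types(n)
    expect_equal(length(types), count_types_gf(n))
    expect_equal(anyDuplicated(types), 0L)
    # unit counts all sum to n
    for (ty in types) {
      expect_equal(sum(parse_cell_type(ty)), n)
    }
  }
  expect_error(enumerate_cell_types(9), "cap")
})

test_that("cell-type notation round-trips", {
  expect_equal(format_cell_type(parse_cell_type("(B)(AA)(AB)")),
               "(AA)(AB)(B)")
  expect_equal(format_cell_type(parse_cell_type("(AB)(BA)")),
               format_cell_type(parse_cell_type("(AB)(AB)")))
  expect_error(parse_cell_type("()"), "empty")
  expect_error(parse_cell_type("AAB"), "parse")
})

test_that("fusion picks uniform molecule pairs, never resolves", {
  f <- fusion_transition_probs("(A)(A)(B)")
  expect_equal(f$prob[f$type == "(AB)(A)"], 2 / 3)
  expect_equal(f$prob[f$type == "(AA)(B)"], 1 / 3)
  # resolution is impossible: (AA)(A)(B) never yields (A)(A)(AB)
  f2 <- fusion_transition_probs("(AA)(A)(B)")
  expect_false("(AB)(A)(A)" %in% f2$type)
  expect_equal(sum(f2$prob), 1)
  # single-molecule types cannot cointegrate further
  expect_equal(nrow(fusion_transition_probs("(AABB)")), 0L)
  for (ty in enumerate_cell_types(4)) {
    f <- fusion_transition_probs(ty)
    if (ncol(parse_cell_type(ty)) >= 2L) {
      expect_equal(sum(f$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("division respects the copy-number control total", {
  d <- division_probs("(AAA)(B)")
  expect_equal(d, data.frame(daughter1 = "(AAA)(B)",
                             daughter2 = "(AAA)(B)", prob = 1))
  d2 <- division_probs("(AAB)")
  expect_equal(d2$prob, 1)
  expect_equal(d2$daughter1, "(AAB)")
  # every enumerated type has a proper daughter distribution
  for (n in 1:5) {
    for (ty in enumerate_cell_types(n)) {
      dd <- division_probs(ty)
      expect_equal(sum(dd$prob), 1, tolerance = 1e-12)
      parent <- parse_cell_type(ty)
      for (r in seq_len(nrow(dd))) {
        al <- rowSums(parse_cell_type(dd$daughter1[r])) +
          rowSums(parse_cell_type(dd$daughter2[r]))
        # daughters jointly carry two copies of the parent's alleles
        expect_equal(al, 2 * rowSums(parent))
      }
    }
  }
})

test_that("all-monomer cells reproduce the regular segregation kernel", {
  for (n in 2:4) {
    for (i in 0:n) {
      # i mutant (B) monomers among n
      ty <- paste0(strrep("(A)", n - i), strrep("(B)", i))
      dd <- division_probs(ty)
      ref <- regular_pair_probs(n, i)
      bcount <- function(lab) sum(parse_cell_type(lab)[2L, ])
      for (r in seq_len(nrow(dd))) {
        j <- bcount(dd$daughter1[r])
        k <- bcount(dd$daughter2[r])
        expect_equal(dd$prob[r], pair_prob(ref, j, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("kappa = 0 reduces exactly to the base regular model", {
  for (n in 2:4) {
    for (smax in c(1, 4)) {
      cfg <- cointegration_config(n, s_min = -0.1, s_max = smax, kappa = 0)
      base <- establishment_regular(fitness_model(n, "dominant",
                                                  s_min = -0.1,
                                                  s_max = smax))
      expect_equal(cointegrate_establishment(cfg), base, tolerance = 1e-10)
    }
  }
})

test_that("homozygote cointegrate types always die out", {
  cfg <- cointegration_config(3, s_min = -0.1, s_max = 1, kappa = 0.1)
  sol <- cointegrate_extinction(cfg)
  for (ty in sol$types) {
    mat <- parse_cell_type(ty)
    if (sum(mat[1L, ]) == 0L || sum(mat[2L, ]) == 0L) {
      expect_equal(sol$Q[[ty]], 1)
    }
  }
})

test_that("cointegration removes the establishment threshold", {
  # s_max = 1 is below the n = 2 regular threshold (2): no establishment
  # without fusion, positive establishment with it
  expect_equal(cointegrate_establishment(
    cointegration_config(2, -0.1, 1, kappa = 0)), 0)
  p1 <- cointegrate_establishment(cointegration_config(2, -0.1, 1, kappa = 1))
  expect_gt(p1, 0)
  # monotone nondecreasing in kappa, bounded by the immediate-fusion limit
  kappas <- c(0, 1e-3, 1e-2, 1e-1, 1)
  for (smax in c(0.3, 1)) {
    ps <- vapply(kappas, function(k) {
      cointegrate_establishment(cointegration_config(4, -0.1, smax, k))
    }, numeric(1))
    expect_true(all(diff(ps) >= -1e-12))
    pinf <- kappa_infinity_establishment(
      cointegration_config(4, -0.1, smax, Inf))
    expect_true(all(ps <= pinf + 1e-12))
  }
})

test_that("immediate-fusion limit is single-type binary branching", {
  expect_equal(kappa_infinity_establishment(
    cointegration_config(4, -0.1, 1, Inf)), 1 / 2)
  expect_equal(cointegrate_establishment(
    cointegration_config(3, -0.1, 2, Inf)), 2 / 3)
  # vanishes at criticality
  expect_lt(kappa_infinity_establishment(
    cointegration_config(4, -0.1, 1e-9, Inf)), 1e-8)
})
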