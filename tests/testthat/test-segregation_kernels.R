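test_that("regular kernel matches hand values and enumeration", {
  d <- regular_pair_probs(2, 1)
  expect_equal(pair_prob(d, 1, 1), 2 / 3)
  expect_equal(pair_prob(d, 0, 2), 1 / 3)
  d0 <- regular_pair_probs(5, 0)
  expect_equal(d0, data.frame(j = 0L, k = 0L, prob = 1))
  # exhaustive labelled-copy enumeration, all parents, n <= 4
  for (n in 1:4) {
    for (i in 0:n) {
      got <- regular_pair_probs(n, i)
      ref <- enum_regular_pairs(n, i)
      expect_equal(got$j, ref$j)
      expect_equal(got$prob, ref$prob, tolerance = 1e-12)
      expect_equal(sum(got$prob), 1, tolerance = 1e-12)
      expect_true(all(got$j + got$k == 2 * i))    # diagonal support
    }
  }
})

test_that("Polya copy pmf matches the urn DP oracle", {
  expect_equal(unname(polya_copy_pmf(2, 1)), c(0, 1, 1, 1, 0) / 3)
  expect_equal(unname(polya_copy_pmf(3, 0)), c(1, rep(0, 6)))
  expect_equal(unname(polya_copy_pmf(2, 2)), c(0, 0, 0, 0, 1))
  for (n in 1:5) {
    for (i in 0:n) {
      expect_equal(unname(polya_copy_pmf(n, i)), dp_polya(n, i),
                   tolerance = 1e-12)
    }
  }
})

test_that("random kernel composes urn and split correctly", {
  d <- random_pair_probs(2, 1)
  marg_het <- pair_prob(d, 1, 1) + pair_prob(d, 1, 0) / 2 +
    pair_prob(d, 1, 2) / 2
  expect_equal(marg_het, 5 / 9)
  expect_equal(random_pair_probs(3, 0),
               data.frame(j = 0L, k = 0L, prob = 1),
               ignore_attr = TRUE)
  # dual route: direct closed form vs polya_copy_pmf x segregation_split_pmf
  for (n in 1:5) {
    for (i in 0:n) {
      direct <- random_pair_probs(n, i)
      expect_equal(sum(direct$prob), 1, tolerance = 1e-12)
      urn <- dp_polya(n, i)
      for (r in seq_len(nrow(direct))) {
        m <- direct$j[r] + direct$k[r]
        sp <- segregation_split_pmf(n, m)
        expect_equal(direct$prob[r],
                     urn[m + 1L] * pair_prob(sp, direct$j[r], direct$k[r]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("conditional single-mutation law matches its enumeration oracle", {
  expect_equal(unname(conditional_single_mutation_pmf(2)), c(5, 1) / 6)
  for (n in 2:6) {
    pmf <- conditional_single_mutation_pmf(n)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_equal(unname(pmf), enum_single_mutation(n), tolerance = 1e-12)
  }
  # no mass above n plasmids (C(n, m) vanishes)
  expect_length(conditional_single_mutation_pmf(2), 2L)
})

test_that("segregation split is the doubled hypergeometric", {
  sp <- segregation_split_pmf(2, 2)
  expect_equal(pair_prob(sp, 1, 1), 2 / 3)
  expect_equal(pair_prob(sp, 0, 2), 1 / 3)
  expect_equal(segregation_split_pmf(4, 0),
               data.frame(j = 0L, k = 0L, prob = 1))
  expect_equal(segregation_split_pmf(3, 6),
               data.frame(j = 3L, k = 3L, prob = 1))
  for (n in 2:5) for (m in 0:(2 * n)) {
    expect_equal(sum(segregation_split_pmf(n, m)$prob), 1,
                 tolerance = 1e-12)
  }
  expect_error(segregation_split_pmf(2, 5), "0..2n")
})

test_that("head-start distribution is a proper mixture", {
  for (n in 2:6) {
    hs <- single_mutation_pair_pmf(n)
    expect_equal(sum(hs$prob), 1, tolerance = 1e-12)
    expect_true(all(hs$j + hs$k >= 1 & hs$j + hs$k <= n))
  }
})

test_that("kernel invariants hold across modes", {
  for (n in 2:6) {
    for (mode in c("regular", "random")) {
      ker <- pair_kernel(n, mode)
      # homozygote absorption
      expect_equal(ker$pair_probs[[1L]],
                   data.frame(j = 0L, k = 0L, prob = 1),
                   ignore_attr = TRUE)
      expect_equal(ker$pair_probs[[n + 1L]],
                   data.frame(j = n, k = n, prob = 1),
                   ignore_attr = TRUE)
      # rows are probability distributions
      expect_equal(unname(rowSums(ker$marginal)), rep(1, n + 1L),
                   tolerance = 1e-12)
      # neutral segregation conserves the expected mutant count
      expect_equal(unname(ker$marginal %*% (0:n))[, 1L], 0:n,
                   tolerance = 1e-12)
      # allele-relabelling symmetry: parent i vs parent n - i
      for (i in 0:n) {
        a <- ker$pair_probs[[i + 1L]]
        b <- ker$pair_probs[[n - i + 1L]]
        for (r in seq_len(nrow(a))) {
          expect_equal(pair_prob(b, n - a$j[r], n - a$k[r]), a$prob[r],
                       tolerance = 1e-12)
        }
      }
    }
    # both modes are point masses at the homozygote parents
    expect_equal(regular_pair_probs(n, 0), random_pair_probs(n, 0),
                 ignore_attr = TRUE)
    expect_equal(regular_pair_probs(n, n), random_pair_probs(n, n),
                 ignore_attr = TRUE)
  }
})

test_that("kernel_table is tidy and cached kernels are reused", {
  ker <- pair_kernel(3, "regular")
  tab <- kernel_table(ker)
  expect_named(tab, c("n", "mode", "i", "j", "k", "prob"))
  expect_equal(sum(tab$prob), 4)                  # one unit of mass per parent
  expect_identical(pair_kernel(3, "regular"), ker)
})
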