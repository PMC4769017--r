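test_that("pairwise differences respect the deletion mode", {
  aln <- aa_alignment(c(a = "ACD", b = "ACD"))
  pd <- pairwise_differences(aln, "pairwise")
  expect_equal(pd$diffs["a", "b"], 0L)
  expect_equal(pd$sites["a", "b"], 3L)

  aln2 <- aa_alignment(c(a = "ACD", b = "ACE"))
  expect_equal(pairwise_differences(aln2)$diffs["a", "b"], 1L)

  # gap site dropped for the pair only under pairwise deletion
  aln3 <- aa_alignment(c(a = "A-D", b = "ACD"))
  pd3 <- pairwise_differences(aln3, "pairwise")
  expect_equal(pd3$diffs["a", "b"], 0L)
  expect_equal(pd3$sites["a", "b"], 2L)

  # X counts as missing, like a gap
  aln4 <- aa_alignment(c(a = "AXD", b = "ACD"))
  expect_equal(pairwise_differences(aln4)$sites["a", "b"], 2L)

  # complete deletion drops the gapped column for every pair
  aln5 <- aa_alignment(c(a = "A-D", b = "ACD", c = "ACD"))
  pd5 <- pairwise_differences(aln5, "complete")
  expect_true(all(pd5$sites[upper.tri(pd5$sites)] == 2L))
})

test_that("pairs with no comparable sites are flagged", {
  aln <- aa_alignment(c(a = "A--", b = "--C", c = "ACD"))
  pd <- pairwise_differences(aln, "pairwise")
  expect_equal(attr(pd, "no_overlap")[1, ], c("a", "b"))
})

test_that("segregating sites follow the per-column rule", {
  same <- aa_alignment(c(a = "ACDE", b = "ACDE", c = "ACDE"))
  expect_equal(segregating_sites(same, "pairwise")$S, 0L)
  # columns (A,A,A), (A,A,T), (A,C,G) -> S = 2
  aln <- aa_alignment(c(s1 = "AAA", s2 = "AAC", s3 = "ATG"))
  expect_equal(segregating_sites(aln, "pairwise")$S, 2L)
  # column (A,-,A) is not segregating under pairwise deletion
  gap <- aa_alignment(c(s1 = "AC", s2 = "-C", s3 = "AC"))
  got <- segregating_sites(gap, "pairwise")
  expect_equal(got$S, 0L)
  expect_equal(got$n_used, 2L)
  # under complete deletion the gapped column is excluded from n_used
  got2 <- segregating_sites(gap, "complete")
  expect_equal(got2$n_used, 1L)
})

test_that("tajima_d rejects degenerate inputs", {
  two <- aa_alignment(c(a = "ACDE", b = "ACDF"))
  expect_error(tajima_d(two), "at least 4")
  same <- aa_alignment(c(a = "ACDE", b = "ACDE", c = "ACDE", d = "ACDE"))
  expect_error(tajima_d(same), "S = 0")
  expect_error(tajima_d_from_summary(3, 10, 100, 0.1), "at least 4")
  expect_error(tajima_d_from_summary(10, 0, 100, 0.1), "S = 0")
})

test_that("tajima_d agrees with its own summary entry point", {
  set.seed(9)
  for (rep in 1:10) {
    aln <- rand_alignment(sample(4:7, 1), sample(8:20, 1), gap_prob = 0.05)
    res <- tryCatch(tajima_d(aln), error = function(e) NULL)
    if (is.null(res)) next
    again <- tajima_d_from_summary(res$m, res$S, res$n, res$pi)
    expect_equal(again$D, res$D, tolerance = 1e-12)
  }
})

test_that("tajima_d equals the brute-force pair/column oracle", {
  set.seed(22)
  tried <- 0
  for (rep in 1:150) {
    aln <- rand_alignment(sample(4:6, 1), sample(4:12, 1),
                          gap_prob = sample(c(0, 0.15), 1))
    res <- tryCatch(tajima_d(aln), error = function(e) NULL)
    if (is.null(res)) next
    tried <- tried + 1
    expect_equal(res$D, brute_tajima_d(aln), tolerance = 1e-12)
  }
  expect_gt(tried, 50)
})

test_that("D is positive iff pi*n exceeds S/a1 and is permutation-invariant", {
  set.seed(4)
  for (rep in 1:20) {
    aln <- rand_alignment(5, 15, gap_prob = 0)
    res <- tryCatch(tajima_d(aln), error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(sign(res$D), sign(res$k_hat - res$S / res$a1))
    perm <- sample(n_seqs(aln))
    seqs <- apply(aln$mat, 1, paste, collapse = "")[perm]
    names(seqs) <- aln$ids[perm]
    expect_equal(tajima_d(aa_alignment(seqs))$D, res$D, tolerance = 1e-12)
  }
})

test_that("theta is exactly p_s / a1", {
  res <- tajima_d_from_summary(24, 265, 301, 0.514011)
  expect_equal(res$theta, res$p_s / res$a1)
})

test_that("relative-rate counts partition the complete-deletion sites", {
  same <- aa_alignment(c(A = strrep("A", 10), B = strrep("A", 10),
                         C = strrep("A", 10)))
  cc <- relative_rate_counts(same, "C")
  expect_equal(cc$identical_all, 10L)
  expect_equal(cc$unique_a + cc$unique_b + cc$unique_c + cc$divergent_all, 0L)

  # columns (A,A,A), (T,A,A), (A,T,A), (C,G,T)
  aln <- aa_alignment(c(A = "ATAC", B = "AATG", C = "AAAT"))
  cc2 <- relative_rate_counts(aln, "C")
  expect_equal(cc2$identical_all, 1L)
  expect_equal(cc2$unique_a, 1L)
  expect_equal(cc2$unique_b, 1L)
  expect_equal(cc2$divergent_all, 1L)

  expect_error(relative_rate_counts(rand_alignment(4, 6), "s1"), "exactly 3")
  allgap <- aa_alignment(c(A = "-A", B = "A-", C = "AA"))
  expect_error(relative_rate_counts(allgap, "C"), "complete deletion")
})

test_that("the five categories sum to n_used on random triples", {
  set.seed(12)
  for (rep in 1:25) {
    aln <- rand_alignment(3, sample(5:40, 1), gap_prob = 0.1)
    cc <- tryCatch(relative_rate_counts(aln, "s3"),
                   error = function(e) NULL)
    if (is.null(cc)) next
    expect_equal(cc$identical_all + cc$unique_a + cc$unique_b +
                   cc$unique_c + cc$divergent_all, cc$n_used)
  }
})

test_that("relative_rate_test computes the chi-square and its tail", {
  r1 <- relative_rate_test(64, 38)
  expect_equal(round(r1$chi2, 2), 6.63)
  r2 <- relative_rate_test(52, 34)
  expect_equal(round(r2$chi2, 2), 3.77)
  # symmetric in A and B
  r1s <- relative_rate_test(38, 64)
  expect_equal(r1s$chi2, r1$chi2)
  expect_equal(r1s$p, r1$p)
  # equal counts give a null result; zero counts are flagged
  expect_equal(relative_rate_test(7, 7)$chi2, 0)
  expect_equal(relative_rate_test(7, 7)$p, 1)
  z <- relative_rate_test(0, 0)
  expect_true(z$no_information)
  expect_equal(z$chi2, 0)
  expect_equal(z$p, 1)
})

test_that("chi2_upper_tail is a valid monotone tail probability", {
  expect_equal(chi2_upper_tail(0), 1)
  expect_error(chi2_upper_tail(-1), "non-negative")
  x <- seq(0, 20, by = 0.5)
  expect_true(all(diff(chi2_upper_tail(x)) < 0))
  # df-1 tail equals the complementary error function of sqrt(x/2)
  erfc <- function(z) 2 * pnorm(z * sqrt(2), lower.tail = FALSE)
  expect_equal(chi2_upper_tail(6.63), erfc(sqrt(6.63 / 2)), tolerance = 1e-12)
})
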