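# Molecular-evolution statistics on amino-acid alignments: Tajima's test
# of neutrality and Tajima's relative-rate test, with pairwise- and
# complete-deletion handling of gaps and ambiguous residues (X, B, Z are
# treated as missing, like gaps).

.is_missing <- function(x) x %in% MISSING_RESIDUES

#' Pairwise difference counts between aligned sequences
#'
#' For each sequence pair, counts differing residues over comparable
#' sites. Under `pairwise` deletion a site is comparable when both
#' sequences carry a non-missing residue; under `complete` deletion only
#' columns where *every* sequence is non-missing are used. Gaps and the
#' ambiguity codes X, B, Z count as missing.
#'
#' @param aln An `aa_alignment`.
#' @param gap_mode `"pairwise"` or `"complete"`.
#' @return A list with symmetric matrices `diffs` and `sites` (dimnames =
#'   sequence ids). Pairs with zero comparable sites have `sites = 0` and
#'   are flagged in attribute `"no_overlap"` (a two-column matrix of ids).
#' @export
pairwise_differences <- function(aln, gap_mode = c("pairwise", "complete")) {
  stopifnot(inherits(aln, "aa_alignment"))
  gap_mode <- match.arg(gap_mode)
  m <- n_seqs(aln)
  mat <- aln$mat
  miss <- matrix(.is_missing(mat), nrow = m)
  if (gap_mode == "complete") {
    keep <- colSums(miss) == 0L
    mat <- mat[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
  }
  diffs <- matrix(0L, m, m, dimnames = list(aln$ids, aln$ids))
  sites <- matrix(0L, m, m, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    use <- !miss[i, ] & !miss[j, ]
    sites[i, j] <- sites[j, i] <- sum(use)
    diffs[i, j] <- diffs[j, i] <- sum(mat[i, use] != mat[j, use])
  }
  no <- which(upper.tri(sites) & sites == 0L, arr.ind = TRUE)
  flag <- if (nrow(no) > 0L)
    cbind(aln$ids[no[, 1]], aln$ids[no[, 2]]) else NULL
  structure(list(diffs = diffs, sites = sites), no_overlap = flag)
}

#' Segregating sites of an alignment
#'
#' A usable column is segregating when it holds at least two distinct
#' non-missing residues. Under `complete` deletion, columns containing
#' any missing entry are discarded and `n_used` counts the remainder;
#' under `pairwise` deletion all columns are retained (`n_used` equals the
#' alignment length) and segregation is judged on the non-missing residues
#' of each column.
#'
#' @param aln An `aa_alignment`.
#' @param gap_mode `"pairwise"` or `"complete"`.
#' @return A list with integers `S` and `n_used`.
#' @export
segregating_sites <- function(aln, gap_mode = c("pairwise", "complete")) {
  stopifnot(inherits(aln, "aa_alignment"))
  gap_mode <- match.arg(gap_mode)
  mat <- aln$mat
  miss <- matrix(.is_missing(mat), nrow = nrow(mat))
  if (gap_mode == "complete") {
    keep <- colSums(miss) == 0L
    mat <- mat[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
  }
  seg <- vapply(seq_len(ncol(mat)), function(j) {
    r <- mat[!miss[, j], j]
    length(unique(r)) >= 2L
  }, logical(1))
  list(S = sum(seg), n_used = ncol(mat))
}

#' Drop low-coverage alignment columns
#'
#' Removes columns whose fraction of non-missing residues is below
#' `min_coverage` (e.g. 0.95 allows fewer than 5% gaps/missing/ambiguous
#' entries per retained site).
#'
#' @param aln An `aa_alignment`.
#' @param min_coverage Minimum per-column fraction of non-missing entries.
#' @return A filtered `aa_alignment`.
#' @export
filter_site_coverage <- function(aln, min_coverage = 0.95) {
  stopifnot(inherits(aln, "aa_alignment"), min_coverage > 0, min_coverage <= 1)
  miss <- matrix(.is_missing(aln$mat), nrow = n_seqs(aln))
  keep <- 1 - colMeans(miss) >= min_coverage
  if (!any(keep)) stop("no column passes the coverage filter")
  structure(list(ids = aln$ids, mat = aln$mat[, keep, drop = FALSE]),
            class = "aa_alignment")
}

# Tajima's variance coefficients for m sequences.
tajima_coefficients <- function(m) {
  stopifnot(m >= 4L)
  i <- seq_len(m - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

.tajima_result <- function(m, n, S, k_hat, coef) {
  p_s <- S / n
  D <- (k_hat - S / coef$a1) /
    sqrt(coef$e1 * S + coef$e2 * S * (S - 1))
  structure(c(list(m = as.integer(m), n = as.integer(n), S = as.integer(S),
                   p_s = p_s, theta = p_s / coef$a1,
                   k_hat = k_hat, pi = k_hat / n, D = D), coef),
            class = "tajima_d")
}

#' Tajima's test of neutrality on an amino-acid alignment
#'
#' Computes the standardized difference D between the mean pairwise
#' diversity and the segregating-site estimator. `k_hat` is the mean
#' number of pairwise differences under pairwise deletion (pairs with no
#' comparable sites are excluded from the mean); `S` and `p_s = S/n` come
#' from [segregating_sites()] in pairwise mode; `theta = p_s / a1` is the
#' Watterson-type per-site estimate and `pi = k_hat / n` the per-site
#' diversity. D = (k_hat - S/a1) / sqrt(e1 S + e2 S (S-1)) with the usual
#' coefficients a1, a2, b1, b2, c1, c2, e1, e2.
#'
#' @param aln An `aa_alignment` with at least 4 sequences.
#' @param min_coverage Optional per-column coverage pre-filter (e.g. 0.95);
#'   `NULL` (default) uses every column.
#' @return An object of class `tajima_d` carrying `m`, `n`, `S`, `p_s`,
#'   `theta`, `pi`, `k_hat`, `D` and the coefficients.
#' @export
tajima_d <- function(aln, min_coverage = NULL) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!is.null(min_coverage)) aln <- filter_site_coverage(aln, min_coverage)
  m <- n_seqs(aln)
  if (m < 4L) stop("Tajima's D needs at least 4 sequences, got ", m)
  seg <- segregating_sites(aln, "pairwise")
  if (seg$S == 0L)
    stop("undefined statistic: no segregating sites (S = 0)")
  pd <- pairwise_differences(aln, "pairwise")
  ut <- upper.tri(pd$sites)
  use <- ut & pd$sites > 0L
  k_hat <- mean(pd$diffs[use])
  .tajima_result(m, seg$n_used, seg$S, k_hat, tajima_coefficients(m))
}

#' Tajima's D from printed summary statistics
#'
#' Verification entry point for published tables: given the sequence count
#' `m`, segregating sites `S`, site count `n` and per-site diversity `pi`,
#' sets `k_hat = pi * n` and computes D exactly as [tajima_d()] does.
#'
#' @param m Number of sequences (>= 4).
#' @param S Segregating sites (>= 1).
#' @param n Number of sites (>= S).
#' @param pi Per-site pairwise diversity in `[0, 1]`.
#' @return A `tajima_d` object.
#' @export
tajima_d_from_summary <- function(m, S, n, pi) {
  if (m < 4L) stop("Tajima's D needs at least 4 sequences, got ", m)
  if (S < 1L) stop("undefined statistic: no segregating sites (S = 0)")
  stopifnot(n >= S, pi >= 0, pi <= 1)
  .tajima_result(m, n, S, pi * n, tajima_coefficients(m))
}

#' @export
print.tajima_d <- function(x, ...) {
  cat("Tajima's test of neutrality (amino acids)\n")
  cat(sprintf("  m = %d sequences, n = %d sites, S = %d segregating\n",
              x$m, x$n, x$S))
  cat(sprintf("  p_s = %.6f   theta = %.6f   pi = %.6f\n",
              x$p_s, x$theta, x$pi))
  cat(sprintf("  D = %.6f\n", x$D))
  invisible(x)
}

#' Site partition for Tajima's relative-rate test
#'
#' For exactly three aligned sequences and a designated outgroup, columns
#' surviving complete deletion are partitioned into: identical in all
#' three; unique difference in A (B = C != A); unique in B (A = C != B);
#' unique in C (A = B != C); and divergent (all three distinct). For three
#' sequences these five categories are exhaustive.
#'
#' @param aln An `aa_alignment` with exactly 3 sequences.
#' @param outgroup Id (or index) of the outgroup sequence C; the remaining
#'   two, in alignment order, are A and B.
#' @return Object of class `relrate_counts`: list with `id_a`, `id_b`,
#'   `id_c`, `n_used`, `identical_all`, `divergent_all`, `unique_a`,
#'   `unique_b`, `unique_c`.
#' @export
relative_rate_counts <- function(aln, outgroup = 3L) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (n_seqs(aln) != 3L)
    stop("relative-rate test needs exactly 3 sequences, got ", n_seqs(aln))
  ic <- if (is.character(outgroup)) match(outgroup, aln$ids) else as.integer(outgroup)
  if (is.na(ic) || ic < 1L || ic > 3L) stop("outgroup not found: ", outgroup)
  iab <- setdiff(1:3, ic)
  mat <- aln$mat
  keep <- colSums(matrix(.is_missing(mat), nrow = 3L)) == 0L
  mat <- mat[, keep, drop = FALSE]
  n_used <- ncol(mat)
  if (n_used == 0L) stop("no site survives complete deletion")
  a <- mat[iab[1], ]; b <- mat[iab[2], ]; c <- mat[ic, ]
  identical_all <- sum(a == b & b == c)
  unique_a <- sum(b == c & a != b)
  unique_b <- sum(a == c & a != b)
  unique_c <- sum(a == b & a != c)
  divergent_all <- sum(a != b & b != c & a != c)
  structure(list(id_a = aln$ids[iab[1]], id_b = aln$ids[iab[2]],
                 id_c = aln$ids[ic], n_used = n_used,
                 identical_all = identical_all,
                 divergent_all = divergent_all,
                 unique_a = unique_a, unique_b = unique_b,
                 unique_c = unique_c),
            class = "relrate_counts")
}

#' @export
print.relrate_counts <- function(x, ...) {
  cat("Relative-rate site partition (complete deletion)\n")
  cat(sprintf("  A = %s, B = %s, C (outgroup) = %s; %d sites used\n",
              x$id_a, x$id_b, x$id_c, x$n_used))
  cat(sprintf("  identical %d | unique A %d | unique B %d | unique C %d | divergent %d\n",
              x$identical_all, x$unique_a, x$unique_b, x$unique_c,
              x$divergent_all))
  invisible(x)
}

#' Tajima's relative-rate test
#'
#' Tests equality of evolutionary rate between two ingroup sequences A and
#' B against an outgroup C via chi-square =
#' (unique_A - unique_B)^2 / (unique_A + unique_B) on 1 degree of freedom.
#'
#' @param x A `relrate_counts` object, or the unique-difference count of
#'   sequence A.
#' @param unique_b Unique-difference count of sequence B (when `x` is a
#'   count).
#' @return Object of class `relrate_test`: list with `unique_a`,
#'   `unique_b`, `chi2`, `df`, `p`, `no_information` (TRUE when both
#'   counts are zero, giving chi2 = 0, p = 1), and the counts object when
#'   one was supplied.
#' @export
relative_rate_test <- function(x, unique_b = NULL) {
  if (inherits(x, "relrate_counts")) {
    ua <- x$unique_a; ub <- x$unique_b; counts <- x
  } else {
    ua <- as.numeric(x); ub <- as.numeric(unique_b); counts <- NULL
  }
  stopifnot(ua >= 0, ub >= 0)
  if (ua + ub == 0) {
    res <- list(unique_a = ua, unique_b = ub, chi2 = 0, df = 1L, p = 1,
                no_information = TRUE, counts = counts)
  } else {
    chi2 <- (ua - ub)^2 / (ua + ub)
    res <- list(unique_a = ua, unique_b = ub, chi2 = chi2, df = 1L,
                p = chi2_upper_tail(chi2, 1L), no_information = FALSE,
                counts = counts)
  }
  structure(res, class = "relrate_test")
}

#' @export
print.relrate_test <- function(x, ...) {
  cat("Tajima's relative-rate test\n")
  cat(sprintf("  unique differences: A = %g, B = %g\n", x$unique_a, x$unique_b))
  cat(sprintf("  chi-square = %.2f (df = 1), p = %.5g%s\n", x$chi2, x$p,
              if (x$no_information) "  [no information]" else ""))
  invisible(x)
}

#' Upper-tail chi-square probability
#'
#' @param x Non-negative statistic value(s).
#' @param df Degrees of freedom, default 1.
#' @return Upper-tail probability P(X >= x).
#' @export
chi2_upper_tail <- function(x, df = 1L) {
  if (any(x < 0)) stop("chi-square statistic must be non-negative")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}
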