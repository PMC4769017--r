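# Independent oracles and small generators shared across tests.

# All spans of `s` matched by an anchored regex, by exhaustive substring
# enumeration. Used as the zero-mismatch oracle for the pattern engine.
naive_spans <- function(rx, s) {
  L <- nchar(s)
  out <- character(0)
  if (L == 0L) return(out)
  for (st in seq_len(L)) for (en in st:L)
    if (grepl(paste0("^", rx, "$"), substr(s, st, en), perl = TRUE))
      out <- c(out, paste(st, en))
  out
}

# Random pattern as parallel PROSITE text and regex, rendered separately
# so the oracle does not share the package's parser.
rand_pattern <- function(alpha = c("A", "C", "D", "E")) {
  rand_elem <- function() {
    t <- sample(c("literal", "set", "negated", "wildcard"), 1)
    el <- switch(t,
      literal = { r <- sample(alpha, 1); list(pro = r, rx = r) },
      set = { r <- sample(alpha, sample(2:3, 1))
              list(pro = paste0("[", paste(r, collapse = ""), "]"),
                   rx = paste0("[", paste(r, collapse = ""), "]")) },
      negated = { r <- sample(alpha, sample(1:2, 1))
                  list(pro = paste0("{", paste(r, collapse = ""), "}"),
                       rx = paste0("[^", paste(r, collapse = ""), "]")) },
      wildcard = list(pro = "x", rx = "."))
    kind <- sample(c("none", "fixed", "range"), 1, prob = c(.6, .25, .15))
    if (kind == "fixed") {
      k <- sample(2:3, 1)
      el$pro <- sprintf("%s(%d)", el$pro, k)
      el$rx <- sprintf("(?:%s){%d}", el$rx, k)
    } else if (kind == "range") {
      i <- sample(1:2, 1); j <- i + sample(1:2, 1)
      el$pro <- sprintf("%s(%d,%d)", el$pro, i, j)
      el$rx <- sprintf("(?:%s){%d,%d}", el$rx, i, j)
    }
    el
  }
  els <- replicate(sample(1:4, 1), rand_elem(), simplify = FALSE)
  list(pro = paste(vapply(els, `[[`, "", "pro"), collapse = "-"),
       rx = paste(vapply(els, `[[`, "", "rx"), collapse = ""))
}

# Brute-force Tajima's D by direct enumeration of pairs and columns.
brute_tajima_d <- function(aln) {
  mat <- aln$mat
  m <- nrow(mat); n <- ncol(mat)
  missing <- c("-", "X", "B", "Z")
  seg <- 0L
  for (j in seq_len(n)) {
    r <- mat[, j]; r <- r[!(r %in% missing)]
    if (length(unique(r)) >= 2L) seg <- seg + 1L
  }
  ks <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    use <- !(mat[i, ] %in% missing) & !(mat[j, ] %in% missing)
    if (sum(use) > 0L) ks <- c(ks, sum(mat[i, use] != mat[j, use]))
  }
  k_hat <- mean(ks)
  i <- seq_len(m - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (m + 1) / (3 * (m - 1)); b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k_hat - seg / a1) / sqrt(e1 * seg + e2 * seg * (seg - 1))
}

# Random gapped alignment (character strings) for property tests.
rand_alignment <- function(m, n, alpha = c("A", "C", "D", "E"),
                           gap_prob = 0.1) {
  seqs <- vapply(seq_len(m), function(i) {
    s <- sample(alpha, n, replace = TRUE)
    g <- runif(n) < gap_prob
    s[g] <- sample(c("-", "X"), sum(g), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", seq_len(m))
  aa_alignment(seqs)
}

# Compose a kinase-like sequence around given anchor/loop pieces.
plant_domain <- function(pre = "MKT", loop = "QQQQQQQQQQ", triplet = "TEY",
                         spacer = "LMNKLA", post = "GDSV",
                         n_anchor = "HRDLKPN", c_anchor = "TRWYRAP") {
  paste0(pre, n_anchor, loop, triplet, spacer, c_anchor, post)
}
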