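# Seeded synthetic-data generators: kinase-like proteins with planted
# anchors and activation-loop triplets, star-genealogy alignments with
# controlled diversity, and three-sequence alignments with exact
# relative-rate site partitions. All generators are pure functions of
# their arguments (including the seed).

#' Default synthetic cohort specification
#'
#' A compact species table emulating the structure of a fungal MAPK
#' census: every catalogued novel motif (TTY, TIY, TNY, THY, TSY, KGY,
#' TQY, SEY, SDY) appears in the division where it was reported, alongside
#' the canonical TEY/TGY repertoire. One row per species; `motifs` is the
#' comma-separated motif multiset of that species (one MAPK per motif).
#'
#' @return data.frame with columns `genus`, `species_epithet`, `division`,
#'   `motifs`.
#' @export
default_cohort <- function() {
  data.frame(
    genus = c("Aplanochytrium", "Aurantiochytrium", "Saccharomyces",
              "Xanthoria", "Dekkera", "Hanseniaspora", "Umbelopsis",
              "Meliniomyces", "Pichia"),
    species_epithet = c("kerguelense", "limacinum", "cerevisiae",
                        "parietina", "bruxellensis", "valbyensis",
                        "ramanniana", "bicolor", "stipitis"),
    division = c("Labyrinthulomycota", "Labyrinthulomycota", "Ascomycota",
                 "Ascomycota", "Ascomycota", "Ascomycota",
                 "Mucoromycotina", "Basidiomycota", "Ascomycota"),
    motifs = c("TTY",
               "TIY, SEY",
               "TEY, TGY, TNY, KGY",
               "TEY, TGY, TNY, KGY",
               "TEY, TGY, THY",
               "TEY, TGY, TSY",
               "TEY, TGY, TQY",
               "TEY, TGY, SDY",
               "TEY, TGY, TNY"),
    stringsAsFactors = FALSE)
}

.pattern_literal <- function(p) {
  # literal residue string of a fixed literal-only pattern
  paste(vapply(p$elements, function(el) {
    if (el$type != "literal" || el$min != 1L || el$max != 1L)
      stop("generator anchors must be literal fixed-length patterns")
    el$residues
  }, character(1)), collapse = "")
}

.mutate_residues <- function(s, k) {
  # mutate k distinct positions of character vector s to a different residue
  if (k == 0L) return(s)
  pos <- sample(seq_along(s), k)
  for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1L)
  s
}

#' Generate a cohort of kinase-like proteins with planted motifs
#'
#' Each record is background + N anchor + loop + triplet + spacer +
#' C anchor + background. Backgrounds are uniform over the 20 amino acids;
#' the loop and spacer exclude Y so the planted triplet is the unique
#' activation-loop candidate; the spacer length is drawn inside the
#' catalog's offset window. Anchors may be mutated at `anchor_mutations`
#' random positions. Records whose composed sequence yields anchor hits
#' anywhere other than the planted spans (at a mismatch budget of
#' `max(2, anchor_mutations)`) are redrawn, so a scanner whose budget
#' covers the generator's recovers every planted domain.
#'
#' @param species data.frame with columns `genus`, `species_epithet`,
#'   `division`, `motifs` (comma-separated 3-residue motifs, one MAPK per
#'   motif); default [default_cohort()].
#' @param catalog [anchor_catalog()] providing anchors and offset window.
#' @param anchor_mutations Mutations planted per anchor (default 0).
#' @param bg_len Length range of each background flank, default c(30, 80).
#' @param loop_len Length range of the loop segment between the N anchor
#'   and the triplet, default c(6, 20).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return list with `records` (a `protein_records` data.frame) and
#'   `truth` (data.frame of planted spans: `id`, `genus`,
#'   `species_epithet`, `division`, `triplet`, `n_start`, `n_end`,
#'   `c_start`, `c_end`, `triplet_start`, `triplet_end`).
#' @export
gen_kinase_cohort <- function(species = default_cohort(),
                              catalog = anchor_catalog(),
                              anchor_mutations = 0L,
                              bg_len = c(30L, 80L),
                              loop_len = c(6L, 20L),
                              seed = 1L) {
  stopifnot(all(c("genus", "species_epithet", "division", "motifs")
                %in% names(species)))
  set.seed(seed)
  n_pat <- .pattern_literal(catalog$n_anchor)
  c_pat <- .pattern_literal(catalog$c_anchor)
  budget <- max(2L, anchor_mutations)
  noY <- setdiff(AA20, "Y")
  recs <- list(); truth <- list()
  for (si in seq_len(nrow(species))) {
    motifs <- toupper(trimws(strsplit(species$motifs[si], ",")[[1]]))
    if (any(nchar(motifs) != 3L))
      stop("motif(s) not of length 3 for ",
           species$genus[si], " ", species$species_epithet[si])
    base <- make_gene_name(species$genus[si], species$species_epithet[si])
    for (mi in seq_along(motifs)) {
      id <- if (length(motifs) > 1L) paste0(base, "-", LETTERS[mi]) else base
      for (try in seq_len(50L)) {
        bg1 <- sample(AA20, sample(bg_len[1]:bg_len[2], 1L), replace = TRUE)
        bg2 <- sample(AA20, sample(bg_len[1]:bg_len[2], 1L), replace = TRUE)
        loop <- sample(noY, sample(loop_len[1]:loop_len[2], 1L), replace = TRUE)
        spacer <- sample(noY,
                         sample(catalog$offset_window[1]:catalog$offset_window[2], 1L),
                         replace = TRUE)
        na <- .mutate_residues(strsplit(n_pat, "")[[1]], anchor_mutations)
        ca <- .mutate_residues(strsplit(c_pat, "")[[1]], anchor_mutations)
        s <- c(bg1, na, loop, strsplit(motifs[mi], "")[[1]], spacer, ca, bg2)
        seq <- paste(s, collapse = "")
        n_start <- length(bg1) + 1L
        n_end <- n_start + nchar(n_pat) - 1L
        t_start <- n_end + length(loop) + 1L
        c_start <- t_start + 3L + length(spacer)
        c_end <- c_start + nchar(c_pat) - 1L
        nh <- match_pattern(catalog$n_anchor, seq, budget)
        ch <- match_pattern(catalog$c_anchor, seq, budget)
        ok <- nrow(nh) == 1L && nh$start == n_start &&
              nrow(ch) == 1L && ch$start == c_start
        if (ok) break
        if (try == 50L) stop("could not place anchors uniquely for ", id)
      }
      recs[[length(recs) + 1L]] <- data.frame(
        id = id, genus = species$genus[si],
        species_epithet = species$species_epithet[si],
        division = species$division[si], residues = seq,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, genus = species$genus[si],
        species_epithet = species$species_epithet[si],
        division = species$division[si], triplet = motifs[mi],
        n_start = n_start, n_end = n_end,
        c_start = c_start, c_end = c_end,
        triplet_start = t_start, triplet_end = t_start + 2L,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  class(records) <- c("protein_records", "data.frame")
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate a star-genealogy amino-acid alignment
#'
#' A uniform random ancestral sequence is mutated independently in each of
#' `m` descendant sequences: each site substitutes with probability `rate`
#' to a residue drawn uniformly from the 19 alternatives.
#'
#' @param m Number of sequences (>= 2).
#' @param n Number of sites (>= 1).
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return An `aa_alignment` (ids `seq1` ... `seqm`).
#' @export
gen_alignment <- function(m, n, rate, seed = 1L) {
  stopifnot(m >= 2L, n >= 1L)
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop("rate must be a probability in [0, 1]")
  set.seed(seed)
  anc <- sample(AA20, n, replace = TRUE)
  seqs <- vapply(seq_len(m), function(i) {
    s <- anc
    hit <- stats::runif(n) < rate
    if (any(hit))
      s[hit] <- vapply(s[hit], function(r) sample(setdiff(AA20, r), 1L),
                       character(1))
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("seq", seq_len(m))
  aa_alignment(seqs)
}

#' Neutral-null substitution rate for a star genealogy
#'
#' A star genealogy over-represents rare variants at low substitution
#' rates (every substitution is private to one lineage), which biases
#' Tajima's D negative, while saturation at high rates biases it positive.
#' The rate at which D is centred on zero solves
#' `p_diff(r) = p_poly(r, m) / a1`, where
#' `p_diff = 1 - (1-r)^2 - r^2/19` is the expected per-site pairwise
#' difference, `p_poly = 1 - (1-r)^m - 19 (r/19)^m` the probability that a
#' column is polymorphic, and `a1` the (m-1)-th harmonic number — the
#' star-genealogy analogue of mutation-drift equilibrium where the
#' diversity-based and segregating-site-based estimators agree in
#' expectation.
#'
#' @param m Number of sequences (>= 4).
#' @return The calibrated per-site substitution probability.
#' @export
star_neutral_rate <- function(m) {
  stopifnot(m >= 4L)
  a1 <- sum(1 / seq_len(m - 1L))
  f <- function(r) (1 - (1 - r)^2 - r^2 / 19) -
    (1 - (1 - r)^m - 19 * (r / 19)^m) / a1
  stats::uniroot(f, c(1e-4, 0.9), tol = 1e-10)$root
}

#' Generate a three-sequence alignment with an exact site partition
#'
#' Columns are constructed per category — identical in all three, unique
#' difference in A, in B, in C, and fully divergent — then shuffled. For
#' three sequences these categories are exhaustive, so
#' `shared_pair_remainder` must be 0. [relative_rate_counts()] on the
#' output (outgroup = third id) recovers the requested partition exactly.
#'
#' @param identical_all,unique_a,unique_b,unique_c,divergent_all
#'   Non-negative column counts per category.
#' @param shared_pair_remainder Must be 0 (kept for interface symmetry).
#' @param ids Three sequence ids, default `c("A", "B", "C")` with C the
#'   intended outgroup.
#' @param seed Integer seed.
#' @return An `aa_alignment` of 3 sequences.
#' @export
gen_triple <- function(identical_all, unique_a, unique_b, unique_c,
                       divergent_all, shared_pair_remainder = 0L,
                       ids = c("A", "B", "C"), seed = 1L) {
  counts <- c(identical_all, unique_a, unique_b, unique_c, divergent_all)
  stopifnot(all(counts >= 0L), length(ids) == 3L, !anyDuplicated(ids))
  if (shared_pair_remainder != 0L)
    stop("for three sequences the five categories are exhaustive; ",
         "shared_pair_remainder must be 0")
  n <- sum(counts)
  if (n < 1L) stop("alignment would have zero sites")
  set.seed(seed)
  cols <- matrix("", nrow = 3L, ncol = n)
  k <- 0L
  add <- function(maker, times) {
    for (t in seq_len(times)) {
      k <<- k + 1L
      cols[, k] <<- maker()
    }
  }
  add(function() rep(sample(AA20, 1L), 3L), identical_all)
  add(function() { r <- sample(AA20, 2L); c(r[2], r[1], r[1]) }, unique_a)
  add(function() { r <- sample(AA20, 2L); c(r[1], r[2], r[1]) }, unique_b)
  add(function() { r <- sample(AA20, 2L); c(r[1], r[1], r[2]) }, unique_c)
  add(function() sample(AA20, 3L), divergent_all)
  cols <- cols[, sample(n), drop = FALSE]
  seqs <- apply(cols, 1L, paste, collapse = "")
  names(seqs) <- ids
  aa_alignment(seqs)
}
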