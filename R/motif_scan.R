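# Kinase-domain anchoring and activation-loop triplet extraction.
#
# A MAPK catalytic domain is recognised by two conserved anchors flanking
# the activation segment: the catalytic-loop motif H-R-D-L-K-P-N upstream
# and the APE-region motif T-R-W-Y-R-A-P downstream. The phospho-acceptor
# triplet (T-x-Y and variants) lies between them.

#' Anchor catalog for kinase-domain scanning
#'
#' @param n_anchor PROSITE text of the N-terminal (catalytic-loop) anchor.
#' @param c_anchor PROSITE text of the C-terminal anchor.
#' @param max_mismatches Per-anchor mismatch budget (violated fixed-length
#'   pattern elements), default 2.
#' @param first_residues Allowed residues at the first triplet position;
#'   default `c("T","S","K")`, covering every catalogued motif. Use
#'   [AA20] for an unrestricted exploratory scan.
#' @param offset_window Integer pair `(min,max)`: admissible number of
#'   residues strictly between the triplet end and the C-anchor start.
#'   Default `c(4, 14)`, a heuristic derived from MAPK domain geometry.
#' @return An object of class `anchor_catalog`.
#' @export
anchor_catalog <- function(n_anchor = "H-R-D-L-K-P-N",
                           c_anchor = "T-R-W-Y-R-A-P",
                           max_mismatches = 2L,
                           first_residues = c("T", "S", "K"),
                           offset_window = c(4L, 14L)) {
  if (is.character(n_anchor)) n_anchor <- parse_prosite(n_anchor)
  if (is.character(c_anchor)) c_anchor <- parse_prosite(c_anchor)
  stopifnot(max_mismatches >= 0L, length(offset_window) == 2L,
            offset_window[1] <= offset_window[2])
  structure(list(n_anchor = n_anchor, c_anchor = c_anchor,
                 max_mismatches = as.integer(max_mismatches),
                 first_residues = toupper(first_residues),
                 offset_window = as.integer(offset_window)),
            class = "anchor_catalog")
}

#' Read an anchor catalog from a key:value text config
#'
#' Recognised keys: `n_anchor`, `c_anchor`, `max_mismatches`,
#' `first_residues` (comma-separated), `offset_min`, `offset_max`.
#' Missing keys fall back to the defaults of [anchor_catalog()].
#'
#' @param path Path to the config file.
#' @return An `anchor_catalog`.
#' @export
read_anchor_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*:\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  names(vals) <- trimws(keys)
  get <- function(k, default) if (k %in% names(vals)) trimws(vals[[k]]) else default
  anchor_catalog(
    n_anchor = get("n_anchor", "H-R-D-L-K-P-N"),
    c_anchor = get("c_anchor", "T-R-W-Y-R-A-P"),
    max_mismatches = as.integer(get("max_mismatches", "2")),
    first_residues = trimws(strsplit(get("first_residues", "T,S,K"), ",")[[1]]),
    offset_window = c(as.integer(get("offset_min", "4")),
                      as.integer(get("offset_max", "14"))))
}

#' @export
print.anchor_catalog <- function(x, ...) {
  cat("Anchor catalog\n")
  cat("  N anchor:      ", format_prosite(x$n_anchor), "\n")
  cat("  C anchor:      ", format_prosite(x$c_anchor), "\n")
  cat("  mismatch budget:", x$max_mismatches, "per anchor\n")
  cat("  first residues: ", paste(x$first_residues, collapse = ", "), "\n")
  cat("  offset window:  ", x$offset_window[1], "-", x$offset_window[2],
      "residues to C anchor\n")
  invisible(x)
}

#' Extract the activation-loop triplet between two anchor spans
#'
#' Candidate triplets start at positions `i` strictly between the anchors
#' with `residue(i)` in `first_residues` and `residue(i+2) == "Y"`, the
#' whole triplet inside the open region. Among candidates whose gap
#' (residues strictly between triplet end and C-anchor start) falls in
#' `offset_window`, the one closest to the C anchor wins; if none falls in
#' the window, the candidate nearest the C anchor overall wins; ties go to
#' the leftmost.
#'
#' @param residues Unaligned protein sequence (string).
#' @param n_span Integer pair: 1-based inclusive span of the N anchor.
#' @param c_span Integer pair: span of the C anchor.
#' @param catalog An [anchor_catalog()].
#' @return A list with `triplet`, `start`, `end`, or `NULL` when no
#'   candidate exists.
#' @export
extract_activation_motif <- function(residues, n_span, c_span,
                                     catalog = anchor_catalog()) {
  s <- strsplit(toupper(residues), "")[[1]]
  lo <- n_span[2] + 1L
  hi <- c_span[1] - 1L
  if (hi - lo + 1L < 3L) return(NULL)
  starts <- lo:(hi - 2L)
  ok <- s[starts] %in% catalog$first_residues & s[starts + 2L] == "Y"
  cand <- starts[ok]
  if (length(cand) == 0L) return(NULL)
  gap <- c_span[1] - (cand + 2L) - 1L
  inwin <- gap >= catalog$offset_window[1] & gap <= catalog$offset_window[2]
  pool <- if (any(inwin)) cand[inwin] else cand
  gpool <- gap[match(pool, cand)]
  best <- pool[order(gpool, pool)][1]   # closest to C anchor, then leftmost
  list(triplet = paste(s[best:(best + 2L)], collapse = ""),
       start = best, end = best + 2L)
}

#' Locate kinase domains and activation-loop triplets in one protein
#'
#' Both anchors are matched with the catalog's mismatch budget. Each
#' N-anchor hit is paired with its nearest downstream C-anchor hit leaving
#' room for a triplet, and the activation-loop triplet is extracted from
#' the region between them. Pairs whose inter-anchor region holds no
#' triplet candidate are dropped. The annotation with the fewest total
#' anchor mismatches (then leftmost) is flagged `primary`.
#'
#' @param record A one-row `protein_records` data.frame, or a list/row with
#'   `id` and `residues`.
#' @param catalog An [anchor_catalog()].
#' @return data.frame with columns `record_id`, `n_start`, `n_end`,
#'   `n_mismatches`, `c_start`, `c_end`, `c_mismatches`, `loop_start`,
#'   `loop_end`, `triplet`, `triplet_start`, `triplet_end`, `primary`;
#'   zero rows when the record has no anchored domain.
#' @export
find_kinase_domain <- function(record, catalog = anchor_catalog()) {
  id <- as.character(record$id)
  residues <- as.character(record$residues)
  empty <- data.frame(record_id = character(0), n_start = integer(0),
                      n_end = integer(0), n_mismatches = integer(0),
                      c_start = integer(0), c_end = integer(0),
                      c_mismatches = integer(0), loop_start = integer(0),
                      loop_end = integer(0), triplet = character(0),
                      triplet_start = integer(0), triplet_end = integer(0),
                      primary = logical(0))
  nh <- match_pattern(catalog$n_anchor, residues, catalog$max_mismatches)
  ch <- match_pattern(catalog$c_anchor, residues, catalog$max_mismatches)
  if (nrow(nh) == 0L || nrow(ch) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(nh))) {
    down <- ch[ch$start > nh$end[i] + 3L, , drop = FALSE]
    if (nrow(down) == 0L) next
    j <- which.min(down$start)
    mot <- extract_activation_motif(residues,
                                    c(nh$start[i], nh$end[i]),
                                    c(down$start[j], down$end[j]),
                                    catalog)
    if (is.null(mot)) next
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = id,
      n_start = nh$start[i], n_end = nh$end[i],
      n_mismatches = nh$mismatches[i],
      c_start = down$start[j], c_end = down$end[j],
      c_mismatches = down$mismatches[j],
      loop_start = nh$end[i] + 1L, loop_end = down$start[j] - 1L,
      triplet = mot$triplet,
      triplet_start = mot$start, triplet_end = mot$end,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  total_mm <- out$n_mismatches + out$c_mismatches
  out$primary <- seq_len(nrow(out)) == order(total_mm, out$n_start)[1]
  rownames(out) <- NULL
  out
}

#' Scan a collection of proteins for MAPK activation-loop motifs
#'
#' Runs [find_kinase_domain()] on every record and attaches taxon metadata
#' and the motif classification from [classify_motif()].
#'
#' @param records A `protein_records` data.frame.
#' @param catalog An [anchor_catalog()].
#' @param motifs A [motif_catalog()].
#' @return data.frame: one row per annotation with spans, triplet, motif
#'   class, taxon columns and the derived gene name (paralogs suffixed
#'   -A, -B, ... in order of appearance within a species).
#' @export
scan_proteins <- function(records, catalog = anchor_catalog(),
                          motifs = motif_catalog()) {
  ann <- lapply(seq_len(nrow(records)), function(i)
    find_kinase_domain(records[i, , drop = FALSE], catalog))
  ann <- do.call(rbind, ann)
  if (is.null(ann) || nrow(ann) == 0L) {
    return(cbind(data.frame(record_id = character(0)),
                 genus = character(0), species_epithet = character(0),
                 division = character(0)))
  }
  i <- match(ann$record_id, records$id)
  ann$genus <- records$genus[i]
  ann$species_epithet <- records$species_epithet[i]
  ann$division <- records$division[i]
  cls <- classify_motif(ann$triplet, motifs)
  ann$motif_class <- cls$motif_class
  ann$note <- cls$note
  # gene naming: genus/species initials + MPK, suffixed by appearance order
  has_tax <- !is.na(ann$genus) & !is.na(ann$species_epithet)
  ann$gene_name <- NA_character_
  if (any(has_tax)) {
    base <- make_gene_name(ann$genus[has_tax], ann$species_epithet[has_tax])
    sp <- paste(ann$genus[has_tax], ann$species_epithet[has_tax])
    k <- stats::ave(seq_along(sp), sp, FUN = seq_along)
    n_per <- stats::ave(seq_along(sp), sp, FUN = length)
    ann$gene_name[has_tax] <- ifelse(n_per > 1L,
                                     paste0(base, "-", LETTERS[k]), base)
  }
  rownames(ann) <- NULL
  ann
}
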