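# FASTA / aligned-FASTA input-output and consensus annotation.

#' The 20 standard amino acids
#'
#' X, B and Z are additionally accepted on input but treated as missing
#' data by the evolution statistics. Exported so callers can request an
#' unrestricted first-residue set in [anchor_catalog()].
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_EXT <- c(AA20, "X", "B", "Z")
MISSING_RESIDUES <- c("-", "X", "B", "Z")

#' Read protein sequences from a FASTA file
#'
#' Reads plain (unaligned) FASTA and returns one row per entry. Residues are
#' upper-cased, a single terminal stop (`*`) is stripped, and any character
#' outside the extended amino-acid alphabet (20 standard residues plus
#' `X`, `B`, `Z`) is rejected with its position.
#'
#' @param path Path to a FASTA file.
#' @param metadata Optional data.frame with columns `id`, `genus`,
#'   `species_epithet`, `division`; joined onto the records by `id`.
#' @return A data.frame of class `protein_records` with columns `id`,
#'   `genus`, `species_epithet`, `division`, `residues`.
#' @export
read_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not readable as FASTA: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA format error: no sequence entries in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  residues <- toupper(as.character(set))
  residues <- sub("\\*$", "", residues)
  for (k in seq_along(residues)) {
    bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET_EXT, collapse = "")),
                   residues[[k]])
    if (bad != -1L)
      stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                   substr(residues[[k]], bad, bad), bad, ids[[k]]))
    if (nchar(residues[[k]]) == 0L)
      stop("empty sequence for id '", ids[[k]], "'")
  }
  protein_records(ids, residues, metadata)
}

#' Construct a set of protein records
#'
#' @param id Character vector of unique ids.
#' @param residues Character vector of unaligned amino-acid sequences.
#' @param metadata Optional data.frame keyed by `id` carrying `genus`,
#'   `species_epithet` and `division`.
#' @return A `protein_records` data.frame.
#' @export
protein_records <- function(id, residues, metadata = NULL) {
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  rec <- data.frame(id = as.character(id),
                    genus = NA_character_,
                    species_epithet = NA_character_,
                    division = NA_character_,
                    residues = toupper(as.character(residues)),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    need <- c("id", "genus", "species_epithet", "division")
    miss <- setdiff(need, names(metadata))
    if (length(miss) > 0L)
      stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    i <- match(rec$id, metadata$id)
    hit <- !is.na(i)
    rec$genus[hit] <- as.character(metadata$genus[i[hit]])
    rec$species_epithet[hit] <- as.character(metadata$species_epithet[i[hit]])
    rec$division[hit] <- as.character(metadata$division[i[hit]])
  }
  class(rec) <- c("protein_records", "data.frame")
  rec
}

#' Write protein records (or any named sequences) to FASTA
#'
#' @param x A `protein_records` data.frame, or a named character vector of
#'   sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- x$residues
    names(seqs) <- x$id
  } else {
    seqs <- x
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Construct an amino-acid alignment
#'
#' @param seqs Named character vector of gapped sequences of equal length
#'   (gap character `-`; `.` is normalised to `-`).
#' @return An object of class `aa_alignment`: a list with elements `ids`
#'   (character) and `mat` (character matrix, one row per sequence, one
#'   column per site).
#' @export
aa_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("alignment sequences must be named")
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(seqs) < 2L)
    stop("an alignment needs at least 2 sequences, got ", length(seqs))
  seqs <- chartr(".", "-", toupper(seqs))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    ref <- as.integer(names(sort(table(len), decreasing = TRUE))[1])
    off <- ids[len != ref]
    stop("ragged alignment: sequence(s) ", paste(off, collapse = ", "),
         " differ in length from the majority length ", ref)
  }
  if (len[[1]] < 1L) stop("alignment has zero sites")
  ok <- sprintf("^[%s-]*$", paste(AA_ALPHABET_EXT, collapse = ""))
  bad <- !grepl(ok, seqs)
  if (any(bad))
    stop("illegal character(s) in aligned sequence(s): ",
         paste(ids[bad], collapse = ", "))
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  structure(list(ids = ids, mat = mat), class = "aa_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (all entries the same length).
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no sequence entries in ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  aa_alignment(seqs)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  names(seqs) <- aln$ids
  write_fasta(seqs, path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d sequences x %d sites\n",
              n_seqs(x), n_sites(x)))
  show <- utils::head(x$ids, 6L)
  for (id in show) {
    s <- paste(x$mat[id, seq_len(min(50L, n_sites(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (n_sites(x) > 50L) "..." else ""))
  }
  if (n_seqs(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Number of sites (columns) of an alignment
#' @param aln An `aa_alignment`.
#' @return Integer column count.
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' Number of sequences (rows) of an alignment
#' @param aln An `aa_alignment`.
#' @return Integer row count.
#' @export
n_seqs <- function(aln) nrow(aln$mat)

#' Per-column consensus annotation
#'
#' For each alignment column the frequency `f` of the most frequent
#' non-gap residue is computed over the non-gap entries of that column.
#' The column is annotated `high` when `f >= high_level`, `low` when
#' `low_level <= f < high_level`, and `none` otherwise (all-gap columns
#' are `none`). Among co-maximal residues the alphabetically smallest is
#' reported, so output is deterministic.
#'
#' @param aln An `aa_alignment`.
#' @param high_level High consensus threshold (fraction), default 0.90.
#' @param low_level Low consensus threshold (fraction), default 0.50.
#' @return An object of class `consensus_annotation`: data.frame with one
#'   row per column and columns `site`, `residue`, `frequency`, `symbol`.
#' @export
consensus_annotation <- function(aln, high_level = 0.90, low_level = 0.50) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!(high_level > low_level && low_level > 0))
    stop("need high_level > low_level > 0")
  n <- n_sites(aln)
  residue <- character(n)
  freq <- numeric(n)
  symbol <- character(n)
  for (j in seq_len(n)) {
    col <- aln$mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) {
      residue[j] <- NA_character_; freq[j] <- 0; symbol[j] <- "none"
      next
    }
    tab <- table(col)
    top <- tab[tab == max(tab)]
    residue[j] <- sort(names(top))[1]      # alphabetical tie-break
    freq[j] <- max(tab) / length(col)
    symbol[j] <- if (freq[j] >= high_level) "high"
                 else if (freq[j] >= low_level) "low"
                 else "none"
  }
  structure(data.frame(site = seq_len(n), residue = residue,
                       frequency = freq, symbol = symbol,
                       stringsAsFactors = FALSE),
            class = c("consensus_annotation", "data.frame"),
            high_level = high_level, low_level = low_level)
}

#' Write a tabular report as TSV
#'
#' Tab-separated UTF-8, one header line, rows in input order; no quoting
#' and no row names.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}
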