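# PROSITE-syntax pattern engine.
#
# Supported syntax: dash-separated elements, each a literal residue,
# an ambiguity set [ACD], a negated set {P}, or the wildcard x; any
# element may carry a repeat count (i) or a repeat range (i,j).
# Optional terminal '.' and '<' / '>' anchors are accepted.

#' Parse a PROSITE-syntax pattern
#'
#' @param text Pattern text, e.g. `"H-R-D-L-K-P-N"` or `"[LIV]-G-{P}-x(2)"`.
#' @param accession Optional PROSITE accession to attach (e.g. `"PS00107"`).
#' @return An object of class `prosite_pattern`: list with `elements`
#'   (each a list with `type` in literal/set/negated/wildcard, `residues`,
#'   `min`, `max`), `source_text`, `accession`, and anchoring flags.
#' @export
parse_prosite <- function(text, accession = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  text <- gsub("\\s", "", text)
  text <- sub("\\.$", "", text)
  anchor_n <- grepl("^<", text)
  anchor_c <- grepl(">$", text)
  text <- sub("^<", "", text)
  text <- sub(">$", "", text)
  if (nchar(text) == 0L) stop("empty pattern")
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  offset <- 0L   # character offset of current element within the stripped text
  elements <- list()
  for (p in parts) {
    if (nchar(p) == 0L)
      stop("empty pattern element at offset ", offset + 1L)
    el <- .parse_prosite_element(p, offset)
    elements[[length(elements) + 1L]] <- el
    offset <- offset + nchar(p) + 1L
  }
  structure(list(elements = elements, source_text = raw,
                 accession = accession,
                 anchor_n = anchor_n, anchor_c = anchor_c),
            class = "prosite_pattern")
}

.parse_prosite_element <- function(p, offset) {
  m <- regexec("^([A-Zx]|\\[[A-Z]*\\]|\\{[A-Z]*\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$",
               p)[[1]]
  if (m[1] == -1L)
    stop("malformed pattern element '", p, "' at offset ", offset + 1L)
  core <- substr(p, m[2], m[2] + attr(m, "match.length")[2] - 1L)
  rep_i <- if (m[3] > 0L)
    as.integer(substr(p, m[3], m[3] + attr(m, "match.length")[3] - 1L)) else 1L
  rep_j <- if (length(m) >= 4L && m[4] > 0L)
    as.integer(substr(p, m[4], m[4] + attr(m, "match.length")[4] - 1L)) else rep_i
  if (rep_i < 1L || rep_i > rep_j)
    stop("bad repeat range (", rep_i, ",", rep_j, ") at offset ", offset + 1L,
         ": need 1 <= i <= j")
  if (core == "x") {
    type <- "wildcard"; residues <- NULL
  } else if (startsWith(core, "[")) {
    residues <- strsplit(substr(core, 2L, nchar(core) - 1L), "")[[1]]
    if (length(residues) == 0L)
      stop("empty ambiguity set at offset ", offset + 1L)
    type <- "set"
  } else if (startsWith(core, "{")) {
    residues <- strsplit(substr(core, 2L, nchar(core) - 1L), "")[[1]]
    if (length(residues) == 0L)
      stop("empty negated set at offset ", offset + 1L)
    type <- "negated"
  } else {
    type <- "literal"; residues <- core
  }
  list(type = type, residues = residues, min = rep_i, max = rep_j)
}

#' Serialise a pattern back to canonical PROSITE text
#'
#' Canonical form: upper-case residues, set members sorted alphabetically,
#' unit repeats omitted, elements joined by dashes, no anchors unless
#' present in the source.
#'
#' @param p A `prosite_pattern`.
#' @return A single string.
#' @export
format_prosite <- function(p) {
  stopifnot(inherits(p, "prosite_pattern"))
  one <- function(el) {
    core <- switch(el$type,
      literal  = el$residues,
      wildcard = "x",
      set      = paste0("[", paste(sort(unique(el$residues)), collapse = ""), "]"),
      negated  = paste0("{", paste(sort(unique(el$residues)), collapse = ""), "}"))
    if (el$min == 1L && el$max == 1L) core
    else if (el$min == el$max) sprintf("%s(%d)", core, el$min)
    else sprintf("%s(%d,%d)", core, el$min, el$max)
  }
  body <- paste(vapply(p$elements, one, character(1)), collapse = "-")
  paste0(if (isTRUE(p$anchor_n)) "<" else "", body,
         if (isTRUE(p$anchor_c)) ">" else "")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("PROSITE pattern", if (!is.null(x$accession)) paste0("[", x$accession, "]"),
      ":", format_prosite(x), "\n")
  invisible(x)
}

# Does residue r satisfy element el (ignoring repeats)?
.element_ok <- function(el, r) {
  switch(el$type,
    literal  = r == el$residues,
    wildcard = TRUE,
    set      = r %in% el$residues,
    negated  = !(r %in% el$residues))
}

# Expand fixed repeats into unit elements so that mismatches are counted
# per fixed-length element position; variable ranges are kept intact and
# must match exactly.
.compile_pattern <- function(p) {
  out <- list()
  for (el in p$elements) {
    if (el$min == el$max && el$min > 1L) {
      unit <- el; unit$min <- 1L; unit$max <- 1L
      out <- c(out, rep(list(unit), el$min))
    } else {
      out <- c(out, list(el))
    }
  }
  out
}

#' Match a PROSITE pattern against a protein sequence
#'
#' Reports every span of `seq` matched by the pattern with at most
#' `max_mismatches` violated fixed-length elements. Variable-range
#' elements (e.g. `x(2,4)`) must match exactly and contribute no
#' mismatches; wildcards can never mismatch. For each distinct span the
#' minimal mismatch count over registers is reported. Spans are 1-based
#' inclusive, sorted by start and then by length (shorter first).
#'
#' @param p A `prosite_pattern` or pattern text (parsed on the fly).
#' @param seq An unaligned amino-acid sequence (string).
#' @param max_mismatches Mismatch budget, default 0.
#' @return data.frame with columns `start`, `end`, `mismatches`;
#'   zero rows when nothing matches.
#' @export
match_pattern <- function(p, seq, max_mismatches = 0L) {
  if (is.character(p)) p <- parse_prosite(p)
  stopifnot(inherits(p, "prosite_pattern"), max_mismatches >= 0L)
  s <- strsplit(toupper(seq), "")[[1]]
  if (length(s) > 0 && any(s == "-")) stop("sequence must be ungapped")
  els <- .compile_pattern(p)
  L <- length(s)
  hits <- list()
  # recursive register exploration with mismatch pruning
  explore <- function(start, pos, ei, mm) {
    if (ei > length(els)) {
      if (isTRUE(p$anchor_c) && pos != L + 1L) return(invisible())
      key <- sprintf("%d:%d", start, pos - 1L)
      prev <- hits[[key]]
      if (is.null(prev) || prev > mm) hits[[key]] <<- mm
      return(invisible())
    }
    el <- els[[ei]]
    if (el$min == 1L && el$max == 1L) {
      if (pos > L) return(invisible())
      mm2 <- mm + if (.element_ok(el, s[pos])) 0L else 1L
      # wildcards cannot be "violated"; a failed wildcard is impossible anyway
      if (mm2 <= max_mismatches) explore(start, pos + 1L, ei + 1L, mm2)
    } else {
      for (k in el$min:el$max) {
        if (pos + k - 1L > L) break
        if (k == 0L || all(vapply(seq_len(k),
                                  function(o) .element_ok(el, s[pos + o - 1L]),
                                  logical(1))))
          explore(start, pos + k, ei + 1L, mm)
      }
    }
  }
  starts <- if (isTRUE(p$anchor_n)) 1L else seq_len(max(L, 0L))
  for (st in starts) explore(st, st, 1L, 0L)
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  key <- names(hits)
  start <- as.integer(sub(":.*", "", key))
  end <- as.integer(sub(".*:", "", key))
  out <- data.frame(start = start, end = end,
                    mismatches = as.integer(unlist(hits)))
  out <- out[order(out$start, out$end - out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
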