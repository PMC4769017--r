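# Activation-loop motif catalog, classification and census summaries.

#' Activation-loop motif catalog
#'
#' The default catalog carries the four canonical MAPK phospho-acceptor
#' motifs (TEY, TGY, TDY, TPY) and the nine variants reported from fungal
#' genomes (TTY, TIY, TNY, THY, TSY, KGY, TQY, SEY, SDY), together with
#' the phylogenetic-group memberships (groups A-D) of the fungal motifs.
#' TDY, although canonical in plants and animals, has not been observed in
#' fungal MAPKs; classification flags it.
#'
#' @param canonical Character vector of canonical motifs.
#' @param novel Character vector of novel motifs.
#' @param group_map Named list: motif -> character vector of group labels.
#' @return An object of class `motif_catalog`.
#' @export
motif_catalog <- function(canonical = c("TEY", "TGY", "TDY", "TPY"),
                          novel = c("TTY", "TIY", "TNY", "THY", "TSY",
                                    "KGY", "TQY", "SEY", "SDY"),
                          group_map = list(
                            TEY = c("A", "B", "C", "D"),
                            TGY = c("A", "B", "C", "D"),
                            TNY = c("A", "C"),
                            THY = c("A", "B"),
                            TSY = "A",
                            TQY = "B",
                            KGY = c("A", "C"),
                            TTY = "D", TIY = "D", SEY = "D", SDY = "D")) {
  canonical <- toupper(canonical); novel <- toupper(novel)
  if (length(intersect(canonical, novel)) > 0L)
    stop("canonical and novel motif sets overlap: ",
         paste(intersect(canonical, novel), collapse = ", "))
  if (any(nchar(c(canonical, novel)) != 3L))
    stop("motifs must be 3-residue strings")
  bad <- setdiff(names(group_map), c(canonical, novel))
  if (length(bad) > 0L)
    stop("group_map key(s) not in catalog: ", paste(bad, collapse = ", "))
  labs <- unique(unlist(group_map))
  if (!all(labs %in% c("A", "B", "C", "D")))
    stop("group labels must be drawn from A, B, C, D")
  structure(list(canonical = canonical, novel = novel, group_map = group_map),
            class = "motif_catalog")
}

#' Read a motif catalog from a TSV config
#'
#' Columns: `motif`, `class` (`canonical`/`novel`), `groups`
#' (comma-separated group labels, may be empty). The packaged default is
#' at `system.file("extdata", "motif_catalog.tsv", package = "mapkloop")`.
#'
#' @param path Path to the TSV file.
#' @return A `motif_catalog`.
#' @export
read_motif_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("motif", "class", "groups")
  if (!all(need %in% names(tab)))
    stop("motif catalog needs columns: ", paste(need, collapse = ", "))
  gm <- lapply(tab$groups, function(g) {
    if (is.na(g) || g == "") return(character(0))
    g <- trimws(strsplit(g, ",")[[1]])
    g[g != ""]
  })
  names(gm) <- toupper(tab$motif)
  gm <- gm[vapply(gm, length, integer(1)) > 0L]
  motif_catalog(canonical = tab$motif[tab$class == "canonical"],
                novel = tab$motif[tab$class == "novel"],
                group_map = gm)
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat("Activation-loop motif catalog\n")
  cat("  canonical:", paste(x$canonical, collapse = ", "), "\n")
  cat("  novel:    ", paste(x$novel, collapse = ", "), "\n")
  invisible(x)
}

# Catalog display/report order: TEY, TGY, remaining canonical, then novel.
catalog_order <- function(catalog) {
  c("TEY", "TGY", setdiff(catalog$canonical, c("TEY", "TGY")), catalog$novel)
}

#' Classify activation-loop triplets
#'
#' Exact, case-insensitive lookup against the catalog. TDY is annotated as
#' unobserved in fungal MAPKs (a plant/animal motif).
#'
#' @param triplet Character vector of 3-residue triplets.
#' @param catalog A [motif_catalog()].
#' @return data.frame with columns `triplet` (normalised), `motif_class`
#'   (`canonical`, `novel` or `unknown`) and `note`.
#' @export
classify_motif <- function(triplet, catalog = motif_catalog()) {
  triplet <- toupper(as.character(triplet))
  if (any(nchar(triplet) != 3L))
    stop("triplet(s) not of length 3: ",
         paste(triplet[nchar(triplet) != 3L], collapse = ", "))
  cls <- ifelse(triplet %in% catalog$canonical, "canonical",
         ifelse(triplet %in% catalog$novel, "novel", "unknown"))
  note <- ifelse(triplet == "TDY",
                 "canonical in plants/animals; not observed in fungal MAPKs",
                 "")
  data.frame(triplet = triplet, motif_class = cls, note = note,
             stringsAsFactors = FALSE)
}

#' Per-species census of annotated MAPKs
#'
#' One row per species in order of first appearance: the MAPK count and
#' the de-duplicated motif set in catalog order (TEY first, TGY second,
#' remaining canonical, then novel; motifs absent from the catalog last,
#' in order of appearance).
#'
#' @param annotations data.frame with columns `genus`, `species_epithet`,
#'   `division` and `triplet` (one row per annotated MAPK), e.g. from
#'   [scan_proteins()].
#' @param catalog A [motif_catalog()].
#' @return data.frame with columns `species`, `division`, `n_mapks`,
#'   `motifs` (comma-separated).
#' @export
summarize_by_species <- function(annotations, catalog = motif_catalog()) {
  need <- c("genus", "species_epithet", "division", "triplet")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0L)
    stop("annotations lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(annotations) == 0L)
    return(data.frame(species = character(0), division = character(0),
                      n_mapks = integer(0), motifs = character(0)))
  sp <- paste(annotations$genus, annotations$species_epithet)
  ord <- catalog_order(catalog)
  out <- lapply(unique(sp), function(s) {
    rows <- annotations[sp == s, , drop = FALSE]
    mot <- unique(toupper(rows$triplet))
    mot <- c(ord[ord %in% mot], setdiff(mot, ord))
    data.frame(species = s, division = rows$division[1],
               n_mapks = nrow(rows),
               motifs = paste(mot, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Motif repertoire per phylogenetic group
#'
#' @param annotations data.frame with columns `group` (labels among A-D)
#'   and `triplet`.
#' @param catalog A [motif_catalog()].
#' @return data.frame with columns `group` and `motifs` (catalog order);
#'   groups without annotations are omitted.
#' @export
summarize_by_group <- function(annotations, catalog = motif_catalog()) {
  if (!all(c("group", "triplet") %in% names(annotations)))
    stop("annotations need columns 'group' and 'triplet'")
  bad <- setdiff(unique(annotations$group), c("A", "B", "C", "D"))
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (nrow(annotations) == 0L)
    return(data.frame(group = character(0), motifs = character(0)))
  ord <- catalog_order(catalog)
  groups <- sort(unique(annotations$group))
  out <- lapply(groups, function(g) {
    mot <- unique(toupper(annotations$triplet[annotations$group == g]))
    mot <- c(ord[ord %in% mot], setdiff(mot, ord))
    data.frame(group = g, motifs = paste(mot, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Derive a gene name from the binomial
#'
#' Upper-case initial of the genus plus lower-case initial of the species
#' epithet, followed by "MPK" (e.g. *Aplanochytrium kerguelense* ->
#' "AkMPK"). Paralog suffixes (-A, -B, ...) are appended by the caller.
#'
#' @param genus Character vector of genus names.
#' @param species_epithet Character vector of species epithets.
#' @return Character vector of gene names.
#' @export
make_gene_name <- function(genus, species_epithet) {
  genus <- as.character(genus); species_epithet <- as.character(species_epithet)
  ok <- function(x) length(x) > 0 & !is.na(x) & grepl("^[A-Za-z]", x)
  if (!all(ok(genus)) || !all(ok(species_epithet)))
    stop("genus and species epithet must be non-empty alphabetic strings")
  paste0(toupper(substr(genus, 1L, 1L)),
         tolower(substr(species_epithet, 1L, 1L)), "MPK")
}
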