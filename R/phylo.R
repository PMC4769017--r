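# Distance-based grouping plumbing: p-distances and neighbor joining.
# Group labels (A-D) for motif summaries are assigned by the caller, e.g.
# by cutting the NJ tree or from a file; no likelihood tree is attempted.

#' Pairwise p-distance matrix of an alignment
#'
#' p-distance = differing residues / comparable sites per pair, via
#' [pairwise_differences()].
#'
#' @param aln An `aa_alignment`.
#' @param gap_mode `"pairwise"` (default) or `"complete"` deletion.
#' @return A symmetric numeric matrix with the sequence ids as dimnames.
#' @export
p_distance_matrix <- function(aln, gap_mode = c("pairwise", "complete")) {
  gap_mode <- match.arg(gap_mode)
  pd <- pairwise_differences(aln, gap_mode)
  no <- attr(pd, "no_overlap")
  if (!is.null(no))
    stop("no comparable sites for pair(s): ",
         paste(apply(no, 1L, paste, collapse = "/"), collapse = ", "))
  d <- pd$diffs / pd$sites
  diag(d) <- 0
  d
}

#' Neighbor-joining tree as a newick string
#'
#' Standard neighbor joining (via \pkg{ape}) on a distance matrix; input
#' label order is preserved so ties resolve deterministically, and
#' negative branch lengths are clamped to 0.
#'
#' @param dm Symmetric distance matrix with labels as dimnames (at least
#'   3), or a `dist` object.
#' @return A newick string containing every input label exactly once.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L)
    stop("neighbor joining needs at least 3 labels, got ", nrow(dm))
  if (is.null(rownames(dm)))
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  tree <- ape::nj(as.dist(dm))
  tree$edge.length[tree$edge.length < 0] <- 0
  ape::write.tree(tree)
}
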