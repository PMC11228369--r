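#' Gap scores for differential signature genes
#'
#' For each gene, the gap is the highest exemplar value minus the
#' second-highest. A large gap means one cell type expresses the gene
#' distinctly above all others, which is exactly what a deconvolution
#' signature gene needs. Values here are the exemplars' average ranks (the
#' pipeline is rank-based throughout). A tie at the maximum gives gap 0.
#'
#' @param exemplar_mat Numeric matrix, genes x exemplars (>= 2 exemplars).
#' @return Data frame with `gene_id`, `gap` and `argmax` (the
#'   highest-expressing exemplar; at a tie, the first in column order).
#' @export
gap_scores <- function(exemplar_mat) {
  stopifnot(is.matrix(exemplar_mat))
  if (ncol(exemplar_mat) < 2L) stop("gap scores need at least 2 exemplars")
  top2 <- t(apply(exemplar_mat, 1, function(v) {
    o <- order(v, decreasing = TRUE)
    c(v[o[1]], v[o[2]], o[1])
  }))
  data.frame(
    gene_id = rownames(exemplar_mat),
    gap = top2[, 1] - top2[, 2],
    argmax = colnames(exemplar_mat)[top2[, 3]],
    stringsAsFactors = FALSE
  )
}

#' Select signature genes by gap score
#'
#' Keeps the `ceiling(fraction * G)` genes with the largest gap; boundary
#' ties are broken lexicographically by gene id. A fully degenerate input
#' (all gaps equal) still returns a deterministic selection, with a warning.
#'
#' @param gaps Data frame from [gap_scores()].
#' @param fraction Fraction of genes to keep, in (0, 1]. Default 0.20.
#' @return Character vector of selected gene ids.
#' @export
select_signature_genes <- function(gaps, fraction = 0.20) {
  stopifnot(fraction > 0, fraction <= 1)
  g <- nrow(gaps)
  k <- ceiling(fraction * g)
  if (length(unique(gaps$gap)) == 1L) {
    warning("all gap scores equal; selection falls back to gene id order")
  }
  ord <- order(-gaps$gap, gaps$gene_id)
  sort(gaps$gene_id[ord[seq_len(k)]])
}

#' Assemble the deconvolution signature matrix
#'
#' Restricts the exemplar matrix to the selected signature genes, keeping
#' the exemplar column order.
#'
#' @param exemplar_mat Numeric matrix, genes x exemplars.
#' @param selected Character vector of signature gene ids (subset of the
#'   matrix's rownames).
#' @return Genes x exemplars numeric matrix (a `SignatureMatrix`).
#' @export
build_signature_matrix <- function(exemplar_mat, selected) {
  if (length(selected) == 0L) stop("empty signature gene selection")
  missing <- setdiff(selected, rownames(exemplar_mat))
  if (length(missing)) {
    stop("selected genes absent from exemplar matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  exemplar_mat[selected, , drop = FALSE]
}

#' One-call signature matrix from exemplars
#'
#' @param exemplars List of `exemplar_signature` objects.
#' @param fraction Signature gene fraction. Default 0.20.
#' @return Genes x exemplars signature matrix.
#' @export
signature_matrix_from_exemplars <- function(exemplars, fraction = 0.20) {
  em <- exemplar_matrix(exemplars)
  sel <- select_signature_genes(gap_scores(em), fraction = fraction)
  build_signature_matrix(em, sel)
}
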