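# Probe-to-gene collapse and the expression/variability pre-filters.

#' Collapse a probe-level matrix to one row per gene by maximal IQR
#'
#' When several probes map to the same gene symbol, the probe with the
#' largest inter-quartile range of expression across all samples represents
#' the gene (more robust than averaging).  Ties go to the lexicographically
#' smallest probe id.  Probes without annotation are dropped with a message;
#' probes annotated to more than one gene are dropped by default or
#' duplicated into each gene with `multi_gene = "duplicate"`.
#'
#' @param probes numeric matrix, probe rows x sample columns.
#' @param annotation data frame with columns `probe_id`, `gene_symbol`.
#' @param multi_gene policy for probes mapping to several genes.
#' @return numeric matrix with one row per gene symbol (first-appearance
#'   order of the selected probes).
#' @export
collapse_probes <- function(probes, annotation,
                            multi_gene = c("drop", "duplicate")) {
  multi_gene <- match.arg(multi_gene)
  stopifnot(is.matrix(probes), !is.null(rownames(probes)))
  if (!all(c("probe_id", "gene_symbol") %in% names(annotation))) {
    stop("annotation must have columns probe_id, gene_symbol")
  }
  ann <- unique(annotation[c("probe_id", "gene_symbol")])
  ann <- ann[ann$probe_id %in% rownames(probes), , drop = FALSE]
  multi <- unique(ann$probe_id[duplicated(ann$probe_id)])
  if (length(multi)) {
    if (multi_gene == "drop") {
      message("collapse_probes: dropped ", length(multi),
              " probe(s) annotated to multiple genes")
      ann <- ann[!ann$probe_id %in% multi, , drop = FALSE]
    } else {
      message("collapse_probes: duplicated ", length(multi),
              " multi-gene probe(s) into each mapped gene")
    }
  }
  unannotated <- setdiff(rownames(probes), ann$probe_id)
  if (length(unannotated)) {
    message("collapse_probes: dropped ", length(unannotated),
            " unannotated probe(s)")
  }
  if (nrow(ann) == 0L) stop("no annotated probes left to collapse")
  iqr <- apply(probes, 1L, IQR, na.rm = TRUE)
  # deterministic winner per gene: max IQR, ties to smallest probe id
  ann <- ann[order(ann$gene_symbol, -iqr[ann$probe_id], ann$probe_id), ]
  winners <- ann[!duplicated(ann$gene_symbol), , drop = FALSE]
  # restore first-appearance order of the winning probes in the input matrix
  winners <- winners[order(match(winners$probe_id, rownames(probes))), ]
  out <- probes[winners$probe_id, , drop = FALSE]
  rownames(out) <- winners$gene_symbol
  out
}

#' Remove low-expression and low-variability genes
#'
#' Two sequential rank filters: genes are ranked by mean intensity across
#' samples and the lowest `floor(low_expression_fraction * G)` removed
#' (un-expressed genes); the survivors are ranked by standard deviation and
#' the lowest `floor(low_variability_fraction * G)` removed (un-informative
#' genes).  Both fractions refer to the input gene count `G`, so 10 genes at
#' 0.2/0.2 go 10 to 8 to 6.  The original row order of the surviving genes
#' is preserved.
#' Genes containing missing values are dropped first with a message (rank
#' comparisons need complete vectors).
#'
#' @param expr numeric matrix, gene rows x sample columns.
#' @param low_expression_fraction,low_variability_fraction fractions in
#'   `[0, 1)` removed at each step (default 0.20 each).
#' @return the filtered matrix.
#' @export
filter_genes <- function(expr, low_expression_fraction = 0.20,
                         low_variability_fraction = 0.20) {
  stopifnot(is.matrix(expr))
  if (low_expression_fraction < 0 || low_expression_fraction >= 1 ||
      low_variability_fraction < 0 || low_variability_fraction >= 1) {
    stop("filter fractions must be in [0, 1)")
  }
  has_na <- rowSums(is.na(expr)) > 0L
  if (any(has_na)) {
    message("filter_genes: dropped ", sum(has_na), " gene(s) with missing values")
    expr <- expr[!has_na, , drop = FALSE]
  }
  if (nrow(expr) == 0L) stop("no complete genes to filter")
  G <- nrow(expr)
  drop_lowest <- function(mat, stat, k) {
    k <- min(k, nrow(mat) - 1L)
    if (k <= 0L) return(mat)
    # ties broken by row name for determinism
    ord <- order(stat, rownames(mat))
    mat[setdiff(seq_len(nrow(mat)), ord[seq_len(k)]), , drop = FALSE]
  }
  expr <- drop_lowest(expr, rowMeans(expr), floor(low_expression_fraction * G))
  expr <- drop_lowest(expr, apply(expr, 1L, sd),
                      floor(low_variability_fraction * G))
  if (nrow(expr) == 0L) stop("all genes removed by the filters")
  expr
}
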