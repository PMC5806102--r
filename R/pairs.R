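# Binary gene-pair indicator features.  A pair (a, b) scores 1 in a sample
# iff gene a is expressed strictly above gene b there; ties and reversals
# score 0.  Because only the within-sample ordering enters, the features
# are exactly invariant to strictly monotone per-sample transforms.

#' Enumerate all unordered gene pairs
#'
#' Produces the `G * (G - 1) / 2` unordered pairs of the input genes, each
#' once, oriented so the gene occurring earlier in the input occupies
#' `gene_a`.  Ordering is deterministic (1-2, 1-3, ..., 2-3, ...).
#'
#' @param genes character vector of unique gene ids (length >= 2).
#' @return data frame with columns `gene_a`, `gene_b`.
#' @examples
#' nrow(enumerate_pairs(letters[1:5]))  # 10
#' @export
enumerate_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene ids in input")
  if (length(genes) < 2L) stop("at least 2 genes are required")
  idx <- combn(seq_along(genes), 2L)
  data.frame(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Pair indicator for a single value pair
#'
#' 1 iff `x_a > x_b` strictly; 0 otherwise (including exact ties).
#'
#' @param x_a,x_b expression values.
#' @return integer 0/1.
#' @export
pair_indicator <- function(x_a, x_b) {
  if (anyNA(x_a) || anyNA(x_b)) stop("missing expression value in pair comparison")
  as.integer(x_a > x_b)
}

#' Build the pairs x samples indicator matrix
#'
#' @param expr numeric matrix, gene rows x sample columns.
#' @param pairs data frame with columns `gene_a`, `gene_b` (e.g. from
#'   [enumerate_pairs()]).
#' @return integer 0/1 matrix with one row per pair (named `"A|B"`) and one
#'   column per sample.
#' @export
build_pair_matrix <- function(expr, pairs) {
  stopifnot(is.matrix(expr))
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(expr))
  if (length(missing)) {
    stop("pair gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  if (anyNA(expr[unique(c(pairs$gene_a, pairs$gene_b)), ])) {
    stop("missing expression values among pair genes; drop incomplete genes first")
  }
  m <- (expr[pairs$gene_a, , drop = FALSE] > expr[pairs$gene_b, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  m
}

#' Drop near-constant pair indicators
#'
#' Removes pairs whose indicator is 1 in fewer than `min_fraction` or more
#' than `1 - min_fraction` of samples.  The default 0 removes only constant
#' (all-0 or all-1) pairs, which carry no information for the penalised fit.
#'
#' @param m pair indicator matrix from [build_pair_matrix()].
#' @param min_fraction fraction in `[0, 0.5]`.
#' @return the pruned matrix.
#' @export
prune_degenerate_pairs <- function(m, min_fraction = 0) {
  stopifnot(is.matrix(m))
  if (min_fraction < 0 || min_fraction > 0.5) stop("min_fraction must be in [0, 0.5]")
  freq <- rowMeans(m)
  keep <- freq > 0 & freq < 1 & freq >= min_fraction & freq <= 1 - min_fraction
  if (any(!keep)) {
    message("prune_degenerate_pairs: removed ", sum(!keep), " of ", nrow(m),
            " pair(s)")
  }
  m[keep, , drop = FALSE]
}

# Split "A|B" pair row names back into a pairs data frame.
pairs_from_rownames <- function(m) {
  parts <- strsplit(rownames(m), "|", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1L),
             gene_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}
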