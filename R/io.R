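# Readers and writers for the tabular formats the pipeline touches:
# GEO series-matrix-style expression files, plain TSV expression/survival
# tables, and the signature file (TSV + JSON sidecar).

#' Read an expression matrix from a GEO series-matrix file or plain TSV
#'
#' Handles the GEO series-matrix dialect: lines starting with `!` are
#' metadata; the data table sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` (when those markers are absent, all
#' non-metadata lines are parsed).  Plain TSV files (header of sample ids,
#' first column of row ids) are read the same way.  Non-numeric cells become
#' `NA` with a warning.
#'
#' @param path file path.
#' @return numeric matrix, rows = probes or genes, columns = samples.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- startsWith(lines, "!")
  if (any(meta)) {
    begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(begin) == 1L && length(end) == 1L && end > begin + 1L) {
      tab <- lines[(begin + 1L):(end - 1L)]
    } else {
      tab <- lines[!meta]
    }
  } else {
    tab <- lines
  }
  tab <- tab[nzchar(trimws(tab))]
  if (length(tab) < 2L) stop("empty expression table in ", path)
  df <- read.delim(text = tab, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 2L) stop("expression table needs a row-id column plus samples")
  row_ids <- gsub('^"|"$', "", as.character(df[[1L]]))
  sample_ids <- gsub('^"|"$', "", colnames(df)[-1L])
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row ids in ", path)
  }
  vals <- df[-1L][] # copy
  n_bad <- 0L
  mat <- vapply(vals, function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    suppressWarnings(num <- as.numeric(col))
    n_bad <<- n_bad + sum(is.na(num) & !is.na(col) & toupper(col) != "NA")
    num
  }, numeric(nrow(df)))
  mat <- matrix(mat, nrow = nrow(df), dimnames = list(row_ids, sample_ids))
  if (n_bad > 0L) {
    warning(n_bad, " non-numeric cell(s) set to NA while reading ", path)
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' @param expr numeric matrix with row (gene/probe) and column (sample) names.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample survival data from TSV
#'
#' Expects columns `sample_id`, `time`, `event`; any extra columns are kept
#' as clinical covariates.  Event labels other than 0/1 are translated via
#' `event_map` (e.g. `c(Death = 1, Alive = 0)`); unknown labels are an error.
#'
#' @param path file path.
#' @param event_map named vector mapping event labels to 0/1.
#' @return validated data frame with `sample_id`, `time`, `event` first and
#'   clinical covariates after.
#' @export
read_survival <- function(path, event_map = c("0" = 0, "1" = 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival file must have columns sample_id, time, event; found: ",
         paste(names(df), collapse = ", "))
  }
  lab <- as.character(df$event)
  unknown <- setdiff(unique(lab), names(event_map))
  if (length(unknown)) {
    stop("unknown event label(s): ", paste(unknown, collapse = ", "),
         "; extend event_map")
  }
  df$event <- as.integer(event_map[lab])
  df <- df[c(need, setdiff(names(df), need))]
  as_survival_df(df)
}

#' Construct a gene-pair signature model
#'
#' A signature is an ordered list of gene pairs with Cox coefficients, an
#' optional risk-score cutoff and an optional evaluation horizon.  The risk
#' score of a sample is `sum_k coefficient_k * I(expr[gene_a_k] >
#' expr[gene_b_k])`.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`, `coefficient`.
#' @param cutoff risk-score threshold dividing high (`score >= cutoff`) from
#'   low risk, or `NULL` if not yet estimated.
#' @param horizon ROC evaluation time in the survival table's units, or
#'   `NULL`.
#' @return object of class `pair_signature`.
#' @export
pair_signature <- function(pairs, cutoff = NULL, horizon = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "coefficient") %in% names(pairs))) {
    stop("pairs must have columns gene_a, gene_b, coefficient")
  }
  if (nrow(pairs) == 0L) stop("a signature needs at least one gene pair")
  if (any(pairs$gene_a == pairs$gene_b)) stop("gene_a and gene_b must differ")
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  if (anyDuplicated(key)) stop("duplicate gene pairs in signature")
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  pairs$coefficient <- as.numeric(pairs$coefficient)
  structure(list(pairs = pairs, cutoff = cutoff, horizon = horizon),
            class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat("Gene-pair signature:", nrow(x$pairs), "pairs,",
      length(unique(c(x$pairs$gene_a, x$pairs$gene_b))), "distinct genes\n")
  if (!is.null(x$cutoff)) cat("  cutoff:", format(x$cutoff), "(score >= cutoff -> high risk)\n")
  if (!is.null(x$horizon)) cat("  horizon:", x$horizon, "\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Write / read a signature (TSV + JSON sidecar)
#'
#' The TSV holds `gene_a`, `gene_b`, `coefficient` (17 significant digits,
#' lossless for doubles); the sidecar `<path-sans-ext>.json` holds the
#' cutoff, horizon and a free-text provenance note.
#'
#' @param model a [pair_signature()].
#' @param path TSV path.
#' @param provenance free-text note stored in the sidecar.
#' @return `write_signature`: invisibly, the TSV path.
#' @export
write_signature <- function(model, path, provenance = "gpsig") {
  stopifnot(inherits(model, "pair_signature"))
  df <- model$pairs
  df$coefficient <- sprintf("%.17g", df$coefficient)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(cutoff = model$cutoff, horizon = model$horizon, provenance = provenance),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signature
#' @return `read_signature`: the [pair_signature()] with cutoff/horizon from
#'   the sidecar when present.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  cutoff <- NULL; horizon <- NULL
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    cutoff <- meta$cutoff; horizon <- meta$horizon
  }
  pair_signature(df, cutoff = cutoff, horizon = horizon)
}

#' The published seven-pair gastric-cancer signature
#'
#' The seven gene pairs with L1-penalised Cox coefficients reported for a
#' GPL570 gastric-cancer training cohort (n = 300), together with the
#' published risk-score cutoff of -0.154 selected on the 5-year
#' time-dependent ROC curve (60 with follow-up in months).  Shipped as a
#' read-only fixture: the coefficients come from a cross-validated stochastic
#' selection and are not expected to be reproduced exactly by refitting.
#'
#' @return a [pair_signature()] with 7 pairs over 12 distinct genes.
#' @examples
#' sig <- gastric_signature()
#' sum(sig$pairs$coefficient)
#' @export
gastric_signature <- function() {
  path <- system.file("extdata", "gastric_seven_pairs.tsv", package = "gpsig",
                      mustWork = TRUE)
  read_signature(path)
}

#' Load an expression + survival cohort bundle
#'
#' Reads the expression matrix and survival table and aligns them on sample
#' ids: samples present in only one of the two are dropped with a message,
#' and the survival rows are reordered to the expression column order.
#'
#' @param expr_path expression file (series-matrix dialect or TSV).
#' @param surv_path survival TSV.
#' @param event_map passed to [read_survival()].
#' @return list with aligned `expression`, `survival` and `clinical`
#'   (extra survival columns, or `NULL`).
#' @export
read_cohort <- function(expr_path, surv_path, event_map = c("0" = 0, "1" = 1)) {
  expr <- read_series_matrix(expr_path)
  surv <- read_survival(surv_path, event_map = event_map)
  common <- intersect(colnames(expr), surv$sample_id)
  if (length(common) == 0L) stop("no samples shared by expression and survival")
  dropped <- (ncol(expr) - length(common)) + (nrow(surv) - length(common))
  if (dropped > 0L) {
    message("read_cohort: dropped ", dropped,
            " sample(s) present in only one of expression/survival")
  }
  expr <- expr[, common, drop = FALSE]
  surv <- surv[match(common, surv$sample_id), , drop = FALSE]
  rownames(surv) <- NULL
  clin_cols <- setdiff(names(surv), c("sample_id", "time", "event"))
  list(expression = expr,
       survival = surv[c("sample_id", "time", "event")],
       clinical = if (length(clin_cols)) surv[c("sample_id", clin_cols)] else NULL)
}
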