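# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce and validate per-sample survival data
#'
#' Accepts a data frame with at least `time` and `event` columns (an optional
#' `sample_id` column is kept; extra columns are treated as clinical
#' covariates and preserved).  Times must be strictly positive and events
#' coded 0/1.
#'
#' @param surv a data frame with columns `time` and `event`.
#' @return the validated data frame, with `sample_id` as character if present.
#' @keywords internal
as_survival_df <- function(surv) {
  if (inherits(surv, "Surv")) {
    surv <- data.frame(time = surv[, "time"], event = surv[, "status"])
  }
  if (!is.data.frame(surv)) {
    stop("survival data must be a data frame with columns 'time' and 'event'")
  }
  if (!all(c("time", "event") %in% names(surv))) {
    stop("survival data must contain columns 'time' and 'event'")
  }
  if (!is.numeric(surv$time)) stop("'time' must be numeric")
  bad <- which(!is.finite(surv$time) | surv$time <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite follow-up time in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!all(surv$event %in% c(0, 1))) {
    stop("'event' must be coded 0 (censored) / 1 (event)")
  }
  surv$event <- as.integer(surv$event)
  if ("sample_id" %in% names(surv)) {
    surv$sample_id <- as.character(surv$sample_id)
    if (anyDuplicated(surv$sample_id)) stop("duplicate sample_id in survival data")
  }
  surv
}

# Check that an expression matrix and survival table describe the same
# samples in the same order; returns invisibly.
check_aligned <- function(expr, surv) {
  if (ncol(expr) != nrow(surv)) {
    stop("expression (", ncol(expr), " samples) and survival (", nrow(surv),
         " rows) are not aligned")
  }
  if ("sample_id" %in% names(surv) && !is.null(colnames(expr))) {
    if (!identical(colnames(expr), surv$sample_id)) {
      stop("sample identifiers of expression and survival differ or are reordered")
    }
  }
  invisible(TRUE)
}

# Deterministic child seeds derived from one parent seed (kept within the
# 32-bit integer range R requires).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483647)
}
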