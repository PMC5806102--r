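# End-to-end orchestration: training (preprocess -> screen -> pairs -> fit
# -> cutoff -> evaluate) and validation of a frozen signature on a new
# cohort.  Every stochastic stage takes an explicit seed recorded in the
# manifest, so reruns are byte-identical.

#' Default pipeline parameters
#'
#' @param low_expr_frac,low_var_frac pre-filter fractions (see
#'   [filter_genes()]).
#' @param alpha,B screening threshold and permutation count (see
#'   [screen_prognostic_genes()]).
#' @param min_fraction pair pruning threshold (see
#'   [prune_degenerate_pairs()]).
#' @param n_folds,rule penalised-Cox cross-validation settings.
#' @param horizon ROC horizon in the survival table's time unit (60 for
#'   5 years of monthly follow-up).
#' @param span NNE span, `NULL` for the `0.25 * n^(-0.2)` default.
#' @param seed master seed; stage seeds are derived from it.
#' @return a named list of parameters for [run_training()].
#' @export
pipeline_params <- function(low_expr_frac = 0.20, low_var_frac = 0.20,
                            alpha = 0.05, B = 1000L, min_fraction = 0,
                            n_folds = 10L, rule = "1se", horizon = 60,
                            span = NULL, seed = 1L) {
  list(low_expr_frac = low_expr_frac, low_var_frac = low_var_frac,
       alpha = alpha, B = as.integer(B), min_fraction = min_fraction,
       n_folds = as.integer(n_folds), rule = rule, horizon = horizon,
       span = span, seed = as.integer(seed))
}

#' Train a gene-pair signature end to end
#'
#' Runs the full training workflow on an aligned cohort: gene pre-filters,
#' median-split log-rank screening with permutation p-values, pair
#' enumeration and indicator construction, L1-penalised Cox selection,
#' time-dependent ROC at the horizon, corner-distance cutoff, risk-group
#' classification and KM / hazard-ratio / concordance evaluation.
#'
#' @param expr gene x sample expression matrix (probe-collapsed).
#' @param surv aligned survival data frame (`sample_id`, `time`, `event`).
#' @param params list from [pipeline_params()].
#' @param out_dir optional directory; when given, the signature, screening
#'   table, ROC curve, KM curves and a manifest JSON are written there.
#' @return list with `signature` (cutoff and horizon filled in), `scores`,
#'   `groups`, `roc`, `comparison` (a `group_comparison`), `cindex`,
#'   `screen`, `diagnostics`, `counts`, `manifest`.
#' @export
run_training <- function(expr, surv, params = pipeline_params(),
                         out_dir = NULL) {
  if (is.null(expr) || is.null(surv)) {
    stop("run_training needs both an expression matrix and survival data")
  }
  surv <- as_survival_df(surv)
  check_aligned(expr, surv)
  seed <- params$seed

  filtered <- filter_genes(expr, params$low_expr_frac, params$low_var_frac)
  screen <- screen_prognostic_genes(filtered, surv, alpha = params$alpha,
                                    B = params$B,
                                    seed = derive_seed(seed, 1L))
  if (nrow(screen) < 2L) {
    stop("stage screening: fewer than 2 prognostic genes at alpha = ",
         params$alpha)
  }
  pairs <- enumerate_pairs(screen$gene)
  m <- build_pair_matrix(filtered, pairs)
  m <- prune_degenerate_pairs(m, params$min_fraction)
  if (nrow(m) == 0L) stop("stage pairs: no informative pairs left")

  fit <- tryCatch(
    fit_penalized_cox(m, surv, n_folds = params$n_folds,
                      seed = derive_seed(seed, 2L), rule = params$rule),
    error = function(e) {
      if (!grepl("no pairs selected", conditionMessage(e)) ||
          identical(params$rule, "min")) stop(e)
      message("run_training: empty model at the 1SE penalty; ",
              "falling back to the CV-minimum penalty")
      fit_penalized_cox(m, surv, n_folds = params$n_folds,
                        seed = derive_seed(seed, 2L), rule = "min")
    })
  model <- fit$model
  scores <- risk_score(model, filtered)
  roc <- td_roc_nne(scores, surv, t = params$horizon, span = params$span)
  cutoff <- optimal_cutoff(roc)
  model$cutoff <- cutoff
  model$horizon <- params$horizon
  groups <- classify(scores, cutoff)
  comparison <- group_hr(surv, groups)
  cindex <- harrell_cindex(scores, surv)
  km <- km_estimate(surv, groups)

  counts <- c(genes_in = nrow(expr), genes_filtered = nrow(filtered),
              genes_prognostic = nrow(screen), pairs_candidate = nrow(pairs),
              pairs_after_prune = nrow(m), pairs_selected = nrow(model$pairs))
  manifest <- list(
    package = "gpsig",
    version = as.character(utils::packageVersion("gpsig")),
    params = params[setdiff(names(params), "span")],
    rule_used = fit$diagnostics$rule,
    span = params$span %||% roc$span,
    stage_seeds = list(screening = derive_seed(seed, 1L),
                       cv_folds = derive_seed(seed, 2L)),
    counts = as.list(counts)
  )
  report <- list(signature = model, scores = scores, groups = groups,
                 roc = roc, comparison = comparison, cindex = cindex,
                 km = km, screen = screen, diagnostics = fit$diagnostics,
                 counts = counts, manifest = manifest)
  if (!is.null(out_dir)) write_training_outputs(report, out_dir)
  report
}

write_training_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_signature(report$signature, file.path(out_dir, "signature.tsv"),
                  provenance = "gpsig::run_training")
  write.table(report$screen, file.path(out_dir, "screening.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  roc_df <- data.frame(threshold = report$roc$thresholds,
                       fpr = report$roc$fpr, tpr = report$roc$tpr)
  write.table(roc_df, file.path(out_dir, "roc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$km, file.path(out_dir, "km.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' Validate a frozen signature on a new cohort
#'
#' Applies a trained signature — formula and cutoff unchanged, nothing
#' re-estimated — to an independent cohort: risk scores, classification at
#' the stored cutoff, KM curves, hazard ratio and concordance index.
#'
#' @param signature a [pair_signature()] with a cutoff (e.g. from
#'   [run_training()] or [read_signature()]).
#' @param expr expression matrix of the validation cohort; must contain all
#'   signature genes.
#' @param surv aligned survival data frame.
#' @param horizon optional ROC horizon; defaults to the signature's, and the
#'   ROC/AUC step is skipped when neither is available.
#' @param span NNE span.
#' @return list with `scores`, `groups`, `comparison`, `cindex`, `km`, and
#'   `roc` (`NULL` when no horizon).
#' @export
run_validation <- function(signature, expr, surv, horizon = NULL,
                           span = NULL) {
  stopifnot(inherits(signature, "pair_signature"))
  if (is.null(signature$cutoff)) {
    stop("the signature has no cutoff; train or load one first")
  }
  surv <- as_survival_df(surv)
  check_aligned(expr, surv)
  scores <- risk_score(signature, expr)
  groups <- classify(scores, signature$cutoff)
  if (length(unique(groups)) < 2L) {
    warning("all samples fall on one side of the cutoff in this cohort")
    comparison <- NULL
  } else {
    comparison <- group_hr(surv, groups)
  }
  horizon <- horizon %||% signature$horizon
  roc <- if (!is.null(horizon)) td_roc_nne(scores, surv, t = horizon,
                                           span = span) else NULL
  list(scores = scores, groups = groups, comparison = comparison,
       cindex = harrell_cindex(scores, surv),
       km = km_estimate(surv, groups), roc = roc)
}
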