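# Sparse signature selection by L1-penalised Cox regression on the pair
# indicators, the resulting risk score, and the two published controls
# (leave-one-pair-out sensitivity, random pseudo-signature).

# Event-stratified, seeded fold assignment: events and censored samples are
# each spread evenly over folds so every fold sees events.
stratified_foldid <- function(event, n_folds, seed) {
  foldid <- integer(length(event))
  withr::with_seed(seed, {
    for (grp in list(which(event == 1L), which(event == 0L))) {
      if (length(grp)) {
        foldid[grp] <- sample(rep_len(seq_len(n_folds), length(grp)))
      }
    }
  })
  foldid
}

#' Select gene pairs by cross-validated L1-penalised Cox regression
#'
#' Maximises the L1-penalised Cox partial likelihood (Breslow ties) along a
#' log-spaced penalty path and picks the penalty by `n_folds`-fold
#' cross-validation of the partial-likelihood deviance: by default the 1-SE
#' rule — the largest penalty whose mean CV deviance is within one standard
#' error of the minimum.  The pairs with nonzero coefficients at that
#' penalty form the signature.
#'
#' @param m pair indicator matrix (pairs x samples).
#' @param surv aligned survival data frame.
#' @param n_folds cross-validation folds (default 10), stratified by event
#'   status.
#' @param seed integer seed for the fold assignment.
#' @param rule `"1se"` (default) or `"min"`.
#' @param penalty optional fixed penalty; when given, cross-validation is
#'   skipped and the model is extracted at this penalty (0 gives the
#'   unpenalised fit).
#' @param nlambda,lambda_min_ratio penalty-path construction (100 values
#'   down to 0.01 x the smallest all-zero penalty).
#' @return list with `model` (a [pair_signature()] without cutoff) and
#'   `diagnostics` (penalty path, CV deviance mean/SE, nonzero counts,
#'   chosen penalty, fold ids, seed).
#' @export
fit_penalized_cox <- function(m, surv, n_folds = 10L, seed = 1L,
                              rule = c("1se", "min"), penalty = NULL,
                              nlambda = 100L, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  surv <- as_survival_df(surv)
  check_aligned(m, surv)
  if (sum(surv$event) < 2L) stop("at least 2 events are required")
  sds <- apply(m, 1L, sd)
  if (all(sds == 0)) stop("all pair indicators are constant")
  x <- t(m)
  y <- survival::Surv(surv$time, surv$event)

  if (!is.null(penalty)) {
    # fixed-penalty fit along a short path ending at the requested penalty
    sd0 <- glmnet::glmnet(x, y, family = "cox", nlambda = 5L)
    lmax <- max(sd0$lambda)
    lam <- exp(seq(log(lmax), log(max(penalty, lmax * 1e-4)), length.out = 30L))
    if (penalty < min(lam)) lam <- c(lam, penalty)
    fit <- glmnet::glmnet(x, y, family = "cox", lambda = lam)
    beta <- as.numeric(coef(fit, s = penalty, exact = TRUE, x = x, y = y))
    names(beta) <- rownames(m)
    diag <- list(penalty = penalty, rule = "fixed", seed = seed)
  } else {
    foldid <- stratified_foldid(surv$event, n_folds, seed)
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio)
    chosen <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    beta <- as.numeric(coef(cv, s = chosen))
    names(beta) <- rownames(m)
    diag <- list(lambda = cv$lambda, cv_deviance = cv$cvm, cv_se = cv$cvsd,
                 n_nonzero = cv$nzero, penalty_min = cv$lambda.min,
                 penalty_1se = cv$lambda.1se, penalty = chosen, rule = rule,
                 foldid = foldid, seed = seed)
  }
  nz <- which(beta != 0)
  if (length(nz) == 0L) {
    stop("no pairs selected at the chosen penalty (rule = ", diag$rule,
         "); try rule = \"min\" or a denser cohort")
  }
  pairs <- pairs_from_rownames(m[nz, , drop = FALSE])
  pairs$coefficient <- beta[nz]
  list(model = pair_signature(pairs), diagnostics = diag)
}

#' Risk score of a signature on an expression matrix
#'
#' `score_s = sum_k coef_k * I(expr[gene_a_k, s] > expr[gene_b_k, s])`.
#' Computable on any cohort containing the signature genes, with no
#' renormalisation — the score depends only on within-sample orderings.
#'
#' @param model a [pair_signature()].
#' @param expr numeric matrix, gene rows x sample columns.
#' @return named numeric vector of per-sample scores.
#' @export
risk_score <- function(model, expr) {
  stopifnot(inherits(model, "pair_signature"))
  ind <- build_pair_matrix(expr, model$pairs)
  scores <- as.numeric(crossprod(ind, model$pairs$coefficient))
  names(scores) <- colnames(expr)
  scores
}

#' Leave-one-pair-out sensitivity analysis
#'
#' For each signature entry, recomputes the risk score with that entry
#' omitted (remaining coefficients unchanged) and reports the concordance
#' index and the time-dependent AUC at the horizon next to the full model's.
#'
#' @param model a [pair_signature()] with >= 2 entries.
#' @param expr expression matrix of the evaluation cohort.
#' @param surv aligned survival data.
#' @param horizon ROC horizon (defaults to the model's).
#' @param span NNE span (defaults as in [td_roc_nne()]).
#' @return data frame with one row per omitted pair: `omitted`, `cindex`,
#'   `auc`, `delta_cindex`, `delta_auc`; full-model metrics in attributes
#'   `"full_cindex"` / `"full_auc"`.
#' @export
sensitivity_leave_one_pair_out <- function(model, expr, surv,
                                           horizon = NULL, span = NULL) {
  stopifnot(inherits(model, "pair_signature"))
  if (nrow(model$pairs) < 2L) stop("sensitivity analysis needs >= 2 entries")
  surv <- as_survival_df(surv)
  horizon <- horizon %||% model$horizon
  if (is.null(horizon)) stop("an evaluation horizon is required")
  ind <- build_pair_matrix(expr, model$pairs)
  coefs <- model$pairs$coefficient
  full_scores <- as.numeric(crossprod(ind, coefs))
  metric <- function(scores) {
    c(cindex = harrell_cindex(scores, surv)$cindex,
      auc = td_roc_nne(scores, surv, t = horizon, span = span)$auc)
  }
  full <- metric(full_scores)
  rows <- lapply(seq_len(nrow(model$pairs)), function(k) {
    sc <- full_scores - coefs[k] * ind[k, ]
    m <- metric(sc)
    data.frame(omitted = rownames(ind)[k], cindex = m[["cindex"]],
               auc = m[["auc"]],
               delta_cindex = m[["cindex"]] - full[["cindex"]],
               delta_auc = m[["auc"]] - full[["auc"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full_cindex") <- full[["cindex"]]
  attr(out, "full_auc") <- full[["auc"]]
  out
}

#' Random pseudo-signature control
#'
#' Samples `2 * n_pairs` genes without replacement from the prognostic gene
#' list, pairs them consecutively, fits the `n_pairs` indicator coefficients
#' by unpenalised Cox regression (Breslow ties), and evaluates the
#' time-dependent AUC at the horizon.  On a cohort where the sampled genes
#' carry no signal the AUC should sit near 0.5 — the control for how much
#' performance the signature machinery manufactures by itself.
#'
#' @param prognostic_genes character vector to sample from (>= `2 * n_pairs`).
#' @param expr expression matrix containing those genes.
#' @param surv aligned survival data.
#' @param n_pairs number of random pairs (default 7).
#' @param horizon ROC horizon.
#' @param span NNE span (defaults as in [td_roc_nne()]).
#' @param seed integer seed for the gene sample.
#' @return list with `model` (a [pair_signature()]), `auc`, and `roc`.
#' @export
pseudo_signature <- function(prognostic_genes, expr, surv, n_pairs = 7L,
                             horizon = 60, span = NULL, seed = 1L) {
  prognostic_genes <- as.character(prognostic_genes)
  if (length(prognostic_genes) < 2L * n_pairs) {
    stop("need at least ", 2L * n_pairs, " prognostic genes, have ",
         length(prognostic_genes))
  }
  surv <- as_survival_df(surv)
  picked <- withr::with_seed(seed,
    sample(prognostic_genes, 2L * n_pairs, replace = FALSE))
  pairs <- data.frame(gene_a = picked[seq(1L, 2L * n_pairs, by = 2L)],
                      gene_b = picked[seq(2L, 2L * n_pairs, by = 2L)],
                      stringsAsFactors = FALSE)
  ind <- build_pair_matrix(expr, pairs)
  ind <- prune_degenerate_pairs(ind)
  if (nrow(ind) == 0L) stop("all sampled pairs are constant in this cohort")
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ t(ind),
                         ties = "breslow")
  pairs <- pairs_from_rownames(ind)
  pairs$coefficient <- unname(coef(fit))
  model <- pair_signature(pairs, horizon = horizon)
  scores <- risk_score(model, expr)
  roc <- td_roc_nne(scores, surv, t = horizon, span = span)
  list(model = model, auc = roc$auc, roc = roc)
}
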