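# Evaluation machinery: Kaplan-Meier curves, time-dependent ROC by
# nearest-neighbour estimation (cumulative cases / dynamic controls),
# ROC-based cutoff selection, hazard-ratio group comparison, Harrell's
# concordance index with a paired-bootstrap comparison, and subgroup
# analysis.

# Kaplan-Meier survival probability at a single time t.  Samples are sorted
# by (time, -event) so censored observations tied with events remain at
# risk for them; the product over individual event rows telescopes to the
# pooled (1 - d/n) factors.
km_at <- function(time, event, t) {
  o <- order(time, -event)
  time <- time[o]; event <- event[o]
  atrisk <- length(time):1L
  use <- event == 1L & time <= t
  if (!any(use)) return(1)
  prod(1 - 1 / atrisk[use])
}

#' Kaplan-Meier estimate, optionally per group
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' step function(s) in tidy form.
#'
#' @param surv survival data frame (`time`, `event`).
#' @param group optional group labels.
#' @return data frame with `time`, `n_risk`, `n_event`, `survival` and,
#'   when grouped, `group`.  The curve is right-continuous, non-increasing,
#'   with S(0) = 1.
#' @export
km_estimate <- function(surv, group = NULL) {
  surv <- as_survival_df(surv)
  y <- survival::Surv(surv$time, surv$event)
  if (is.null(group)) {
    fit <- survival::survfit(y ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv)
  } else {
    if (length(group) != nrow(surv)) stop("group labels not aligned to survival")
    g <- as.factor(group)
    if (any(table(g) == 0L)) stop("empty group in km_estimate")
    fit <- survival::survfit(y ~ g)
    grp <- if (is.null(fit$strata)) {
      rep(levels(g)[1L], length(fit$time))
    } else {
      rep(sub("^g=", "", names(fit$strata)), fit$strata)
    }
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv, group = grp)
  }
}

#' Time-dependent ROC curve by nearest-neighbour estimation
#'
#' Cumulative-case / dynamic-control ROC at horizon `t`: cases are samples
#' with an event by `t`, controls are survivors past `t`.  Under censoring
#' the joint distribution of (marker, survival) is estimated by the
#' nearest-neighbour smoother: each sample's conditional survival
#' `S_i(t) = P(T > t | X = x_i)` is the Kaplan-Meier estimate over its
#' marker-rank neighbourhood `{j : |rank_j - rank_i| <= span * n}` (a
#' symmetric window containing about `2 * span * n` samples).  Then for
#' each threshold `c`,
#' `TPR(c) = P(X > c, T <= t) / P(T <= t)` and
#' `FPR(c) = P(X > c, T > t) / P(T > t)`,
#' both monotone in `c`, so the curve runs from (1,1) to (0,0); AUC by the
#' trapezoid rule.
#'
#' @param scores numeric marker (higher = higher risk).
#' @param surv aligned survival data frame.
#' @param t horizon, within the observed follow-up range.
#' @param span smoothing span in (0, 0.5]; default `0.25 * n^(-0.20)`.
#' @return object of class `td_roc`: list with `horizon`, `span`,
#'   `thresholds` (ascending, starting at `-Inf`), `tpr`, `fpr`, `auc`,
#'   and `survival_at_t`.
#' @export
td_roc_nne <- function(scores, surv, t, span = NULL) {
  surv <- as_survival_df(surv)
  n <- length(scores)
  if (n != nrow(surv)) stop("scores and survival are not aligned")
  if (anyNA(scores)) stop("missing risk scores")
  if (t <= 0 || t > max(surv$time)) {
    stop("horizon t must lie within the observed follow-up range (0, ",
         format(max(surv$time)), "]")
  }
  span <- span %||% (0.25 * n^(-0.20))
  if (span <= 0 || span > 0.5) stop("span must be in (0, 0.5]")

  r <- rank(scores, ties.method = "average")
  halfwidth <- span * n
  Si <- vapply(seq_len(n), function(i) {
    idx <- which(abs(r - r[i]) <= halfwidth)
    km_at(surv$time[idx], surv$event[idx], t)
  }, numeric(1L))
  S_t <- mean(Si)
  if (S_t >= 1) stop("no events by the horizon t = ", format(t))
  if (S_t <= 0) stop("no survivors past the horizon t = ", format(t))

  # sweep thresholds over the unique scores (plus -Inf); strict X > c
  ord <- order(scores, decreasing = TRUE)
  cum_S <- cumsum(Si[ord]) / n          # P(X > c, T > t) walking c down
  cum_n <- seq_len(n) / n               # P(X > c)
  sc_sorted <- scores[ord]
  last_of_value <- which(sc_sorted != c(sc_sorted[-1L], -Inf))
  thr <- c(-Inf, rev(sc_sorted[last_of_value]))
  joint <- c(cum_S[n], rev(cum_S[last_of_value]))
  marg <- c(cum_n[n], rev(cum_n[last_of_value]))
  # the threshold equal to a score value excludes that score (strict >)
  joint <- c(joint[-1L], 0)
  marg <- c(marg[-1L], 0)
  fpr <- pmin(1, pmax(0, joint / S_t))
  tpr <- pmin(1, pmax(0, (marg - joint) / (1 - S_t)))
  fpr[1L] <- 1; tpr[1L] <- 1

  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1L] + tpr[o][-length(o)]) / 2)
  structure(list(horizon = t, span = span, thresholds = thr, tpr = tpr,
                 fpr = fpr, auc = auc, survival_at_t = S_t),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat("Time-dependent ROC (NNE): horizon", format(x$horizon),
      " span", format(round(x$span, 4)), "\n")
  cat("  AUC:", format(round(x$auc, 4)),
      " S(t):", format(round(x$survival_at_t, 4)), "\n")
  invisible(x)
}

#' Cutoff minimising the distance to the perfect-classification corner
#'
#' Returns the threshold whose ROC point is closest (Euclidean distance) to
#' (FPR = 0, TPR = 1); exact ties break toward the lower threshold.
#'
#' @param roc a `td_roc` object.
#' @return the optimal threshold (a score value).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "td_roc"))
  finite <- is.finite(roc$thresholds)
  if (!any(finite)) stop("degenerate ROC curve: no finite thresholds")
  d <- sqrt((1 - roc$tpr[finite])^2 + roc$fpr[finite]^2)
  thr <- roc$thresholds[finite]
  thr[which.min(d)]  # thresholds ascend, so the first minimum is the lowest
}

#' Classify samples into risk groups
#'
#' @param scores numeric risk scores.
#' @param cutoff risk-score threshold; `score >= cutoff` is high risk.
#' @return factor with levels `"low"`, `"high"`.
#' @export
classify <- function(scores, cutoff) {
  factor(ifelse(scores >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Hazard ratio and log-rank comparison of two risk groups
#'
#' Univariate Cox fit (Breslow ties) of the high-vs-low indicator with a
#' Wald 95% confidence interval, plus the log-rank p-value.
#'
#' @param surv survival data frame.
#' @param groups factor with levels `low`, `high` (any two-level factor
#'   works; the second level is the numerator of the hazard ratio).
#' @return object of class `group_comparison`: list with `n_high`, `n_low`,
#'   `hr`, `ci` (length-2), `logrank_p`, and `degenerate` (TRUE when a
#'   group has no events, making the HR non-finite in the limit).
#' @export
group_hr <- function(surv, groups) {
  surv <- as_survival_df(surv)
  g <- as.factor(groups)
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("two non-empty groups are required")
  }
  if (sum(surv$event) == 0L) stop("no events in either group")
  events_by_group <- tapply(surv$event, g, sum)
  degenerate <- any(events_by_group == 0L)
  if (degenerate) {
    warning("a group has no events; the hazard ratio is unstable")
  }
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ g,
                         ties = "breslow")
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  lr <- logrank_test(surv, g)
  structure(list(
    n_low = sum(g == levels(g)[1L]), n_high = sum(g == levels(g)[2L]),
    hr = exp(beta), ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
    logrank_p = lr$p_value, logrank_statistic = lr$statistic,
    degenerate = degenerate
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("high vs low risk: HR %.3f (95%% CI %.3f-%.3f), log-rank p %s\n",
              x$hr, x$ci[1L], x$ci[2L], format.pval(x$logrank_p, digits = 3)))
  cat("  n_high:", x$n_high, " n_low:", x$n_low, "\n")
  invisible(x)
}

#' Harrell's concordance index
#'
#' Probability that, of a comparable pair of samples (the earlier time must
#' be an event), the one with the higher score fails first; score ties count
#' one half.  Computed from the pair counts of [survival::concordance()]
#' with an asymptotic 95% confidence interval.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param surv aligned survival data frame.
#' @return list with `cindex`, `ci`, `se`, `n_pairs` (comparable pairs).
#' @export
harrell_cindex <- function(scores, surv) {
  surv <- as_survival_df(surv)
  if (length(scores) != nrow(surv)) stop("scores and survival are not aligned")
  fit <- survival::concordance(
    survival::Surv(surv$time, surv$event) ~ scores, reverse = TRUE)
  cnt <- as.numeric(fit$count)
  names(cnt) <- names(fit$count)
  n_pairs <- cnt[["concordant"]] + cnt[["discordant"]] + cnt[["tied.x"]]
  if (n_pairs == 0) stop("no comparable pairs for the concordance index")
  cindex <- (cnt[["concordant"]] + 0.5 * cnt[["tied.x"]]) / n_pairs
  se <- sqrt(fit$var)
  list(cindex = cindex, ci = cindex + c(-1, 1) * qnorm(0.975) * se,
       se = se, n_pairs = n_pairs)
}

#' Paired-bootstrap comparison of two concordance indices
#'
#' Both markers are scored on the same samples; `B` bootstrap resamples of
#' the samples give the distribution of the difference in Harrell's C, and
#' a two-sided p-value from its normal approximation.
#'
#' @param scores_a,scores_b two risk-score vectors on the same samples.
#' @param surv aligned survival data frame.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return list with `cindex_a`, `cindex_b`, `delta` (a minus b), `p_value`,
#'   `boot_se`, `B`.
#' @export
compare_cindex <- function(scores_a, scores_b, surv, B = 1000L, seed = 1L) {
  surv <- as_survival_df(surv)
  n <- nrow(surv)
  if (length(scores_a) != n || length(scores_b) != n) {
    stop("score vectors and survival are not aligned")
  }
  surv <- surv[c("time", "event")]   # resamples duplicate rows; ids irrelevant
  ca <- harrell_cindex(scores_a, surv)$cindex
  cb <- harrell_cindex(scores_b, surv)$cindex
  delta <- ca - cb
  boot <- withr::with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, replace = TRUE)
      sv <- surv[idx, , drop = FALSE]
      if (sum(sv$event) == 0L) return(NA_real_)
      harrell_cindex(scores_a[idx], sv)$cindex -
        harrell_cindex(scores_b[idx], sv)$cindex
    }, numeric(1L))
  })
  boot <- boot[!is.na(boot)]
  boot_se <- sd(boot)
  p <- if (!is.finite(boot_se) || boot_se == 0) {
    if (delta == 0) 1 else 0
  } else {
    2 * pnorm(-abs(delta) / boot_se)
  }
  list(cindex_a = ca, cindex_b = cb, delta = delta, p_value = min(1, p),
       boot_se = boot_se, B = B)
}

#' Subgroup analysis of the risk-group hazard ratio
#'
#' Recomputes [group_hr()] inside each level of each requested clinical
#' variable.  Strata with fewer than 2 events, or without both risk groups,
#' are flagged and skipped rather than fabricated.
#'
#' @param surv survival data frame.
#' @param groups risk-group factor aligned to `surv`.
#' @param clinical data frame of covariates aligned to `surv`.
#' @param variables character vector of clinical column names to stratify on.
#' @return data frame with one row per (variable, level): `variable`,
#'   `level`, `n_high`, `n_low`, `hr`, `ci_low`, `ci_high`, `logrank_p`,
#'   `skipped`.
#' @export
subgroup_analysis <- function(surv, groups, clinical, variables) {
  surv <- as_survival_df(surv)
  g <- as.factor(groups)
  missing_vars <- setdiff(variables, names(clinical))
  if (length(missing_vars)) {
    stop("unknown clinical column(s): ", paste(missing_vars, collapse = ", "))
  }
  if (nrow(clinical) != nrow(surv)) stop("clinical table not aligned to survival")
  rows <- list()
  for (v in variables) {
    for (lev in unique(as.character(clinical[[v]]))) {
      sel <- !is.na(clinical[[v]]) & clinical[[v]] == lev
      row <- data.frame(variable = v, level = lev,
                        n_high = sum(g[sel] == levels(g)[2L]),
                        n_low = sum(g[sel] == levels(g)[1L]),
                        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        logrank_p = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE)
      if (sum(surv$event[sel]) >= 2L && length(unique(g[sel])) == 2L) {
        cmp <- group_hr(surv[sel, , drop = FALSE], droplevels(g[sel]))
        row$hr <- cmp$hr; row$ci_low <- cmp$ci[1L]; row$ci_high <- cmp$ci[2L]
        row$logrank_p <- cmp$logrank_p; row$skipped <- FALSE
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
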