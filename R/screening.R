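# Per-gene prognostic screening: two-group log-rank test with
# permutation-based p-values.  The log-rank chi-square is implemented as a
# vectorised kernel over a matrix of group-label columns so that thousands
# of permutations per gene stay cheap; survival::survdiff gives the same
# statistic and serves as the cross-check in the test suite.

# Precompute the tie blocks of a survival sample, shared by all label
# vectors: samples sorted by (time, -event), block boundaries at distinct
# times, per-block at-risk and event counts.
logrank_prep <- function(time, event) {
  o <- order(time, -event)
  time <- time[o]; event <- as.numeric(event[o])
  n <- length(time)
  last <- which(time != c(time[-1L], Inf))      # last index of each tie block
  first <- c(1L, utils::head(last, -1L) + 1L)
  d <- cumsum(event)[last] - c(0, cumsum(event)[utils::head(last, -1L)])
  keep <- d > 0                                  # blocks with >= 1 event
  list(order = o, n = n, event = event,
       first = first[keep], last = last[keep], d = d[keep],
       atrisk = n - first[keep] + 1)
}

# Chi-square log-rank statistic for each column of a 0/1 label matrix Z
# (rows = samples in ORIGINAL order).  Returns a vector of statistics.
logrank_chisq <- function(prep, Z) {
  Z <- as.matrix(Z)[prep$order, , drop = FALSE]
  storage.mode(Z) <- "double"
  cumZ <- apply(Z, 2L, cumsum)                       # n x B
  cumZe <- apply(Z * prep$event, 2L, cumsum)         # events in group 1
  tot1 <- cumZ[prep$n, , drop = FALSE]               # group-1 size, 1 x B
  first <- prep$first; last <- prep$last
  before <- ifelse(first > 1L, first - 1L, NA_integer_)
  n1 <- matrix(rep(tot1, each = length(first)), nrow = length(first))
  nz <- !is.na(before)
  n1[nz, ] <- n1[nz, ] - cumZ[before[nz], , drop = FALSE]
  prev <- rbind(matrix(0, 1L, ncol(cumZe)),
                cumZe[utils::head(last, -1L), , drop = FALSE])
  d1 <- cumZe[last, , drop = FALSE] - prev
  nb <- prep$atrisk; d <- prep$d
  p1 <- n1 / nb
  oe <- colSums(d1 - d * p1)
  vv <- colSums(d * p1 * (1 - p1) * ifelse(nb > 1, (nb - d) / (nb - 1), 0))
  stat <- ifelse(vv > 0, oe^2 / vv, 0)
  unname(stat)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square from the hypergeometric
#' observed-minus-expected sums over distinct event times (ties pooled
#' within an event time), with its asymptotic p-value.
#'
#' @param surv data frame with columns `time` (positive) and `event` (0/1).
#' @param groups binary group labels (two levels), one per sample.
#' @return list with `statistic`, `p_value`, `n` (per-group sizes).
#' @examples
#' surv <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1))
#' logrank_test(surv, c("A", "A", "B", "B"))
#' @export
logrank_test <- function(surv, groups) {
  surv <- as_survival_df(surv)
  if (length(groups) != nrow(surv)) stop("groups and survival are not aligned")
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2L) stop("exactly two non-empty groups are required")
  if (sum(surv$event) == 0L) stop("log-rank test needs at least one event")
  z <- as.numeric(g == levels(g)[2L])
  prep <- logrank_prep(surv$time, surv$event)
  stat <- logrank_chisq(prep, matrix(z, ncol = 1L))
  list(statistic = stat,
       p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       n = table(g))
}

#' Permutation p-value for the two-group log-rank statistic
#'
#' Group labels are permuted `B` times; the p-value is
#' `(1 + #\{permuted statistic >= observed\}) / (B + 1)`, so its smallest
#' attainable value is `1 / (B + 1)`.
#'
#' @inheritParams logrank_test
#' @param B number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `statistic`, `p_asymptotic`, `p_permutation`, `B`.
#' @export
permutation_pvalue <- function(surv, groups, B = 1000L, seed = 1L) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  obs <- logrank_test(surv, groups)
  g <- as.factor(groups)
  z <- as.numeric(g == levels(g)[2L])
  prep <- logrank_prep(surv$time, surv$event)
  perm <- withr::with_seed(seed, {
    Z <- vapply(seq_len(B), function(i) z[sample.int(length(z))],
                numeric(length(z)))
    logrank_chisq(prep, Z)
  })
  list(statistic = obs$statistic,
       p_asymptotic = obs$p_value,
       p_permutation = (1 + sum(perm >= obs$statistic)) / (B + 1),
       B = B)
}

#' Screen genes for prognostic value by median-split log-rank tests
#'
#' Each gene is dichotomised at its median across samples (values at or
#' above the median form the high group); the two groups are compared with
#' the log-rank test and a permutation p-value.  Genes whose permutation
#' p-value is below `alpha` are returned sorted by decreasing statistic.
#' Genes whose median split leaves one group empty (e.g. constant genes)
#' are skipped with a message.
#'
#' @param expr numeric matrix, gene rows x sample columns.
#' @param surv survival data frame aligned to the columns of `expr`.
#' @param alpha significance threshold on the permutation p-value.
#' @param B permutations per gene.
#' @param seed integer seed (one stream drives all genes).
#' @return data frame `gene`, `statistic`, `p_asymptotic`, `p_permutation`,
#'   `n_high`, `n_low` for the significant genes; the full per-gene table is
#'   attached as attribute `"full"` and skipped genes as `"skipped"`.
#' @export
screen_prognostic_genes <- function(expr, surv, alpha = 0.05, B = 1000L,
                                    seed = 1L) {
  surv <- as_survival_df(surv)
  check_aligned(expr, surv)
  if (sum(surv$event) == 0L) stop("screening needs at least one event")
  B <- as.integer(B)
  n <- ncol(expr)
  prep <- logrank_prep(surv$time, surv$event)

  med <- apply(expr, 1L, median)
  H <- expr >= med                       # gene x sample high-group indicator
  n_high <- rowSums(H)
  usable <- n_high > 0L & n_high < n
  if (any(!usable)) {
    message("screen_prognostic_genes: skipped ", sum(!usable),
            " gene(s) with a degenerate median split")
  }
  genes <- rownames(expr)[usable]
  Zobs <- t(H[usable, , drop = FALSE]) * 1   # sample x gene
  stat_obs <- logrank_chisq(prep, Zobs)

  p_perm <- withr::with_seed(seed, {
    vapply(seq_along(genes), function(j) {
      z <- Zobs[, j]
      Z <- vapply(seq_len(B), function(i) z[sample.int(n)], numeric(n))
      (1 + sum(logrank_chisq(prep, Z) >= stat_obs[j])) / (B + 1)
    }, numeric(1L))
  })

  full <- data.frame(
    gene = genes, statistic = stat_obs,
    p_asymptotic = pchisq(stat_obs, df = 1L, lower.tail = FALSE),
    p_permutation = p_perm,
    n_high = n_high[usable], n_low = n - n_high[usable],
    stringsAsFactors = FALSE, row.names = NULL
  )
  sig <- full[full$p_permutation < alpha, , drop = FALSE]
  sig <- sig[order(-sig$statistic), , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "full") <- full
  attr(sig, "skipped") <- rownames(expr)[!usable]
  sig
}
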