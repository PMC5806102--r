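# Synthetic survival cohorts with planted prognostic gene pairs.
#
# The generator draws per-gene normal expression, computes the linear
# predictor from planted pair indicators, and draws exponential event times
# with hazard proportional to exp(eta).  Censoring is administrative:
# uniform on [0, tau] with tau solved numerically for the target rate.

MONOTONE_DISTORTIONS <- list(
  identity = identity,
  exp      = exp,
  sigmoid  = stats::plogis,
  cube     = function(x) x^3,
  softplus = function(x) log1p(exp(pmin(x, 700)))
)

#' Configuration for a synthetic survival cohort
#'
#' @param n_samples number of samples (patients).
#' @param n_genes number of genes.
#' @param planted_pairs data frame with integer columns `gene_a`, `gene_b`
#'   (1-based gene indices, `gene_a != gene_b`) and numeric `beta`, the true
#'   log-hazard contribution of the indicator `I(expr[a] > expr[b])`.
#'   `NULL` or zero rows plants no signal.
#' @param baseline_scale mean of the exponential baseline event-time
#'   distribution (study time units; defaults emulate months).
#' @param censoring_rate target fraction of censored samples, in `[0, 1)`.
#' @param batch_shift,batch_scale,monotone_distortion default batch
#'   transform recorded in the config (see [apply_batch_transform()]).
#' @param probes_per_gene default probe multiplicity for
#'   [generate_probe_matrix()].
#' @param seed integer seed; all randomness of the cohort flows from it.
#' @return an object of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_samples, n_genes, planted_pairs = NULL,
                             baseline_scale = 60, censoring_rate = 0.3,
                             batch_shift = 0, batch_scale = 1,
                             monotone_distortion = "identity",
                             probes_per_gene = 1L, seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_genes <- as.integer(n_genes)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be a positive integer")
  if (is.na(n_genes) || n_genes < 1L) stop("n_genes must be a positive integer")
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    if (nrow(planted_pairs) == 0L) planted_pairs <- NULL
  }
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("gene_a", "gene_b", "beta") %in% names(planted_pairs)))
    a <- planted_pairs$gene_a; b <- planted_pairs$gene_b
    if (any(a == b)) stop("planted pair indices must be distinct within a pair")
    if (any(c(a, b) < 1L) || any(c(a, b) > n_genes)) {
      stop("planted pair gene index out of range 1..n_genes")
    }
  }
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0, 1)")
  if (baseline_scale <= 0) stop("baseline_scale must be positive")
  if (batch_scale <= 0) stop("batch_scale must be positive")
  if (!monotone_distortion %in% names(MONOTONE_DISTORTIONS)) {
    stop("unknown monotone distortion '", monotone_distortion, "'; available: ",
         paste(names(MONOTONE_DISTORTIONS), collapse = ", "))
  }
  if (probes_per_gene < 1L) stop("probes_per_gene must be >= 1")
  structure(list(
    n_samples = n_samples, n_genes = n_genes, planted_pairs = planted_pairs,
    baseline_scale = baseline_scale, censoring_rate = censoring_rate,
    batch_shift = batch_shift, batch_scale = batch_scale,
    monotone_distortion = monotone_distortion,
    probes_per_gene = as.integer(probes_per_gene), seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic cohort with known prognostic gene pairs
#'
#' Per-gene expression is i.i.d. normal across samples (gene means drawn
#' around 8 on the log2-intensity scale, per-gene standard deviations in
#' \[0.5, 1.5\]).  The two genes of a planted pair share the same mean so the
#' pair indicator splits the cohort roughly 50/50 and carries the planted
#' log-hazard.  Event times are exponential with hazard
#' `exp(eta) / baseline_scale` where
#' `eta = sum_k beta_k * I(expr[a_k] > expr[b_k])`; censoring times are
#' uniform on `[0, tau]` with `tau` solved so that the expected censored
#' fraction matches `censoring_rate`.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_cohort`: a list with `expression`
#'   (genes x samples matrix), `survival` (data frame `sample_id`, `time`,
#'   `event`), `clinical` (data frame with `sex` and `age_group` covariates),
#'   `truth` (the planted pairs with gene names) and `config`.
#' @examples
#' coh <- generate_cohort(synthetic_config(50, 10, seed = 7))
#' dim(coh$expression)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples; G <- config$n_genes
  withr::with_seed(config$seed, {
    mu <- rnorm(G, mean = 8, sd = 1)
    sds <- runif(G, 0.5, 1.5)
    if (!is.null(config$planted_pairs)) {
      # genes of a planted pair share a mean -> balanced, informative indicator
      for (k in seq_len(nrow(config$planted_pairs))) {
        a <- config$planted_pairs$gene_a[k]; b <- config$planted_pairs$gene_b[k]
        mu[b] <- mu[a]
      }
    }
    expr <- matrix(rnorm(G * n), nrow = G, ncol = n) * sds + mu
    gene_ids <- sprintf("g%03d", seq_len(G))
    sample_ids <- sprintf("s%03d", seq_len(n))
    dimnames(expr) <- list(gene_ids, sample_ids)

    eta <- numeric(n)
    truth <- NULL
    if (!is.null(config$planted_pairs)) {
      pp <- config$planted_pairs
      for (k in seq_len(nrow(pp))) {
        ind <- as.numeric(expr[pp$gene_a[k], ] > expr[pp$gene_b[k], ])
        eta <- eta + pp$beta[k] * ind
      }
      truth <- data.frame(gene_a = gene_ids[pp$gene_a], gene_b = gene_ids[pp$gene_b],
                          beta = pp$beta, stringsAsFactors = FALSE)
    }
    # centring eta keeps baseline_scale the cohort's typical event-time
    # scale whatever is planted; hazards stay proportional to exp(eta)
    t_event <- rexp(n, rate = exp(eta - mean(eta)) / config$baseline_scale)

    if (config$censoring_rate > 0) {
      # P(censored | tau) = mean(min(T, tau)) / tau, decreasing in tau
      f <- function(tau) mean(pmin(t_event, tau)) / tau - config$censoring_rate
      tau <- uniroot(f, lower = min(t_event) * 1e-6,
                     upper = max(t_event) * 1e6, tol = 1e-10)$root
      cens <- runif(n, 0, tau)
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    survival <- data.frame(sample_id = sample_ids, time = time, event = event,
                           stringsAsFactors = FALSE)
    clinical <- data.frame(
      sample_id = sample_ids,
      sex = sample(c("male", "female"), n, replace = TRUE),
      age_group = sample(c("<65", ">=65"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  structure(list(expression = expr, survival = survival, clinical = clinical,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic survival cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "genes\n")
  cat("  events:", sum(x$survival$event), " censored:",
      sum(1 - x$survival$event), "\n")
  if (!is.null(x$truth)) {
    cat("  planted pairs:", nrow(x$truth), "\n")
  }
  invisible(x)
}

#' Apply a per-sample monotone batch distortion to a cohort
#'
#' Transforms every expression value by `x -> f(scale * x + shift)` with `f`
#' a strictly increasing function from a named registry.  Survival data are
#' untouched.  Because the transform is strictly monotone, all within-sample
#' gene orderings — and therefore every pair indicator and risk score — are
#' preserved exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param shift,scale affine part of the distortion (`scale > 0`).
#' @param distortion one of `"identity"`, `"exp"`, `"sigmoid"`, `"cube"`,
#'   `"softplus"`.
#' @return the cohort with transformed expression.
#' @export
apply_batch_transform <- function(cohort, shift = 0, scale = 1,
                                  distortion = "identity") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (scale <= 0) stop("scale must be positive (the transform must be increasing)")
  if (!distortion %in% names(MONOTONE_DISTORTIONS)) {
    stop("unknown monotone distortion '", distortion, "'; available: ",
         paste(names(MONOTONE_DISTORTIONS), collapse = ", "))
  }
  f <- MONOTONE_DISTORTIONS[[distortion]]
  cohort$expression <- f(scale * cohort$expression + shift)
  cohort
}

#' Expand a cohort's gene matrix into a multi-probe matrix
#'
#' Emulates microarray platforms where several probes map to one gene
#' symbol.  Probe `j` of a gene carries the gene's expression plus
#' independent noise of standard deviation `(j - 1) * noise_step`, so probe
#' 1 reproduces the gene exactly and later probes have increasing variance
#' (hence, with high probability, increasing inter-quartile range).
#'
#' @param cohort a `synthetic_cohort`.
#' @param probes_per_gene probes per gene (>= 1).
#' @param seed integer seed for the probe noise.
#' @param noise_step standard-deviation increment per extra probe.
#' @return a list with `probes` (probe x sample matrix) and `annotation`
#'   (data frame `probe_id`, `gene_symbol`).
#' @export
generate_probe_matrix <- function(cohort, probes_per_gene = NULL, seed = NULL,
                                  noise_step = 1.0) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  probes_per_gene <- as.integer(probes_per_gene %||% cohort$config$probes_per_gene)
  if (probes_per_gene < 1L) stop("probes_per_gene must be >= 1")
  seed <- as.integer(seed %||% derive_seed(cohort$config$seed, 17L))
  expr <- cohort$expression
  G <- nrow(expr); n <- ncol(expr); P <- probes_per_gene
  genes <- rownames(expr)
  probe_id <- as.vector(t(outer(genes, seq_len(P), function(g, j) sprintf("%s_p%d", g, j))))
  annotation <- data.frame(probe_id = probe_id,
                           gene_symbol = rep(genes, each = P),
                           stringsAsFactors = FALSE)
  probes <- matrix(NA_real_, nrow = G * P, ncol = n,
                   dimnames = list(probe_id, colnames(expr)))
  withr::with_seed(seed, {
    for (j in seq_len(P)) {
      noise_sd <- (j - 1) * noise_step
      noise <- if (noise_sd > 0) matrix(rnorm(G * n, sd = noise_sd), G, n) else 0
      probes[seq(j, G * P, by = P), ] <- expr + noise
    }
  })
  list(probes = probes, annotation = annotation)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `expression.tsv` (gene rows x sample columns), `survival.tsv`
#' (`sample_id`, `time`, `event`), `clinical.tsv` and, if the cohort has
#' planted pairs, `truth.tsv` (`gene_a`, `gene_b`, `beta`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             survival = file.path(dir, "survival.tsv"),
             clinical = file.path(dir, "clinical.tsv"))
  write_expression(cohort$expression, paths[["expression"]])
  write.table(cohort$survival, paths[["survival"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.tsv"))
    write.table(cohort$truth, paths[["truth"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
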