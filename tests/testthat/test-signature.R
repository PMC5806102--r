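# Penalised Cox selection, risk scores and the two published controls.

make_planted <- function(seed, n = 300, G = 50, beta = 0.8, n_pairs = 5) {
  cfg <- synthetic_config(n, G,
    planted_pairs = data.frame(gene_a = seq(1, 2 * n_pairs, 2),
                               gene_b = seq(2, 2 * n_pairs, 2),
                               beta = beta),
    seed = seed)
  generate_cohort(cfg)
}

test_that("the unpenalised limit agrees with a Newton-Raphson Cox oracle", {
  coh <- make_planted(41, n = 60, G = 6, beta = 1.2, n_pairs = 3)
  m <- build_pair_matrix(coh$expression,
                         data.frame(gene_a = c("g001", "g003", "g005"),
                                    gene_b = c("g002", "g004", "g006")))
  fit <- fit_penalized_cox(m, coh$survival, penalty = 0)
  oracle <- survival::coxph(
    survival::Surv(coh$survival$time, coh$survival$event) ~ t(m),
    ties = "breslow")
  got <- setNames(fit$model$pairs$coefficient,
                  paste(fit$model$pairs$gene_a, fit$model$pairs$gene_b, sep = "|"))
  want <- setNames(unname(coef(oracle)), rownames(m))
  expect_equal(got[names(want)], want, tolerance = 1e-4)
})

test_that("cross-validated selection is seeded, sparse and 1SE-consistent", {
  coh <- make_planted(42)
  m <- prune_degenerate_pairs(
    build_pair_matrix(coh$expression, enumerate_pairs(rownames(coh$expression))))
  fit1 <- fit_penalized_cox(m, coh$survival, seed = 7)
  fit2 <- fit_penalized_cox(m, coh$survival, seed = 7)
  expect_identical(fit1$model$pairs, fit2$model$pairs)
  d <- fit1$diagnostics
  expect_gte(d$penalty_1se, d$penalty_min)   # 1SE picks the sparser side
  expect_identical(d$lambda, sort(d$lambda, decreasing = TRUE))
  i_1se <- which.min(abs(d$lambda - d$penalty_1se))
  i_min <- which.min(abs(d$lambda - d$penalty_min))
  expect_lte(d$n_nonzero[[i_1se]], d$n_nonzero[[i_min]])
  # the 1SE deviance is within one SE of the minimum, by construction
  expect_lte(d$cv_deviance[i_1se],
             min(d$cv_deviance) + d$cv_se[which.min(d$cv_deviance)] + 1e-8)
  # planted signal is found (full recovery statistics live in the
  # acceptance suite)
  planted <- paste(coh$truth$gene_a, coh$truth$gene_b, sep = "|")
  sel <- paste(fit1$model$pairs$gene_a, fit1$model$pairs$gene_b, sep = "|")
  expect_gte(sum(planted %in% sel), 3)
})

test_that("fit rejects event-free and constant designs", {
  coh <- make_planted(43, n = 40, G = 6, n_pairs = 2)
  m <- build_pair_matrix(coh$expression,
                         enumerate_pairs(rownames(coh$expression)))
  surv0 <- coh$survival
  surv0$event <- 0L
  expect_error(fit_penalized_cox(m, surv0), "events")
  mc <- matrix(1L, 3, 40, dimnames = list(c("a|b", "c|d", "e|f"),
                                          colnames(coh$expression)))
  expect_error(fit_penalized_cox(mc, coh$survival), "constant")
})

test_that("risk scores sum coefficients over active indicators", {
  sig <- gastric_signature()
  genes <- unique(c(sig$pairs$gene_a, sig$pairs$gene_b))
  # no gene sits in both slots, so putting every slot-1 gene high and every
  # slot-2 gene low realises all seven indicators at once
  expect_length(intersect(sig$pairs$gene_a, sig$pairs$gene_b), 0L)
  expr <- matrix(0, length(genes), 2, dimnames = list(genes, c("up", "down")))
  expr[unique(sig$pairs$gene_a), "up"] <- 10
  expr[unique(sig$pairs$gene_b), "up"] <- 1
  expr[, "down"] <- -expr[, "up"]
  sc <- risk_score(sig, expr)
  # "up" realises gene_a > gene_b for every pair listed in catalog order
  expect_equal(unname(sc["up"]), sum(sig$pairs$coefficient), tolerance = 1e-12)
  expect_equal(unname(sc["up"]), -0.086106771, tolerance = 1e-9)
  expect_equal(unname(sc["down"]), 0)   # every indicator 0 -> empty sum
  expect_error(risk_score(sig, expr[-1, , drop = FALSE]), "ACOT7")
})

test_that("leave-one-pair-out reporting is complete and exact for no-ops", {
  coh <- make_planted(44, n = 200, G = 12, beta = c(2, 0.3, 0.3), n_pairs = 3)
  sig <- pair_signature(data.frame(
    gene_a = c(coh$truth$gene_a, "g011"),
    gene_b = c(coh$truth$gene_b, "g012"),
    coefficient = c(2, 0.3, 0.3, 0)))   # last entry: zero coefficient
  tab <- sensitivity_leave_one_pair_out(sig, coh$expression, coh$survival,
                                        horizon = 60)
  expect_equal(nrow(tab), 4L)
  noop <- tab[tab$omitted == "g011|g012", ]
  expect_equal(noop$delta_cindex, 0)
  expect_equal(noop$delta_auc, 0)
  # the dominant planted pair costs the most concordance when omitted
  expect_equal(tab$omitted[which.min(tab$cindex)],
               paste(coh$truth$gene_a[1], coh$truth$gene_b[1], sep = "|"))
})

test_that("pseudo-signatures have the requested shape and seeded sampling", {
  coh <- generate_cohort(synthetic_config(150, 30, seed = 45))
  ps1 <- suppressMessages(pseudo_signature(rownames(coh$expression),
                                           coh$expression, coh$survival,
                                           n_pairs = 7, horizon = 60, seed = 3))
  ps2 <- suppressMessages(pseudo_signature(rownames(coh$expression),
                                           coh$expression, coh$survival,
                                           n_pairs = 7, horizon = 60, seed = 3))
  expect_equal(nrow(ps1$model$pairs), 7L)
  expect_equal(length(unique(c(ps1$model$pairs$gene_a,
                               ps1$model$pairs$gene_b))), 14L)
  expect_identical(ps1$model$pairs, ps2$model$pairs)
  expect_true(ps1$auc >= 0 && ps1$auc <= 1)
  expect_error(pseudo_signature(paste0("g", 1:10), coh$expression,
                                coh$survival, n_pairs = 7), "at least 14")
})
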