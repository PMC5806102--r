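# Kaplan-Meier, NNE time-dependent ROC, cutoff, hazard ratio, concordance
# and subgroups.

test_that("Kaplan-Meier matches hand product-limit values", {
  # three events -> 2/3, 1/3, 0
  surv <- data.frame(time = c(1, 2, 3), event = 1L)
  km <- km_estimate(surv)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  none <- km_estimate(data.frame(time = c(2, 5, 9), event = 0L))
  expect_true(all(none$survival == 1))

  # turning the last observation from event to censored leaves the curve
  # unchanged before it, and removes the final drop
  a <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 1)))
  b <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 0)))
  expect_equal(a$survival[a$time <= 2], b$survival[b$time <= 2],
               tolerance = 1e-12)
  expect_equal(min(b$survival), 1 / 3, tolerance = 1e-12)

  # random fixture vs the oracle at every event time
  surv <- random_surv(40, 77)
  km <- km_estimate(surv)
  for (i in seq_len(nrow(km))) {
    expect_equal(km$survival[i],
                 oracle_km(surv$time, surv$event, km$time[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_error(km_estimate(surv, group = rep(c("A"), 40)) , NA)
})

test_that("NNE ROC is exact for a perfect marker in the unsmoothed limit", {
  surv <- data.frame(time = sort(runif(60, 1, 100)), event = 1L)
  roc <- td_roc_nne(-seq_len(60), surv, t = 50, span = 0.001)
  expect_equal(roc$auc, 1, tolerance = 1e-12)
  # and a sign-flipped perfect marker scores 0
  roc_flip <- td_roc_nne(seq_len(60), surv, t = 50, span = 0.001)
  expect_equal(roc_flip$auc, 0, tolerance = 1e-12)
})

test_that("NNE ROC curve is a valid monotone curve through the corners", {
  coh <- generate_cohort(synthetic_config(300, 3, seed = 52))
  scores <- withr::with_seed(1, rnorm(300))
  roc <- td_roc_nne(scores, coh$survival, t = 60)
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
  expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
  expect_true(all(diff(roc$tpr) <= 1e-12))  # thresholds ascend, rates fall
  expect_true(all(diff(roc$fpr) <= 1e-12))
  expect_equal(c(roc$tpr[1], roc$fpr[1]), c(1, 1))
  expect_equal(c(roc$tpr[length(roc$tpr)], roc$fpr[length(roc$fpr)]), c(0, 0))
  expect_gte(roc$auc, 0)
  expect_lte(roc$auc, 1)
  # null marker: AUC near one half
  expect_lt(abs(roc$auc - 0.5), 0.08)
  # anti-symmetry under score sign flip
  roc2 <- td_roc_nne(-scores, coh$survival, t = 60)
  expect_equal(roc$auc + roc2$auc, 1, tolerance = 1e-6)
  expect_error(td_roc_nne(scores, coh$survival, t = 1e6), "follow-up")
})

test_that("the corner-distance cutoff minimises over the curve", {
  toy <- structure(list(horizon = 60, span = 0.1,
                        thresholds = c(-Inf, 1, 2, 3),
                        tpr = c(1, 0.9, 0.8, 0),
                        fpr = c(1, 0.5, 0.1, 0),
                        auc = NA, survival_at_t = 0.5),
                   class = "td_roc")
  # distances: 1 (skipped -Inf is the corner (1,1)), ~0.51, ~0.22, 1
  expect_equal(optimal_cutoff(toy), 2)
  # containing the perfect corner -> that threshold exactly
  toy$tpr <- c(1, 1, 0.5, 0); toy$fpr <- c(1, 0, 0, 0)
  expect_equal(optimal_cutoff(toy), 1)
  # exact ties break toward the lower threshold
  toy$tpr <- c(1, 0.8, 0.8, 0); toy$fpr <- c(1, 0.2, 0.2, 0)
  expect_equal(optimal_cutoff(toy), 1)
})

test_that("classification uses the >= boundary, as for the published cutoff", {
  sc <- c(a = -0.2, b = -0.154, c = -0.0861, d = 0.3)
  gr <- classify(sc, -0.154)
  expect_identical(as.character(gr), c("low", "high", "high", "high"))
  expect_true(all(classify(c(-1, -2), -0.154) == "low"))
  # the all-indicators-on score of the shipped signature is high risk
  expect_identical(as.character(classify(-0.086106771, -0.154)), "high")
})

test_that("hazard ratios behave under symmetry, label swap and truth", {
  surv <- data.frame(time = c(1, 3, 6, 9, 1, 3, 6, 9),
                     event = c(1, 0, 1, 1, 1, 0, 1, 1))
  g <- rep(c("low", "high"), each = 4)
  cmp <- group_hr(surv, factor(g, levels = c("low", "high")))
  expect_equal(cmp$hr, 1, tolerance = 1e-6)
  expect_true(cmp$ci[1] <= cmp$hr && cmp$hr <= cmp$ci[2])
  expect_equal(cmp$n_high + cmp$n_low, 8L)

  surv2 <- random_surv(80, 91)
  g2 <- withr::with_seed(14, sample(c("low", "high"), 80, replace = TRUE))
  a <- group_hr(surv2, factor(g2, levels = c("low", "high")))
  b <- group_hr(surv2, factor(g2, levels = c("high", "low")))
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-9)

  # generating truth: planted group effect of log-hazard 1.0
  coh <- generate_cohort(synthetic_config(300, 4,
    planted_pairs = data.frame(gene_a = 1, gene_b = 2, beta = 1.0),
    seed = 23))
  grp <- classify(as.numeric(coh$expression[1, ] > coh$expression[2, ]), 0.5)
  cmp2 <- group_hr(coh$survival, grp)
  se <- (log(cmp2$ci[2]) - log(cmp2$hr)) / qnorm(0.975)
  expect_lt(abs(log(cmp2$hr) - 1.0), 2 * se)

  surv0 <- surv; surv0$event <- 0L
  expect_error(group_hr(surv0, g), "no events")
})

test_that("Harrell C equals exhaustive pair enumeration and its limits", {
  # perfect concordant marker without censoring
  surv <- data.frame(time = sort(runif(20, 1, 50)), event = 1L)
  expect_equal(harrell_cindex(-seq_len(20), surv)$cindex, 1)
  # brute-force agreement on censored fixtures, including score ties
  for (seed in c(1, 2, 3)) {
    surv <- random_surv(50, seed)
    sc <- withr::with_seed(seed + 10, round(rnorm(50), 1))
    res <- harrell_cindex(sc, surv)
    expect_equal(res$cindex, oracle_cindex(surv$time, surv$event, sc),
                 tolerance = 1e-9)
    expect_true(res$ci[1] <= res$cindex && res$cindex <= res$ci[2])
  }
  # null marker on a large cohort sits near one half
  coh <- generate_cohort(synthetic_config(300, 2, seed = 61))
  sc <- withr::with_seed(3, rnorm(300))
  expect_lt(abs(harrell_cindex(sc, coh$survival)$cindex - 0.5), 0.06)
})

test_that("paired bootstrap C comparison is symmetric, calibrated and powered", {
  coh <- generate_cohort(synthetic_config(200, 2, seed = 62,
    censoring_rate = 0.2))
  surv <- coh$survival
  same <- withr::with_seed(5, rnorm(200))
  res <- compare_cindex(same, same, surv, B = 100, seed = 1)
  expect_equal(res$delta, 0)
  expect_equal(res$p_value, 1)

  perfect <- -surv$time + withr::with_seed(6, rnorm(200, sd = 1e-6))
  noise <- withr::with_seed(7, rnorm(200))
  ab <- compare_cindex(perfect, noise, surv, B = 300, seed = 2)
  ba <- compare_cindex(noise, perfect, surv, B = 300, seed = 2)
  expect_lt(ab$p_value, 0.05)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("subgroup analysis reproduces the whole-cohort row and flags gaps", {
  coh <- generate_cohort(synthetic_config(200, 4,
    planted_pairs = data.frame(gene_a = 1, gene_b = 2, beta = 1.2),
    seed = 63))
  groups <- classify(as.numeric(coh$expression[1, ] > coh$expression[2, ]), 0.5)
  clinical <- coh$clinical
  clinical$all <- "all"
  clinical$rare <- c("tiny", rep("rest", 199))
  tab <- subgroup_analysis(coh$survival, groups, clinical,
                           c("all", "sex", "rare"))
  whole <- group_hr(coh$survival, groups)
  row_all <- tab[tab$variable == "all", ]
  expect_equal(row_all$hr, whole$hr, tolerance = 1e-12)
  expect_equal(row_all$logrank_p, whole$logrank_p, tolerance = 1e-12)
  expect_true(tab$skipped[tab$level == "tiny"])
  expect_true(all(is.na(tab$hr[tab$skipped])))
  # independent covariate: per-stratum log-HR within 2 SE of the truth
  for (lev in c("male", "female")) {
    sel <- clinical$sex == lev
    cmp <- group_hr(coh$survival[sel, ], droplevels(groups[sel]))
    se <- (log(cmp$ci[2]) - log(cmp$hr)) / qnorm(0.975)
    expect_lt(abs(log(cmp$hr) - 1.2), 2 * se)
  }
  expect_error(subgroup_analysis(coh$survival, groups, clinical, "nope"),
               "unknown clinical column")
})
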