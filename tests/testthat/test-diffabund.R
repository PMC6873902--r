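test_that("replicate QC drops samples with substantially fewer features", {
  means <- matrix(20, nrow = 40, ncol = 2,
                  dimnames = list(sprintf("F%02d", 1:40),
                                  c("WT.NT", "TG.NT")))
  tab <- toy_table(means, n = 5)
  # one TG.NT replicate observes only 10% of the median feature count
  poor <- tab$genotype == "TG" & tab$replicate == 1 &
    tab$feature_id %in% sprintf("F%02d", 5:40)
  tab$intensity[poor] <- NA
  out <- qc_exclude_replicates(tab, 0.5)
  expect_identical(attr(out, "excluded_samples"), "TG.NT.r1")
  expect_false("TG.NT.r1" %in% out$sample_id)

  all_equal <- toy_table(means, n = 5)
  expect_identical(attr(qc_exclude_replicates(all_equal), "excluded_samples"),
                   character(0))
  expect_error(qc_exclude_replicates(tab, 1.5), "min_fraction")
})

test_that("minimum-observation rule is 3-of-5, relaxing to 2-of-4", {
  expect_equal(min_obs_required(5), 3L)
  expect_equal(min_obs_required(4), 2L)
  expect_equal(min_obs_required(c(5, 4, 6)), c(3L, 2L, 3L))
})

test_that("presence/absence calling composes the min-obs rule", {
  means <- matrix(20, nrow = 3, ncol = 2,
                  dimnames = list(c("A", "B", "C"), c("TG.NT", "WT.NT")))
  tab <- toy_table(means, n = 5)
  tab <- blank_out(tab, "A", "WT.NT", 1:5)      # 5-of-5 vs 0-of-5
  tab <- blank_out(tab, "B", "TG.NT", 1:2)      # 3-of-5 vs 5-of-5
  tab <- blank_out(tab, "C", "TG.NT", 1:3)      # 2-of-5 both sides
  tab <- blank_out(tab, "C", "WT.NT", 1:3)
  calls <- call_presence(tab, "TG.NT", "WT.NT")
  expect_equal(calls$call[calls$feature_id == "A"], "present_only")
  expect_equal(calls$call[calls$feature_id == "B"], "quantitative")
  expect_equal(calls$call[calls$feature_id == "C"], "excluded")
  expect_error(call_presence(tab, "TG.bogus", "WT.NT"), "unknown condition")
})

test_that("blood-flagged proteins vanish from every downstream list", {
  means <- matrix(c(22, 18, 20, 20), nrow = 2, byrow = TRUE,
                  dimnames = list(c("BLOOD1", "OK1"), c("TG.NT", "WT.NT")))
  tab <- toy_table(means, n = 5, noise_sd = 0.1)
  filt <- filter_features(tab, blood_ids = "BLOOD1")
  res <- adjust_and_call(fit_contrasts(
    filt, list("TG.NT-WT.NT" = c("TG.NT" = 1, "WT.NT" = -1))))
  expect_false("BLOOD1" %in% res$feature_id)
  expect_equal(attr(filt, "filter_log")[["blood_removed"]], 1)
})

test_that("contrast estimates, SEs and p-values match the lm oracle", {
  set.seed(21)
  means <- matrix(rnorm(8 * 3, 20, 1), nrow = 3,
                  dimnames = list(
                    c("F1", "F2", "F3"),
                    as.vector(outer(genotype_levels(), treatment_levels(),
                                    condition_label))))
  tab <- toy_table(means, n = 5, noise_sd = 0.3, seed = 22)
  ctr <- list("TG.NT-WT.NT" = c("TG.NT" = 1, "WT.NT" = -1),
              "inter" = c("TG.greentea" = 1, "TG.NT" = -1,
                          "WT.greentea" = -1, "WT.NT" = 1))
  res <- fit_contrasts(tab, ctr)
  for (f in rownames(means)) {
    sub <- tab[tab$feature_id == f, ]
    sub$cell <- factor(condition_label(sub$genotype, sub$treatment))
    fit <- lm(log2(intensity) ~ 0 + cell, data = sub)
    for (cname in names(ctr)) {
      w <- ctr[[cname]]
      L <- stats::setNames(rep(0, nlevels(sub$cell)), levels(sub$cell))
      L[names(w)] <- w
      est <- sum(L * coef(fit))
      se <- sqrt(drop(t(L) %*% vcov(fit) %*% L))
      row <- res[res$feature_id == f & res$contrast == cname, ]
      expect_equal(row$log2FC, est, tolerance = 1e-10)
      expect_equal(row$SE, se, tolerance = 1e-10)
      expect_equal(row$p,
                   2 * pt(abs(est / se), fit$df.residual, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("noiseless cell means give exact fold changes", {
  means <- matrix(c(11, 10, 10.5, 10), nrow = 1,
                  dimnames = list("F1", c("TG.NT", "WT.NT",
                                          "TG.greentea", "WT.greentea")))
  tab <- toy_table(means, n = 5, noise_sd = 0)
  res <- fit_contrasts(tab, list(
    "TG.NT-WT.NT" = c("TG.NT" = 1, "WT.NT" = -1),
    "inter" = c("TG.greentea" = 1, "TG.NT" = -1,
                "WT.greentea" = -1, "WT.NT" = 1)))
  expect_equal(res$log2FC[res$contrast == "TG.NT-WT.NT"], 1.0,
               tolerance = 1e-12)
  # (10.5 - 11) - (10 - 10) = -0.5
  expect_equal(res$log2FC[res$contrast == "inter"], -0.5, tolerance = 1e-12)
  expect_equal(res$p[res$contrast == "TG.NT-WT.NT"], 0)
})

test_that("p-values are uniform under a permuted-label global null", {
  set.seed(31)
  means <- matrix(20, nrow = 1000, ncol = 2,
                  dimnames = list(sprintf("F%04d", 1:1000),
                                  c("TG.NT", "WT.NT")))
  tab <- toy_table(means, n = 5, noise_sd = 0.3, seed = 31)
  res <- fit_contrasts(tab, list("TG.NT-WT.NT" = c("TG.NT" = 1,
                                                   "WT.NT" = -1)))
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment and thresholds drive the calls", {
  res <- data.frame(feature_id = sprintf("F%d", 1:4),
                    contrast = "TG.NT-WT.NT",
                    log2FC = c(1, 0.25, 1, 0.5),
                    SE = 0.1, df = 8,
                    p = c(0.01, 0.02, 0.03, 0.04),
                    call = "quantitative", n_obs_a = 5L, n_obs_b = 5L,
                    stringsAsFactors = FALSE)
  out <- adjust_and_call(res, alpha = 0.05, lfc = 0.3)
  expect_equal(out$adj_p, rep(0.04, 4))        # BH step-up by hand
  expect_equal(out$call, c("up", "ns", "up", "up"))  # |lfc| gate on F2

  res$p <- c(0.01, 0.01, 0.06, 0.06)
  res$log2FC <- c(1, -1, 1, 1)
  out <- adjust_and_call(res, alpha = 0.05, lfc = 0.3)
  expect_equal(out$call[2], "down")
  expect_equal(out$call[3], "ns")              # fails alpha after BH
  expect_error(adjust_and_call(res[0, ]), "empty")
})

test_that("quantitative and presence calls are mutually exclusive", {
  d <- generate_design(5)
  pr <- generate_proteome(d, n_features = 300, frac_affected = 0.2,
                          missing_steepness = 2, missing_midpoint = 18,
                          seed = 13)
  res <- adjust_and_call(fit_contrasts(
    pr$table, list("TG.NT-WT.NT" = c("TG.NT" = 1, "WT.NT" = -1))))
  expect_equal(anyDuplicated(res$feature_id), 0)
  pres <- res$call %in% c("present_only", "absent_only")
  expect_true(all(is.na(res$log2FC[pres])))
  expect_true(all(is.finite(res$log2FC[!pres])))
  # estimator is exactly the difference of cell means (brute force)
  tab <- pr$table[!is.na(pr$table$intensity), ]
  cm <- tapply(log2(tab$intensity),
               list(tab$feature_id, condition_label(tab$genotype,
                                                    tab$treatment)), mean)
  quant <- res[!pres, ]
  expect_equal(quant$log2FC,
               unname(cm[quant$feature_id, "TG.NT"] -
                        cm[quant$feature_id, "WT.NT"]),
               tolerance = 1e-12)
})

test_that("planted genotype effects are recovered with small error", {
  d <- generate_design(5)
  pr <- generate_proteome(d, n_features = 1000, frac_affected = 0.1,
                          effect_size = 1, noise_sd = 0.25,
                          missing_steepness = 0, seed = 17)
  res <- fit_contrasts(pr$table,
                       list("TG.NT-WT.NT" = c("TG.NT" = 1, "WT.NT" = -1)))
  aff <- pr$truth[pr$truth$affected, ]
  est <- res$log2FC[match(aff$feature_id, res$feature_id)]
  err <- abs(est - aff$genotype_effect)
  expect_lt(mean(err), 0.2)
  expect_gte(mean(err < 0.5), 0.95)
})

test_that("relaxed 2-of-4 rule applies after replicate exclusion", {
  means <- matrix(20, nrow = 1, ncol = 2,
                  dimnames = list("F1", c("TG.NT", "WT.NT")))
  tab <- toy_table(means, n = 5)
  tab <- tab[tab$sample_id != "TG.NT.r5", ]     # group left with 4 reps
  tab <- blank_out(tab, "F1", "TG.NT", 1:2)     # 2-of-4 observed
  calls <- call_presence(tab, "TG.NT", "WT.NT")
  expect_equal(calls$call, "quantitative")      # 2-of-4 is quantifiable
})
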