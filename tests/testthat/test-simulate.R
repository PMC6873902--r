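test_that("design enumerates the full factorial with unique sample ids", {
  d <- generate_design(5)
  expect_equal(nrow(d), 40)
  expect_equal(length(unique(d$sample_id)), 40)
  expect_equal(nrow(generate_design(2)), 16)
  expect_setequal(unique(paste(d$genotype, d$treatment)),
                  as.vector(outer(genotype_levels(), treatment_levels(),
                                  paste)))
  expect_identical(generate_design(3, seed = 9)$sample_id,
                   generate_design(3, seed = 9)$sample_id)
  expect_error(generate_design(1), "n_replicates")
})

test_that("proteome generator plants the requested truth structure", {
  d <- generate_design(5)
  none <- generate_proteome(d, n_features = 50, frac_affected = 0, seed = 3)
  expect_true(all(none$truth$class_greentea == "unaffected"))
  expect_true(all(none$truth$genotype_effect == 0))

  full <- generate_proteome(d, n_features = 200, frac_affected = 0.1,
                            missing_steepness = 0, seed = 3)
  expect_equal(sum(full$truth$affected), 20)  # exact by construction
  expect_false(anyNA(full$table$intensity))   # degenerate missingness

  again <- generate_proteome(d, n_features = 200, frac_affected = 0.1,
                             missing_steepness = 0, seed = 3)
  expect_identical(full$table, again$table)
  expect_identical(full$truth, again$truth)

  expect_error(generate_proteome(d, n_features = 0), "n_features")
  expect_error(generate_proteome(d, recovery_mix = c(rescued = 0.5)),
               "sum to 1")
})

test_that("planted effects reproduce the planted rescue class exactly", {
  d <- generate_design(5)
  pr <- generate_proteome(d, n_features = 400, frac_affected = 0.25,
                          seed = 11)
  aff <- pr$truth[pr$truth$affected, ]
  for (tr in treated_levels()) {
    g <- aff$genotype_effect
    t_gap <- g * (1 - aff[[paste0("fraction_", tr)]])
    f <- recovery_fraction(g, t_gap)
    expect_equal(f, aff[[paste0("fraction_", tr)]], tolerance = 1e-12)
    expect_identical(classify_recovery(f), aff[[paste0("class_", tr)]])
  }
})

test_that("missingness rate is non-increasing in true log2 intensity", {
  d <- generate_design(5)
  pr <- generate_proteome(d, n_features = 1000, frac_affected = 0,
                          missing_steepness = 2, missing_midpoint = 18,
                          seed = 5)
  miss_by_feature <- tapply(is.na(pr$table$intensity),
                            pr$table$feature_id, mean)
  base <- pr$truth$baseline[match(names(miss_by_feature),
                                  pr$truth$feature_id)]
  dec <- cut(base, stats::quantile(base, 0:10 / 10), include.lowest = TRUE)
  rate <- tapply(miss_by_feature, dec, mean)
  expect_true(all(diff(rate) <= 0.01))
})

test_that("phospho generator builds motif-structured windows", {
  d <- generate_design(3)
  ph <- generate_phospho(d, n_sites = 300, frac_motif = 1, p_full = 0,
                         halfwidth = 7, seed = 4)
  expect_true(all(nchar(ph$windows$window) == 15))
  m <- do.call(rbind, strsplit(ph$windows$window, ""))
  expect_identical(unname(m[, 8]), ph$windows$residue)
  # every TG-upregulated serine site carries the +1 proline
  up_s <- ph$truth$tg_up & ph$windows$residue == "S"
  expect_true(all(m[up_s, 9] == "P"))
  expect_true(all(ph$windows$loc_prob >= 0 & ph$windows$loc_prob <= 1))
  expect_error(generate_phospho(d, halfwidth = 1), "halfwidth")
  expect_error(generate_phospho(d, halfwidth = 2, p_full = 0.1),
               "halfwidth too small")
})

test_that("low localization probabilities empty the phospho DE path", {
  d <- generate_design(5)
  ph <- generate_phospho(d, n_sites = 80, seed = 6)
  ph$table$loc_prob <- 0.49
  pr <- generate_proteome(d, n_features = 20, seed = 6)
  both <- rbind(phosphoRescue:::fill_phospho_cols(pr$table), ph$table)
  filtered <- filter_features(both, loc_prob_min = 0.5)
  expect_equal(sum(filtered$feature_kind == "phosphopeptide"), 0)
})

test_that("background network growth yields exactly 2N-3 scored edges", {
  ids <- sprintf("P%03d", 1:150)
  net <- generate_network(ids, n_extra_nodes = 50, seed = 2)
  expect_equal(nrow(net$edges), 2 * 200 - 3)
  expect_true(all(net$edges$combined_score > 0.9 &
                    net$edges$combined_score <= 1))
  net2 <- generate_network(ids, n_extra_nodes = 50, seed = 2)
  expect_identical(net$edges, net2$edges)
  hi <- generate_network(ids, n_extra_nodes = 0,
                         score_range = c(0.95, 1), seed = 2)
  expect_true(all(hi$edges$combined_score > 0.9))
  expect_error(generate_network(character(0)), "non-empty")
})

test_that("behavior generator reproduces requested DI structure", {
  d <- generate_design(4)
  beh0 <- generate_behavior(d, di_sd = 0, seed = 8)
  mu <- c("WT.NT" = 40, "WT.greentea" = 42, "WT.EE" = 42,
          "WT.greentea+EE" = 40, "TG.NT" = 0, "TG.greentea" = 32,
          "TG.EE" = 15, "TG.greentea+EE" = 30)
  expect_equal(unname(beh0$DI),
               unname(mu[paste(beh0$genotype, beh0$treatment, sep = ".")]),
               tolerance = 1e-9)
  beh <- generate_behavior(d, di_sd = 12, seed = 8)
  expect_true(all(beh$TN + beh$TF <= beh$total + 1e-9))
  expect_equal(beh$DI, (beh$TN - beh$TF) / beh$total * 100,
               tolerance = 1e-12)
  # law of large numbers on the planted group gap
  big <- generate_behavior(generate_design(200),
                           group_di_means = c(
                             "WT.NT" = 40, "WT.greentea" = 40,
                             "WT.EE" = 40, "WT.greentea+EE" = 40,
                             "TG.NT" = 0, "TG.greentea" = 0,
                             "TG.EE" = 0, "TG.greentea+EE" = 0),
                           di_sd = 12, seed = 9)
  gap <- mean(big$DI[big$genotype == "WT" & big$treatment == "NT"]) -
    mean(big$DI[big$genotype == "TG" & big$treatment == "NT"])
  expect_equal(gap, 40, tolerance = 3)
  expect_error(generate_behavior(d, group_di_means = c("WT.NT" = 120)),
               "\\[-100, 100\\]")
})
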