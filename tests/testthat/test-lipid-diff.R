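# Differential lipidomics pipeline stages and the class-level sign test.

test_that("total-intensity normalization makes every sample sum to one", {
  m <- toy_matrix(c(2, 3, 5, 1, 1, 2), n_control = 1, n_treated = 1,
                  n_features = 3)
  nm <- normalize_total(m)
  expect_equal(nm$values[, 1], c(lip1 = 0.2, lip2 = 0.3, lip3 = 0.5))
  expect_equal(unname(colSums(nm$values)), c(1, 1), tolerance = 1e-12)
  expect_identical(nm$state, "normalized")
  # all-zero sample errors with its name
  m2 <- toy_matrix(c(1, 2, 0, 0), n_control = 1, n_treated = 1,
                   n_features = 2)
  expect_error(normalize_total(m2), "s2")
  # state machine refuses double normalization
  expect_error(normalize_total(nm), "raw")
})

test_that("log offset is three orders below the smallest positive value", {
  m <- toy_matrix(c(1e-4, 0, 0.3, 0.5, 0.2, 0.1), n_control = 1,
                  n_treated = 1, n_features = 3)
  m$state <- "normalized"
  lm <- log_transform(m)
  expect_equal(lm$provenance$log_offset, 1e-7)
  expect_equal(lm$values["lip2", 1], log(1e-7))
  # round trip: exp(out) - delta reproduces the input
  expect_equal(exp(lm$values) - 1e-7,
               matrix(c(1e-4, 0, 0.3, 0.5, 0.2, 0.1), 3, 2,
                      dimnames = dimnames(lm$values)),
               tolerance = 1e-12)
  # monotone: ordering of values is preserved
  v <- c(0.5, 0.2, 0.1, 1e-4, 0, 0.3)
  expect_identical(order(as.vector(lm$values)), order(c(1e-4, 0, 0.3,
                                                        0.5, 0.2, 0.1)))
})

test_that("subtractive offset rule errors when it would be nonpositive", {
  m <- toy_matrix(c(1e-4, 0.2, 0.3, 0.5), n_control = 1, n_treated = 1,
                  n_features = 2)
  m$state <- "normalized"
  expect_error(log_transform(m, offset_rule = "subtractive"), "nonpositive")
  m2 <- toy_matrix(c(2, 3, 5, 7), n_control = 1, n_treated = 1,
                   n_features = 2)
  m2$state <- "normalized"
  lm2 <- log_transform(m2, offset_rule = "subtractive")
  expect_equal(lm2$provenance$log_offset, 2 - 1e-3)
})

test_that("presence filter applies the >= 2/3 detection rule per arm", {
  # 3 controls + 3 treated, hand-constructed detection patterns
  vals <- rbind(
    everywhere = c(1, 1, 1, 1, 1, 1),
    two_thirds_ctrl = c(1, 1, 0, 0, 0, 0), # 2/3 controls -> kept
    one_third_each = c(1, 0, 0, 1, 0, 0),  # 1/3 both arms -> dropped
    absent = c(0, 0, 0, 0, 0, 0)
  )
  colnames(vals) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = colnames(vals), patient = "P1",
                     arm = rep(c("control", "treated"), each = 3))
  m <- presence_filter(intensity_matrix(vals, meta))
  expect_setequal(rownames(m$values), c("everywhere", "two_thirds_ctrl"))
  expect_setequal(m$provenance$presence_dropped,
                  c("one_third_each", "absent"))
})

test_that("presence filter is monotone in its threshold", {
  sim <- simulate_lipidomics(sim_config(n_classes = 5, lipids_per_class = 10,
                                        detection_rate = 0.6, seed = 21))
  m <- intensity_matrix(sim$values, sim$metadata)
  kept <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(f) {
    nrow(presence_filter(m, fraction = f)$values)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("per-patient presence scope requires the rule in every patient", {
  # samples: P1 = (C, C, T, T), P2 = (C, C, T, T)
  # lipA: detected in both P1 controls and one P2 control only
  vals <- rbind(lipA = c(1, 1, 0, 0, 1, 0, 0, 0),
                lipB = c(1, 1, 1, 1, 1, 1, 1, 1))
  colnames(vals) <- paste0("s", 1:8)
  meta <- data.frame(
    sample_id = colnames(vals),
    patient = rep(c("P1", "P2"), each = 4),
    arm = rep(c("control", "control", "treated", "treated"), 2)
  )
  m <- intensity_matrix(vals, meta)
  # per patient: P2 control fraction 1/2 < 2/3 and treated 0 -> dropped
  expect_identical(rownames(presence_filter(m)$values), "lipB")
  # pooled: control fraction 3/4 >= 2/3 -> kept
  expect_setequal(rownames(presence_filter(m, scope = "pooled")$values),
                  c("lipA", "lipB"))
})

test_that("recurrence (HPD stand-in) filter counts per-arm recurrence", {
  feats <- list(c("a", "b"), c("a"), c("a", "c"), c("b"), c("b", "c"))
  arm <- c("control", "control", "control", "treated", "treated")
  kept <- hpd_filter(feats, arm, min_fraction = 0.6)
  # a: 3/3 controls; b: 1/3 + 2/2 treated; c: 1/3 + 1/2
  expect_setequal(kept, c("a", "b"))
  expect_identical(hpd_filter(list(character(0)), "control"), character(0))
})

test_that("patient centering zeroes control means and measures shifts", {
  # controls log 1,2,3 ; treated log 5 -> treated fold-change 3
  vals <- matrix(exp(c(1, 2, 3, 5)), 1, 4,
                 dimnames = list("lip1", paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4), patient = "P1",
                     arm = c("control", "control", "control", "treated"))
  m <- intensity_matrix(vals, meta)
  m$values <- log(m$values); m$state <- "log"
  fc <- center_on_controls(m)
  expect_equal(unname(fc$mean_fc), 3)
  expect_equal(mean(fc$centered[1, 1:3]), 0, tolerance = 1e-12)
  # patient with no controls errors by name
  meta2 <- meta; meta2$arm <- "treated"
  m2 <- intensity_matrix(vals, meta2)
  m2$values <- log(m2$values); m2$state <- "log"
  expect_error(center_on_controls(m2), "P1")
})

test_that("per-lipid t-test matches the closed form and flags degenerates", {
  mk_fc <- function(treated_rows) {
    n <- ncol(treated_rows)
    centered <- cbind(matrix(0, nrow(treated_rows), 2), treated_rows)
    rownames(centered) <- paste0("lip", seq_len(nrow(treated_rows)))
    colnames(centered) <- paste0("s", seq_len(n + 2))
    structure(list(
      centered = centered,
      samples = data.frame(sample_id = colnames(centered),
                           patient = "P1",
                           arm = c("control", "control", rep("treated", n))),
      mean_fc = rowMeans(treated_rows), n_treated = n,
      provenance = list()), class = "fold_change_table")
  }
  res <- lipid_ttest(mk_fc(rbind(c(1, 2, 3))))
  # closed form: t = mean / (sd / sqrt(n)) and t tail oracle
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_identical(res$df, 2L)
  expect_equal(res$p, 2 * stats::pt(-3.4641016, 2), tolerance = 1e-6)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)

  sym <- lipid_ttest(mk_fc(rbind(c(-1, 1))))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  degen <- lipid_ttest(mk_fc(rbind(c(2, 2, 2), c(0, 0, 0))))
  expect_equal(degen$p, c(0, 1))
  expect_identical(degen$flag, rep("degenerate_variance", 2))

  single <- lipid_ttest(mk_fc(rbind(c(1.5))))
  expect_identical(single$flag, "insufficient_n")
  expect_true(is.na(single$p))
})

test_that("class binomial test counts signs and uses the exact pmf", {
  fc <- c(rep(1, 9), -1)
  names(fc) <- paste0("l", 1:10)
  cm <- data.frame(feature_id = names(fc), class = "PC")
  res <- class_binomial_test(fc, cm)
  expect_identical(res$n_up, 9L)
  expect_identical(res$n_down, 1L)
  expect_equal(res$p_hat, 0.9)
  expect_equal(res$statistic, log(1.8), tolerance = 1e-12)
  expect_equal(res$p_value, 22 / 1024) # enumeration of Binomial(10, 1/2)

  balanced <- class_binomial_test(
    stats::setNames(c(rep(1, 5), rep(-1, 5)), paste0("l", 1:10)),
    stats::setNames(rep("SM", 10), paste0("l", 1:10)))
  expect_equal(balanced$statistic, 0)
  expect_equal(balanced$p_value, 1)

  one <- class_binomial_test(c(l1 = 0.5), c(l1 = "FA"))
  expect_equal(one$p_hat, 1)
  expect_equal(one$p_value, 1) # Binomial(1, 1/2): both outcomes equally likely
})

test_that("ties are excluded but counted; empty classes are flagged", {
  fc <- stats::setNames(c(1, -1, 0, 0), paste0("l", 1:4))
  cm <- stats::setNames(c("A", "A", "A", "B"), paste0("l", 1:4))
  res <- class_binomial_test(fc, cm)
  a <- res[res$class == "A", ]
  expect_identical(a$n_tie, 1L)
  expect_identical(a$n, 2L)
  b <- res[res$class == "B", ]
  expect_identical(b$flag, "insufficient_data")
  expect_true(is.na(b$statistic))
  expect_error(class_binomial_test(c(zz = 1), cm), "missing from class map")
})

test_that("exact binomial p-values match binom.test across n <= 25", {
  for (n in c(1:10, 15, 20, 25)) {
    for (k in 0:n) {
      expect_equal(lipidsign:::exact_binom_p(k, n, 0.5),
                   stats::binom.test(k, n, 0.5)$p.value,
                   tolerance = 1e-12)
      expect_equal(lipidsign:::exact_binom_p(k, n, 0.5), enum_binom_p(k, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("pipeline on one patient with zero noise recovers injected effects", {
  sim <- simulate_lipidomics(sim_config(
    n_patients = 1, n_classes = 4, lipids_per_class = 6,
    class_effects = c(0, -1, 0.5, 0), lipid_noise_sd = 0,
    patient_effect_sd = 0, seed = 31))
  fit <- lipid_diff(sim, normalization = "none")
  # recovery is exact up to the log offset delta = min positive x 1e-3,
  # which bounds each log discrepancy by 1e-3
  expect_equal(unname(fit$fold_changes$mean_fc),
               unname(sim$truth$lipid_effects[names(fit$fold_changes$mean_fc)]),
               tolerance = 1e-3)
  cls <- stats::setNames(sim$class_map$class, sim$class_map$feature_id)
  per_class <- tapply(fit$fold_changes$mean_fc,
                      cls[names(fit$fold_changes$mean_fc)], mean)
  expect_equal(as.numeric(per_class[names(sim$truth$class_effects)]),
               unname(sim$truth$class_effects), tolerance = 1e-3)
})

test_that("negating all effects flips statistic signs and keeps p-values", {
  # note ln(p_hat / 0.5) is not antisymmetric in magnitude (ln 1.8 vs
  # ln 0.2 for 9:1 up/down), so the symmetry is in sign and p-value only
  base_cfg <- function(sgn, seed) sim_config(
    n_classes = 5, lipids_per_class = 12,
    class_effects = sgn * c(0.8, 0, -0.4, 0.2, 0), lipid_noise_sd = 0,
    patient_effect_sd = 0.3, seed = seed)
  a <- lipid_diff(simulate_lipidomics(base_cfg(1, 11)),
                  normalization = "none")$class_results
  b <- lipid_diff(simulate_lipidomics(base_cfg(-1, 11)),
                  normalization = "none")$class_results
  nz <- !is.na(a$statistic) & a$statistic != 0
  expect_identical(sign(a$statistic[nz]), -sign(b$statistic[nz]))
  expect_identical(a$n_up, b$n_down)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("pipeline is permutation-equivariant in samples and features", {
  sim <- simulate_lipidomics(sim_config(n_classes = 3, lipids_per_class = 8,
                                        class_effects = c(0.5, 0, -0.5),
                                        seed = 13))
  fit1 <- lipid_diff(sim)
  set.seed(1)
  ps <- sample(ncol(sim$values)); pf <- sample(nrow(sim$values))
  sim2 <- sim
  sim2$values <- sim$values[pf, ps]
  sim2$metadata <- sim$metadata[ps, ]
  fit2 <- lipid_diff(sim2)
  expect_equal(fit1$class_results, fit2$class_results)
  expect_equal(sort(fit1$lipid_tests$p), sort(fit2$lipid_tests$p))
})

test_that("fit object prints, summarizes, and exposes coefficients", {
  sim <- simulate_lipidomics(sim_config(n_classes = 3, lipids_per_class = 6,
                                        seed = 17))
  fit <- lipid_diff(sim)
  expect_output(print(fit), "Differential lipidomics")
  expect_output(print(summary(fit)), "binomial sign tests")
  co <- coef(fit)
  expect_named(co)
  expect_length(co, 3L)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
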