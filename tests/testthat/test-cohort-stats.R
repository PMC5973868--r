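# Cohort statistics: rank-sum tests, Storey q-values, growth metrics, IRS.

test_that("exact rank-sum p matches enumeration for small tie-free inputs", {
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "nonempty")
  w <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, 1 / 3)
  # identical tie-free groups after jitter: p = 1
  w2 <- wilcoxon_ranksum(c(1, 4, 5), c(2, 3, 6))
  expect_equal(w2$p_value, 1, tolerance = 1e-12)
  # all group-size splits up to n = 12, random tie-free data, vs combn oracle
  set.seed(19)
  for (n in c(4, 6, 8, 10, 12)) {
    for (na in 1:(n - 1)) {
      x <- sample(seq_len(100), n) # distinct integers -> tie-free
      a <- x[seq_len(na)]; b <- x[-seq_len(na)]
      got <- wilcoxon_ranksum(a, b)
      expect_identical(got$method, "exact")
      expect_equal(got$p_value, enum_wilcox_p(a, b), tolerance = 1e-12,
                   label = sprintf("n=%d na=%d", n, na))
    }
  }
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50) + 2
  w <- wilcoxon_ranksum(a, b)
  expect_identical(w$method, "normal_approx")
  expect_lt(w$p_value, 1e-4)
  # ties force the approximate path even for small n, with a notice
  expect_message(wt <- wilcoxon_ranksum(c(1, 1, 2), c(2, 3, 3)), "ties")
  expect_identical(wt$method, "normal_approx")
  # agreement with the reference implementation on the same convention
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("q-values with pi0 = 1 equal Benjamini-Hochberg exactly", {
  set.seed(23)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- storey_qvalues(p, pi0 = 1)
    expect_equal(q$q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pi0 is estimated near 1 on uniform null p-values", {
  set.seed(29)
  ok <- vapply(1:100, function(i) {
    storey_qvalues(runif(1000))$pi0 >= 0.8
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # single p = 1 -> q = 1
  expect_equal(storey_qvalues(1)$q, 1)
})

test_that("q-values are monotone in p and detect planted signal", {
  set.seed(31)
  p <- c(runif(50, 0, 1e-5), runif(950))
  res <- storey_qvalues(p)
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_true(all(res$q[1:50] < 0.05))
  expect_gt(res$pi0, 0.5)
})

test_that("endpoint t-test matches the pooled and Welch closed forms", {
  expect_error(endpoint_ttest(1, c(1, 2)), "two values")
  same <- endpoint_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  res <- endpoint_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.6742, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), 4),
               tolerance = 1e-12)
  expect_equal(res$p_value, 0.0214, tolerance = 1e-2)
  # Welch df by the Welch-Satterthwaite hand formula
  a <- c(1, 2, 3, 10); b <- c(4, 4.5, 5)
  wl <- endpoint_ttest(a, b, welch = TRUE)
  va <- var(a) / length(a); vb <- var(b) / length(b)
  df_hand <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(wl$df, df_hand, tolerance = 1e-10)
})

test_that("tumor volume follows the caliper formula and scales cubically", {
  expect_equal(tumor_volume(1, 1), 0.52)
  expect_equal(tumor_volume(5, 10), 130.0)
  expect_error(tumor_volume(0, 5), "positive")
  for (c_ in c(0.5, 2, 3)) {
    expect_equal(tumor_volume(3 * c_, 7 * c_), c_^3 * tumor_volume(3, 7),
                 tolerance = 1e-12)
  }
})

test_that("fold-change curves are baseline-normalized per animal", {
  g <- data.frame(animal_id = "a1", arm = "control", week = 0:2,
                  volume_mm3 = c(100, 200, 400))
  expect_equal(fold_change_curves(g)$fold_change, c(1, 2, 4))
  # width/length inputs are converted first
  g2 <- data.frame(animal_id = "a1", arm = "control", week = 0:1,
                   width_mm = c(5, 5), length_mm = c(10, 20))
  expect_equal(fold_change_curves(g2)$fold_change, c(1, 2))
  g3 <- data.frame(animal_id = "a1", arm = "control", week = 0:1,
                   volume_mm3 = c(0, 10))
  expect_error(fold_change_curves(g3), "baseline")
})

test_that("TGI is 0 for identical arms and 1 for a flat treated arm", {
  ctrl <- simulate_growth(3, 5, 0.3, 0.3, noise_sd = 0, seed = 1)
  tg <- auc_tgi(ctrl, n_boot = 200, seed = 1)
  expect_equal(tg$tgi, 0, tolerance = 1e-12)
  expect_true(tg$ci[["lower"]] <= 0 && tg$ci[["upper"]] >= 0)
  # control doubling weekly, treated flat: hand trapezoid of t*log2 over
  # [0, 5] is 12.5*log2; span-normalized 2.5*log2; treated aAUC = 0
  g <- simulate_growth(3, 5, log(2), 0, noise_sd = 0, seed = 1)
  tg2 <- auc_tgi(g, n_boot = 100, seed = 2)
  expect_equal(tg2$aauc_control, 2.5 * log(2), tolerance = 1e-12)
  expect_equal(tg2$aauc_treated, 0, tolerance = 1e-12)
  expect_equal(tg2$tgi, 1, tolerance = 1e-12)
})

test_that("bootstrap CI is deterministic under a fixed seed and ordered", {
  g <- simulate_growth(6, 5, 0.35, 0.1, noise_sd = 0.15, seed = 41)
  a <- auc_tgi(g, n_boot = 500, seed = 7)
  b <- auc_tgi(g, n_boot = 500, seed = 7)
  expect_identical(a$ci, b$ci)
  expect_lte(a$ci[["lower"]], a$tgi)
  expect_gte(a$ci[["upper"]], a$tgi)
  # relabeling animals within an arm leaves the estimate unchanged
  g2 <- g
  g2$animal_id <- factor(g2$animal_id,
                         levels = unique(g2$animal_id),
                         labels = sprintf("x%02d", seq_along(unique(g2$animal_id))))
  g2$animal_id <- as.character(g2$animal_id)
  expect_equal(auc_tgi(g2, n_boot = 10, seed = 1)$tgi, a$tgi,
               tolerance = 1e-12)
})

test_that("TGI detects a positive effect in most noisy replicates", {
  hits <- vapply(1:200, function(r) {
    g <- simulate_growth(5, 5, 0.3, 0.15, noise_sd = 0.05, seed = r)
    auc_tgi(g, n_boot = 10, seed = r)$tgi > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("immunoreactivity score multiplies intensity by percent category", {
  expect_identical(as.integer(irs_score(3, 80)), 9L)
  expect_identical(as.integer(irs_score(0, 55)), 0L)
  # printed bin boundaries: 10% is category 1, 11% category 2
  expect_identical(as.integer(irs_score(2, 10)), 2L)
  expect_identical(as.integer(irs_score(2, 11)), 4L)
  expect_identical(as.integer(irs_score(2, 10.5)), 2L) # (10, 11) stays cat 1
  expect_identical(as.integer(irs_score(1, 0)), 0L)
  expect_error(irs_score(4, 50), "0..3")
  expect_error(irs_score(2, 101), "\\[0, 100\\]")
})
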