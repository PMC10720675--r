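ln_toy <- tibble::tibble(
  patient_id = c("P1", "P1", "P1", "P2", "P2"),
  involvement = c("involved", "cancer_free", "cancer_free", "involved", "involved"),
  gc_count = c(1L, 3L, 2L, 4L, 0L),
  mean_gc_area_mm2 = c(0.05, 0.07, 0.06, 0.08, NA),
  mean_gc_circularity = c(0.8, 0.7, 0.75, 0.6, NA),
  sinus_area_mm2 = c(0.1, 0.4, 0.2, 0.05, 0.3),
  normalized_sinus_area = c(0.05, 0.2, 0.1, 0.02, 0.15),
  scs_width_um = c(10, 30, 20, 15, 25),
  time = c(24, 24, 24, 60, 60), event = c(1L, 1L, 1L, 0L, 0L))

test_that("patient aggregation supports mean, total and max modes", {
  ag <- aggregate_patient(ln_toy, mode = "mean", subset = "all")
  expect_equal(ag$mean_gc_count[ag$patient_id == "P1"], 2.0)
  tot <- aggregate_patient(ln_toy, mode = "total_gc")
  expect_equal(tot$total_gc_count, c(6L, 4L))
  mx <- aggregate_patient(ln_toy, mode = "max_sinus")
  expect_equal(mx$max_sinus_area_mm2, c(0.4, 0.3))
  # subset filter: P1 cancer-free LNs only
  cf <- aggregate_patient(ln_toy, mode = "mean", subset = "cancer_free")
  expect_equal(cf$mean_gc_count[cf$patient_id == "P1"], 2.5)
  expect_true(is.na(cf$mean_gc_count[cf$patient_id == "P2"]))  # excluded
  expect_error(aggregate_patient(ln_toy, mode = "median"), "arg")
})

test_that("dichotomize honours the printed boundary conventions", {
  expect_equal(as.character(dichotomize(c(1.5, 2.0, 3.0), 2, "gte")),
               c("low", "high", "high"))
  expect_equal(as.character(dichotomize(c(0.13, 0.14), 0.13, "gt")),
               c("low", "high"))
  expect_warning(g <- dichotomize(c(1, 1, 1), 5, "gte"), "one side")
  expect_true(attr(g, "degenerate"))
})

test_that("minimal-p scan returns the best admissible cut", {
  withr::with_seed(1, {
    v <- runif(60, 0, 10)
    grp <- v >= 5
    time <- rexp(60, 0.02 * ifelse(grp, 0.25, 1))
    event <- rep(1L, 60)
  })
  oc <- optimal_cutoff(v, time, event, min_group_frac = 0.1)
  # minimal p is <= p at any prespecified admissible cut (minimum property)
  for (cut in c(2, 5, 8)) {
    g <- v >= cut
    expect_lte(oc$p, nodemorph:::logrank_p(time, event, g) + 1e-12)
  }
  expect_gt(oc$n_cuts, 10)
  # two distinct values leave exactly one admissible cut
  v2 <- rep(c(1, 2), each = 10)
  oc2 <- optimal_cutoff(v2, rexp(20, 0.05), rep(1L, 20), min_group_frac = 0.1)
  expect_equal(oc2$n_cuts, 1L)
  expect_error(optimal_cutoff(rep(3, 10), rexp(10), rep(1L, 10)), "distinct")
})

test_that("minimal-p approach is optimistic on null data", {
  # the method's known multiple-testing bias: under the null, the minimal p
  # falls below the 0.05 level far more often than the nominal 5 percent
  ps <- withr::with_seed(42, vapply(1:30, function(i) {
    v <- runif(100); time <- rexp(100, 0.05); ev <- rep(1L, 100)
    optimal_cutoff(v, time, ev, min_group_frac = 0.1)$p
  }, 1))
  expect_gte(mean(ps < 0.05), 0.25)
  expect_lt(median(ps), 0.25)
})

test_that("log-rank statistic matches the hand contingency computation", {
  time <- c(2, 4, 5, 7, 9, 12); event <- c(1, 1, 0, 1, 1, 1)
  g <- c(0, 1, 0, 1, 0, 1)
  km <- km_logrank(time, event, g)
  expect_equal(km$chisq, logrank_chisq_hand(time, event, g), tolerance = 1e-10)
  expect_equal(km$p, pchisq(km$chisq, 1, lower.tail = FALSE))
})

test_that("KM curves are proper survival functions", {
  withr::with_seed(3, {
    time <- rexp(40, 0.05); event <- rbinom(40, 1, 0.8)
    g <- rep(c("a", "b"), 20)
  })
  km <- km_logrank(time, event, g)
  for (grp in c("a", "b")) {
    s <- km$curves$surv[km$curves$group == grp]
    expect_true(all(diff(s) <= 1e-12))   # non-increasing
    expect_lte(max(s), 1)
  }
  # duplicated data across groups -> null identity
  t2 <- c(time, time); e2 <- c(event, event); g2 <- rep(c("a", "b"), each = 40)
  expect_gt(km_logrank(t2, e2, g2)$p, 0.99)
  expect_error(km_logrank(time, event, rep("a", 40)), "2 non-empty groups")
  expect_error(km_logrank(c(1, 2), c(0, 0), c("a", "b")), "events|2 non-empty")
})

test_that("exact permutation p matches independent exhaustive enumeration", {
  time <- c(1, 3, 4, 6, 8, 9, 11, 13)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  g <- c(1, 1, 0, 1, 0, 0, 1, 0)
  km <- km_logrank(time, event, g, p_method = "permutation")
  obs <- logrank_chisq_hand(time, event, g)
  combs <- combn(8, 4)
  stats <- apply(combs, 2, function(ix) {
    a <- rep(0, 8); a[ix] <- 1
    logrank_chisq_hand(time, event, a)
  })
  expect_equal(km$p, mean(stats >= obs - 1e-12), tolerance = 1e-12)
})

test_that("Cox recovery on a planted cohort and its error modes", {
  coh <- generate_cohort(cohort_spec(n_patients = 400L, seed = 10L))
  pat <- aggregate_patient(coh, mode = "mean")
  pat$group <- dichotomize(pat$mean_gc_count, 2, "gte")
  cox <- cox_ph(pat, ~ group)
  td <- tidy(cox)
  # point estimate lands in the planted neighbourhood; frequentist CI
  # coverage is asserted across 50 replicates in the acceptance suite
  expect_true(td$hr[1] > 0.2 && td$hr[1] < 0.45)
  gl <- glance(cox)
  expect_lt(gl$p_likelihood, 0.001)
  # null cohort: CI covers 1
  coh0 <- generate_cohort(cohort_spec(
    n_patients = 400L, seed = 11L,
    feature_effect = list(feature = "mean_gc_count", cutoff = 2, hr = 1)))
  pat0 <- aggregate_patient(coh0, mode = "mean")
  pat0$group <- dichotomize(pat0$mean_gc_count, 2, "gte")
  td0 <- tidy(cox_ph(pat0, ~ group))
  expect_true(td0$conf_low[1] <= 1 && 1 <= td0$conf_high[1])
  # zero events
  pat$event <- 0L
  expect_error(cox_ph(pat, ~ group), "few events")
})

test_that("rank tests and FDR adjustment match their conventions", {
  # identical samples -> p = 1 under the mid-rank ties convention
  d_id <- tibble::tibble(value = rep(c(1, 2, 3, 4, 5), 2),
                         group = rep(c("a", "b"), each = 5))
  expect_equal(group_compare(d_id, test = "wilcoxon")$p, 1)
  # strongly shifted distributions
  withr::with_seed(5, {
    d_sh <- tibble::tibble(value = c(rnorm(50), rnorm(50, 3)),
                           group = rep(c("a", "b"), each = 50))
  })
  expect_lt(group_compare(d_sh, test = "wilcoxon")$p, 0.001)
  expect_lt(group_compare(d_sh, test = "kruskal")$p, 0.001)
  expect_error(group_compare(tibble::tibble(value = 1:3, group = "a")), "2 groups")
  # BH by hand: [0.01, 0.02, 0.03] -> [0.03, 0.03, 0.03]
  fam <- tibble::tibble(value = rep(d_sh$value, 3), group = rep(d_sh$group, 3),
                        feature = rep(c("f1", "f2", "f3"), each = 100))
  out <- group_compare(fam, test = "wilcoxon", adjust = "fdr")
  expect_equal(out$p_adj, p.adjust(out$p, "BH"))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  byhand <- rev(cummin(rev(c(0.01, 0.02, 0.03) * 3 / (1:3))))
  expect_equal(byhand, rep(0.03, 3))
})

test_that("Pearson correlation matches hand computation", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10))$r, 1.0)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1.0)
  x <- c(1, 2, 4, 5, 9); y <- c(2, 1, 5, 4, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- pearson_correlation(x, y)
  expect_equal(out$r, r_hand)
  t_stat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(out$p, 2 * pt(abs(t_stat), 3, lower.tail = FALSE))
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "variance")
})

test_that("the tnbc preset encodes the published cut-offs", {
  ps <- cutoff_preset("tnbc")
  expect_equal(ps$cutoff[ps$feature == "mean_gc_count"], 2)
  expect_equal(ps$orientation[ps$feature == "mean_gc_count"], "gte")
  expect_equal(ps$cutoff[ps$feature == "normalized_sinus_area"], 0.13)
  expect_equal(ps$orientation[ps$feature == "normalized_sinus_area"], "gt")
  expect_equal(ps$cutoff[ps$feature == "scs_width_um"], 20)
  expect_error(cutoff_preset("other"), "unknown preset")
})
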