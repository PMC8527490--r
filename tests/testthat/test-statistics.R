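test_that("per-sample rates and asymmetry match hand-computed values", {
  mk <- toy_markers(100L, pairs = 1L)
  v <- c(rep("AAAA", 5), rep("BBBB", 3), rep("AABB", 92))
  cfgm <- toy_config(mk, list(t1 = v, t2 = rep("AABB", 100)))
  s <- summarize_samples(cfgm)
  expect_equal(s$he_rate_pct, c(8.00, 0.00))
  expect_equal(s$asymmetry_pct, c(62.5, NA))
  expect_equal(s$n_classified, c(100L, 100L))
})

test_that("rate decomposition aaaa + bbbb = total holds exactly pre-rounding", {
  withr::local_seed(31)
  mk <- toy_markers(37L, pairs = 1:2)
  for (i in 1:20) {
    cfgm <- toy_config(mk, list(t = random_config_seq(nrow(mk))))
    s <- summarize_samples(cfgm)
    expect_identical(s$he_rate_pct, s$aaaa_rate_pct + s$bbbb_rate_pct)
  }
})

test_that("cohort shares behave on concentrated, even and empty conversion patterns", {
  mk <- toy_markers(10L, pairs = 1:4)
  base <- rep("AABB", nrow(mk))
  on_pair <- function(p, k, what = "AAAA") {
    v <- base; v[which(mk$pair_index == p)[seq_len(k)]] <- what; v
  }
  # conversions only on pair 4
  co <- summarize_cohort(toy_config(mk, list(t1 = on_pair(4, 3), t2 = on_pair(4, 2))), mk)
  expect_equal(co$pairs$share_pct[co$pairs$pair_index == 4], 100)
  expect_equal(sum(co$pairs$share_pct), 100)
  # equal conversions on pairs 1 and 2
  co2 <- summarize_cohort(toy_config(mk, list(t1 = on_pair(1, 2), t2 = on_pair(2, 2))), mk)
  expect_equal(co2$pairs$share_pct[co2$pairs$pair_index %in% 1:2], c(50, 50))
  # zero conversions is flagged and shares are undefined
  co3 <- summarize_cohort(toy_config(mk, list(t1 = base)), mk)
  expect_equal(co3$genome$flag, "no_conversions")
  expect_true(all(is.na(co3$pairs$share_pct)))
})

test_that("per-pair shares always sum to 100 when conversions exist", {
  withr::local_seed(99)
  mk <- toy_markers(15L, pairs = 1:5)
  for (i in 1:20) {
    cfgm <- toy_config(mk, list(a = random_config_seq(nrow(mk)),
                                b = random_config_seq(nrow(mk))))
    co <- summarize_cohort(cfgm, mk)
    if (co$genome$n_converted > 0) {
      expect_equal(sum(co$pairs$share_pct), 100, tolerance = 1e-9)
    }
  }
})

test_that("conversion bias reports pooled direction rates and labels asymmetry", {
  mk <- toy_markers(100L, pairs = 1:10)
  base <- rep("AABB", 1000L)
  mk_cfg <- function(n_a, n_b) {
    v <- base
    if (n_a > 0) v[seq_len(n_a)] <- "AAAA"
    if (n_b > 0) v[500 + seq_len(n_b)] <- "BBBB"
    v
  }
  bal <- conversion_bias(summarize_cohort(toy_config(mk, list(t = mk_cfg(10, 10))), mk))
  expect_equal(unlist(bal$pooled, use.names = FALSE), c(1.00, 1.00))
  expect_equal(bal$samples$bias_label, "balanced")

  onesided <- conversion_bias(summarize_cohort(toy_config(mk, list(t = mk_cfg(30, 0))), mk))
  expect_equal(unlist(onesided$pooled, use.names = FALSE), c(3.00, 0.00))
  expect_equal(onesided$samples$bias_label, "AAAA-biased")

  # a 58.6/41.4 split sits just outside the default 50+/-5 band but is
  # captured as balanced under a wider band
  near <- conversion_bias(summarize_cohort(toy_config(mk, list(t = mk_cfg(58, 41))), mk))
  expect_equal(near$samples$asymmetry_pct, 100 * 58 / 99, tolerance = 1e-6)
  expect_equal(near$samples$bias_label, "AAAA-biased")
  wide <- conversion_bias(summarize_cohort(toy_config(mk, list(t = mk_cfg(58, 41))), mk),
                          balanced_band = 10)
  expect_equal(wide$samples$bias_label, "balanced")
})

test_that("total collapse requires every classified locus converted one way", {
  mk <- toy_markers(6L, pairs = 1:2)
  all_a <- c(rep("AAAA", 6), rep("AABB", 6))
  nearly <- all_a; nearly[3] <- "AABB"
  with_na <- c(rep("BBBB", 5), NA, rep("AABB", 6))
  cfgm <- toy_config(mk, list(t1 = all_a, t2 = nearly, t3 = with_na))
  tc <- detect_total_collapse(cfgm, mk)
  pick <- function(s, p) tc[tc$sample_id == s & tc$pair_index == p, ]
  expect_true(pick("t1", 1)$collapse); expect_equal(pick("t1", 1)$direction, "AAAA")
  expect_false(pick("t2", 1)$collapse)
  expect_true(pick("t3", 1)$collapse); expect_equal(pick("t3", 1)$direction, "BBBB")
  # undefined on a pair with zero classified loci
  cfg0 <- toy_config(mk, list(t1 = c(rep(NA_character_, 6), rep("AABB", 6))))
  expect_true(is.na(detect_total_collapse(cfg0, mk)$collapse[1]))
})

test_that("collapse flags agree with the simulator truth log on clean data", {
  cfg <- sim_config(n_pairs = 3L, loci_per_pair = 30L, p_he = 0.6,
                    n_generations = 10L, error_rate = 0, missing_rate = 0,
                    n_lineages = 5L, seed = 21L)
  co <- simulate_cohort(cfg)
  cfgm <- classify_configurations(co$calls, co$samples)
  tc <- detect_total_collapse(cfgm, co$markers)
  for (l in seq_len(cfg$n_lineages)) {
    dos <- co$lineages[[l]]$truth$dosage[, cfg$n_generations]
    for (p in 1:3) {
      d <- dos[co$markers$pair_index == p]
      want <- all(d == 4L) || all(d == 0L)
      got <- tc$collapse[tc$sample_id == co$samples$sample_id[l] &
                           tc$pair_index == p]
      expect_identical(got, want)
    }
  }
})

test_that("trend statistics recover monotone, constant and degenerate series", {
  up <- tibble::tibble(he_rate_pct = c(1, 2, 3, 4), generation = 1:4)
  tr <- generation_trend(up, n_perm = 2000, seed = 4)
  expect_equal(tr$rho, 1)
  expect_equal(tr$slope, 1)
  expect_lt(tr$p_perm, 0.10)   # only 24 label orders exist at n = 4

  flat <- tibble::tibble(he_rate_pct = rep(2.5, 5), generation = 1:5)
  tf <- generation_trend(flat, n_perm = 100, seed = 1)
  expect_equal(tf$rho, 0)
  expect_equal(tf$p_perm, 1)

  expect_error(generation_trend(up[1:2, ]), ">= 3 samples")

  td <- tidy(tr)
  expect_equal(td$term, c("spearman_rho", "theil_sen_slope"))
  gl <- glance(tr)
  expect_equal(gl$n_samples, 4L)
  expect_true(all(c("rho", "slope", "p_perm", "seed") %in% names(gl)))
})
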