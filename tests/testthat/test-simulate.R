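test_that("the null model yields all-heterozygous calls and an empty truth log", {
  cfg <- sim_config(n_pairs = 2L, loci_per_pair = 30L, p_he = 0, p_gc = 0,
                    error_rate = 0, missing_rate = 0, n_generations = 6L,
                    seed = 9L)
  sim <- simulate_lineage(cfg)
  expect_true(all(as.matrix(sim$calls[-1]) == "HET"))
  expect_equal(nrow(sim$truth$events), 0L)
  expect_true(all(sim$truth$dosage == 2L))
  expect_false(any(sim$truth$altered))
  expect_equal(balanced_exchange_fraction(sim$truth), 0)
})

test_that("the same seed reproduces bitwise-identical output and lineages are count-stable", {
  cfg <- sim_config(n_pairs = 2L, loci_per_pair = 25L, p_he = 0.3,
                    p_gc = 1e-3, n_generations = 4L, seed = 101L)
  a <- simulate_lineage(cfg)
  b <- simulate_lineage(cfg)
  expect_identical(a, b)

  cfg3 <- sim_config(n_pairs = 2L, loci_per_pair = 25L, p_he = 0.3,
                     n_generations = 4L, n_lineages = 3L, seed = 55L)
  cfg5 <- sim_config(n_pairs = 2L, loci_per_pair = 25L, p_he = 0.3,
                     n_generations = 4L, n_lineages = 5L, seed = 55L)
  co3 <- simulate_cohort(cfg3); co5 <- simulate_cohort(cfg5)
  expect_identical(co3$calls, co5$calls[names(co3$calls)])
})

test_that("crossovers conserve per-locus dosage within the meiotic cell; conversions do not", {
  cfg <- sim_config(n_pairs = 1L, loci_per_pair = 40L, p_he = 1, p_gc = 0,
                    seed = 1L)
  orig <- polyhe:::.init_state(cfg)[[1]]
  t_rel <- seq_len(40L) / 41
  withr::with_seed(12, {
    for (i in 1:50) {
      me <- polyhe:::.meiosis_events(orig, t_rel, cfg, 1L, 1L, 1L)
      expect_identical(colSums(me$orig), colSums(orig))
      orig <- me$orig
    }
  })
  # with conversion switched on, total A-origin content can change
  cfg_gc <- sim_config(n_pairs = 1L, loci_per_pair = 40L, p_he = 0, p_gc = 0.2,
                       seed = 1L)
  changed <- withr::with_seed(13, {
    any(vapply(1:50, function(i) {
      me <- polyhe:::.meiosis_events(polyhe:::.init_state(cfg_gc)[[1]],
                                     t_rel, cfg_gc, 1L, 1L, 1L)
      !identical(colSums(me$orig), colSums(polyhe:::.init_state(cfg_gc)[[1]]))
    }, logical(1)))
  })
  expect_true(changed)
})

test_that("a forced reciprocal exchange leaves all altered loci balanced; selfing fixes them", {
  # at the cell level a reciprocal crossover keeps 2:2 dosage at every locus
  cfg <- sim_config(n_pairs = 1L, loci_per_pair = 30L, p_he = 1, p_gc = 0,
                    distal_bias = 1, seed = 2L)
  t_rel <- seq_len(30L) / 31
  st <- polyhe:::.init_state(cfg)[[1]]
  me <- withr::with_seed(42, polyhe:::.meiosis_events(st, t_rel, cfg, 1L, 1L, 1L))
  d <- colSums(me$orig)
  alt <- colSums(me$orig[1:2, , drop = FALSE]) < 2L |
    colSums(me$orig[3:4, , drop = FALSE]) > 0L
  expect_true(any(alt))
  expect_true(all(d[alt] == 2L))   # every altered locus still balanced

  # across generations of selfing the invisible (balanced) fraction shrinks
  frac_at <- function(seed, gen) {
    sim <- simulate_lineage(sim_config(n_pairs = 2L, loci_per_pair = 40L,
                                       p_he = 0.5, p_gc = 0, error_rate = 0,
                                       missing_rate = 0, n_generations = 8L,
                                       seed = seed))
    balanced_exchange_fraction(sim$truth, gen)
  }
  fr <- vapply(1:40, function(s) c(frac_at(s, 2L), frac_at(s, 8L)), numeric(2))
  expect_gte(stats::median(fr[1, ]), stats::median(fr[2, ]))
})

test_that("crossover positions concentrate distally as the bias parameter grows", {
  mean_d <- vapply(c(1, 2, 4), function(b) {
    pos <- withr::with_seed(200 + b, {
      unlist(lapply(1:50, function(s) {
        sim <- simulate_lineage(sim_config(n_pairs = 2L, loci_per_pair = 10L,
                                           p_he = 0.8, p_gc = 0, distal_bias = b,
                                           n_generations = 4L, seed = s))
        ev <- sim$truth$events
        ev$pos_rel[ev$type == "crossover"]
      }))
    })
    mean(pmin(pos, 1 - pos))
  }, numeric(1))
  expect_true(mean_d[1] > mean_d[2] && mean_d[2] > mean_d[3])
})

test_that("replicate disagreement from genotyping error fires the consistency filter at the expected rate", {
  err <- 0.01
  cfg <- sim_config(n_pairs = 4L, loci_per_pair = 500L, p_he = 0, p_gc = 0,
                    error_rate = err, missing_rate = 0, n_generations = 2L,
                    n_lineages = 1L, seed = 31L)
  sim <- emit_cohort(cfg, withr::local_tempdir(), n_replicates = 2L)
  calls <- read_genotype_table(sim$genotypes)
  samples <- read_sample_metadata(sim$samples)
  rc <- replicate_consistency_filter(calls, samples)
  n_removed <- length(rc$removed_markers)
  # two replicates disagree with prob q = 2e(1-e) + e^2/2; three replicate
  # groups (two parents + one plant) give per-marker removal 1 - (1-q)^3
  q <- 2 * err * (1 - err) + err^2 / 2
  p_rm <- 1 - (1 - q)^3
  L <- 2000L
  expect_gt(n_removed, stats::qbinom(0.0005, L, p_rm))
  expect_lt(n_removed, stats::qbinom(0.9995, L, p_rm))
})

test_that("heavy dropout removes most markers at the missingness stage", {
  cfg <- sim_config(n_pairs = 2L, loci_per_pair = 100L, p_he = 0,
                    error_rate = 0, missing_rate = 0.5, n_generations = 2L,
                    n_lineages = 2L, seed = 77L)
  sim <- emit_cohort(cfg, withr::local_tempdir())
  qc_cfg <- filter_config(min_sample_call_rate = 0)  # keep the noisy samples
  qc <- tryCatch(
    run_qc(read_genotype_table(sim$genotypes), read_marker_map(sim$markers),
           read_sample_metadata(sim$samples), qc_cfg),
    error = function(e) e)
  if (inherits(qc, "error")) {
    fail(paste("qc errored:", conditionMessage(qc)))
  }
  rpt <- qc$report
  expect_gt(rpt$removed[rpt$stage == "marker_missingness"], 100L)
})

test_that("emitted cohorts include oriented parent columns and parse end-to-end", {
  cfg <- sim_config(n_pairs = 2L, loci_per_pair = 20L, p_he = 0.3,
                    error_rate = 0, missing_rate = 0, n_generations = 3L,
                    n_lineages = 2L, seed = 12L)
  sim <- emit_cohort(cfg, withr::local_tempdir())
  calls <- read_genotype_table(sim$genotypes)
  samples <- read_sample_metadata(sim$samples)
  pa_cols <- samples$sample_id[samples$role == "PARENT_A"]
  expect_true(all(as.matrix(calls[pa_cols]) == "HOM_A"))
  expect_true(file.exists(sim$truth_events) && file.exists(sim$truth_dosage))
  dos <- readr::read_tsv(sim$truth_dosage, show_col_types = FALSE)
  expect_equal(nrow(dos), 40L)
  expect_true(all(as.matrix(dos[-1]) %in% 0:4))
})
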