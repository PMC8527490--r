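#' Simulation settings for a selfing neoallotetraploid lineage
#'
#' The simulator follows a single selfing lineage founded by an induced
#' AABB allotetraploid (S0: two A-origin and two B-origin chromosomes per
#' homoeologous pair). Each generation, two gametes are drawn from
#' independent meioses of the parent. Meiosis uses bivalent disomic pairing;
#' with probability `p_he` per pair a single homoeologous crossover occurs
#' between one A-origin-slot and one B-origin-slot chromosome, at a relative
#' position drawn from a symmetric U-shaped density on (0,1) with weight
#' proportional to `[u(1-u)]^(1/b - 1)` (a Beta(1/b, 1/b) law; `b = 1` is
#' uniform, larger `b` concentrates crossovers distally). Gene conversion
#' copies the ancestry of a short tract from a homoeologous chromosome at
#' rate `p_gc` per locus per meiosis. The chip-like readout is dosage-blind:
#' only loci where all four copies share one parental origin are called
#' homozygous; genotyping error and missingness are then applied per call.
#'
#' @param n_pairs Number of homoeologous chromosome pairs. Default 10.
#' @param loci_per_pair Diagnostic loci per pair (recycled to `n_pairs`).
#'   Default 400 (about 4,000 genome-wide, emulating a ~4,263-locus panel).
#' @param chrom_length_bp Chromosome length in bp per pair (recycled).
#'   Default 1.5e8.
#' @param p_he Probability of one homoeologous crossover per pair per
#'   meiosis. Default 0.05.
#' @param distal_bias Beta-shape parameter `b >= 1` for crossover position.
#'   Default 4.
#' @param p_gc Gene-conversion probability per locus per meiosis.
#'   Default 1e-4.
#' @param gc_tract_loci Conversion tract length in loci. Default 1.
#' @param n_generations Selfing generations to simulate. Default 8.
#' @param error_rate Per-call mis-genotyping probability (call flipped to a
#'   uniformly chosen other non-missing state). Default 0.002.
#' @param missing_rate Per-call dropout probability. Default 0.02.
#' @param n_lineages Number of independent lineages (cohort runs). Default 1.
#' @param marker_spacing `"equal"` (default; equally spaced positions, which
#'   makes segment geometry analytically checkable) or `"uniform"` (positions
#'   drawn uniformly along the chromosome).
#' @param seed Integer seed; every random draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 10L, loci_per_pair = 400L,
                       chrom_length_bp = 1.5e8, p_he = 0.05, distal_bias = 4,
                       p_gc = 1e-4, gc_tract_loci = 1L, n_generations = 8L,
                       error_rate = 0.002, missing_rate = 0.02,
                       n_lineages = 1L, marker_spacing = c("equal", "uniform"),
                       seed = 1L) {
  marker_spacing <- match.arg(marker_spacing)
  n_pairs <- as.integer(n_pairs)
  loci_per_pair <- rep_len(as.integer(loci_per_pair), n_pairs)
  chrom_length_bp <- rep_len(as.numeric(chrom_length_bp), n_pairs)
  stopifnot(n_pairs >= 1L, all(loci_per_pair >= 1L),
            p_he >= 0, p_he <= 1, p_gc >= 0, p_gc <= 1,
            error_rate >= 0, error_rate <= 1, missing_rate >= 0, missing_rate <= 1,
            distal_bias >= 1, gc_tract_loci >= 1L, n_generations >= 1L,
            n_lineages >= 1L)
  structure(list(n_pairs = n_pairs, loci_per_pair = loci_per_pair,
                 chrom_length_bp = chrom_length_bp, p_he = p_he,
                 distal_bias = distal_bias, p_gc = p_gc,
                 gc_tract_loci = as.integer(gc_tract_loci),
                 n_generations = as.integer(n_generations),
                 error_rate = error_rate, missing_rate = missing_rate,
                 n_lineages = as.integer(n_lineages),
                 marker_spacing = marker_spacing, seed = as.integer(seed)),
            class = "sim_config")
}

# Marker map for a simulated genome; equal spacing unless cfg says uniform.
.sim_markers <- function(cfg) {
  purrr::map_dfr(seq_len(cfg$n_pairs), function(p) {
    L <- cfg$loci_per_pair[p]
    len <- cfg$chrom_length_bp[p]
    pos <- if (cfg$marker_spacing == "equal") {
      as.integer(round(seq_len(L) * len / (L + 1)))
    } else {
      sort(as.integer(ceiling(stats::runif(L) * (len - 1))))
    }
    pos <- pmax(1L, pos)
    while (anyDuplicated(pos)) pos <- as.integer(pos + cumsum(duplicated(pos)))
    tibble::tibble(
      marker_id = sprintf("AX-%02d%05d", p, seq_len(L)),
      pair_index = p, chrom_label = sprintf("B%02d", p), pos_bp = pos,
      allele_a_parent = "A", allele_b_parent = "B"
    )
  })
}

# Initial S0 state: per pair a 4 x L logical matrix of origins (TRUE = A).
# Rows 1-2 are the A-slot chromosomes, rows 3-4 the B-slot chromosomes.
.init_state <- function(cfg) {
  lapply(seq_len(cfg$n_pairs), function(p) {
    L <- cfg$loci_per_pair[p]
    rbind(matrix(TRUE, 2L, L), matrix(FALSE, 2L, L))
  })
}

# Meiotic events on one pair's 4 x L origin matrix: possible homoeologous
# crossover, then gene-conversion events. Crossovers exchange material
# (per-locus dosage across the four haplotypes is conserved); conversions
# copy it (the only non-conserving event).
.meiosis_events <- function(orig, pos_rel, cfg, pair, generation, meiosis) {
  L <- ncol(orig)
  events <- list()
  if (cfg$p_he > 0 && stats::runif(1) < cfg$p_he) {
    u <- stats::rbeta(1, 1 / cfg$distal_bias, 1 / cfg$distal_bias)
    i <- sample(1:2, 1L); j <- sample(3:4, 1L)
    aff <- pos_rel > u
    if (any(aff)) {
      tmp <- orig[i, aff]
      orig[i, aff] <- orig[j, aff]
      orig[j, aff] <- tmp
    }
    events <- c(events, list(tibble::tibble(
      generation = generation, meiosis = meiosis, pair_index = pair,
      type = "crossover", pos_rel = u,
      pos_bp = as.numeric(ceiling(u * cfg$chrom_length_bp[pair])),
      start_idx = NA_integer_, tract_len = NA_integer_,
      hap_from = i, hap_to = j)))
  }
  if (cfg$p_gc > 0) {
    k <- stats::rbinom(1L, L, cfg$p_gc)
    if (k > 0L) {
      starts <- sample.int(L, k)
      for (s in starts) {
        r <- sample.int(4L, 1L)
        d <- if (r <= 2L) sample(3:4, 1L) else sample(1:2, 1L)
        idx <- s:min(s + cfg$gc_tract_loci - 1L, L)
        orig[r, idx] <- orig[d, idx]
        events <- c(events, list(tibble::tibble(
          generation = generation, meiosis = meiosis, pair_index = pair,
          type = "conversion", pos_rel = NA_real_, pos_bp = NA_real_,
          start_idx = s, tract_len = length(idx), hap_from = d, hap_to = r)))
      }
    }
  }
  list(orig = orig, events = events)
}

# One meiosis: events then one gamete (one A-slot + one B-slot chromosome).
.meiosis_pair <- function(orig, pos_rel, cfg, pair, generation, meiosis) {
  me <- .meiosis_events(orig, pos_rel, cfg, pair, generation, meiosis)
  gamete <- me$orig[c(sample(1:2, 1L), sample(3:4, 1L)), , drop = FALSE]
  list(gamete = gamete, events = me$events)
}

# Dosage-blind chip readout of a dosage vector d_A in 0..4.
.readout_calls <- function(d_a) {
  ifelse(d_a == 4L, "HOM_A", ifelse(d_a == 0L, "HOM_B", "HET"))
}

# Genotyping error then dropout, independently per call.
.apply_noise <- function(calls, error_rate, missing_rate) {
  n <- length(calls)
  if (error_rate > 0) {
    flip <- stats::runif(n) < error_rate
    if (any(flip)) {
      other <- lapply(calls[flip], function(v) setdiff(.call_levels, v))
      calls[flip] <- vapply(other, function(o) o[sample.int(2L, 1L)], character(1))
    }
  }
  if (missing_rate > 0) calls[stats::runif(n) < missing_rate] <- NA_character_
  calls
}

#' Simulate one selfing lineage
#'
#' Runs the forward model of [sim_config()] for one lineage and returns the
#' per-generation genotype readout together with a complete truth log.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed overriding `cfg$seed` (used by
#'   [simulate_cohort()] to split the stream per lineage).
#' @param markers Optional pre-built marker map (used by [simulate_cohort()]
#'   so all lineages share one map); default builds it from `cfg`.
#' @return List with
#'   `markers` (simulated marker map),
#'   `calls` (wide tibble: `marker_id` + one noisy call column per
#'   generation, named `S1`..`Sn`),
#'   `true_calls` (same before error/missingness), and
#'   `truth`: `events` (tibble of crossover/conversion events),
#'   `dosage` (loci x generations integer matrix of A-subgenome dosage
#'   `d_A` in 0..4), `altered` (loci x generations logical: any haplotype
#'   changed origin relative to S0).
#' @export
simulate_lineage <- function(cfg, seed = cfg$seed, markers = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(as.integer(seed), {
    if (is.null(markers)) markers <- .sim_markers(cfg)
    pos_rel <- lapply(seq_len(cfg$n_pairs), function(p) {
      markers$pos_bp[markers$pair_index == p] / cfg$chrom_length_bp[p]
    })
    state <- .init_state(cfg)
    L_tot <- sum(cfg$loci_per_pair)
    G <- cfg$n_generations
    dosage <- matrix(NA_integer_, L_tot, G)
    altered <- matrix(NA, L_tot, G)
    calls <- matrix(NA_character_, L_tot, G)
    true_calls <- matrix(NA_character_, L_tot, G)
    all_events <- list()
    row_of_pair <- split(seq_len(L_tot), markers$pair_index)
    for (g in seq_len(G)) {
      new_state <- vector("list", cfg$n_pairs)
      for (p in seq_len(cfg$n_pairs)) {
        m1 <- .meiosis_pair(state[[p]], pos_rel[[p]], cfg, p, g, 1L)
        m2 <- .meiosis_pair(state[[p]], pos_rel[[p]], cfg, p, g, 2L)
        new_state[[p]] <- rbind(m1$gamete[1L, ], m2$gamete[1L, ],
                                m1$gamete[2L, ], m2$gamete[2L, ])
        all_events <- c(all_events, m1$events, m2$events)
      }
      state <- new_state
      for (p in seq_len(cfg$n_pairs)) {
        rows <- row_of_pair[[as.character(p)]]
        d <- colSums(state[[p]])
        dosage[rows, g] <- as.integer(d)
        altered[rows, g] <- colSums(state[[p]][1:2, , drop = FALSE]) < 2L |
          colSums(state[[p]][3:4, , drop = FALSE]) > 0L
      }
      tc <- .readout_calls(dosage[, g])
      true_calls[, g] <- tc
      calls[, g] <- .apply_noise(tc, cfg$error_rate, cfg$missing_rate)
    }
    gen_names <- paste0("S", seq_len(G))
    events <- if (length(all_events) > 0) dplyr::bind_rows(all_events) else
      tibble::tibble(generation = integer(0), meiosis = integer(0),
                     pair_index = integer(0), type = character(0),
                     pos_rel = numeric(0), pos_bp = numeric(0),
                     start_idx = integer(0), tract_len = integer(0),
                     hap_from = integer(0), hap_to = integer(0))
    list(
      markers = markers,
      calls = dplyr::bind_cols(tibble::tibble(marker_id = markers$marker_id),
                               stats::setNames(as.data.frame(calls,
                                                             stringsAsFactors = FALSE),
                                               gen_names)),
      true_calls = dplyr::bind_cols(tibble::tibble(marker_id = markers$marker_id),
                                    stats::setNames(as.data.frame(true_calls,
                                                                  stringsAsFactors = FALSE),
                                                    gen_names)),
      truth = list(events = events, dosage = dosage, altered = altered)
    )
  })
}

#' Simulate a cohort of independent lineages
#'
#' Each lineage runs [simulate_lineage()] with its own seed derived from the
#' cohort seed by a per-lineage counter (`seed + lineage index`), so adding
#' lineages never perturbs earlier ones. Every lineage is sampled (read out)
#' at one target generation.
#'
#' @param cfg A [sim_config()]; `cfg$n_lineages` lineages are simulated.
#' @param generations Integer vector of sampling generations, recycled to
#'   `n_lineages`. Default `cfg$n_generations` for all.
#' @param event Cohort label written into the sample metadata. Default
#'   `"SimEvent1"`.
#' @return List with `markers`, `calls` (wide tibble: `marker_id` + one
#'   column per sampled lineage), `samples` (metadata tibble with roles,
#'   generations and replicate groups), `lineages` (list of full
#'   [simulate_lineage()] results) and `cfg`.
#' @export
simulate_cohort <- function(cfg, generations = cfg$n_generations,
                            event = "SimEvent1") {
  stopifnot(inherits(cfg, "sim_config"))
  gens <- rep_len(as.integer(generations), cfg$n_lineages)
  stopifnot(all(gens >= 1L), all(gens <= cfg$n_generations))
  markers <- withr::with_seed(cfg$seed, .sim_markers(cfg))
  lineages <- lapply(seq_len(cfg$n_lineages), function(l) {
    simulate_lineage(cfg, seed = cfg$seed + l, markers = markers)
  })
  ids <- sprintf("%s-S%d-pl%02d", event, gens, seq_len(cfg$n_lineages))
  calls <- tibble::tibble(marker_id = markers$marker_id)
  for (l in seq_len(cfg$n_lineages)) {
    calls[[ids[l]]] <- lineages[[l]]$calls[[paste0("S", gens[l])]]
  }
  samples <- tibble::tibble(sample_id = ids, role = "TETRAPLOID", event = event,
                            generation = gens, replicate_group = ids)
  list(markers = markers, calls = calls, samples = samples,
       lineages = lineages, generations = gens, cfg = cfg)
}

#' Fraction of ancestry-altered loci invisible to the dosage readout
#'
#' A balanced homoeologous exchange changes which chromosome carries which
#' ancestry but leaves the 2:2 subgenome dosage intact, so chip genotyping
#' cannot see it. This reports, at a given generation, the fraction of loci
#' whose ancestry was altered (any haplotype changed origin relative to S0)
#' but whose dosage is still 2:2.
#'
#' @param truth The `truth` element of a [simulate_lineage()] result.
#' @param generation Generation to evaluate (default: last simulated).
#' @return A fraction in `[0, 1]`; 0 when no locus was altered.
#' @export
balanced_exchange_fraction <- function(truth, generation = ncol(truth$dosage)) {
  alt <- truth$altered[, generation]
  if (!any(alt)) return(0)
  mean(truth$dosage[alt, generation] == 2L)
}

#' Emit a simulated cohort as pipeline input files
#'
#' Writes a simulated cohort in the exact tabular dialects the readers
#' expect, including two clean synthetic parent columns (all `AA` / all
#' `BB`, subject to the same error/missingness model) and `n_replicates`
#' technical-replicate columns per plant with independent noise, so the full
#' QC-to-trend pipeline runs end-to-end on simulator output.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param generations Sampling generation per lineage (recycled).
#' @param event Cohort label.
#' @param n_replicates Technical replicates per plant (>= 1). Default 2.
#' @param dialect Genotype dialect to write. Default `"axiom_letters"`.
#' @return Invisibly, a named list of file paths (`genotypes`, `markers`,
#'   `samples`, `truth_events`, `truth_dosage`) plus the in-memory `cohort`.
#' @export
emit_cohort <- function(cfg, dir, generations = cfg$n_generations,
                        event = "SimEvent1", n_replicates = 2L,
                        dialect = "axiom_letters") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(cfg, generations, event)
  markers <- cohort$markers
  L <- nrow(markers)
  withr::with_seed(cfg$seed + 100003L, {
    calls <- tibble::tibble(marker_id = markers$marker_id)
    meta <- list()
    add_plant <- function(plant_id, true_vec, role, generation) {
      for (r in seq_len(n_replicates)) {
        sid <- if (n_replicates > 1L) sprintf("%s_r%d", plant_id, r) else plant_id
        calls[[sid]] <<- .apply_noise(true_vec, cfg$error_rate, cfg$missing_rate)
        meta[[length(meta) + 1L]] <<- tibble::tibble(
          sample_id = sid, role = role, event = event,
          generation = if (role == "TETRAPLOID") generation else NA_integer_,
          replicate_group = plant_id)
      }
    }
    add_plant("ParentA", rep("HOM_A", L), "PARENT_A", NA_integer_)
    add_plant("ParentB", rep("HOM_B", L), "PARENT_B", NA_integer_)
    for (l in seq_len(cfg$n_lineages)) {
      g <- cohort$generations[l]
      plant <- cohort$samples$sample_id[l]
      true_vec <- cohort$lineages[[l]]$true_calls[[paste0("S", g)]]
      add_plant(plant, true_vec, "TETRAPLOID", g)
    }
    samples <- dplyr::bind_rows(meta)
  })
  paths <- list(genotypes = file.path(dir, "genotypes.tsv"),
                markers = file.path(dir, "marker_map.tsv"),
                samples = file.path(dir, "samples.tsv"),
                truth_events = file.path(dir, "truth_events.tsv"),
                truth_dosage = file.path(dir, "truth_dosage.tsv"))
  write_genotype_table(calls, paths$genotypes, dialect = dialect)
  write_marker_map(markers, paths$markers)
  write_sample_metadata(samples, paths$samples)
  events <- purrr::map_dfr(seq_len(cfg$n_lineages), function(l) {
    ev <- cohort$lineages[[l]]$truth$events
    if (nrow(ev) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(lineage = cohort$samples$sample_id[l])[
      rep(1L, nrow(ev)), , drop = FALSE], ev)
  })
  if (nrow(events) == 0) {
    events <- tibble::tibble(lineage = character(0), generation = integer(0),
                             meiosis = integer(0), pair_index = integer(0),
                             type = character(0), pos_rel = numeric(0),
                             pos_bp = numeric(0), start_idx = integer(0),
                             tract_len = integer(0), hap_from = integer(0),
                             hap_to = integer(0))
  }
  readr::write_tsv(events, paths$truth_events, progress = FALSE, na = "NA")
  dos <- tibble::tibble(marker_id = markers$marker_id)
  for (l in seq_len(cfg$n_lineages)) {
    dos[[cohort$samples$sample_id[l]]] <-
      cohort$lineages[[l]]$truth$dosage[, cohort$generations[l]]
  }
  readr::write_tsv(dos, paths$truth_dosage, progress = FALSE)
  invisible(c(paths, list(cohort = cohort)))
}
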