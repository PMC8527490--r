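#' Quality-control filter settings
#'
#' Thresholds follow standard Axiom-array practice for this kind of study:
#' samples are retained when their call rate is strictly above
#' `min_sample_call_rate`, markers are retained when minor-allele frequency is
#' strictly above `min_maf` and missingness is at most `max_marker_missing`,
#' and markers with inconsistent calls between technical replicates of the
#' same plant are discarded.
#'
#' @param min_sample_call_rate Minimum per-sample call rate (retained when
#'   strictly greater). Default 0.90.
#' @param min_maf Minimum minor-allele frequency in the tetraploid cohort
#'   (retained when strictly greater). Default 0.05.
#' @param max_marker_missing Maximum per-marker missing fraction (removed when
#'   strictly greater). Default 0.20.
#' @param require_replicate_consistency Discard markers with conflicting
#'   replicate calls and collapse replicate columns. Default `TRUE`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_sample_call_rate = 0.90, min_maf = 0.05,
                          max_marker_missing = 0.20,
                          require_replicate_consistency = TRUE) {
  stopifnot(min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            max_marker_missing >= 0, max_marker_missing <= 1)
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_maf = min_maf,
                 max_marker_missing = max_marker_missing,
                 require_replicate_consistency = isTRUE(require_replicate_consistency)),
            class = "filter_config")
}

#' Per-sample call rate
#'
#' @param calls Wide call tibble.
#' @return Tibble with `sample_id` and `call_rate` (fraction of non-missing
#'   calls over all markers).
#' @export
sample_call_rate <- function(calls) {
  n_markers <- nrow(calls)
  if (n_markers == 0L) abort("call rate undefined: zero markers")
  cols <- .sample_cols(calls)
  tibble::tibble(
    sample_id = cols,
    call_rate = vapply(cols, function(s) mean(!is.na(calls[[s]])), numeric(1),
                       USE.NAMES = FALSE)
  )
}

#' Per-marker missingness
#'
#' @param calls Wide call tibble.
#' @return Tibble with `marker_id` and `missingness` (fraction of samples with
#'   a missing call).
#' @export
marker_missingness <- function(calls) {
  cols <- .sample_cols(calls)
  if (length(cols) == 0L) abort("missingness undefined: zero samples")
  m <- is.na(as.matrix(calls[cols]))
  tibble::tibble(marker_id = calls$marker_id, missingness = rowMeans(m))
}

#' Per-marker minor-allele frequency
#'
#' Allele copies are counted from the calls (homozygote = 2 copies,
#' heterozygote = 1 of each) over the non-missing calls of `cohort`;
#' `maf = min(f, 1 - f)` where `f` is the second-allele frequency. Markers
#' with no data in the cohort get `NA`.
#'
#' @param calls Wide call tibble.
#' @param cohort Character vector of sample columns to count over.
#' @return Tibble with `marker_id` and `maf`.
#' @export
minor_allele_frequency <- function(calls, cohort) {
  stopifnot(length(cohort) > 0, all(cohort %in% names(calls)))
  m <- as.matrix(calls[cohort])
  n_b <- rowSums(2 * (m == "HOM_B"), na.rm = TRUE) + rowSums(m == "HET", na.rm = TRUE)
  n_tot <- 2 * rowSums(!is.na(m))
  f <- ifelse(n_tot > 0, n_b / n_tot, NA_real_)
  tibble::tibble(marker_id = calls$marker_id, maf = pmin(f, 1 - f))
}

#' Replicate-consistency filter and replicate collapse
#'
#' A marker is discarded when any replicate group (samples sharing
#' `replicate_group`) carries two non-missing, unequal calls at that marker.
#' Pairs with one missing call are consistent (missingness is
#' non-informative). Surviving replicate groups are collapsed to one
#' consensus column per plant, named by `replicate_group`, taking the
#' non-missing value when any replicate has one.
#'
#' @param calls Wide call tibble.
#' @param samples Sample metadata tibble.
#' @return List with `calls` (collapsed), `samples` (one row per plant) and
#'   `removed_markers` (character vector of discarded marker ids).
#' @export
replicate_consistency_filter <- function(calls, samples) {
  samples <- samples[samples$sample_id %in% names(calls), ]
  rg <- samples$replicate_group
  rg[is.na(rg) | rg == ""] <- samples$sample_id[is.na(rg) | rg == ""]
  samples$replicate_group <- rg
  groups <- split(samples$sample_id, factor(rg, levels = unique(rg)))
  removed <- character(0)
  consensus <- list()
  meta_rows <- integer(0)
  for (g in names(groups)) {
    ids <- groups[[g]]
    m <- as.matrix(calls[ids])
    if (length(ids) > 1L) {
      n_distinct <- apply(m, 1L, function(r) length(unique(r[!is.na(r)])))
      removed <- c(removed, calls$marker_id[n_distinct > 1L])
    }
    # consensus: first non-missing value in the group (identical by consistency)
    cons <- m[, 1L]
    if (ncol(m) > 1L) {
      for (j in seq(2L, ncol(m))) {
        take <- is.na(cons) & !is.na(m[, j])
        cons[take] <- m[take, j]
      }
    }
    consensus[[g]] <- unname(cons)
    meta_rows <- c(meta_rows, match(ids[1L], samples$sample_id))
  }
  removed <- sort(unique(removed))
  out_calls <- tibble::tibble(marker_id = calls$marker_id)
  for (g in names(groups)) out_calls[[g]] <- consensus[[g]]
  out_samples <- samples[meta_rows, ]
  out_samples$sample_id <- names(groups)
  keep <- !(out_calls$marker_id %in% removed)
  list(calls = out_calls[keep, ], samples = out_samples, removed_markers = removed)
}

#' Select parental-diagnostic loci
#'
#' Keeps markers at which the A-genome parent and the B-genome parent carry
#' non-missing, opposite homozygous calls, and orients every retained call so
#' that `HOM_A` is the A-parent homozygote and `HOM_B` the B-parent
#' homozygote. At these loci the tetraploid's subgenome dosage is inferable
#' from the chip call.
#'
#' @param calls Wide call tibble (after QC).
#' @param markers Marker map tibble covering the call rows.
#' @param samples Sample metadata tibble; must contain exactly one retained
#'   `PARENT_A` and one `PARENT_B` sample.
#' @return List with `calls` (oriented, diagnostic loci only), `markers`
#'   (diagnostic subset, `allele_a_parent`/`allele_b_parent` filled with the
#'   parental call codes when not already set) and `n_diagnostic`.
#' @export
select_diagnostic_loci <- function(calls, markers, samples) {
  pa <- samples$sample_id[samples$role == "PARENT_A"]
  pb <- samples$sample_id[samples$role == "PARENT_B"]
  pa <- intersect(pa, names(calls)); pb <- intersect(pb, names(calls))
  if (length(pa) != 1L || length(pb) != 1L) {
    abort("diagnostic selection needs exactly one retained PARENT_A and one PARENT_B sample")
  }
  a <- calls[[pa]]; b <- calls[[pb]]
  hom <- c("HOM_A", "HOM_B")
  keep <- !is.na(a) & !is.na(b) & a %in% hom & b %in% hom & a != b
  flipped <- keep & a == "HOM_B"        # letter-allele B belongs to parent A here
  out <- calls[keep, ]
  flip_rows <- flipped[keep]
  if (any(flip_rows)) {
    cols <- .sample_cols(out)
    m <- as.matrix(out[cols])
    mf <- m[flip_rows, , drop = FALSE]
    sw <- mf
    sw[mf == "HOM_A"] <- "HOM_B"
    sw[mf == "HOM_B"] <- "HOM_A"
    m[flip_rows, ] <- sw
    out[cols] <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  }
  mk <- markers[match(out$marker_id, markers$marker_id), ]
  fill <- is.na(mk$allele_a_parent) | is.na(mk$allele_b_parent)
  mk$allele_a_parent[fill] <- ifelse(flip_rows[fill], "B", "A")
  mk$allele_b_parent[fill] <- ifelse(flip_rows[fill], "A", "B")
  list(calls = out, markers = mk, n_diagnostic = nrow(out))
}

#' Run the full marker/sample quality-control pipeline
#'
#' Stages run in a fixed order: per-sample call rate, replicate-consistency
#' discard and replicate collapse, per-marker missingness, tetraploid-cohort
#' minor-allele frequency, then parental-diagnostic selection with
#' orientation. The stage order matters: replicates are collapsed before
#' per-marker statistics so plants are not double-counted, and MAF is
#' computed on the tetraploid cohort only (the fixed parents would distort
#' allele frequencies).
#'
#' @param calls Wide call tibble in map order (see [normalize_marker_order()]).
#' @param markers Marker map tibble.
#' @param samples Sample metadata tibble.
#' @param config A [filter_config()].
#' @return List with `calls` (oriented diagnostic calls), `markers`
#'   (diagnostic loci), `samples` (retained, replicate-collapsed),
#'   `report` (per-stage provenance tibble with `stage`, `removed`,
#'   `retained`) and `n_diagnostic_pre_maf` (diagnostic count before the MAF
#'   stage, for comparison).
#' @export
run_qc <- function(calls, markers, samples, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  calls <- normalize_marker_order(calls, markers)
  report <- list()
  n0 <- nrow(calls)

  # stage 1: sample call rate (strict >)
  scr <- sample_call_rate(calls)
  keep_samples <- scr$sample_id[scr$call_rate > config$min_sample_call_rate]
  dropped_samples <- setdiff(scr$sample_id, keep_samples)
  calls <- calls[c("marker_id", keep_samples)]
  samples <- samples[samples$sample_id %in% keep_samples, ]
  report$sample_call_rate <- c(removed = 0L, retained = n0)

  # stage 2: replicate consistency + collapse
  if (config$require_replicate_consistency) {
    rc <- replicate_consistency_filter(calls, samples)
    report$replicate_consistency <- c(removed = length(rc$removed_markers),
                                      retained = nrow(rc$calls))
    calls <- rc$calls; samples <- rc$samples
  } else {
    report$replicate_consistency <- c(removed = 0L, retained = nrow(calls))
  }

  # stage 3: marker missingness (remove when strictly > max)
  mm <- marker_missingness(calls)
  rm_miss <- mm$marker_id[mm$missingness > config$max_marker_missing]
  calls <- calls[!(calls$marker_id %in% rm_miss), ]
  report$marker_missingness <- c(removed = length(rm_miss), retained = nrow(calls))

  # diagnostic count before MAF (reported for comparison with post-MAF count)
  tet <- intersect(samples$sample_id[samples$role == "TETRAPLOID"], names(calls))
  pre <- tryCatch(select_diagnostic_loci(calls, markers, samples)$n_diagnostic,
                  error = function(e) NA_integer_)

  # stage 4: MAF over the tetraploid cohort (retain when strictly > min;
  # all-missing markers removed as "no data")
  if (length(tet) > 0) {
    maf <- minor_allele_frequency(calls, tet)
    rm_maf <- maf$marker_id[is.na(maf$maf) | maf$maf <= config$min_maf]
  } else {
    rm_maf <- character(0)
  }
  calls <- calls[!(calls$marker_id %in% rm_maf), ]
  report$maf <- c(removed = length(rm_maf), retained = nrow(calls))

  # stage 5: diagnostic selection + orientation
  diag <- select_diagnostic_loci(calls, markers, samples)
  report$diagnostic_selection <- c(removed = nrow(calls) - diag$n_diagnostic,
                                   retained = diag$n_diagnostic)

  rep_tbl <- tibble::tibble(
    stage = names(report),
    removed = vapply(report, `[[`, integer(1), "removed"),
    retained = vapply(report, `[[`, integer(1), "retained")
  )
  list(calls = diag$calls, markers = diag$markers, samples = samples,
       report = rep_tbl, dropped_samples = dropped_samples,
       n_diagnostic_pre_maf = pre)
}
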