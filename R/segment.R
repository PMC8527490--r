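#' Segmentation settings
#'
#' Converted loci come in two patterns: runs of adjacent converted loci
#' ("blocks", attributed to tetrasomic meiotic crossover) and isolated
#' converted loci ("interspersed", attributed to gene conversion). A run must
#' contain at least `min_block_loci` converted loci to be called a block;
#' shorter runs are reported locus-by-locus as interspersed events. Up to
#' `max_gap_loci` consecutive unresolved (no-call) loci are tolerated inside
#' a run; a balanced `AABB` locus always terminates it.
#'
#' @param min_block_loci Minimum converted loci per block (>= 2). Default 3:
#'   the smallest run unlikely to arise from independent single-locus
#'   conversions at the conversion densities seen in this kind of data.
#' @param max_gap_loci Maximum consecutive unresolved loci tolerated inside a
#'   run. Default 1.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(min_block_loci = 3L, max_gap_loci = 1L) {
  min_block_loci <- as.integer(min_block_loci)
  max_gap_loci <- as.integer(max_gap_loci)
  stopifnot(min_block_loci >= 2L, max_gap_loci >= 0L)
  structure(list(min_block_loci = min_block_loci, max_gap_loci = max_gap_loci),
            class = "segmentation_config")
}

#' Segment one chromosome pair of one sample
#'
#' Scans an ordered configuration sequence and partitions its converted loci
#' into maximal runs of one converted configuration (`AAAA` or `BBBB`),
#' tolerating up to `max_gap_loci` consecutive unresolved loci inside a run;
#' an `AABB` locus or a locus of the other converted configuration always
#' breaks the run. Runs with at least `min_block_loci` converted loci become
#' one `BLOCK` segment; the converted loci of shorter runs are emitted as
#' single-locus `INTERSPERSED` segments. Segments never overlap and jointly
#' cover every converted locus exactly once. A converted locus that could
#' extend either of two gap-separated runs joins the earlier (left) run, a
#' consequence of the deterministic left-to-right scan.
#'
#' @param configs Character vector over `{"AABB","AAAA","BBBB", NA}` in locus
#'   order along the chromosome pair.
#' @param cfg A [segmentation_config()].
#' @param pos_bp Optional integer vector of locus positions (same length as
#'   `configs`) used to fill `start_bp`/`end_bp`.
#' @return Tibble of segments: `config`, `kind`, `start_idx`, `end_idx`
#'   (1-based inclusive indices into `configs`), `n_loci`, and
#'   `start_bp`/`end_bp` when positions are given.
#' @export
segment_pair <- function(configs, cfg = segmentation_config(), pos_bp = NULL) {
  stopifnot(inherits(cfg, "segmentation_config"))
  known <- c("AABB", "AAAA", "BBBB")
  if (any(!is.na(configs) & !(configs %in% known))) {
    abort("unknown configuration code in sequence")
  }
  conv <- which(configs %in% c("AAAA", "BBBB"))
  empty <- tibble::tibble(config = character(0), kind = character(0),
                          start_idx = integer(0), end_idx = integer(0),
                          n_loci = integer(0))
  if (!is.null(pos_bp)) {
    stopifnot(length(pos_bp) == length(configs))
    empty$start_bp <- integer(0); empty$end_bp <- integer(0)
  }
  if (length(conv) == 0L) return(empty)

  cum_aabb <- cumsum(!is.na(configs) & configs == "AABB")
  if (length(conv) > 1L) {
    i <- conv[-length(conv)]; j <- conv[-1L]
    aabb_between <- cum_aabb[j - 1L] - cum_aabb[i]
    gap_na <- j - i - 1L                      # all-NA when no AABB between
    brk <- (configs[i] != configs[j]) | (aabb_between > 0L) |
      (aabb_between == 0L & gap_na > cfg$max_gap_loci)
  } else {
    brk <- logical(0)
  }
  run_id <- cumsum(c(TRUE, brk))
  run_n <- tabulate(run_id)
  first_of_run <- conv[!duplicated(run_id)]
  last_of_run <- conv[!duplicated(run_id, fromLast = TRUE)]
  is_block <- run_n >= cfg$min_block_loci
  inter_loci <- conv[!is_block[run_id]]
  start_idx <- c(first_of_run[is_block], inter_loci)
  ord <- order(start_idx)
  out <- tibble::tibble(
    config = c(configs[first_of_run[is_block]], configs[inter_loci])[ord],
    kind = rep(c("BLOCK", "INTERSPERSED"),
               c(sum(is_block), length(inter_loci)))[ord],
    start_idx = start_idx[ord],
    end_idx = c(last_of_run[is_block], inter_loci)[ord],
    n_loci = c(run_n[is_block], rep(1L, length(inter_loci)))[ord]
  )
  if (!is.null(pos_bp)) {
    out$start_bp <- pos_bp[out$start_idx]
    out$end_bp <- pos_bp[out$end_idx]
  }
  out
}

#' Segment every sample and chromosome pair of a configuration matrix
#'
#' @param config Wide configuration tibble from [classify_configurations()],
#'   rows in marker-map order.
#' @param markers Marker map tibble covering the rows (provides `pair_index`
#'   and `pos_bp`).
#' @param cfg A [segmentation_config()].
#' @return Tibble of segments with `sample_id`, `pair_index`, `config`,
#'   `kind`, `start_idx`, `end_idx` (indices into the pair's ordered loci),
#'   `start_bp`, `end_bp`, `n_loci`. Output is independent of sample order.
#' @export
segment_all <- function(config, markers, cfg = segmentation_config()) {
  mk <- markers[match(config$marker_id, markers$marker_id), ]
  if (anyNA(mk$marker_id)) abort("configuration rows missing from the marker map")
  cols <- .sample_cols(config)
  pair_rows <- split(seq_len(nrow(config)), mk$pair_index)
  out <- purrr::map_dfr(cols, function(s) {
    purrr::map_dfr(names(pair_rows), function(p) {
      rows <- pair_rows[[p]]
      segs <- segment_pair(config[[s]][rows], cfg, pos_bp = mk$pos_bp[rows])
      if (nrow(segs) == 0L) return(NULL)
      dplyr::bind_cols(tibble::tibble(sample_id = s,
                                      pair_index = as.integer(p))[rep(1L, nrow(segs)), ],
                       segs)
    })
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(sample_id = character(0), pair_index = integer(0),
                          config = character(0), kind = character(0),
                          start_idx = integer(0), end_idx = integer(0),
                          n_loci = integer(0), start_bp = integer(0),
                          end_bp = integer(0))
  }
  out
}

#' Distal enrichment of exchange blocks
#'
#' For each segment midpoint, computes the relative distance `d` in `[0, 0.5]`
#' to the nearest chromosome end, where the chromosome extent is the span
#' from the first to the last diagnostic locus of the pair. Compares blocks
#' against interspersed loci with a one-sided Wilcoxon rank-sum test of the
#' hypothesis that blocks lie closer to the ends (smaller `d`).
#'
#' @param segments Segment tibble from [segment_all()].
#' @param markers Marker map of the diagnostic loci.
#' @return One-row tibble: `n_block`, `n_interspersed`, `mean_d_block`,
#'   `mean_d_interspersed`, `p_value`. With no blocks the statistic is
#'   undefined and the means/p-value are `NA`.
#' @export
distal_enrichment <- function(segments, markers) {
  ext <- markers %>%
    dplyr::group_by(.data$pair_index) %>%
    dplyr::summarise(lo = min(.data$pos_bp), hi = max(.data$pos_bp), .groups = "drop")
  seg <- dplyr::left_join(segments, ext, by = "pair_index") %>%
    dplyr::mutate(mid = (.data$start_bp + .data$end_bp) / 2,
                  d = pmin(.data$mid - .data$lo, .data$hi - .data$mid) /
                    (.data$hi - .data$lo))
  d_block <- seg$d[seg$kind == "BLOCK"]
  d_inter <- seg$d[seg$kind == "INTERSPERSED"]
  p <- if (length(d_block) > 0 && length(d_inter) > 0) {
    suppressWarnings(stats::wilcox.test(d_block, d_inter,
                                        alternative = "less")$p.value)
  } else NA_real_
  tibble::tibble(
    n_block = length(d_block), n_interspersed = length(d_inter),
    mean_d_block = if (length(d_block) > 0) mean(d_block) else NA_real_,
    mean_d_interspersed = if (length(d_inter) > 0) mean(d_inter) else NA_real_,
    p_value = p
  )
}

#' Write a segment table
#'
#' Writes `segments.tsv` with the segmentation settings echoed in `#` header
#' comment lines.
#'
#' @param segments Segment tibble from [segment_all()].
#' @param path Output TSV path.
#' @param cfg The [segmentation_config()] used (echoed in the header).
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, cfg = segmentation_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# min_block_loci=%d max_gap_loci=%d",
                     cfg$min_block_loci, cfg$max_gap_loci), con)
  cols <- c("sample_id", "pair_index", "config", "kind",
            "start_bp", "end_bp", "n_loci")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(segments) > 0) {
    body <- do.call(paste, c(lapply(segments[cols], as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
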