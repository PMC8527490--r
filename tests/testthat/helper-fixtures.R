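# Small in-code fixtures shared across test files.

toy_markers <- function(n_per_pair = 5L, pairs = 1:2, spacing_bp = 100L) {
  purrr::map_dfr(pairs, function(p) {
    tibble::tibble(
      marker_id = sprintf("m%02d_%03d", p, seq_len(n_per_pair)),
      pair_index = as.integer(p),
      chrom_label = sprintf("B%02d", p),
      pos_bp = as.integer(seq_len(n_per_pair) * spacing_bp),
      allele_a_parent = "A", allele_b_parent = "B"
    )
  })
}

# Wide call tibble from a named list of per-sample call vectors.
toy_calls <- function(markers, sample_calls) {
  out <- tibble::tibble(marker_id = markers$marker_id)
  for (s in names(sample_calls)) out[[s]] <- sample_calls[[s]]
  out
}

toy_samples <- function(sample_ids, roles = NULL, event = "Ev1",
                        generations = NULL) {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    role = roles %||% rep("TETRAPLOID", n),
    event = event,
    generation = generations %||% rep(NA_integer_, n),
    replicate_group = sample_ids
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
`%>%` <- dplyr::`%>%`

# Wide configuration tibble from per-sample configuration vectors.
toy_config <- function(markers, sample_configs) {
  out <- tibble::tibble(marker_id = markers$marker_id)
  for (s in names(sample_configs)) out[[s]] <- sample_configs[[s]]
  out
}
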