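#' Classify oriented calls into genome configurations
#'
#' At a parental-diagnostic locus the chip call reveals subgenome dosage only
#' when all four homoeologous copies carry the same parental allele: `HET`
#' means the balanced `AABB` configuration (any mixed dosage, the readout is
#' dosage-blind), `HOM_A` means `AAAA`, `HOM_B` means `BBBB`, and a missing
#' call is `UNRESOLVED` (`NA`).
#'
#' @param call Character vector of oriented calls.
#' @return Character vector over `{"AABB","AAAA","BBBB"}` with `NA` for
#'   unresolved loci.
#' @export
classify_call <- function(call) {
  lut <- c(HET = "AABB", HOM_A = "AAAA", HOM_B = "BBBB")
  bad <- !is.na(call) & !(call %in% names(lut))
  if (any(bad)) abort(sprintf("unknown call value '%s'", call[which(bad)[1]]))
  unname(lut[call])
}

#' Build the per-locus configuration matrix
#'
#' Applies [classify_call()] element-wise to the tetraploid samples of an
#' oriented diagnostic call table. Classification is pointwise: no
#' information is shared across samples or loci.
#'
#' @param calls Oriented wide call tibble (diagnostic loci).
#' @param samples Sample metadata; only `TETRAPLOID` samples are classified.
#' @return Wide tibble `marker_id` + one column per tetraploid sample with
#'   values in `{"AABB","AAAA","BBBB", NA}`.
#' @export
classify_configurations <- function(calls, samples) {
  tet <- intersect(samples$sample_id[samples$role == "TETRAPLOID"], names(calls))
  if (length(tet) == 0L) abort("no tetraploid samples present in the call table")
  out <- tibble::tibble(marker_id = calls$marker_id)
  for (s in tet) out[[s]] <- classify_call(calls[[s]])
  out
}

#' Per-sample configuration tallies
#'
#' @param config Wide configuration tibble from [classify_configurations()].
#' @return Tibble with one row per sample: `n_AABB`, `n_AAAA`, `n_BBBB`,
#'   `n_UNRESOLVED`; the four tallies always sum to the number of diagnostic
#'   loci.
#' @export
configuration_tallies <- function(config) {
  cols <- .sample_cols(config)
  purrr::map_dfr(cols, function(s) {
    v <- config[[s]]
    tibble::tibble(sample_id = s,
                   n_AABB = sum(v == "AABB", na.rm = TRUE),
                   n_AAAA = sum(v == "AAAA", na.rm = TRUE),
                   n_BBBB = sum(v == "BBBB", na.rm = TRUE),
                   n_UNRESOLVED = sum(is.na(v)))
  })
}

#' Write a configuration matrix
#'
#' Writes `configurations.tsv`-style output: marker annotation columns
#' followed by one column per sample with codes `AABB`/`AAAA`/`BBBB`/`NA`.
#'
#' @param config Wide configuration tibble.
#' @param markers Marker map tibble covering the rows.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_configurations <- function(config, markers, path) {
  mk <- markers[match(config$marker_id, markers$marker_id),
                c("marker_id", "chrom_label", "pos_bp")]
  readr::write_tsv(dplyr::bind_cols(mk, config[.sample_cols(config)]),
                   path, progress = FALSE, na = "NA")
  invisible(path)
}

#' Read a configuration matrix written by [write_configurations()]
#'
#' @param path Path to the TSV.
#' @return List with `config` (wide configuration tibble) and `markers`.
#' @export
read_configurations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = "NA", progress = FALSE)
  need <- c("marker_id", "chrom_label", "pos_bp")
  if (!all(need %in% names(raw))) {
    abort(sprintf("configuration table '%s' must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  markers <- tibble::tibble(marker_id = raw$marker_id, chrom_label = raw$chrom_label,
                            pos_bp = as.integer(raw$pos_bp),
                            allele_a_parent = NA_character_,
                            allele_b_parent = NA_character_)
  markers$pair_index <- parse_pair_index(markers$chrom_label)
  markers <- markers[, c("marker_id", "pair_index", "chrom_label", "pos_bp",
                         "allele_a_parent", "allele_b_parent")]
  config <- raw[, c("marker_id", setdiff(names(raw), need))]
  bad <- vapply(.sample_cols(config),
                function(s) any(!is.na(config[[s]]) &
                                  !(config[[s]] %in% c("AABB", "AAAA", "BBBB"))),
                logical(1))
  if (any(bad)) abort("configuration table contains unknown configuration codes")
  list(config = config, markers = markers)
}
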