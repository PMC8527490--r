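#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

# Internal call vocabulary. Calls are stored as character with NA for no-calls.
# Until diagnostic selection runs, HOM_A/HOM_B are oriented to the marker's
# first/second lettered allele (Axiom "A"/"B" allele, or VCF REF/ALT);
# select_diagnostic_loci() re-orients them to the A-/B-genome parents.
.call_levels <- c("HOM_A", "HET", "HOM_B")

.dialects <- list(
  axiom_letters = c(AA = "HOM_A", AB = "HET", BB = "HOM_B", NoCall = NA_character_),
  numeric       = c(`0` = "HOM_A", `1` = "HET", `2` = "HOM_B", `-1` = NA_character_)
)

#' Read a genotype-call table
#'
#' Reads a tab-separated genotype table (one row per marker, one column per
#' sample, first column `marker_id`) and normalizes the call codes of the
#' given dialect into the internal vocabulary `HOM_A`/`HET`/`HOM_B`/`NA`.
#'
#' @param path Path to a TSV file.
#' @param dialect Call-code dialect: `"axiom_letters"` (`AA`/`AB`/`BB`/`NoCall`)
#'   or `"numeric"` (`0`/`1`/`2`/`-1`).
#' @return A tibble with column `marker_id` followed by one character column
#'   per sample.
#' @export
read_genotype_table <- function(path, dialect = c("axiom_letters", "numeric")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L || names(raw)[1] != "marker_id") {
    abort(sprintf("malformed header in '%s': first column must be 'marker_id'", path))
  }
  dup <- raw$marker_id[duplicated(raw$marker_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate marker_id in '%s': %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  map <- .dialects[[dialect]]
  out <- raw
  for (j in seq(2L, ncol(raw))) {
    codes <- raw[[j]]
    bad <- !(codes %in% names(map))
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("unknown code '%s' (dialect %s) at marker '%s', sample '%s'",
                    codes[i], dialect, raw$marker_id[i], names(raw)[j]))
    }
    out[[j]] <- unname(map[codes])
  }
  out
}

#' Write a genotype-call table
#'
#' Inverse of [read_genotype_table()]: internal calls are encoded back into
#' the dialect's codes and written as UTF-8, tab-separated, LF-terminated.
#'
#' @inheritParams read_genotype_table
#' @param calls Wide call tibble (`marker_id` + one column per sample).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(calls, path, dialect = c("axiom_letters", "numeric")) {
  dialect <- match.arg(dialect)
  map <- .dialects[[dialect]]
  rev_map <- stats::setNames(names(map), unname(map))
  missing_code <- names(map)[is.na(map)]
  out <- calls
  for (j in seq(2L, ncol(calls))) {
    v <- calls[[j]]
    enc <- ifelse(is.na(v), missing_code, rev_map[v])
    if (anyNA(enc)) abort("calls contain values outside the internal vocabulary")
    out[[j]] <- unname(enc)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a marker map
#'
#' Reads a tab-separated marker map with columns `marker_id`, `chrom_label`,
#' `pos_bp` and optional `allele_a_parent`, `allele_b_parent`. The
#' homoeologous pair index is parsed from the digits of `chrom_label`
#' (`"B04"` -> 4); positions are 1-based on the B-subgenome pseudomolecule.
#' The returned map is sorted by `(pair_index, pos_bp, marker_id)`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of markers.
#' @export
read_marker_map <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("marker_id", "chrom_label", "pos_bp")
  if (!all(need %in% names(raw))) {
    abort(sprintf("marker map '%s' must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  markers <- tibble::tibble(
    marker_id = raw$marker_id,
    chrom_label = raw$chrom_label,
    pos_bp = suppressWarnings(as.integer(raw$pos_bp)),
    allele_a_parent = if ("allele_a_parent" %in% names(raw)) raw$allele_a_parent else NA_character_,
    allele_b_parent = if ("allele_b_parent" %in% names(raw)) raw$allele_b_parent else NA_character_
  )
  markers$pair_index <- parse_pair_index(markers$chrom_label)
  if (anyNA(markers$pos_bp) || any(markers$pos_bp < 1L)) {
    abort(sprintf("marker map '%s': pos_bp must be an integer >= 1", path))
  }
  dup <- markers$marker_id[duplicated(markers$marker_id)]
  if (length(dup) > 0) abort(sprintf("duplicate marker_id in map: %s", dup[1]))
  dplyr::arrange(markers, .data$pair_index, .data$pos_bp, .data$marker_id) %>%
    dplyr::select("marker_id", "pair_index", "chrom_label", "pos_bp",
                  "allele_a_parent", "allele_b_parent")
}

#' Parse homoeologous pair indices from chromosome labels
#'
#' @param chrom_label Character vector like `"B04"` or `"A10"`.
#' @return Integer vector of pair indices in 1..10.
#' @export
parse_pair_index <- function(chrom_label) {
  ok <- grepl("^[AB][0-9]{1,2}$", chrom_label)
  if (!all(ok)) {
    abort(sprintf("unrecognized chrom_label '%s' (expected e.g. 'B04')",
                  chrom_label[which(!ok)[1]]))
  }
  idx <- as.integer(sub("^[AB]", "", chrom_label))
  if (any(idx < 1L | idx > 10L)) {
    abort("pair_index parsed from chrom_label must be in 1..10")
  }
  idx
}

#' Write a marker map
#'
#' @param markers Marker tibble as returned by [read_marker_map()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(markers, path) {
  readr::write_tsv(
    dplyr::select(markers, "marker_id", "chrom_label", "pos_bp",
                  dplyr::any_of(c("allele_a_parent", "allele_b_parent"))),
    path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `role` (`PARENT_A`, `PARENT_B`, `TETRAPLOID`),
#' `event`, `generation` (selfing generation, empty for parents) and
#' `replicate_group` (shared by technical replicates of one plant).
#'
#' @param path Path to a TSV file.
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "role", "event", "generation", "replicate_group")
  if (!all(need %in% names(raw))) {
    abort(sprintf("sample metadata '%s' must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  bad_role <- setdiff(unique(raw$role), c("PARENT_A", "PARENT_B", "TETRAPLOID"))
  if (length(bad_role) > 0) abort(sprintf("unknown sample role '%s'", bad_role[1]))
  samples <- tibble::as_tibble(raw[need])
  samples$generation <- suppressWarnings(as.integer(samples$generation))
  if (any(!is.na(samples$generation) & samples$generation < 1L)) {
    abort("generation must be >= 1 when set")
  }
  if (any(samples$role != "TETRAPLOID" & !is.na(samples$generation))) {
    abort("parents must have unset generation")
  }
  samples
}

#' Write sample metadata
#'
#' @param samples Sample tibble as returned by [read_sample_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Reads bi-allelic SNP records and maps GT fields `0/0`, `0/1`, `1/1`, `./.`
#' to `HOM_A`, `HET`, `HOM_B`, `NA` (REF/ALT oriented; parental orientation is
#' applied later by [select_diagnostic_loci()]). Multi-allelic records are
#' skipped with a warning. Phased separators (`|`) are accepted.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @return A list with `calls` (wide call tibble) and `markers` (marker map
#'   tibble built from CHROM/POS, with `chrom_label` taken from CHROM).
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("skipped %d multi-allelic record(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  norm <- gsub("\\|", "/", gt)
  lut <- c(`0/0` = "HOM_A", `0/1` = "HET", `1/0` = "HET", `1/1` = "HOM_B",
           `./.` = NA_character_, `.` = NA_character_)
  bad <- !is.na(norm) & !(norm %in% names(lut))
  if (any(bad)) abort(sprintf("unsupported GT value '%s'", norm[which(bad)[1]]))
  calls_mat <- matrix(lut[ifelse(is.na(norm), "./.", norm)],
                      nrow = nrow(norm), dimnames = dimnames(norm))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  markers <- tibble::tibble(
    marker_id = ids, chrom_label = fix$CHROM,
    pos_bp = as.integer(fix$POS),
    allele_a_parent = NA_character_, allele_b_parent = NA_character_
  )
  markers$pair_index <- parse_pair_index(markers$chrom_label)
  markers <- dplyr::arrange(markers, .data$pair_index, .data$pos_bp, .data$marker_id) %>%
    dplyr::select("marker_id", "pair_index", "chrom_label", "pos_bp",
                  "allele_a_parent", "allele_b_parent")
  calls <- tibble::as_tibble(cbind(tibble::tibble(marker_id = ids),
                                   as.data.frame(calls_mat, stringsAsFactors = FALSE)))
  calls <- calls[match(markers$marker_id, calls$marker_id), ]
  list(calls = calls, markers = markers)
}

#' Order a call table by the marker map
#'
#' Subsets the call table to mapped markers and sorts rows into the map's
#' canonical `(pair_index, pos_bp, marker_id)` order.
#'
#' @param calls Wide call tibble.
#' @param markers Marker map tibble.
#' @return The reordered call tibble.
#' @export
normalize_marker_order <- function(calls, markers) {
  missing_map <- setdiff(calls$marker_id, markers$marker_id)
  if (length(missing_map) > 0) {
    abort(sprintf("%d marker(s) absent from the map, e.g. '%s'",
                  length(missing_map), missing_map[1]))
  }
  calls[match(intersect(markers$marker_id, calls$marker_id), calls$marker_id), ]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.sample_cols <- function(calls) setdiff(names(calls), "marker_id")
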