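#' Per-sample homoeologous-exchange summaries
#'
#' For each tetraploid sample, counts classified (non-unresolved) loci and
#' converted loci genome-wide and computes the detected exchange rate
#' `he_rate_pct = 100 * (n_AAAA + n_BBBB) / n_classified`, its direction
#' components `aaaa_rate_pct` and `bbbb_rate_pct`, and the conversion
#' asymmetry `asymmetry_pct = 100 * n_AAAA / (n_AAAA + n_BBBB)`. Unresolved
#' loci never enter a denominator. Rates are kept at full precision; round
#' only for display.
#'
#' @param config Wide configuration tibble from [classify_configurations()].
#' @return Tibble with one row per sample: `n_classified`, `n_AAAA`,
#'   `n_BBBB`, `he_rate_pct`, `aaaa_rate_pct`, `bbbb_rate_pct`,
#'   `asymmetry_pct` (`NA` when no conversions), plus a `flag` column marking
#'   degenerate samples with zero classified loci.
#' @export
summarize_samples <- function(config) {
  configuration_tallies(config) %>%
    dplyr::mutate(
      n_classified = .data$n_AABB + .data$n_AAAA + .data$n_BBBB,
      n_converted = .data$n_AAAA + .data$n_BBBB,
      aaaa_rate_pct = ifelse(.data$n_classified > 0,
                             100 * .data$n_AAAA / .data$n_classified, NA_real_),
      bbbb_rate_pct = ifelse(.data$n_classified > 0,
                             100 * .data$n_BBBB / .data$n_classified, NA_real_),
      # summed so the decomposition he = aaaa + bbbb holds exactly
      he_rate_pct = .data$aaaa_rate_pct + .data$bbbb_rate_pct,
      asymmetry_pct = ifelse(.data$n_converted > 0,
                             100 * .data$n_AAAA / .data$n_converted, NA_real_),
      flag = ifelse(.data$n_classified == 0, "no_classified_loci", "")
    ) %>%
    dplyr::select("sample_id", "n_classified", "n_AABB", "n_AAAA", "n_BBBB",
                  "n_converted", "he_rate_pct", "aaaa_rate_pct",
                  "bbbb_rate_pct", "asymmetry_pct", "flag")
}

#' Per-sample, per-chromosome-pair counts
#'
#' @param config Wide configuration tibble.
#' @param markers Marker map of the diagnostic loci.
#' @return Tibble with `sample_id`, `pair_index`, `n_classified`, `n_AAAA`,
#'   `n_BBBB`, `n_converted`.
#' @export
summarize_sample_pairs <- function(config, markers) {
  mk <- markers[match(config$marker_id, markers$marker_id), ]
  config %>%
    tidyr::pivot_longer(-"marker_id", names_to = "sample_id", values_to = "config") %>%
    dplyr::left_join(mk[c("marker_id", "pair_index")], by = "marker_id") %>%
    dplyr::group_by(.data$sample_id, .data$pair_index) %>%
    dplyr::summarise(
      n_classified = sum(!is.na(.data$config)),
      n_AAAA = sum(.data$config == "AAAA", na.rm = TRUE),
      n_BBBB = sum(.data$config == "BBBB", na.rm = TRUE),
      .groups = "drop"
    ) %>%
    dplyr::mutate(n_converted = .data$n_AAAA + .data$n_BBBB)
}

#' Cohort-level homoeologous-exchange summary
#'
#' Pools loci over the cohort's samples. Two genome-wide figures are
#' reported because both are in common use: the pooled rate
#' (`pooled_he_rate_pct`, converted loci over classified loci summed across
#' samples) and the mean of per-sample rates (`mean_he_rate_pct`). Per
#' chromosome pair, two views of the distribution are given:
#' `share_pct` (the pair's percentage of all converted loci in the cohort,
#' summing to 100 when any conversion exists) and `within_rate_pct` (the
#' conversion rate among the pair's own classified loci).
#'
#' @param config Wide configuration tibble for the cohort's samples.
#' @param markers Marker map of the diagnostic loci.
#' @param event Optional cohort label echoed in the output.
#' @return List of class `he_cohort` with `samples` (per-sample summary),
#'   `genome` (one-row tibble of cohort figures) and `pairs` (per-pair
#'   tibble).
#' @export
summarize_cohort <- function(config, markers, event = NA_character_) {
  per_sample <- summarize_samples(config)
  pairs <- summarize_sample_pairs(config, markers) %>%
    dplyr::group_by(.data$pair_index) %>%
    dplyr::summarise(n_classified = sum(.data$n_classified),
                     n_AAAA = sum(.data$n_AAAA), n_BBBB = sum(.data$n_BBBB),
                     n_converted = sum(.data$n_converted), .groups = "drop")
  tot_conv <- sum(pairs$n_converted)
  pairs <- pairs %>%
    dplyr::mutate(
      share_pct = if (tot_conv > 0) 100 * .data$n_converted / tot_conv else NA_real_,
      within_rate_pct = ifelse(.data$n_classified > 0,
                               100 * .data$n_converted / .data$n_classified,
                               NA_real_)
    )
  n_classified <- sum(pairs$n_classified)
  genome <- tibble::tibble(
    event = event,
    n_samples = nrow(per_sample),
    n_classified = n_classified,
    n_converted = tot_conv,
    pooled_he_rate_pct = ifelse(n_classified > 0, 100 * tot_conv / n_classified, NA_real_),
    pooled_aaaa_rate_pct = ifelse(n_classified > 0,
                                  100 * sum(pairs$n_AAAA) / n_classified, NA_real_),
    pooled_bbbb_rate_pct = ifelse(n_classified > 0,
                                  100 * sum(pairs$n_BBBB) / n_classified, NA_real_),
    mean_he_rate_pct = mean(per_sample$he_rate_pct, na.rm = TRUE),
    min_he_rate_pct = suppressWarnings(min(per_sample$he_rate_pct, na.rm = TRUE)),
    max_he_rate_pct = suppressWarnings(max(per_sample$he_rate_pct, na.rm = TRUE)),
    flag = ifelse(tot_conv == 0, "no_conversions", "")
  )
  structure(list(samples = per_sample, genome = genome, pairs = pairs),
            class = "he_cohort")
}

#' @export
print.he_cohort <- function(x, ...) {
  g <- x$genome
  cat(sprintf("Homoeologous-exchange cohort summary%s\n",
              ifelse(is.na(g$event), "", paste0(" [", g$event, "]"))))
  cat(sprintf("  samples: %d   classified loci (pooled): %d\n",
              g$n_samples, g$n_classified))
  cat(sprintf("  pooled rate: %.2f%%  (AAAA %.2f%% / BBBB %.2f%%)\n",
              g$pooled_he_rate_pct, g$pooled_aaaa_rate_pct, g$pooled_bbbb_rate_pct))
  cat(sprintf("  per-sample rate: mean %.2f%%, range %.2f%%..%.2f%%\n",
              g$mean_he_rate_pct, g$min_he_rate_pct, g$max_he_rate_pct))
  invisible(x)
}

#' Direction bias of conversions
#'
#' Reports the pooled AAAA and BBBB conversion rates and labels each sample
#' by its asymmetry: `balanced` when the AAAA share of conversions lies
#' within `balanced_band` percentage points of 50, otherwise `AAAA-biased`
#' or `BBBB-biased`; samples with no conversions are `no_conversions`. Most
#' neoallotetraploid individuals show severe bias to one direction; the few
#' with near-50/50 splits stand out as exceptions.
#'
#' @param cohort An `he_cohort` from [summarize_cohort()].
#' @param balanced_band Half-width (percentage points) of the balanced label
#'   around 50. Default 5.
#' @return List with `pooled` (one-row tibble: `aaaa_rate_pct`,
#'   `bbbb_rate_pct`) and `samples` (tibble with `sample_id`,
#'   `asymmetry_pct`, `bias_label`).
#' @export
conversion_bias <- function(cohort, balanced_band = 5) {
  stopifnot(inherits(cohort, "he_cohort"))
  lab <- function(a) {
    dplyr::case_when(
      is.na(a) ~ "no_conversions",
      abs(a - 50) <= balanced_band ~ "balanced",
      a > 50 ~ "AAAA-biased",
      TRUE ~ "BBBB-biased"
    )
  }
  list(
    pooled = tibble::tibble(aaaa_rate_pct = cohort$genome$pooled_aaaa_rate_pct,
                            bbbb_rate_pct = cohort$genome$pooled_bbbb_rate_pct),
    samples = dplyr::transmute(cohort$samples, .data$sample_id,
                               .data$asymmetry_pct,
                               bias_label = lab(.data$asymmetry_pct))
  )
}

#' Detect total collapse of a chromosome pair
#'
#' A pair has "totally collapsed" in a sample when every classified locus on
#' it carries the same converted configuration (all `AAAA` or all `BBBB`),
#' i.e. the assayed loci of the pair have been entirely converted to one
#' subgenome. Pairs with zero classified loci are undefined (`NA`).
#'
#' @param config Wide configuration tibble.
#' @param markers Marker map of the diagnostic loci.
#' @return Tibble with `sample_id`, `pair_index`, `n_classified`, `collapse`
#'   (logical, `NA` when undefined) and `direction` (`"AAAA"`, `"BBBB"` or
#'   `NA`).
#' @export
detect_total_collapse <- function(config, markers) {
  summarize_sample_pairs(config, markers) %>%
    dplyr::mutate(
      collapse = dplyr::if_else(.data$n_classified == 0, NA,
                                .data$n_AAAA == .data$n_classified |
                                  .data$n_BBBB == .data$n_classified),
      direction = dplyr::case_when(
        .data$n_classified == 0 ~ NA_character_,
        .data$n_AAAA == .data$n_classified ~ "AAAA",
        .data$n_BBBB == .data$n_classified ~ "BBBB",
        TRUE ~ NA_character_
      )
    ) %>%
    dplyr::select("sample_id", "pair_index", "n_classified", "collapse", "direction")
}

#' Generational accumulation trend of exchange rates
#'
#' Tests whether detected exchange rates increase over selfing generations
#' using rank-based statistics that assume nothing about the rate
#' distribution: the Spearman rank correlation of `he_rate_pct` against
#' `generation`, a Theil-Sen slope (median of pairwise slopes, in percentage
#' points per generation), and a one-sided permutation p-value obtained by
#' permuting generation labels (`rho_perm >= rho_obs`).
#'
#' @param data Tibble with columns `he_rate_pct` and `generation` (one row
#'   per sample; rows with either value missing are dropped).
#' @param n_perm Number of label permutations. Default 10000.
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `he_trend` with fields `n_samples`, `rho`,
#'   `slope`, `p_perm`, `n_perm`, `seed`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
generation_trend <- function(data, n_perm = 10000L, seed = 1L) {
  stopifnot(all(c("he_rate_pct", "generation") %in% names(data)))
  d <- data[!is.na(data$he_rate_pct) & !is.na(data$generation), ]
  if (nrow(d) < 3L || length(unique(d$generation)) < 2L) {
    abort("trend needs >= 3 samples spanning >= 2 distinct generations")
  }
  x <- as.numeric(d$generation); y <- as.numeric(d$he_rate_pct)
  rho <- if (stats::sd(y) == 0) 0 else
    suppressWarnings(stats::cor(x, y, method = "spearman"))
  # Theil-Sen: median slope over pairs with distinct generations
  cmb <- utils::combn(length(x), 2L)
  dx <- x[cmb[2L, ]] - x[cmb[1L, ]]
  dy <- y[cmb[2L, ]] - y[cmb[1L, ]]
  slope <- stats::median(dy[dx != 0] / dx[dx != 0])
  if (rho == 0 && stats::sd(y) == 0) {
    p_perm <- 1
  } else {
    p_perm <- withr::with_seed(as.integer(seed), {
      rx <- rank(x); ry <- rank(y)
      obs <- stats::cor(rx, ry)
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        stats::cor(sample(rx), ry) >= obs - 1e-12
      }, logical(1)))
      (1 + hits) / (1 + n_perm)
    })
  }
  intercept <- stats::median(y) - slope * stats::median(x)
  structure(list(n_samples = nrow(d), rho = rho, slope = slope,
                 intercept = intercept, p_perm = p_perm,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 data = tibble::tibble(generation = x, he_rate_pct = y)),
            class = "he_trend")
}

#' @export
print.he_trend <- function(x, ...) {
  cat("Generational trend of homoeologous exchange\n")
  cat(sprintf("  n = %d samples; Spearman rho = %.3f; Theil-Sen slope = %.3f %%/generation\n",
              x$n_samples, x$rho, x$slope))
  cat(sprintf("  one-sided permutation p = %.4g (%d permutations, seed %d)\n",
              x$p_perm, x$n_perm, x$seed))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy he_trend
#' @export
tidy.he_trend <- function(x, ...) {
  tibble::tibble(term = c("spearman_rho", "theil_sen_slope"),
                 estimate = c(x$rho, x$slope))
}

#' @method glance he_trend
#' @export
glance.he_trend <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, rho = x$rho, slope = x$slope,
                 p_perm = x$p_perm, n_perm = x$n_perm, seed = x$seed)
}
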