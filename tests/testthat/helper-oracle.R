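# Independent oracles used to cross-check the implementation. Both are
# deliberately written on different machinery from the package code paths
# they check.

# Run-length segmentation oracle via regular expressions. The configuration
# sequence is encoded as a string (A = AAAA, B = BBBB, O = AABB, N = NA) and
# maximal gap-tolerant runs of one converted letter are enumerated with a
# greedy leftmost regex, which also realizes the join-left tie-break.
# Returns a canonical integer matrix with one row per segment:
# (start_idx, end_idx, n_loci, config [1 = AAAA, 2 = BBBB],
#  kind [1 = BLOCK, 2 = INTERSPERSED]), ordered by start_idx.
oracle_segment <- function(configs, min_block_loci = 3L, max_gap_loci = 1L) {
  enc <- rep("O", length(configs))
  enc[is.na(configs)] <- "N"
  enc[!is.na(configs) & configs == "AAAA"] <- "A"
  enc[!is.na(configs) & configs == "BBBB"] <- "B"
  s <- paste(enc, collapse = "")
  start <- integer(0); end <- integer(0); n <- integer(0)
  cfgcode <- integer(0); kind <- integer(0)
  for (ci in 1:2) {
    ch <- c("A", "B")[ci]
    pat <- sprintf("%s(?:N{0,%d}%s)*", ch, max_gap_loci, ch)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      from <- as.integer(m[k])
      len <- attr(m, "match.length")[k]
      seg_chars <- strsplit(substr(s, from, from + len - 1L), "")[[1]]
      idx <- from - 1L + which(seg_chars == ch)
      if (length(idx) >= min_block_loci) {
        start <- c(start, idx[1L]); end <- c(end, idx[length(idx)])
        n <- c(n, length(idx)); cfgcode <- c(cfgcode, ci); kind <- c(kind, 1L)
      } else {
        start <- c(start, idx); end <- c(end, idx)
        n <- c(n, rep(1L, length(idx)))
        cfgcode <- c(cfgcode, rep(ci, length(idx)))
        kind <- c(kind, rep(2L, length(idx)))
      }
    }
  }
  out <- cbind(start_idx = start, end_idx = end, n_loci = n,
               config = cfgcode, kind = kind)
  out[order(out[, "start_idx"]), , drop = FALSE]
}

# Canonical matrix form of a segment_pair() result, for fast comparison.
canon_segments <- function(segs) {
  out <- cbind(start_idx = as.integer(segs$start_idx),
               end_idx = as.integer(segs$end_idx),
               n_loci = as.integer(segs$n_loci),
               config = as.integer(ifelse(segs$config == "AAAA", 1L, 2L)),
               kind = as.integer(ifelse(segs$kind == "BLOCK", 1L, 2L)))
  out[order(out[, "start_idx"]), , drop = FALSE]
}

random_config_seq <- function(n, p = c(AABB = 0.6, AAAA = 0.15, BBBB = 0.15, NA_ = 0.1)) {
  sample(c("AABB", "AAAA", "BBBB", NA), n, replace = TRUE, prob = p)
}

# Coarse dosage-chain Monte-Carlo oracle for the mean detected exchange rate.
# Tracks only the four per-locus origin bits of each pair (2:2 -> 3:1 at a
# homoeologous crossover, 3:1 -> 4:0 by selfing fixation), vectorized over
# lineages x loci; no breakpoint lists, event logs or tract machinery.
# Returns the per-lineage genome-wide detected rate (%) for n_lineages
# independent chains.
oracle_dosage_rates <- function(n_lineages, n_generations, p_he, distal_bias,
                                p_gc, error_rate, missing_rate,
                                loci_per_pair, n_pairs, seed) {
  withr::with_seed(as.integer(seed), {
    tot_classified <- numeric(n_lineages)
    tot_converted <- numeric(n_lineages)
    for (p in seq_len(n_pairs)) {
      L <- loci_per_pair
      t_rel <- seq_len(L) / (L + 1)               # equally spaced loci
      H <- list(matrix(TRUE, n_lineages, L), matrix(TRUE, n_lineages, L),
                matrix(FALSE, n_lineages, L), matrix(FALSE, n_lineages, L))
      for (g in seq_len(n_generations)) {
        gam <- vector("list", 2L)
        for (m in 1:2) {
          Hm <- H
          occ <- stats::runif(n_lineages) < p_he
          if (any(occ)) {
            u <- stats::rbeta(n_lineages, 1 / distal_bias, 1 / distal_bias)
            i_pick <- sample(1:2, n_lineages, replace = TRUE)
            j_pick <- sample(3:4, n_lineages, replace = TRUE)
            aff <- occ & outer(u, t_rel, `<`)     # loci distal to the breakpoint
            for (i in 1:2) for (j in 3:4) {
              rows <- i_pick == i & j_pick == j
              mask <- aff & rows
              if (any(mask)) {
                tmp <- Hm[[i]][mask]
                Hm[[i]][mask] <- Hm[[j]][mask]
                Hm[[j]][mask] <- tmp
              }
            }
          }
          if (p_gc > 0) {
            hit <- matrix(stats::runif(n_lineages * L) < p_gc, n_lineages, L)
            if (any(hit)) {
              r_pick <- matrix(sample(1:4, n_lineages * L, replace = TRUE),
                               n_lineages, L)
              d_flip <- matrix(sample(0:1, n_lineages * L, replace = TRUE),
                               n_lineages, L)
              for (r in 1:4) {
                dset <- if (r <= 2) 3:4 else 1:2
                for (di in 1:2) {
                  d <- dset[di]
                  mask <- hit & r_pick == r & d_flip == (di - 1L)
                  if (any(mask)) Hm[[r]][mask] <- Hm[[d]][mask]
                }
              }
            }
          }
          pa <- sample(1:2, n_lineages, replace = TRUE)
          pb <- sample(3:4, n_lineages, replace = TRUE)
          a_row <- Hm[[1]]; a_row[pa == 2L, ] <- Hm[[2]][pa == 2L, ]
          b_row <- Hm[[3]]; b_row[pb == 4L, ] <- Hm[[4]][pb == 4L, ]
          gam[[m]] <- list(a = a_row, b = b_row)
        }
        H <- list(gam[[1]]$a, gam[[2]]$a, gam[[1]]$b, gam[[2]]$b)
      }
      d <- H[[1]] + H[[2]] + H[[3]] + H[[4]]
      true_conv <- d == 4L | d == 0L
      # dosage-blind readout with genotyping error: a flipped homozygous call
      # stays converted half the time, a flipped heterozygous call always
      # becomes converted
      flip <- matrix(stats::runif(n_lineages * L) < error_rate, n_lineages, L)
      keepconv <- matrix(stats::runif(n_lineages * L) < 0.5, n_lineages, L)
      obs_conv <- ifelse(flip, ifelse(true_conv, keepconv, TRUE), true_conv)
      called <- matrix(stats::runif(n_lineages * L) >= missing_rate,
                       n_lineages, L)
      tot_classified <- tot_classified + rowSums(called)
      tot_converted <- tot_converted + rowSums(obs_conv & called)
    }
    100 * tot_converted / tot_classified
  })
}
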