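#' Median-normalize the two intensity channels of a barcode table
#'
#' Each channel is scaled so its median over barcodes is 1. Zero
#' intensities are first replaced by a pseudocount equal to half the
#' smallest positive value in that channel, so downstream log ratios stay
#' finite.
#'
#' @param table a `barcode_table` (see [simulate_gim_cross()]) or a data
#'   frame with columns `barcode_id`, `gene`, `chrom`, `pos`,
#'   `intensity_query`, `intensity_control`.
#' @return The table with both channels normalized; attributes preserved.
#' @export
normalize_arrays <- function(table) {
  table <- validate_barcode_table(table)
  for (ch in c("intensity_query", "intensity_control")) {
    v <- table[[ch]]
    pos <- v[v > 0]
    if (length(pos) == 0L)
      stop(sprintf("channel '%s' is all zero", ch))
    v[v == 0] <- min(pos) / 2
    table[[ch]] <- v / stats::median(v)
  }
  table
}

#' Per-barcode linkage scores
#'
#' The screen read-out per barcode is the log2 enrichment of the control
#' channel over the query channel. Barcodes counter-selected in the query
#' pool (i.e. genetically linked to the suppressor) score high, so the
#' linked locus appears as a local maximum of the smoothed score track.
#'
#' @param table a normalized `barcode_table` (see [normalize_arrays()]).
#' @return A `scored_barcodes` data frame: `barcode_id`, `gene`, `chrom`,
#'   `pos`, `score`, sorted by (chrom, pos) in genome order.
#' @export
compute_scores <- function(table) {
  table <- validate_barcode_table(table)
  if (any(table$intensity_query <= 0) || any(table$intensity_control <= 0))
    stop("non-positive intensities; run normalize_arrays() first")
  out <- data.frame(barcode_id = table$barcode_id, gene = table$gene,
                    chrom = table$chrom, pos = table$pos,
                    score = log2(table$intensity_control /
                                   table$intensity_query),
                    stringsAsFactors = FALSE)
  chrom_order <- attr(table, "chrom_order")
  if (is.null(chrom_order)) chrom_order <- unique(out$chrom)
  out <- out[order(match(out$chrom, chrom_order), out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("scored_barcodes", "data.frame")
  out
}

validate_barcode_table <- function(table) {
  need <- c("barcode_id", "gene", "chrom", "pos",
            "intensity_query", "intensity_control")
  if (!all(need %in% names(table)))
    stop("barcode table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(table$barcode_id))
    stop("duplicate barcode_id values")
  if (any(table$intensity_query < 0) || any(table$intensity_control < 0))
    stop("intensities must be non-negative")
  cfg <- attr(table, "config")
  if (!is.null(cfg)) attr(table, "chrom_order") <- cfg$genome$chrom
  table
}

#' Sliding-window smoothing of barcode linkage scores
#'
#' Per chromosome, the score track is smoothed with a plain mean over
#' every run of `W` consecutive barcodes (step 1, full windows only; no
#' edge shrinkage). Each window is anchored at the median position of its
#' `W` barcodes (mean of the two middle positions when `W` is even).
#' Chromosomes with fewer than `W` barcodes yield no windows and are
#' reported with a warning.
#'
#' @param scored a `scored_barcodes` data frame (see [compute_scores()]),
#'   sorted by (chrom, pos).
#' @param W window size in barcodes (>= 2). Default 20.
#' @return A `linkage_profile` data frame: `chrom`, `center` (bp),
#'   `score` (window mean), `start_index` (row of the window's first
#'   barcode in `scored`); attribute `W`.
#' @export
sliding_window_profile <- function(scored, W = 20) {
  check_scalar(W, "W", lower = 2)
  W <- as.integer(W)
  scored <- as.data.frame(scored)
  idx <- split(seq_len(nrow(scored)), factor(scored$chrom,
                                             levels = unique(scored$chrom)))
  pieces <- lapply(idx, function(ii) {
    n <- length(ii)
    if (any(diff(scored$pos[ii]) < 0))
      stop("barcodes must be sorted by position within chromosomes")
    if (n < W) {
      warning(sprintf("chromosome '%s' has %d barcodes (< W = %d): skipped",
                      scored$chrom[ii[1]], n, W))
      return(NULL)
    }
    cs <- cumsum(scored$score[ii])
    means <- (cs[W:n] - c(0, cs)[seq_len(n - W + 1)]) / W
    centers <- vapply(seq_len(n - W + 1), function(s) {
      stats::median(scored$pos[ii[s:(s + W - 1)]])
    }, numeric(1))
    data.frame(chrom = scored$chrom[ii[1]], center = centers, score = means,
               start_index = ii[seq_len(n - W + 1)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), center = numeric(0),
                      score = numeric(0), start_index = integer(0))
  rownames(out) <- NULL
  attr(out, "W") <- W
  class(out) <- c("linkage_profile", "data.frame")
  out
}

# window means of a permuted genome-wide score vector, returning only the
# genome-wide maximum; starts/ends index a single concatenated vector and
# never span a chromosome boundary
perm_max_window <- function(score_perm, starts, ends, W) {
  cs <- cumsum(score_perm)
  max((cs[ends] - c(0, cs)[starts]) / W)
}

#' Call suppressor loci from a smoothed linkage profile
#'
#' Local maxima of the per-chromosome smoothed track (windows whose score
#' is >= both neighbours; plateaus collapse to their leftmost window) are
#' kept when their prominence above the chromosome's median window score
#' exceeds `min_prominence` (default: one median absolute deviation of
#' that chromosome's window scores). Significance comes from a permutation
#' null: barcode scores are shuffled genome-wide with positions fixed, the
#' profile recomputed, and the genome-wide maximum window score recorded
#' per permutation; for each peak,
#' p = (1 + #\{perm max >= peak score\}) / (n_perm + 1).
#'
#' @param profile a `linkage_profile` (see [sliding_window_profile()]).
#' @param scored the `scored_barcodes` the profile was computed from.
#' @param n_perm number of permutations (>= 100). Default 1000.
#' @param min_prominence minimum peak prominence over the chromosome
#'   median window score; `NULL` (default) uses one MAD of the same
#'   chromosome's window scores.
#' @param seed integer seed for the permutations.
#' @return A `locus_calls` data frame sorted by (p, -score): `chrom`,
#'   `peak_pos` (bp), `score`, `p_value`, `candidate_genes`
#'   (comma-separated genes whose barcodes fall in the peak window),
#'   `rank`; attributes `n_perm` and `null_model = "genome-wide score
#'   shuffle"`. Zero rows when no peak passes the prominence filter.
#' @export
call_loci <- function(profile, scored, n_perm = 1000, min_prominence = NULL,
                      seed = NULL) {
  stopifnot(inherits(profile, "linkage_profile"))
  check_scalar(n_perm, "n_perm", lower = 100)
  W <- attr(profile, "W")
  empty <- data.frame(chrom = character(0), peak_pos = numeric(0),
                      score = numeric(0), p_value = numeric(0),
                      candidate_genes = character(0), rank = integer(0))
  class(empty) <- c("locus_calls", "data.frame")
  if (nrow(profile) == 0L) return(empty)

  peaks <- do.call(rbind, lapply(split(profile, profile$chrom), function(pf) {
    s <- pf$score
    n <- length(s)
    left <- c(-Inf, s[-n])
    right <- c(s[-1], -Inf)
    is_max <- s >= left & s >= right
    # collapse plateaus: keep only the leftmost window of a tied run
    is_max[is_max & c(FALSE, diff(s) == 0)] <- FALSE
    prom_cut <- if (is.null(min_prominence)) stats::mad(s) else min_prominence
    keep <- is_max & (s - stats::median(s)) > prom_cut
    pf[keep, , drop = FALSE]
  }))
  if (is.null(peaks) || nrow(peaks) == 0L) return(empty)

  # permutation null: genome-wide score shuffle, positions fixed
  idx <- split(seq_len(nrow(scored)), factor(scored$chrom,
                                             levels = unique(scored$chrom)))
  starts <- integer(0); ends <- integer(0)
  for (ii in idx) {
    n <- length(ii)
    if (n >= W) {
      starts <- c(starts, ii[1] + seq_len(n - W + 1) - 1L)
      ends <- c(ends, ii[1] + seq.int(W - 1L, n - 1L))
    }
  }
  sc <- scored$score
  perm_max <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm_max_window(sc[sample.int(length(sc))], starts, ends, W)
    }, numeric(1))
  })

  genes_in_window <- vapply(peaks$start_index, function(s) {
    paste(unique(scored$gene[s:(s + W - 1)]), collapse = ",")
  }, character(1))
  out <- data.frame(chrom = peaks$chrom, peak_pos = peaks$center,
                    score = peaks$score,
                    p_value = vapply(peaks$score, function(x) {
                      (1 + sum(perm_max >= x)) / (n_perm + 1)
                    }, numeric(1)),
                    candidate_genes = genes_in_window,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$score), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "null_model") <- "genome-wide score shuffle"
  class(out) <- c("locus_calls", "data.frame")
  out
}

#' One-call suppressor mapping pipeline
#'
#' Convenience wrapper: normalize, score, smooth and call loci.
#'
#' @inheritParams normalize_arrays
#' @inheritParams sliding_window_profile
#' @inheritParams call_loci
#' @return A list with elements `scored`, `profile`, `calls`.
#' @examples
#' cfg <- gim_sim_config(n_barcodes = 1000, noise_cv = 0.1)
#' bt <- simulate_gim_cross(cfg, seed = 7)
#' res <- map_suppressor(bt, n_perm = 100, seed = 7)
#' res$calls[1, ]
#' @export
map_suppressor <- function(table, W = 20, n_perm = 1000,
                           min_prominence = NULL, seed = NULL) {
  scored <- compute_scores(normalize_arrays(table))
  profile <- sliding_window_profile(scored, W = W)
  calls <- call_loci(profile, scored, n_perm = n_perm,
                     min_prominence = min_prominence, seed = seed)
  list(scored = scored, profile = profile, calls = calls)
}

#' @export
print.locus_calls <- function(x, n = 10, ...) {
  cat(sprintf("Locus calls: %d peak(s); permutation null (%s, n_perm = %s)\n",
              nrow(x), attr(x, "null_model"), attr(x, "n_perm")))
  if (nrow(x) > 0) {
    top <- utils::head(x, n)
    print.data.frame(cbind(top[, c("rank", "chrom", "peak_pos", "score",
                                   "p_value")],
                           top_gene = sub(",.*", "", top$candidate_genes)),
                     row.names = FALSE)
    if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  }
  invisible(x)
}
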