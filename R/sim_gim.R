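#' Configuration for a synthetic genetic-linkage (GIM) screen
#'
#' Collects the generative parameters for a simulated meiotic cross of a
#' suppressor-bearing query strain against the barcoded genome-wide deletion
#' collection, followed by pooled competitive growth. Spores carrying the
#' suppressor grow with doubling time `tau_suppressed`; spores without it
#' grow with `tau_unsuppressed`. Barcoded deletions genetically linked to
#' the suppressor locus are counter-selected: the spores retaining the
#' deletion-collection allele at a linked position mostly lack the
#' suppressor, grow slowly, and their barcodes end up depleted in the query
#' pool relative to the control pool.
#'
#' @param genome a [genome_map()]; default [yeast_genome_map()].
#' @param n_barcodes number of barcoded deletion strains placed along the
#'   genome (proportional to chromosome length, evenly spaced).
#' @param suppressor_locus list or vector `(chrom, pos)` giving the
#'   suppressor position in bp.
#' @param query_locus optional `(chrom, pos)` of the query deletion marker;
#'   when set, barcodes linked to it are additionally depleted in the query
#'   channel (marker-linkage positive control). Default `NULL` (off).
#' @param tau_suppressed doubling time (min) of suppressor-carrying spores.
#'   Default 135.
#' @param tau_unsuppressed doubling time (min) of spores without the
#'   suppressor. Default 180. Must be >= `tau_suppressed`.
#' @param competition_time pooled competitive-growth duration in minutes.
#'   Default 1350 (~10 generations of the faster grower).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   intensity noise, applied independently per channel. Default 0.2.
#' @param baseline mean intensity scale of each channel. Default 1000.
#' @return An object of class `gim_sim_config` (a list of the above).
#' @export
gim_sim_config <- function(genome = yeast_genome_map(),
                           n_barcodes = 4500,
                           suppressor_locus = list(chrom = "chrXVI",
                                                   pos = 500000),
                           query_locus = NULL,
                           tau_suppressed = 135,
                           tau_unsuppressed = 180,
                           competition_time = 1350,
                           noise_cv = 0.2,
                           baseline = 1000) {
  stopifnot(inherits(genome, "genome_map"))
  check_scalar(n_barcodes, "n_barcodes", lower = 2)
  check_scalar(tau_suppressed, "tau_suppressed", lower = 0, strict_lower = TRUE)
  check_scalar(tau_unsuppressed, "tau_unsuppressed", lower = 0,
               strict_lower = TRUE)
  if (tau_suppressed > tau_unsuppressed)
    stop("'tau_suppressed' must be <= 'tau_unsuppressed'")
  check_scalar(competition_time, "competition_time", lower = 0)
  check_scalar(noise_cv, "noise_cv", lower = 0)
  check_locus <- function(locus, what) {
    locus <- as.list(locus)
    if (is.null(names(locus)) || !all(c("chrom", "pos") %in% names(locus)))
      locus <- stats::setNames(locus[1:2], c("chrom", "pos"))
    chrom <- as.character(locus$chrom)
    pos <- as.numeric(locus$pos)
    i <- match(chrom, genome$chrom)
    if (is.na(i)) stop(sprintf("%s chromosome '%s' not in genome", what, chrom))
    if (!is.finite(pos) || pos < 1 || pos > genome$length[i])
      stop(sprintf("%s position %s outside chromosome '%s'", what,
                   format(pos), chrom))
    list(chrom = chrom, pos = pos)
  }
  suppressor_locus <- check_locus(suppressor_locus, "suppressor")
  if (!is.null(query_locus)) query_locus <- check_locus(query_locus, "query")
  structure(list(genome = genome, n_barcodes = as.integer(n_barcodes),
                 suppressor_locus = suppressor_locus,
                 query_locus = query_locus,
                 tau_suppressed = tau_suppressed,
                 tau_unsuppressed = tau_unsuppressed,
                 competition_time = competition_time,
                 noise_cv = noise_cv, baseline = baseline),
            class = "gim_sim_config")
}

# deterministic barcode layout: counts proportional to chromosome length
# (largest-remainder rounding), positions evenly spaced within chromosomes
barcode_layout <- function(genome, n_barcodes) {
  share <- genome$length / sum(genome$length) * n_barcodes
  n_per <- floor(share)
  rem <- n_barcodes - sum(n_per)
  if (rem > 0) {
    top <- order(share - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[top] <- n_per[top] + 1L
  }
  chrom <- rep(genome$chrom, n_per)
  pos <- unlist(lapply(seq_len(nrow(genome)), function(i) {
    k <- n_per[i]
    if (k == 0L) return(numeric(0))
    round(seq_len(k) * genome$length[i] / (k + 1))
  }), use.names = FALSE)
  data.frame(
    barcode_id = sprintf("bc%05d", seq_along(chrom)),
    gene = sprintf("gene_%s_%04d", sub("^chr", "", chrom),
                   unlist(lapply(n_per, seq_len), use.names = FALSE)),
    chrom = chrom, pos = pos, stringsAsFactors = FALSE
  )
}

#' Simulate a barcode-linkage screen (GIM cross with pooled competition)
#'
#' For each barcode at position x, the fraction p of marker-selected spores
#' that carry the suppressor allele is the Haldane recombination fraction
#' between x and the suppressor locus on its chromosome (0.5 elsewhere).
#' After `competition_time` T minutes of pooled growth, the query-pool
#' abundance of the barcode is proportional to
#' \deqn{a = p \, 2^{T/\tau_s} + (1-p) \, 2^{T/\tau_u},}
#' while the control pool has no fitness differential (abundance 1 per
#' barcode). Channel abundances are scaled to mean 1, multiplied by
#' `baseline` and by independent lognormal noise with CV `noise_cv`.
#' Linked barcodes are therefore depleted in the query channel. If
#' `query_locus` is set, the query channel is further multiplied by twice
#' the recombination fraction to the query marker (the double-recombinant
#' retention, 1 for unlinked barcodes), emulating the marker-linkage
#' positive-control peak.
#'
#' @param config a [gim_sim_config()].
#' @param seed integer seed for the intensity noise; `NULL` uses the
#'   current RNG state.
#' @return A `barcode_table`: data frame with columns `barcode_id`, `gene`,
#'   `chrom`, `pos`, `intensity_query`, `intensity_control`; attributes
#'   `map_function = "haldane"` and `config`.
#' @examples
#' cfg <- gim_sim_config(n_barcodes = 500, noise_cv = 0)
#' bt <- simulate_gim_cross(cfg, seed = 1)
#' head(bt)
#' @export
simulate_gim_cross <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gim_sim_config"))
  layout <- barcode_layout(config$genome, config$n_barcodes)
  if (config$n_barcodes < 40L)
    warning("fewer than 40 barcodes: downstream 20-barcode windows ",
            "will be sparse")
  cm_kb <- attr(config$genome, "cm_per_kb")
  p <- rep(0.5, nrow(layout))
  on_chr <- layout$chrom == config$suppressor_locus$chrom
  d_cm <- abs(layout$pos[on_chr] - config$suppressor_locus$pos) / 1000 * cm_kb
  p[on_chr] <- haldane_recomb(d_cm)

  growth_s <- 2^(config$competition_time / config$tau_suppressed)
  growth_u <- 2^(config$competition_time / config$tau_unsuppressed)
  a_query <- p * growth_s + (1 - p) * growth_u
  if (!is.null(config$query_locus)) {
    on_q <- layout$chrom == config$query_locus$chrom
    d_q <- abs(layout$pos[on_q] - config$query_locus$pos) / 1000 * cm_kb
    a_query[on_q] <- a_query[on_q] * 2 * haldane_recomb(d_q)
  }
  a_query <- a_query / mean(a_query)
  a_control <- rep(1, nrow(layout))

  n <- nrow(layout)
  noise <- with_local_seed(seed, {
    list(q = rlnorm_cv(n, config$noise_cv),
         c = rlnorm_cv(n, config$noise_cv))
  })
  out <- layout
  out$intensity_query <- a_query * config$baseline * noise$q
  out$intensity_control <- a_control * config$baseline * noise$c
  attr(out, "map_function") <- "haldane"
  attr(out, "config") <- config
  class(out) <- c("barcode_table", "data.frame")
  out
}
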