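# independent brute-force oracles used across tests

# naive sliding-window profile: explicit double loop per chromosome
brute_force_profile <- function(scored, W) {
  rows <- list()
  for (ch in unique(scored$chrom)) {
    sub <- scored[scored$chrom == ch, ]
    n <- nrow(sub)
    if (n < W) next
    for (s in seq_len(n - W + 1)) {
      win <- sub[s:(s + W - 1), ]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, center = median(win$pos), score = mean(win$score),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# random scored-barcode instance on a handful of chromosomes
random_scored <- function(n, n_chrom = 3) {
  chrom <- sort(sample(paste0("c", seq_len(n_chrom)), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(ii)
    sort(sample.int(1e6, length(ii)))), use.names = FALSE)
  out <- data.frame(barcode_id = paste0("b", seq_len(n)),
                    gene = paste0("g", seq_len(n)),
                    chrom = chrom, pos = pos, score = rnorm(n),
                    stringsAsFactors = FALSE)
  class(out) <- c("scored_barcodes", "data.frame")
  out
}

# noiseless barcode table with a known suppressor, small genome
small_cross <- function(n_barcodes = 300, noise_cv = 0, seed = 1,
                        sup = list(chrom = "chrB", pos = 4e5), ...) {
  gm <- genome_map(c("chrA", "chrB", "chrC"), c(8e5, 8e5, 8e5))
  cfg <- gim_sim_config(genome = gm, n_barcodes = n_barcodes,
                        suppressor_locus = sup, noise_cv = noise_cv, ...)
  simulate_gim_cross(cfg, seed = seed)
}
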