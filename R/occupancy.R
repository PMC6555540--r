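#' Summarize per-gene polymerase counts
#'
#' Mean, median, method-of-moments negative-binomial dispersion and a
#' seeded percentile-bootstrap confidence interval for the mean of
#' Miller-spread style per-gene counts.
#'
#' @param sc a `spread_counts` object (see [simulate_spread_counts()]) or
#'   a list with `strain`, `counts`.
#' @param n_boot bootstrap resamples. Default 2000.
#' @param conf_level confidence level. Default 0.95.
#' @param seed integer seed for the bootstrap.
#' @return A `count_summary` list: `strain`, `n_genes`, `mean`, `ci`,
#'   `median`, `dispersion` (NB size; `Inf` when variance <= mean).
#' @export
summarize_counts <- function(sc, n_boot = 2000, conf_level = 0.95,
                             seed = NULL) {
  counts <- sc$counts
  if (length(counts) == 0L) stop("empty counts")
  if (length(counts) < 2L) stop("need >= 2 genes to summarize")
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- mean(counts)
  v <- stats::var(counts)
  dispersion <- if (v > m) m^2 / (v - m) else Inf
  boot_means <- with_local_seed(seed, {
    n <- length(counts)
    vapply(seq_len(n_boot),
           function(b) mean(counts[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(boot_means, c(alpha / 2, 1 - alpha / 2)))
  structure(list(strain = sc$strain %||% "strain",
                 n_genes = length(counts), mean = m, ci = ci,
                 median = stats::median(counts), dispersion = dispersion),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("%s: %.1f polymerases/gene (95%% CI %.1f-%.1f), N = %d\n",
              x$strain, x$mean, x$ci[1], x$ci[2], x$n_genes))
  invisible(x)
}

#' Compare per-gene polymerase counts between two strains
#'
#' Welch two-sample t-test by default (the test used for the occupancy
#' comparisons in this line of experiments), with Mann-Whitney as a
#' distribution-free alternative.
#'
#' @param a,b `spread_counts` objects.
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return An `occupancy_comparison` list: `strains`, `diff_means`,
#'   `statistic`, `p_value`, `test`.
#' @export
compare_counts <- function(a, b, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  ca <- a$counts; cb <- b$counts
  if (length(ca) < 2L || length(cb) < 2L) stop("need >= 2 counts per strain")
  if (method == "welch" && stats::var(ca) == 0 && stats::var(cb) == 0 &&
      mean(ca) == mean(cb)) {
    warning("both samples constant and identical: p set to 1")
    res <- list(statistic = 0, p.value = 1)
  } else {
    res <- if (method == "welch") stats::t.test(ca, cb)
           else stats::wilcox.test(ca, cb, exact = FALSE)
  }
  structure(list(strains = c(a$strain %||% "a", b$strain %||% "b"),
                 diff_means = mean(ca) - mean(cb),
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 test = if (method == "welch") "Welch t" else "Mann-Whitney"),
            class = "occupancy_comparison")
}

#' Relative Pol I occupancy from a ChIP percent-input table
#'
#' Each replicate's percent-input value is divided by the reference
#' strain's per-amplicon median, then the median and SD of the normalized
#' values are reported per (strain, amplicon), with a Welch t-test of each
#' strain against the reference per amplicon.
#'
#' @param tbl data frame with columns `amplicon`, `strain`, `replicate`,
#'   `percent_input` (>= 0); at least 3 replicates per (strain, amplicon)
#'   are expected (a warning is issued otherwise).
#' @param reference_strain strain used as the occupancy reference
#'   (normalized median 1 by construction).
#' @param alpha significance level for flagging differences. Default 0.01.
#' @return A list with `summary` (data frame: `amplicon`, `strain`,
#'   `median_rel`, `sd_rel`, `n`) and `tests` (data frame: `amplicon`,
#'   `strain`, `p_value`, `significant`).
#' @export
chip_relative_occupancy <- function(tbl, reference_strain, alpha = 0.01) {
  need <- c("amplicon", "strain", "replicate", "percent_input")
  if (!all(need %in% names(tbl)))
    stop("ChIP table needs columns: ", paste(need, collapse = ", "))
  if (any(tbl$percent_input < 0)) stop("percent_input must be >= 0")
  if (!reference_strain %in% tbl$strain)
    stop(sprintf("reference strain '%s' absent", reference_strain))
  n_rep <- stats::aggregate(replicate ~ amplicon + strain, tbl, length)
  if (any(n_rep$replicate < 3))
    warning("fewer than 3 replicates for some (strain, amplicon) pairs")

  ref_med <- tapply(tbl$percent_input[tbl$strain == reference_strain],
                    tbl$amplicon[tbl$strain == reference_strain],
                    stats::median)
  if (!all(unique(tbl$amplicon) %in% names(ref_med)))
    stop("reference strain missing for some amplicon")
  if (any(ref_med == 0)) stop("reference median is zero for some amplicon")

  tbl$rel <- tbl$percent_input / ref_med[as.character(tbl$amplicon)]
  agg <- function(f) stats::aggregate(rel ~ amplicon + strain, tbl, f)
  med <- agg(stats::median); names(med)[3] <- "median_rel"
  sdv <- agg(stats::sd); names(sdv)[3] <- "sd_rel"
  nn <- agg(length); names(nn)[3] <- "n"
  summary <- Reduce(function(x, y) merge(x, y, by = c("amplicon", "strain")),
                    list(med, sdv, nn))
  summary <- summary[order(summary$amplicon, summary$strain), ]
  rownames(summary) <- NULL

  others <- setdiff(unique(tbl$strain), reference_strain)
  tests <- do.call(rbind, lapply(unique(tbl$amplicon), function(am) {
    ref_vals <- tbl$rel[tbl$strain == reference_strain & tbl$amplicon == am]
    do.call(rbind, lapply(others, function(st) {
      v <- tbl$rel[tbl$strain == st & tbl$amplicon == am]
      p <- if (length(v) >= 2 && length(ref_vals) >= 2 &&
               (stats::var(v) > 0 || stats::var(ref_vals) > 0))
        stats::t.test(v, ref_vals)$p.value else NA_real_
      data.frame(amplicon = am, strain = st, p_value = p,
                 significant = !is.na(p) & p < alpha,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL
  list(summary = summary, tests = tests)
}
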