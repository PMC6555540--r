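#' Normalize a signal table to its internal-control probe
#'
#' Per (strain, replicate), every probe's signal is divided by that
#' replicate's control-probe signal (e.g. 5S for run-on slot blots, SCR1
#' or PGK1 for northerns). Replicate-level loading differences cancel by
#' construction; the control probe normalizes to exactly 1.
#'
#' @param tbl a `signal_table` (see [simulate_signal_table()]) or data
#'   frame with columns `probe`, `strain`, `replicate`, `signal` (>= 0).
#' @param control_probe control probe name; default taken from the
#'   table's `control_probe` attribute.
#' @return A `normalized_signals` data frame: `probe`, `strain`,
#'   `replicate`, `normalized`; attribute `control_probe`.
#' @export
normalize_to_control <- function(tbl, control_probe =
                                   attr(tbl, "control_probe")) {
  need <- c("probe", "strain", "replicate", "signal")
  if (!all(need %in% names(tbl)))
    stop("signal table needs columns: ", paste(need, collapse = ", "))
  if (is.null(control_probe))
    stop("'control_probe' must be given (table carries no default)")
  if (any(tbl$signal < 0)) stop("signals must be non-negative")
  key <- paste(tbl$strain, tbl$replicate, sep = "\r")
  ctrl <- tbl[tbl$probe == control_probe, ]
  if (nrow(ctrl) == 0L)
    stop(sprintf("control probe '%s' not found", control_probe))
  ctrl_key <- paste(ctrl$strain, ctrl$replicate, sep = "\r")
  if (anyDuplicated(ctrl_key))
    stop("multiple control-probe rows per (strain, replicate)")
  missing <- setdiff(unique(key), ctrl_key)
  if (length(missing) > 0L)
    stop("no control-probe row for (strain, replicate): ",
         paste(gsub("\r", ", ", missing), collapse = "; "))
  denom <- stats::setNames(ctrl$signal, ctrl_key)[key]
  zero <- denom == 0
  if (any(zero))
    stop("zero control signal in (strain, replicate): ",
         paste(unique(gsub("\r", ", ", key[zero])), collapse = "; "))
  out <- data.frame(probe = tbl$probe, strain = tbl$strain,
                    replicate = tbl$replicate,
                    normalized = tbl$signal / unname(denom),
                    stringsAsFactors = FALSE)
  attr(out, "control_probe") <- control_probe
  class(out) <- c("normalized_signals", "data.frame")
  out
}

#' Average a group of probes into a pseudo-probe
#'
#' Per (strain, replicate), the arithmetic mean of the group's normalized
#' values is reported under a new probe name — e.g. the "Pol I" group
#' (5'ETS, 18S.2, 25S.1, 3'ETS) of a run-on blot.
#'
#' @param ns a `normalized_signals` data frame (see
#'   [normalize_to_control()]).
#' @param group character vector of probe names to average.
#' @param name name of the resulting pseudo-probe. Default
#'   `"group(<probes>)"`.
#' @return `ns` with the pseudo-probe rows appended.
#' @export
probe_group_mean <- function(ns, group,
                             name = paste0("group(",
                                           paste(group, collapse = "+"), ")")) {
  stopifnot(inherits(ns, "normalized_signals"))
  missing <- setdiff(group, unique(ns$probe))
  if (length(missing) > 0L)
    stop("group probes absent from table: ", paste(missing, collapse = ", "))
  sub <- ns[ns$probe %in% group, ]
  agg <- stats::aggregate(normalized ~ strain + replicate, sub, mean)
  # every (strain, replicate) must carry the full group
  n_probes <- stats::aggregate(normalized ~ strain + replicate, sub, length)
  if (any(n_probes$normalized != length(group)))
    stop("some (strain, replicate) pairs lack part of the probe group")
  add <- data.frame(probe = name, strain = agg$strain,
                    replicate = agg$replicate, normalized = agg$normalized,
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(ns), add)
  attr(out, "control_probe") <- attr(ns, "control_probe")
  class(out) <- c("normalized_signals", "data.frame")
  out
}

#' Fold changes versus a reference strain (ratio of medians)
#'
#' Per probe (or pseudo-probe), fold = median(normalized in strain) /
#' median(normalized in reference), with a seeded percentile-bootstrap CI
#' obtained by resampling replicates within each strain. The ratio of
#' medians is used rather than the mean of ratios for robustness with
#' 2-3 replicates.
#'
#' @param ns a `normalized_signals` data frame.
#' @param reference_strain the strain whose folds are 1 by definition.
#' @param n_boot bootstrap resamples. Default 2000.
#' @param conf_level confidence level. Default 0.95.
#' @param seed integer seed for the bootstrap.
#' @return A `fold_changes` data frame: `probe`, `strain`, `fold`,
#'   `ci_lower`, `ci_upper` (reference strain rows included, fold 1).
#' @export
fold_change <- function(ns, reference_strain, n_boot = 2000,
                        conf_level = 0.95, seed = NULL) {
  stopifnot(inherits(ns, "normalized_signals"))
  if (!reference_strain %in% ns$strain)
    stop(sprintf("reference strain '%s' absent", reference_strain))
  alpha <- 1 - conf_level
  combos <- unique(ns[, c("probe", "strain")])
  rows <- with_local_seed(seed, {
    lapply(seq_len(nrow(combos)), function(i) {
      pr <- combos$probe[i]; st <- combos$strain[i]
      v <- ns$normalized[ns$probe == pr & ns$strain == st]
      r <- ns$normalized[ns$probe == pr & ns$strain == reference_strain]
      if (length(r) == 0L)
        stop(sprintf("reference strain has no probe '%s'", pr))
      ref_med <- stats::median(r)
      if (ref_med == 0) stop(sprintf("reference median 0 for probe '%s'", pr))
      fold <- stats::median(v) / ref_med
      boot <- vapply(seq_len(n_boot), function(b) {
        stats::median(v[sample.int(length(v), replace = TRUE)]) /
          stats::median(r[sample.int(length(r), replace = TRUE)])
      }, numeric(1))
      ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                                   na.rm = TRUE))
      data.frame(probe = pr, strain = st, fold = fold,
                 ci_lower = ci[1], ci_upper = ci[2],
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fold_changes", "data.frame")
  out
}
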