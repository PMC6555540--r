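#' Simulate an exponential growth curve with multiplicative noise
#'
#' OD600 readings follow od(t) = od0 * 2^(t / tau) * noise, with
#' independent lognormal noise of the requested CV at each time point.
#'
#' @param tau_min true doubling time in minutes (> 0).
#' @param t_grid time points in minutes, strictly increasing, >= 4 values.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param od0 optical density at t = 0. Default 0.05.
#' @param strain strain label attached to the curve.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A `growth_curve`: data frame with columns `time` (min) and `od`,
#'   attribute `strain`.
#' @examples
#' gc <- simulate_growth_curve(102, seq(0, 600, length.out = 20),
#'                             noise_cv = 0.02, seed = 1)
#' fit_doubling_time(gc)
#' @export
simulate_growth_curve <- function(tau_min, t_grid, noise_cv = 0,
                                  od0 = 0.05, strain = "strain", seed = NULL) {
  check_scalar(tau_min, "tau_min", lower = 0, strict_lower = TRUE)
  check_scalar(od0, "od0", lower = 0, strict_lower = TRUE)
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 4L || any(diff(t_grid) <= 0))
    stop("'t_grid' must be strictly increasing with >= 4 points")
  noise <- with_local_seed(seed, rlnorm_cv(length(t_grid), noise_cv))
  out <- data.frame(time = t_grid, od = od0 * 2^(t_grid / tau_min) * noise)
  attr(out, "strain") <- strain
  class(out) <- c("growth_curve", "data.frame")
  out
}

#' Simulate per-gene polymerase counts (Miller-spread style)
#'
#' Draws i.i.d. per-gene polymerase counts from a negative binomial with
#' the given mean and dispersion (`size` parameter); `dispersion = Inf`
#' gives the Poisson limit.
#'
#' @param mean_count true mean polymerases per gene (> 0).
#' @param n_genes number of spread genes counted (>= 1).
#' @param dispersion negative-binomial size parameter (> 0); `Inf` for
#'   Poisson. Default `Inf`.
#' @param strain strain label.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A `spread_counts` object: list with `strain`, `counts`
#'   (non-negative integers), `n_genes`.
#' @export
simulate_spread_counts <- function(mean_count, n_genes, dispersion = Inf,
                                   strain = "strain", seed = NULL) {
  check_scalar(mean_count, "mean_count", lower = 0, strict_lower = TRUE)
  check_scalar(n_genes, "n_genes", lower = 1)
  if (!is.numeric(dispersion) || length(dispersion) != 1L ||
      is.na(dispersion) || dispersion <= 0)
    stop("'dispersion' must be a positive number or Inf")
  counts <- with_local_seed(seed, {
    if (is.infinite(dispersion)) stats::rpois(n_genes, mean_count)
    else stats::rnbinom(n_genes, mu = mean_count, size = dispersion)
  })
  structure(list(strain = strain, counts = as.integer(counts),
                 n_genes = as.integer(n_genes)),
            class = "spread_counts")
}

#' Simulate a replicate signal table with an internal-control probe
#'
#' Generates long-format probe x strain x replicate signals as
#' baseline * fold * loading * noise. A replicate-level loading multiplier
#' is applied to every probe of that (strain, replicate) — including the
#' control probe — so that dividing by the control signal removes loading
#' exactly. Fold effects are specified per (strain, probe); the reference
#' strain and the control probe must have fold 1.
#'
#' @param folds data frame with columns `strain`, `probe`, `fold` giving
#'   the true fold of each probe in each strain relative to the reference
#'   strain. Every strain must include a row for `control_probe` with
#'   fold 1, and the reference strain must have fold 1 everywhere.
#' @param control_probe name of the internal-control probe (e.g. "5S",
#'   "SCR1", "PGK1").
#' @param reference_strain name of the reference strain.
#' @param n_replicates replicates per strain. Default 3.
#' @param noise_cv CV of the per-signal lognormal noise. Default 0.2.
#' @param loading_cv CV of the per-replicate loading multiplier (shared by
#'   all probes of a replicate). Default 0.3.
#' @param baseline named vector of per-probe baseline intensities, or a
#'   single number. Default 100.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A `signal_table`: data frame with columns `probe`, `strain`,
#'   `replicate`, `signal`; attribute `control_probe`.
#' @examples
#' folds <- expand.grid(strain = c("WT", "mut"),
#'                      probe = c("18S.2", "5S"), stringsAsFactors = FALSE)
#' folds$fold <- ifelse(folds$strain == "mut" & folds$probe == "18S.2", 3, 1)
#' st <- simulate_signal_table(folds, control_probe = "5S",
#'                             reference_strain = "WT", noise_cv = 0, seed = 1)
#' fold_change(normalize_to_control(st, "5S"), reference_strain = "WT")
#' @export
simulate_signal_table <- function(folds, control_probe, reference_strain,
                                  n_replicates = 3, noise_cv = 0.2,
                                  loading_cv = 0.3, baseline = 100,
                                  seed = NULL) {
  folds <- as.data.frame(folds)
  if (!all(c("strain", "probe", "fold") %in% names(folds)))
    stop("'folds' needs columns strain, probe, fold")
  folds$strain <- as.character(folds$strain)
  folds$probe <- as.character(folds$probe)
  if (!control_probe %in% folds$probe)
    stop(sprintf("control probe '%s' missing from the fold map",
                 control_probe))
  if (!reference_strain %in% folds$strain)
    stop(sprintf("reference strain '%s' missing from the fold map",
                 reference_strain))
  if (any(folds$fold[folds$probe == control_probe] != 1))
    stop("the control probe must have fold 1 in every strain")
  if (any(folds$fold[folds$strain == reference_strain] != 1))
    stop("the reference strain must have fold 1 for every probe")
  check_scalar(n_replicates, "n_replicates", lower = 1)

  probes <- unique(folds$probe)
  if (length(baseline) == 1L && is.null(names(baseline)))
    baseline <- stats::setNames(rep(baseline, length(probes)), probes)
  if (!all(probes %in% names(baseline)))
    stop("'baseline' must cover every probe")

  grid <- merge(folds,
                expand.grid(strain = unique(folds$strain),
                            replicate = seq_len(n_replicates),
                            stringsAsFactors = FALSE),
                by = "strain")
  grid <- grid[order(grid$strain, grid$replicate, grid$probe), ]
  out <- with_local_seed(seed, {
    rep_key <- paste(grid$strain, grid$replicate)
    loading <- rlnorm_cv(length(unique(rep_key)), loading_cv)
    names(loading) <- unique(rep_key)
    grid$signal <- baseline[grid$probe] * grid$fold * loading[rep_key] *
      rlnorm_cv(nrow(grid), noise_cv)
    grid
  })
  out <- out[, c("probe", "strain", "replicate", "signal")]
  rownames(out) <- NULL
  attr(out, "control_probe") <- control_probe
  class(out) <- c("signal_table", "data.frame")
  out
}

#' Simulate colony counts for suppressor-frequency estimation
#'
#' Models plating of `n_cells` cells with and without UV irradiation.
#' Spontaneous suppressor colonies are Binomial(n_cells, freq); after UV,
#' only `survival_fraction` of cells survive and the per-cell suppressor
#' probability is multiplied by `uv_fold`:
#' Binomial(round(n_cells * survival_fraction), freq * uv_fold).
#'
#' @param freq spontaneous per-cell suppressor frequency, in (0, 1).
#' @param n_cells number of cells plated per condition.
#' @param uv_fold fold increase of the suppressor frequency after UV
#'   (>= 1). Default 10.
#' @param survival_fraction fraction of cells surviving UV, in (0, 1].
#'   Default 0.5.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return List of two `fluctuation_counts` objects (`spontaneous`, `uv`),
#'   each with fields `cells_plated`, `suppressor_colonies`, `condition`,
#'   `survival_fraction`.
#' @export
simulate_fluctuation <- function(freq, n_cells, uv_fold = 10,
                                 survival_fraction = 0.5, seed = NULL) {
  check_scalar(freq, "freq", lower = 0, upper = 1)
  if (freq >= 1) stop("'freq' must be < 1")
  check_scalar(n_cells, "n_cells", lower = 1)
  check_scalar(uv_fold, "uv_fold", lower = 1)
  check_scalar(survival_fraction, "survival_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (freq * uv_fold >= 1)
    stop("freq * uv_fold must be < 1")
  n_uv <- round(n_cells * survival_fraction)
  counts <- with_local_seed(seed, {
    list(sp = stats::rbinom(1, n_cells, freq),
         uv = stats::rbinom(1, n_uv, freq * uv_fold))
  })
  fc <- function(cells, colonies, condition, survival) {
    structure(list(cells_plated = cells, suppressor_colonies = colonies,
                   condition = condition, survival_fraction = survival),
              class = "fluctuation_counts")
  }
  list(spontaneous = fc(n_cells, counts$sp, "spontaneous", 1),
       uv = fc(n_cells, counts$uv, "UV", survival_fraction))
}
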