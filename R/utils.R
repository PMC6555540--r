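# internal helpers shared across generators and estimators

# multiplicative lognormal noise with E[noise] = 1 and the requested
# coefficient of variation; cv = 0 returns exact ones
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("'noise_cv' must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# run expr under a local RNG stream; seed = NULL leaves the global RNG alone
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  withr::with_seed(as.integer(seed), expr)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop(sprintf("'%s' = %g is out of range", name, x))
  invisible(x)
}
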