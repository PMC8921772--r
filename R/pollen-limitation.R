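# Pollen limitation: the fraction of potential seed set lost to inadequate
# pollinator service, PL = 1 - mean(seeds_C) / mean(seeds_HP).

#' Pollen-limitation index
#'
#' @param seeds_C,seeds_HP Seeds-per-plant values (or cell means) of the
#'   open-pollinated and hand-pollinated plants.
#' @return `1 - mean(seeds_C) / mean(seeds_HP)`, a dimensionless index in
#'   (-Inf, 1]; 0 means no limitation, negative values mean C plants
#'   out-yielded HP plants.
#' @export
#' @examples
#' pl_index(56.4, 114.4)  # 0.507: half the potential seed set lost
pl_index <- function(seeds_C, seeds_HP) {
  if (length(seeds_C) == 0L || length(seeds_HP) == 0L) {
    stop("both treatment arms must be non-empty")
  }
  m_hp <- mean(seeds_HP)
  if (m_hp == 0) stop("mean HP seed set is zero; pollen limitation undefined")
  1 - mean(seeds_C) / m_hp
}

#' Bootstrap confidence interval for pollen limitation
#'
#' Resamples the two treatment arms independently with replacement (each at
#' its own sample size, via the stratified bootstrap of the `boot` package),
#' recomputes the index per replicate, and returns percentile bounds.
#' Replicates whose resampled HP mean is zero leave the index undefined and
#' are dropped and counted; more than 1% dropped triggers a warning.
#'
#' @inheritParams pl_index
#' @param n_boot Number of bootstrap iterations (>= 200); default 2000.
#' @param level Confidence level; default 0.95.
#' @param seed Integer RNG seed; results are reproducible.
#' @return An object of class `pl_result` with fields `estimate`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`, `n_C`, `n_HP`, `n_dropped`, `level`.
#' @export
pl_bootstrap <- function(seeds_C, seeds_HP, n_boot = 2000L, level = 0.95,
                         seed = 1L) {
  if (n_boot < 200L) stop("n_boot must be at least 200")
  est <- pl_index(seeds_C, seeds_HP)
  dat <- data.frame(seeds = c(seeds_C, seeds_HP),
                    arm = rep(c("C", "HP"),
                              c(length(seeds_C), length(seeds_HP))))
  is_C <- dat$arm == "C"
  stat <- function(d, i) {
    s <- d$seeds[i]  # stratified resampling keeps arm positions fixed
    m_hp <- mean(s[!is_C])
    if (m_hp == 0) return(NA_real_)
    1 - mean(s[is_C]) / m_hp
  }
  set.seed(seed)
  bt <- boot::boot(dat, stat, R = n_boot, strata = as.integer(is_C))
  reps <- bt$t[, 1L]
  n_dropped <- sum(is.na(reps))
  if (n_dropped > 0.01 * n_boot) {
    warning(n_dropped, " of ", n_boot,
            " bootstrap replicates had zero HP mean and were dropped")
  }
  alpha <- (1 - level) / 2
  ci <- quantile(reps[!is.na(reps)], c(alpha, 1 - alpha), names = FALSE)
  structure(list(estimate = est, ci_low = ci[1L], ci_high = ci[2L],
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 n_C = length(seeds_C), n_HP = length(seeds_HP),
                 n_dropped = n_dropped, level = level),
            class = "pl_result")
}

#' @export
as.data.frame.pl_result <- function(x, ...) {
  data.frame(estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
             n_boot = x$n_boot, seed = x$seed, n_C = x$n_C, n_HP = x$n_HP,
             n_dropped = x$n_dropped, level = x$level)
}

#' @export
print.pl_result <- function(x, ...) {
  cat(sprintf(
    "Pollen limitation: %.3f  [%.3f, %.3f] (%d%% percentile CI, %d reps; n_C = %d, n_HP = %d)\n",
    x$estimate, x$ci_low, x$ci_high, round(100 * x$level), x$n_boot,
    x$n_C, x$n_HP))
  invisible(x)
}
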