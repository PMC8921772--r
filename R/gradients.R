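# Standardized selection-gradient estimation in the Lande-Arnold tradition:
# relative fitness (seeds per plant over the cell mean) regressed on traits
# standardized to mean 0, variance 1 within the analysis cell.

#' Construct a standardized design for gradient estimation
#'
#' Low-level constructor used by [standardize_cell()] and by tests that need
#' exact control over `z` and relative fitness.
#'
#' @param z Numeric matrix of standardized traits (plants x traits).
#' @param w_rel Numeric vector of relative fitness, mean 1.
#' @param trait_names Column labels for `z`.
#' @param cell Optional named list identifying the analysis cell.
#' @param zero_fitness_policy Policy that produced the design (recorded in
#'   downstream tables).
#' @param validate Check the standardization invariants (column means 0 and
#'   sample variances 1 to 1e-10, `mean(w_rel)` 1).
#' @return An object of class `standardized_design`.
#' @export
new_standardized_design <- function(z, w_rel, trait_names = colnames(z),
                                    cell = NULL,
                                    zero_fitness_policy = "include",
                                    validate = TRUE) {
  z <- as.matrix(z)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(z)))
  colnames(z) <- trait_names
  if (nrow(z) != length(w_rel)) stop("z and w_rel differ in length")
  if (anyNA(z) || anyNA(w_rel)) stop("missing values in standardized design")
  if (validate) {
    cm <- colMeans(z)
    cv <- apply(z, 2, var)
    if (any(abs(cm) > 1e-10)) stop("z columns are not centered")
    if (any(abs(cv - 1) > 1e-8)) stop("z columns do not have unit variance")
    if (abs(mean(w_rel) - 1) > 1e-10) stop("mean relative fitness is not 1")
  }
  structure(list(z = z, w_rel = as.numeric(w_rel),
                 trait_names = trait_names, cell = cell,
                 zero_fitness_policy = zero_fitness_policy),
            class = "standardized_design")
}

#' Standardize traits and relativize fitness within an analysis cell
#'
#' Trait columns are centered and scaled by the within-cell sample SD
#' (n - 1 denominator); relative fitness is seeds per plant divided by the
#' within-cell mean.  Both use the records remaining after the zero-fitness
#' policy is applied, so the invariants (column mean 0, variance 1, mean
#' relative fitness 1) hold on the analyzed set.
#'
#' @param records Data frame of plant records for a single analysis cell.
#' @param traits Character vector of trait columns ([trait_spec()]).
#' @param zero_fitness_policy `"include"` (default: zero-seed plants carry
#'   relative fitness 0) or `"exclude"`.
#' @param fitness Fitness column; default `"seeds_per_plant"`.
#' @param cell Optional named list identifying the cell (site/year/nutrient
#'   and pollination), carried into every downstream table.
#' @return A `standardized_design`.
#' @export
standardize_cell <- function(records, traits,
                             zero_fitness_policy = c("include", "exclude"),
                             fitness = "seeds_per_plant", cell = NULL) {
  zero_fitness_policy <- match.arg(zero_fitness_policy)
  missing <- setdiff(c(traits, fitness), names(records))
  if (length(missing) > 0L) {
    stop("column(s) not in records: ", paste(missing, collapse = ", "))
  }
  if (zero_fitness_policy == "exclude") {
    records <- records[records[[fitness]] > 0, , drop = FALSE]
  }
  n <- nrow(records)
  if (n < length(traits) + 2L) {
    stop("cell has ", n, " plants; need at least ", length(traits) + 2L)
  }
  x <- as.matrix(records[traits])
  if (anyNA(x)) stop("missing trait values in cell")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("trait(s) constant within cell: ",
         paste(traits[sds == 0], collapse = ", "))
  }
  w <- records[[fitness]]
  if (anyNA(w)) stop("missing fitness values in cell")
  if (mean(w) == 0) stop("all plants have zero fitness; relative fitness undefined")
  z <- scale(x)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  new_standardized_design(z, w / mean(w), trait_names = traits, cell = cell,
                          zero_fitness_policy = zero_fitness_policy,
                          validate = FALSE)
}

.gradient_table <- function(trait, estimate, se, tstat, p, vif, kind, fit,
                            design, extra = NULL) {
  out <- data.frame(trait = trait, estimate = estimate, std_error = se,
                    t_statistic = tstat, p_value = p, vif = vif,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  s <- summary(fit)
  structure(out, class = c("gradient_table", "data.frame"),
            kind = kind, n = length(design$w_rel),
            r_squared = unname(s$r.squared),
            residual_df = unname(fit$df.residual),
            cell = design$cell,
            zero_fitness_policy = design$zero_fitness_policy,
            vif_all = extra$vif_all)
}

#' Estimate directional selection gradients
#'
#' Ordinary least squares of relative fitness on all standardized traits
#' jointly; the partial regression coefficients are the directional
#' gradients beta_i, with t-based standard errors and p-values and a VIF per
#' trait.
#'
#' @param design A `standardized_design`.
#' @return A `gradient_table`: one row per trait with `estimate`,
#'   `std_error`, `t_statistic`, `p_value` and `vif`; model-level attributes
#'   `kind`, `n`, `r_squared`, `residual_df`.
#' @export
fit_directional <- function(design) {
  stopifnot(inherits(design, "standardized_design"))
  df <- data.frame(.w = design$w_rel, design$z, check.names = FALSE)
  fit <- lm(.w ~ ., data = df)
  if (anyNA(coef(fit))) {
    stop("singular design: collinear trait column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  cf <- summary(fit)$coefficients[-1L, , drop = FALSE]
  vif <- if (ncol(design$z) >= 2L) compute_vif(design$z) else
    rep(NA_real_, ncol(design$z))
  .gradient_table(design$trait_names, cf[, 1L], cf[, 2L], cf[, 3L],
                  cf[, 4L], unname(vif), "directional", fit, design,
                  extra = list(vif_all = vif))
}

#' Estimate quadratic (stabilizing or disruptive) selection gradients
#'
#' OLS of relative fitness on all linear terms plus all pure squared terms
#' (no cross-products).  Following standard practice, the reported gradient
#' gamma_ii and its standard error are twice the fitted coefficient of
#' z_i^2 and its standard error; t statistics and p-values are unchanged by
#' the doubling.
#'
#' @inheritParams fit_directional
#' @return A `gradient_table` of the quadratic gradients (one row per
#'   trait).  The linear-term coefficients of the same model are available
#'   in attribute `linear_terms`, and VIFs of the full linear-plus-squared
#'   design in `vif_all`.
#' @export
fit_quadratic <- function(design) {
  stopifnot(inherits(design, "standardized_design"))
  k <- ncol(design$z)
  n <- length(design$w_rel)
  if (n <= 2L * k + 2L) {
    stop("need more than ", 2L * k + 2L, " plants for the quadratic model; have ", n)
  }
  zsq <- design$z^2
  colnames(zsq) <- paste0(design$trait_names, "_sq")
  df <- data.frame(.w = design$w_rel, design$z, zsq, check.names = FALSE)
  fit <- lm(.w ~ ., data = df)
  if (anyNA(coef(fit))) {
    stop("singular design: collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  lin <- cf[design$trait_names, , drop = FALSE]
  quad <- cf[colnames(zsq), , drop = FALSE]
  vif_all <- compute_vif(cbind(design$z, zsq))
  out <- .gradient_table(design$trait_names,
                         2 * quad[, 1L], 2 * quad[, 2L], quad[, 3L],
                         quad[, 4L], unname(vif_all[colnames(zsq)]),
                         "quadratic", fit, design,
                         extra = list(vif_all = vif_all))
  attr(out, "linear_terms") <- data.frame(
    trait = design$trait_names, estimate = lin[, 1L], std_error = lin[, 2L],
    t_statistic = lin[, 3L], p_value = lin[, 4L], row.names = NULL)
  out
}

#' Variance inflation factors of a design matrix
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from regressing column j on
#' all remaining columns (with intercept).  Values of 5 or more are flagged
#' as problematic multicollinearity; perfectly collinear columns report
#' `Inf`.
#'
#' @param x Numeric matrix with at least two columns and more rows than
#'   columns.
#' @return Named numeric vector of VIFs with a logical attribute `flagged`
#'   marking entries `>= 5`.
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 predictor columns")
  if (nrow(x) <= ncol(x)) stop("need more rows than predictor columns")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  vif <- vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  attr(vif, "flagged") <- vif >= 5
  vif
}
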