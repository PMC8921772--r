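# Factorial ANOVA on (log-transformed) traits and fitness, and ANCOVA
# interaction models testing whether selection varies across the design.

.anova_table <- function(at, response, factors, transform = "none",
                         ss_type = "I", extra = NULL) {
  df_den <- at["Residuals", "Df"]
  keep <- setdiff(rownames(at), "Residuals")
  out <- data.frame(term = keep, df_num = at[keep, "Df"],
                    df_den = df_den, F_statistic = at[keep, "F value"],
                    p_value = at[keep, "Pr(>F)"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("anova_table", "data.frame"),
            response = response, factors = factors, transform = transform,
            ss_type = ss_type, sum_sq = at[keep, "Sum Sq"],
            total_ss = sum(at[, "Sum Sq"]), flagged = extra$flagged)
}

.check_factor_cells <- function(records, factors) {
  for (f in factors) {
    if (length(unique(records[[f]])) < 2L) {
      stop("factor ", f, " has fewer than 2 observed levels")
    }
  }
  if (length(factors) > 1L) {
    tab <- table(records[factors])
    if (any(tab == 0L)) {
      empty <- which(tab == 0L, arr.ind = TRUE)
      lab <- apply(empty, 1L, function(ix) {
        paste(mapply(function(f, i) dimnames(tab)[[f]][i],
                     seq_along(factors), ix), collapse = " x ")
      })
      warning("empty design cell(s): ", paste(lab, collapse = "; "),
              " (model may be rank deficient)")
    }
  }
  invisible(NULL)
}

#' Full-factorial ANOVA on a trait or fitness component
#'
#' Fits the complete factorial linear model of the (optionally log10-
#' transformed) response on the given design factors and reports per-term F
#' tests.  Sequential (Type I) sums of squares are the default; Type III
#' (with sum-to-zero contrasts, via `car`) is available for unbalanced data.
#'
#' @param records Plant-record data frame.
#' @param response Response column name.
#' @param factors Character vector of factor columns; all main effects and
#'   interactions up to the full order are tested.
#' @param transform `"log10"` (default; the response must be strictly
#'   positive) or `"none"`.
#' @param ss_type `"I"` (sequential) or `"III"`.
#' @return An `anova_table`: per term `df_num`, `df_den`, `F_statistic`,
#'   `p_value`, with the model metadata as attributes.
#' @export
factorial_anova <- function(records, response, factors,
                            transform = c("log10", "none"),
                            ss_type = c("I", "III")) {
  transform <- match.arg(transform)
  ss_type <- match.arg(ss_type)
  missing <- setdiff(c(response, factors), names(records))
  if (length(missing) > 0L) {
    stop("column(s) not in records: ", paste(missing, collapse = ", "))
  }
  y <- records[[response]]
  if (transform == "log10") {
    bad <- which(!is.na(y) & y <= 0)
    if (length(bad) > 0L) {
      stop("log10 transform needs a positive response; offending row(s): ",
           paste(head(bad, 20L), collapse = ", "),
           if (length(bad) > 20L) ", ..." else "")
    }
    y <- log10(y)
  }
  dat <- records[factors]
  dat[] <- lapply(dat, factor)
  .check_factor_cells(dat, factors)
  dat$.y <- y
  form <- as.formula(paste(".y ~", paste(factors, collapse = " * ")))
  if (ss_type == "I") {
    fit <- lm(form, data = dat)
    .anova_table(anova(fit), response, factors, transform, "I")
  } else {
    fit <- lm(form, data = dat,
              contrasts = setNames(rep(list("contr.sum"), length(factors)),
                                   factors))
    a3 <- car::Anova(fit, type = 3)
    a3 <- a3[setdiff(rownames(a3), "(Intercept)"), , drop = FALSE]
    .anova_table(a3, response, factors, transform, "III")
  }
}

#' ANCOVA test for variation in (pollinator-mediated) selection
#'
#' Pools the plants of every analysis cell after within-cell trait
#' standardization and fitness relativization, then fits the linear model of
#' relative fitness on the trait covariates fully crossed with the design
#' factors and the pollination treatment.  Significant
#' trait x factor x pollination interactions indicate that
#' pollinator-mediated selection varies across that factor; the fitted table
#' flags the traits whose three- or higher-way interactions with pollination
#' fall below `alpha`.
#'
#' @param records Plant-record data frame spanning both pollination levels
#'   and all factor levels.
#' @param traits Trait columns entering as covariates ([trait_spec()]).
#' @param factors Design factors to cross with the traits, e.g.
#'   `c("site", "year")` or `"nutrient"`.
#' @param pollination Pollination treatment column; default `"pollination"`.
#' @param standardize `"within_cell"` (default: traits standardized and
#'   fitness relativized within each factor x pollination cell before
#'   pooling) or `"global"`.
#' @param fitness Fitness column; default `"seeds_per_plant"`.
#' @param alpha Significance level used for the interaction flags.
#' @param ss_type `"I"` or `"III"`.
#' @return An `anova_table` with attribute `flagged`: the subset of
#'   trait x factor(s) x pollination interaction rows with
#'   `p_value < alpha`.
#' @export
ancova_selection_variation <- function(records, traits, factors,
                                       pollination = "pollination",
                                       standardize = c("within_cell",
                                                       "global"),
                                       fitness = "seeds_per_plant",
                                       alpha = 0.05,
                                       ss_type = c("I", "III")) {
  standardize <- match.arg(standardize)
  ss_type <- match.arg(ss_type)
  missing <- setdiff(c(traits, factors, pollination, fitness),
                     names(records))
  if (length(missing) > 0L) {
    stop("column(s) not in records: ", paste(missing, collapse = ", "))
  }
  for (f in c(factors, pollination)) {
    if (length(unique(records[[f]])) < 2L) {
      stop("factor ", f, " has fewer than 2 observed levels; ",
           "cannot test variation across it")
    }
  }
  cellf <- interaction(records[c(factors, pollination)], drop = TRUE)
  z <- matrix(NA_real_, nrow(records), length(traits),
              dimnames = list(NULL, traits))
  w <- rep(NA_real_, nrow(records))
  if (standardize == "within_cell") {
    for (lev in levels(cellf)) {
      ix <- which(cellf == lev)
      z[ix, ] <- scale(as.matrix(records[ix, traits, drop = FALSE]))
      w[ix] <- records[[fitness]][ix] / mean(records[[fitness]][ix])
    }
  } else {
    z[] <- scale(as.matrix(records[traits]))
    w <- records[[fitness]] / mean(records[[fitness]])
  }
  dat <- as.data.frame(z)
  for (f in c(factors, pollination)) dat[[f]] <- factor(records[[f]])
  dat$.w <- w
  rhs <- paste0("(", paste(traits, collapse = " + "), ") * ",
                paste(c(factors, pollination), collapse = " * "))
  form <- as.formula(paste(".w ~", rhs))
  n_terms <- ncol(model.matrix(form, dat))
  if (nrow(dat) <= n_terms + 1L) {
    stop("insufficient degrees of freedom for the full interaction model: ",
         "need at least ", n_terms + 2L, " plants, have ", nrow(dat))
  }
  out <- if (ss_type == "I") {
    fit <- lm(form, data = dat)
    .anova_table(anova(fit), fitness, c(factors, pollination), "none", "I")
  } else {
    ctr <- setNames(rep(list("contr.sum"), length(factors) + 1L),
                    c(factors, pollination))
    fit <- lm(form, data = dat, contrasts = ctr)
    a3 <- car::Anova(fit, type = 3)
    a3 <- a3[setdiff(rownames(a3), "(Intercept)"), , drop = FALSE]
    .anova_table(a3, fitness, c(factors, pollination), "none", "III")
  }
  # flag trait x factor(s) x pollination interactions below alpha
  parts <- strsplit(out$term, ":", fixed = TRUE)
  is_pm <- vapply(parts, function(p) {
    any(p %in% traits) && pollination %in% p && any(p %in% factors)
  }, logical(1))
  flagged <- out[is_pm & out$p_value < alpha, , drop = FALSE]
  attr(out, "flagged") <- flagged
  attr(out, "standardize") <- standardize
  out
}

#' ANOVA on the strength of selection
#'
#' Tests whether the absolute selection gradients assembled by
#' [strength_table()] differ among design-factor levels (e.g. site, year and
#' their interaction, or nutrient level).
#'
#' @param strengths Output of [strength_table()] (optionally pre-filtered to
#'   one `kind`).
#' @param factors Explanatory factor columns present in `strengths`.
#' @param response `"pm_strength"` (default) or `"net_strength"`.
#' @param interaction Include factor interactions (only meaningful with two
#'   or more factors).
#' @return An `anova_table`.
#' @export
strength_anova <- function(strengths, factors,
                           response = c("pm_strength", "net_strength"),
                           interaction = TRUE) {
  response <- match.arg(response)
  missing <- setdiff(c(response, factors), names(strengths))
  if (length(missing) > 0L) {
    stop("column(s) not in strengths: ", paste(missing, collapse = ", "))
  }
  dat <- strengths[factors]
  dat[] <- lapply(dat, factor)
  dat$.y <- strengths[[response]]
  sep <- if (interaction && length(factors) > 1L) " * " else " + "
  form <- as.formula(paste(".y ~", paste(factors, collapse = sep)))
  fit <- lm(form, data = dat)
  if (fit$df.residual == 0L) {
    stop("saturated model: no residual degrees of freedom; ",
         "drop the interaction or provide more strength values per cell")
  }
  at <- anova(fit)
  if (sum(at[, "Sum Sq"]) < 1e-24) {  # constant response: F is 0, not 0/0
    at[, "F value"] <- 0
    at[, "Pr(>F)"] <- 1
    at["Residuals", c("F value", "Pr(>F)")] <- NA
  }
  .anova_table(at, response, factors, "none", "I")
}

#' Levene's test of variance homogeneity (diagnostic only)
#'
#' Convenience wrapper around `car::leveneTest`; reported as a diagnostic
#' alongside ANOVA tables, never used to gate an analysis.
#'
#' @param records Data frame.
#' @param response Response column.
#' @param factors Grouping factor column(s); groups are their interaction.
#' @return A one-row data frame with `F_statistic`, `df_num`, `df_den`,
#'   `p_value`.
#' @export
variance_homogeneity <- function(records, response, factors) {
  g <- interaction(records[factors], drop = TRUE)
  lt <- car::leveneTest(records[[response]], g)
  data.frame(F_statistic = lt[1L, "F value"], df_num = lt[1L, "Df"],
             df_den = lt[2L, "Df"], p_value = lt[1L, "Pr(>F)"])
}
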