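# Pollinator-mediated selection: the C-minus-HP difference in gradients.
# Hand pollination removes pollen limitation, so any selection remaining in
# HP plants is non-pollinator-mediated and the difference isolates the
# pollinator component.

.cell_sans_pollination <- function(cell) {
  if (is.null(cell)) return(NULL)
  cell[setdiff(names(cell), "pollination")]
}

#' Pollinator-mediated selection contrast between matched cells
#'
#' Per trait, `delta = estimate_C - estimate_HP` and
#' `se_delta = sqrt(se_C^2 + se_HP^2)` (independent fits).  A normal
#' z statistic and two-sided p-value are attached as a descriptive guide;
#' formal tests of variation in selection are the ANCOVA interaction models
#' in [ancova_selection_variation()].
#'
#' @param grad_C,grad_HP `gradient_table`s of the same kind and trait set
#'   from the open-pollination (C) and hand-pollination (HP) cells of the
#'   same site/year or nutrient level.  Mismatched cells are refused.
#' @return A `contrast_table`: one row per trait with `delta`, `se_delta`,
#'   `z_statistic`, `p_value`.
#' @export
contrast_gradients <- function(grad_C, grad_HP) {
  stopifnot(inherits(grad_C, "gradient_table"),
            inherits(grad_HP, "gradient_table"))
  if (!identical(attr(grad_C, "kind"), attr(grad_HP, "kind"))) {
    stop("gradient tables are of different kinds (directional vs quadratic)")
  }
  if (!identical(grad_C$trait, grad_HP$trait)) {
    stop("trait sets do not align between the two gradient tables")
  }
  cC <- .cell_sans_pollination(attr(grad_C, "cell"))
  cH <- .cell_sans_pollination(attr(grad_HP, "cell"))
  if (!is.null(cC) && !is.null(cH) && !identical(cC, cH)) {
    stop("cells are not matched (differ beyond the pollination level); ",
         "refusing a cross-cell contrast")
  }
  delta <- grad_C$estimate - grad_HP$estimate
  se <- sqrt(grad_C$std_error^2 + grad_HP$std_error^2)
  degenerate <- se == 0 & delta != 0
  if (any(degenerate)) {
    warning("zero contrast SE with nonzero delta for trait(s): ",
            paste(grad_C$trait[degenerate], collapse = ", "))
  }
  z <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  out <- data.frame(trait = grad_C$trait, delta = delta, se_delta = se,
                    z_statistic = z, p_value = 2 * pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("contrast_table", "data.frame"),
            kind = attr(grad_C, "kind"), cell = cC,
            n_C = attr(grad_C, "n"), n_HP = attr(grad_HP, "n"))
}

#' Assemble selection-strength table
#'
#' Long-format table of the absolute net selection gradients (|beta_C| or
#' |gamma_C|) and absolute pollinator-mediated gradients (|delta|) per trait
#' and cell, the response consumed by [strength_anova()].
#'
#' @param net List of C-cell `gradient_table`s.
#' @param pm List of `contrast_table`s, pairwise matched to `net` (same
#'   order, same cells, same kind, same traits).
#' @return A `data.frame` with the cell key columns plus `kind`, `trait`,
#'   `net_strength` and `pm_strength`; all strengths are non-negative.
#' @export
strength_table <- function(net, pm) {
  if (inherits(net, "gradient_table")) net <- list(net)
  if (inherits(pm, "contrast_table")) pm <- list(pm)
  if (length(net) != length(pm)) {
    stop("need one contrast table per net gradient table")
  }
  rows <- vector("list", length(net))
  for (i in seq_along(net)) {
    g <- net[[i]]; d <- pm[[i]]
    if (!identical(g$trait, d$trait)) {
      stop("trait sets do not align for table pair ", i)
    }
    if (!identical(attr(g, "kind"), attr(d, "kind"))) {
      stop("kinds do not align for table pair ", i)
    }
    cg <- .cell_sans_pollination(attr(g, "cell"))
    cd <- attr(d, "cell")
    if (!is.null(cg) && !is.null(cd) && !identical(cg, cd)) {
      stop("cells do not align for table pair ", i)
    }
    cell_cols <- if (is.null(cg)) {
      data.frame(cell = rep(i, nrow(g)))
    } else {
      as.data.frame(cg, stringsAsFactors = FALSE)[rep(1L, nrow(g)), ,
                                                  drop = FALSE]
    }
    rows[[i]] <- cbind(cell_cols,
                       data.frame(kind = attr(g, "kind"), trait = g$trait,
                                  net_strength = abs(g$estimate),
                                  pm_strength = abs(d$delta),
                                  stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
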