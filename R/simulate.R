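# Synthetic field experiments.  Traits are drawn from a multivariate normal
# with per-cell means/SDs taken (by default) from the published per-cell
# moments; expected seed set follows the standard quadratic fitness surface
# on within-cell standardized traits, reduced multiplicatively for open-
# pollinated plants to emulate pollen limitation, and realized as an
# overdispersed (gamma-mixed Poisson) count.

#' Configure a synthetic pollination experiment
#'
#' Builds the full generative specification for one of the two supported
#' designs.  Defaults reproduce the field designs cell by cell: sample sizes
#' and trait/fitness moments from [design_moments()], exchangeable trait
#' correlation 0.3, and an overdispersed seed-count model whose cell means
#' equal the published seeds-per-plant means (so pollen limitation is already
#' embodied in the C-cell baselines and `pl_intensity` stays 1).
#'
#' @param design `"two_site_two_year"` or `"nutrient_garden"`.
#' @param cells Data frame of cell keys and `n`; default the design's
#'   published cells.  Must keep the design's key columns.
#' @param moments Long data frame as returned by [design_moments()] giving
#'   per-cell trait means and SDs.
#' @param trait_cor Exchangeable correlation among the generated traits
#'   (scalar in (-1/k, 1)), or a full positive-definite correlation matrix
#'   with one row per generated trait.
#' @param true_beta,true_gamma True standardized selection gradients over
#'   `selection_traits`.  Either `NULL` (zero), a numeric vector applied to
#'   every cell, a list with components `C` and `HP`, or a function taking a
#'   one-row cell data frame and returning the vector for that cell.
#' @param baseline_fitness Expected seeds per plant for a trait-average
#'   plant: `NULL` to use each cell's published seeds-per-plant mean, or a
#'   single number applied to every cell (the usual choice when injecting
#'   `pl_intensity`).
#' @param pl_intensity Multiplicative seed-set retention for C plants, in
#'   (0, 1]; expected C seed set is `pl_intensity` times the HP expectation,
#'   so the induced pollen-limitation index is `1 - pl_intensity`.
#' @param fitness_noise Size (dispersion) parameter of the negative-binomial
#'   seed count model; smaller is more overdispersed.  The default 2.5 makes
#'   the seeds-per-plant SD comparable to its mean, as in the field data.
#' @param dropout Per-cell probability that a plant dies before fruiting
#'   (recorded with zero fitness components); default 0.
#' @param selection_traits Traits carrying the injected selection surface;
#'   default [trait_spec()] for the design.
#' @param seed Integer RNG seed; the simulation is fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(design = c("two_site_two_year", "nutrient_garden"),
                       cells = NULL, moments = NULL, trait_cor = 0.3,
                       true_beta = NULL, true_gamma = NULL,
                       baseline_fitness = NULL, pl_intensity = 1,
                       fitness_noise = 2.5, dropout = 0,
                       selection_traits = NULL, seed = 1L) {
  design <- match.arg(design)
  if (is.null(cells)) {
    cells <- if (design == "two_site_two_year") .exp1_cells() else .exp2_cells()
  }
  if (is.null(moments)) moments <- design_moments(design)
  if (is.null(selection_traits)) {
    selection_traits <- trait_spec(
      if (design == "two_site_two_year") "exp1" else "exp2")
  }
  if (any(cells$n < 10L)) stop("every cell must have n >= 10")
  if (!(pl_intensity > 0 && pl_intensity <= 1)) {
    stop("pl_intensity must be in (0, 1]")
  }
  if (fitness_noise <= 0) stop("fitness_noise must be positive")
  gen_traits <- setdiff(unique(moments$trait),
                        c("fruit_production", "seeds_per_fruit",
                          "seeds_per_plant"))
  if (is.matrix(trait_cor)) {
    if (nrow(trait_cor) != length(gen_traits) ||
        ncol(trait_cor) != length(gen_traits)) {
      stop("trait_cor matrix must be ", length(gen_traits), " x ",
           length(gen_traits))
    }
    ev <- eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) stop("trait correlation matrix is not positive definite")
  } else {
    k <- length(gen_traits)
    if (trait_cor >= 1 || trait_cor <= -1 / (k - 1)) {
      stop("exchangeable trait_cor of ", trait_cor, " over ", k,
           " traits is not positive definite")
    }
  }
  structure(
    list(design = design, cells = cells, moments = moments,
         trait_cor = trait_cor, true_beta = true_beta,
         true_gamma = true_gamma, baseline_fitness = baseline_fitness,
         pl_intensity = pl_intensity, fitness_noise = fitness_noise,
         dropout = dropout, selection_traits = selection_traits,
         seed = as.integer(seed)),
    class = "sim_config")
}

.cell_gradient <- function(spec, cell, traits) {
  k <- length(traits)
  if (is.null(spec)) return(rep(0, k))
  if (is.function(spec)) spec <- spec(cell)
  if (is.list(spec) && !is.null(names(spec))) spec <- spec[[cell$pollination]]
  if (is.null(spec)) return(rep(0, k))
  if (length(spec) == 1L) spec <- rep(spec, k)
  if (length(spec) != k) {
    stop("gradient vector must have one entry per selection trait (", k, ")")
  }
  as.numeric(spec)
}

.cell_label <- function(cell) {
  keys <- setdiff(names(cell), c("n", "pollination"))
  paste(c(unlist(cell[keys]), cell$pollination), collapse = "_")
}

#' Simulate a pollination experiment from a configuration
#'
#' Draws correlated floral traits cell by cell, computes each plant's
#' expected seed set from the configured selection surface
#' `baseline * (1 + sum(beta_i z_i) + 0.5 * sum(gamma_ii z_i^2))` on
#' within-cell standardized traits (floored at a small positive value and
#' multiplied by `pl_intensity` for C plants), and realizes seeds per plant
#' as a negative-binomial count.  Fruit production is drawn from its cell
#' moments and seeds per fruit set so that
#' `seeds_per_plant = fruit_production * seeds_per_fruit` holds exactly.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_output`: a list with `records` (a
#'   data.frame of plant records) and `truth` (the configuration used).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cells <- config$cells
  keys <- setdiff(names(cells), "n")
  gen_traits <- setdiff(unique(config$moments$trait),
                        c("fruit_production", "seeds_per_fruit",
                          "seeds_per_plant"))
  k <- length(gen_traits)
  R <- if (is.matrix(config$trait_cor)) config$trait_cor else {
    m <- matrix(config$trait_cor, k, k)
    diag(m) <- 1
    m
  }
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, , drop = FALSE]
    n <- cell$n
    mom <- config$moments
    for (key in keys) mom <- mom[mom[[key]] == cell[[key]], , drop = FALSE]
    if (nrow(mom) == 0L) stop("no moments for cell ", .cell_label(cell))
    mu <- setNames(mom$mean, mom$trait)
    sg <- setNames(mom$sd, mom$trait)
    Sigma <- R * (sg[gen_traits] %o% sg[gen_traits])
    traits <- MASS::mvrnorm(n, mu[gen_traits], Sigma)
    if (n == 1L) traits <- matrix(traits, nrow = 1L,
                                  dimnames = list(NULL, gen_traits))
    df <- as.data.frame(traits)
    # integer-valued fields: round, with counts floored at 1 flower
    df$flowering_start <- round(df$flowering_start)
    df$flowering_duration <- pmax(round(df$flowering_duration), 0)
    df$flowering_end <- df$flowering_start + df$flowering_duration
    df$n_flowers <- pmax(round(df$n_flowers), 1)
    for (tr in intersect(c("plant_height", "corolla_size",
                           "corolla_tube_size", "corolla_tube_length"),
                         gen_traits)) {
      df[[tr]] <- pmax(df[[tr]], 0.05)
    }

    sel <- config$selection_traits
    z <- scale(as.matrix(df[sel]))
    beta <- .cell_gradient(config$true_beta, cell, sel)
    gamma <- .cell_gradient(config$true_gamma, cell, sel)
    base <- if (is.null(config$baseline_fitness)) {
      unname(mu["seeds_per_plant"])
    } else {
      config$baseline_fitness
    }
    surface <- 1 + drop(z %*% beta) + 0.5 * drop(z^2 %*% gamma)
    floor_at <- 1e-3
    n_floored <- sum(surface < floor_at)
    if (n_floored > 0.1 * n) {
      warning("expected fitness non-positive for ", n_floored, "/", n,
              " plants in cell ", .cell_label(cell),
              "; selection surface too steep for this trait distribution")
    }
    mu_fit <- base * pmax(surface, floor_at)
    if (cell$pollination == "C") mu_fit <- mu_fit * config$pl_intensity
    seeds <- rnbinom(n, size = config$fitness_noise, mu = mu_fit)

    fruits <- pmax(round(rnorm(n, mu["fruit_production"],
                               sg["fruit_production"])), 0)
    fruits[seeds > 0 & fruits == 0] <- 1
    spf <- ifelse(fruits > 0, seeds / fruits, 0)

    if (config$dropout > 0) {
      dead <- runif(n) < config$dropout
      seeds[dead] <- 0L
      fruits[dead] <- 0L
      spf[dead] <- 0
      df$died <- dead
    }
    rec <- cbind(
      data.frame(plant_id = sprintf("%s_%03d", .cell_label(cell),
                                    seq_len(n)),
                 stringsAsFactors = FALSE),
      cell[rep(1L, n), keys, drop = FALSE],
      df[c(intersect(c("flowering_start", "flowering_end",
                       "flowering_duration"), names(df)),
           setdiff(gen_traits, c("flowering_start", "flowering_end",
                                 "flowering_duration")),
           intersect("died", names(df)))]
    )
    rec$fruit_production <- fruits
    rec$seeds_per_fruit <- spf
    rec$seeds_per_plant <- seeds
    rownames(rec) <- NULL
    out[[i]] <- rec
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  structure(list(records = records, truth = config), class = "sim_output")
}

#' Canned, seeded experiment fixtures
#'
#' @param name One of `"exp1_default"` (the two-site / two-year design at its
#'   published cell sizes and moments), `"exp2_default"` (the
#'   nutrient-addition garden), `"null"` (the two-site design with no
#'   selection, no pollen limitation and a common fitness baseline), or
#'   `"strong_selection"` (directional gradients (0.3, 0.3, 0.4, 0.2, 0, 0)
#'   in C cells and half that in HP cells).
#' @param seed Overrides the fixture's default seed.
#' @param n Optional common per-cell sample size overriding the design's.
#' @param config_only Return the `sim_config` instead of simulating.
#' @return A `sim_output` (or `sim_config` when `config_only = TRUE`).
#' @export
make_fixture <- function(name, seed = NULL, n = NULL, config_only = FALSE) {
  fixtures <- c("exp1_default", "exp2_default", "null", "strong_selection")
  if (!is.character(name) || length(name) != 1L || !name %in% fixtures) {
    stop("unknown fixture; valid names: ", paste(fixtures, collapse = ", "))
  }
  cfg <- switch(name,
    exp1_default = sim_config("two_site_two_year", seed = 101L),
    exp2_default = sim_config("nutrient_garden", seed = 102L),
    null = sim_config("two_site_two_year", baseline_fitness = 60,
                      pl_intensity = 1, seed = 103L),
    strong_selection = sim_config(
      "two_site_two_year",
      true_beta = list(C = c(0.3, 0.3, 0.4, 0.2, 0, 0),
                       HP = c(0.15, 0.15, 0.2, 0.1, 0, 0)),
      baseline_fitness = 100, seed = 104L)
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(n)) cfg$cells$n <- as.integer(n)
  if (config_only) cfg else simulate_experiment(cfg)
}
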