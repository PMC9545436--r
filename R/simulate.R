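#' Configuration for the synthetic landscape generator
#'
#' Defines the study conditions the generator emulates: a spatially
#' autocorrelated multivariate climate surface, populations sampled at grid
#' cells, "adaptive" SNPs whose allele frequencies follow logistic clines in
#' one climate variable, and "neutral" SNPs drawn under Balding-Nichols
#' hierarchical population structure. Defaults are the desk-scale study
#' conditions used throughout the package's validation: 50 populations of 20
#' individuals, 200 adaptive SNPs with cline slopes |b| in [1.5, 3], 2000
#' neutral SNPs at F = 0.1, on a 60 x 60 grid of 800 m cells.
#'
#' @param n_rows,n_cols Grid shape.
#' @param cellsize Cell edge length in metres.
#' @param n_populations Number of sampled populations (grid cells).
#' @param n_individuals Total individuals, distributed as evenly as possible
#'   across populations.
#' @param n_adaptive,n_neutral SNP counts per class.
#' @param b_range Absolute cline-slope range for adaptive SNPs (slope sign is
#'   randomized); `b_range = c(0, 0)` gives degenerate flat clines.
#' @param a_range Cline-intercept range (on the logit scale).
#' @param drivers Candidate driver variables for adaptive SNPs (default: all
#'   20); each adaptive SNP is assigned one, cycling through the set.
#' @param fst Balding-Nichols differentiation parameter F in (0, 1).
#' @param adaptive_structure If `TRUE`, adaptive SNPs additionally receive a
#'   Balding-Nichols population deviation, confounding structure with
#'   adaptation (default off).
#' @param corr_length Climate-field spatial correlation length, in cells.
#' @param trend_weight Fraction (on the variance scale) of each latent climate
#'   field contributed by a smooth planar gradient with random orientation;
#'   the remainder is a Gaussian random field.
#' @param correlation Optional 20 x 20 inter-variable correlation matrix
#'   (canonical variable order). Default: a two-factor
#'   (temperature/moisture) structure with within-group correlation 0.6,
#'   between-factor correlation 0.3, and variable signs from
#'   [climate_variables()].
#' @param seed Master seed; all randomness derives from it in a fixed order.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_rows = 60, n_cols = 60, cellsize = 800,
                              n_populations = 50, n_individuals = 1000,
                              n_adaptive = 200, n_neutral = 2000,
                              b_range = c(1.5, 3), a_range = c(-1, 1),
                              drivers = climate_variable_names(),
                              fst = 0.1, adaptive_structure = FALSE,
                              corr_length = 12, trend_weight = 0.5,
                              correlation = NULL, seed = 1) {
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)", call. = FALSE)
  if (any(!is.finite(b_range)) || length(b_range) != 2) {
    stop("b_range must be two finite values", call. = FALSE)
  }
  if (!all(drivers %in% climate_variable_names())) {
    stop("unknown driver variable", call. = FALSE)
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(dim(correlation), c(20L, 20L)))) {
      stop("correlation must be 20 x 20", call. = FALSE)
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation matrix is not positive semi-definite", call. = FALSE)
    }
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cellsize = cellsize,
         n_populations = n_populations, n_individuals = n_individuals,
         n_adaptive = n_adaptive, n_neutral = n_neutral,
         b_range = sort(abs(b_range)), a_range = a_range, drivers = drivers,
         fst = fst, adaptive_structure = adaptive_structure,
         corr_length = corr_length, trend_weight = trend_weight,
         correlation = correlation, seed = seed),
    class = "simulation_config"
  )
}

# Deterministic per-stage seed derived from the master seed; stays < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483647)
}

# Default inter-variable correlation: two latent factors (temperature,
# moisture) correlated 0.3, loadings sqrt(0.6) with per-variable sign.
default_climate_correlation <- function() {
  cv <- climate_variables()
  L <- matrix(0, 20, 2)
  L[cbind(seq_len(20), ifelse(cv$group == "temperature", 1L, 2L))] <-
    sqrt(0.6) * cv$sign
  Phi <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  C <- L %*% Phi %*% t(L)
  diag(C) <- 1
  dimnames(C) <- list(cv$variable, cv$variable)
  C
}

# One standardized smooth field on an n_rows x n_cols torus: FFT-smoothed
# Gaussian white noise (squared-exponential kernel, correlation length ell in
# cells) blended with a planar trend of random orientation.
smooth_field <- function(n_rows, n_cols, ell, trend_weight) {
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  kern <- exp(-(outer(dr^2, dc^2, `+`)) / (2 * ell^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (n_rows * n_cols)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  theta <- stats::runif(1, 0, 2 * pi)
  tr <- outer(seq_len(n_rows), seq_len(n_cols),
              function(r, c) sin(theta) * r + cos(theta) * c)
  tr <- (tr - mean(tr)) / stats::sd(tr)
  f <- sqrt(trend_weight) * tr + sqrt(1 - trend_weight) * sm
  (f - mean(f)) / stats::sd(f)
}

#' Simulate a multiband climate grid
#'
#' Generates 20 named bands as standardized smooth random fields (FFT-smoothed
#' Gaussian noise plus a planar trend), linearly mixed to the configured
#' inter-variable correlation, then affinely rescaled into the plausible
#' ranges of [climate_variables()] (so e.g. MAT spans at most -7.3 to 10.3
#' degrees C). Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return A [climate_grid()] tibble with all cells masked in.
#' @export
simulate_climate_grid <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, "climate_grid"))
  C <- cfg$correlation %||% default_climate_correlation()
  n_cell <- cfg$n_rows * cfg$n_cols
  E <- vapply(seq_len(20), function(i) {
    as.vector(smooth_field(cfg$n_rows, cfg$n_cols, cfg$corr_length,
                           cfg$trend_weight))
  }, numeric(n_cell))
  # orthonormalize the latent fields (their linear combinations stay smooth),
  # then color, so the realized cross-band correlations equal C exactly
  E <- scale(E, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(E)) * sqrt(n_cell)
  ev <- eigen(C, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Fm <- Q %*% rt
  cv <- climate_variables()
  for (j in seq_len(20)) {
    rng <- range(Fm[, j])
    Fm[, j] <- cv$lo[j] + (Fm[, j] - rng[1]) / diff(rng) * (cv$hi[j] - cv$lo[j])
  }
  colnames(Fm) <- cv$variable
  cells <- tibble::as_tibble(cbind(
    expand.grid(x = (seq_len(cfg$n_cols) - 0.5) * cfg$cellsize,
                y = (rev(seq_len(cfg$n_rows)) - 0.5) * cfg$cellsize)[, c("x", "y")],
    Fm))
  climate_grid(cells, cellsize = cfg$cellsize, crs = "synthetic-equal-area")
}

#' Place sampled populations on a climate grid
#'
#' Draws population centers without replacement from the grid's masked-in
#' cells and assigns individuals to populations as evenly as possible; each
#' individual inherits its cell's climate row.
#'
#' @param cfg A [simulation_config()].
#' @param grid A [climate_grid()].
#' @return A list with `locations` (tibble: population_id, x, y) and `climate`
#'   (per-individual climate tibble with sample_id, population_id).
#' @export
place_samples <- function(cfg, grid) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (nrow(grid) == 0) stop("grid has no masked-in cells", call. = FALSE)
  if (cfg$n_populations > nrow(grid)) {
    stop("more populations than available grid cells", call. = FALSE)
  }
  set.seed(derive_seed(cfg$seed, "place_samples"))
  rows <- sort(sample.int(nrow(grid), cfg$n_populations))
  locs <- tibble::tibble(
    population_id = sprintf("pop_%03d", seq_len(cfg$n_populations)),
    x = grid$x[rows], y = grid$y[rows])
  base <- cfg$n_individuals %/% cfg$n_populations
  extra <- cfg$n_individuals %% cfg$n_populations
  sizes <- rep(base, cfg$n_populations) + (seq_len(cfg$n_populations) <= extra)
  pop_of <- rep(seq_len(cfg$n_populations), sizes)
  climate <- tibble::as_tibble(
    grid[rows[pop_of], climate_variable_names(), drop = FALSE])
  climate <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("ind_%05d", seq_len(cfg$n_individuals)),
                   population_id = locs$population_id[pop_of]),
    climate)
  list(locations = locs, climate = climate)
}

#' Simulate genotypes with known adaptive architecture
#'
#' Adaptive SNP `j`: individual `i` receives dosage `Binomial(2, p_ij)` with
#' `p_ij = plogis(a_j + b_j * z_ij)`, `z` the standardized driver variable.
#' Neutral SNP: ancestral frequency `pi ~ Uniform(0.1, 0.9)`; population
#' frequency `~ Beta(pi (1-F)/F, (1-pi)(1-F)/F)` (Balding-Nichols); dosages
#' `Binomial(2, population frequency)`. Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @param climate Per-individual climate tibble from [place_samples()] (must
#'   have `sample_id`, `population_id` and the 20 variables).
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth` (tibble:
#'   snp_id, class, driver, a, b, ancestral_freq).
#' @export
simulate_genotypes <- function(cfg, climate) {
  stopifnot(inherits(cfg, "simulation_config"))
  check_climate_columns(climate)
  if (!all(c("sample_id", "population_id") %in% names(climate))) {
    stop("climate table must carry sample_id and population_id", call. = FALSE)
  }
  set.seed(derive_seed(cfg$seed, "genotypes"))
  n <- nrow(climate)
  pops <- factor(climate$population_id, levels = unique(climate$population_id))
  n_pop <- nlevels(pops)

  n_a <- cfg$n_adaptive
  n_n <- cfg$n_neutral
  drv <- rep_len(cfg$drivers, max(n_a, 1))[seq_len(n_a)]
  a_j <- stats::runif(n_a, cfg$a_range[1], cfg$a_range[2])
  b_j <- stats::runif(n_a, cfg$b_range[1], cfg$b_range[2]) *
    sample(c(-1, 1), n_a, replace = TRUE)

  dos <- matrix(NA_integer_, n, n_a + n_n)
  if (n_a > 0) {
    Z <- scale(as.matrix(climate[climate_variable_names()]))
    Z[is.nan(Z)] <- 0  # constant predictor across samples
    for (j in seq_len(n_a)) {
      eta <- a_j[j] + b_j[j] * Z[, drv[j]]
      if (cfg$adaptive_structure) {
        pi_j <- stats::plogis(a_j[j])
        qpop <- stats::rbeta(n_pop, pi_j * (1 - cfg$fst) / cfg$fst,
                             (1 - pi_j) * (1 - cfg$fst) / cfg$fst)
        eta <- eta + stats::qlogis(pmin(pmax(qpop[as.integer(pops)], 1e-6),
                                        1 - 1e-6)) - stats::qlogis(pi_j)
      }
      dos[, j] <- stats::rbinom(n, 2, stats::plogis(eta))
    }
  }
  pi_n <- numeric(0)
  if (n_n > 0) {
    pi_n <- stats::runif(n_n, 0.1, 0.9)
    for (j in seq_len(n_n)) {
      qpop <- stats::rbeta(n_pop, pi_n[j] * (1 - cfg$fst) / cfg$fst,
                           (1 - pi_n[j]) * (1 - cfg$fst) / cfg$fst)
      dos[, n_a + j] <- stats::rbinom(n, 2, qpop[as.integer(pops)])
    }
  }
  ids <- c(if (n_a > 0) sprintf("snp_a%04d", seq_len(n_a)),
           if (n_n > 0) sprintf("snp_n%04d", seq_len(n_n)))
  truth <- tibble::tibble(
    snp_id = ids,
    class = rep(c("adaptive", "neutral"), c(n_a, n_n)),
    driver = c(drv, rep(NA_character_, n_n)),
    a = c(a_j, rep(NA_real_, n_n)),
    b = c(b_j, rep(NA_real_, n_n)),
    ancestral_freq = c(rep(NA_real_, n_a), pi_n))
  g <- genotype_matrix(dos, sample_ids = climate$sample_id, snp_ids = ids,
                       population_ids = climate$population_id,
                       set_label = "custom")
  list(genotypes = g, truth = truth)
}

#' Simulate a full synthetic landscape
#'
#' Convenience wrapper chaining [simulate_climate_grid()], [place_samples()]
#' and [simulate_genotypes()].
#'
#' @param cfg A [simulation_config()].
#' @return A list with `grid`, `locations`, `climate`, `genotypes`, `truth`
#'   and the `config` itself.
#' @export
simulate_landscape <- function(cfg = simulation_config()) {
  grid <- simulate_climate_grid(cfg)
  pl <- place_samples(cfg, grid)
  gt <- simulate_genotypes(cfg, pl$climate)
  list(grid = grid, locations = pl$locations, climate = pl$climate,
       genotypes = gt$genotypes, truth = gt$truth, config = cfg)
}
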