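# Per-biome climate/NPP envelopes for the synthetic generator. NPP means for
# the major biomes follow reported global biome means (gC/m2/yr): EBF 1325.7,
# DBF 789.3, ENF 402.4, DNF 275.8, crop 231.3, crop/natural 412.5; the
# remainder are field-plausible choices (see the methods vignette). t_mean /
# t_amp are the annual mean and seasonal semi-amplitude of soil temperature
# (deg C); swc_frac is mean soil water content as a fraction of porosity.
.biome_envelopes <- function() {
  data.frame(
    biome    = c("ENF", "EBF", "DNF", "DBF", "MF", "CSH", "OSH", "WL",
                 "GRA", "CRO", "CRN", "BAR", "TUN"),
    npp_mean = c(402.4, 1325.7, 275.8, 789.3, 600, 350, 150, 500,
                 300, 231.3, 412.5, 30, 80),
    t_mean   = c(2, 25, -4, 12, 8, 15, 18, 10, 10, 12, 12, 20, -8),
    t_amp    = c(12, 3, 18, 10, 12, 8, 10, 10, 12, 10, 10, 12, 14),
    swc_frac = c(0.55, 0.75, 0.50, 0.60, 0.55, 0.45, 0.30, 0.85,
                 0.50, 0.55, 0.55, 0.15, 0.50),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic gridded forcing set
#'
#' Builds a small seeded grid of synthetic model inputs — biome map, soil
#' texture, daily soil temperature and volumetric soil water content for one
#' repeating year, and annual NPP — with per-biome envelopes that emulate
#' the statistical structure of global forcing archives (tropical biomes
#' warm and wet with high NPP, boreal/tundra cold, barren dry and
#' unproductive). All randomness is governed by \code{seed}; identical seed
#' and configuration give bit-identical grids.
#'
#' @param biomes character vector of biome codes to include (must be keys of
#'   the shipped parameter table); every requested biome appears in at least
#'   one cell
#' @param shape integer length-2, grid rows x cols (>= 2x2)
#' @param seed integer RNG seed
#' @param n_days days in the repeating forcing year (default 365)
#' @return object of class \code{synthetic_grid}: list with \code{cells}
#'   (data.frame: cell, row, col, biome, clay, silt, sand, porosity, npp),
#'   matrices \code{t_soil} and \code{swc} (cells x days), \code{seed},
#'   \code{shape}
#' @examples
#' g <- generate_grid(shape = c(4, 4), seed = 1)
#' head(g$cells)
#' @export
generate_grid <- function(biomes = .biome_envelopes()$biome,
                          shape = c(20, 20), seed, n_days = 365) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  seed <- as.integer(seed)
  if (length(shape) != 2L || any(shape < 2))
    stop("shape must be at least 2 x 2", call. = FALSE)
  env <- .biome_envelopes()
  unknown <- setdiff(biomes, env$biome)
  if (length(unknown))
    stop(sprintf("unknown biome code(s): %s; known: %s",
                 paste(unknown, collapse = ", "),
                 paste(env$biome, collapse = ", ")), call. = FALSE)
  n_cells <- prod(shape)
  if (n_cells < length(biomes))
    stop("grid too small to host every requested biome", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # every biome at least once, remainder sampled uniformly
  biome <- c(biomes, sample(biomes, n_cells - length(biomes),
                            replace = TRUE))
  biome <- sample(biome)  # shuffle placements
  idx <- match(biome, env$biome)
  clay <- stats::runif(n_cells, 0.10, 0.35)
  silt <- stats::runif(n_cells, 0.25, 0.50)
  sand <- 1 - clay - silt
  porosity <- stats::runif(n_cells, 0.40, 0.50)
  npp <- env$npp_mean[idx] * exp(stats::rnorm(n_cells, 0, 0.25))
  cells <- data.frame(cell = seq_len(n_cells),
                      row = rep(seq_len(shape[1]), times = shape[2]),
                      col = rep(seq_len(shape[2]), each = shape[1]),
                      biome = biome, clay = clay, silt = silt, sand = sand,
                      porosity = porosity, npp = npp,
                      stringsAsFactors = FALSE)
  day <- seq_len(n_days)
  season <- sin(2 * pi * (day - 91) / n_days)  # peak near midsummer
  t_soil <- matrix(NA_real_, n_cells, n_days)
  swc <- matrix(NA_real_, n_cells, n_days)
  for (i in seq_len(n_cells)) {
    e <- env[idx[i], ]
    t_soil[i, ] <- e$t_mean + e$t_amp * season +
      stats::rnorm(n_days, 0, 1.5)
    # wetter in the cool season, damped noise, clamped into [0, porosity]
    frac <- e$swc_frac * (1 - 0.15 * season) +
      stats::rnorm(n_days, 0, 0.05)
    swc[i, ] <- pmin(pmax(frac, 0.02), 1) * porosity[i]
  }
  structure(list(cells = cells, t_soil = t_soil, swc = swc,
                 seed = seed, shape = shape, n_days = n_days),
            class = "synthetic_grid")
}

#' @export
print.synthetic_grid <- function(x, ...) {
  cat(sprintf("<synthetic_grid %dx%d cells, %d forcing days, seed %d>\n",
              x$shape[1], x$shape[2], x$n_days, x$seed))
  print(table(x$cells$biome))
  invisible(x)
}

# save/restore the global RNG state so generators don't perturb user code
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Construct a transfer system from raw matrices
#'
#' Low-level constructor for hand-built (possibly fewer-than-13-pool)
#' systems, used by the toy fixtures and test oracles. Validates the sign
#' pattern and column sums.
#'
#' @param A transfer matrix (+1 diagonal, non-positive off-diagonal,
#'   routed column fractions <= 1)
#' @param c_rates vector of positive potential turnover rates
#' @param B allocation vector (non-negative, sums to 1)
#' @param names optional pool names
#' @return object of class \code{transfer_system}
#' @export
as_transfer_system <- function(A, c_rates, B, names = NULL) {
  n <- length(c_rates)
  stopifnot(nrow(A) == n, ncol(A) == n, length(B) == n)
  if (any(abs(diag(A) - 1) > 1e-12))
    stop("A must have unit diagonal", call. = FALSE)
  off <- A - diag(diag(A))
  if (any(off > 1e-12))
    stop("off-diagonal entries of A must be <= 0", call. = FALSE)
  if (any(1 - colSums(A) > 1 + 1e-12))
    stop("routed fractions exceed 1 in some column", call. = FALSE)
  if (any(c_rates <= 0)) stop("turnover rates must be > 0", call. = FALSE)
  if (abs(sum(B) - 1) > 1e-9) stop("B must sum to 1", call. = FALSE)
  if (is.null(names)) names <- paste0("pool_", seq_len(n))
  dimnames(A) <- list(names, names)
  layout <- list(names = names, n = n)
  structure(list(A = A, C = diag(c_rates, n), B = stats::setNames(B, names),
                 layout = layout, biome = "fixture",
                 respired = colSums(A)),
            class = "transfer_system")
}

#' Toy fixture systems with closed-form expectations
#'
#' Registry of small hand-analysable systems used throughout the test
#' suite: \code{"one_pool"} (residence time 1/c), \code{"chain_2"} and
#' \code{"chain_3"} (cascades with residence time the sum of reciprocal
#' rates), and \code{"full_13_default"} (the shipped EBF parameterisation
#' with its reported-scale scalars).
#'
#' @param name fixture identifier
#' @return list with \code{sys} (a \code{transfer_system}), \code{xi}
#'   (diagonal scalar matrix), \code{U} (influx) and, where closed forms
#'   exist, \code{tau_expected}
#' @export
fixture_system <- function(name = c("one_pool", "chain_2", "chain_3",
                                    "full_13_default")) {
  registry <- c("one_pool", "chain_2", "chain_3", "full_13_default")
  if (!is.character(name) || !name[1] %in% registry)
    stop(sprintf("unknown fixture '%s'; registry: %s",
                 as.character(name)[1], paste(registry, collapse = ", ")),
         call. = FALSE)
  name <- match.arg(name)
  switch(name,
    one_pool = {
      c1 <- 0.5
      list(sys = as_transfer_system(matrix(1), c1, 1, "pool"),
           xi = diag(1), U = 10, tau_expected = 1 / c1)
    },
    chain_2 = {
      cr <- c(0.8, 0.25)
      A <- diag(2); A[2, 1] <- -1
      list(sys = as_transfer_system(A, cr, c(1, 0), c("veg", "litter")),
           xi = diag(2), U = 5, tau_expected = sum(1 / cr))
    },
    chain_3 = {
      cr <- c(1.0, 0.4, 0.05)
      A <- diag(3); A[2, 1] <- -1; A[3, 2] <- -0.6
      list(sys = as_transfer_system(A, cr, c(1, 0, 0),
                                    c("veg", "litter", "soil")),
           xi = diag(3), U = 2,
           tau_expected = 1 / cr[1] + 1 / cr[2] + 0.6 / cr[3])
    },
    full_13_default = {
      params <- default_parameter_table()[["EBF"]]
      sys <- transfer_system(params, default_soil_texture())
      list(sys = sys,
           xi = environmental_scalar_matrix(0.69, 0.53),
           U = 1325.7, tau_expected = NULL)
    })
}

#' Random valid 13-pool system (test harness)
#'
#' Draws a random biome parameterisation, soil texture and litter/soil
#' environmental scalar, producing a valid 13-pool system for randomized
#' property and oracle-equivalence tests. Turnover rates are drawn
#' log-uniformly in [0.05, 15] / yr and the litter/soil scalar uniformly in
#' [0.3, 1], so the slowest effective rate stays above 0.015 / yr and a
#' 1000-year spin-up integration is within numerical convergence of the
#' analytic equilibrium.
#'
#' @param seed integer RNG seed
#' @return list with \code{sys}, \code{xi}, \code{U}
#' @export
random_system <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b <- stats::runif(4); b <- b / sum(b)
  cr <- exp(stats::runif(13, log(0.05), log(15)))
  params <- biome_params("random", b = b,
                         LN = stats::runif(1, 5, 40),
                         Lleaf = stats::runif(1, 0.05, 0.4),
                         Lfroot = stats::runif(1, 0.05, 0.4),
                         Lwood = stats::runif(1, 0.1, 0.5),
                         c = cr)
  texture <- soil_texture(clay = stats::runif(1, 0.05, 0.4),
                          silt = stats::runif(1, 0.2, 0.5),
                          porosity = stats::runif(1, 0.35, 0.55))
  s <- stats::runif(1, 0.3, 1)
  xi <- environmental_scalar_matrix(sqrt(s), sqrt(s))
  list(sys = transfer_system(params, texture), xi = xi,
       U = stats::runif(1, 50, 1500))
}
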