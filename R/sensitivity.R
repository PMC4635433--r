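# Apply a relative perturbation to one named parameter of a
# (biome_params, soil_texture) pair, re-clamping to the valid domain.
# Texture perturbations absorb the complement into the sand fraction.
.perturb <- function(params, texture, param, factor) {
  p <- params
  tx <- texture
  clamp01 <- function(v, eps = 1e-6) pmin(pmax(v, eps), 1 - eps)
  if (param %in% c("LN")) {
    p$LN <- p$LN * factor
  } else if (param %in% c("Lleaf", "Lfroot", "Lwood")) {
    p[[param]] <- clamp01(p[[param]] * factor)
  } else if (param %in% c("clay", "silt")) {
    v <- clamp01(tx[[param]] * factor)
    other <- if (param == "clay") tx$silt else tx$clay
    sand <- 1 - v - other
    if (sand < 0) stop(sprintf(
      "perturbing '%s' by factor %.3f leaves no sand fraction",
      param, factor), call. = FALSE)
    tx <- soil_texture(clay = if (param == "clay") v else tx$clay,
                       silt = if (param == "silt") v else tx$silt,
                       porosity = tx$porosity)
  } else if (param == "porosity") {
    tx <- soil_texture(tx$clay, tx$silt, porosity = clamp01(tx$porosity *
                                                              factor))
  } else if (grepl("^c_\\d+$", param)) {
    k <- as.integer(sub("^c_", "", param))
    p$c[k] <- p$c[k] * factor
  } else if (param %in% c("b_leaf", "b_wood", "b_froot", "b_croot")) {
    k <- match(param, c("b_leaf", "b_wood", "b_froot", "b_croot"))
    b <- p$b
    b[k] <- b[k] * factor
    p$b <- b / sum(b)  # renormalise the allocation simplex
  } else {
    stop(sprintf("unknown parameter '%s'", param), call. = FALSE)
  }
  list(params = p, texture = tx)
}

#' Relative (elasticity-style) sensitivity index
#'
#' Symmetric central-difference relative sensitivity of a model output to
#' one parameter:
#' \deqn{S = \frac{[O(p(1+\delta)) - O(p(1-\delta))] / O(p)}{2\delta}}
#' the relative change in output per relative change in parameter. A
#' parameter is classified sensitive when |S| > 0.2.
#'
#' @param model_fn function taking (\code{biome_params},
#'   \code{soil_texture}) and returning a scalar output (default: baseline
#'   residence time)
#' @param param parameter name: one of \code{LN}, \code{Lleaf},
#'   \code{Lfroot}, \code{Lwood}, \code{clay}, \code{silt},
#'   \code{porosity}, \code{b_leaf}/\code{b_wood}/\code{b_froot}/
#'   \code{b_croot} (renormalised on the simplex), or \code{c_1}..\code{c_13}
#' @param base a \code{\link{biome_params}}
#' @param texture a \code{\link{soil_texture}}
#' @param delta relative perturbation (default 0.10)
#' @return object of class \code{sensitivity_result}: list with
#'   \code{parameter}, \code{S}, \code{perturbation}, \code{sensitive}
#' @export
sensitivity_index <- function(model_fn = function(p, tx)
                                baseline_residence_time(
                                  transfer_system(p, tx))$tau,
                              param, base, texture = default_soil_texture(),
                              delta = 0.10) {
  stopifnot(delta > 0, inherits(base, "biome_params"))
  O0 <- model_fn(base, texture)
  if (!is.finite(O0) || O0 == 0)
    stop("model output at the base point is 0; relative sensitivity undefined",
         call. = FALSE)
  up <- .perturb(base, texture, param, 1 + delta)
  dn <- .perturb(base, texture, param, 1 - delta)
  S <- as.numeric(((model_fn(up$params, up$texture) -
                    model_fn(dn$params, dn$texture)) / O0) / (2 * delta))
  structure(list(parameter = param, S = S, perturbation = delta,
                 sensitive = abs(S) > 0.2),
            class = "sensitivity_result")
}

#' Sensitivity screen across biomes and parameters
#'
#' Full cross of biomes and parameters for a given output (default baseline
#' residence time), with |S| ranking within each biome and the |S| > 0.2
#' sensitivity classification.
#'
#' @param biomes biome codes (default: all in the shipped table)
#' @param parameters parameter names (default L/N, the three lignin
#'   contents and the clay/silt texture fractions)
#' @param delta relative perturbation (default 0.10)
#' @param params parameter table (named list of \code{\link{biome_params}})
#' @param texture a \code{\link{soil_texture}} held common across biomes
#' @param model_fn output functional, as in \code{\link{sensitivity_index}}
#' @return data.frame with columns biome, parameter, S, abs_S, sensitive,
#'   rank (1 = largest |S| within the biome)
#' @export
sensitivity_screen <- function(biomes = NULL,
                               parameters = c("LN", "Lleaf", "Lfroot",
                                              "Lwood", "clay", "silt"),
                               delta = 0.10,
                               params = default_parameter_table(),
                               texture = default_soil_texture(),
                               model_fn = function(p, tx)
                                 baseline_residence_time(
                                   transfer_system(p, tx))$tau) {
  if (is.null(biomes)) biomes <- names(params)
  missing <- setdiff(biomes, names(params))
  if (length(missing))
    stop(sprintf("no parameters for biome(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  rows <- list()
  for (b in biomes) {
    S <- vapply(parameters, function(pp)
      sensitivity_index(model_fn, pp, params[[b]], texture, delta)$S,
      numeric(1))
    rows[[b]] <- data.frame(biome = b, parameter = parameters, S = S,
                            abs_S = abs(S), sensitive = abs(S) > 0.2,
                            rank = rank(-abs(S), ties.method = "first"),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
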