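#' Pool layout of the 13-pool carbon cycle model
#'
#' The model tracks carbon in 13 pools: 4 vegetation pools (leaf, woody,
#' fine root, coarse root), 5 litter pools (surface metabolic, surface
#' structural, soil metabolic, soil structural, coarse detritus) and 4 soil
#' organic matter pools (surface microbe, soil microbe, slow, passive).
#' Vegetation pools occupy indices 1--4 so that the environmental-scalar
#' diagonal pattern (1, 1, 1, 1, xi_5, ..., xi_13) is well formed: climate
#' limits decomposition of litter and soil carbon only.
#'
#' @return An object of class \code{pool_layout}: a list with \code{names}
#'   (ordered pool identifiers), \code{class_of} (named character vector
#'   mapping each pool to \code{"vegetation"}, \code{"litter"} or
#'   \code{"soil"}) and \code{n} (always 13).
#' @examples
#' lay <- pool_layout()
#' table(lay$class_of)
#' @export
pool_layout <- function() {
  names <- c("leaf", "woody", "froot", "croot",
             "surface_metabolic", "surface_structural",
             "soil_metabolic", "soil_structural", "coarse_detritus",
             "surface_microbe", "soil_microbe", "slow", "passive")
  class_of <- c(rep("vegetation", 4L), rep("litter", 5L), rep("soil", 4L))
  names(class_of) <- names
  structure(list(names = names, class_of = class_of, n = 13L),
            class = "pool_layout")
}

#' Indices of pools by class
#'
#' @param layout a \code{pool_layout}
#' @param class one of "vegetation", "litter", "soil"
#' @return integer indices into the pool ordering
#' @export
pool_indices <- function(layout = pool_layout(),
                         class = c("vegetation", "litter", "soil")) {
  class <- match.arg(class)
  which(unname(layout$class_of) == class)
}

#' Per-biome parameter set
#'
#' Bundles the biome-level parameters that determine the baseline (climate
#' free) carbon residence time: NPP allocation fractions to the four
#' vegetation pools, the litter lignin:nitrogen ratio controlling the
#' metabolic/structural split of fresh litter, lignin mass fractions of leaf,
#' fine-root and woody tissue (which set the structural-litter routing into
#' microbial versus slow soil carbon), and the 13 potential turnover rates.
#'
#' @param biome biome identifier (IGBP-style code, e.g. "EBF")
#' @param b numeric length-4 allocation fractions in pool order
#'   (leaf, woody, froot, croot); must be non-negative and sum to 1
#' @param LN litter lignin:nitrogen ratio (dimensionless, > 0)
#' @param Lleaf,Lfroot,Lwood lignin mass fractions in (0, 1)
#' @param c numeric length-13 potential turnover rates (1/yr), in pool order
#' @param forest logical; whether the biome is a forest class (used only for
#'   reporting/grouping)
#' @return an object of class \code{biome_params}
#' @export
biome_params <- function(biome, b, LN, Lleaf, Lfroot, Lwood, c,
                         forest = NA) {
  if (length(b) != 4L || any(!is.finite(b)) || any(b < 0))
    stop("allocation fractions 'b' must be 4 finite non-negative numbers",
         call. = FALSE)
  if (abs(sum(b) - 1) > 1e-9)
    stop(sprintf("allocation fractions for biome '%s' sum to %.10f, not 1",
                 biome, sum(b)), call. = FALSE)
  if (!is.finite(LN) || LN <= 0)
    stop("lignin:nitrogen ratio 'LN' must be positive", call. = FALSE)
  for (nm in c("Lleaf", "Lfroot", "Lwood")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop(sprintf("lignin fraction '%s' must lie in (0, 1)", nm),
           call. = FALSE)
  }
  if (length(c) != 13L || any(!is.finite(c)) || any(c <= 0))
    stop("potential turnover rates 'c' must be 13 positive numbers",
         call. = FALSE)
  lay <- pool_layout()
  names(b) <- lay$names[1:4]
  names(c) <- lay$names
  structure(list(biome = as.character(biome), b = b, LN = LN,
                 Lleaf = Lleaf, Lfroot = Lfroot, Lwood = Lwood,
                 c = c, forest = forest),
            class = "biome_params")
}

#' @export
print.biome_params <- function(x, ...) {
  cat(sprintf("<biome_params '%s'%s>\n", x$biome,
              if (isTRUE(x$forest)) " (forest)" else ""))
  cat(" allocation:", paste(sprintf("%s=%.2f", names(x$b), x$b),
                            collapse = " "), "\n")
  cat(sprintf(" L/N=%.1f  Lleaf=%.2f Lfroot=%.2f Lwood=%.2f\n",
              x$LN, x$Lleaf, x$Lfroot, x$Lwood))
  cat(" turnover (1/yr):", paste(signif(x$c, 3), collapse = " "), "\n")
  invisible(x)
}

#' Soil texture descriptor
#'
#' Clay/silt/sand mass fractions plus total porosity. Texture enters the
#' transfer matrix through the clay and clay+silt modifiers of soil-pool
#' routing, and porosity normalises volumetric soil water content for the
#' moisture scalar.
#'
#' @param clay,silt,sand mass fractions summing to 1 (tolerance 1e-6)
#' @param porosity total soil porosity, in (0, 1)
#' @return an object of class \code{soil_texture}
#' @export
soil_texture <- function(clay, silt, sand = 1 - clay - silt,
                         porosity = 0.45) {
  v <- c(clay = clay, silt = silt, sand = sand)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("clay, silt and sand must be fractions in [0, 1]", call. = FALSE)
  if (abs(sum(v) - 1) > 1e-6)
    stop(sprintf("clay + silt + sand = %.8f, must equal 1", sum(v)),
         call. = FALSE)
  if (!is.finite(porosity) || porosity <= 0 || porosity >= 1)
    stop("porosity must lie in (0, 1)", call. = FALSE)
  structure(list(clay = clay, silt = silt, sand = sand,
                 porosity = porosity),
            class = "soil_texture")
}
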