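#' Metabolic fraction of fresh litter
#'
#' Fresh leaf and fine-root litter is partitioned between a fast metabolic
#' pool and a slow structural pool according to the lignin:nitrogen ratio of
#' the residue, using the classic CENTURY linear form
#' \deqn{f_{met} = 0.85 - 0.018 \, (L/N)}
#' clamped to [0, 1]. Higher L/N (more recalcitrant residue) routes less
#' carbon through the metabolic pathway.
#'
#' @param LN lignin:nitrogen ratio (> 0); vectorised
#' @return metabolic fraction(s) in [0, 1], non-increasing in \code{LN}
#' @examples
#' metabolic_fraction(20)   # 0.85 - 0.018 * 20 = 0.49
#' @export
metabolic_fraction <- function(LN) {
  if (any(!is.finite(LN)) || any(LN <= 0))
    stop("lignin:nitrogen ratio must be positive and finite", call. = FALSE)
  pmin(pmax(0.85 - 0.018 * LN, 0), 1)
}

#' NPP allocation vector
#'
#' Expands the four vegetation allocation fractions into the 13-vector
#' B = (b_leaf, b_wood, b_froot, b_croot, 0, ..., 0): carbon influx (NPP)
#' enters the system through the vegetation pools only.
#'
#' @param params a \code{\link{biome_params}}
#' @param layout a \code{\link{pool_layout}}
#' @return numeric length-13 vector summing to 1, entries 5--13 zero
#' @export
build_allocation_vector <- function(params, layout = pool_layout()) {
  stopifnot(inherits(params, "biome_params"))
  B <- numeric(layout$n)
  B[1:4] <- params$b
  names(B) <- layout$names
  B
}

#' Potential turnover matrix C
#'
#' Diagonal 13x13 matrix of potential (climate-unlimited) turnover rates in
#' 1/yr. The reciprocal of each diagonal entry is the pool's intrinsic
#' residence time.
#'
#' @inheritParams build_allocation_vector
#' @return 13x13 diagonal matrix with \code{params$c} on the diagonal
#' @export
build_turnover_matrix <- function(params, layout = pool_layout()) {
  stopifnot(inherits(params, "biome_params"))
  if (any(params$c <= 0))
    stop("all potential turnover rates must be positive", call. = FALSE)
  C <- diag(params$c, nrow = layout$n)
  dimnames(C) <- list(layout$names, layout$names)
  C
}

# Fixed CENTURY-lineage routing constants. Respiration is the unrouted
# remainder of each donor column; fractions below are of the *exiting* flux.
.routing <- list(
  met_to_microbe    = 0.45,  # metabolic litter -> microbial pool
  struct_nonlig     = 0.55,  # non-lignin structural (surface) -> surface microbe
  struct_nonlig_soil = 0.45, # non-lignin structural (soil) -> soil microbe
  struct_lig        = 0.70,  # lignin structural -> slow pool
  surf_microbe_slow = 0.40,  # surface microbe -> slow
  passive_to_microbe = 0.45  # passive -> soil microbe
)

#' Carbon transfer matrix A
#'
#' Assembles the 13x13 transfer matrix with +1 on the diagonal and negative
#' off-diagonal entries \code{-f_ij}, where \code{f_ij} is the fraction of
#' carbon exiting pool j that enters pool i; the remainder of each column,
#' \code{1 - sum(f_ij)}, is respired as CO2. Routing follows the
#' CENTURY-lineage topology:
#' \itemize{
#'   \item leaf -> surface metabolic / surface structural, split by
#'     \code{\link{metabolic_fraction}(LN)}; fine root -> soil metabolic /
#'     soil structural with the same split;
#'   \item woody and coarse root -> coarse detritus (whole exiting flux);
#'   \item structural litter splits into a lignin share (to the slow pool)
#'     and a non-lignin share (to the microbial pool) set by the tissue
#'     lignin fractions;
#'   \item soil microbe routing to slow and passive carries the clay and
#'     clay+silt texture modifiers (respired fraction
#'     \code{0.85 - 0.68 (clay + silt)}; stabilised-to-passive fraction
#'     \code{0.003 + 0.032 clay});
#'   \item the passive pool receives from microbe and slow pools and
#'     transfers back minimally.
#' }
#'
#' A is independent of climate; all forcing dependence is carried by the
#' environmental scalar matrix.
#'
#' @param params a \code{\link{biome_params}}
#' @param texture a \code{\link{soil_texture}}
#' @param layout a \code{\link{pool_layout}}
#' @return 13x13 transfer matrix satisfying the column-sum and sign
#'   invariants (checked; violations raise an error naming the column)
#' @export
build_transfer_matrix <- function(params, texture, layout = pool_layout()) {
  stopifnot(inherits(params, "biome_params"), inherits(texture, "soil_texture"))
  n <- layout$n
  A <- diag(1, n)
  dimnames(A) <- list(layout$names, layout$names)
  r <- .routing
  fmet <- metabolic_fraction(params$LN)
  route <- function(from, to, frac) A[to, from] <<- A[to, from] - frac

  # vegetation -> litter: whole exiting flux becomes litter (no respiration
  # at litterfall)
  route("leaf", "surface_metabolic", fmet)
  route("leaf", "surface_structural", 1 - fmet)
  route("froot", "soil_metabolic", fmet)
  route("froot", "soil_structural", 1 - fmet)
  route("woody", "coarse_detritus", 1)
  route("croot", "coarse_detritus", 1)

  # litter -> soil
  route("surface_metabolic", "surface_microbe", r$met_to_microbe)
  route("soil_metabolic", "soil_microbe", r$met_to_microbe)
  route("surface_structural", "surface_microbe",
        (1 - params$Lleaf) * r$struct_nonlig)
  route("surface_structural", "slow", params$Lleaf * r$struct_lig)
  route("soil_structural", "soil_microbe",
        (1 - params$Lfroot) * r$struct_nonlig_soil)
  route("soil_structural", "slow", params$Lfroot * r$struct_lig)
  route("coarse_detritus", "soil_microbe",
        (1 - params$Lwood) * r$struct_nonlig_soil)
  route("coarse_detritus", "slow", params$Lwood * r$struct_lig)

  # soil -> soil, texture-modified
  clay <- texture$clay
  clay_silt <- texture$clay + texture$silt
  route("surface_microbe", "slow", r$surf_microbe_slow)
  resp_active <- 0.85 - 0.68 * clay_silt       # f(clay_silt)
  to_passive_a <- 0.003 + 0.032 * clay         # f(clay)
  route("soil_microbe", "passive", to_passive_a)
  route("soil_microbe", "slow", (1 - resp_active) - to_passive_a)
  to_passive_s <- 0.003 + 0.009 * clay
  route("slow", "passive", to_passive_s)
  route("slow", "soil_microbe", 0.45 - to_passive_s)
  route("passive", "soil_microbe", r$passive_to_microbe)

  routed <- 1 - colSums(A)  # colSums(A) = 1 - sum of routed fractions
  bad <- which(routed > 1 + 1e-12)
  if (length(bad))
    stop(sprintf("transfer fractions out of column '%s' sum to %.6f > 1",
                 layout$names[bad[1]], routed[bad[1]]), call. = FALSE)
  A
}

#' Assemble the (A, C, B) transfer system for one biome / grid cell
#'
#' @inheritParams build_transfer_matrix
#' @return object of class \code{transfer_system}: list with matrices
#'   \code{A}, \code{C}, vector \code{B}, the \code{layout}, and the donor
#'   respired fractions \code{respired} (per column, \code{1 - sum|a_ij|})
#' @export
transfer_system <- function(params, texture, layout = pool_layout()) {
  A <- build_transfer_matrix(params, texture, layout)
  C <- build_turnover_matrix(params, layout)
  B <- build_allocation_vector(params, layout)
  routed <- 1 - colSums(A)  # fraction of each exiting flux routed onward
  respired <- 1 - routed    # remainder leaves the system as CO2
  structure(list(A = A, C = C, B = B, layout = layout,
                 biome = params$biome, respired = respired),
            class = "transfer_system")
}

#' @export
print.transfer_system <- function(x, ...) {
  cat(sprintf("<transfer_system biome='%s' 13 pools>\n", x$biome))
  cat(" allocation B:", paste(signif(x$B[1:4], 3), collapse = " "), "\n")
  cat(" turnover diag(C):", paste(signif(diag(x$C), 3), collapse = " "), "\n")
  invisible(x)
}
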