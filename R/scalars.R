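#' Lloyd-Taylor temperature scalar
#'
#' Soil-temperature limitation on decomposition following the Lloyd-Taylor
#' respiration equation
#' \deqn{R(T) \propto \exp\!\left[E_0\left(\frac{1}{T_{ref}-T_0} -
#'   \frac{1}{T-T_0}\right)\right]}
#' with temperatures in Kelvin, normalised to equal 1 at the reference
#' temperature and clamped to [0, 1]. The published constants
#' E0 = 308.56 K and T0 = 227.13 K are the defaults; the equation has a
#' singularity at T = T0 (about -46 C), below which the scalar is 0.
#'
#' @param t_soil soil temperature in degrees C (vectorised)
#' @param E0 activation-energy-like parameter (K)
#' @param T0 singularity temperature (K)
#' @param t_ref reference temperature in degrees C at which the scalar is 1
#' @return temperature scalar(s) in [0, 1], non-decreasing in \code{t_soil}
#' @examples
#' lloyd_taylor_scalar(10)  # 1 at the 10 C reference
#' lloyd_taylor_scalar(5)
#' @export
lloyd_taylor_scalar <- function(t_soil, E0 = 308.56, T0 = 227.13,
                                t_ref = 10) {
  TK <- t_soil + 273.15
  Tr <- t_ref + 273.15
  out <- numeric(length(TK))
  bad <- TK <= T0
  if (any(bad)) {
    warning(sprintf("%d soil temperature(s) at or below the Lloyd-Taylor %s",
                    sum(bad), sprintf("singularity (%.2f C); scalar set to 0",
                                      T0 - 273.15)), call. = FALSE)
    out[bad] <- 0
  }
  ok <- !bad
  out[ok] <- exp(E0 * (1 / (Tr - T0) - 1 / (TK[ok] - T0)))
  pmin(pmax(out, 0), 1)
}

#' Q10 temperature scalar
#'
#' The standard Q10 respiration temperature response
#' \deqn{\xi_t = Q_{10}^{(T_{soil}-T_{ref})/10}} clamped to [0, 1]; equals 1
#' at the reference temperature.
#'
#' @param t_soil soil temperature in degrees C (vectorised)
#' @param Q10 temperature sensitivity (> 1), default 2
#' @param t_ref reference temperature in degrees C
#' @return temperature scalar(s) in [0, 1]
#' @examples
#' q10_scalar(0, Q10 = 2, t_ref = 10)  # one decade below reference: 0.5
#' @export
q10_scalar <- function(t_soil, Q10 = 2, t_ref = 10) {
  if (!is.finite(Q10) || Q10 <= 1)
    stop("Q10 must be a finite value greater than 1", call. = FALSE)
  pmin(pmax(Q10^((t_soil - t_ref) / 10), 0), 1)
}

#' Piecewise ("subsection") moisture scalar on relative soil water content
#'
#' Moisture limitation as a function of soil water content expressed as a
#' fraction of porosity, k = swc / porosity. The response is piecewise
#' linear and unimodal: it rises from a predefined lower limit of 0.25 at
#' k = 0 to 1 at the optimum k, then declines toward saturation (anoxia
#' limitation) without falling below the floor. This is the scheme used by
#' diagnostic models that normalise soil water by texture-derived porosity.
#'
#' @param swc volumetric soil water content (vectorised)
#' @param porosity total soil porosity (> 0)
#' @param floor lower limit of the scalar (default 0.25)
#' @param k_opt relative water content at which the scalar peaks (default 0.75)
#' @param wet_value scalar value at full saturation, >= \code{floor}
#'   (default 0.5)
#' @return moisture scalar(s) in [\code{floor}, 1]
#' @examples
#' beps_moisture_scalar(0, 0.45)      # dry floor: 0.25
#' beps_moisture_scalar(0.3375, 0.45) # optimum k = 0.75: 1
#' @export
beps_moisture_scalar <- function(swc, porosity, floor = 0.25,
                                 k_opt = 0.75, wet_value = 0.5) {
  if (any(!is.finite(porosity)) || any(porosity <= 0))
    stop("porosity must be positive", call. = FALSE)
  if (wet_value < floor)
    stop("wet_value must not fall below the floor", call. = FALSE)
  k <- swc / porosity
  if (any(k > 1 + 1e-12) || any(k < -1e-12)) {
    warning("soil water content outside [0, porosity]; clamping",
            call. = FALSE)
    k <- pmin(pmax(k, 0), 1)
  }
  dry <- floor + (1 - floor) * k / k_opt
  wet <- 1 - (1 - wet_value) * (k - k_opt) / (1 - k_opt)
  ifelse(k <= k_opt, dry, wet)
}

#' Parabolic moisture scalar on saturation fraction
#'
#' Moisture limitation as a single smooth function of soil water content
#' expressed as a fraction of the saturated condition, used over the whole
#' moisture range (no piecewise sections). The parabola peaks at 1 at an
#' optimum saturation fraction and declines toward both the dry and the
#' saturated ends, capturing the inhibition of microbial activity under both
#' drought and over-hydration.
#'
#' @param theta_frac soil water content as a fraction of saturation
#'   (vectorised)
#' @param theta_opt optimum saturation fraction (default 0.6)
#' @param width shape parameter: half-width at which the parabola would
#'   reach 0 (default 1.2, keeping the absolute slope below 1 over the
#'   admissible range)
#' @return moisture scalar(s) in [0, 1]
#' @examples
#' cable_moisture_scalar(0.6)  # 1 at the optimum
#' cable_moisture_scalar(0)    # 0.75 at the dry end
#' @export
cable_moisture_scalar <- function(theta_frac, theta_opt = 0.6, width = 1.2) {
  if (any(theta_frac < -1e-12) || any(theta_frac > 1 + 1e-12)) {
    warning("saturation fraction outside [0, 1]; clamping", call. = FALSE)
    theta_frac <- pmin(pmax(theta_frac, 0), 1)
  }
  pmin(pmax(1 - ((theta_frac - theta_opt) / width)^2, 0), 1)
}

#' Linear moisture scalar (LPJ form)
#'
#' The published LPJ-DGVM moisture response: 0.25 + 0.75 * W1 where W1 is
#' the upper-layer soil water content fraction.
#'
#' @param W1 upper-layer soil water content fraction (vectorised)
#' @return moisture scalar(s) in [0.25, 1]
#' @export
lpj_moisture_scalar <- function(W1) {
  if (any(W1 < -1e-12) || any(W1 > 1 + 1e-12)) {
    warning("W1 outside [0, 1]; clamping", call. = FALSE)
    W1 <- pmin(pmax(W1, 0), 1)
  }
  0.25 + 0.75 * W1
}

# Reconstructed forms for schemes whose equations are not published here;
# shapes follow each model family's documented behaviour (see the methods
# vignette). All are flagged reconstructed in the registry.
.casa_moisture <- function(p) pmin(pmax(0.1 + 0.9 * pmin(p, 1), 0), 1)
.orchidee_moisture <- function(theta) pmin(pmax(0.25 + 0.75 * theta, 0), 1)
.century_moisture <- function(x) pmin(pmax(1 / (1 + 30 * exp(-8.5 * x)), 0), 1)
.century_temperature <- function(t_soil)
  pmin(pmax(0.56 + (1.46 * atan(pi * 0.0309 * (t_soil - 15.7))) / pi, 0), 1)

#' Registry of environmental scalar schemes
#'
#' Named registry of the temperature/moisture scalar scheme pairs used by
#' major terrestrial biosphere models. Each entry carries the temperature
#' function, the moisture function, the moisture variable the scheme
#' consumes, and whether the formula is published here (\code{"printed"}) or
#' reconstructed from the model family's cited sources
#' (\code{"reconstructed"}).
#'
#' Moisture variables: \code{"k"} soil water content as a fraction of
#' porosity; \code{"theta1"} fraction of saturation; \code{"theta"} soil
#' water content used directly; \code{"p"} water budget (precipitation +
#' soil water) / potential evapotranspiration; \code{"W1"} upper-layer soil
#' water fraction; \code{"x"} precipitation / potential evapotranspiration.
#'
#' @param name optional scheme name; if missing, the full registry is
#'   returned
#' @return a single scheme (list with \code{name}, \code{temperature_fn},
#'   \code{moisture_fn}, \code{moisture_variable}, \code{provenance}) or the
#'   named list of all schemes
#' @examples
#' names(scalar_scheme_registry())
#' scalar_scheme_registry("beps")$moisture_variable
#' @export
scalar_scheme_registry <- function(name) {
  reg <- list(
    beps = list(temperature_fn = lloyd_taylor_scalar,
                moisture_fn = function(k) beps_moisture_scalar(k, 1),
                moisture_variable = "k", provenance = "printed"),
    cable = list(temperature_fn = q10_scalar,
                 moisture_fn = cable_moisture_scalar,
                 moisture_variable = "theta1", provenance = "printed"),
    casa = list(temperature_fn = q10_scalar,
                moisture_fn = .casa_moisture,
                moisture_variable = "p", provenance = "reconstructed"),
    intec = list(temperature_fn = lloyd_taylor_scalar,
                 moisture_fn = function(k) beps_moisture_scalar(k, 1),
                 moisture_variable = "k", provenance = "reconstructed"),
    ibis = list(temperature_fn = lloyd_taylor_scalar,
                moisture_fn = function(theta)
                  beps_moisture_scalar(theta, 1),
                moisture_variable = "theta", provenance = "reconstructed"),
    lpj = list(temperature_fn = lloyd_taylor_scalar,
               moisture_fn = lpj_moisture_scalar,
               moisture_variable = "W1", provenance = "printed"),
    orchidee = list(temperature_fn = q10_scalar,
                    moisture_fn = .orchidee_moisture,
                    moisture_variable = "theta",
                    provenance = "reconstructed"),
    dlem = list(temperature_fn = lloyd_taylor_scalar,
                moisture_fn = cable_moisture_scalar,
                moisture_variable = "theta", provenance = "reconstructed"),
    century = list(temperature_fn = .century_temperature,
                   moisture_fn = .century_moisture,
                   moisture_variable = "x", provenance = "reconstructed")
  )
  for (nm in names(reg)) reg[[nm]]$name <- nm
  if (missing(name)) return(reg)
  if (!name %in% names(reg))
    stop(sprintf("unknown scalar scheme '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  reg[[name]]
}

#' Expand cell scalars to the 13x13 diagonal environmental matrix
#'
#' Builds the diagonal matrix with the pattern (1, 1, 1, 1, xi, ..., xi):
#' temperature and moisture limit the decomposition of litter and soil
#' pools, while vegetation pool turnover (set by phenology/mortality, here
#' prescribed) carries no environmental limitation.
#'
#' @param xi_t temperature scalar in [0, 1]
#' @param xi_w moisture scalar in [0, 1]
#' @param layout a \code{\link{pool_layout}}
#' @return 13x13 diagonal matrix
#' @examples
#' diag(environmental_scalar_matrix(0.69, 0.53))
#' @export
environmental_scalar_matrix <- function(xi_t, xi_w, layout = pool_layout()) {
  stopifnot(length(xi_t) == 1L, length(xi_w) == 1L)
  if (!is.finite(xi_t) || xi_t < 0 || xi_t > 1 ||
      !is.finite(xi_w) || xi_w < 0 || xi_w > 1)
    stop("xi_t and xi_w must lie in [0, 1]", call. = FALSE)
  d <- rep(xi_t * xi_w, layout$n)
  d[pool_indices(layout, "vegetation")] <- 1
  xi <- diag(d, nrow = layout$n)
  dimnames(xi) <- list(layout$names, layout$names)
  xi
}
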