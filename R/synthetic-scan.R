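#' Parameters for the synthetic circumpapillary scan generator
#'
#' Defaults describe a plausible healthy peripapillary RNFL: 2048 A-scans on
#' the 3.4-mm circle, quadrant PR/UD following the superior/inferior-high
#' "double hump" (about 10-14 degree/100 um), quadrant thicknesses around
#' 70-130 um, 3-um axial sampling and 0.5-degree retardation noise.
#'
#' @param n_ascans number of A-scans on the circle (divisible by 4).
#' @param true_slopes generative PR/UD per quadrant, degree/100 um, named
#'   (T, S, N, I) or length-1.
#' @param thickness_um generative RNFL thickness per quadrant, um.
#' @param axial_pixel_um axial sampling step, um/pixel.
#' @param noise_sd additive Gaussian retardation noise SD, degrees.
#' @param inner_depth_um depth of the inner RNFL boundary below the scan
#'   origin, um (constant around the circle).
#' @param laterality \code{"OD"} or \code{"OS"}.
#' @param seed integer RNG seed.
#' @return List of class \code{scan_gen_params}.
#' @export
scan_gen_params <- function(n_ascans = 2048,
                            true_slopes = c(T = 10, S = 14, N = 10, I = 14),
                            thickness_um = c(T = 70, S = 120, N = 80, I = 130),
                            axial_pixel_um = 3,
                            noise_sd = 0.5,
                            inner_depth_um = 120,
                            laterality = "OD",
                            seed = 1L) {
  if (n_ascans < 4 || n_ascans %% 4 != 0)
    stop("n_ascans must be a positive multiple of 4", call. = FALSE)
  true_slopes <- .as_quadrant_vector(true_slopes, "true_slopes")
  thickness_um <- .as_quadrant_vector(thickness_um, "thickness_um")
  if (any(thickness_um <= 0)) stop("thickness_um must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  .stopifnot_scalar_pos(axial_pixel_um, "axial_pixel_um")
  .check_laterality(laterality)
  structure(list(n_ascans = as.integer(n_ascans), true_slopes = true_slopes,
                 thickness_um = thickness_um, axial_pixel_um = axial_pixel_um,
                 noise_sd = noise_sd, inner_depth_um = inner_depth_um,
                 laterality = laterality, seed = as.integer(seed)),
            class = "scan_gen_params")
}

#' Generate a synthetic circumpapillary PS-OCT scan
#'
#' Each A-scan receives a linear retardation-versus-depth profile within the
#' RNFL, ret(d) = slope_q/100 * d + noise, sampled at the axial pixel pitch
#' from the inner to the outer boundary of its quadrant, with quadrant
#' membership following the same angular convention as
#' \code{\link{partition_quadrants}}. Ground truth (slopes, thicknesses) is
#' stored on the returned scan. Deterministic given the seed.
#'
#' @param params a \code{\link{scan_gen_params}} object.
#' @return A \code{\link{circ_scan}} whose \code{ground_truth} holds the
#'   generative parameters.
#' @export
gen_circumpapillary_scan <- function(params = scan_gen_params()) {
  stopifnot(inherits(params, "scan_gen_params"))
  set.seed(params$seed)
  n <- params$n_ascans
  angles <- (seq_len(n) - 1) * 360 / n
  quad <- .quadrant_of_angle(angles, params$laterality)
  inner <- rep(params$inner_depth_um, n)
  outer <- inner + params$thickness_um[quad]
  n_samp <- floor(params$thickness_um[quad] / params$axial_pixel_um) + 1L
  idx <- rep.int(seq_len(n), n_samp)
  rel_depth <- unlist(lapply(n_samp, function(k)
    (seq_len(k) - 1) * params$axial_pixel_um), use.names = FALSE)
  slope <- params$true_slopes[quad][idx]
  ret <- slope / 100 * rel_depth
  if (params$noise_sd > 0)
    ret <- ret + rnorm(length(ret), 0, params$noise_sd)
  profiles <- data.frame(ascan_index = idx,
                         angle_deg = angles[idx],
                         depth_um = inner[idx] + rel_depth,
                         retardation_deg = ret)
  boundaries <- data.frame(ascan_index = seq_len(n), angle_deg = angles,
                           inner_um = inner, outer_um = outer)
  circ_scan(profiles, boundaries, params$laterality,
            ground_truth = list(true_slopes = params$true_slopes,
                                thickness_um = params$thickness_um,
                                params = params))
}
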