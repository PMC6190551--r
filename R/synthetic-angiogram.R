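#' Parameters for the synthetic angiogram generator
#'
#' Defaults emulate a 3 x 3 mm enface macular angiogram on the native
#' 245-px grid: a handful of large through-going vessels (30-50 um), a
#' denser bed of microvessels (10-20 um, below the 25-um caliber split), a
#' central avascular disc, and additive background noise on an 8-bit gray
#' scale.
#'
#' @param field_mm physical side length, mm.
#' @param grid_px native grid side, px.
#' @param n_large,n_micro vessel counts.
#' @param large_width_um caliber range of large vessels (entirely >= 25 um).
#' @param micro_width_um caliber range of microvessels (entirely < 25 um).
#' @param faz_radius_mm radius of the central avascular disc, mm.
#' @param faz_center_offset_px \code{c(x, y)} offset of the FAZ center from
#'   the grid center, px.
#' @param background_level background gray level, 8-bit units.
#' @param contrast vessel brightness above background, 8-bit units.
#' @param background_noise_sd additive Gaussian noise SD, 8-bit units.
#' @param plexus,axial_length_mm,laterality angiogram metadata.
#' @param seed integer RNG seed.
#' @return List of class \code{vessel_gen_params}.
#' @export
vessel_gen_params <- function(field_mm = 3, grid_px = 245,
                              n_large = 6, n_micro = 60,
                              large_width_um = c(30, 50),
                              micro_width_um = c(10, 20),
                              faz_radius_mm = 0.3,
                              faz_center_offset_px = c(0, 0),
                              background_level = 40, contrast = 100,
                              background_noise_sd = 15,
                              plexus = "superficial",
                              axial_length_mm = 23.95, laterality = "OD",
                              seed = 1L) {
  if (any(micro_width_um >= 25))
    stop("micro_width_um range must lie entirely below 25 um", call. = FALSE)
  if (any(large_width_um < 25))
    stop("large_width_um range must lie entirely at or above 25 um",
         call. = FALSE)
  if (faz_radius_mm >= field_mm / 2)
    stop("faz_radius_mm must be smaller than half the field", call. = FALSE)
  if (n_large < 0 || n_micro < 0) stop("vessel counts must be >= 0", call. = FALSE)
  structure(list(field_mm = field_mm, grid_px = as.integer(grid_px),
                 n_large = as.integer(n_large), n_micro = as.integer(n_micro),
                 large_width_um = large_width_um,
                 micro_width_um = micro_width_um,
                 faz_radius_mm = faz_radius_mm,
                 faz_center_offset_px = faz_center_offset_px,
                 background_level = background_level, contrast = contrast,
                 background_noise_sd = background_noise_sd,
                 plexus = plexus, axial_length_mm = axial_length_mm,
                 laterality = laterality, seed = as.integer(seed)),
            class = "vessel_gen_params")
}

# one spline-smoothed random-walk centerline across/inside the grid.
# Returns a two-column matrix of (x, y) samples about 0.7 px apart.
.vessel_path <- function(grid_px, spanning = TRUE) {
  step <- grid_px / 8
  if (spanning) {
    side <- sample.int(4, 1)
    start <- switch(side,
                    c(1, runif(1, 1, grid_px)),
                    c(grid_px, runif(1, 1, grid_px)),
                    c(runif(1, 1, grid_px), 1),
                    c(runif(1, 1, grid_px), grid_px))
    heading <- atan2(grid_px / 2 - start[2], grid_px / 2 - start[1]) +
      runif(1, -0.5, 0.5)
    n_ctrl <- 14L
    jitter <- 0.35
  } else {
    start <- c(runif(1, 1, grid_px), runif(1, 1, grid_px))
    heading <- runif(1, 0, 2 * pi)
    n_ctrl <- 6L
    jitter <- 0.55
    step <- grid_px / 14
  }
  ctrl <- matrix(NA_real_, n_ctrl, 2)
  ctrl[1, ] <- start
  for (i in 2:n_ctrl) {
    heading <- heading + rnorm(1, 0, jitter)
    ctrl[i, ] <- ctrl[i - 1, ] + step * c(cos(heading), sin(heading))
  }
  t_ctrl <- seq_len(n_ctrl)
  t_fine <- seq(1, n_ctrl, by = 0.7 / step)
  cbind(stats::spline(t_ctrl, ctrl[, 1], xout = t_fine)$y,
        stats::spline(t_ctrl, ctrl[, 2], xout = t_fine)$y)
}

# stamp a path with a circular brush of given radius (px) into logical mask
.stamp_path <- function(mask, path, radius_px) {
  g <- nrow(mask)
  r <- max(radius_px, 0)
  ri <- ceiling(r)
  off <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  off <- off[off$dx^2 + off$dy^2 <= max(r, 0.5)^2, , drop = FALSE]
  xs <- round(rep(path[, 1], each = nrow(off)) + off$dx)
  ys <- round(rep(path[, 2], each = nrow(off)) + off$dy)
  ok <- xs >= 1 & xs <= g & ys >= 1 & ys <= g
  mask[cbind(ys[ok], xs[ok])] <- TRUE
  mask
}

#' Generate a synthetic enface angiogram with ground truth
#'
#' Vessels are rendered as spline-smoothed random walks stamped with a
#' circular brush of the sampled caliber: large vessels span the field,
#' microvessels form shorter tortuous segments. Vessels are erased inside
#' the central avascular disc, the scene is shaded (background + contrast),
#' Gaussian noise added, and gray levels quantized to 8 bits. The stored
#' ground truth holds the clean vessel mask, the per-pixel caliber class,
#' and the FAZ center. Deterministic given the seed.
#'
#' @param params a \code{\link{vessel_gen_params}} object.
#' @return An \code{\link{angiogram}}; \code{ground_truth} holds
#'   \code{vessel_mask}, \code{class_map} (0 none, 1 micro, 2 large),
#'   \code{faz_center_px}, \code{faz_radius_px} and \code{params}.
#' @export
gen_angiogram <- function(params = vessel_gen_params()) {
  stopifnot(inherits(params, "vessel_gen_params"))
  set.seed(params$seed)
  g <- params$grid_px
  upp <- params$field_mm * 1000 / g
  cls <- matrix(0L, g, g)
  stamp_set <- function(n, width_range, spanning, code) {
    for (i in seq_len(n)) {
      w <- runif(1, width_range[1], width_range[2])
      path <- .vessel_path(g, spanning)
      m <- .stamp_path(matrix(FALSE, g, g), path, (w / 2) / upp)
      cls[m] <<- code                    # later stamps overwrite; large last
    }
  }
  stamp_set(params$n_micro, params$micro_width_um, spanning = FALSE, code = 1L)
  stamp_set(params$n_large, params$large_width_um, spanning = TRUE, code = 2L)
  faz_center <- c((g + 1) / 2, (g + 1) / 2) + params$faz_center_offset_px
  faz_r_px <- params$faz_radius_mm * 1000 / upp
  xs <- matrix(rep(seq_len(g), each = g), g, g)
  ys <- matrix(rep(seq_len(g), times = g), g, g)
  inside_faz <- (xs - faz_center[1])^2 + (ys - faz_center[2])^2 <= faz_r_px^2
  cls[inside_faz] <- 0L
  img <- matrix(params$background_level, g, g) + params$contrast * (cls > 0)
  if (params$background_noise_sd > 0)
    img <- img + rnorm(g * g, 0, params$background_noise_sd)
  img <- round(pmin(pmax(img, 0), 255)) / 255
  angiogram(img, field_mm = params$field_mm, plexus = params$plexus,
            axial_length_mm = params$axial_length_mm,
            laterality = params$laterality,
            ground_truth = list(vessel_mask = cls > 0, class_map = cls,
                                faz_center_px = faz_center,
                                faz_radius_px = faz_r_px, params = params))
}

#' Binary fractal fixtures with closed-form dimension
#'
#' Deterministic test patterns whose box-counting dimension is known in
#' closed form: a one-pixel horizontal line (D = 1), a filled square (D = 2)
#' and a depth-5 Sierpinski carpet (D = log 8 / log 3 = 1.8928).
#'
#' @param kind \code{"line"}, \code{"filled_square"} or
#'   \code{"sierpinski_carpet"}.
#' @param size_px grid side; the carpet requires a multiple of 243 (3^5).
#' @return Logical matrix with attribute \code{theoretical_dimension}.
#' @export
gen_fractal_fixture <- function(kind = c("line", "filled_square",
                                         "sierpinski_carpet"),
                                size_px = 729) {
  kind <- match.arg(kind)
  if (kind == "line") {
    m <- matrix(FALSE, size_px, size_px)
    m[floor(size_px / 2), ] <- TRUE
    return(structure(m, theoretical_dimension = 1.0))
  }
  if (kind == "filled_square") {
    return(structure(matrix(TRUE, size_px, size_px),
                     theoretical_dimension = 2.0))
  }
  # depth-5 carpet: cell (i, j) of the 243-grid is empty iff any of its five
  # base-3 digit pairs is (1, 1); scaled up by an integer cell size
  if (size_px < 243 || size_px %% 243 != 0)
    stop("sierpinski_carpet needs size_px a multiple of 243 (3^5)",
         call. = FALSE)
  unit <- size_px %/% 243L
  idx <- 0:242
  digits <- sapply(0:4, function(k) (idx %/% 3^k) %% 3)  # 243 x 5
  mid <- digits == 1
  base <- matrix(TRUE, 243, 243)
  for (k in 1:5)
    base <- base & !outer(mid[, k], mid[, k], `&`)
  m <- base[rep(seq_len(243), each = unit), rep(seq_len(243), each = unit)]
  structure(m, theoretical_dimension = log(8) / log(3))
}
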