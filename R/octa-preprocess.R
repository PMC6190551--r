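#' Construct an enface OCTA angiogram object
#'
#' @param pixels square numeric matrix of gray levels in [0, 1]
#'   (rows = y, columns = x).
#' @param field_mm physical side length of the scan field, mm.
#' @param plexus \code{"superficial"} or \code{"deep"}.
#' @param axial_length_mm ocular axial length, mm (> 1.82, the zero of
#'   Bennett's formula).
#' @param laterality \code{"OD"} or \code{"OS"}.
#' @param ground_truth optional generator ground truth.
#' @return Object of class \code{angiogram}.
#' @export
angiogram <- function(pixels, field_mm = 3, plexus = c("superficial", "deep"),
                      axial_length_mm = 23.95, laterality = "OD",
                      ground_truth = NULL) {
  plexus <- match.arg(plexus)
  .check_laterality(laterality)
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop("pixels must be a square matrix", call. = FALSE)
  .stopifnot_scalar_pos(field_mm, "field_mm")
  if (axial_length_mm <= 1.82)
    stop("axial_length_mm must exceed 1.82 mm", call. = FALSE)
  structure(list(pixels = pixels, grid_px = nrow(pixels), field_mm = field_mm,
                 plexus = plexus, axial_length_mm = axial_length_mm,
                 laterality = laterality, ground_truth = ground_truth),
            class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf("enface OCTA angiogram: %dx%d px, %.1f mm field, %s plexus, %s, AL %.2f mm\n",
              x$grid_px, x$grid_px, x$field_mm, x$plexus, x$laterality,
              x$axial_length_mm))
  invisible(x)
}

#' Micrometres per pixel of an angiogram grid
#' @param ang an \code{\link{angiogram}}, or a field size in mm.
#' @param grid_px grid side in pixels (when \code{ang} is a field size).
#' @return um per pixel.
#' @export
um_per_px <- function(ang, grid_px = NULL) {
  if (inherits(ang, "angiogram")) return(ang$field_mm * 1000 / ang$grid_px)
  ang * 1000 / grid_px
}

#' Bennett ocular magnification scaling factor
#'
#' Transverse magnification scaling factor from axial length,
#' \code{3.382 * 0.013062 * (AL - 1.82)}. Used to correct fundus feature
#' dimensions for the elongated myopic eye.
#'
#' @param axial_length_mm ocular axial length in mm (>= 1.82, the formula's
#'   zero).
#' @return Dimensionless scaling factor.
#' @examples
#' bennett_scaling_factor(24.34)  # 0.9948
#' bennett_scaling_factor(26.94)  # 1.1097
#' @export
bennett_scaling_factor <- function(axial_length_mm) {
  if (any(!is.finite(axial_length_mm)) || any(axial_length_mm < 1.82))
    stop("axial length must be finite and >= 1.82 mm", call. = FALSE)
  3.382 * 0.013062 * (axial_length_mm - 1.82)
}

#' Resize an angiogram to the analysis grid
#'
#' Upsamples the native grid (245 px for a 3-mm scan) to the analysis
#' resolution, by default 1024 x 1024, using bilinear interpolation. At
#' 1024 px over 3 mm one pixel is about 2.93 um.
#'
#' @param ang an \code{\link{angiogram}}.
#' @param size_px analysis grid side, default 1024.
#' @return The resized \code{angiogram}.
#' @export
resize_to_analysis_grid <- function(ang, size_px = 1024) {
  stopifnot(inherits(ang, "angiogram"))
  if (nrow(ang$pixels) != ncol(ang$pixels))
    stop("angiogram grid is not square", call. = FALSE)
  img <- EBImage::resize(EBImage::Image(ang$pixels), w = size_px, h = size_px,
                         filter = "bilinear")
  ang$pixels <- matrix(EBImage::imageData(img), size_px, size_px)
  ang$grid_px <- as.integer(size_px)
  ang
}

#' Apply Bennett magnification correction to an angiogram
#'
#' Rescales the image about its center by the ratio of the eye's Bennett
#' factor to an emmetropic reference factor, then center-crops (ratio > 1)
#' or symmetrically pads with the background level (ratio < 1) back to the
#' original grid, so features take on their true retinal dimensions at a
#' fixed pixel pitch.
#'
#' @param ang an \code{\link{angiogram}} (typically already on the analysis
#'   grid).
#' @param factor Bennett factor of the imaged eye; default computed from the
#'   angiogram's axial length.
#' @param reference_al_mm axial length defining the reference factor
#'   (default 23.95 mm, emmetropic).
#' @return The corrected \code{angiogram}.
#' @export
magnification_correct <- function(ang,
                                  factor = bennett_scaling_factor(ang$axial_length_mm),
                                  reference_al_mm = 23.95) {
  stopifnot(inherits(ang, "angiogram"))
  .stopifnot_scalar_pos(factor, "factor")
  ratio <- factor / bennett_scaling_factor(reference_al_mm)
  px <- ang$grid_px
  if (abs(ratio - 1) < 1e-12) return(ang)
  new_px <- max(2L, round(px * ratio))
  img <- EBImage::resize(EBImage::Image(ang$pixels), w = new_px, h = new_px,
                         filter = "bilinear")
  m <- matrix(EBImage::imageData(img), new_px, new_px)
  if (new_px >= px) {                      # enlarge then center-crop
    off <- floor((new_px - px) / 2)
    out <- m[off + seq_len(px), off + seq_len(px)]
  } else {                                 # shrink then pad with background
    border <- c(ang$pixels[1, ], ang$pixels[px, ], ang$pixels[, 1], ang$pixels[, px])
    out <- matrix(stats::median(border), px, px)
    off <- floor((px - new_px) / 2)
    out[off + seq_len(new_px), off + seq_len(new_px)] <- m
  }
  ang$pixels <- out
  ang
}

#' Binarize vessels in an enface angiogram
#'
#' Polarity is normalized so vessels are bright (the image is inverted when
#' the above-threshold region covers the majority of the field), then
#' contrast-limited adaptive histogram equalization, background removal by
#' subtracting a large-kernel median estimate, a global Otsu threshold, and
#' removal of connected components below a minimum area.
#'
#' @param ang an \code{\link{angiogram}} or a numeric gray matrix.
#' @param median_radius radius (px) of the median background kernel; default
#'   scales with the grid (about grid/50).
#' @param min_area_px minimum connected-component area kept; default scales
#'   with the pixel area relative to the 245-px native grid.
#' @param clahe_blocks number of CLAHE tiles per side.
#' @return Logical matrix of vessel foreground. A constant input yields an
#'   empty map with attribute \code{flag_constant = TRUE} and a warning.
#' @export
binarize_vessels <- function(ang, median_radius = NULL, min_area_px = NULL,
                             clahe_blocks = 8) {
  x <- if (inherits(ang, "angiogram")) ang$pixels else ang
  stopifnot(is.matrix(x))
  px <- nrow(x)
  if (is.null(median_radius)) median_radius <- max(3L, round(px / 50))
  if (is.null(min_area_px)) min_area_px <- max(3L, round(5 * (px / 245)^2))
  rng <- range(x)
  if (diff(rng) < 1e-9) {
    warning("constant image: returning empty vessel map")
    return(structure(matrix(FALSE, px, ncol(x)), flag_constant = TRUE))
  }
  x <- (x - rng[1]) / diff(rng)
  # polarity: vessels are the bright minority
  th0 <- EBImage::otsu(EBImage::Image(x))
  if (mean(x > th0) > 0.5) {
    x <- 1 - x
    th0 <- EBImage::otsu(EBImage::Image(x))
  }
  # no-signal guard: on a pure-noise Gaussian image the Otsu split separates
  # the two halves by about 2.6 background SDs whatever the noise scale;
  # genuine vessel contrast sits well above 3
  fg0 <- x > th0
  separation <- (mean(x[fg0]) - mean(x[!fg0])) / stats::sd(x[!fg0])
  if (!is.finite(separation) || separation < 3) {
    warning("no detectable vessel signal: returning empty vessel map")
    return(structure(matrix(FALSE, px, ncol(x)), flag_constant = FALSE,
                     flag_no_signal = TRUE))
  }
  x <- .clahe_pad(x, clahe_blocks)
  bg <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(x),
                                                 size = median_radius))
  x <- pmax(x - bg, 0)
  if (max(x) > 0) x <- x / max(x)
  th <- EBImage::otsu(EBImage::Image(x))
  bin <- matrix(x > th, px, ncol(x))
  # drop speckle components
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_area_px)
    bin <- matrix(lab %in% keep, px, ncol(x))
  }
  structure(bin, flag_constant = FALSE)
}

# CLAHE requires dimensions divisible by the tile counts; pad by edge
# replication, equalize, crop back
.clahe_pad <- function(x, blocks) {
  nr <- nrow(x); nc <- ncol(x)
  nr2 <- ceiling(nr / blocks) * blocks
  nc2 <- ceiling(nc / blocks) * blocks
  xp <- x[c(seq_len(nr), rep(nr, nr2 - nr)), c(seq_len(nc), rep(nc, nc2 - nc))]
  out <- EBImage::imageData(EBImage::clahe(EBImage::Image(xp),
                                           nx = blocks, ny = blocks))
  out[seq_len(nr), seq_len(nc)]
}

#' Skeletonize a binary vessel map
#'
#' Zhang-Suen morphological thinning to unit-width 8-connected centerlines,
#' implemented as vectorised whole-image passes.
#'
#' @param binary logical or 0/1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize_map <- function(binary) {
  stopifnot(is.matrix(binary))
  p <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  if (!any(p > 0)) return(p > 0)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # 8-neighbourhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      p2 <- .shift_mat(p, 1, 0);  p3 <- .shift_mat(p, 1, 1)
      p4 <- .shift_mat(p, 0, 1);  p5 <- .shift_mat(p, -1, 1)
      p6 <- .shift_mat(p, -1, 0); p7 <- .shift_mat(p, -1, -1)
      p8 <- .shift_mat(p, 0, -1); p9 <- .shift_mat(p, 1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        p[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p > 0
}

#' Separate a vessel map into micro- and large-vessel compartments
#'
#' Local vessel diameter is estimated at skeleton points from the Euclidean
#' distance transform (diameter = (2 d - 1) pixels, converted to um); each
#' skeleton point is classed micro (< 25 um) or large, and every foreground
#' pixel inherits the class of its nearest skeleton point by breadth-first
#' class propagation. Micro and large partition the foreground exactly.
#'
#' @param binary logical foreground matrix.
#' @param um_per_px physical pixel size, um.
#' @param threshold_um caliber split, default 25 um.
#' @return List with logical matrices \code{micro} and \code{large}, the
#'   \code{skeleton} of the full map, and \code{diameter_um} (NA off
#'   skeleton).
#' @export
separate_by_diameter <- function(binary, um_per_px, threshold_um = 25) {
  stopifnot(is.matrix(binary))
  .stopifnot_scalar_pos(um_per_px, "um_per_px")
  binary <- binary != 0
  empty <- matrix(FALSE, nrow(binary), ncol(binary))
  if (!any(binary))
    return(list(micro = empty, large = empty, skeleton = empty,
                diameter_um = matrix(NA_real_, nrow(binary), ncol(binary))))
  skel <- skeletonize_map(binary)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(binary)))
  diam <- matrix(NA_real_, nrow(binary), ncol(binary))
  diam[skel] <- pmax(2 * d[skel] - 1, 1) * um_per_px
  cls <- matrix(0L, nrow(binary), ncol(binary))   # 1 micro, 2 large
  cls[skel & diam < threshold_um] <- 1L
  cls[skel & diam >= threshold_um] <- 2L
  # breadth-first propagation into the remaining foreground; ties go to the
  # large class so large-vessel masks stay conservative (complete)
  repeat {
    unassigned <- binary & cls == 0L
    if (!any(unassigned)) break
    grew <- FALSE
    for (k in c(2L, 1L)) {
      src <- cls == k
      nb <- .shift_mat(src, 1, 0) + .shift_mat(src, -1, 0) +
            .shift_mat(src, 0, 1) + .shift_mat(src, 0, -1) +
            .shift_mat(src, 1, 1) + .shift_mat(src, 1, -1) +
            .shift_mat(src, -1, 1) + .shift_mat(src, -1, -1)
      take <- unassigned & nb > 0 & cls == 0L
      if (any(take)) {
        cls[take] <- k
        grew <- TRUE
      }
    }
    if (!grew) {            # isolated foreground with no skeleton class
      cls[unassigned] <- 1L
      break
    }
  }
  list(micro = cls == 1L, large = cls == 2L, skeleton = skel,
       diameter_um = diam)
}

#' Remove superficial large-vessel projection artifacts from a deep map
#'
#' Subtracts the superficial-plexus large-vessel mask, dilated by a small
#' margin, from the deep-plexus foreground. Deep-plexus angiograms carry
#' shadow copies of overlying large vessels; this masks them out before
#' density analysis.
#'
#' @param deep_binary logical deep-plexus foreground.
#' @param superficial_large logical superficial large-vessel mask, same shape.
#' @param margin_px dilation margin in pixels, default 1.
#' @return Cleaned logical deep foreground.
#' @export
remove_projection_artifacts <- function(deep_binary, superficial_large,
                                        margin_px = 1) {
  if (!identical(dim(deep_binary), dim(superficial_large)))
    stop("deep map and superficial large-vessel mask differ in shape",
         call. = FALSE)
  mask <- superficial_large != 0
  if (margin_px > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * margin_px + 1, shape = "disc")
    mask <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask), brush)) > 0
  }
  (deep_binary != 0) & !mask
}

#' Detect the foveal avascular zone center
#'
#' Casts radial rays from the grid center, smooths each intensity profile,
#' and marks the first location of maximal positive intensity gradient as the
#' FAZ boundary on that ray; the returned center is the centroid of boundary
#' points after one refinement iteration recasting rays from the first
#' centroid estimate.
#'
#' @param x gray matrix (vessels bright, FAZ dark) or \code{angiogram}.
#' @param ray_step_deg angular ray spacing, default 5 degrees.
#' @param min_gradient minimum smoothed gradient for a ray to count as
#'   detected (on the normalized [0,1] intensity scale).
#' @param max_radius_frac search radius as a fraction of the half-grid.
#' @return Numeric \code{c(x, y)} pixel coordinates of the FAZ center.
#' @export
detect_faz_center <- function(x, ray_step_deg = 5, min_gradient = 0.02,
                              max_radius_frac = 0.9) {
  if (inherits(x, "angiogram")) x <- x$pixels
  stopifnot(is.matrix(x))
  rng <- range(x)
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  nr <- nrow(x); nc <- ncol(x)
  smooth_w <- max(5L, round(min(nr, nc) / 60))
  if (smooth_w %% 2 == 0) smooth_w <- smooth_w + 1L
  kern <- rep(1 / smooth_w, smooth_w)
  cast <- function(cx, cy) {
    angs <- seq(0, 360 - ray_step_deg, by = ray_step_deg) * pi / 180
    rmax <- floor(min(nr, nc) / 2 * max_radius_frac) - 1L
    pts <- matrix(NA_real_, length(angs), 2)
    for (i in seq_along(angs)) {
      r <- seq_len(rmax)
      xi <- round(cx + r * cos(angs[i]))
      yi <- round(cy + r * sin(angs[i]))
      ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
      if (sum(ok) < 3 * smooth_w) next
      prof <- x[cbind(yi[ok], xi[ok])]
      sm <- stats::filter(prof, kern, sides = 2)
      g <- diff(sm)
      g[is.na(g)] <- -Inf
      gmax <- max(g)
      if (gmax <= min_gradient) next
      # walking outward from the center, the FAZ rim is the first strong
      # positive gradient; distant vessel edges may have larger gradients
      # but come later
      j <- which(g >= 0.5 * gmax)[1]
      pts[i, ] <- c(xi[ok][j], yi[ok][j])
    }
    pts
  }
  # robust centroid: rays whose gradient maximum lands far beyond the typical
  # boundary radius (distant vessel edges) are trimmed before averaging
  centroid <- function(pts, cx, cy) {
    ok <- stats::complete.cases(pts)
    if (mean(ok) < 0.5) return(NULL)
    r <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
    keep <- ok & r <= 1.8 * stats::median(r[ok])
    colMeans(pts[keep, , drop = FALSE])
  }
  # initialize inside the avascular disc: the FAZ is the largest vessel-free
  # clearance near the image center, so seed the ray origin at the maximum of
  # the background distance transform (lightly penalized by distance from the
  # grid center, since the fovea sits near the scan center by protocol).
  # When the FAZ is displaced from the grid center the ray origin must lie
  # inside the disc for the outward gradient search to see its rim.
  bin <- suppressWarnings(binarize_vessels(x))
  if (any(bin)) {
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(!bin)))
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr), times = nc), nr, nc)
    score <- d - 0.15 * sqrt((xs - nc / 2)^2 + (ys - nr / 2)^2)
    hw <- round(0.18 * min(nr, nc))
    win_r <- (nr %/% 2 - hw):(nr %/% 2 + hw)
    win_c <- (nc %/% 2 - hw):(nc %/% 2 + hw)
    sub <- score[win_r, win_c]
    j <- which(sub == max(sub), arr.ind = TRUE)
    c0 <- c(win_c[1] + mean(j[, 2]) - 1, win_r[1] + mean(j[, 1]) - 1)
  } else {
    c0 <- c(nc / 2, nr / 2)
  }
  ctr <- centroid(cast(c0[1], c0[2]), c0[1], c0[2])
  if (is.null(ctr))
    stop("FAZ detection failed: no intensity-gradient boundary on at least ",
         "half of the radial rays", call. = FALSE)
  for (it in 1:2) {                       # refinement passes
    ctr2 <- centroid(cast(ctr[1], ctr[2]), ctr[1], ctr[2])
    if (is.null(ctr2))
      stop("FAZ detection failed on refinement pass", call. = FALSE)
    ctr <- ctr2
  }
  # divergence guard: the rim centroid must stay close to the clearance
  # seed; a large jump means the rays latched onto peripheral structure
  # (possible in very sparse networks), in which case the seed is the more
  # trustworthy estimate
  if (sqrt(sum((ctr - c0)^2)) > 0.12 * min(nr, nc)) ctr <- c0
  c(x = unname(ctr[1]), y = unname(ctr[2]))
}

#' Mirror a grid horizontally for left eyes
#'
#' Left-eye (OS) images are flipped about the vertical axis so that the
#' nasal/temporal sides line up with right-eye images; right-eye (OD) input
#' is returned unchanged.
#'
#' @param grid matrix.
#' @param laterality \code{"OD"} or \code{"OS"}.
#' @return The (possibly mirrored) matrix.
#' @export
flip_if_left <- function(grid, laterality) {
  .check_laterality(laterality)
  if (laterality == "OS") grid[, ncol(grid):1, drop = FALSE] else grid
}

#' Annulus analysis mask
#'
#' Logical mask of pixels whose center distance from a given center lies
#' between the inner and outer annulus radii (defaults 0.6 and 2.5 mm
#' diameter, the macular analysis annulus).
#'
#' @param grid_px grid side length, px.
#' @param um_per_px physical pixel size, um.
#' @param center \code{c(x, y)} center in px; default grid center.
#' @param inner_diameter_mm,outer_diameter_mm annulus diameters, mm.
#' @return Logical matrix.
#' @export
annulus_mask <- function(grid_px, um_per_px, center = NULL,
                         inner_diameter_mm = 0.6, outer_diameter_mm = 2.5) {
  .stopifnot_scalar_pos(um_per_px, "um_per_px")
  if (inner_diameter_mm > outer_diameter_mm)
    stop("inner annulus diameter exceeds outer diameter", call. = FALSE)
  if (is.null(center)) center <- c((grid_px + 1) / 2, (grid_px + 1) / 2)
  r_in <- inner_diameter_mm * 1000 / 2 / um_per_px
  r_out <- outer_diameter_mm * 1000 / 2 / um_per_px
  if (center[1] - r_out < 1 || center[1] + r_out > grid_px ||
      center[2] - r_out < 1 || center[2] + r_out > grid_px)
    stop("annulus (outer radius ", round(r_out, 1),
         " px) does not fit inside the grid", call. = FALSE)
  xs <- matrix(rep(seq_len(grid_px), each = grid_px), grid_px, grid_px)
  ys <- matrix(rep(seq_len(grid_px), times = grid_px), grid_px, grid_px)
  d <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  d >= r_in & d <= r_out
}
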