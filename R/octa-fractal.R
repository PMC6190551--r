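#' Rotated-grid box-counting fractal dimension
#'
#' Box sizes form a geometric ladder from \code{max_box_px} down to 2 px
#' (exact ratio 1/sqrt(2)). For every size the counting
#' grid is rotated through 0 to <360 degrees in \code{rotation_step_deg}
#' increments -- implemented as rotation of the foreground point set about
#' \code{center}, which avoids raster resampling -- and the minimum non-empty
#' box count over rotations is kept. Dbox is minus the least-squares slope of
#' log(count) on log(box size). Boxes are anchored at the bounding-box
#' minimum of the (rotated) point set.
#'
#' @param binary logical/0-1 matrix of foreground pixels (e.g. a skeleton
#'   restricted to the analysis annulus).
#' @param max_box_px largest box size, default 104 px.
#' @param rotation_step_deg grid rotation increment, default 15 degrees; use
#'   360 for a single unrotated grid.
#' @param center \code{c(x, y)} rotation center in px; default grid center.
#' @return Object of class \code{density_result}: \code{dbox},
#'   \code{box_sizes}, \code{counts}, \code{n_px}.
#' @export
box_counting_dimension <- function(binary, max_box_px = 104,
                                   rotation_step_deg = 15, center = NULL) {
  stopifnot(is.matrix(binary))
  pts <- which(binary != 0, arr.ind = TRUE)
  n_px <- nrow(pts)
  if (n_px < 10)
    stop("box counting needs at least 10 foreground pixels (got ", n_px, ")",
         call. = FALSE)
  if (is.null(center))
    center <- c((ncol(binary) + 1) / 2, (nrow(binary) + 1) / 2)
  xy <- cbind(pts[, 2] - center[1], pts[, 1] - center[2])  # (x, y) about center
  sizes <- .box_size_ladder(max_box_px)
  if (length(sizes) < 3)
    stop("fewer than 3 distinct box sizes in the ladder", call. = FALSE)
  thetas <- seq(0, 360 - rotation_step_deg, by = rotation_step_deg) * pi / 180
  counts <- rep(Inf, length(sizes))
  for (th in thetas) {
    rot <- xy %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    x0 <- min(rot[, 1]); y0 <- min(rot[, 2])
    for (i in seq_along(sizes)) {
      s <- sizes[i]
      ix <- floor((rot[, 1] - x0) / s)
      iy <- floor((rot[, 2] - y0) / s)
      cnt <- length(unique(ix * 1e6 + iy))
      if (cnt < counts[i]) counts[i] <- cnt
    }
  }
  fit <- stats::lm.fit(cbind(1, log(sizes)), log(counts))
  structure(list(dbox = -unname(fit$coefficients[2]),
                 box_sizes = sizes, counts = counts, n_px = n_px,
                 rotation_step_deg = rotation_step_deg),
            class = "density_result")
}

# geometric box-size ladder: max_box down to 2 px, exact ratio 1/sqrt(2).
# Sizes are kept real-valued: the point set is rotated by arbitrary angles
# anyway, and integer-rounded sizes create lattice-commensurability
# artifacts (sizes that divide a structured pattern exactly count low while
# neighbouring sizes count high, biasing the log-log slope).
.box_size_ladder <- function(max_box_px) {
  v <- max_box_px
  sizes <- numeric(0)
  while (v >= 2) {
    sizes <- c(sizes, v)
    v <- v / sqrt(2)
  }
  sort(unique(sizes), decreasing = TRUE)
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("box-counting fractal dimension Dbox = %.4f (%d foreground px, %d box sizes, %g deg rotation step)\n",
              x$dbox, x$n_px, length(x$box_sizes), x$rotation_step_deg))
  invisible(x)
}

#' Full enface vessel-density pipeline
#'
#' Composes the macular microvasculature analysis: resize to the analysis
#' grid, Bennett magnification correction, vessel binarization, caliber
#' separation at 25 um, (deep plexus only) removal of superficial
#' large-vessel projection artifacts, skeletonization of the microvessel
#' compartment, left-eye flip, FAZ center detection, annulus restriction
#' (0.6/2.5 mm diameters about the FAZ center) and rotated-grid box counting
#' of the annulus-restricted skeleton.
#'
#' @param ang input \code{\link{angiogram}} (native grid).
#' @param companion superficial-plexus companion \code{angiogram}, required
#'   to deproject a deep-plexus input.
#' @param analysis_px analysis grid side, default 1024.
#' @param max_box_px,rotation_step_deg box-counting settings.
#' @param reference_al_mm emmetropic reference axial length for the
#'   magnification correction.
#' @param keep_maps if \code{TRUE} attach the intermediate maps.
#' @return A \code{density_result} with added fields \code{plexus},
#'   \code{faz_center_px}, \code{n_skeleton_px}, \code{um_per_px} and
#'   (optionally) \code{maps}.
#' @export
vessel_density_pipeline <- function(ang, companion = NULL, analysis_px = 1024,
                                    max_box_px = 104, rotation_step_deg = 15,
                                    reference_al_mm = 23.95,
                                    keep_maps = FALSE) {
  stopifnot(inherits(ang, "angiogram"))
  upp <- um_per_px(ang$field_mm, analysis_px)
  prep <- function(a) {
    a <- resize_to_analysis_grid(a, analysis_px)
    magnification_correct(a, reference_al_mm = reference_al_mm)
  }
  a <- prep(ang)
  bin <- binarize_vessels(a)
  sep <- separate_by_diameter(bin, upp)
  micro <- sep$micro
  if (ang$plexus == "deep" && !is.null(companion)) {
    stopifnot(inherits(companion, "angiogram"))
    comp <- prep(companion)
    comp_sep <- separate_by_diameter(binarize_vessels(comp), upp)
    micro <- remove_projection_artifacts(micro, comp_sep$large, margin_px = 2)
  }
  skel <- skeletonize_map(micro)
  gray <- flip_if_left(a$pixels, ang$laterality)
  skel <- flip_if_left(skel, ang$laterality)
  faz <- detect_faz_center(gray)
  # the annulus must fit inside the field: constrain the center accordingly
  r_out <- 2.5 * 1000 / 2 / upp
  faz_c <- pmin(pmax(faz, r_out + 1), analysis_px - r_out - 1)
  annulus <- annulus_mask(analysis_px, upp, center = faz_c)
  target <- skel & annulus
  res <- box_counting_dimension(target, max_box_px = max_box_px,
                                rotation_step_deg = rotation_step_deg,
                                center = faz_c)
  res$plexus <- ang$plexus
  res$faz_center_px <- faz
  res$n_skeleton_px <- sum(target)
  res$um_per_px <- upp
  if (keep_maps)
    res$maps <- list(gray = gray, binary = bin, micro = micro, skeleton = skel,
                     annulus = annulus)
  res
}
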