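#' Theoretical axial resolution of an OCT system
#'
#' Coherence-length axial resolution of a Gaussian-spectrum OCT source,
#' \eqn{(2 \ln 2 / \pi) \lambda_c^2 / \Delta\lambda}, divided by the tissue
#' refractive index. For an 840-nm source with 50-nm bandwidth this gives
#' 6.23 um in air and about 4.5 um in retinal tissue (n = 1.38).
#'
#' @param center_wavelength_nm source center wavelength, nm.
#' @param bandwidth_nm full-width-half-maximum spectral bandwidth, nm.
#' @param refractive_index medium refractive index (1 for air, 1.38 for
#'   retinal tissue).
#' @return Axial resolution in micrometres.
#' @examples
#' theoretical_axial_resolution(840, 50)        # 6.23 um in air
#' theoretical_axial_resolution(840, 50, 1.38)  # in retinal tissue
#' @export
theoretical_axial_resolution <- function(center_wavelength_nm, bandwidth_nm,
                                         refractive_index = 1) {
  .stopifnot_scalar_pos(center_wavelength_nm, "center_wavelength_nm")
  .stopifnot_scalar_pos(bandwidth_nm, "bandwidth_nm")
  .stopifnot_scalar_pos(refractive_index, "refractive_index")
  res_nm <- (2 * log(2) / pi) * center_wavelength_nm^2 / bandwidth_nm
  res_nm / 1000 / refractive_index
}

# quadrant of an A-scan given its angle on the scan circle.
# Convention (right eye, OD): temporal at 0 deg, superior at 90, nasal at
# 180, inferior at 270, each quadrant covering +/- 45 deg about its center.
# Left-eye (OS) scans are mirrored in angle (a -> 360 - a) before assignment
# so that temporal/nasal are anatomically consistent across eyes.
.quadrant_of_angle <- function(angle_deg, laterality = "OD") {
  a <- angle_deg %% 360
  if (laterality == "OS") a <- (360 - a) %% 360
  q <- character(length(a))
  q[a < 45 | a >= 315] <- "T"
  q[a >= 45 & a < 135] <- "S"
  q[a >= 135 & a < 225] <- "N"
  q[a >= 225 & a < 315] <- "I"
  q
}

#' Construct a circumpapillary PS-OCT scan object
#'
#' Container for a circular scan around the optic nerve head: per-A-scan
#' retardation-versus-depth profiles within the RNFL, the segmented RNFL
#' boundaries, and eye laterality.
#'
#' @param profiles data.frame with columns \code{ascan_index},
#'   \code{angle_deg}, \code{depth_um}, \code{retardation_deg}; one row per
#'   sampled depth, depths non-decreasing within each A-scan.
#' @param boundaries data.frame with columns \code{ascan_index},
#'   \code{angle_deg}, \code{inner_um}, \code{outer_um}; one row per A-scan,
#'   angles strictly increasing on [0, 360).
#' @param laterality \code{"OD"} or \code{"OS"}.
#' @param ground_truth optional list of generator ground truth.
#' @return An object of class \code{circ_scan}.
#' @export
circ_scan <- function(profiles, boundaries, laterality = "OD",
                      ground_truth = NULL) {
  .check_laterality(laterality)
  need_p <- c("ascan_index", "angle_deg", "depth_um", "retardation_deg")
  need_b <- c("ascan_index", "angle_deg", "inner_um", "outer_um")
  if (!all(need_p %in% names(profiles)))
    stop("profiles must have columns: ", paste(need_p, collapse = ", "),
         call. = FALSE)
  if (!all(need_b %in% names(boundaries)))
    stop("boundaries must have columns: ", paste(need_b, collapse = ", "),
         call. = FALSE)
  ang <- boundaries$angle_deg
  if (any(ang < 0 | ang >= 360) || is.unsorted(ang, strictly = TRUE))
    stop("boundary angles must be strictly increasing on [0, 360)",
         call. = FALSE)
  if (any(boundaries$outer_um <= boundaries$inner_um))
    stop("outer RNFL boundary must exceed inner boundary for every A-scan",
         call. = FALSE)
  structure(list(profiles = profiles, boundaries = boundaries,
                 laterality = laterality, n_ascans = nrow(boundaries),
                 ground_truth = ground_truth),
            class = "circ_scan")
}

#' @export
print.circ_scan <- function(x, ...) {
  cat(sprintf("circumpapillary PS-OCT scan: %d A-scans, %s eye, %d profile points\n",
              x$n_ascans, x$laterality, nrow(x$profiles)))
  invisible(x)
}

#' Partition a circumpapillary scan into TSNI quadrants
#'
#' Splits the A-scans of a circular scan into temporal, superior, nasal and
#' inferior quadrants. Quadrant centers sit at 0/90/180/270 degrees for a
#' right eye, each covering 90 degrees; left-eye scans are mirrored in angle
#' before assignment so quadrant labels stay anatomically consistent.
#'
#' @param scan a \code{\link{circ_scan}}.
#' @return Named list (\code{T}, \code{S}, \code{N}, \code{I}); each element
#'   holds \code{profiles} and \code{boundaries} subsets plus \code{n_ascans}.
#' @export
partition_quadrants <- function(scan) {
  stopifnot(inherits(scan, "circ_scan"))
  n <- scan$n_ascans
  if (n %% 4L != 0L)
    stop("number of A-scans (", n, ") is not divisible by 4", call. = FALSE)
  qb <- .quadrant_of_angle(scan$boundaries$angle_deg, scan$laterality)
  qp <- qb[match(scan$profiles$ascan_index, scan$boundaries$ascan_index)]
  out <- lapply(.QUADRANTS, function(q) {
    list(quadrant = q,
         profiles = scan$profiles[qp == q, , drop = FALSE],
         boundaries = scan$boundaries[qb == q, , drop = FALSE],
         n_ascans = sum(qb == q))
  })
  names(out) <- .QUADRANTS
  counts <- vapply(out, `[[`, integer(1), "n_ascans")
  if (any(counts != n / 4L))
    stop("quadrant partition is unbalanced: ", paste(counts, collapse = "/"),
         call. = FALSE)
  out
}

#' Normalize a retardation-depth profile to its first sample
#'
#' Shifts a profile so that its first point lies at depth 0 and retardation 0
#' (the RNFL inner surface becomes the origin). A pure translation, so the
#' least-squares slope of retardation versus depth is unchanged.
#'
#' @param profile data.frame with columns \code{depth_um} and
#'   \code{retardation_deg}, depths non-decreasing.
#' @return The shifted profile.
#' @export
normalize_profile <- function(profile) {
  if (is.null(profile) || nrow(profile) == 0L)
    stop("empty retardation profile", call. = FALSE)
  profile$depth_um <- profile$depth_um - profile$depth_um[1L]
  profile$retardation_deg <- profile$retardation_deg - profile$retardation_deg[1L]
  profile
}

#' Fit phase retardation per unit depth (PR/UD) for one quadrant
#'
#' Pools the (depth, retardation) points of all A-scans in a quadrant and
#' fits one ordinary least-squares line, retardation = a + b * depth. The
#' PR/UD is the slope b expressed per 100 um of depth (degree/100 um),
#' proportional to RNFL birefringence.
#'
#' @param quadrant_profiles a single profile data.frame or a list of them
#'   (columns \code{depth_um}, \code{retardation_deg}).
#' @return Slope in degree/100 um with attributes \code{n_points} and
#'   \code{intercept}.
#' @export
fit_pr_ud <- function(quadrant_profiles) {
  if (is.data.frame(quadrant_profiles)) quadrant_profiles <- list(quadrant_profiles)
  depth <- unlist(lapply(quadrant_profiles, `[[`, "depth_um"), use.names = FALSE)
  ret <- unlist(lapply(quadrant_profiles, `[[`, "retardation_deg"), use.names = FALSE)
  n <- length(depth)
  if (n < 2L)
    stop("need at least 2 points to fit PR/UD", call. = FALSE)
  if (length(unique(depth)) < 2L)
    stop("degenerate fit: all depths identical", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, depth), ret)
  slope <- unname(fit$coefficients[2L]) * 100
  structure(slope, n_points = n, intercept = unname(fit$coefficients[1L]))
}

#' Mean RNFL thickness of a quadrant segment
#'
#' Mean of (outer - inner) RNFL boundary depth over the quadrant's A-scans,
#' in micrometres. Circular scans cannot be magnification-corrected with
#' Bennett's formula, so the thickness is reported uncorrected.
#'
#' @param segment one element of \code{\link{partition_quadrants}} output
#'   (or any list with a \code{boundaries} data.frame).
#' @return Mean thickness in um.
#' @export
rnfl_thickness <- function(segment) {
  b <- segment$boundaries
  if (is.null(b) || nrow(b) == 0L || anyNA(b$inner_um) || anyNA(b$outer_um))
    stop("missing RNFL boundary data", call. = FALSE)
  mean(b$outer_um - b$inner_um)
}

#' Per-quadrant and average PR/UD and RNFL thickness for a scan
#'
#' Runs the full birefringence chain: quadrant partitioning, per-A-scan
#' profile normalization, pooled least-squares PR/UD fit per quadrant, and
#' mean RNFL thickness per quadrant. The scan-average PR/UD is the unweighted
#' mean of the four quadrant slopes.
#'
#' @param scan a \code{\link{circ_scan}}.
#' @return Object of class \code{quadrant_result}: named \code{pr_ud} and
#'   \code{thickness_um} vectors (T, S, N, I), their averages, and the number
#'   of points used in each fit.
#' @export
summarize_scan <- function(scan) {
  quads <- partition_quadrants(scan)
  pr_ud <- thick <- npts <- setNames(numeric(4), .QUADRANTS)
  for (q in .QUADRANTS) {
    seg <- quads[[q]]
    prof <- seg$profiles
    # per-A-scan normalization to the first sample, vectorised: profiles are
    # depth-ordered within each A-scan, so the first row per index is the
    # inner-boundary sample
    first <- !duplicated(prof$ascan_index)
    at <- match(prof$ascan_index, prof$ascan_index[first])
    norm <- data.frame(
      depth_um = prof$depth_um - prof$depth_um[first][at],
      retardation_deg = prof$retardation_deg - prof$retardation_deg[first][at])
    s <- fit_pr_ud(norm)
    pr_ud[q] <- as.numeric(s)
    npts[q] <- attr(s, "n_points")
    thick[q] <- rnfl_thickness(seg)
  }
  structure(list(pr_ud = pr_ud,
                 average_pr_ud = mean(pr_ud),
                 thickness_um = thick,
                 average_thickness_um = mean(thick),
                 n_points_fit = npts,
                 laterality = scan$laterality),
            class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat("PR/UD (degree/100 um):\n")
  print(round(x$pr_ud, 3))
  cat(sprintf("average PR/UD: %.3f degree/100 um\n", x$average_pr_ud))
  cat("RNFL thickness (um):\n")
  print(round(x$thickness_um, 1))
  cat(sprintf("average thickness: %.1f um\n", x$average_thickness_um))
  invisible(x)
}
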