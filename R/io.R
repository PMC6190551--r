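#' Write / read an angiogram as 8-bit grayscale PNG plus JSON sidecar
#'
#' The sidecar records \code{field_mm}, \code{plexus}, \code{axial_length_mm}
#' and \code{laterality} (and, when present, generator ground truth other
#' than image-sized matrices).
#'
#' @param ang an \code{\link{angiogram}}.
#' @param png_path output PNG path.
#' @param json_path output JSON path; default replaces the extension.
#' @return Invisibly, the two paths.
#' @export
write_angiogram <- function(ang, png_path,
                            json_path = sub("\\.png$", ".json", png_path)) {
  stopifnot(inherits(ang, "angiogram"))
  png::writePNG(ang$pixels, png_path)
  meta <- list(field_mm = ang$field_mm, plexus = ang$plexus,
               axial_length_mm = ang$axial_length_mm,
               laterality = ang$laterality)
  if (!is.null(ang$ground_truth)) {
    gt <- ang$ground_truth
    gt$vessel_mask <- NULL; gt$class_map <- NULL   # image-sized; regenerate
    gt$params <- unclass(gt$params)
    meta$ground_truth <- gt
  }
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, json_path))
}

#' @rdname write_angiogram
#' @param png_path PNG path to read.
#' @export
read_angiogram <- function(png_path,
                           json_path = sub("\\.png$", ".json", png_path)) {
  px <- png::readPNG(png_path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  angiogram(px, field_mm = meta$field_mm, plexus = meta$plexus,
            axial_length_mm = meta$axial_length_mm,
            laterality = meta$laterality,
            ground_truth = meta$ground_truth)
}

#' Write / read a circumpapillary scan as CSV plus JSON sidecar
#'
#' The CSV holds the profile table (\code{ascan_index}, \code{angle_deg},
#' \code{depth_um}, \code{retardation_deg}); the sidecar holds laterality,
#' RNFL boundaries and any generator ground truth.
#'
#' @param scan a \code{\link{circ_scan}}.
#' @param csv_path output CSV path.
#' @param json_path output JSON path.
#' @return Invisibly, the two paths.
#' @export
write_scan <- function(scan, csv_path,
                       json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(scan, "circ_scan"))
  utils::write.csv(scan$profiles, csv_path, row.names = FALSE)
  gt <- scan$ground_truth
  if (!is.null(gt) && !is.null(gt$params)) gt$params <- unclass(gt$params)
  jsonlite::write_json(list(laterality = scan$laterality,
                            boundaries = scan$boundaries,
                            ground_truth = gt),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' @rdname write_scan
#' @export
read_scan <- function(csv_path,
                      json_path = sub("\\.csv$", ".json", csv_path)) {
  profiles <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  circ_scan(profiles, as.data.frame(meta$boundaries),
            laterality = meta$laterality, ground_truth = meta$ground_truth)
}

#' Write / read cohort and velocity tables as CSV
#'
#' @param x a \code{cohort_table} or velocity data.frame.
#' @param path CSV path.
#' @return \code{write_table_csv}: the path, invisibly;
#'   \code{read_cohort_csv}: a \code{cohort_table};
#'   \code{read_velocity_csv}: a velocity data.frame.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path)
  out$group <- factor(out$group, levels = intersect(c("HC", "MM", "HM"),
                                                    unique(out$group)))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @rdname write_table_csv
#' @export
read_velocity_csv <- function(path) {
  utils::read.csv(path)
}

#' Write a study report or density result as JSON
#'
#' @param x a \code{study_report}, \code{density_result},
#'   \code{quadrant_result} or \code{eye_velocity_summary}.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(.report_to_list(x), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}

.report_to_list <- function(x) {
  if (inherits(x, "study_report")) {
    list(anova = lapply(x$anova, function(a)
           a[c("F", "p", "df_between", "df_within")]),
         pairwise = x$pairwise,
         correlations = x$correlations,
         regression = x$regression[c("F", "p", "r_squared", "df1", "df2", "n")],
         n_dropped = as.list(x$n_dropped))
  } else if (inherits(x, "density_result")) {
    x$maps <- NULL
    unclass(x)
  } else {
    unclass(x)
  }
}
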