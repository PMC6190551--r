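#' Validate an RFI per-vessel velocity table
#'
#' Checks the sign convention (arteriolar flow toward the fovea is negative,
#' venular flow away is positive): records violating it are kept but
#' flagged. Records with a branch order outside {2, 3, 4} are rejected
#' (the measurement covers the second to fourth vessel branches).
#'
#' @param records data.frame with columns \code{vessel_id},
#'   \code{vessel_type} ("arteriole"/"venule"), \code{branch_order},
#'   \code{velocity_mm_s}.
#' @return List: \code{records} (kept rows), \code{warnings} (character),
#'   \code{n_rejected}.
#' @export
validate_records <- function(records) {
  need <- c("vessel_id", "vessel_type", "branch_order", "velocity_mm_s")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("velocity table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad_rows <- which(!records$vessel_type %in% c("arteriole", "venule") |
                    !is.finite(records$velocity_mm_s))
  if (length(bad_rows))
    stop("unparsable velocity rows: ", paste(bad_rows, collapse = ", "),
         call. = FALSE)
  warnings <- character(0)
  reject <- !records$branch_order %in% c(2, 3, 4)
  if (any(reject))
    warnings <- c(warnings, sprintf(
      "rejected %d record(s) with branch order outside {2,3,4}: %s",
      sum(reject), paste(records$vessel_id[reject], collapse = ", ")))
  kept <- records[!reject, , drop = FALSE]
  viol <- (kept$vessel_type == "arteriole" & kept$velocity_mm_s > 0) |
          (kept$vessel_type == "venule" & kept$velocity_mm_s < 0)
  if (any(viol))
    warnings <- c(warnings, sprintf(
      "sign-convention violation (kept) in: %s",
      paste(kept$vessel_id[viol], collapse = ", ")))
  list(records = kept, warnings = warnings, n_rejected = sum(reject))
}

#' Bennett-compensate RFI velocities for ocular magnification
#'
#' Multiplies every velocity by the ratio of the eye's Bennett scaling
#' factor to the emmetropic reference factor (linear lateral-magnification
#' scaling), so velocities from elongated eyes are expressed on a common
#' retinal scale. A single multiplicative constant per eye: ratios between
#' vessels are preserved exactly.
#'
#' @param records velocity data.frame (see \code{\link{validate_records}}).
#' @param axial_length_mm axial length of the eye, mm.
#' @param reference_al_mm reference axial length, default 23.95 mm.
#' @return The records with scaled \code{velocity_mm_s} and an added
#'   attribute \code{compensation_factor}.
#' @export
compensate_velocity <- function(records, axial_length_mm,
                                reference_al_mm = 23.95) {
  k <- bennett_scaling_factor(axial_length_mm) /
    bennett_scaling_factor(reference_al_mm)
  records$velocity_mm_s <- records$velocity_mm_s * k
  attr(records, "compensation_factor") <- k
  records
}

#' Summarize per-eye blood-flow speed
#'
#' Mean speed (magnitude of signed velocity) per vessel type. A vessel type
#' with no records has its mean omitted (NA) and is flagged.
#'
#' @param records velocity data.frame.
#' @return Object of class \code{eye_velocity_summary}:
#'   \code{mean_arteriolar_speed}, \code{mean_venular_speed},
#'   \code{n_arterioles}, \code{n_venules}, \code{missing_classes}.
#' @export
summarize_eye <- function(records) {
  a <- abs(records$velocity_mm_s[records$vessel_type == "arteriole"])
  v <- abs(records$velocity_mm_s[records$vessel_type == "venule"])
  missing <- c("arteriole", "venule")[c(length(a) == 0, length(v) == 0)]
  structure(list(
    mean_arteriolar_speed = if (length(a)) mean(a) else NA_real_,
    mean_venular_speed = if (length(v)) mean(v) else NA_real_,
    n_arterioles = length(a), n_venules = length(v),
    missing_classes = missing),
    class = "eye_velocity_summary")
}

#' @export
print.eye_velocity_summary <- function(x, ...) {
  cat(sprintf("eye blood-flow summary: arteriolar %.2f mm/s (n=%d), venular %.2f mm/s (n=%d)\n",
              x$mean_arteriolar_speed, x$n_arterioles,
              x$mean_venular_speed, x$n_venules))
  if (length(x$missing_classes))
    cat("missing classes:", paste(x$missing_classes, collapse = ", "), "\n")
  invisible(x)
}
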