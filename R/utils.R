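# internal helpers shared across modules

# shift a matrix by (dr, dc) with zero fill; used by the vectorised thinning
# and class-propagation passes
.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(TRUE)
}

# quadrant codes in fixed anatomical order
.QUADRANTS <- c("T", "S", "N", "I")

.check_laterality <- function(laterality) {
  if (!is.character(laterality) || length(laterality) != 1L ||
      !laterality %in% c("OD", "OS"))
    stop("laterality must be \"OD\" (right eye) or \"OS\" (left eye)",
         call. = FALSE)
  laterality
}

# named-vector coercion for per-quadrant parameters
.as_quadrant_vector <- function(x, name) {
  if (length(x) == 1L) x <- rep(x, 4L)
  if (length(x) != 4L)
    stop(sprintf("'%s' must have length 1 or 4 (T, S, N, I)", name),
         call. = FALSE)
  if (is.null(names(x))) names(x) <- .QUADRANTS
  x[.QUADRANTS]
}
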