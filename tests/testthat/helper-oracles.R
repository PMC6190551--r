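# independent oracles used across tests; deliberately naive implementations

# closed-form OLS slope from the normal equations
ols_slope_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# nested-loop box counter: for each box of the grid anchored at the point-set
# bounding-box minimum, scan all points for membership
brute_force_box_counts <- function(binary, sizes) {
  pts <- which(binary != 0, arr.ind = TRUE)
  x <- pts[, 2]; y <- pts[, 1]
  x0 <- min(x); y0 <- min(y)
  vapply(sizes, function(s) {
    nx <- floor((max(x) - x0) / s) + 1
    ny <- floor((max(y) - y0) / s) + 1
    cnt <- 0L
    for (i in seq_len(nx) - 1) {
      lo_x <- x0 + i * s; hi_x <- x0 + (i + 1) * s
      in_x <- x >= lo_x & x < hi_x
      if (!any(in_x)) next
      for (j in seq_len(ny) - 1) {
        lo_y <- y0 + j * s; hi_y <- y0 + (j + 1) * s
        if (any(in_x & y >= lo_y & y < hi_y)) cnt <- cnt + 1L
      }
    }
    cnt
  }, numeric(1))
}

# mirror a circumpapillary scan in angle and flip its laterality label;
# anatomically the same eye recorded under the opposite-eye convention
mirror_scan <- function(scan) {
  mirror <- function(a) (360 - a) %% 360
  b <- scan$boundaries
  b$angle_deg <- mirror(b$angle_deg)
  p <- scan$profiles
  p$angle_deg <- mirror(p$angle_deg)
  ord_b <- order(b$angle_deg)
  b <- b[ord_b, ]
  ord_p <- order(p$angle_deg, p$depth_um)
  p <- p[ord_p, ]
  circ_scan(p, b, laterality = if (scan$laterality == "OD") "OS" else "OD",
            ground_truth = scan$ground_truth)
}

# 8-connected component count via an explicit pixel-adjacency graph
count_components8 <- function(m) {
  pts <- which(m, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) return(0L)
  id <- matrix(0L, nrow(m), ncol(m))
  id[pts] <- seq_len(n)
  edges <- integer(0)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    p2 <- cbind(pts[, 1] + d[1], pts[, 2] + d[2])
    ok <- p2[, 1] >= 1 & p2[, 1] <= nrow(m) & p2[, 2] >= 1 & p2[, 2] <= ncol(m)
    ok[ok] <- m[p2[ok, , drop = FALSE]]
    if (any(ok))
      edges <- c(edges, rbind(id[pts[ok, , drop = FALSE]],
                              id[p2[ok, , drop = FALSE]]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::gorder(g))
  igraph::components(g)$no
}

# straight horizontal bar mask
make_bar <- function(grid, width, len) {
  m <- matrix(FALSE, grid, grid)
  r0 <- floor((grid - width) / 2)
  c0 <- floor((grid - len) / 2)
  m[r0 + seq_len(width), c0 + seq_len(len)] <- TRUE
  m
}

# toy scan with chosen per-quadrant slopes/thickness, optionally noiseless
toy_scan <- function(slopes, thickness = c(T = 100, S = 120, N = 80, I = 110),
                     n_ascans = 32, noise_sd = 0, laterality = "OD",
                     seed = 1) {
  gen_circumpapillary_scan(scan_gen_params(
    n_ascans = n_ascans, true_slopes = slopes, thickness_um = thickness,
    noise_sd = noise_sd, laterality = laterality, seed = seed))
}
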