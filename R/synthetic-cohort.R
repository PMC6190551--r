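#' Parameters for the synthetic three-group cohort generator
#'
#' Defaults reproduce the study conditions of a three-group myopia cohort:
#' 29 healthy controls (HC), 22 moderate myopes (MM), 17 high myopes (HM);
#' axial length and spherical equivalent distributed per group as in the
#' study demographics (AL 24.34/25.39/26.94 +/- 0.72/1.16/0.63 mm;
#' SE -1.39/-4.63/-7.28 +/- 0.95/0.99/1.05 D); an isolated inferior-quadrant
#' PR/UD deficit in HM; macular vessel density (Dbox) ordered HC > MM > HM
#' with all pairwise separations; blood-flow velocities identical across
#' groups (null endpoint); and, by default, zero cross-correlation between
#' birefringence and vascular traits.
#'
#' All per-trait arguments are per-group vectors (HC, MM, HM) or, for PR/UD
#' and RNFL thickness, 3 x 4 matrices (rows = groups, columns = T, S, N, I).
#'
#' @param n_per_group group sizes, named (HC, MM, HM).
#' @param al_mean,al_sd axial length mean/SD per group, mm.
#' @param se_mean,se_sd spherical equivalent mean/SD per group, D.
#' @param pr_ud_mean 3 x 4 matrix of quadrant PR/UD means, degree/100 um.
#' @param pr_ud_sd quadrant PR/UD SD, degree/100 um (scalar).
#' @param rnfl_mean 3 x 4 matrix of quadrant RNFL thickness means, um.
#' @param rnfl_sd quadrant thickness SD, um (scalar).
#' @param dbox_sup_mean,dbox_deep_mean Dbox means per group.
#' @param dbox_sd Dbox SD (scalar).
#' @param arteriolar_mean,venular_mean speed means per group, mm/s.
#' @param arteriolar_sd,venular_sd speed SDs, mm/s (scalars).
#' @param biref_vascular_correlation latent correlation between the inferior
#'   PR/UD and deep Dbox traits (Gaussian copula); default 0.
#' @param quadrant_correlation equicorrelation between the four quadrant
#'   draws of PR/UD and of RNFL thickness within an eye (shared eye-level
#'   factor); default 0.5. Keeps per-quadrant marginal SDs unchanged while
#'   giving the per-eye average a realistically wide variance.
#' @param seed integer RNG seed.
#' @return List of class \code{cohort_gen_params}.
#' @export
cohort_gen_params <- function(n_per_group = c(HC = 29, MM = 22, HM = 17),
                              al_mean = c(24.34, 25.39, 26.94),
                              al_sd = c(0.72, 1.16, 0.63),
                              se_mean = c(-1.39, -4.63, -7.28),
                              se_sd = c(0.95, 0.99, 1.05),
                              pr_ud_mean = rbind(HC = c(10, 14, 10, 14),
                                                 MM = c(10, 14, 10, 14),
                                                 HM = c(10, 14, 10, 11.5)),
                              pr_ud_sd = 2,
                              rnfl_mean = rbind(HC = c(70, 120, 80, 130),
                                                MM = c(70, 120, 80, 130),
                                                HM = c(62, 110, 78, 120)),
                              rnfl_sd = 8,
                              dbox_sup_mean = c(1.72, 1.68, 1.64),
                              dbox_deep_mean = c(1.70, 1.66, 1.62),
                              dbox_sd = 0.025,
                              arteriolar_mean = c(3.8, 3.8, 3.8),
                              arteriolar_sd = 0.7,
                              venular_mean = c(2.9, 2.9, 2.9),
                              venular_sd = 0.6,
                              biref_vascular_correlation = 0,
                              quadrant_correlation = 0.5,
                              seed = 1L) {
  if (any(n_per_group < 2)) stop("group sizes must be >= 2", call. = FALSE)
  sds <- c(al_sd, se_sd, pr_ud_sd, rnfl_sd, dbox_sd, arteriolar_sd, venular_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (abs(biref_vascular_correlation) > 1)
    stop("biref_vascular_correlation must lie in [-1, 1]", call. = FALSE)
  if (quadrant_correlation < 0 || quadrant_correlation > 1)
    stop("quadrant_correlation must lie in [0, 1]", call. = FALSE)
  if (is.null(names(n_per_group))) names(n_per_group) <- c("HC", "MM", "HM")
  colnames(pr_ud_mean) <- colnames(rnfl_mean) <- .QUADRANTS
  structure(list(n_per_group = n_per_group,
                 al_mean = al_mean, al_sd = al_sd,
                 se_mean = se_mean, se_sd = se_sd,
                 pr_ud_mean = pr_ud_mean, pr_ud_sd = pr_ud_sd,
                 rnfl_mean = rnfl_mean, rnfl_sd = rnfl_sd,
                 dbox_sup_mean = dbox_sup_mean,
                 dbox_deep_mean = dbox_deep_mean, dbox_sd = dbox_sd,
                 arteriolar_mean = arteriolar_mean,
                 arteriolar_sd = arteriolar_sd,
                 venular_mean = venular_mean, venular_sd = venular_sd,
                 biref_vascular_correlation = biref_vascular_correlation,
                 quadrant_correlation = quadrant_correlation,
                 seed = as.integer(seed)),
            class = "cohort_gen_params")
}

#' Generate a synthetic per-eye cohort table
#'
#' One record per eye, traits drawn as independent Gaussians per group,
#' except the inferior PR/UD and deep Dbox pair, which share a bivariate
#' Gaussian copula with the configured cross-trait correlation (default 0).
#' The per-eye average PR/UD and average RNFL thickness are the unweighted
#' means of the four drawn quadrant values. Deterministic given the seed.
#'
#' @param params a \code{\link{cohort_gen_params}} object.
#' @return A \code{data.frame} of class \code{cohort_table} with columns
#'   \code{eye_id}, \code{group}, \code{laterality}, \code{axial_length_mm},
#'   \code{spherical_equivalent_d}, \code{pr_ud_t/s/n/i/avg},
#'   \code{rnfl_t/s/n/i/avg}, \code{dbox_superficial}, \code{dbox_deep},
#'   \code{arteriolar_speed}, \code{venular_speed}; ground truth in
#'   \code{attr(, "ground_truth")}.
#' @export
gen_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  set.seed(params$seed)
  groups <- names(params$n_per_group)
  rows <- lapply(seq_along(groups), function(gi) {
    n <- params$n_per_group[gi]
    # quadrant draws share an eye-level factor (equicorrelation rho_q) so
    # per-quadrant marginals keep the stated SD while the per-eye average
    # varies realistically
    rho_q <- params$quadrant_correlation
    equicorr <- function(means, s) {
      z_eye <- rnorm(n)
      sapply(1:4, function(q)
        means[q] + s * (sqrt(rho_q) * z_eye + sqrt(1 - rho_q) * rnorm(n)))
    }
    pr <- equicorr(params$pr_ud_mean[gi, ], params$pr_ud_sd)
    rn <- equicorr(params$rnfl_mean[gi, ], params$rnfl_sd)
    # bivariate copula for the inferior PR/UD x deep Dbox pair
    rho <- params$biref_vascular_correlation
    z1 <- if (params$pr_ud_sd > 0)
      (pr[, 4] - params$pr_ud_mean[gi, 4]) / params$pr_ud_sd else rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    dbox_deep <- params$dbox_deep_mean[gi] + params$dbox_sd * z2
    data.frame(group = groups[gi],
               laterality = sample(c("OD", "OS"), n, replace = TRUE),
               axial_length_mm = rnorm(n, params$al_mean[gi], params$al_sd[gi]),
               spherical_equivalent_d = rnorm(n, params$se_mean[gi],
                                              params$se_sd[gi]),
               pr_ud_t = pr[, 1], pr_ud_s = pr[, 2], pr_ud_n = pr[, 3],
               pr_ud_i = pr[, 4], pr_ud_avg = rowMeans(pr),
               rnfl_t = rn[, 1], rnfl_s = rn[, 2], rnfl_n = rn[, 3],
               rnfl_i = rn[, 4], rnfl_avg = rowMeans(rn),
               dbox_superficial = rnorm(n, params$dbox_sup_mean[gi],
                                        params$dbox_sd),
               dbox_deep = dbox_deep,
               arteriolar_speed = rnorm(n, params$arteriolar_mean[gi],
                                        params$arteriolar_sd),
               venular_speed = rnorm(n, params$venular_mean[gi],
                                     params$venular_sd))
  })
  out <- do.call(rbind, rows)
  out <- cbind(eye_id = sprintf("eye%03d", seq_len(nrow(out))), out)
  out$group <- factor(out$group, levels = groups)
  attr(out, "ground_truth") <- params
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Generate a synthetic per-vessel RFI velocity table for one eye
#'
#' Signed velocities follow the field convention: arteriolar flow toward the
#' fovea is negative, venular flow away from the fovea is positive. Branch
#' orders are drawn from {2, 3, 4}.
#'
#' @param n_arterioles,n_venules vessel counts.
#' @param arteriolar_mean,venular_mean mean speeds (magnitudes), mm/s.
#' @param arteriolar_sd,venular_sd speed SDs, mm/s.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{vessel_id}, \code{vessel_type},
#'   \code{branch_order}, \code{velocity_mm_s}; ground truth in
#'   \code{attr(, "ground_truth")}.
#' @export
gen_velocity_table <- function(n_arterioles = 6, n_venules = 6,
                               arteriolar_mean = 3.8, arteriolar_sd = 0.7,
                               venular_mean = 2.9, venular_sd = 0.6,
                               seed = 1L) {
  if (n_arterioles < 1 || n_venules < 1)
    stop("need at least one vessel of each type", call. = FALSE)
  set.seed(seed)
  speeds_a <- abs(rnorm(n_arterioles, arteriolar_mean, arteriolar_sd))
  speeds_v <- abs(rnorm(n_venules, venular_mean, venular_sd))
  out <- data.frame(
    vessel_id = c(sprintf("A%02d", seq_len(n_arterioles)),
                  sprintf("V%02d", seq_len(n_venules))),
    vessel_type = rep(c("arteriole", "venule"), c(n_arterioles, n_venules)),
    branch_order = sample(2:4, n_arterioles + n_venules, replace = TRUE),
    velocity_mm_s = c(-speeds_a, speeds_v))
  attr(out, "ground_truth") <- list(arteriolar_mean = arteriolar_mean,
                                    venular_mean = venular_mean)
  out
}
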