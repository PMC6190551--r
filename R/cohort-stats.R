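#' One-way analysis of variance
#'
#' Classic between/within decomposition computed from first principles:
#' F = (SSB / (k-1)) / (SSW / (N-k)), with the p value from the upper tail
#' of the central F distribution. Zero within-group variance with unequal
#' means yields F = Inf, p = 0 and a degenerate flag.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return List of class \code{anova_result}: \code{F}, \code{p},
#'   \code{df_between}, \code{df_within}, sums of squares, \code{mse},
#'   \code{group_means}, \code{group_n}, \code{degenerate}.
#' @export
one_way_anova <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  k <- nlevels(groups)
  n_g <- tabulate(groups)
  if (k < 2 || any(n_g < 2))
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  N <- length(values)
  gm <- setNames(as.numeric(tapply(values, groups, mean)), levels(groups))
  grand <- mean(values)
  ssb <- sum(n_g * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df_b <- k - 1L; df_w <- N - k
  mse <- ssw / df_w
  degenerate <- ssw < .Machine$double.eps * max(1, sum(values^2))
  if (degenerate && ssb > 0) {
    f <- Inf; p <- 0
  } else if (degenerate) {
    f <- 0; p <- 1
  } else {
    f <- (ssb / df_b) / mse
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(F = f, p = p, df_between = df_b, df_within = df_w,
                 ss_between = ssb, ss_within = ssw, ss_total = ssb + ssw,
                 mse = mse, group_means = gm, group_n = n_g,
                 degenerate = degenerate),
            class = "anova_result")
}

#' Fisher least-significant-difference post hoc tests
#'
#' For every pair of groups, t = (m_i - m_j) / sqrt(MSE (1/n_i + 1/n_j))
#' with the pooled ANOVA mean-square error on the within-group degrees of
#' freedom; two-sided p, no multiplicity adjustment (the LSD convention).
#' For k = 2 this reduces exactly to the pooled two-sample t test.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param anova optional precomputed \code{\link{one_way_anova}} result on
#'   the same data (recomputed when absent).
#' @return data.frame with one row per pair: \code{group_i}, \code{group_j},
#'   \code{mean_diff}, \code{se}, \code{t}, \code{p}, \code{df}.
#' @export
fisher_lsd <- function(values, groups, anova = NULL) {
  if (is.null(anova)) anova <- one_way_anova(values, groups)
  gm <- anova$group_means; n_g <- anova$group_n
  lv <- names(gm)
  pairs <- utils::combn(seq_along(lv), 2)
  out <- data.frame(group_i = lv[pairs[1, ]], group_j = lv[pairs[2, ]])
  out$mean_diff <- unname(gm[pairs[1, ]] - gm[pairs[2, ]])
  out$se <- unname(sqrt(anova$mse * (1 / n_g[pairs[1, ]] + 1 / n_g[pairs[2, ]])))
  if (anova$mse <= 0) {
    out$t <- ifelse(out$mean_diff == 0, 0, Inf * sign(out$mean_diff))
    out$p <- ifelse(out$mean_diff == 0, 1, 0)
    attr(out, "degenerate") <- TRUE
  } else {
    out$t <- out$mean_diff / out$se
    out$p <- 2 * stats::pt(abs(out$t), anova$df_within, lower.tail = FALSE)
  }
  out$df <- anova$df_within
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation with t-based p value
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return List: \code{r}, \code{t}, \code{p}, \code{n}.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, t = t, p = p, n = n)
}

#' Overall F test of a multiple linear regression
#'
#' Ordinary least squares via QR on the intercept-augmented design matrix;
#' overall F = (R^2 / p) / ((1 - R^2) / (N - p - 1)) against the null that
#' all slope coefficients are zero.
#'
#' @param y response vector.
#' @param predictors numeric matrix or data.frame of predictor columns.
#' @return List: \code{F}, \code{p}, \code{r_squared}, \code{coefficients},
#'   \code{df1}, \code{df2}, \code{n}.
#' @export
multiple_regression_overall <- function(y, predictors) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1)
    stop("need more observations than predictors plus intercept",
         call. = FALSE)
  D <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    drop_cols <- colnames(D)[qrd$pivot[(qrd$rank + 1):ncol(D)]]
    stop("collinear design: rank-deficient in column(s) ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrd, y)
  fitted <- drop(D %*% beta)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  r2 <- 1 - sse / sst
  df1 <- p; df2 <- n - p - 1
  if (sse <= .Machine$double.eps * sst) {
    f <- Inf; pv <- 0; r2 <- 1
  } else {
    f <- (r2 / df1) / ((1 - r2) / df2)
    pv <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, p = pv, r_squared = r2, coefficients = beta,
       df1 = df1, df2 = df2, n = n)
}

#' Total sample size for a one-way ANOVA at a target power
#'
#' Smallest balanced total N such that the noncentral-F power of the k-group
#' one-way ANOVA reaches the target, with noncentrality lambda = f^2 N
#' (Cohen's f).
#'
#' @param effect_f Cohen's f effect size (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param k_groups number of groups.
#' @return Total N (multiple of \code{k_groups}) with attribute
#'   \code{achieved_power}.
#' @export
anova_sample_size <- function(effect_f, alpha = 0.05, power = 0.80,
                              k_groups = 3) {
  .stopifnot_scalar_pos(effect_f, "effect_f")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie strictly between 0 and 1", call. = FALSE)
  k <- as.integer(k_groups)
  for (n_per in 2:ceiling(1e6 / k)) {
    N <- n_per * k
    df1 <- k - 1L; df2 <- N - k
    crit <- stats::qf(1 - alpha, df1, df2)
    pw <- stats::pf(crit, df1, df2, ncp = effect_f^2 * N, lower.tail = FALSE)
    if (pw >= power)
      return(structure(N, achieved_power = pw))
  }
  stop("target power unattainable within N <= 1e6", call. = FALSE)
}

#' Run the full cohort statistical analysis
#'
#' For every endpoint (quadrant and average PR/UD, quadrant and average RNFL
#' thickness, superficial/deep Dbox, arteriolar/venular speed, axial length,
#' spherical equivalent): one-way ANOVA across groups followed by Fisher LSD
#' pairwise tests (LSD is computed regardless of the omnibus p; both are
#' reported). Pearson correlations of average and inferior PR/UD against
#' axial length, refraction, speeds and densities. An overall multiple
#' regression of average PR/UD on refraction, axial length, speeds and
#' densities. Rows with missing values are dropped listwise per analysis and
#' counted.
#'
#' @param cohort a \code{cohort_table} data.frame (see
#'   \code{\link{gen_cohort}}).
#' @return Object of class \code{study_report}: \code{anova} (named list),
#'   \code{pairwise} (named list of LSD tables), \code{correlations}
#'   (data.frame), \code{regression}, \code{n_dropped}.
#' @export
run_study_analysis <- function(cohort) {
  endpoints <- c("pr_ud_t", "pr_ud_s", "pr_ud_n", "pr_ud_i", "pr_ud_avg",
                 "rnfl_t", "rnfl_s", "rnfl_n", "rnfl_i", "rnfl_avg",
                 "dbox_superficial", "dbox_deep",
                 "arteriolar_speed", "venular_speed",
                 "axial_length_mm", "spherical_equivalent_d")
  endpoints <- intersect(endpoints, names(cohort))
  anovas <- pairwise <- setNames(vector("list", length(endpoints)), endpoints)
  n_dropped <- setNames(integer(length(endpoints)), endpoints)
  for (e in endpoints) {
    ok <- is.finite(cohort[[e]])
    n_dropped[e] <- sum(!ok)
    a <- one_way_anova(cohort[[e]][ok], cohort$group[ok])
    anovas[[e]] <- a
    pairwise[[e]] <- fisher_lsd(cohort[[e]][ok], cohort$group[ok], a)
  }
  vascular <- c("axial_length_mm", "spherical_equivalent_d",
                "arteriolar_speed", "venular_speed",
                "dbox_superficial", "dbox_deep")
  vascular <- intersect(vascular, names(cohort))
  cors <- do.call(rbind, lapply(c("pr_ud_avg", "pr_ud_i"), function(b) {
    do.call(rbind, lapply(vascular, function(v) {
      ct <- tryCatch(pearson_correlation(cohort[[b]], cohort[[v]]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              n = sum(complete.cases(
                                                cohort[c(b, v)]))))
      data.frame(birefringence = b, against = v, r = ct$r, p = ct$p, n = ct$n)
    }))
  }))
  rownames(cors) <- NULL
  reg <- tryCatch(multiple_regression_overall(cohort$pr_ud_avg,
                                              cohort[vascular]),
                  error = function(e) list(F = NA_real_, p = NA_real_,
                                           r_squared = NA_real_,
                                           coefficients = NULL,
                                           df1 = length(vascular),
                                           df2 = NA_integer_,
                                           n = nrow(cohort),
                                           note = conditionMessage(e)))
  structure(list(anova = anovas, pairwise = pairwise, correlations = cors,
                 regression = reg, n_dropped = n_dropped),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("cohort analysis report\n")
  cat(sprintf("%-24s %10s %10s\n", "endpoint", "F", "p"))
  for (e in names(x$anova))
    cat(sprintf("%-24s %10.3f %10.4f\n", e, x$anova[[e]]$F, x$anova[[e]]$p))
  cat(sprintf("\nmultiple regression of average PR/UD: F = %.3f, p = %.3f, R^2 = %.3f (n = %d)\n",
              x$regression$F, x$regression$p, x$regression$r_squared,
              x$regression$n))
  invisible(x)
}
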