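# Clustered two-group comparison for fellow-eye data: a Gaussian-identity
# generalized estimating equation with exchangeable working correlation and
# cluster-robust (sandwich) standard errors, plus Bonferroni correction and
# the SCP:DCP ratio metrics.

# Moment-based GEE fit. y: response; X: design matrix (with intercept);
# cluster: cluster id vector. Returns coefficients, robust covariance,
# working correlation alpha and dispersion phi.
gee_gaussian <- function(y, X, cluster, maxit = 50, tol = 1e-10,
                         working = c("exchangeable", "independence")) {
  working <- match.arg(working)
  stopifnot(length(y) == nrow(X), length(cluster) == nrow(X))
  p <- ncol(X)
  n <- length(y)
  qrX <- qr(X)
  if (qrX$rank < p) stop("singular design matrix: a model term is constant ",
                         "or collinear")
  beta <- qr.coef(qrX, y)
  idx <- split(seq_len(n), cluster)
  alpha <- 0
  for (it in seq_len(maxit)) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (n - p)
    # exchangeable correlation moment estimator over within-cluster pairs
    pair_sum <- 0
    n_pairs <- 0
    for (ii in idx) {
      ni <- length(ii)
      if (ni < 2) next
      ei <- e[ii]
      pair_sum <- pair_sum + (sum(ei)^2 - sum(ei^2)) / 2
      n_pairs <- n_pairs + ni * (ni - 1) / 2
    }
    alpha <- if (n_pairs > p) pair_sum / phi / (n_pairs - p) else 0
    alpha <- min(max(alpha, 0), 0.99)
    if (working == "independence") alpha <- 0
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      Xi <- X[ii, , drop = FALSE]
      yi <- y[ii]
      # R^{-1} for exchangeable: (I - a/(1+(n-1)a) J) / (1-a)
      if (ni == 1) {
        Ri_inv <- matrix(1, 1, 1)
      } else {
        Ri_inv <- (diag(ni) - alpha / (1 + (ni - 1) * alpha) *
                     matrix(1, ni, ni)) / (1 - alpha)
      }
      A <- A + crossprod(Xi, Ri_inv %*% Xi)
      b <- b + crossprod(Xi, Ri_inv %*% yi)
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  # bias-corrected sandwich covariance (Mancl-DeRouen): cluster residuals
  # are inflated by (I - H_i)^{-1}, which counters the downward bias of the
  # plain sandwich under high-leverage covariates and few clusters
  e <- y - X %*% beta
  phi <- sum(e^2) / (n - p)
  A <- matrix(0, p, p)
  Vinv_list <- lapply(idx, function(ii) {
    ni <- length(ii)
    if (ni == 1) {
      matrix(1 / phi, 1, 1)
    } else {
      (diag(ni) - alpha / (1 + (ni - 1) * alpha) *
         matrix(1, ni, ni)) / (1 - alpha) / phi
    }
  })
  for (k in seq_along(idx)) {
    Xi <- X[idx[[k]], , drop = FALSE]
    A <- A + crossprod(Xi, Vinv_list[[k]] %*% Xi)
  }
  A_inv <- solve(A)
  B <- matrix(0, p, p)
  for (k in seq_along(idx)) {
    ii <- idx[[k]]
    Xi <- X[ii, , drop = FALSE]
    Hi <- Xi %*% A_inv %*% crossprod(Xi, Vinv_list[[k]])
    ei <- solve(diag(length(ii)) - Hi, e[ii])
    s <- crossprod(Xi, Vinv_list[[k]] %*% ei)
    B <- B + tcrossprod(s)
  }
  vcov <- A_inv %*% B %*% A_inv
  list(coefficients = setNames(as.numeric(beta), colnames(X)),
       vcov = vcov, alpha = alpha, phi = phi,
       n_obs = n, n_clusters = length(idx))
}

# Build one comparison_result from a fitted GEE and a coefficient name.
# Wald test against a t reference with (clusters - p) degrees of freedom,
# the usual finite-sample correction for cluster-robust inference.
gee_result <- function(fit, term, metric) {
  est <- fit$coefficients[[term]]
  se <- sqrt(diag(fit$vcov))[[which(names(fit$coefficients) == term)]]
  z <- est / se
  df <- max(fit$n_clusters - length(fit$coefficients), 1)
  p <- 2 * stats::pt(-abs(z), df = df)
  structure(
    list(metric = metric, estimate = est, se = se, p_raw = p,
         p_bonferroni = NA_real_, n_eyes = fit$n_obs,
         n_clusters = fit$n_clusters, alpha = fit$alpha),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "%s: estimate %.4f (robust SE %.4f), p = %.4g%s  [%d eyes, %d patients]\n",
    x$metric, x$estimate, x$se, x$p_raw,
    if (is.na(x$p_bonferroni)) "" else
      sprintf(" (Bonferroni %.4g)", x$p_bonferroni),
    x$n_eyes, x$n_clusters))
  invisible(x)
}

#' Compare one metric between DME and no-DME eyes
#'
#' Fits the marginal linear model `metric ~ dme + dr_stage` with patients as
#' clusters, exchangeable working correlation and cluster-robust standard
#' errors, and returns the DME coefficient with its two-sided p value.
#'
#' @param table cohort data frame (see [make_cohort]) with columns
#'   `patient_id`, `dme`, `dr_stage` and the metric.
#' @param metric metric column name, e.g. `"scp_gpd_pct"`.
#' @param adjust_stage adjust for DR stage (default TRUE).
#' @param working working correlation structure: `"exchangeable"`
#'   (default) or `"independence"`.
#' @return A `comparison_result`: `estimate`, `se`, `p_raw`,
#'   `p_bonferroni` (NA until a family correction is applied), `n_eyes`,
#'   `n_clusters`.
#' @export
compare_groups <- function(table, metric, adjust_stage = TRUE,
                           working = c("exchangeable", "independence")) {
  working <- match.arg(working)
  stopifnot(is.data.frame(table), metric %in% names(table))
  keep <- !is.na(table[[metric]])
  table <- table[keep, , drop = FALSE]
  if (length(unique(table$dme)) < 2) {
    stop("all eyes are in one DME group: no comparison possible")
  }
  for (g in c(TRUE, FALSE)) {
    if (length(unique(table$patient_id[table$dme == g])) < 2) {
      stop("need at least 2 patient clusters per group")
    }
  }
  if (stats::var(table[[metric]]) == 0) {
    stop("singular design: metric is constant")
  }
  X <- cbind(`(Intercept)` = 1, dme = as.numeric(table$dme))
  if (adjust_stage) {
    stage <- as.numeric(table$dr_stage == "PDR")
    if (length(unique(stage)) > 1) X <- cbind(X, stage_pdr = stage)
  }
  fit <- gee_gaussian(table[[metric]], X, table$patient_id,
                      working = working)
  gee_result(fit, "dme", metric)
}

#' Bonferroni correction
#'
#' @param p_values vector of raw p values in \[0, 1\].
#' @param m family size; defaults to `length(p_values)`.
#' @return Adjusted p values, each `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), m >= 1)
  pmin(1, p_values * m)
}

#' Compare every metric between groups with Bonferroni correction
#'
#' Runs [compare_groups] for each metric column and applies the Bonferroni
#' correction over the family.
#'
#' @param table cohort data frame.
#' @param metrics metric column names; defaults to every `scp_`/`dcp_`
#'   metric column plus `faz_area_mm2` present in the table.
#' @param m Bonferroni family size; defaults to the number of metrics.
#' @param adjust_stage adjust for DR stage.
#' @return A data frame with one row per metric: estimate, robust SE, raw
#'   and Bonferroni-corrected p values, eyes and clusters.
#' @export
compare_all_metrics <- function(table, metrics = NULL, m = NULL,
                                adjust_stage = TRUE) {
  if (is.null(metrics)) {
    metrics <- intersect(
      c("faz_area_mm2", grep("^(scp|dcp)_", names(table), value = TRUE)),
      names(table))
  }
  if (is.null(m)) m <- length(metrics)
  rows <- lapply(metrics, function(mt) {
    r <- compare_groups(table, mt, adjust_stage = adjust_stage)
    data.frame(metric = mt, estimate = r$estimate, se = r$se,
               p_raw = r$p_raw, n_eyes = r$n_eyes,
               n_clusters = r$n_clusters, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p_raw, m = m)
  out
}

#' SCP:DCP ratio metrics
#'
#' Per-eye ratios of the superficial to the deep plexus for the
#' nonperfusion and density metrics; a ratio is missing when its DCP
#' denominator is 0 or missing.
#'
#' @param table cohort data frame with `scp_`/`dcp_` metric columns.
#' @return The table with added columns `cnp_ratio`, `gpd_ratio`,
#'   `vd_ratio`.
#' @export
plexus_ratios <- function(table) {
  safe_div <- function(a, b) ifelse(!is.na(b) & b != 0, a / b, NA_real_)
  table$cnp_ratio <- safe_div(table$scp_cnp_pct, table$dcp_cnp_pct)
  table$gpd_ratio <- safe_div(table$scp_gpd_pct, table$dcp_gpd_pct)
  table$vd_ratio <- safe_div(table$scp_vd, table$dcp_vd)
  table
}

#' Within-subgroup association of a metric with central subfield thickness
#'
#' Fits the clustered marginal model `metric ~ cst_um` within the DME or
#' no-DME subgroup with cluster-robust standard errors.
#'
#' @param table cohort data frame.
#' @param subgroup `"DME"` or `"noDME"`.
#' @param metric metric column name.
#' @return A `comparison_result` for the CST coefficient (per micrometre).
#' @export
cst_association <- function(table, subgroup = c("DME", "noDME"), metric) {
  subgroup <- match.arg(subgroup)
  stopifnot(metric %in% names(table), "cst_um" %in% names(table))
  sel <- if (subgroup == "DME") table$dme else !table$dme
  table <- table[sel & !is.na(table[[metric]]), , drop = FALSE]
  if (nrow(table) == 0) stop("subgroup is empty")
  if (length(unique(table$patient_id)) < 2) {
    stop("need at least 2 patient clusters in the subgroup")
  }
  if (stats::var(table[[metric]]) == 0) {
    stop("singular design: metric is constant in the subgroup")
  }
  X <- cbind(`(Intercept)` = 1, cst_um = table$cst_um)
  fit <- gee_gaussian(table[[metric]], X, table$patient_id)
  gee_result(fit, "cst_um", paste0(metric, " ~ CST (", subgroup, ")"))
}

#' Demographic group comparisons
#'
#' Conventional unclustered comparisons of the clinical covariates between
#' DME groups: Welch t tests for continuous variables, chi-square for
#' categorical ones.
#'
#' @param table cohort data frame.
#' @return A data frame with variable, test and p value.
#' @export
compare_demographics <- function(table) {
  res <- list()
  for (v in intersect(c("cst_um", "bcva_logmar"), names(table))) {
    t <- stats::t.test(table[[v]][table$dme], table[[v]][!table$dme])
    res[[v]] <- data.frame(variable = v, test = "t", p = t$p.value)
  }
  if ("dr_stage" %in% names(table)) {
    ct <- table(table$dr_stage, table$dme)
    if (all(dim(ct) == c(2, 2))) {
      p <- stats::chisq.test(ct, correct = FALSE)$p.value
      res$dr_stage <- data.frame(variable = "dr_stage", test = "chi-square",
                                 p = p)
    }
  }
  do.call(rbind, res)
}
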