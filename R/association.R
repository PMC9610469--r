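# Phage-phenotype association scanning: logistic regression of phage
# detection on a phenotype with covariate adjustment (age + sex, and
# optionally the log-transformed abundance of the predicted host),
# Benjamini-Hochberg multiple-testing correction within each analysis.

#' Logistic regression of phage detection on a phenotype
#'
#' Fits `outcome ~ phenotype + covariates` with a binomial GLM (IRLS,
#' convergence tolerance 1e-8, up to 100 iterations) and returns the Wald
#' two-sided test of the phenotype coefficient. Fits showing complete
#' separation or non-convergence are flagged so callers can exclude them
#' from multiple-testing correction.
#'
#' @param outcome logical (or 0/1) vector of phage detections.
#' @param predictor numeric phenotype vector.
#' @param covariates data.frame of adjustment covariates (may be empty).
#' @return list with `beta`, `se`, `p` (for the phenotype coefficient)
#'   and `flagged` (separation / non-convergence).
#' @export
fit_logistic <- function(outcome, predictor, covariates = NULL) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("outcome is constant; both classes are required")
  df <- data.frame(.y = y, .x = predictor)
  if (!is.null(covariates) && ncol(covariates) > 0L)
    df <- cbind(df, covariates)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (!".x" %in% rownames(co))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, flagged = TRUE))
  flagged <- sep_warn || !fit$converged || abs(co[".x", "Estimate"]) > 15
  list(beta = co[".x", "Estimate"], se = co[".x", "Std. Error"],
       p = co[".x", "Pr(>|z|)"], flagged = flagged)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH q-values for a vector of p-values (a thin wrapper over
#' [stats::p.adjust()] with input validation).
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA`s propagate.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Phage-phenotype association scan
#'
#' For every (vOTU, phenotype) combination fits two logistic regressions
#' of detection on the phenotype: the base model adjusted for age and
#' sex, and the host-adjusted model additionally including the
#' log-transformed abundance of the vOTU's predicted host (zeros handled
#' with a pseudocount of half the smallest nonzero host abundance in the
#' analysis). Continuous phenotypes are standardized. BH correction is
#' applied within each model family; vOTUs never or always detected in
#' the analyzed samples are skipped, as are flagged (separated or
#' non-convergent) fits.
#'
#' @param detections logical matrix, samples x vOTUs.
#' @param phenotypes data.frame of phenotype columns (numeric; binary
#'   phenotypes as 0/1).
#' @param covariates data.frame with columns `age` and `sex` (sex coded
#'   0/1).
#' @param host_abundance optional numeric matrix, samples x vOTUs, of
#'   predicted-host abundances; columns matching `detections`. vOTUs
#'   without a host column get `NA` host-adjusted results.
#' @return data.frame with columns `votu`, `phenotype`, `model`
#'   (`"base"`/`"host_adjusted"`), `beta`, `se`, `p`, `fdr`,
#'   `significant` (fdr < `fdr_threshold`), `flagged`.
#' @param fdr_threshold significance threshold on the q-value.
#' @export
association_scan <- function(detections, phenotypes, covariates,
                             host_abundance = NULL, fdr_threshold = 0.05) {
  stopifnot(nrow(detections) == nrow(phenotypes),
            nrow(detections) == nrow(covariates))
  votus <- colnames(detections)
  std <- function(x) {
    ux <- unique(x[!is.na(x)])
    if (length(ux) > 2L && sd(x, na.rm = TRUE) > 0)
      (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
    else x
  }
  pseudo <- NA_real_
  if (!is.null(host_abundance)) {
    nz <- host_abundance[host_abundance > 0]
    pseudo <- if (length(nz) > 0L) min(nz) / 2 else 1
  }
  rows <- list()
  for (v in votus) {
    y <- detections[, v]
    if (length(unique(y)) < 2L) next        # never/always detected
    host_cov <- NULL
    if (!is.null(host_abundance) && v %in% colnames(host_abundance))
      host_cov <- log(host_abundance[, v] + pseudo)
    for (ph in colnames(phenotypes)) {
      x <- std(phenotypes[[ph]])
      base <- fit_logistic(y, x, covariates)
      rows[[length(rows) + 1L]] <- data.frame(
        votu = v, phenotype = ph, model = "base",
        beta = base$beta, se = base$se, p = base$p, flagged = base$flagged)
      if (!is.null(host_cov)) {
        adj <- fit_logistic(y, x, cbind(covariates, log_host = host_cov))
        rows[[length(rows) + 1L]] <- data.frame(
          votu = v, phenotype = ph, model = "host_adjusted",
          beta = adj$beta, se = adj$se, p = adj$p, flagged = adj$flagged)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(votu = character(), phenotype = character(),
                      model = character(), beta = numeric(), se = numeric(),
                      p = numeric(), fdr = numeric(), significant = logical(),
                      flagged = logical()))
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (m in unique(res$model)) {
    sel <- res$model == m & !res$flagged
    res$fdr[sel] <- bh_fdr(res$p[sel])
  }
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_threshold
  rownames(res) <- NULL
  res
}
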