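# Phenotype adjustment, single-SNP association, pairwise interaction
# regression, and polygenic-score construction. The interaction model is
#   Y = b0 + b1*gA + b2*gB + b3*gA*gB (+ b4*PRS)
# fitted by ordinary least squares on the covariate-adjusted phenotype; the
# reported test is the two-sided Student-t test of b3 = 0 with residual
# degrees of freedom.

#' Adjust a binary phenotype for covariates
#'
#' Fits a logistic regression of the case/control status on an intercept
#' plus the covariates (iteratively reweighted least squares) and returns
#' the response residuals `y - fitted probability`. These residuals are the
#' phenotype used by every downstream association test, mirroring the
#' common workaround for interaction scans that cannot take covariates.
#'
#' @param y binary vector in `{0, 1}`.
#' @param covariates optional numeric matrix (columns are e.g. ancestry
#'   principal components); an intercept is always included.
#' @return An `adjusted_phenotype`: list with `values` (residuals) and
#'   `provenance` (covariate names used).
#' @export
adjust_phenotype <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_netepi("validation", "y must be binary 0/1")
  if (is.null(covariates) || NCOL(covariates) == 0) {
    fitted <- rep(mean(y), length(y))
    prov <- character(0)
  } else {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
    }
    X <- cbind(`(Intercept)` = 1, covariates)
    if (qr(X)$rank < ncol(X)) {
      stop_netepi("validation", "covariate matrix is rank deficient")
    }
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = list(epsilon = 1e-12, maxit = 100L))
    )
    fitted <- fit$fitted.values
    if (any(fitted < 1e-10 | fitted > 1 - 1e-10)) {
      j <- which.max(abs(fit$coefficients[-1]))
      stop_netepi("separation",
                  "perfect separation suspected (covariate %s drives fitted probabilities to 0/1)",
                  colnames(covariates)[j])
    }
    prov <- colnames(covariates)
  }
  structure(list(values = y - fitted, provenance = prov),
            class = "adjusted_phenotype")
}

as_y_values <- function(y_adj) {
  if (inherits(y_adj, "adjusted_phenotype")) y_adj$values else as.numeric(y_adj)
}

#' Single-SNP linear association
#'
#' Simple linear regression of the adjusted phenotype on one dosage column
#' (complete-case); Wald-type two-sided p-value from the Student-t with
#' `n - 2` degrees of freedom.
#'
#' @param g dosage column.
#' @param y_adj adjusted phenotype (vector or [adjust_phenotype()] output).
#' @return list with `beta`, `se`, `p`, `n_used`, `flag` (`NA` or
#'   `"monomorphic"`; flagged results are excluded downstream).
#' @export
single_snp_assoc <- function(g, y_adj) {
  y <- as_y_values(y_adj)
  ok <- !is.na(g) & !is.na(y)
  g2 <- g[ok]; y2 <- y[ok]
  n <- length(g2)
  if (n < 3L) stop_netepi("validation", "need >= 3 complete cases")
  if (stats::var(g2) == 0) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n_used = n,
                flag = "monomorphic"))
  }
  sxx <- sum((g2 - mean(g2))^2)
  beta <- sum((g2 - mean(g2)) * y2) / sxx
  resid <- y2 - mean(y2) - beta * (g2 - mean(g2))
  rss <- sum(resid^2)
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  tstat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- clamp_p(2 * stats::pt(-abs(tstat), df = n - 2))
  list(beta = beta, se = se, p = p, n_used = n, flag = NA_character_)
}

# Core OLS engine: one SNP pair design [1, gA, gB, gA*gB, extra...] against
# one or many phenotype vectors (columns of Y). Returns the b3 row of the
# coefficient solve, its t statistic and p-value per phenotype. Degenerate
# (rank-deficient) designs yield p = 1 with a reason.
pair_ols <- function(ga, gb, Y, extra = NULL, y_ok = NULL) {
  Y <- as.matrix(Y)
  if (is.null(y_ok)) y_ok <- rowSums(is.na(Y)) == 0L
  ok <- !is.na(ga) & !is.na(gb) & y_ok
  if (!is.null(extra)) ok <- ok & rowSums(is.na(as.matrix(extra))) == 0L
  X <- cbind(1, ga, gb, ga * gb)
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  if (all(ok)) {
    Yc <- Y
  } else {
    X <- X[ok, , drop = FALSE]
    Yc <- Y[ok, , drop = FALSE]
  }
  n <- nrow(X)
  k <- ncol(X)
  nb <- ncol(Yc)
  fail <- function(reason) {
    list(beta3 = rep(NA_real_, nb), se3 = rep(NA_real_, nb),
         stat = rep(NA_real_, nb), p = rep(1, nb), n_used = n,
         degenerate = TRUE, reason = reason)
  }
  if (n < k + 1L) return(fail("too few complete cases"))
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || any(diag(R) < sqrt(.Machine$double.eps) * sqrt(max(diag(XtX))))) {
    return(fail("rank-deficient design"))
  }
  XtY <- crossprod(X, Yc)                       # k x nb
  beta <- backsolve(R, forwardsolve(t(R), XtY)) # k x nb
  rss <- pmax(colSums(Yc * Yc) - colSums(XtY * beta), 0)
  inv <- chol2inv(R)
  df <- n - k
  se3 <- sqrt(inv[3 + 1, 3 + 1] * rss / df)
  b3 <- beta[4, ]
  tstat <- ifelse(se3 > 0, b3 / se3, sign(b3) * Inf)
  p <- clamp_p(2 * stats::pt(-abs(tstat), df = df))
  list(beta3 = b3, se3 = se3, stat = tstat, p = p, n_used = n,
       degenerate = FALSE, reason = NA_character_)
}

#' Two-SNP interaction test
#'
#' Ordinary least squares of the adjusted phenotype on
#' `[1, gA, gB, gA*gB]` plus optional extra covariates (e.g. a polygenic
#' score); two-sided Student-t p-value for the interaction coefficient with
#' residual degrees of freedom. Samples missing either genotype are dropped
#' for this pair only. A rank-deficient design is flagged degenerate and
#' recorded with p = 1.
#'
#' @param g_a,g_b dosage columns.
#' @param y_adj adjusted phenotype.
#' @param extra_covariates optional numeric matrix of additional columns.
#' @param snp_a,snp_b optional SNP ids carried into the result.
#' @return An `interaction_result` list: `snp_a`, `snp_b`, `beta3`, `se3`,
#'   `statistic`, `p`, `n_used`, `adjusted_for_prs`, `degenerate`, `reason`.
#' @export
interaction_test <- function(g_a, g_b, y_adj, extra_covariates = NULL,
                             snp_a = NA_character_, snp_b = NA_character_) {
  y <- as_y_values(y_adj)
  r <- pair_ols(g_a, g_b, matrix(y, ncol = 1), extra = extra_covariates)
  structure(list(snp_a = snp_a, snp_b = snp_b, beta3 = r$beta3[1],
                 se3 = r$se3[1], statistic = r$stat[1], p = r$p[1],
                 n_used = r$n_used,
                 adjusted_for_prs = !is.null(extra_covariates),
                 degenerate = r$degenerate, reason = r$reason),
            class = "interaction_result")
}

#' Scan a set of candidate SNP pairs
#'
#' Runs [interaction_test()] on every model and retains results with
#' `p <= store_threshold` (the storage threshold is deliberately at least as
#' large as the largest truncation point used downstream, so the
#' truncated-product statistics are exact). Degenerate pairs are logged in
#' the `"degenerate"` attribute. Output rows are ordered by p-value, then
#' SNP ids.
#'
#' @param models a `snp_models` data.frame.
#' @param dataset a [genotype_dataset()].
#' @param y_adj adjusted phenotype.
#' @param store_threshold retain results with p at or below this (default
#'   0.05).
#' @param extra_covariates optional matrix added to every design.
#' @return data.frame `snp_a`, `snp_b`, `beta3`, `se3`, `statistic`, `p`,
#'   `n_used`; attributes `n_tested` and `degenerate`.
#' @export
scan_pairs <- function(models, dataset, y_adj, store_threshold = 0.05,
                       extra_covariates = NULL) {
  y <- as_y_values(y_adj)
  res <- scan_pairs_multi(models, dataset, matrix(y, ncol = 1),
                          extra = extra_covariates)
  out <- data.frame(snp_a = models$snp_a, snp_b = models$snp_b,
                    beta3 = res$beta3[, 1], se3 = res$se3[, 1],
                    statistic = res$stat[, 1], p = res$p[, 1],
                    n_used = res$n_used, stringsAsFactors = FALSE)
  degenerate <- out[res$degenerate, c("snp_a", "snp_b"), drop = FALSE]
  if (nrow(degenerate)) degenerate$reason <- res$reason[res$degenerate]
  out <- out[out$p <= store_threshold, , drop = FALSE]
  out <- out[order(out$p, out$snp_a, out$snp_b), ]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(models)
  attr(out, "degenerate") <- degenerate
  out
}

# Vectorized scan: every model against every phenotype column of Y.
# Returns matrices (n_models x n_phenotypes).
scan_pairs_multi <- function(models, dataset, Y, extra = NULL) {
  np <- nrow(models)
  nb <- ncol(Y)
  ia <- match(models$snp_a, dataset$snps$snp_id)
  ib <- match(models$snp_b, dataset$snps$snp_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop_netepi("validation", "SNP model refers to SNP absent from dataset")
  }
  p <- matrix(1, np, nb)
  beta3 <- se3 <- stat <- matrix(NA_real_, np, nb)
  n_used <- integer(np)
  degenerate <- logical(np)
  reason <- rep(NA_character_, np)
  G <- dataset$genotypes
  y_ok <- rowSums(is.na(Y)) == 0L
  for (i in seq_len(np)) {
    r <- pair_ols(G[, ia[i]], G[, ib[i]], Y, extra = extra, y_ok = y_ok)
    p[i, ] <- r$p
    beta3[i, ] <- r$beta3
    se3[i, ] <- r$se3
    stat[i, ] <- r$stat
    n_used[i] <- r$n_used
    degenerate[i] <- r$degenerate
    reason[i] <- r$reason
  }
  list(p = p, beta3 = beta3, se3 = se3, stat = stat, n_used = n_used,
       degenerate = degenerate, reason = reason)
}

#' Greedy LD clumping
#'
#' PLINK-style clumping of single-SNP summary statistics: SNPs are visited
#' in order of ascending p-value (ties broken by position, then id); each
#' index SNP removes all not-yet-clumped SNPs on the same chromosome within
#' `window_kb` kilobases whose dosage r-squared with the index exceeds
#' `r2_max` (and whose p-value is at most `p_max`). The kept list is the
#' index SNPs, in visiting order.
#'
#' @param summary data.frame with columns `snp_id`, `beta`, `p`.
#' @param dataset a [genotype_dataset()].
#' @param window_kb clumping window (default 250).
#' @param p_max only SNPs with p at or below this can be clumped away
#'   (default 1).
#' @param r2_max r-squared above which a SNP is clumped (default 0.1).
#' @return Character vector of kept SNP ids.
#' @export
clump <- function(summary, dataset, window_kb = 250, p_max = 1, r2_max = 0.1) {
  j <- match(summary$snp_id, dataset$snps$snp_id)
  if (anyNA(j)) stop_netepi("validation", "summary covers SNPs absent from dataset")
  pos <- dataset$snps$position[j]
  chr <- dataset$snps$chromosome[j]
  ord <- order(summary$p, pos, summary$snp_id)
  alive <- rep(TRUE, nrow(summary))
  kept <- character(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, summary$snp_id[i])
    alive[i] <- FALSE
    cand <- which(alive & chr == chr[i] &
                    abs(pos - pos[i]) <= window_kb * 1000 &
                    summary$p <= p_max)
    for (k in cand) {
      r2 <- pairwise_r2(dataset$genotypes[, j[i]], dataset$genotypes[, j[k]])
      if (!is.na(r2) && r2 > r2_max) alive[k] <- FALSE
    }
  }
  kept
}

#' Polygenic risk score (average effect size)
#'
#' Per sample, the sum of `beta * dosage` over the kept SNPs with
#' non-missing genotype, divided by the number of non-missing kept SNPs for
#' that sample. A sample with no non-missing kept SNP gets `NA` and is
#' excluded from PRS-adjusted tests.
#'
#' @param dataset a [genotype_dataset()].
#' @param kept_snps character vector of SNP ids (non-empty).
#' @param betas numeric weights, either named by SNP id or aligned with
#'   `kept_snps`.
#' @return A `prs_vector`: list with `score`, `included_snps`, `weights`.
#' @export
compute_prs <- function(dataset, kept_snps, betas) {
  if (!length(kept_snps)) stop_netepi("validation", "kept_snps is empty")
  if (!is.null(names(betas))) betas <- betas[kept_snps]
  if (length(betas) != length(kept_snps) || anyNA(betas)) {
    stop_netepi("validation", "betas must align with kept_snps")
  }
  j <- match(kept_snps, dataset$snps$snp_id)
  if (anyNA(j)) stop_netepi("validation", "kept SNP absent from dataset")
  G <- dataset$genotypes[, j, drop = FALSE]
  W <- matrix(betas, nrow(G), ncol(G), byrow = TRUE)
  contrib <- G * W
  n_ok <- rowSums(!is.na(G))
  score <- unname(ifelse(n_ok > 0, rowSums(contrib, na.rm = TRUE) / n_ok,
                         NA_real_))
  structure(list(score = score, included_snps = kept_snps,
                 weights = stats::setNames(as.numeric(betas), kept_snps)),
            class = "prs_vector")
}

#' Single-SNP summary statistics for the whole dataset
#'
#' Convenience wrapper running [single_snp_assoc()] on every SNP; used to
#' feed [clump()] and [compute_prs()]. Monomorphic SNPs get `NA` rows.
#'
#' @param dataset a [genotype_dataset()].
#' @param y_adj adjusted phenotype.
#' @return data.frame `snp_id`, `beta`, `se`, `p`.
#' @export
snp_summary_stats <- function(dataset, y_adj) {
  y <- as_y_values(y_adj)
  res <- lapply(seq_len(nrow(dataset$snps)), function(j) {
    r <- tryCatch(single_snp_assoc(dataset$genotypes[, j], y),
                  error = function(e) list(beta = NA_real_, se = NA_real_,
                                           p = NA_real_))
    data.frame(snp_id = dataset$snps$snp_id[j], beta = r$beta, se = r$se,
               p = r$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
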