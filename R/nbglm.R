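# Negative-binomial GLM engine, vectorised across genes.
#
# Model per gene: log mu = beta0 + beta1 * x + offset, counts NB(mu, phi)
# with Var = mu + phi mu^2. The engine fits all genes at once by IRLS with
# closed-form (at most 2x2) weighted least squares per gene, which keeps the
# per-permutation cost of the benchmark low without compiled code.

# y: G x n counts; xvec: length-n covariate or NULL (intercept-only);
# offset: length-n log effective library sizes; phi: scalar or length-G.
nb_irls <- function(y, xvec, offset, phi, maxit = 100L, tol = 1e-10) {
  G <- nrow(y)
  n <- ncol(y)
  off <- matrix(offset, G, n, byrow = TRUE)
  beta0 <- log((rowSums(y) + 0.5) / sum(exp(offset)))
  beta1 <- if (is.null(xvec)) NULL else numeric(G)
  converged <- rep(FALSE, G)
  info_det <- rep(NA_real_, G)
  mu <- NULL
  for (it in seq_len(maxit)) {
    eta <- beta0 + off
    if (!is.null(xvec)) eta <- eta + outer(beta1, xvec)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - off) + (y - mu) / mu
    Sw <- rowSums(w)
    Swz <- rowSums(w * z)
    if (is.null(xvec)) {
      new0 <- Swz / Sw
      delta <- abs(new0 - beta0)
      beta0 <- new0
      info_det <- Sw
    } else {
      wx <- sweep(w, 2, xvec, "*")
      Swx <- rowSums(wx)
      Swxx <- rowSums(sweep(wx, 2, xvec, "*"))
      Swxz <- rowSums(wx * z)
      dt <- Sw * Swxx - Swx^2
      bad <- !is.finite(dt) | dt < 1e-300
      dt[bad] <- NA
      new1 <- (Sw * Swxz - Swx * Swz) / dt
      new0 <- (Swz - Swx * new1) / Sw
      new1[bad] <- beta1[bad]
      new0[bad] <- beta0[bad]
      # clamp to keep separated genes (one group all zero) on a finite
      # boundary instead of diverging
      new1 <- pmin(pmax(new1, -20), 20)
      new0 <- pmin(pmax(new0, -30), 30)
      delta <- pmax(abs(new0 - beta0), abs(new1 - beta1))
      beta0 <- new0
      beta1 <- new1
      info_det <- dt
    }
    converged <- is.finite(delta) & delta < tol
    if (all(converged)) break
  }
  eta <- beta0 + off
  if (!is.null(xvec)) eta <- eta + outer(beta1, xvec)
  eta <- pmin(pmax(eta, -30), 30)
  list(beta0 = beta0, beta1 = beta1, mu = exp(eta),
       info_det = info_det, converged = converged)
}

# NB deviance per gene (Poisson limit handled for phi < 1e-8)
nb_deviance <- function(y, mu, phi) {
  G <- nrow(y)
  phi <- rep_len(phi, G)
  t1 <- y * log(ifelse(y == 0, 1, y / mu))
  pois_dev <- 2 * rowSums(t1 - (y - mu))
  small <- phi < 1e-8
  if (all(small)) return(pois_dev)
  phin <- pmax(phi, 1e-8)
  t2 <- (y + 1 / phin) * log((1 + phin * y) / (1 + phin * mu))
  dev <- 2 * rowSums(t1 - t2)
  dev[small] <- pois_dev[small]
  dev
}

# NB log-likelihood per gene (Poisson limit for phi < 1e-8)
nb_loglik <- function(y, mu, phi) {
  G <- nrow(y)
  phi <- rep_len(phi, G)
  small <- phi < 1e-8
  ll <- rep(NA_real_, G)
  if (any(!small)) {
    yy <- y[!small, , drop = FALSE]
    mm <- mu[!small, , drop = FALSE]
    sz <- 1 / phi[!small]
    ll[!small] <- rowSums(stats::dnbinom(yy, size = sz, mu = mm, log = TRUE))
  }
  if (any(small)) {
    ll[small] <- rowSums(stats::dpois(y[small, , drop = FALSE],
                                      lambda = mu[small, , drop = FALSE],
                                      log = TRUE))
  }
  ll
}

#' Estimate per-gene NB dispersions with empirical-Bayes trend shrinkage
#'
#' Evaluates, per gene, the Cox-Reid adjusted profile likelihood (APL) of
#' the dispersion on a log-spaced grid. The gene-wise APL curve is then
#' averaged with a trend curve — the abundance-local moving-average mean
#' APL across genes — with fixed weights: residual degrees of freedom for
#' the gene, `prior_df` for the trend. The shrunk dispersion maximises this
#' weighted average (quadratic interpolation around the grid maximum).
#' Shrinking whole likelihood curves rather than point estimates keeps genes
#' with flat, uninformative likelihoods at the trend instead of letting a
#' boundary maximum drag their dispersion towards zero.
#'
#' @param y genes-by-samples count matrix.
#' @param xvec numeric covariate (0/1 condition indicator) or `NULL`.
#' @param offset log effective library sizes.
#' @param prior_df prior weight (effective samples) of the trend; default 10.
#' @param span fraction of genes in the moving-average window that defines
#'   the abundance-local trend curve.
#' @return list with `phi_mle` (gene-wise APL maximiser), `phi_trend`
#'   (trend-curve maximiser), `phi_shrunk` (weighted-APL maximiser, used for
#'   testing), `abundance` (average log2 CPM).
#' @export
estimate_dispersion <- function(y, xvec, offset, prior_df = 10, span = 0.5) {
  y <- as.matrix(y)
  G <- nrow(y)
  n <- ncol(y)
  lg <- seq(log(1e-4), log(20), length.out = 19)
  apl <- matrix(-Inf, G, length(lg))
  for (k in seq_along(lg)) {
    phi <- exp(lg[k])
    fit <- nb_irls(y, xvec, offset, phi, maxit = 30L, tol = 1e-8)
    ld <- log(pmax(fit$info_det, 1e-300))
    apl[, k] <- nb_loglik(y, fit$mu, phi) - 0.5 * ld
  }
  apl[!is.finite(apl)] <- NA_real_
  abundance <- log2((rowSums(y) + 0.5) / (sum(exp(offset)) + 1) * 1e6)

  # centre each gene's curve at its own maximum: row-constant shifts leave
  # every argmax unchanged but stop large-likelihood genes from dominating
  # the local averages that define the trend curve
  rmax <- suppressWarnings(apply(apl, 1L, max, na.rm = TRUE))
  rmax[!is.finite(rmax)] <- 0
  apl <- apl - rmax

  # trend curve: abundance-local mean of the centred APL curves, computed as
  # a moving average over abundance-ordered genes (a local mean is bounded
  # by the data, unlike local-linear smoothers that overshoot at the edges)
  apl_trend <- apl
  if (G >= 10) {
    ord <- order(abundance)
    width <- max(11L, ceiling(span * G))
    half <- width %/% 2L
    lo <- pmax(seq_len(G) - half, 1L)
    hi <- pmin(seq_len(G) + half, G)
    for (k in seq_along(lg)) {
      v <- apl[ord, k]
      ok <- is.finite(v)
      cs <- cumsum(c(0, ifelse(ok, v, 0)))
      cn <- cumsum(c(0, as.numeric(ok)))
      m <- (cs[hi + 1L] - cs[lo]) / pmax(cn[hi + 1L] - cn[lo], 1)
      m[(cn[hi + 1L] - cn[lo]) == 0] <- NA_real_
      apl_trend[ord, k] <- m
    }
  }

  resid_df <- n - if (is.null(xvec)) 1L else 2L
  w <- prior_df / max(resid_df, 1)
  grid_argmax <- function(mat) {
    mat[!is.finite(mat)] <- -Inf
    best <- max.col(mat, ties.method = "first")
    lphi <- lg[best]
    bad <- !is.finite(mat[cbind(seq_len(nrow(mat)), best)])
    h <- lg[2] - lg[1]
    i <- which(best > 1 & best < length(lg))
    if (length(i)) {
      y1 <- mat[cbind(i, best[i] - 1L)]
      y2 <- mat[cbind(i, best[i])]
      y3 <- mat[cbind(i, best[i] + 1L)]
      den <- y1 - 2 * y2 + y3
      ok <- is.finite(den) & den < -1e-12
      shift <- ifelse(ok, 0.5 * h * (y1 - y3) / den, 0)
      lphi[i] <- lg[best[i]] + pmin(pmax(shift, -h), h)
    }
    lphi[bad] <- NA_real_
    lphi
  }
  lphi_mle <- grid_argmax(apl)
  lphi_trend <- grid_argmax(apl_trend)
  apl_w <- apl
  fin_t <- is.finite(apl_trend)
  apl_w[fin_t] <- (apl[fin_t] + w * apl_trend[fin_t]) / (1 + w)
  miss <- !is.finite(apl_w) & fin_t
  apl_w[miss] <- apl_trend[miss]   # no gene-wise curve: follow the trend
  lphi_shrunk <- grid_argmax(apl_w)
  fallback <- !is.finite(lphi_shrunk)
  lphi_shrunk[fallback] <- lphi_trend[fallback]
  lphi_shrunk[!is.finite(lphi_shrunk)] <- log(0.1)
  list(
    phi_mle = exp(lphi_mle),
    phi_trend = exp(lphi_trend),
    phi_shrunk = exp(lphi_shrunk),
    abundance = abundance
  )
}

#' Negative-binomial likelihood-ratio test on a pseudobulk matrix
#'
#' Per gene: estimates the NB dispersion (unless a fixed value is given),
#' fits the full GLM `log mu = beta0 + beta1 * 1[case] + offset` and the null
#' model without the condition term by IRLS, and tests `beta1 = 0` with
#' `LR = deviance(null) - deviance(full)` against a chi-squared distribution
#' with 1 degree of freedom. Offsets are log effective library sizes
#' (library size times TMM factor). P-values are Benjamini-Hochberg adjusted
#' within the table.
#'
#' @param pb a `pseudobulk` object (see [aggregate_pseudobulk()]), ideally
#'   gene-filtered via [filter_expressed_pb()] and normalised via
#'   [tmm_norm_factors()].
#' @param dispersion `NULL` to estimate per-gene shrunk dispersions (see
#'   [estimate_dispersion()]), or a fixed value/vector (0 gives the Poisson
#'   limit).
#' @param prior_df trend prior weight for dispersion shrinkage.
#' @param disp_floor_trend if `TRUE` (default) the dispersion used for
#'   testing is floored at the trend: gene-wise estimates may exceed the
#'   trend but not fall below it. With a few dozen samples, below-trend
#'   estimates are dominated by estimation noise — and are biased low
#'   precisely when a label split happens to align with donor-level
#'   variability, which would otherwise inflate the LRT.
#' @param ref_condition condition treated as the reference (log fold changes
#'   are case over reference); defaults to `"control"` when present.
#' @return a `deg_table` data.frame: `gene`, `logFC` (log2), `logCPM`, `LR`,
#'   `p_value`, `adj_pval`, `dispersion`, `converged`.
#' @export
fit_nb_lrt <- function(pb, dispersion = NULL, prior_df = 10,
                       disp_floor_trend = TRUE, ref_condition = NULL) {
  stopifnot(inherits(pb, "pseudobulk"))
  cond <- pb$samples$condition
  lev <- unique(cond)
  if (length(lev) != 2) stop("need exactly two conditions")
  if (any(table(cond) < 2)) stop("need >= 2 donors per condition")
  ref <- ref_condition %||% (if ("control" %in% lev) "control" else sort(lev)[1])
  xvec <- as.numeric(cond != ref)
  y <- as.matrix(pb$counts)
  keep <- rowSums(y) > 0
  if (!all(keep)) {
    warning(sprintf("excluding %d all-zero gene(s)", sum(!keep)))
  }
  yk <- y[keep, , drop = FALSE]
  offset <- log(pb$samples$lib_size * pb$norm_factors)

  if (is.null(dispersion)) {
    disp <- estimate_dispersion(yk, xvec, offset, prior_df = prior_df)
    phi <- if (disp_floor_trend) {
      pmax(disp$phi_shrunk, disp$phi_trend, na.rm = TRUE)
    } else {
      disp$phi_shrunk
    }
  } else {
    phi <- rep_len(dispersion, nrow(yk))
  }

  full <- nb_irls(yk, xvec, offset, phi)
  null <- nb_irls(yk, NULL, offset, phi)
  lr <- pmax(nb_deviance(yk, null$mu, phi) - nb_deviance(yk, full$mu, phi), 0)
  pval <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  logcpm <- rowMeans(log2(sweep(
    yk + 0.5, 2, pb$samples$lib_size * pb$norm_factors + 1, "/") * 1e6))
  conv <- full$converged & null$converged
  lr[!conv] <- NA_real_
  pval[!conv] <- NA_real_

  tab <- data.frame(
    gene = rownames(y)[keep] %||% which(keep),
    logFC = full$beta1 / log(2),
    logCPM = logcpm,
    LR = lr,
    p_value = pval,
    adj_pval = bh_adjust(pval),
    dispersion = phi,
    converged = conv,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  class(tab) <- c("deg_table", "data.frame")
  attr(tab, "cell_type") <- pb$cell_type
  attr(tab, "ref_condition") <- ref
  tab
}
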