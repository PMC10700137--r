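#' Ridge-stabilized negative-binomial GLM with Wald tests
#'
#' Fits an NB regression with log link and a log size-factor offset by
#' iteratively reweighted least squares (Fisher scoring) at a fixed
#' dispersion. A small ridge penalty on the non-intercept coefficients keeps
#' the fit finite when a design cell has all-zero counts (complete allelic
#' silencing). Coefficients are reported in log2 units; standard errors come
#' from the penalized information matrix at convergence and Wald p-values
#' from the normal approximation z = beta / SE.
#'
#' @param y Non-negative integer counts, one observation per design row.
#' @param design Numeric design matrix; first column must be the intercept.
#' @param size_factors Positive offsets entering as log(sf); length nrow(design).
#' @param dispersion NB dispersion alpha in variance = mu + alpha * mu^2.
#'   Values below 1e-12 are fitted as Poisson.
#' @param ridge Ridge penalty on non-intercept coefficients (default 1e-8,
#'   large enough to keep all-zero design cells finite without disturbing
#'   the additivity of the per-allele and interaction coefficients).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   maximum absolute coefficient change (natural-log scale).
#' @param lfc_cap Reported absolute log2 coefficients are capped here
#'   (default 12); the cap is recorded in the \code{capped} flag.
#' @return list with \code{log2fc} (coefficients, log2), \code{se} (log2),
#'   \code{stat} (Wald z), \code{p}, \code{converged}, \code{capped},
#'   \code{mu} (fitted means).
#' @export
fit_nb_glm_wald <- function(y, design, size_factors, dispersion,
                            ridge = 1e-8, max_iter = 100L, tol = 1e-8,
                            lfc_cap = 12) {
  X <- as.matrix(design)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(size_factors) == n, all(size_factors > 0),
            n >= p, dispersion >= 0)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  off <- log(size_factors)
  alpha <- max(dispersion, 0)
  pen <- diag(c(0, rep(ridge, p - 1L)), nrow = p)

  beta <- qr.solve(X, log(pmax(y, 0.5)) - off)
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + off, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- eta - off + (y - mu) / mu
    XtWX <- crossprod(X, w * X)
    beta_new <- solve(XtWX + pen, crossprod(X, w * z))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  cov_beta <- solve(XtWX + pen)
  se <- sqrt(pmax(diag(cov_beta), 0))
  stat <- beta / se
  pval <- 2 * stats::pnorm(-abs(stat))
  if (!converged) pval[] <- 1
  log2fc <- beta / log(2)
  capped <- abs(log2fc) > lfc_cap
  capped[1L] <- FALSE  # intercept is a baseline, never capped
  log2fc[capped] <- sign(log2fc[capped]) * lfc_cap
  nm <- colnames(X)
  list(log2fc = stats::setNames(log2fc, nm),
       se = stats::setNames(se / log(2), nm),
       stat = stats::setNames(stat, nm),
       p = stats::setNames(pval, nm),
       converged = converged, capped = capped,
       mu = exp(pmin(pmax(drop(X %*% beta) + off, -30), 30)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the non-missing entries; NA/NaN p-values
#' propagate unchanged and do not count toward the number of tests.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @return Vector of q-values, same length and order.
#' @examples adjust_bh(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(q) <- names(p)
  q
}
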