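#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per column of a count matrix by the
#' median-of-ratios method: each column's counts are divided by the per-gene
#' geometric mean across columns, and the column's size factor is the median
#' of those ratios over the reference genes (rows with a strictly positive
#' geometric mean, i.e. no zero in any column). Factors are rescaled so their
#' geometric mean is 1, making normalized counts comparable across runs.
#'
#' @param counts Non-negative integer matrix, genes in rows, analysis columns
#'   (samples, or sample-by-allele columns) in columns.
#' @return Numeric vector of size factors, one per column, geometric mean 1.
#' @examples
#' m <- matrix(c(10, 30, 50, 20, 60, 100), nrow = 3)
#' estimate_size_factors(m)  # c(0.7071, 1.4142)
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (ncol(counts) < 1L || nrow(counts) < 1L) stop("empty count matrix")
  log_geo <- rowMeans(log(counts))
  ref <- is.finite(log_geo)
  if (!any(ref)) stop("no common reference genes")
  log_ratios <- log(counts[ref, , drop = FALSE]) - log_geo[ref]
  sf <- exp(apply(log_ratios, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Gene-wise negative-binomial dispersion by method of moments
#'
#' For each gene, computes the grand mean of normalized counts and the pooled
#' within-group variance (group means centred out, Bessel-corrected with
#' pooled degrees of freedom), then solves the NB variance relation
#' variance = mean + alpha * mean^2 for alpha, truncated below at a small
#' floor. Genes whose variance does not exceed their mean (the Poisson case)
#' get the floor; all-zero genes get the floor and are flagged untestable.
#'
#' @param counts Non-negative integer matrix, genes x columns.
#' @param size_factors Positive size factors, one per column.
#' @param groups Factor (or coercible) of length ncol giving replicate groups;
#'   at least one group needs two or more columns.
#' @param floor Lower bound for alpha (default 1e-8).
#' @return data.frame with columns \code{mean}, \code{var_within},
#'   \code{alpha}, \code{untestable}, one row per gene.
#' @export
estimate_dispersions <- function(counts, size_factors, groups, floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  stopifnot(length(size_factors) == ncol(counts),
            length(groups) == ncol(counts), all(size_factors > 0))
  tab <- table(groups)
  if (!any(tab >= 2L)) stop("need >= 2 replicates in at least one group")
  norm <- sweep(counts, 2L, size_factors, "/")
  m <- rowMeans(norm)
  ss <- 0
  df <- 0L
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2L) next
    sub <- norm[, idx, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(idx) - 1L
  }
  s2 <- ss / df
  alpha <- pmax(floor, (s2 - m) / m^2)
  untestable <- m == 0
  alpha[untestable] <- floor
  data.frame(mean = m, var_within = s2, alpha = alpha,
             untestable = untestable, row.names = rownames(counts))
}
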