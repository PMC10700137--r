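#' Aggregate contact analysis anchored on peak-pair bins
#'
#' Averages contact-matrix submatrices centred on pairs of bins that both
#' contain a peak, and compares them with an equal number of random
#' background pairs in which neither bin contains a peak, sampled to match
#' the foreground's distance distribution (stratified by |i - j|; if a
#' distance stratum has too few background pairs the nearest distance is
#' used, with a warning). The enrichment is the ratio of the central entries
#' of the two aggregates.
#'
#' @param matrix Symmetric numeric contact matrix.
#' @param peaks Integer vector of 1-based bin indices containing a peak.
#' @param window Bins on each side of the anchor (default 5); pairs whose
#'   windows leave the matrix are dropped.
#' @param distance_range Allowed |i - j| in bins (default c(1, nbins - 1)).
#' @param seed Integer seed for background sampling.
#' @return list: \code{fg_aggregate}, \code{bg_aggregate}
#'   ((2 window + 1)^2 matrices), \code{enrichment}, \code{n_fg},
#'   \code{n_bg}.
#' @export
aggregate_peak_contacts <- function(matrix, peaks, window = 5L,
                                    distance_range = NULL, seed = 1L) {
  m <- unclass(matrix)
  n <- nrow(m)
  if (!isTRUE(all.equal(m, t(m)))) stop("contact matrix must be symmetric")
  if (is.null(distance_range)) distance_range <- c(1L, n - 1L)
  w <- as.integer(window)
  if (w < 0L || 2L * w + 1L > n) stop("window out of matrix bounds")
  peaks <- unique(as.integer(peaks))
  if (length(peaks) && (min(peaks) < 1L || max(peaks) > n)) {
    stop("peaks outside the matrix")
  }
  in_bounds <- function(i) i - w >= 1L & i + w <= n
  has_peak <- logical(n); has_peak[peaks] <- TRUE

  pair_grid <- function(bins_ok) {
    idx <- which(bins_ok & in_bounds(seq_len(n)))
    if (length(idx) < 2L) return(NULL)
    pairs <- expand.grid(i = idx, j = idx)
    pairs <- pairs[pairs$i < pairs$j, ]
    d <- pairs$j - pairs$i
    pairs[d >= distance_range[1L] & d <= distance_range[2L], ]
  }
  fg <- pair_grid(has_peak)
  if (is.null(fg) || !nrow(fg)) stop("no foreground pairs")
  bg_pool <- pair_grid(!has_peak)
  if (is.null(bg_pool) || !nrow(bg_pool)) stop("no background pairs available")

  set.seed(seed)
  fg_d <- fg$j - fg$i
  bg_d <- bg_pool$j - bg_pool$i
  picked <- integer(0)
  fallback <- FALSE
  for (d in sort(unique(fg_d))) {
    need <- sum(fg_d == d)
    cand <- which(bg_d == d)
    if (length(cand) < need) {
      fallback <- TRUE
      ord <- order(abs(bg_d - d))
      cand <- ord[seq_len(min(need * 3L, length(ord)))]
    }
    picked <- c(picked, sample(cand, need, replace = length(cand) < need))
  }
  if (fallback) warning("insufficient background pairs at some distances; ",
                        "nearest-distance fallback used")
  bg <- bg_pool[picked, ]

  agg <- function(pairs) {
    acc <- base::matrix(0, 2L * w + 1L, 2L * w + 1L)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      acc <- acc + m[(i - w):(i + w), (j - w):(j + w)]
    }
    acc / nrow(pairs)
  }
  fg_agg <- agg(fg); bg_agg <- agg(bg)
  centre <- w + 1L
  list(fg_aggregate = fg_agg, bg_aggregate = bg_agg,
       enrichment = fg_agg[centre, centre] / bg_agg[centre, centre],
       n_fg = nrow(fg), n_bg = nrow(bg))
}
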