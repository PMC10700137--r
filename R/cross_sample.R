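#' k-means clustering of allelic fold-change profiles
#'
#' Clusters genes on their clone-by-allele log2 fold-change matrix with
#' standard Lloyd k-means, seeded, keeping the best of \code{n_init}
#' restarts by total within-cluster sum of squares. Missing entries
#' (untested genes) are imputed as 0 with a message.
#'
#' @param lfc_matrix Numeric matrix, genes x (clone x allele) log2FC columns.
#' @param k Number of clusters (default 14, the resolution used for a
#'   four-clone matrix).
#' @param seed Integer seed.
#' @param n_init Number of random restarts (default 10).
#' @return Integer vector of cluster labels, one per row, with the fitted
#'   \code{kmeans} object as attribute \code{fit}.
#' @export
cluster_allelic_fc <- function(lfc_matrix, k = 14L, seed = 1L, n_init = 10L) {
  m <- as.matrix(lfc_matrix)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(m)) stop("k exceeds the number of genes")
  if (anyNA(m)) {
    message("imputing ", sum(is.na(m)), " missing log2FC entries as 0")
    m[is.na(m)] <- 0
  }
  set.seed(seed)
  fit <- stats::kmeans(m, centers = k, nstart = n_init, iter.max = 1000L,
                       algorithm = "Lloyd")
  structure(fit$cluster, fit = fit)
}

#' Cross-clone consistency of monoallelic transitions
#'
#' For genes that undergo a bi-to-mono transition in two clones, decides
#' whether expression was lost from the same strain allele in both
#' (\code{same_allele}) or from opposite alleles (\code{reversed_allele}),
#' and maps each clone's lost allele to its parental origin using the cross:
#' allele 2 is CAST, so the lost allele is maternal exactly when its strain
#' matches the mother. For reciprocal crosses a reversed allele with
#' consistent parental origin is imprinting-like; for clones of the same
#' cross a reversed allele is random-monoallelic-like.
#'
#' @param calls_a,calls_b \code{CategoryCall} data.frames (or any data.frame
#'   with gene_id, category) for the two clones.
#' @param cross_a,cross_b \code{\link{cross_info}} for the two clones.
#' @return data.frame per shared bi-to-mono gene: gene_id, lost alleles,
#'   mode, parental origins, origin_consistent, label.
#' @export
classify_cross_clone_consistency <- function(calls_a, calls_b,
                                             cross_a, cross_b) {
  stopifnot(inherits(cross_a, "cross_info"), inherits(cross_b, "cross_info"))
  lost_of <- function(calls) {
    bm <- calls$category %in% c("bi_to_mono_A1", "bi_to_mono_A2")
    stats::setNames(ifelse(calls$category[bm] == "bi_to_mono_A2", "a1", "a2"),
                    calls$gene_id[bm])
  }
  la <- lost_of(calls_a); lb <- lost_of(calls_b)
  shared <- intersect(names(la), names(lb))
  if (!length(shared)) {
    return(data.frame(gene_id = character(), lost_a = character(),
                      lost_b = character(), mode = character(),
                      origin_a = character(), origin_b = character(),
                      origin_consistent = logical(), label = character()))
  }
  origin <- function(lost, cross) {
    ifelse(lost == maternal_allele(cross), "maternal", "paternal")
  }
  lost_a <- la[shared]; lost_b <- lb[shared]
  mode <- ifelse(lost_a == lost_b, "same_allele", "reversed_allele")
  oa <- origin(lost_a, cross_a); ob <- origin(lost_b, cross_b)
  consistent <- oa == ob
  reciprocal <- maternal_allele(cross_a) != maternal_allele(cross_b)
  label <- rep("strain_consistent", length(shared))
  rev <- mode == "reversed_allele"
  if (reciprocal) {
    label[rev & consistent] <- "imprinting_like"
    label[rev & !consistent] <- "inconsistent"
  } else {
    label[rev] <- "random_monoallelic_like"
  }
  data.frame(gene_id = shared, lost_a = unname(lost_a),
             lost_b = unname(lost_b), mode = unname(mode),
             origin_a = unname(oa), origin_b = unname(ob),
             origin_consistent = unname(consistent), label = label)
}

#' k-means variant of the same/reversed allele split
#'
#' Alternative to the deterministic rule: clusters the per-gene
#' (allele1, allele2) log2FC profiles of two clones into two groups and
#' labels each cluster by its centroid's loss pattern (which allele is more
#' negative in each clone). Agrees with
#' \code{\link{classify_cross_clone_consistency}} on separable data.
#'
#' @param lfc_a,lfc_b Two-column matrices (log2FC of a1, a2) for the shared
#'   genes in clones A and B, same row order.
#' @param seed Integer seed.
#' @return Character vector "same_allele"/"reversed_allele" per gene.
#' @export
consistency_kmeans <- function(lfc_a, lfc_b, seed = 1L) {
  x <- cbind(as.matrix(lfc_a), as.matrix(lfc_b))
  stopifnot(ncol(x) == 4L)
  cl <- cluster_allelic_fc(x, k = 2L, seed = seed)
  centers <- attr(cl, "fit")$centers
  lab <- apply(centers, 1L, function(ce) {
    lost_a <- if (ce[1L] <= ce[2L]) "a1" else "a2"
    lost_b <- if (ce[3L] <= ce[4L]) "a1" else "a2"
    if (lost_a == lost_b) "same_allele" else "reversed_allele"
  })
  unname(lab[cl])
}

#' Identify X-inactivation escapees in a female clone
#'
#' A gene on the X chromosome escapes inactivation when its inactive-X
#' allele is expressed in wild type: mean wild-type normalized counts on the
#' Xi allele above \code{min_xi_count} and a WT Xi fraction
#' (Xi / (allele1 + allele2)) strictly between \code{frac_bounds}. Escapees
#' whose Xi-allele knockout log2FC falls below the strict silencing
#' threshold are flagged as regulated by the perturbation.
#'
#' @param table An \code{AlleleCountTable} for the clone.
#' @param suite The clone's \code{DESuiteResult}.
#' @param cross \code{\link{cross_info}} with \code{xi_allele} set.
#' @param annotation data.frame with gene_id and chrom ("chrX" marks X).
#' @param thresholds An \code{\link{ase_thresholds}} (strict_lfc).
#' @param min_xi_count Minimum WT Xi normalized count (default 10).
#' @param frac_bounds Open interval for the Xi fraction (default c(0.1, 0.9)).
#' @return data.frame of class \code{EscapeeCall} per X-linked gene:
#'   gene_id, xi_mean, xi_fraction, is_escapee, xi_log2FC, is_msl2_regulated.
#' @export
identify_escapees <- function(table, suite, cross, annotation,
                              thresholds = ase_thresholds(),
                              min_xi_count = 10, frac_bounds = c(0.1, 0.9)) {
  stopifnot(inherits(table, "AlleleCountTable"),
            inherits(suite, "DESuiteResult"), inherits(cross, "cross_info"))
  if (cross$xi_allele == "none") stop("not an XCI-informative clone")
  xi <- cross$xi_allele
  x_genes <- annotation$gene_id[annotation$chrom %in% c("chrX", "X")]
  idx <- which(table$gene_id %in% x_genes)
  if (!length(idx)) {
    stop("no X-linked genes found in the table")
  }
  wt <- compute_wt_allele_stats(table, suite$size_factors$allelic)
  wt <- wt[idx, ]
  xi_mean <- if (xi == "a1") wt$wt_mean_a1 else wt$wt_mean_a2
  tot <- wt$wt_mean_a1 + wt$wt_mean_a2
  xi_frac <- ifelse(tot > 0, xi_mean / tot, NaN)
  is_esc <- !is.na(xi_frac) & xi_mean > min_xi_count &
    xi_frac > frac_bounds[1L] & xi_frac < frac_bounds[2L]
  xi_de <- if (xi == "a1") suite$allele1 else suite$allele2
  xi_lfc <- xi_de$log2FC[idx]
  msl2 <- is_esc & !is.na(xi_lfc) & xi_lfc < thresholds$strict_lfc
  out <- data.frame(gene_id = table$gene_id[idx], xi_allele = xi,
                    xi_mean = xi_mean, xi_fraction = xi_frac,
                    is_escapee = is_esc, xi_log2FC = xi_lfc,
                    is_msl2_regulated = msl2)
  class(out) <- c("EscapeeCall", "data.frame")
  out
}

#' Two-sided Fisher enrichment of a gene set in an annotation
#'
#' Builds the 2x2 membership table of a query set against an annotation set
#' within a universe and tests association with the exact two-sided
#' hypergeometric test (sum of tables with probability at most that of the
#' observed table). The reported odds ratio is the sample odds ratio, with a
#' 0.5 Haldane correction applied (and flagged) only when a cell is zero.
#'
#' @param query,annotation Character vectors, subsets of \code{universe}.
#' @param universe Character vector of all eligible genes.
#' @return list: odds_ratio, p, table (2x2), haldane (logical).
#' @export
fisher_enrichment <- function(query, annotation, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query); annotation <- unique(annotation)
  if (!all(query %in% universe)) stop("query not contained in universe")
  if (!all(annotation %in% universe)) stop("annotation not contained in universe")
  a <- length(intersect(query, annotation))
  b <- length(setdiff(query, annotation))
  cc <- length(setdiff(annotation, query))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2L, 2L,
                dimnames = list(query = c("in", "out"),
                                annotation = c("in", "out")))
  p <- min(stats::fisher.test(tab, alternative = "two.sided")$p.value, 1)
  haldane <- any(tab == 0L)
  h <- if (haldane) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  list(odds_ratio = or, p = p, table = tab, haldane = haldane)
}

#' Haploinsufficiency summary per category
#'
#' For each category of genes, reports how many fall in a user-supplied
#' haploinsufficient-gene table, the quantiles of their haploinsufficiency
#' scores, the triplosensitive fraction, and a two-sided Fisher enrichment
#' against the universe.
#'
#' @param category_calls data.frame with gene_id and category.
#' @param hi_table data.frame with gene_id, hi_score in [0,1] and a 0/1
#'   triplosensitive flag; gene ids must be unique.
#' @param universe Character vector of all genes considered.
#' @return data.frame, one row per category: n, n_hi, frac_hi, score
#'   quantiles (q25/q50/q75), frac_triplo, odds_ratio, p.
#' @export
haploinsufficiency_summary <- function(category_calls, hi_table, universe) {
  if (anyDuplicated(hi_table$gene_id)) stop("duplicated gene ids in hi_table")
  stopifnot(all(hi_table$hi_score >= 0 & hi_table$hi_score <= 1))
  hi_genes <- intersect(hi_table$gene_id, universe)
  cats <- sort(unique(category_calls$category))
  rows <- lapply(cats, function(cc) {
    genes <- intersect(category_calls$gene_id[category_calls$category == cc],
                       universe)
    in_hi <- intersect(genes, hi_genes)
    sc <- hi_table$hi_score[match(in_hi, hi_table$gene_id)]
    tr <- hi_table$triplosensitive[match(in_hi, hi_table$gene_id)]
    fe <- fisher_enrichment(genes, hi_genes, universe)
    qs <- if (length(sc)) stats::quantile(sc, c(0.25, 0.5, 0.75))
          else rep(NA_real_, 3L)
    data.frame(category = cc, n = length(genes), n_hi = length(in_hi),
               frac_hi = if (length(genes)) length(in_hi) / length(genes) else NA_real_,
               score_q25 = qs[[1L]], score_q50 = qs[[2L]], score_q75 = qs[[3L]],
               frac_triplo = if (length(in_hi)) mean(tr) else NA_real_,
               odds_ratio = fe$odds_ratio, p = fe$p)
  })
  do.call(rbind, rows)
}
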