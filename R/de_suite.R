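#' Run the three-mode allelic differential expression suite
#'
#' Fits, per gene, the four NB GLM Wald contrasts used throughout the
#' package: the standard knockout-versus-wild-type test on total counts, the
#' per-allele tests on allele 1 and allele 2 counts separately, and the
#' allele-specific test from the interaction coefficient of the model
#' \code{~ allele + condition + allele:condition} on the stacked
#' sample-by-allele layout. All allele-level fits share one set of size
#' factors and one gene-wise dispersion, which makes the interaction
#' coefficient algebraically equal to the difference of the two per-allele
#' log2 fold changes.
#'
#' Size factors are median-of-ratios; by default the allelic modes estimate
#' them on the sample-by-allele column layout (capturing allele-assignment
#' differences between samples), with \code{sf_mode = "total"} reusing the
#' total-count factors instead. Genes with mean normalized total count below
#' \code{filter_min_mean} are not tested (NA statistics). BH q-values are
#' computed per mode over the tested genes.
#'
#' @param table An \code{AlleleCountTable} with both conditions present at
#'   two or more replicates each.
#' @param filter_min_mean Minimum mean normalized total count (default 1).
#' @param sf_mode "allelic" (default) or "total": size factors for the
#'   allele-level modes.
#' @param ridge,lfc_cap Passed to \code{\link{fit_nb_glm_wald}}.
#' @return list of class \code{DESuiteResult} with data.frames
#'   \code{standard}, \code{allele1}, \code{allele2}, \code{allele_specific}
#'   (columns gene_id, base_mean, log2FC, SE, stat, p, q, tested), plus
#'   \code{size_factors} (list: total, allelic) and \code{dispersions}.
#' @export
run_de_suite <- function(table, filter_min_mean = 1,
                         sf_mode = c("allelic", "total"),
                         ridge = 1e-8, lfc_cap = 12) {
  stopifnot(inherits(table, "AlleleCountTable"))
  sf_mode <- match.arg(sf_mode)
  cond <- factor(table$samples$condition, levels = c("WT", "KO"))
  if (any(table(cond) < 2L)) stop("each condition needs >= 2 replicates")
  ko <- as.numeric(cond == "KO")
  ng <- length(table$gene_id)

  sf_tot <- estimate_size_factors(table$total)
  base_mean_tot <- rowMeans(sweep(table$total, 2L, sf_tot, "/"))
  tested <- base_mean_tot >= filter_min_mean

  lay <- allele_layout(table)
  sf_all <- if (sf_mode == "allelic") estimate_size_factors(lay$counts)
            else {
              s <- rep(sf_tot, 2L)
              names(s) <- colnames(lay$counts)
              s / exp(mean(log(s)))
            }
  disp_tot <- estimate_dispersions(table$total, sf_tot, cond)
  groups_all <- interaction(lay$columns$condition, lay$columns$allele)
  disp_all <- estimate_dispersions(lay$counts, sf_all, groups_all)

  ko_all <- as.numeric(lay$columns$condition == "KO")
  al2 <- as.numeric(lay$columns$allele == "a2")
  X_std <- cbind(intercept = 1, condition = ko)
  X_int <- cbind(intercept = 1, allele = al2, condition = ko_all,
                 interaction = al2 * ko_all)
  is_a1 <- lay$columns$allele == "a1"
  X_al <- cbind(intercept = 1, condition = ko_all[is_a1])
  norm_all <- sweep(lay$counts, 2L, sf_all, "/")

  empty <- function() data.frame(
    gene_id = table$gene_id, base_mean = NA_real_, log2FC = NA_real_,
    SE = NA_real_, stat = NA_real_, p = NA_real_, q = NA_real_,
    tested = FALSE)
  res <- list(standard = empty(), allele1 = empty(), allele2 = empty(),
              allele_specific = empty())
  res$standard$base_mean <- base_mean_tot
  res$allele1$base_mean <- rowMeans(norm_all[, is_a1, drop = FALSE])
  res$allele2$base_mean <- rowMeans(norm_all[, !is_a1, drop = FALSE])
  res$allele_specific$base_mean <- rowMeans(norm_all)

  fill <- function(df, g, fit, coef) {
    df$log2FC[g] <- fit$log2fc[coef]
    df$SE[g] <- fit$se[coef]
    df$stat[g] <- fit$stat[coef]
    df$p[g] <- fit$p[coef]
    df$tested[g] <- TRUE
    df
  }
  for (g in which(tested)) {
    a_tot <- disp_tot$alpha[g]
    a_all <- disp_all$alpha[g]
    f_std <- fit_nb_glm_wald(table$total[g, ], X_std, sf_tot, a_tot,
                             ridge = ridge, lfc_cap = lfc_cap)
    res$standard <- fill(res$standard, g, f_std, "condition")
    f_int <- fit_nb_glm_wald(lay$counts[g, ], X_int, sf_all, a_all,
                             ridge = ridge, lfc_cap = lfc_cap)
    res$allele_specific <- fill(res$allele_specific, g, f_int, "interaction")
    f_a1 <- fit_nb_glm_wald(lay$counts[g, is_a1], X_al, sf_all[is_a1], a_all,
                            ridge = ridge, lfc_cap = lfc_cap)
    res$allele1 <- fill(res$allele1, g, f_a1, "condition")
    f_a2 <- fit_nb_glm_wald(lay$counts[g, !is_a1], X_al, sf_all[!is_a1], a_all,
                            ridge = ridge, lfc_cap = lfc_cap)
    res$allele2 <- fill(res$allele2, g, f_a2, "condition")
  }
  for (m in names(res)) res[[m]]$q <- adjust_bh(res[[m]]$p)
  structure(c(res, list(size_factors = list(total = sf_tot, allelic = sf_all),
                        dispersions = list(total = disp_tot, allelic = disp_all),
                        samples = table$samples)),
            class = "DESuiteResult")
}

#' @export
print.DESuiteResult <- function(x, ...) {
  cat("DESuiteResult:", nrow(x$standard), "genes,",
      sum(x$standard$tested), "tested\n")
  invisible(x)
}
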