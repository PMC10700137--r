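#' Allele-resolved count table
#'
#' Container for one clone's gene-by-sample counts resolved into allele 1
#' (reference strain), allele 2 (CAST) and totals. Totals include reads not
#' assignable to either allele, so \code{a1 + a2 <= total} holds entrywise.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param samples data.frame with columns \code{sample_id}, \code{clone_id},
#'   \code{condition} ("WT"/"KO"), \code{replicate}.
#' @param a1,a2,total Integer matrices, genes x samples.
#' @return Object of class \code{AlleleCountTable}.
#' @export
allele_count_table <- function(gene_id, samples, a1, a2, total) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2); total <- as.matrix(total)
  stopifnot(nrow(a1) == length(gene_id), all(dim(a1) == dim(a2)),
            all(dim(a1) == dim(total)), nrow(samples) == ncol(a1))
  req <- c("sample_id", "clone_id", "condition", "replicate")
  if (!all(req %in% names(samples))) {
    stop("samples must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(samples$condition %in% c("WT", "KO"))) {
    stop("condition must be WT or KO")
  }
  for (m in list(a1, a2, total)) {
    if (any(m < 0) || any(m != floor(m))) stop("counts must be non-negative integers")
  }
  if (any(a1 + a2 > total)) stop("allelic counts exceed totals")
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  storage.mode(total) <- "integer"
  dimnames(a1) <- dimnames(a2) <- dimnames(total) <-
    list(gene_id, samples$sample_id)
  structure(list(gene_id = as.character(gene_id),
                 samples = as.data.frame(samples),
                 a1 = a1, a2 = a2, total = total),
            class = "AlleleCountTable")
}

#' @export
print.AlleleCountTable <- function(x, ...) {
  cat("AlleleCountTable:", length(x$gene_id), "genes x",
      nrow(x$samples), "samples (clone",
      paste(unique(x$samples$clone_id), collapse = ","), ")\n")
  cat("  conditions:", paste(table(x$samples$condition), names(table(x$samples$condition)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.AlleleCountTable <- function(x) c(length(x$gene_id), nrow(x$samples))

#' Stack allelic counts into the sample-by-allele column layout
#'
#' Returns a genes x (2 * samples) matrix with the a1 columns first, then the
#' a2 columns, together with the column metadata used by the allelic and
#' interaction GLMs.
#'
#' @param table An \code{AlleleCountTable}.
#' @return list with \code{counts}, \code{columns} (data.frame sample_id,
#'   condition, allele).
#' @export
allele_layout <- function(table) {
  stopifnot(inherits(table, "AlleleCountTable"))
  counts <- cbind(table$a1, table$a2)
  cols <- rbind(
    data.frame(sample_id = table$samples$sample_id,
               condition = table$samples$condition, allele = "a1"),
    data.frame(sample_id = table$samples$sample_id,
               condition = table$samples$condition, allele = "a2"))
  colnames(counts) <- paste(cols$sample_id, cols$allele, sep = ".")
  list(counts = counts, columns = cols)
}
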