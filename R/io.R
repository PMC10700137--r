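#' Write an allele count table as long-format TSV
#'
#' Columns: gene_id, sample_id, clone, condition, replicate, allele
#' (a1 | a2 | total), count.
#'
#' @param table An \code{AlleleCountTable}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "AlleleCountTable"))
  s <- table$samples
  rows <- lapply(c("a1", "a2", "total"), function(al) {
    m <- table[[al]]
    data.frame(gene_id = rep(table$gene_id, times = ncol(m)),
               sample_id = rep(s$sample_id, each = nrow(m)),
               clone = rep(s$clone_id, each = nrow(m)),
               condition = rep(s$condition, each = nrow(m)),
               replicate = rep(s$replicate, each = nrow(m)),
               allele = al, count = as.vector(m))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-resolved counts
#'
#' Auto-detects the dialect from the header. The long dialect has an
#' \code{allele} column (as written by \code{\link{write_counts}}); the wide
#' dialect has a \code{gene_id} column followed by sample columns named
#' \code{<sample_id>.<a1|a2|total>} and needs a metadata table (sample_id,
#' clone_id, condition, replicate) via \code{metadata}.
#'
#' @param path TSV file.
#' @param metadata Optional data.frame or TSV path with sample metadata
#'   (wide dialect only).
#' @return An \code{AlleleCountTable} (single clone) or a named list of
#'   tables (one per clone).
#' @export
read_counts <- function(path, metadata = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if ("allele" %in% header) .read_counts_long(path) else
    .read_counts_wide(path, metadata)
}

.read_counts_long <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "sample_id", "clone", "condition", "replicate",
           "allele", "count")
  if (!all(req %in% names(df))) {
    stop("long counts file needs columns: ", paste(req, collapse = ", "))
  }
  bad_allele <- which(!df$allele %in% c("a1", "a2", "total"))
  if (length(bad_allele)) {
    stop("unknown allele label at line ", bad_allele[1L] + 1L)
  }
  bad_count <- which(is.na(df$count) | df$count < 0 |
                       df$count != floor(df$count))
  if (length(bad_count)) {
    stop("non-integer or negative count at line ", bad_count[1L] + 1L)
  }
  key <- paste(df$gene_id, df$sample_id, df$allele)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (gene, sample, allele) row at line ", dup[1L] + 1L)
  }
  out <- lapply(split(df, df$clone), function(x) {
    genes <- unique(x$gene_id)
    meta <- unique(x[, c("sample_id", "clone", "condition", "replicate")])
    names(meta)[2L] <- "clone_id"
    meta <- meta[order(match(meta$sample_id, x$sample_id)), ]
    grab <- function(al) {
      sub <- x[x$allele == al, ]
      m <- base::matrix(0L, length(genes), nrow(meta),
                        dimnames = list(genes, meta$sample_id))
      m[cbind(match(sub$gene_id, genes), match(sub$sample_id, meta$sample_id))] <-
        as.integer(sub$count)
      m
    }
    allele_count_table(genes, meta, grab("a1"), grab("a2"), grab("total"))
  })
  if (length(out) == 1L) out[[1L]] else out
}

.read_counts_wide <- function(path, metadata) {
  if (is.null(metadata)) stop("wide dialect needs sample metadata")
  if (is.character(metadata)) {
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("wide counts file must start with gene_id")
  genes <- df$gene_id
  grab <- function(al) {
    cols <- paste(metadata$sample_id, al, sep = ".")
    missing <- setdiff(cols, names(df))
    if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
    m <- as.matrix(df[, cols])
    if (any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
      stop("non-integer or negative count in wide table")
    }
    dimnames(m) <- list(genes, metadata$sample_id)
    m
  }
  allele_count_table(genes, metadata, grab("a1"), grab("a2"), grab("total"))
}

#' Write the wide three-matrix dialect
#'
#' @param table An \code{AlleleCountTable}.
#' @param path Counts TSV path; metadata is written next to it with suffix
#'   \code{.meta.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_counts_wide <- function(table, path) {
  stopifnot(inherits(table, "AlleleCountTable"))
  blocks <- lapply(c("a1", "a2", "total"), function(al) {
    m <- table[[al]]
    colnames(m) <- paste(table$samples$sample_id, al, sep = ".")
    m
  })
  df <- data.frame(gene_id = table$gene_id, do.call(cbind, blocks),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$samples, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED3-6, 0-based half-open. The TSS of each interval is its start for
#' plus-strand (or strandless) records and end - 1 for minus-strand records.
#'
#' @param path BED file (tab-separated, no header).
#' @return data.frame sorted by (chrom, start): chrom, start, end, name,
#'   score, strand, tss.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(parts)
  bad <- which(n_col < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1L])
  get <- function(i, default) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else default, "")
  }
  start <- suppressWarnings(as.integer(get(2L, NA)))
  end <- suppressWarnings(as.integer(get(3L, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1L])
  bad <- which(start >= end | start < 0L)
  if (length(bad)) stop("invalid interval (start >= end) at line ", bad[1L])
  strand <- get(6L, "+")
  strand[!strand %in% c("+", "-")] <- "+"
  df <- data.frame(chrom = get(1L, NA), start = start, end = end,
                   name = get(4L, "."),
                   score = suppressWarnings(as.numeric(get(5L, "0"))),
                   strand = strand)
  df$tss <- ifelse(df$strand == "-", df$end - 1L, df$start)
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  df
}

#' Write / read a contact matrix as upper-triangle TSV
#'
#' The TSV stores bin_i, bin_j (1-based, i <= j) and value; the bin size is
#' written to a JSON sidecar \code{<path>.json}.
#'
#' @param matrix Symmetric matrix with attribute \code{bin_size}.
#' @param path Output TSV path.
#' @return \code{path} (write) or the reconstructed matrix (read).
#' @export
write_contacts <- function(matrix, path) {
  m <- unclass(matrix)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  utils::write.table(data.frame(bin_i = idx[, 1L], bin_j = idx[, 2L],
                                value = m[idx]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(n_bins = nrow(m),
               bin_size = attr(matrix, "bin_size"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  df <- utils::read.delim(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  n <- side$n_bins
  m <- base::matrix(0, n, n)
  m[cbind(df$bin_i, df$bin_j)] <- df$value
  m[cbind(df$bin_j, df$bin_i)] <- df$value
  attr(m, "bin_size") <- side$bin_size
  m
}

#' Write a plain TSV with header
#'
#' @param df data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
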