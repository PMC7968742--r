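#' Construct a count table with its design sheet
#'
#' Lightweight container pairing a genes-by-samples matrix of expression
#' counts with a design sheet. The design distinguishes parental "total"
#' libraries from the two F1 allele channels so that downstream contrasts can
#' address parental expression, allele-specific expression, or both.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns. Fractional
#'   counts (from ambiguous-read redistribution) are allowed.
#' @param design `data.frame` with one row per sample column and columns
#'   `sample`, `genotype` (one of `"CBR"`, `"CNI"`, `"F1"`), `sex`
#'   (`"male"`/`"female"`), `replicate`, and `channel` (one of `"total"`,
#'   `"allele_CBR"`, `"allele_CNI"`).
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `design`.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample = paste0("s", 1:4),
#'                 genotype = rep(c("CBR", "CNI"), each = 2),
#'                 sex = "female", replicate = rep(1:2, 2), channel = "total")
#' ct <- count_table(m, d)
#' @export
count_table <- function(counts, design) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), all(counts >= 0, na.rm = TRUE))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- c("sample", "genotype", "sex", "replicate", "channel")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0L)
    stop("design sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(design) != ncol(counts))
    stop("design rows (", nrow(design), ") must match sample columns (",
         ncol(counts), ")")
  if (!is.null(colnames(counts))) {
    if (!all(design$sample == colnames(counts))) {
      if (all(sort(design$sample) == sort(colnames(counts)))) {
        design <- design[match(colnames(counts), design$sample), , drop = FALSE]
      } else {
        stop("design 'sample' ids do not match count column names")
      }
    }
  } else {
    colnames(counts) <- design$sample
  }
  bad_geno <- setdiff(unique(design$genotype), c("CBR", "CNI", "F1"))
  if (length(bad_geno) > 0L)
    stop("unknown genotype value(s): ", paste(bad_geno, collapse = ", "))
  bad_chan <- setdiff(unique(design$channel),
                      c("total", "allele_CBR", "allele_CNI"))
  if (length(bad_chan) > 0L)
    stop("unknown channel value(s): ", paste(bad_chan, collapse = ", "))
  structure(list(counts = counts, design = design), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(genotype = x$design$genotype, channel = x$design$channel)
  print(tab)
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count table by gene and/or sample
#'
#' @param x A `count_table`.
#' @param genes Row index (names, logical or integer); `NULL` keeps all.
#' @param samples Column index; `NULL` keeps all.
#' @return A `count_table` restricted to the requested genes and samples.
#' @export
subset_count_table <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_table"))
  m <- x$counts
  d <- x$design
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(samples)) {
    m <- m[, samples, drop = FALSE]
    d <- d[match(colnames(m), d$sample), , drop = FALSE]
    rownames(d) <- NULL
  }
  count_table(m, d)
}

#' Read counts and design from TSV files
#'
#' The counts file is genes x samples with gene ids in the first column; the
#' design file has the columns described in [count_table()]. Lines starting
#' with `#` are treated as comments (the pipeline writes provenance headers).
#'
#' @param counts_tsv,design_tsv Paths to tab-separated files.
#' @return A `count_table`.
#' @export
read_count_table <- function(counts_tsv, design_tsv) {
  cm <- utils::read.delim(counts_tsv, row.names = 1, check.names = FALSE,
                          comment.char = "#")
  d <- utils::read.delim(design_tsv, check.names = FALSE, comment.char = "#",
                         colClasses = "character")
  d$replicate <- as.integer(d$replicate)
  count_table(as.matrix(cm), d)
}

#' Write a count table to TSV files
#'
#' @param x A `count_table`.
#' @param counts_tsv,design_tsv Output paths.
#' @param header Optional comment line (without the leading `#`) written at the
#'   top of both files, used by the pipeline to record the config hash and seed.
#' @return Invisibly, `x`.
#' @export
write_count_table <- function(x, counts_tsv, design_tsv, header = NULL) {
  stopifnot(inherits(x, "count_table"))
  write_tsv_with_header(data.frame(gene = rownames(x$counts), x$counts,
                                   check.names = FALSE),
                        counts_tsv, header)
  write_tsv_with_header(x$design, design_tsv, header)
  invisible(x)
}

# shared TSV writer: optional '# ...' provenance line then a tab table
write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
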