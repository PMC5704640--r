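#' Construct an expression matrix
#'
#' A lightweight container for gene-by-sample expression values: a numeric
#' matrix with unique gene identifiers as rownames, sample identifiers as
#' colnames, and a declared measurement unit. All downstream functions also
#' accept a plain named numeric matrix (unit `"arbitrary"` is assumed).
#'
#' Values must be finite and non-negative; missing measurements are not
#' allowed inside the matrix — a gene not measured on a platform is simply
#' absent from the rows (see [intersect_genes()]).
#'
#' @param values numeric matrix, genes as rows (unique rownames), samples as
#'   columns (colnames).
#' @param unit one of `"arbitrary"`, `"counts"`, `"RPKM"`, `"FPKM"`,
#'   `"intensity"`.
#' @return an `ExpressionMatrix`: a numeric matrix with a `unit` attribute.
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 5, 3), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_matrix(m, unit = "counts")
#' @export
expression_matrix <- function(values,
                              unit = c("arbitrary", "counts", "RPKM",
                                       "FPKM", "intensity")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_expression_values(values)
  structure(values, unit = unit,
            class = c("ExpressionMatrix", "matrix", "array"))
}

unclass_em <- function(x) {
  attr(x, "unit") <- NULL
  class(x) <- NULL
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
  x
}

validate_expression_values <- function(values) {
  gn <- rownames(values)
  if (is.null(gn) || anyNA(gn) || any(gn == ""))
    stop("gene identifiers (rownames) are required and must be non-empty",
         call. = FALSE)
  if (anyDuplicated(gn)) {
    dup <- unique(gn[duplicated(gn)])
    stop_sprintf("duplicate gene identifiers: %s",
                 paste(head(dup, 5L), collapse = ", "))
  }
  if (is.null(colnames(values)))
    stop("sample identifiers (colnames) are required", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_sprintf(
      "invalid (negative or non-finite) value for gene '%s' in sample '%s'",
      gn[bad[1, 1]], colnames(values)[bad[1, 2]])
  }
  invisible(values)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [unit: %s]\n",
              nrow(x), ncol(x), expr_unit(x)))
  v <- unclass_em(x)
  print(v[seq_len(min(5L, nrow(v))), seq_len(min(5L, ncol(v))), drop = FALSE])
  if (nrow(v) > 5L || ncol(v) > 5L) cat("...\n")
  invisible(x)
}

#' Accessors for expression matrices
#'
#' @param x an `ExpressionMatrix` or plain named numeric matrix.
#' @return `genes()` and `samples()` return character vectors of row/column
#'   identifiers; `expr_unit()` returns the declared unit (`"arbitrary"` for
#'   a plain matrix).
#' @export
genes <- function(x) rownames(as_values(x))

#' @rdname genes
#' @export
samples <- function(x) colnames(as_values(x))

#' @rdname genes
#' @export
expr_unit <- function(x) attr(x, "unit") %||% "arbitrary"

#' Read a gene-by-sample expression table
#'
#' Delimited input is genes-as-rows with the first column holding gene
#' identifiers and the first row holding sample identifiers (tab-separated
#' by default, comma via `format = "csv"`). Matrix Market (`.mtx`) triplet
#' input expects companion one-identifier-per-line text files for genes and
#' samples, as commonly distributed with single-cell matrices.
#'
#' Duplicate gene rows and negative values are validation errors, never
#' silently collapsed or clipped.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"mtx"`.
#' @param genes_path,samples_path companion identifier files for `"mtx"`
#'   input; default: `path` with `.mtx` replaced by `.genes.txt` /
#'   `.samples.txt`.
#' @param unit declared measurement unit of the values.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path,
                                  format = c("auto", "tsv", "csv", "mtx"),
                                  genes_path = NULL, samples_path = NULL,
                                  unit = "arbitrary") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_sprintf("file not found: %s", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    genes_path <- genes_path %||% sub("\\.mtx$", ".genes.txt", path)
    samples_path <- samples_path %||% sub("\\.mtx$", ".samples.txt", path)
    if (!file.exists(genes_path) || !file.exists(samples_path))
      stop("mtx input requires companion gene and sample identifier files",
           call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    gn <- readLines(genes_path)
    sn <- readLines(samples_path)
    if (length(gn) != nrow(m) || length(sn) != ncol(m))
      stop("companion identifier files do not match matrix dimensions",
           call. = FALSE)
    dimnames(m) <- list(gn, sn)
    return(expression_matrix(m, unit = unit))
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("delimited input needs a gene-id column plus >= 1 sample column",
         call. = FALSE)
  gn <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gn
  expression_matrix(m, unit = unit)
}

#' Write an expression matrix as delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_expression_table()` round-trips them to full double precision.
#'
#' @param x matrix or `ExpressionMatrix`.
#' @param path output file.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, sep = "\t") {
  v <- as_values(x)
  chr <- apply(v, 2, function(col) formatC(col, digits = 17, format = "g"))
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(v))
  df <- data.frame(gene_id = rownames(v), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(v))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_table
#' @export
write_expression_mtx <- function(x, path) {
  v <- as_values(x)
  Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), path)
  writeLines(rownames(v), sub("\\.mtx$", ".genes.txt", path))
  writeLines(colnames(v), sub("\\.mtx$", ".samples.txt", path))
  invisible(path)
}

#' Compute RPKM/FPKM from read counts
#'
#' Applies R = 10^9 C / (N L), where C is the mapped-read count of a gene,
#' N the total mapped reads of the sample, and L the summed exon length of
#' the gene in base pairs. For paired-end libraries two reads correspond to
#' one fragment, so the FPKM value is half the RPKM value.
#'
#' @param counts counts matrix (genes x samples).
#' @param gene_lengths named numeric vector of exon lengths in bp, or a
#'   two-column data frame (gene_id, length). Every gene in `counts` must
#'   have a length.
#' @param total_mapped per-sample total mapped reads N (default: column
#'   sums of `counts`); all values must be >= 1.
#' @param paired_end logical; halve values and label the result FPKM.
#' @return an `ExpressionMatrix` with unit `"RPKM"` or `"FPKM"`.
#' @examples
#' cts <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
#' compute_rpkm(cts, c(g1 = 1000), total_mapped = 1e6)  # 10 RPKM
#' @export
compute_rpkm <- function(counts, gene_lengths, total_mapped = NULL,
                         paired_end = FALSE) {
  v <- as_values(counts)
  if (is.data.frame(gene_lengths)) {
    gl <- gene_lengths[[2L]]
    names(gl) <- as.character(gene_lengths[[1L]])
    gene_lengths <- gl
  }
  missing_len <- setdiff(rownames(v), names(gene_lengths))
  if (length(missing_len) > 0)
    stop_sprintf("no exon length for gene(s): %s",
                 paste(head(missing_len, 5L), collapse = ", "))
  L <- gene_lengths[rownames(v)]
  if (any(!is.finite(L) | L < 1))
    stop("exon lengths must be >= 1 bp", call. = FALSE)
  N <- total_mapped %||% colSums(v)
  if (length(N) == 1L) N <- rep(N, ncol(v))
  if (length(N) != ncol(v))
    stop("total_mapped must be length 1 or one value per sample",
         call. = FALSE)
  if (any(!is.finite(N) | N < 1))
    stop("total mapped reads must be >= 1 for every sample", call. = FALSE)
  r <- sweep(v / L, 2, N, "/") * 1e9
  if (paired_end) r <- r / 2
  expression_matrix(r, unit = if (paired_end) "FPKM" else "RPKM")
}

#' Restrict matrices to their common gene universe
#'
#' Platform differences leave some genes unmeasured in some datasets (for
#' example a signature discovered genome-wide may only be partially covered
#' by a BeadArray platform). This restricts every matrix to the shared
#' genes, in the gene order of the first matrix, leaving samples untouched.
#'
#' @param ... expression matrices, or a single list of them.
#' @return a list of matrices over the identical, identically ordered gene
#'   intersection.
#' @export
intersect_genes <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) &&
      !is.matrix(mats[[1L]]) && !inherits(mats[[1L]], "ExpressionMatrix"))
    mats <- mats[[1L]]
  if (length(mats) < 2L) stop("need at least two matrices", call. = FALSE)
  vals <- lapply(mats, as_values)
  common <- Reduce(intersect, lapply(vals, rownames))
  if (length(common) == 0L)
    stop("empty gene intersection across matrices", call. = FALSE)
  common <- rownames(vals[[1L]])[rownames(vals[[1L]]) %in% common]
  lapply(seq_along(mats), function(i) {
    out <- vals[[i]][common, , drop = FALSE]
    if (inherits(mats[[i]], "ExpressionMatrix"))
      out <- expression_matrix(out, unit = expr_unit(mats[[i]]))
    out
  })
}

#' Read gene exon lengths
#'
#' Two-column delimited table (gene_id, exon length in bp).
#'
#' @param path file to read.
#' @param sep field separator.
#' @return named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- as.numeric(tab[[2L]])
  names(out) <- as.character(tab[[1L]])
  if (anyDuplicated(names(out)))
    stop("duplicate gene identifiers in length table", call. = FALSE)
  out
}

#' Read a sample metadata table
#'
#' Delimited table with at least a `sample_id` column; typical columns are
#' `condition`, `input_mass_pg`, `replicate_index` and `role`
#' (high / low input).
#'
#' @param path file to read.
#' @param sep field separator.
#' @return data frame of sample metadata.
#' @export
read_sample_meta <- function(path, sep = "\t") {
  meta <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(meta))
    stop("metadata requires a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  if ("input_mass_pg" %in% colnames(meta) &&
      any(!is.na(meta$input_mass_pg) & meta$input_mass_pg <= 0))
    stop("input_mass_pg must be positive", call. = FALSE)
  meta
}
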