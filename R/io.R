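#' Read a gene expression matrix from tab-delimited text
#'
#' Reads a genes-by-samples matrix of log2-scale expression values. The file
#' must be tab-delimited with the first column holding gene identifiers and
#' the header row holding sample identifiers. Gene identifiers are uppercased
#' on load; duplicate gene rows are collapsed (by per-sample mean by default);
#' missing cells are imputed with the gene's row mean when fewer than 20% of
#' the row is missing, otherwise the gene is dropped.
#'
#' @param path Path to a tab-delimited expression file.
#' @param collapse Policy for duplicate gene rows: `"mean"` (default,
#'   per-sample mean, order-invariant) or `"first"` (keep first occurrence).
#' @param max_missing Maximum fraction of missing cells tolerated per gene row
#'   before the gene is dropped instead of imputed (default 0.2).
#' @param na_tokens Character values treated as missing.
#' @return A numeric matrix with gene rownames and sample colnames, carrying a
#'   `"load_report"` attribute: a list with `n_rows_in`, `collapsed_genes`,
#'   `dropped_genes` (too many missing cells), and `n_imputed` cells.
#' @seealso [write_expression()], [read_clinical()], [join_cohort()]
#' @export
read_expression <- function(path, collapse = c("mean", "first"),
                            max_missing = 0.2,
                            na_tokens = c("", "NA", "NaN", "na", "null", "NULL")) {
  collapse <- match.arg(collapse)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                           check.names = FALSE, quote = "", comment.char = "")
  if (nrow(raw) == 0L) {
    stop("expression file has no data rows: ", path)
  }
  if (ncol(raw) < 2L) {
    stop("expression file needs a gene-id column plus at least one sample column: ", path)
  }
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  gene_in <- toupper(trimws(raw[[1L]]))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  # read.delim already maps the literal string "NA" to NA_character_
  allowed_na <- is.na(body) | trimws(body) %in% na_tokens
  bad <- which(is.na(vals) & !allowed_na, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]], gene_in[bad[1L, 1L]],
                 sample_ids[bad[1L, 2L]]))
  }
  rownames(vals) <- gene_in
  colnames(vals) <- sample_ids

  collapsed <- character(0)
  if (anyDuplicated(gene_in)) {
    collapsed <- sort(unique(gene_in[duplicated(gene_in)]))
    if (collapse == "mean") {
      isna <- is.na(vals)
      v0 <- vals
      v0[isna] <- 0
      sums <- rowsum(v0, group = gene_in, reorder = FALSE)
      cnts <- rowsum(1 - isna, group = gene_in, reorder = FALSE)
      vals <- sums / cnts  # 0/0 -> NaN, treated as missing downstream
    } else {
      vals <- vals[!duplicated(gene_in), , drop = FALSE]
    }
  }

  miss_frac <- rowMeans(is.na(vals))
  dropped <- rownames(vals)[miss_frac >= max_missing & miss_frac > 0]
  keep <- miss_frac < max_missing
  vals <- vals[keep, , drop = FALSE]
  n_imputed <- sum(is.na(vals))
  if (n_imputed > 0L) {
    rm <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm[idx[, 1L]]
  }
  if (nrow(vals) == 0L) {
    stop("no gene rows remain after missing-value filtering: ", path)
  }
  attr(vals, "load_report") <- list(
    n_rows_in = length(gene_in),
    collapsed_genes = collapsed,
    dropped_genes = dropped,
    n_imputed = n_imputed
  )
  vals
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample.
#'
#' @param x Numeric genes-by-samples matrix with rownames and colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Reads a tab-delimited clinical table with required columns `sample_id`,
#' `os_time` (overall survival, months) and `os_event` (1 = death observed,
#' 0 = censored). Any further columns (e.g. `subtype`) are carried along as
#' categorical annotations. Rows whose `os_time` is not a non-negative number
#' or whose `os_event` is not 0/1 are dropped and counted in the load report.
#'
#' @param path Path to a tab-delimited clinical file with a header row.
#' @return A data.frame with at least `sample_id`, `os_time`, `os_event`,
#'   carrying a `"load_report"` attribute with `n_rows_in` and `n_dropped`.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  required <- c("sample_id", "os_time", "os_event")
  missing_col <- setdiff(required, colnames(raw))
  if (length(missing_col) > 0L) {
    stop("clinical table is missing required column(s): ",
         paste(missing_col, collapse = ", "))
  }
  os_time <- suppressWarnings(as.numeric(raw$os_time))
  os_event <- suppressWarnings(as.numeric(raw$os_event))
  ok <- !is.na(os_time) & os_time >= 0 & !is.na(os_event) & os_event %in% c(0, 1)
  out <- raw[ok, , drop = FALSE]
  out$os_time <- os_time[ok]
  out$os_event <- as.integer(os_event[ok])
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample ids in clinical table: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "load_report") <- list(n_rows_in = nrow(raw),
                                   n_dropped = nrow(raw) - nrow(out))
  out
}

#' Write a clinical table as tab-delimited text
#'
#' @param clinical A clinical data.frame as returned by [read_clinical()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set from plain text
#'
#' Accepts either one gene symbol per line, or a two-column tab-delimited
#' `set_name<TAB>gene` file (in which case `set` selects which set to read;
#' default is the first). Symbols are uppercased and de-duplicated.
#'
#' @param path Path to the gene-set file.
#' @param set For two-column files, the set name to extract.
#' @return A character vector of unique uppercase gene symbols.
#' @export
read_gene_set <- function(path, set = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("gene-set file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) >= 2L)) {
    set_name <- vapply(parts, `[[`, "", 1L)
    gene <- vapply(parts, `[[`, "", 2L)
    if (is.null(set)) set <- set_name[1L]
    gene <- gene[set_name == set]
    if (length(gene) == 0L) stop("no genes found for set '", set, "' in ", path)
  } else {
    gene <- vapply(parts, `[[`, "", 1L)
  }
  unique(toupper(gene))
}

#' Write a gene set as one symbol per line
#'
#' @param genes Character vector of gene symbols.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(unique(toupper(genes)), path)
  invisible(path)
}

#' Join an expression matrix with clinical annotations into a cohort
#'
#' Restricts both inputs to their shared sample ids (the intersection);
#' sample order follows the expression matrix.
#'
#' @param expression Numeric genes-by-samples matrix (log2 scale).
#' @param clinical Clinical data.frame with a `sample_id` column.
#' @param name Cohort name.
#' @return An object of class `"cohort"`: a list with elements `name`,
#'   `expression` and `clinical`.
#' @examples
#' x <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' clin <- data.frame(sample_id = paste0("S", 3:7),
#'                    os_time = c(5, 10, 15, 20, 25),
#'                    os_event = c(1, 0, 1, 1, 0))
#' co <- join_cohort(x, clin, "demo")
#' ncol(co$expression)  # 3 shared samples
#' @export
join_cohort <- function(expression, clinical, name = "cohort") {
  stopifnot(is.matrix(expression), is.data.frame(clinical),
            "sample_id" %in% colnames(clinical))
  shared <- intersect(colnames(expression), clinical$sample_id)
  if (length(shared) == 0L) {
    stop("no shared sample ids between expression matrix and clinical table")
  }
  shared <- colnames(expression)[colnames(expression) %in% shared]
  expr <- expression[, shared, drop = FALSE]
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  structure(list(name = name, expression = expr, clinical = clin),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d genes x %d samples, %d clinical records (%d events)\n",
              x$name, nrow(x$expression), ncol(x$expression),
              nrow(x$clinical), sum(x$clinical$os_event)))
  invisible(x)
}
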