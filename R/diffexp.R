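#' Two-group Student t-test per feature
#'
#' Row-wise pooled-variance two-sided Student t-tests on a log2-scale
#' feature-by-sample matrix (genes, or any other feature such as protein
#' abundance). `delta` is the difference of class means on the log2 scale, so
#' `|delta| >= 1` corresponds to at least a two-fold difference. Features with
#' zero pooled variance are reported with `t = 0`, `p = 1` and flagged.
#'
#' @param x Numeric features-by-samples matrix, log2 scale, unstandardized.
#' @param labels Per-sample class labels (two classes, each >= 2 samples).
#' @param positive Label treated as the positive class (see [bccp()] for the
#'   default rule).
#' @param var_equal Pooled-variance Student t (default `TRUE`); set `FALSE`
#'   for the Welch test with Satterthwaite degrees of freedom.
#' @return A data.frame with one row per feature: `gene`, `mean_pos`,
#'   `mean_neg`, `delta` (= mean_pos - mean_neg), `t`, `p`, `n_pos`, `n_neg`,
#'   `zero_variance`.
#' @examples
#' x <- rbind(G1 = c(1, 2, 3, 3, 4, 5))
#' colnames(x) <- paste0("s", 1:6)
#' de_ttest(x, rep(c("A", "B"), each = 3), positive = "A")  # t = -2.449
#' @export
de_ttest <- function(x, labels, positive = NULL, var_equal = TRUE) {
  stopifnot(is.matrix(x), ncol(x) == length(labels))
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must contain exactly 2 classes")
  if (is.null(positive)) positive <- if ("SOH" %in% lv) "SOH" else lv[1L]
  if (!positive %in% lv) stop("positive class '", positive, "' not in labels")
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 2L || n_neg < 2L) {
    stop("each class needs at least 2 samples (got ", n_pos, " / ", n_neg, ")")
  }
  xp <- x[, pos, drop = FALSE]; xn <- x[, !pos, drop = FALSE]
  mp <- rowMeans(xp); mn <- rowMeans(xn)
  vp <- rowSums((xp - mp)^2) / (n_pos - 1L)
  vn <- rowSums((xn - mn)^2) / (n_neg - 1L)
  delta <- mp - mn
  if (var_equal) {
    s2 <- ((n_pos - 1L) * vp + (n_neg - 1L) * vn) / (n_pos + n_neg - 2L)
    se <- sqrt(s2 * (1 / n_pos + 1 / n_neg))
    df <- rep(n_pos + n_neg - 2L, nrow(x))
  } else {
    se <- sqrt(vp / n_pos + vn / n_neg)
    df <- (vp / n_pos + vn / n_neg)^2 /
      ((vp / n_pos)^2 / (n_pos - 1L) + (vn / n_neg)^2 / (n_neg - 1L))
  }
  zero_var <- se == 0
  tval <- ifelse(zero_var, 0, delta / se)
  pval <- ifelse(zero_var, 1, 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  out <- data.frame(
    gene = rownames(x), mean_pos = mp, mean_neg = mn, delta = delta,
    t = tval, p = pval, n_pos = n_pos, n_neg = n_neg,
    zero_variance = zero_var, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Select differentially expressed genes by p-value and fold change
#'
#' A gene is selected iff its two-sided p-value is below `p_cut` AND its
#' absolute log2 mean difference is at least `log2(fold_cut)` ("at least a
#' two-fold difference" is inclusive: `|delta| = 1` exactly passes at
#' `fold_cut = 2`).
#'
#' @param de A [de_ttest()] result table.
#' @param p_cut Raw p-value cutoff (default 0.001; no multiple-testing
#'   correction is applied, matching the raw-cutoff convention of signature
#'   derivation).
#' @param fold_cut Minimum fold change on the linear scale (default 2); must
#'   exceed 1.
#' @return Sorted character vector of selected gene symbols.
#' @export
select_de_genes <- function(de, p_cut = 0.001, fold_cut = 2) {
  stopifnot(is.data.frame(de), nrow(de) > 0L,
            all(c("gene", "delta", "p") %in% colnames(de)))
  if (fold_cut <= 1) stop("fold_cut must be greater than 1")
  sel <- de$p < p_cut & abs(de$delta) >= log2(fold_cut)
  sort(de$gene[sel])
}

#' Intersect gene lists into a core signature
#'
#' The strict intersection of two or more per-cohort DE gene lists, with per-
#' list membership provenance. Genes common to every list form the "core"
#' signature shared across cohorts.
#'
#' @param lists Named list of two or more character vectors of gene symbols.
#' @return An object of class `"core_signature"`: list with `genes` (sorted
#'   intersection), `provenance` (genes-by-lists logical matrix, all `TRUE`
#'   by construction), and `source_counts` (input list sizes). An empty
#'   intersection is a valid empty result with a warning.
#' @examples
#' intersect_gene_lists(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
#'                           c = c("B", "C", "E")))
#' @export
intersect_gene_lists <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2L)
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- paste0("list", seq_along(lists))
  }
  lists <- lapply(lists, function(g) unique(toupper(g)))
  core <- sort(Reduce(intersect, lists))
  if (length(core) == 0L) warning("gene lists have an empty intersection")
  prov <- matrix(vapply(lists, function(g) core %in% g, logical(length(core))),
                 nrow = length(core), ncol = length(lists),
                 dimnames = list(core, names(lists)))
  structure(list(genes = core, provenance = prov,
                 source_counts = lengths(lists)),
            class = "core_signature")
}

#' @export
print.core_signature <- function(x, ...) {
  cat(sprintf("Core signature: %d genes common to %d source lists\n",
              length(x$genes), length(x$source_counts)))
  cat("  source list sizes: ",
      paste(sprintf("%s=%d", names(x$source_counts), x$source_counts),
            collapse = ", "), "\n", sep = "")
  if (length(x$genes) > 0L) {
    shown <- utils::head(x$genes, 8L)
    cat("  genes: ", paste(shown, collapse = ", "),
        if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}
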