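#' Derive a core signature across multiple training cohorts
#'
#' The three-step cross-cancer derivation. For each training cohort:
#' (1) standardize its labeled reference-signature panel and its own
#' expression, train a [bccp()] on the panel, and stratify the cohort's
#' samples into positive/negative subgroups at the posterior `cutoff`;
#' (2) run per-gene pooled t-tests on the cohort's unstandardized log2
#' expression between the two predicted subgroups and select genes at
#' `p < p_cut` with at least a `fold_cut`-fold mean difference. Finally
#' (3) intersect the per-cohort DE lists: genes shared by every cohort form
#' the core signature.
#'
#' @param cohorts Named list of [join_cohort()] objects (or bare log2
#'   genes-by-samples matrices), at least two.
#' @param references List (parallel to `cohorts`) of reference panels, each a
#'   list with `x` (log2 expression of the panel, restricted to that cohort's
#'   original signature genes) and `labels` (its class labels), optionally
#'   `positive`.
#' @param p_cut,fold_cut DE selection thresholds, see [select_de_genes()].
#' @param cutoff Posterior cutoff for step-1 stratification (default 0.5).
#' @param min_coverage Minimum signature coverage for step-1 prediction.
#' @return A `"core_signature"` object (see [intersect_gene_lists()]) with two
#'   extra fields: `stratification` (per-cohort data.frame of step-1 calls)
#'   and `de_sizes` (per-cohort DE list sizes, also in `source_counts`).
#' @seealso [classify_cohort()] for applying the derived signature.
#' @export
derive_core_signature <- function(cohorts, references, p_cut = 0.001,
                                  fold_cut = 2, cutoff = 0.5,
                                  min_coverage = 0.5) {
  stopifnot(is.list(cohorts), is.list(references),
            length(cohorts) >= 2L, length(cohorts) == length(references))
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  de_lists <- vector("list", length(cohorts))
  names(de_lists) <- names(cohorts)
  strat <- de_lists
  for (i in seq_along(cohorts)) {
    nm <- names(cohorts)[i]
    expr <- if (inherits(cohorts[[i]], "cohort")) cohorts[[i]]$expression else cohorts[[i]]
    ref <- references[[i]]
    stopifnot(is.list(ref), is.matrix(ref$x), !is.null(ref$labels))
    model <- bccp(standardize_genes(ref$x), ref$labels,
                  positive = ref$positive)
    calls <- predict(model, standardize_genes(expr), cutoff = cutoff,
                     min_coverage = min_coverage)
    if (length(unique(calls$label)) < 2L) {
      stop("stratification of cohort '", nm, "' produced a single class ('",
           calls$label[1L], "'); cannot run differential expression")
    }
    strat[[i]] <- calls
    de <- de_ttest(expr, calls$label, positive = unname(model$classes[1L]))
    de_lists[[i]] <- select_de_genes(de, p_cut = p_cut, fold_cut = fold_cut)
  }
  core <- intersect_gene_lists(de_lists)
  core$stratification <- strat
  core$de_sizes <- lengths(de_lists)
  core
}

#' Classify a target cohort with a derived signature
#'
#' Projects a gene signature trained on labeled reference expression onto a
#' new cohort: genes are aligned between training and target, both sides are
#' standardized independently, a [bccp()] classifier is fitted on the
#' training panel and applied to the target at the posterior `cutoff`. The
#' classifier's leave-one-out misclassification rate on the training panel is
#' reported alongside as a robustness estimate.
#'
#' @param genes Signature gene symbols (character vector or a
#'   `"core_signature"` object).
#' @param training List with `x` (log2 expression of the labeled training
#'   panel), `labels`, optionally `positive`.
#' @param target A [join_cohort()] object or a log2 genes-by-samples matrix.
#' @param cutoff Posterior cutoff (default 0.5; a posterior exactly at the
#'   cutoff is called negative).
#' @param min_coverage Minimum fraction of signature genes that must survive
#'   alignment and standardization on both sides (default 0.5).
#' @param labels Optional length-2 relabeling of (positive, negative) calls.
#' @return An object of class `"signature_projection"`: list with `calls`
#'   (data.frame `sample_id`, `score`, `posterior`, `label`), `loocv_rate`
#'   (`NA` when a training class has < 3 samples), `coverage`, `model`, and
#'   `signature_size`.
#' @export
classify_cohort <- function(genes, training, target, cutoff = 0.5,
                            min_coverage = 0.5, labels = NULL) {
  if (inherits(genes, "core_signature")) genes <- genes$genes
  genes <- unique(toupper(genes))
  if (length(genes) == 0L) stop("empty signature gene set")
  stopifnot(is.list(training), is.matrix(training$x), !is.null(training$labels))
  expr <- if (inherits(target, "cohort")) target$expression else target
  stopifnot(is.matrix(expr))

  train_x <- training$x[rownames(training$x) %in% genes, , drop = FALSE]
  target_x <- expr[rownames(expr) %in% genes, , drop = FALSE]
  common <- intersect(rownames(train_x), rownames(target_x))
  coverage <- length(common) / length(genes)
  if (coverage < min_coverage) {
    stop(sprintf(
      "signature coverage %.1f%% (%d of %d genes in both training and target) is below the minimum %.1f%%",
      100 * coverage, length(common), length(genes), 100 * min_coverage))
  }
  std <- align_genes(list(standardize_genes(train_x[common, , drop = FALSE]),
                          standardize_genes(target_x[common, , drop = FALSE])))
  model <- bccp(std[[1L]], training$labels, positive = training$positive)
  calls <- predict(model, std[[2L]], cutoff = cutoff, min_coverage = 0,
                   labels = labels)
  tab <- table(training$labels)
  loocv <- if (all(tab >= 3L)) {
    as.numeric(loocv_error(std[[1L]], training$labels,
                           positive = training$positive, cutoff = cutoff))
  } else NA_real_
  structure(list(calls = calls, loocv_rate = loocv, coverage = coverage,
                 model = model, signature_size = length(genes)),
            class = "signature_projection")
}

#' @export
print.signature_projection <- function(x, ...) {
  cat(sprintf("Signature projection: %d-gene signature, coverage %.1f%%\n",
              x$signature_size, 100 * x$coverage))
  print(table(x$calls$label))
  if (!is.na(x$loocv_rate)) {
    cat(sprintf("training LOOCV misclassification rate: %.3f\n", x$loocv_rate))
  }
  invisible(x)
}

#' Metagene score: average signature expression per sample
#'
#' The per-sample mean of (by convention standardized) expression over a gene
#' set, e.g. an EMT metagene averaged over its signature genes. Standardized
#' input makes the average comparable across genes with different dynamic
#' ranges; pass raw log2 expression for an unweighted average on the original
#' scale.
#'
#' @param x Genes-by-samples matrix (standardized by convention).
#' @param genes Signature gene symbols.
#' @return A data.frame with `sample_id` and `score`, with the number of
#'   signature genes found attached as attribute `"n_genes_used"`.
#' @export
metagene_score <- function(x, genes) {
  stopifnot(is.matrix(x))
  genes <- unique(toupper(genes))
  present <- intersect(genes, rownames(x))
  if (length(present) == 0L) stop("no signature genes present in the matrix")
  sc <- colMeans(x[present, , drop = FALSE])
  out <- data.frame(sample_id = colnames(x), score = as.vector(sc),
                    stringsAsFactors = FALSE)
  attr(out, "n_genes_used") <- length(present)
  out
}

#' Probability-based signature score (ISS / TGF-beta style)
#'
#' Identical computation to [classify_cohort()] — a BCCP posterior from a
#' labeled signature reference panel, dichotomized at `cutoff` — but with
#' caller-supplied group names, e.g. `c("high", "low")` for an immune
#' signature score or `c("active", "inactive")` for a pathway-activity
#' signature.
#'
#' @param reference List with `x` (log2 expression of the labeled signature
#'   panel), `labels`, optionally `positive`.
#' @param target A [join_cohort()] object or log2 matrix.
#' @param cutoff Posterior cutoff (default 0.5; exactly at the cutoff gives
#'   the second, "low", label).
#' @param labels Length-2 group names, (positive, negative).
#' @param min_coverage As in [classify_cohort()].
#' @return A `"signature_projection"` object whose calls use `labels`.
#' @export
score_probability_signature <- function(reference, target, cutoff = 0.5,
                                        labels = c("high", "low"),
                                        min_coverage = 0.5) {
  classify_cohort(genes = rownames(reference$x), training = reference,
                  target = target, cutoff = cutoff,
                  min_coverage = min_coverage, labels = labels)
}
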