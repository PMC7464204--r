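#' Fit a Bayesian compound covariate predictor (BCCP)
#'
#' Trains the two-class compound covariate classifier of the BRB-ArrayTools
#' lineage on standardized (z-score) expression. Each signature gene g gets a
#' pooled-variance Student t-statistic weight
#' \deqn{t_g = (m_{+,g} - m_{-,g}) / (s_g \sqrt{1/n_+ + 1/n_-})}
#' and each sample a compound score \eqn{c_j = \sum_g t_g x_{gj}}. Class-
#' conditional Gaussian densities are fitted to the training scores (per-class
#' mean and sample SD), and Bayes' rule with the given priors converts a new
#' sample's score into a posterior probability of the positive class.
#'
#' @param x Standardized genes-by-samples matrix (see [standardize_genes()]).
#' @param labels Per-sample class labels (two distinct values, e.g.
#'   `"SOH"`/`"AH"`).
#' @param genes Signature gene symbols; defaults to all rows of `x`. Genes
#'   absent from `x` are recorded in `$unused_genes`.
#' @param positive Label treated as the positive class. Defaults to `"SOH"`
#'   when that label is present, otherwise the first label in data order.
#' @param priors Length-2 prior probabilities (positive, negative); must sum
#'   to 1. Default equal priors.
#' @return An object of class `"bccp"`: list with `genes` (used), `weights`
#'   (named t-statistics), `classes` (positive, negative), `score_stats`
#'   (per-class n, mean, sd of compound scores), `priors`, `unused_genes`,
#'   `scores` and `labels` of the training samples, and the `call`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 10, 20,
#'             dimnames = list(paste0("G", 1:10), paste0("S", 1:20)))
#' grp <- rep(c("SOH", "AH"), each = 10)
#' x[1:5, grp == "SOH"] <- x[1:5, grp == "SOH"] + 2
#' fit <- bccp(standardize_genes(x), grp)
#' predict(fit, standardize_genes(x))
#' @seealso [predict.bccp()], [loocv_error()], [classify_cohort()]
#' @export
bccp <- function(x, labels, genes = rownames(x), positive = NULL,
                 priors = c(0.5, 0.5)) {
  stopifnot(is.matrix(x), ncol(x) == length(labels))
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must contain exactly 2 classes, got ", length(lv))
  if (is.null(positive)) positive <- if ("SOH" %in% lv) "SOH" else lv[1L]
  if (!positive %in% lv) stop("positive class '", positive, "' not present in labels")
  negative <- setdiff(lv, positive)
  if (length(priors) != 2L || any(priors <= 0) || abs(sum(priors) - 1) > 1e-8) {
    stop("priors must be 2 positive probabilities summing to 1")
  }
  genes <- unique(toupper(genes))
  used <- intersect(genes, rownames(x))
  if (length(used) == 0L) stop("none of the signature genes are present in the matrix")

  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 2L || n_neg < 2L) {
    stop("each class needs at least 2 samples (got ", n_pos, " / ", n_neg, ")")
  }
  xp <- x[used, pos, drop = FALSE]
  xn <- x[used, !pos, drop = FALSE]
  mp <- rowMeans(xp); mn <- rowMeans(xn)
  ssp <- rowSums((xp - mp)^2); ssn <- rowSums((xn - mn)^2)
  s_pooled <- sqrt((ssp + ssn) / (n_pos + n_neg - 2L))
  se <- s_pooled * sqrt(1 / n_pos + 1 / n_neg)
  w <- ifelse(se > 0, (mp - mn) / se, 0)
  names(w) <- used

  scores <- as.vector(crossprod(x[used, , drop = FALSE], w))
  names(scores) <- colnames(x)
  stats <- data.frame(
    class = c(positive, negative),
    n = c(n_pos, n_neg),
    mean = c(mean(scores[pos]), mean(scores[!pos])),
    sd = c(stats::sd(scores[pos]), stats::sd(scores[!pos])),
    stringsAsFactors = FALSE
  )
  if (any(stats$sd <= 0)) {
    stop("compound scores are constant within class '",
         stats$class[which(stats$sd <= 0)[1L]],
         "'; cannot fit a Gaussian score density")
  }
  structure(list(
    genes = used,
    weights = w,
    classes = c(positive = positive, negative = negative),
    score_stats = stats,
    priors = stats::setNames(priors, c(positive, negative)),
    unused_genes = setdiff(genes, used),
    scores = scores,
    labels = labels,
    call = match.call()
  ), class = "bccp")
}

#' Compound covariate scores for new samples
#'
#' Computes the per-sample weighted sum \eqn{c_j = \sum_g t_g x_{gj}} over the
#' model genes present in `newdata`. The fraction of model genes found is
#' attached as the `"coverage"` attribute.
#'
#' @param object A fitted [bccp()] model.
#' @param newdata Standardized genes-by-samples matrix.
#' @param min_coverage Minimum fraction of model genes that must be present
#'   (default 0.5); below this the projection is considered unreliable and an
#'   error is raised.
#' @return Named numeric vector of compound scores.
#' @export
compound_score <- function(object, newdata, min_coverage = 0.5) {
  stopifnot(inherits(object, "bccp"), is.matrix(newdata))
  present <- intersect(object$genes, rownames(newdata))
  coverage <- length(present) / length(object$genes)
  if (length(present) == 0L) stop("no model genes present in newdata")
  if (coverage < min_coverage) {
    stop(sprintf("gene coverage %.1f%% is below the minimum %.1f%%",
                 100 * coverage, 100 * min_coverage))
  }
  sc <- as.vector(crossprod(newdata[present, , drop = FALSE],
                            object$weights[present]))
  names(sc) <- colnames(newdata)
  attr(sc, "coverage") <- coverage
  sc
}

#' Posterior class probabilities and calls from a BCCP model
#'
#' Applies Bayes' rule on the compound score using the fitted Gaussian
#' class-conditional densities:
#' \deqn{P(+|c) = \pi_+ N(c;\mu_+,\sigma_+) / [\pi_+ N(c;\mu_+,\sigma_+) +
#'   \pi_- N(c;\mu_-,\sigma_-)]}
#' A sample is called positive when its posterior strictly exceeds `cutoff`
#' (a posterior exactly at the cutoff is called negative: the positive class
#' is the flagged condition and requires strict evidence).
#'
#' @param object A fitted [bccp()] model.
#' @param newdata Standardized genes-by-samples matrix.
#' @param cutoff Posterior probability cutoff (default 0.5).
#' @param min_coverage Passed to [compound_score()].
#' @param labels Optional length-2 character vector renaming the (positive,
#'   negative) calls, e.g. `c("high", "low")`.
#' @param ... Unused.
#' @return A data.frame with columns `sample_id`, `score`, `posterior` (of the
#'   positive class) and `label`, with the gene `"coverage"` as an attribute.
#' @export
predict.bccp <- function(object, newdata, cutoff = 0.5, min_coverage = 0.5,
                         labels = NULL, ...) {
  sc <- compound_score(object, newdata, min_coverage = min_coverage)
  if (is.null(labels)) labels <- unname(object$classes)
  stopifnot(length(labels) == 2L)
  posterior <- score_posterior(object, sc)
  out <- data.frame(
    sample_id = names(sc),
    score = as.vector(sc),
    posterior = as.vector(posterior),
    label = ifelse(posterior > cutoff, labels[1L], labels[2L]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "coverage") <- attr(sc, "coverage")
  out
}

#' Leave-one-out cross-validated misclassification rate
#'
#' Estimates classifier robustness: each training sample is held out in turn,
#' the t-weights and Gaussian score densities are refitted on the remainder
#' (the signature gene set stays fixed, as it is derived externally), and the
#' held-out sample is classified. The rate is the fraction misclassified.
#'
#' @param x Standardized genes-by-samples matrix.
#' @param labels Per-sample class labels (two classes, each with >= 3 samples
#'   so every fold retains >= 2 per class).
#' @param genes Signature genes (default all rows).
#' @param positive,priors,cutoff As in [bccp()] / [predict.bccp()].
#' @return Misclassification rate in `[0, 1]`, with the per-sample predicted
#'   labels attached as the `"calls"` attribute.
#' @export
loocv_error <- function(x, labels, genes = rownames(x), positive = NULL,
                        priors = c(0.5, 0.5), cutoff = 0.5) {
  stopifnot(is.matrix(x), ncol(x) == length(labels))
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2L) stop("labels must contain exactly 2 classes")
  if (any(tab < 3L)) {
    stop("each class needs at least 3 samples for leave-one-out cross-validation")
  }
  n <- ncol(x)
  calls <- character(n)
  for (j in seq_len(n)) {
    fit <- bccp(x[, -j, drop = FALSE], labels[-j], genes = genes,
                positive = positive, priors = priors)
    calls[j] <- predict(fit, x[, j, drop = FALSE], cutoff = cutoff,
                        min_coverage = 0)$label
  }
  rate <- mean(calls != labels)
  attr(rate, "calls") <- stats::setNames(calls, colnames(x))
  rate
}

#' @export
print.bccp <- function(x, ...) {
  st <- x$score_stats
  cat(sprintf("Bayesian compound covariate predictor (%d genes)\n",
              length(x$genes)))
  cat(sprintf("  classes: %s (positive) vs %s; priors %.2f / %.2f\n",
              x$classes[1L], x$classes[2L], x$priors[1L], x$priors[2L]))
  for (i in 1:2) {
    cat(sprintf("  %-4s n = %3d  score mean = %8.3f  sd = %7.3f\n",
                st$class[i], st$n[i], st$mean[i], st$sd[i]))
  }
  if (length(x$unused_genes) > 0L) {
    cat(sprintf("  %d signature genes absent from training matrix\n",
                length(x$unused_genes)))
  }
  invisible(x)
}

#' @export
summary.bccp <- function(object, cutoff = 0.5, ...) {
  post <- score_posterior(object, object$scores)
  call <- ifelse(post > cutoff, object$classes[1L], object$classes[2L])
  out <- list(model = object,
              resubstitution_accuracy = mean(call == object$labels),
              weight_range = range(object$weights))
  class(out) <- "summary.bccp"
  out
}

# posterior of the positive class for raw compound scores (log-space Bayes)
score_posterior <- function(object, scores) {
  st <- object$score_stats
  lp_pos <- log(object$priors[1L]) +
    stats::dnorm(scores, st$mean[1L], st$sd[1L], log = TRUE)
  lp_neg <- log(object$priors[2L]) +
    stats::dnorm(scores, st$mean[2L], st$sd[2L], log = TRUE)
  as.vector(1 / (1 + exp(lp_neg - lp_pos)))
}

#' @export
print.summary.bccp <- function(x, ...) {
  print(x$model)
  cat(sprintf("  resubstitution accuracy: %.3f\n", x$resubstitution_accuracy))
  cat(sprintf("  weight range: [%.3f, %.3f]\n",
              x$weight_range[1L], x$weight_range[2L]))
  invisible(x)
}

#' @export
coef.bccp <- function(object, ...) object$weights

#' Plot fitted compound-score densities
#'
#' Shows the two Gaussian class-conditional score densities with a rug of the
#' training compound scores, the geometry behind every posterior call.
#'
#' @param x A fitted [bccp()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bccp <- function(x, ...) {
  st <- x$score_stats
  rng <- range(x$scores, st$mean + 3 * st$sd, st$mean - 3 * st$sd)
  grid <- seq(rng[1L], rng[2L], length.out = 400L)
  d1 <- stats::dnorm(grid, st$mean[1L], st$sd[1L])
  d2 <- stats::dnorm(grid, st$mean[2L], st$sd[2L])
  graphics::plot(grid, d1, type = "l", col = "firebrick", lwd = 2,
                 xlab = "compound covariate score", ylab = "density",
                 ylim = c(0, max(d1, d2) * 1.05), ...)
  graphics::lines(grid, d2, col = "steelblue", lwd = 2)
  pos <- x$labels == x$classes[1L]
  graphics::rug(x$scores[pos], col = "firebrick")
  graphics::rug(x$scores[!pos], col = "steelblue", side = 3)
  graphics::legend("topright", legend = st$class, lwd = 2,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Simulate compound scores from a fitted BCCP model
#'
#' Draws scores from the fitted two-component Gaussian score model using the
#' class priors, useful for posterior-calibration checks.
#'
#' @param object A fitted [bccp()] model.
#' @param nsim Number of scores to draw.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data.frame with columns `class` and `score`.
#' @export
simulate.bccp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  st <- object$score_stats
  cls <- sample(st$class, nsim, replace = TRUE, prob = object$priors)
  i <- match(cls, st$class)
  data.frame(class = cls,
             score = stats::rnorm(nsim, st$mean[i], st$sd[i]),
             stringsAsFactors = FALSE)
}
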