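#' Configuration for a synthetic multi-cohort expression study
#'
#' Parameterizes the generator that emulates the statistical structure the
#' cross-cohort signature pipeline assumes: several cohorts of log2-scale
#' expression with two latent classes, a block of differentially expressed
#' genes shared by every cohort, cohort-specific DE blocks, a coherent
#' EMT-like program coupled to the positive class, labeled reference panels
#' for each cohort's original signature, and exponential survival with
#' uniform censoring and a class hazard ratio.
#'
#' Defaults describe the study conditions used throughout the package's tests:
#' 4 cohorts of 120 samples over 5,000 genes; 60 shared and 40 cohort-specific
#' DE genes shifted by 1.5 log2 units against per-gene noise SD 1.0; DE sign
#' drawn once per study per gene with P(up) = 0.8, so shared genes move
#' coherently (and mostly up) across cohorts; 64 EMT genes shifted up by 1.0
#' in positive samples; reference panels of 30 samples per class; baseline
#' hazard log(2)/15 per month (median survival 15 months in the negative
#' class), hazard ratio 3 for the positive class, uniform censoring on
#' (0, 60] months.
#'
#' @param n_cohorts Number of cohorts (>= 2).
#' @param genes_total Total genes per cohort.
#' @param shared_de_genes Number of DE genes shared by all cohorts.
#' @param cohort_specific_de_genes DE genes private to each cohort.
#' @param emt_genes Size of the planted EMT-like metagene set.
#' @param effect_log2 DE shift in log2 units applied to positive samples.
#' @param emt_coupling Upward log2 shift of EMT genes in positive samples.
#' @param noise_sd Per-gene Gaussian noise SD (log2 units).
#' @param samples_per_cohort Samples per cohort.
#' @param positive_fraction Expected fraction of positive-class samples.
#' @param reference_panel_size Reference-panel samples per class.
#' @param prob_up Probability a DE gene's planted sign is positive.
#' @param baseline_hazard Event rate (per month) in the negative class.
#' @param hazard_ratio_positive Hazard ratio of the positive class (>= 1).
#' @param censor_time_max Upper bound of uniform censoring times (months).
#' @param seed Integer seed; all substreams derive from `(seed, cohort)`.
#' @return A validated list of class `"study_config"`.
#' @export
study_config <- function(n_cohorts = 4L, genes_total = 5000L,
                         shared_de_genes = 60L, cohort_specific_de_genes = 40L,
                         emt_genes = 64L, effect_log2 = 1.5,
                         emt_coupling = 1.0, noise_sd = 1.0,
                         samples_per_cohort = 120L, positive_fraction = 0.5,
                         reference_panel_size = 30L, prob_up = 0.8,
                         baseline_hazard = log(2) / 15,
                         hazard_ratio_positive = 3, censor_time_max = 60,
                         seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              genes_total = as.integer(genes_total),
              shared_de_genes = as.integer(shared_de_genes),
              cohort_specific_de_genes = as.integer(cohort_specific_de_genes),
              emt_genes = as.integer(emt_genes),
              effect_log2 = effect_log2, emt_coupling = emt_coupling,
              noise_sd = noise_sd,
              samples_per_cohort = as.integer(samples_per_cohort),
              positive_fraction = positive_fraction,
              reference_panel_size = as.integer(reference_panel_size),
              prob_up = prob_up, baseline_hazard = baseline_hazard,
              hazard_ratio_positive = hazard_ratio_positive,
              censor_time_max = censor_time_max, seed = as.integer(seed))
  if (cfg$n_cohorts < 2L) stop("n_cohorts must be at least 2")
  planted <- cfg$shared_de_genes + cfg$n_cohorts * cfg$cohort_specific_de_genes +
    cfg$emt_genes
  if (planted > cfg$genes_total) {
    stop("planted gene sets (", planted, ") exceed genes_total (",
         cfg$genes_total, ")")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$positive_fraction <= 0 || cfg$positive_fraction >= 1) {
    stop("positive_fraction must be strictly between 0 and 1")
  }
  if (cfg$samples_per_cohort < 4L) stop("samples_per_cohort must be at least 4")
  if (cfg$reference_panel_size < 2L) stop("reference_panel_size must be at least 2")
  if (cfg$baseline_hazard <= 0 || cfg$hazard_ratio_positive < 1 ||
      cfg$censor_time_max <= 0) {
    stop("hazards and censoring horizon must be positive (hazard ratio >= 1)")
  }
  if (cfg$effect_log2 < 0 || cfg$emt_coupling < 0) {
    stop("effect sizes must be non-negative")
  }
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic study config: %d cohorts x %d samples x %d genes (seed %d)\n",
    x$n_cohorts, x$samples_per_cohort, x$genes_total, x$seed))
  cat(sprintf("  DE genes: %d shared + %d per cohort at %.2f log2; %d EMT genes at %.2f\n",
              x$shared_de_genes, x$cohort_specific_de_genes, x$effect_log2,
              x$emt_genes, x$emt_coupling))
  cat(sprintf("  survival: baseline hazard %.4f/month, HR %.1f, censoring U(0, %g)\n",
              x$baseline_hazard, x$hazard_ratio_positive, x$censor_time_max))
  invisible(x)
}

# Study-level layout (gene ids, baseline means, DE signs, planted sets):
# drawn once per study from the seed alone, so every cohort substream sees
# the same shared structure.
study_layout <- function(config) {
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$genes_total))
  baseline <- stats::rnorm(config$genes_total, mean = 8, sd = 2)
  sign <- ifelse(stats::runif(config$genes_total) < config$prob_up, 1, -1)
  names(baseline) <- names(sign) <- genes
  perm <- sample(config$genes_total)
  take <- function(k) {
    idx <- perm[seq_len(k)]
    perm <<- perm[-seq_len(k)]
    genes[idx]
  }
  shared <- sort(take(config$shared_de_genes))
  emt <- sort(take(config$emt_genes))
  specific <- lapply(seq_len(config$n_cohorts), function(i) {
    sort(take(config$cohort_specific_de_genes))
  })
  names(specific) <- cohort_name(seq_len(config$n_cohorts))
  list(genes = genes, baseline = baseline, sign = sign,
       shared = shared, emt = emt, specific = specific)
}

cohort_name <- function(i) sprintf("cohort%d", i)

cohort_seed <- function(config, i, purpose = 0L) {
  config$seed + 10007L * as.integer(i) + as.integer(purpose)
}

# draw a genes x n matrix from the class model shared by cohorts and panels
draw_expression <- function(layout, config, positive, active, sample_ids) {
  n <- length(positive)
  x <- matrix(stats::rnorm(length(layout$genes) * n, mean = layout$baseline,
                           sd = config$noise_sd),
              nrow = length(layout$genes),
              dimnames = list(layout$genes, sample_ids))
  if (any(positive)) {
    if (length(active) > 0L && config$effect_log2 > 0) {
      x[active, positive] <- x[active, positive] +
        layout$sign[active] * config$effect_log2
    }
    if (config$emt_coupling > 0) {
      x[layout$emt, positive] <- x[layout$emt, positive] + config$emt_coupling
    }
  }
  x
}

#' Simulate one cohort of a synthetic study
#'
#' Deterministic given `(config$seed, cohort_index)`: the study-wide layout
#' (baseline means, DE signs, planted gene sets) is re-derived from the seed
#' and the cohort's own samples are drawn from its substream. Positive-class
#' samples are shifted by `effect_log2` (with the study-wide per-gene sign) on
#' the cohort's active genes — the shared set plus its own specific set — and
#' by `emt_coupling` upward on the EMT set.
#'
#' @param config A [study_config()].
#' @param cohort_index Cohort number in `1..n_cohorts`.
#' @return List with `x` (log2 genes-by-samples matrix), `positive` (hidden
#'   true class, logical), `labels` (`"SOH"`/`"AH"`), and `active_genes`.
#' @export
simulate_cohort <- function(config, cohort_index) {
  stopifnot(inherits(config, "study_config"),
            cohort_index >= 1L, cohort_index <= config$n_cohorts)
  layout <- study_layout(config)
  nm <- cohort_name(cohort_index)
  active <- sort(c(layout$shared, layout$specific[[nm]]))
  set.seed(cohort_seed(config, cohort_index, 0L))
  n <- config$samples_per_cohort
  positive <- stats::runif(n) < config$positive_fraction
  ids <- sprintf("C%dS%03d", cohort_index, seq_len(n))
  x <- draw_expression(layout, config, positive, active, ids)
  list(x = x, positive = positive,
       labels = stats::setNames(ifelse(positive, "SOH", "AH"), ids),
       active_genes = active)
}

#' Simulate survival outcomes for a set of samples
#'
#' Event times are exponential with rate `baseline_hazard` times
#' `hazard_ratio_positive` for positive-class samples; censoring times are
#' uniform on `(0, censor_time_max)`; the recorded time is the minimum and
#' the event flag marks whether the event preceded censoring. A categorical
#' `subtype` label correlated with the hidden class (mesenchymal enriched in
#' the positive class) is attached for association tests.
#'
#' @param positive Logical vector of hidden true classes.
#' @param config A [study_config()].
#' @param sample_ids Optional sample ids (default `S1..Sn`).
#' @param seed Optional seed for standalone use.
#' @return A clinical data.frame: `sample_id`, `os_time`, `os_event`,
#'   `subtype`.
#' @export
simulate_survival <- function(positive, config, sample_ids = NULL, seed = NULL) {
  stopifnot(inherits(config, "study_config"), is.logical(positive))
  if (!is.null(seed)) set.seed(seed)
  n <- length(positive)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  rate <- config$baseline_hazard *
    ifelse(positive, config$hazard_ratio_positive, 1)
  t_event <- stats::rexp(n, rate)
  t_censor <- stats::runif(n, 0, config$censor_time_max)
  subtypes <- c("mesenchymal", "classical", "neural", "proneural")
  probs <- rbind(pos = c(0.7, 0.1, 0.1, 0.1), neg = c(0.1, 0.3, 0.3, 0.3))
  subtype <- vapply(positive, function(p) {
    sample(subtypes, 1L, prob = probs[if (p) "pos" else "neg", ])
  }, character(1))
  data.frame(sample_id = sample_ids,
             os_time = pmin(t_event, t_censor),
             os_event = as.integer(t_event <= t_censor),
             subtype = subtype, stringsAsFactors = FALSE)
}

#' Simulate a complete multi-cohort study
#'
#' Generates every input the signature pipeline consumes, on known ground
#' truth: per-cohort expression and clinical tables, a labeled reference
#' panel per cohort (drawn from the same class model and restricted to that
#' cohort's active genes — its "original signature"), and sidecar truth (the
#' planted shared / specific / EMT gene sets and hidden class labels).
#'
#' @param config A [study_config()].
#' @return An object of class `"synthetic_study"`: list with `cohorts`
#'   (list of [join_cohort()] objects), `references` (per cohort: `x`,
#'   `labels`, `positive`), `truth` (`shared`, `specific`, `emt`, `sign`,
#'   `labels`), and `config`.
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  layout <- study_layout(config)
  cohorts <- references <- labels <- vector("list", config$n_cohorts)
  names(cohorts) <- names(references) <- names(labels) <-
    cohort_name(seq_len(config$n_cohorts))
  for (i in seq_len(config$n_cohorts)) {
    nm <- cohort_name(i)
    sim <- simulate_cohort(config, i)
    set.seed(cohort_seed(config, i, 1L))
    clin <- simulate_survival(sim$positive, config,
                              sample_ids = colnames(sim$x))
    cohorts[[nm]] <- join_cohort(sim$x, clin, name = nm)
    set.seed(cohort_seed(config, i, 2L))
    k <- config$reference_panel_size
    ref_pos <- rep(c(TRUE, FALSE), each = k)
    ref_ids <- sprintf("C%dR%03d", i, seq_len(2L * k))
    ref_x <- draw_expression(layout, config, ref_pos, sim$active_genes, ref_ids)
    references[[nm]] <- list(
      x = ref_x[sim$active_genes, , drop = FALSE],
      labels = ifelse(ref_pos, "SOH", "AH"),
      positive = "SOH")
    labels[[nm]] <- sim$labels
  }
  structure(list(cohorts = cohorts, references = references,
                 truth = list(shared = layout$shared,
                              specific = layout$specific,
                              emt = layout$emt,
                              sign = layout$sign,
                              labels = labels),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d cohorts (seed %d)\n",
              x$config$n_cohorts, x$config$seed))
  for (co in x$cohorts) print(co)
  cat(sprintf("truth: %d shared, %d specific/cohort, %d EMT genes\n",
              length(x$truth$shared),
              length(x$truth$specific[[1L]]), length(x$truth$emt)))
  invisible(x)
}

#' Write a synthetic study to a directory of TSV files
#'
#' Emits, per cohort, the expression matrix, clinical table, reference-panel
#' expression and reference labels in the package's standard tab-delimited
#' formats, plus a `truth/` sidecar directory (planted gene sets and hidden
#' labels — kept out of the pipeline-visible files) and a `config.tsv` echo.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$cohorts)) {
    co <- study$cohorts[[nm]]
    write_expression(co$expression, file.path(dir, paste0(nm, "_expression.tsv")))
    write_clinical(co$clinical, file.path(dir, paste0(nm, "_clinical.tsv")))
    ref <- study$references[[nm]]
    write_expression(ref$x, file.path(dir, paste0(nm, "_reference_expression.tsv")))
    utils::write.table(
      data.frame(sample_id = colnames(ref$x), label = ref$labels),
      file.path(dir, paste0(nm, "_reference_labels.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(study$truth$labels[[nm]]),
                 label = unname(study$truth$labels[[nm]])),
      file.path(truth_dir, paste0(nm, "_true_labels.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_set(study$truth$specific[[nm]],
                   file.path(truth_dir, paste0(nm, "_specific_genes.txt")))
  }
  write_gene_set(study$truth$shared, file.path(truth_dir, "shared_genes.txt"))
  write_gene_set(study$truth$emt, file.path(truth_dir, "emt_genes.txt"))
  cfg <- unclass(study$config)
  utils::write.table(
    data.frame(key = names(cfg), value = vapply(cfg, format, character(1))),
    file.path(dir, "config.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
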