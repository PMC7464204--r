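small_cfg <- function(...) {
  study_config(n_cohorts = 2, genes_total = 400, shared_de_genes = 20,
               cohort_specific_de_genes = 10, emt_genes = 12,
               samples_per_cohort = 60, reference_panel_size = 15,
               seed = 42, ...)
}

test_that("generation is deterministic given the seed and cohort index", {
  cfg <- small_cfg()
  a <- simulate_cohort(cfg, 1)
  b <- simulate_cohort(cfg, 1)
  expect_identical(a$x, b$x)
  expect_identical(a$positive, b$positive)
  c2 <- simulate_cohort(cfg, 2)
  expect_false(identical(a$x, c2$x))
  # cohorts share the study-level layout
  expect_identical(a$active_genes[a$active_genes %in% rownames(c2$x)],
                   a$active_genes)

  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohorts$cohort1$expression, s2$cohorts$cohort1$expression)
  expect_identical(s1$truth, s2$truth)
})

test_that("planted effects appear at the configured size; none under the null", {
  cfg <- study_config(n_cohorts = 2, genes_total = 300, shared_de_genes = 20,
                      cohort_specific_de_genes = 0, emt_genes = 10,
                      samples_per_cohort = 200, reference_panel_size = 10,
                      seed = 42)
  sim <- simulate_cohort(cfg, 1)
  # study-level gene sets and signs come from the public truth
  truth <- simulate_study(cfg)$truth
  d <- rowMeans(sim$x[truth$shared, sim$positive]) -
    rowMeans(sim$x[truth$shared, !sim$positive])
  expect_equal(mean(abs(d)), 1.5, tolerance = 0.25 / 1.5)
  expect_equal(unname(mean(d * truth$sign[truth$shared])), 1.5,
               tolerance = 0.25 / 1.5)

  null_cfg <- study_config(n_cohorts = 2, genes_total = 300,
                           shared_de_genes = 20, cohort_specific_de_genes = 0,
                           emt_genes = 10, effect_log2 = 0, emt_coupling = 0,
                           samples_per_cohort = 200, reference_panel_size = 10,
                           seed = 42)
  nsim <- simulate_cohort(null_cfg, 1)
  nd <- rowMeans(nsim$x[truth$shared, nsim$positive]) -
    rowMeans(nsim$x[truth$shared, !nsim$positive])
  se <- sqrt(1 / sum(nsim$positive) + 1 / sum(!nsim$positive))
  expect_lt(max(abs(nd)), 3 * se)
})

test_that("survival times follow the configured exponential law", {
  cfg <- study_config(baseline_hazard = log(2) / 20, hazard_ratio_positive = 1,
                      censor_time_max = 1e6, seed = 42)
  clin <- simulate_survival(rep(FALSE, 2000), cfg, seed = 42)
  expect_equal(median(clin$os_time), 20, tolerance = 0.1)
  expect_true(all(clin$os_event == 1))  # censoring horizon far beyond events

  # a hazard ratio of 3 shortens positive-class survival in every run
  cfg3 <- study_config(hazard_ratio_positive = 3, seed = 42)
  positive <- rep(c(TRUE, FALSE), each = 100)
  for (s in 1:5) {
    cl <- simulate_survival(positive, cfg3, seed = s)
    km_pos <- km_curve(cl$os_time[positive], cl$os_event[positive])
    km_neg <- km_curve(cl$os_time[!positive], cl$os_event[!positive])
    med <- function(km) km$time[which(km$surv <= 0.5)[1]]
    expect_lt(med(km_pos), med(km_neg))
  }

  # subtype labels are correlated with the hidden class
  cl <- simulate_survival(positive, cfg3, seed = 99)
  frac_mes <- tapply(cl$subtype == "mesenchymal", positive, mean)
  expect_gt(frac_mes["TRUE"], frac_mes["FALSE"])
})

test_that("a written study round-trips through the readers", {
  cfg <- small_cfg()
  st <- simulate_study(cfg)
  dir <- file.path(tempdir(), "study_rt")
  write_study(st, dir)

  x <- read_expression(file.path(dir, "cohort1_expression.tsv"))
  expect_equal(unclass(x)[, ], st$cohorts$cohort1$expression[, ],
               tolerance = 1e-6)
  clin <- read_clinical(file.path(dir, "cohort1_clinical.tsv"))
  expect_equal(clin$sample_id, st$cohorts$cohort1$clinical$sample_id)
  expect_equal(clin$os_event, st$cohorts$cohort1$clinical$os_event)

  shared <- read_gene_set(file.path(dir, "truth", "shared_genes.txt"))
  expect_setequal(shared, st$truth$shared)
  ref <- read_expression(file.path(dir, "cohort2_reference_expression.tsv"))
  expect_equal(nrow(ref), length(st$truth$shared) +
                 length(st$truth$specific$cohort2))

  # truth sidecars never leak into pipeline-visible files
  visible <- list.files(dir, pattern = "\\.tsv$")
  expect_false(any(grepl("true|truth", visible)))
})

test_that("invalid configurations are rejected", {
  expect_error(study_config(genes_total = 50), "exceed")
  expect_error(study_config(positive_fraction = 1), "strictly between")
  expect_error(study_config(noise_sd = 0), "positive")
  expect_error(study_config(baseline_hazard = -1), "positive")
  expect_error(study_config(n_cohorts = 1), "at least 2")
  expect_error(simulate_cohort(small_cfg(), 99), "cohort_index")
})
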