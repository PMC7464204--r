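# Shared fixtures built in code.

# Two-class expression matrix: every gene shifted by +delta in the positive
# class, Gaussian noise, labels "SOH"/"AH".
make_two_class <- function(n_genes = 50, n_per_class = 20, delta = 3,
                           sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n_genes * n, sd = sd), n_genes, n,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n))))
  labels <- rep(c("SOH", "AH"), each = n_per_class)
  x[, labels == "SOH"] <- x[, labels == "SOH"] + delta
  list(x = x, labels = labels)
}

# Minimal BCCP object with prescribed score-density parameters, so posterior
# arithmetic can be checked against closed forms. A single unit-weight gene
# makes the compound score equal the expression value.
fake_bccp <- function(mu_pos, mu_neg, sd_pos, sd_neg = sd_pos,
                      priors = c(0.5, 0.5), classes = c("SOH", "AH")) {
  structure(list(
    genes = "G1",
    weights = c(G1 = 1),
    classes = c(positive = classes[1], negative = classes[2]),
    score_stats = data.frame(class = classes, n = c(10L, 10L),
                             mean = c(mu_pos, mu_neg),
                             sd = c(sd_pos, sd_neg),
                             stringsAsFactors = FALSE),
    priors = stats::setNames(priors, classes),
    unused_genes = character(0),
    scores = numeric(0), labels = character(0)
  ), class = "bccp")
}

# 1 x n matrix whose single gene carries the desired compound scores.
score_matrix <- function(scores) {
  matrix(scores, nrow = 1,
         dimnames = list("G1", paste0("S", seq_along(scores))))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
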