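# Brute-force signature-score oracle: explicit loops, no vectorization, kept
# deliberately independent of the package's matrix algebra.
brute_force_scores <- function(values, up, down) {
  n_genes <- nrow(values)
  n_samples <- ncol(values)
  z <- matrix(NA_real_, n_genes, n_samples,
              dimnames = dimnames(values))
  for (g in seq_len(n_genes)) {
    m <- 0
    for (j in seq_len(n_samples)) m <- m + values[g, j]
    m <- m / n_samples
    ss <- 0
    for (j in seq_len(n_samples)) ss <- ss + (values[g, j] - m)^2
    s <- sqrt(ss / (n_samples - 1))
    for (j in seq_len(n_samples)) z[g, j] <- (values[g, j] - m) / s
  }
  scores <- numeric(n_samples)
  for (j in seq_len(n_samples)) {
    up_sum <- 0
    for (g in up) up_sum <- up_sum + z[g, j]
    dn_sum <- 0
    for (g in down) dn_sum <- dn_sum + z[g, j]
    scores[j] <- up_sum / length(up) - dn_sum / length(down)
  }
  names(scores) <- colnames(values)
  scores
}

# Random expression matrix with named genes/samples.
random_matrix <- function(n_genes, n_samples, scale_tag = "log10") {
  vals <- matrix(rnorm(n_genes * n_samples, mean = 2, sd = 1),
                 nrow = n_genes,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 sprintf("S%02d", seq_len(n_samples))))
  expression_matrix(vals, scale_tag = scale_tag)
}

# Minimal two-model, two-arm volume table used across endpoint tests.
toy_volumes <- function() {
  grid <- expand.grid(model = c("MA", "MB"), rep = 1:3,
                      arm = c("control", "treated"), day = c(0L, 7L, 14L),
                      stringsAsFactors = FALSE)
  grid$animal <- paste(grid$model, grid$arm, grid$rep, sep = "_")
  grid$volume <- 120 + 10 * grid$rep +
    ifelse(grid$arm == "control", 12, 4) * grid$day
  volume_series(grid[c("model", "animal", "arm", "day", "volume")])
}

small_spec <- function(seed, ...) {
  cohort_spec(n_models = 24, n_up = 8, n_down = 6, n_background_genes = 8,
              n_animals_per_arm = 1, measurement_days = c(0L, 14L),
              seed = seed, ...)
}
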