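#' Specify a synthetic PDX cohort
#'
#' Parameters of the latent-factor generative model used for end-to-end and
#' parameter-recovery testing. Each model m carries a latent RAS-activation
#' value `a_m ~ N(0, 1) + mutant_shift * 1[mutant]`; signature Up genes load
#' on `+beta`, Down genes on `-beta` (in gene-sd units), background genes
#' are pure noise; the response dT/dC is a linear function of activation
#' calibrated so the population correlation is `rho`; tumor-volume curves
#' are back-constructed from the programmed response so the endpoint module
#' is exercised end-to-end. Defaults mirror the reference trial: 25 models
#' with a 15/10 wild-type/mutant split, a 105/42-gene signature, a small
#' genotype shift so the genotype-score Welch test is typically
#' nonsignificant, and response location/scale matching the reference
#' cohort's dT/dC distribution (mean 0.45, sd 0.5).
#'
#' @param n_models number of PDX models (columns of the matrix).
#' @param n_background_genes genes carrying no signal.
#' @param n_up,n_down signature gene-set sizes.
#' @param beta activation-to-expression effect (gene-sd units).
#' @param rho target population correlation between latent activation and
#'   dT/dC, strictly inside (-1, 1).
#' @param noise_sd per-gene residual sd (log10 units).
#' @param frac_mutant fraction of models labelled KRAS 12/13 mutant.
#' @param mutant_shift latent-activation mean shift for mutants.
#' @param response_mean,response_sd location/scale of dT/dC.
#' @param n_animals_per_arm animals per arm per model.
#' @param measurement_days volume measurement days (must include 0).
#' @param control_growth fold-change of control tumors over the study.
#' @param animal_noise_sd per-animal noise on the volume-change fraction.
#' @param seed integer seed; fully determines the cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_models = 25L, n_background_genes = 100L,
                        n_up = 105L, n_down = 42L, beta = 1, rho = 0.6,
                        noise_sd = 1, frac_mutant = 0.4, mutant_shift = 0.2,
                        response_mean = 0.45, response_sd = 0.5,
                        n_animals_per_arm = 3L,
                        measurement_days = c(0L, 7L, 14L),
                        control_growth = 2, animal_noise_sd = 0.05,
                        seed = 1L) {
  spec <- list(n_models = as.integer(n_models),
               n_background_genes = as.integer(n_background_genes),
               n_up = as.integer(n_up), n_down = as.integer(n_down),
               beta = beta, rho = rho, noise_sd = noise_sd,
               frac_mutant = frac_mutant, mutant_shift = mutant_shift,
               response_mean = response_mean, response_sd = response_sd,
               n_animals_per_arm = as.integer(n_animals_per_arm),
               measurement_days = sort(unique(as.integer(measurement_days))),
               control_growth = control_growth,
               animal_noise_sd = animal_noise_sd,
               seed = as.integer(seed))
  if (spec$n_models < 2L || spec$n_up < 1L || spec$n_down < 1L ||
      spec$n_background_genes < 0L || spec$n_animals_per_arm < 1L)
    abort_validation("infeasible cohort spec: counts out of range")
  if (!is.finite(spec$rho) || abs(spec$rho) >= 1)
    abort_validation("rho must lie strictly inside (-1, 1)")
  if (!is.finite(spec$noise_sd) || spec$noise_sd <= 0)
    abort_validation("noise_sd must be > 0")
  if (spec$frac_mutant < 0 || spec$frac_mutant > 1)
    abort_validation("frac_mutant must lie in [0, 1]")
  if (length(spec$measurement_days) < 2L || spec$measurement_days[1L] != 0L)
    abort_validation("measurement_days must include day 0 and one later day")
  if (spec$control_growth <= 1)
    abort_validation("control_growth must exceed 1 (controls must grow)")
  structure(spec, class = "cohort_spec")
}

# One RNG stream per cohort, split into named substreams so, e.g., changing
# the number of animals does not perturb the expression draws.
substream_seed <- function(seed, stream) {
  k <- match(stream, c("latent", "expression", "response", "volumes"))
  as.integer((as.double(seed) * 48271 + k * 1000003) %% 2147483587)
}

#' Generate a synthetic PDX cohort
#'
#' Draws a full cohort under the latent-factor model of [cohort_spec()]:
#' a log10-scale expression matrix, the matching Up/Down gene signature,
#' per-animal tumor-volume series (exponential control growth,
#' back-constructed treated curves), genotype annotations, and the
#' ground-truth ledger used by recovery tests. Deterministic given the
#' spec, including its seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `pdx_cohort` with elements `expression`
#'   ([expression_matrix()]), `signature` ([gene_signature()]), `volumes`
#'   ([volume_series()]), `annotations` (data.frame), `truth` (data.frame:
#'   `model_id`, `activation`, `kras_allele`, `kras_class`,
#'   `response_mean`, `programmed_dtc`), and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_models = 10, n_up = 5, n_down = 3,
#'                                       n_background_genes = 5, seed = 42))
#' dim(cohort$expression)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  model_ids <- sprintf("M%03d", seq_len(spec$n_models))

  # -- latent substream: genotype labels and activation ---------------------
  set.seed(substream_seed(spec$seed, "latent"))
  n_mut <- round(spec$frac_mutant * spec$n_models)
  mutant <- rep(FALSE, spec$n_models)
  mutant[sample.int(spec$n_models, n_mut)] <- TRUE
  alleles <- ifelse(mutant,
                    sample(c("G12C", "G12D", "G12V", "G13D"),
                           spec$n_models, replace = TRUE),
                    "WT")
  activation <- rnorm(spec$n_models) + spec$mutant_shift * mutant

  # -- expression substream -------------------------------------------------
  set.seed(substream_seed(spec$seed, "expression"))
  up_ids <- sprintf("SIMUP%03d", seq_len(spec$n_up))
  dn_ids <- sprintf("SIMDN%03d", seq_len(spec$n_down))
  bg_ids <- if (spec$n_background_genes > 0L)
    sprintf("SIMBG%04d", seq_len(spec$n_background_genes)) else character(0)
  gene_ids <- c(up_ids, dn_ids, bg_ids)
  n_genes <- length(gene_ids)
  baseline <- rnorm(n_genes, mean = 2.5, sd = 0.5)   # log10 abundance
  loading <- c(rep(spec$beta, spec$n_up), rep(-spec$beta, spec$n_down),
               rep(0, spec$n_background_genes))
  noise <- matrix(rnorm(n_genes * spec$n_models, sd = spec$noise_sd),
                  nrow = n_genes)
  values <- baseline + loading %o% activation + noise
  dimnames(values) <- list(gene_ids, model_ids)
  expr <- expression_matrix(values, scale_tag = "log10")
  signature <- gene_signature("SIM_RAS", up = up_ids, down = dn_ids)

  # -- response substream ---------------------------------------------------
  set.seed(substream_seed(spec$seed, "response"))
  f <- spec$frac_mutant
  pop_mean <- f * spec$mutant_shift
  pop_sd <- sqrt(1 + f * (1 - f) * spec$mutant_shift^2)
  a_std <- (activation - pop_mean) / pop_sd
  eps <- rnorm(spec$n_models)
  r_mean <- spec$response_mean + spec$response_sd * spec$rho * a_std
  dtc <- r_mean + spec$response_sd * sqrt(1 - spec$rho^2) * eps
  # floor far-left tail so back-constructed treated volumes stay positive:
  # V_end = V0 * (1 + dtc * (G - 1)) must exceed zero
  dtc_floor <- -0.93 / (spec$control_growth - 1)
  dtc <- pmax(dtc, dtc_floor)

  # -- volumes substream ----------------------------------------------------
  set.seed(substream_seed(spec$seed, "volumes"))
  t_end <- max(spec$measurement_days)
  rows <- vector("list", spec$n_models)
  for (m in seq_len(spec$n_models)) {
    na <- spec$n_animals_per_arm
    v0_c <- runif(na, 100, 150)
    v0_t <- runif(na, 100, 150)
    eta <- pmax(rnorm(na, sd = spec$animal_noise_sd),
                -0.98 / (spec$control_growth - 1) - dtc[m])
    ctrl <- lapply(seq_len(na), function(i) {
      data.frame(model = model_ids[m],
                 animal = sprintf("%s_C%d", model_ids[m], i),
                 arm = "control", day = spec$measurement_days,
                 volume = v0_c[i] *
                   spec$control_growth^(spec$measurement_days / t_end))
    })
    trt <- lapply(seq_len(na), function(i) {
      change <- (dtc[m] + eta[i]) * v0_t[i] * (spec$control_growth - 1)
      data.frame(model = model_ids[m],
                 animal = sprintf("%s_T%d", model_ids[m], i),
                 arm = "treated", day = spec$measurement_days,
                 volume = v0_t[i] + change * spec$measurement_days / t_end)
    })
    rows[[m]] <- do.call(rbind, c(ctrl, trt))
  }
  volumes <- volume_series(do.call(rbind, rows))

  annotations <- data.frame(model_id = model_ids, kras_allele = alleles,
                            kras_class = kras_class(alleles),
                            stringsAsFactors = FALSE)
  truth <- data.frame(model_id = model_ids, activation = activation,
                      kras_allele = alleles,
                      kras_class = annotations$kras_class,
                      response_mean = r_mean, programmed_dtc = dtc,
                      stringsAsFactors = FALSE)
  structure(list(expression = expr, signature = signature,
                 volumes = volumes, annotations = annotations,
                 truth = truth, spec = spec),
            class = "pdx_cohort")
}

#' @export
print.pdx_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic PDX cohort: %d models, %d genes (%d Up / %d Down signature), seed %d\n",
    x$spec$n_models, nrow(x$expression), x$spec$n_up, x$spec$n_down,
    x$spec$seed))
  invisible(x)
}

# Theoretical corr(score, activation) under the generative model: the score
# averages n_up + n_down independent noisy copies of +/- beta * a.
expected_score_activation_cor <- function(spec) {
  v <- 1 + spec$frac_mutant * (1 - spec$frac_mutant) * spec$mutant_shift^2
  sig <- 2 * spec$beta * sqrt(v)
  sig / sqrt(sig^2 + spec$noise_sd^2 * (1 / spec$n_up + 1 / spec$n_down))
}

#' Parameter-recovery report for a scored synthetic cohort
#'
#' Compares what the pipeline recovered against the cohort's ground truth:
#' the score-activation correlation (against its closed-form expectation
#' under the generative model), the score-response correlation (against
#' `rho` attenuated by the score's own noise), and the genotype Welch test
#' on scores. Pass bands use a Fisher-z interval of half-width
#' `z_width / sqrt(n - 3)` around the expectation.
#'
#' @param cohort a `pdx_cohort` from [generate_cohort()].
#' @param scores the `score_table` obtained by running [score_pipeline()]
#'   on the cohort's matrix and signature (contract error if it was
#'   computed on a different sample set).
#' @param z_width half-width multiplier of the Fisher-z pass band.
#' @return data.frame `(metric, observed, expected, pass)`; the Welch row
#'   reports the p-value with no pass band (its null behaviour is assessed
#'   across seeds, not per cohort).
#' @export
recovery_report <- function(cohort, scores, z_width = 4) {
  stopifnot(inherits(cohort, "pdx_cohort"), inherits(scores, "score_table"))
  prov <- attr(scores, "provenance")
  if (!identical(prov$sample_key, sample_key(cohort$truth$model_id)))
    abort_contract("scores were computed on a different sample set than this cohort")
  s <- scores$score[match(cohort$truth$model_id, scores$sample_id)]
  n <- length(s)
  exp_sa <- expected_score_activation_cor(cohort$spec)
  obs_sa <- cor(s, cohort$truth$activation)
  exp_sr <- exp_sa * cohort$spec$rho
  obs_sr <- cor(s, cohort$truth$programmed_dtc)
  band <- z_width / sqrt(n - 3)
  in_band <- function(obs, expd) abs(atanh(obs) - atanh(expd)) <= band
  mut <- cohort$truth$kras_class != "WT"
  welch_p <- if (sum(mut) >= 2L && sum(!mut) >= 2L)
    welch_t_test(s[!mut], s[mut], subgroup = "WT_vs_mutant")$p_value
  else NA_real_
  data.frame(
    metric = c("cor_score_activation", "cor_score_response",
               "welch_p_genotype"),
    observed = c(obs_sa, obs_sr, welch_p),
    expected = c(exp_sa, exp_sr, NA_real_),
    pass = c(in_band(obs_sa, exp_sa), in_band(obs_sr, exp_sr), NA),
    stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `expr.tsv`, `signature.gmt`, `volumes.csv`, `annotations.csv` and
#' `truth.csv`, the plain-text forms the readers of this package consume.
#'
#' @param cohort a `pdx_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pdx_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expr.tsv"))
  write_signature(cohort$signature, file.path(dir, "signature.gmt"), "gmt")
  write_volumes(cohort$volumes, file.path(dir, "volumes.csv"))
  write.table(cohort$annotations, file.path(dir, "annotations.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
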