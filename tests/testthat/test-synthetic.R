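# Synthetic miRNAome generator: annotation, expression, missingness,
# correlation structure, determinism.

test_that("generated annotation is valid, spans the panel, and yields a
           scheme (c) group large enough to exercise every k-split", {
  pars <- simulation_params(seed = 1)
  set.seed(pars$seed)
  ann <- generate_annotation(pars)
  expect_equal(nrow(ann), 522L)
  expect_no_error(validate_annotation(ann))
  expect_false(anyDuplicated(ann$start) > 0)
  key <- paste(ann$chrom, ann$strand, ann$arm)
  expect_gt(max(table(key)), 25)

  pars1 <- simulation_params(n_chromosomes = 1, n_mirnas = 50, seed = 2)
  set.seed(2)
  ann1 <- generate_annotation(pars1)
  expect_equal(length(unique(ann1$chrom)), 1L)

  set.seed(3); a <- generate_annotation(pars)
  set.seed(3); b <- generate_annotation(pars)
  expect_identical(a, b)
})

test_that("default dataset reproduces the study missingness profile", {
  d <- generate_dataset(simulation_params(seed = 1))
  miss_pairs <- colSums(is.na(d$expression$tumor))
  n_p <- d$params$n_patients
  frac_any <- mean(miss_pairs >= 1)
  expect_gte(frac_any, 0.4)
  expect_lte(frac_any, 0.75)
  expect_true(all(miss_pairs / n_p <= 0.5))  # drop rule applied
  # pairwise missingness: tumor and normal masks coincide
  expect_identical(is.na(d$expression$tumor), is.na(d$expression$normal))
})

test_that("missingness probability is non-decreasing in the baseline Ct", {
  set.seed(7)
  pars <- simulation_params(seed = 7)
  ann <- generate_annotation(pars)
  # regenerate with known baselines by correlating observed missingness
  # against mean raw Ct: low-abundance (high-Ct) miRNAs are lost more often
  d <- generate_expression(ann, pars)
  mean_ct <- colMeans(d$expression$normal, na.rm = TRUE) +
    pars$ct_housekeeping
  miss_frac <- colMeans(is.na(d$expression$normal))
  keep <- !is.nan(mean_ct)
  expect_gt(stats::cor(mean_ct[keep], miss_frac[keep],
                       method = "spearman"), 0.3)
  lo <- miss_frac[keep][mean_ct[keep] <= stats::median(mean_ct[keep])]
  hi <- miss_frac[keep][mean_ct[keep] > stats::median(mean_ct[keep])]
  expect_lt(mean(lo), mean(hi))
})

test_that("truth labels are consistent and respect the signal fractions", {
  d <- generate_dataset(simulation_params(seed = 5))
  expect_identical(d$truth$is_null, d$truth$true_effect == 0)
  expect_true(all(abs(d$truth$true_effect[!d$truth$is_null]) >= 1.5))
  expect_true(all(abs(d$truth$true_effect[!d$truth$is_null]) <= 7))
  expect_gt(sum(!d$truth$is_null), 0)
  expect_gt(mean(d$truth$is_null), 0.8)  # sparse signals

  none <- generate_dataset(simulation_params(frac_signal_groups = 0,
                                             seed = 6))
  expect_true(all(none$truth$is_null))
})

test_that("no group effect means no intra-group correlation excess", {
  pars <- simulation_params(n_mirnas = 400, sigma_b2 = 0,
                            sigma_e2 = 0.96 * 25, ct_cutoff = 1e6,
                            frac_signal_groups = 0, seed = 21)
  d <- generate_dataset(pars)
  sc <- build_scheme(d$annotation, "chrom_strand_arm")
  est <- estimate_correlations(compute_ddct(d$expression), sc)
  expect_lt(abs(est$rho_intra - est$rho_inter), 0.03)
})

test_that("signal recovery matches the closed-form noncentral-t power", {
  # |mu| in [3, 7] Ct, no missingness: empirical detection at p < 0.01
  # should track the noncentral-t power of the offset test at the
  # generator scale (sd 5 Ct), averaged over the realized effects
  pars <- simulation_params(effect_range = c(3, 7), ct_cutoff = 1e6,
                            frac_signal_groups = 0.3, seed = 31)
  d <- generate_dataset(pars)
  res <- test_all(compute_ddct(d$expression), delta = 1)
  alt <- merge(res, d$truth, by = "mirna_id")
  alt <- alt[!alt$is_null, ]
  expect_gt(nrow(alt), 40)
  tcrit <- stats::qt(0.99, pars$n_patients - 1)
  s <- sqrt(pars$sigma_a2 + pars$sigma_b2 + pars$sigma_e2)
  expected <- mean(stats::pt(
    tcrit, pars$n_patients - 1,
    ncp = (abs(alt$true_effect) - 1) * sqrt(pars$n_patients) / s,
    lower.tail = FALSE))
  empirical <- mean(alt$p_raw < 0.01)
  mc_se <- sqrt(expected * (1 - expected) / nrow(alt))
  expect_lt(abs(empirical - expected), 4 * mc_se + 0.02)
  # detected directions match the signs of the true effects
  hit <- alt[alt$p_raw < 0.01, ]
  expect_true(all(ifelse(hit$true_effect > 0, "down", "up") ==
                    hit$direction))
})

test_that("datasets are reproducible and fixtures round-trip through the
           readers", {
  out1 <- file.path(tempfile(), "d1")
  out2 <- file.path(tempfile(), "d2")
  pars <- simulation_params(n_mirnas = 60, seed = 17)
  d1 <- generate_dataset(pars, out_dir = out1)
  d2 <- generate_dataset(pars, out_dir = out2)
  expect_identical(d1$expression, d2$expression)
  expect_identical(readLines(file.path(out1, "expression.csv")),
                   readLines(file.path(out2, "expression.csv")))
  back <- read_expression(file.path(out1, "expression.csv"), "wide")
  expect_equal(back$tumor, d1$expression$tumor, tolerance = 1e-12)
  ann_back <- read_annotation(file.path(out1, "annotation.tsv"))
  expect_identical(ann_back$mirna_id, d1$annotation$mirna_id)
})
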