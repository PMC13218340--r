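#' @title Synthetic paired miRNAome generator
#' @description Seeded generator for annotation + paired delta-Ct data +
#'   ground truth, emulating the statistical structure of a targeted
#'   qPCR miRNA panel on tumor-normal pairs: ~522 miRNAs on 18 patients,
#'   grouped signals concentrated in a minority of
#'   chromosome/strand/arm groups, an exchangeable random-effects
#'   correlation structure (intra-group correlation exceeding
#'   inter-group), and missing-not-at-random pairwise missingness driven
#'   by a raw-Ct detection limit of 40 cycles.
#' @name synthetic-data
NULL

#' Simulation parameters
#'
#' Defaults encode the study conditions this generator emulates: 18
#' patients x 522 miRNAs on 22 autosomes, detection limit at Ct 40,
#' change-score variance V = 25 (within-miRNA sd 5 Ct) split 4% / 11% /
#' 85% between patient, patient-by-group and residual components
#' (correlation targets 0.04 inter / 0.15 intra), effect magnitudes 1.5
#' to 7 Ct in a minority of groups.
#'
#' @param n_patients,n_mirnas,n_chromosomes cohort and panel sizes.
#' @param frac_signal_groups fraction of chromosome/strand/arm groups
#'   that carry signals (default 0.1).
#' @param frac_alt_within_signal_group fraction of non-null miRNAs inside
#'   a signal group (default 0.5).
#' @param effect_range interval for |mu| in Ct units.
#' @param sigma_a2,sigma_b2,sigma_e2 variance components of the
#'   patient, patient-by-group and residual effects.
#' @param ct_baseline_mean,ct_baseline_sd mean and sd of the per-miRNA
#'   raw-Ct baseline.
#' @param ct_housekeeping raw Ct of the endogenous-control reference
#'   (delta-Ct = raw Ct - this).
#' @param ct_cutoff detection limit in PCR cycles (default 40).
#' @param seed integer RNG seed.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 18L, n_mirnas = 522L,
                              n_chromosomes = 22L,
                              frac_signal_groups = 0.1,
                              frac_alt_within_signal_group = 0.5,
                              effect_range = c(1.5, 7),
                              sigma_a2 = 0.04 * 25,
                              sigma_b2 = 0.11 * 25,
                              sigma_e2 = 0.85 * 25,
                              ct_baseline_mean = 28,
                              ct_baseline_sd = 3,
                              ct_housekeeping = 20,
                              ct_cutoff = 40,
                              seed = 1L) {
  stopifnot(n_patients >= 2, n_mirnas >= 2, n_chromosomes >= 1,
            frac_signal_groups >= 0, frac_signal_groups <= 1,
            frac_alt_within_signal_group >= 0,
            frac_alt_within_signal_group <= 1,
            length(effect_range) == 2L, all(effect_range > 0),
            effect_range[1] <= effect_range[2],
            sigma_a2 >= 0, sigma_b2 >= 0, sigma_e2 >= 0,
            ct_baseline_sd >= 0, seed == floor(seed))
  structure(list(n_patients = as.integer(n_patients),
                 n_mirnas = as.integer(n_mirnas),
                 n_chromosomes = as.integer(n_chromosomes),
                 frac_signal_groups = frac_signal_groups,
                 frac_alt_within_signal_group = frac_alt_within_signal_group,
                 effect_range = effect_range,
                 sigma_a2 = sigma_a2, sigma_b2 = sigma_b2,
                 sigma_e2 = sigma_e2,
                 ct_baseline_mean = ct_baseline_mean,
                 ct_baseline_sd = ct_baseline_sd,
                 ct_housekeeping = ct_housekeeping,
                 ct_cutoff = ct_cutoff, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Generate a synthetic miRNA annotation table
#'
#' miRNAs are scattered over chromosomes with Zipf-like chromosome
#' weights and uneven strand (60% +) and arm (65% q) probabilities, so
#' the chromosome/strand/arm partition mixes small and large groups and
#' at least one group comfortably exceeds 25 members at the default
#' panel size. Start coordinates are unique and drawn within a
#' chromosome-length scale that shrinks with chromosome index.
#'
#' @param params a [simulation_params()].
#' @return Annotation data.frame (`mirna_id`, `chrom`, `strand`, `arm`,
#'   `start`), draws taken from the current RNG state.
#' @export
generate_annotation <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_mirnas
  if (n < 2L) stop("need at least 2 miRNAs", call. = FALSE)
  chroms <- as.character(seq_len(params$n_chromosomes))
  w <- 1 / seq_len(params$n_chromosomes)
  chrom <- sample(chroms, n, replace = TRUE, prob = w / sum(w))
  strand <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.6, 0.4))
  arm <- sample(c("p", "q"), n, replace = TRUE, prob = c(0.35, 0.65))
  len <- 2.4e8 / chrom_index(chrom)
  start <- floor(stats::runif(n, 1, len))
  # enforce unique starts (collisions are vanishingly rare at this scale)
  while (anyDuplicated(start)) {
    dup <- duplicated(start)
    start[dup] <- floor(stats::runif(sum(dup), 1, len[dup]))
  }
  data.frame(mirna_id = sprintf("mir-%04d", seq_len(n)),
             chrom = chrom, strand = strand, arm = arm,
             start = as.integer(start), stringsAsFactors = FALSE)
}

#' Generate paired delta-Ct expression with grouped signals and MNAR
#' missingness
#'
#' Normal-tissue delta-Ct is
#' \eqn{baseline_i + a_j + b_{j,g(i)} + e_{j,i}} and tumor delta-Ct adds
#' \eqn{\mu_i + a'_j + b'_{j,g(i)} + e'_{j,i}} with fresh components, so
#' the change score inherits the exchangeable correlation structure.
#' Non-null \eqn{\mu_i} (|mu| in `effect_range`, random sign) occur in
#' `frac_alt_within_signal_group` of the members of a random
#' `frac_signal_groups` fraction of the chromosome/strand/arm groups.
#' Raw Ct is delta-Ct plus the housekeeping level; any raw Ct beyond
#' `ct_cutoff` makes the whole tumor-normal pair missing (MNAR: high-Ct,
#' low-abundance miRNAs are lost more often), and miRNAs with more than
#' 50% missing pairs are dropped, mirroring source-data preprocessing.
#'
#' @param annotation annotation data.frame (from
#'   [generate_annotation()]).
#' @param params a [simulation_params()].
#' @return List: `expression` (an [expression_table], possibly with
#'   fewer miRNAs than `annotation` after the drop rule), `truth`
#'   (data.frame `mirna_id`, `is_null`, `true_effect`, `group_of_truth`,
#'   restricted to kept miRNAs), `annotation` (kept rows). Draws come
#'   from the current RNG state.
#' @export
generate_expression <- function(annotation, params) {
  stopifnot(inherits(params, "simulation_params"))
  ann <- validate_annotation(annotation)
  n_p <- params$n_patients
  n_m <- nrow(ann)
  g <- paste(ann$chrom, ann$strand, ann$arm, sep = ":")
  groups <- unique(g)

  n_sig <- round(params$frac_signal_groups * length(groups))
  sig_groups <- if (n_sig > 0) sample(groups, n_sig) else character(0)
  mu <- numeric(n_m)
  for (sg in sig_groups) {
    members <- which(g == sg)
    n_alt <- round(params$frac_alt_within_signal_group * length(members))
    if (n_alt == 0) next
    alt <- if (length(members) == 1L) members
           else sample(members, n_alt)
    mu[alt] <- sample(c(-1, 1), length(alt), replace = TRUE) *
      stats::runif(length(alt), params$effect_range[1],
                   params$effect_range[2])
  }

  baseline <- stats::rnorm(n_m, params$ct_baseline_mean,
                           params$ct_baseline_sd)
  sa <- sqrt(params$sigma_a2)
  sb <- sqrt(params$sigma_b2)
  se <- sqrt(params$sigma_e2)
  gi <- match(g, groups)

  draw_layer <- function() {
    a <- stats::rnorm(n_p, 0, sa)
    b <- matrix(stats::rnorm(n_p * length(groups), 0, sb), n_p)
    e <- matrix(stats::rnorm(n_p * n_m, 0, se), n_p)
    a + b[, gi, drop = FALSE] + e
  }

  base_rel <- baseline - params$ct_housekeeping
  normal <- sweep(draw_layer(), 2, base_rel, `+`)
  tumor <- normal + draw_layer() +
    matrix(mu, n_p, n_m, byrow = TRUE)
  dimnames(normal) <- dimnames(tumor) <-
    list(sprintf("P%02d", seq_len(n_p)), ann$mirna_id)

  # detection limit on the raw Ct scale: pair missing if either tissue
  # fails to amplify within ct_cutoff cycles
  limit_rel <- params$ct_cutoff - params$ct_housekeeping
  miss <- (normal > limit_rel) | (tumor > limit_rel)
  normal[miss] <- NA_real_
  tumor[miss] <- NA_real_

  keep <- colMeans(miss) <= 0.5
  normal <- normal[, keep, drop = FALSE]
  tumor <- tumor[, keep, drop = FALSE]

  truth <- data.frame(mirna_id = ann$mirna_id, is_null = mu == 0,
                      true_effect = mu, group_of_truth = g,
                      stringsAsFactors = FALSE)[keep, ]
  rownames(truth) <- NULL
  list(expression = expression_table(tumor, normal),
       truth = truth, annotation = ann[keep, ])
}

#' Generate a complete synthetic dataset under one seed
#'
#' Seeds the RNG from `params$seed`, draws the annotation and the paired
#' expression, and optionally writes plain-text fixture files
#' (`expression.csv` wide, `annotation.tsv`, `truth.tsv`) to `out_dir`.
#'
#' @param params a [simulation_params()].
#' @param out_dir optional directory for fixture files.
#' @return As [generate_expression()], plus `params`.
#' @export
generate_dataset <- function(params = simulation_params(),
                             out_dir = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  ann <- generate_annotation(params)
  out <- generate_expression(ann, params)
  out$params <- params
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_wide(out$expression,
                          file.path(out_dir, "expression.csv"))
    utils::write.table(out$annotation,
                       file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write an expression table in the wide dialect
#'
#' Columns `mirna_id`, then `<patient>_tumor` and `<patient>_normal`;
#' missing values as `NA`; comma separator for `.csv` paths, tab
#' otherwise. Inverse of [read_expression()] (wide).
#'
#' @param expr an [expression_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_wide <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(mirna_id = expr$mirna_ids, stringsAsFactors = FALSE)
  for (p in expr$patient_ids) {
    df[[paste0(p, "_tumor")]] <- expr$tumor[p, ]
    df[[paste0(p, "_normal")]] <- expr$normal[p, ]
  }
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
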