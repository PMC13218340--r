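#' @title Random-group-assignment control study
#' @description Repeatedly reassigns hypotheses to groups uniformly at
#'   random while preserving the multiset of group sizes, reruns the
#'   grouped FDR procedures on the *same* p-values (the tumor-normal
#'   pairing is never touched; only group labels are randomized), and
#'   summarizes per-hypothesis detection frequencies and per-replicate
#'   detection counts. Under non-informative random groups the grouped
#'   procedures concentrate toward their single-group counterparts.
#' @name control-study
NULL

#' Randomly reassign hypotheses to groups, preserving group sizes
#'
#' Permutes the assignment vector uniformly at random; the multiset of
#' group sizes is conserved exactly. Draws from the current RNG state.
#'
#' @param scheme a `grouping_scheme`.
#' @return A `grouping_scheme` with level `"random"` (member lists sorted
#'   by id).
#' @export
random_reassign <- function(scheme) {
  validate_scheme(scheme)
  ids <- names(scheme$assignment)
  labels <- unname(scheme$assignment)
  new_assignment <- stats::setNames(sample(labels), ids)
  groups <- lapply(split(ids, new_assignment), sort)
  validate_scheme(new_grouping_scheme(new_assignment, groups, "random",
                                      scheme$k))
}

run_grouped_method <- function(method, p, groups, alpha, tau, epsilon) {
  switch(method,
         tst_gbh = gbh(p, groups, alpha, estimator = "tst"),
         lsl_gbh = gbh(p, groups, alpha, estimator = "lsl"),
         sabha = sabha(p, groups, alpha, tau, epsilon),
         bh = bh_stepup(p, alpha),
         stop("unknown method: ", method, call. = FALSE))
}

summary_stats <- function(x) {
  q <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  list(mean = mean(x), median = stats::median(x), iqr = q)
}

#' Run the random-group-assignment control study
#'
#' For each replicate, the group labels are permuted uniformly at random
#' (sizes preserved) and each grouped method rerun on the fixed p-values.
#' Replicate `r` uses a deterministic RNG substream derived from
#' `(seed, r)`, so results do not depend on evaluation order.
#'
#' @param p named vector of raw p-values (one per hypothesis).
#' @param scheme template `grouping_scheme` supplying the group sizes.
#' @param methods subset of `c("tst_gbh", "lsl_gbh", "sabha")` (BH is
#'   excluded: it does not depend on group assignment).
#' @param alpha FDR level.
#' @param n_reps number of random reassignments.
#' @param seed integer master seed.
#' @param bh_set hypothesis ids rejected by BH, for the overlap summary.
#' @param comparison_set ids for the non-BH overlap summary (e.g.
#'   detections under the informative scheme that BH missed).
#' @param tau,epsilon SABHA tuning parameters.
#' @return Named list (per method) of `control_study_result`: `method`,
#'   `n_reps`, `freq` (detection fraction per hypothesis),
#'   `count_summary`, `bh_overlap_summary`, `nonbh_overlap_summary`,
#'   `seed`.
#' @export
control_study <- function(p, scheme, methods = c("tst_gbh", "lsl_gbh",
                                                 "sabha"),
                          alpha = 0.05, n_reps = 1000L, seed = 1L,
                          bh_set = character(0),
                          comparison_set = character(0),
                          tau = 0.5, epsilon = 0.1) {
  p <- check_pvalues(p)
  validate_scheme(scheme)
  stopifnot(n_reps >= 1)
  methods <- match.arg(methods, c("tst_gbh", "lsl_gbh", "sabha"),
                       several.ok = TRUE)
  ids <- names(p)
  if (!setequal(ids, names(scheme$assignment)))
    stop("scheme must cover exactly the tested hypotheses", call. = FALSE)

  hits <- matrix(0, nrow = length(ids), ncol = length(methods),
                 dimnames = list(ids, methods))
  counts <- matrix(0L, nrow = n_reps, ncol = length(methods),
                   dimnames = list(NULL, methods))
  bh_ov <- counts
  non_ov <- counts

  for (r in seq_len(n_reps)) {
    set.seed((seed + 7919 * r) %% 2147483647)
    rscheme <- random_reassign(scheme)
    groups <- rscheme$assignment[ids]
    for (m in methods) {
      rej <- run_grouped_method(m, p, groups, alpha, tau, epsilon)$rejected
      hits[rej, m] <- hits[rej, m] + 1
      counts[r, m] <- length(rej)
      bh_ov[r, m] <- length(intersect(rej, bh_set))
      non_ov[r, m] <- length(intersect(rej, comparison_set))
    }
  }

  out <- lapply(methods, function(m) {
    structure(list(method = m, n_reps = as.integer(n_reps),
                   freq = hits[, m] / n_reps,
                   count_summary = summary_stats(counts[, m]),
                   bh_overlap_summary = summary_stats(bh_ov[, m]),
                   nonbh_overlap_summary = summary_stats(non_ov[, m]),
                   seed = as.integer(seed)),
              class = "control_study_result")
  })
  stats::setNames(out, methods)
}

#' Tidy summary table of a control study
#'
#' @param results list of `control_study_result` (from
#'   [control_study()]).
#' @return data.frame: one row per method x statistic family (detections,
#'   BH overlap, non-BH overlap) with mean, median and the (25th, 75th)
#'   percentile IQR bounds.
#' @export
summarize_control <- function(results) {
  stopifnot(length(results) > 0L)
  rows <- lapply(results, function(res) {
    fam <- list(detections = res$count_summary,
                bh_overlap = res$bh_overlap_summary,
                nonbh_overlap = res$nonbh_overlap_summary)
    do.call(rbind, lapply(names(fam), function(f) {
      s <- fam[[f]]
      data.frame(method = res$method, statistic = f, mean = s$mean,
                 median = s$median, iqr_lo = s$iqr[1], iqr_hi = s$iqr[2],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
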