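#' @title End-to-end pipeline and scheme sweep
#' @description Orchestrates the complete analysis: change scores ->
#'   directional paired t-tests -> grouping-scheme family -> all four FDR
#'   procedures per scheme -> result table with per-(method, scheme)
#'   detection flags plus a sweep summary of detection counts and
#'   enter/exit transitions between consecutive schemes.
#' @name pipeline
NULL

FDR_METHODS <- c("bh", "tst_gbh", "lsl_gbh", "sabha")

#' Run the full grouped-FDR pipeline
#'
#' @param config a [run_config()].
#' @param expression an [expression_table].
#' @param annotation annotation data.frame covering all miRNAs in
#'   `expression`.
#' @param impute `"none"` (complete-case default) or `"median"` (the
#'   sensitivity variant).
#' @param verbose log one line per stage with counts.
#' @return List: `results` (per-miRNA table sorted by `p_raw`, with one
#'   logical flag column `<method>.<scheme>` per method and scheme; the
#'   BH columns are identical across schemes), `sweep` (see
#'   [scheme_sweep()]), `detections` (nested list scheme -> method ->
#'   rejected ids), `tests`, `schemes`.
#' @export
run_pipeline <- function(config, expression, annotation,
                         impute = c("none", "median"), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"),
            inherits(expression, "expression_table"))
  impute <- match.arg(impute)
  ann <- validate_annotation(annotation)
  missing_ann <- setdiff(expression$mirna_ids, ann$mirna_id)
  if (length(missing_ann))
    stop("unannotated miRNA(s): ",
         paste(utils::head(missing_ann, 5), collapse = ", "),
         call. = FALSE)
  ann <- ann[ann$mirna_id %in% expression$mirna_ids, ]

  say <- function(...) if (verbose) message(sprintf(...))
  ddct <- compute_ddct(expression)
  if (impute == "median") ddct <- median_impute(ddct)
  tests <- test_all(ddct, delta = config$delta)
  say("tests: %d miRNAs tested (%d untestable)", nrow(tests),
      sum(tests$note != ""))

  schemes <- scheme_family(ann, config$k_values)
  say("schemes: %d built (%s)", length(schemes),
      paste(names(schemes), collapse = ", "))

  p <- stats::setNames(tests$p_raw, tests$mirna_id)
  detections <- list()
  for (sname in names(schemes)) {
    groups <- schemes[[sname]]$assignment[names(p)]
    detections[[sname]] <- list(
      bh = bh_stepup(p, config$alpha)$rejected,
      tst_gbh = gbh(p, groups, config$alpha, "tst")$rejected,
      lsl_gbh = gbh(p, groups, config$alpha, "lsl")$rejected,
      sabha = sabha(p, groups, config$alpha, config$tau,
                    config$epsilon)$rejected)
    say("fdr [%s]: %s", sname,
        paste(sprintf("%s=%d", FDR_METHODS,
                      lengths(detections[[sname]][FDR_METHODS])),
              collapse = " "))
  }

  results <- merge(tests, ann, by = "mirna_id", sort = FALSE)
  for (sname in names(detections))
    for (m in FDR_METHODS)
      results[[paste(m, sname, sep = ".")]] <-
        results$mirna_id %in% detections[[sname]][[m]]
  results <- results[order(results$p_raw, results$mirna_id), ]
  rownames(results) <- NULL

  list(results = results, sweep = scheme_sweep(detections),
       detections = detections, tests = tests, schemes = schemes)
}

#' Detection counts and enter/exit transitions across schemes
#'
#' @param detections nested list: scheme -> method -> character vector of
#'   detected ids, in family order.
#' @return List: `counts` (data.frame scheme x method) and `transitions`
#'   (data.frame with `from`, `to`, `method`, `entered`, `exited` as
#'   comma-joined id lists).
#' @export
scheme_sweep <- function(detections) {
  stopifnot(length(detections) >= 2L)
  snames <- names(detections)
  methods <- names(detections[[1L]])
  counts <- data.frame(scheme = snames, stringsAsFactors = FALSE)
  for (m in methods)
    counts[[m]] <- vapply(detections, function(d) length(d[[m]]),
                          integer(1))
  trans <- list()
  for (i in seq_along(snames)[-1L]) {
    for (m in methods) {
      prev <- detections[[i - 1L]][[m]]
      cur <- detections[[i]][[m]]
      trans[[length(trans) + 1L]] <- data.frame(
        from = snames[i - 1L], to = snames[i], method = m,
        entered = paste(sort(setdiff(cur, prev)), collapse = ","),
        exited = paste(sort(setdiff(prev, cur)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  list(counts = counts, transitions = do.call(rbind, trans))
}
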