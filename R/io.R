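#' @title Readers, writers and containers for paired delta-Ct data
#' @description An `expression_table` holds paired tumor/normal delta-Ct
#'   values as two patients x miRNAs matrices with an enforced pairwise
#'   missingness invariant: a (patient, miRNA) pair is either observed in
#'   both tissues or missing in both. Missing values are encoded as empty
#'   fields or the literal `NA` on disk and written back as `NA`.
#' @name io-model
NULL

TISSUES <- c("tumor", "normal")

#' Construct a paired expression table
#'
#' @param tumor,normal numeric matrices, patients x miRNAs, with
#'   identical dimnames (patient ids as rownames, miRNA ids as colnames).
#' @param repair if `TRUE` (default), a pair observed in only one tissue
#'   is set missing in both, with a warning; if `FALSE` such a pair is an
#'   error.
#' @return An object of class `expression_table`: list with `tumor`,
#'   `normal`, `patient_ids`, `mirna_ids`.
#' @export
expression_table <- function(tumor, normal, repair = TRUE) {
  stopifnot(is.matrix(tumor), is.matrix(normal),
            identical(dim(tumor), dim(normal)),
            identical(dimnames(tumor), dimnames(normal)))
  if (is.null(rownames(tumor)) || is.null(colnames(tumor)))
    stop("patient and miRNA ids (dimnames) are required", call. = FALSE)
  if (anyDuplicated(rownames(tumor)) || anyDuplicated(colnames(tumor)))
    stop("patient and miRNA ids must be unique", call. = FALSE)
  if (any(is.infinite(tumor)) || any(is.infinite(normal)))
    stop("Ct values must be finite where present", call. = FALSE)
  half <- xor(is.na(tumor), is.na(normal))
  if (any(half)) {
    if (!repair)
      stop("pairs observed in only one tissue violate pairwise missingness",
           call. = FALSE)
    warning(sprintf(
      "%d pair(s) observed in only one tissue; set missing in both", sum(half)))
    tumor[half] <- NA_real_
    normal[half] <- NA_real_
  }
  structure(list(tumor = tumor, normal = normal,
                 patient_ids = rownames(tumor),
                 mirna_ids = colnames(tumor)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d patients x %d miRNAs, %d missing pairs\n",
              length(x$patient_ids), length(x$mirna_ids),
              sum(is.na(x$tumor))))
  invisible(x)
}

parse_na <- function(x) {
  x <- trimws(x)
  x[x == "" | x == "NA"] <- NA
  suppressWarnings(out <- as.numeric(x))
  if (any(is.na(out) & !is.na(x)))
    stop("non-numeric expression value", call. = FALSE)
  out
}

#' Read a paired delta-Ct expression file
#'
#' Wide dialect: one row per miRNA, first column `mirna_id`, then one
#' column `<patient>_<tissue>` per patient and tissue (tissue in
#' `tumor`/`normal`). Long dialect: columns `mirna_id`, `patient_id`,
#' `tissue`, `delta_ct`. Field separator is inferred from the extension
#' (`,` for `.csv`, tab otherwise). Pairs present in only one tissue are
#' repaired to missing-in-both with a warning.
#'
#' @param path file path.
#' @param dialect `"wide"` or `"long"`.
#' @return An [expression_table].
#' @export
read_expression <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (names(df)[1] != "mirna_id")
      stop("malformed header: first column must be 'mirna_id'", call. = FALSE)
    if (anyDuplicated(df$mirna_id))
      stop("duplicate mirna_id rows", call. = FALSE)
    cols <- names(df)[-1]
    m <- regmatches(cols, regexec("^(.+)_(tumor|normal)$", cols))
    if (any(lengths(m) != 3L))
      stop("malformed header: expected <patient>_<tissue> columns",
           call. = FALSE)
    patients <- unique(vapply(m, `[`, "", 2L))
    for (tis in TISSUES) {
      missing_cols <- setdiff(paste0(patients, "_", tis), cols)
      if (length(missing_cols))
        stop("malformed header: missing column(s) ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    mk <- function(tis) {
      mat <- sapply(paste0(patients, "_", tis),
                    function(cn) parse_na(df[[cn]]))
      mat <- matrix(mat, nrow = nrow(df),
                    dimnames = list(df$mirna_id, patients))
      t(mat)
    }
    expression_table(mk("tumor"), mk("normal"))
  } else {
    need <- c("mirna_id", "patient_id", "tissue", "delta_ct")
    if (!all(need %in% names(df)))
      stop("malformed header: long dialect needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    if (!all(df$tissue %in% TISSUES))
      stop("tissue labels must be 'tumor' or 'normal'", call. = FALSE)
    if (anyDuplicated(df[c("mirna_id", "patient_id", "tissue")]))
      stop("duplicate (patient, miRNA, tissue) rows", call. = FALSE)
    patients <- unique(df$patient_id)
    mirnas <- unique(df$mirna_id)
    mk <- function(tis) {
      mat <- matrix(NA_real_, length(patients), length(mirnas),
                    dimnames = list(patients, mirnas))
      sub <- df[df$tissue == tis, ]
      mat[cbind(sub$patient_id, sub$mirna_id)] <- parse_na(sub$delta_ct)
      mat
    }
    expression_table(mk("tumor"), mk("normal"))
  }
}

#' Read a miRNA annotation table
#'
#' TSV with columns `mirna_id`, `chrom`, `strand` (`+`/`-`), `arm`
#' (`p`/`q`), `start` (1-based integer coordinate).
#'
#' @param path file path.
#' @return data.frame of validated annotation records in file order.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("mirna_id", "chrom", "strand", "arm", "start")
  if (!all(need %in% names(df)))
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  validate_annotation(transform(df, start = suppressWarnings(
    as.numeric(start))))
}

validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  need <- c("mirna_id", "chrom", "strand", "arm", "start")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ann$mirna_id))
    stop("duplicate mirna_id in annotation", call. = FALSE)
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (!all(ann$arm %in% c("p", "q")))
    stop("arm must be 'p' or 'q'", call. = FALSE)
  if (anyNA(ann$start) || any(ann$start != floor(ann$start)))
    stop("start must be an integer coordinate", call. = FALSE)
  if (any(ann$start < 1))
    stop("start must be >= 1 (1-based coordinates)", call. = FALSE)
  ann$start <- as.integer(ann$start)
  ann
}

#' Write a result table sorted by raw p-value
#'
#' Writes a TSV with one header line, rows in ascending `p_raw`
#' (ties broken by `mirna_id`), missing values as `NA`.
#'
#' @param rows data.frame containing at least `mirna_id` and `p_raw`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0L,
            all(c("mirna_id", "p_raw") %in% names(rows)))
  rows <- rows[order(rows$p_raw, rows$mirna_id), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run configuration for the grouped-FDR pipeline
#'
#' @param alpha FDR level in (0, 1).
#' @param epsilon SABHA lower clip in (0, 1).
#' @param tau SABHA censoring threshold in (0, 1).
#' @param delta fold-change offset in Ct units (>= 0).
#' @param k_values maximum group sizes for the refined schemes (integers
#'   >= 2, descending).
#' @param n_reps control-study replication count.
#' @param seed integer RNG seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, epsilon = 0.1, tau = 0.5, delta = 1,
                       k_values = seq(25L, 5L, by = -2L), n_reps = 1000L,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, epsilon > 0, epsilon <= 1,
            tau > 0, tau < 1, delta >= 0,
            all(k_values == floor(k_values)), all(k_values >= 2),
            n_reps >= 1, seed == floor(seed))
  structure(list(alpha = alpha, epsilon = epsilon, tau = tau, delta = delta,
                 k_values = as.integer(k_values),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form `key = value` (or `key<TAB>value`); `k_values` is a
#' comma-separated list. Unknown keys are an error; missing keys take
#' their defaults.
#'
#' @param path file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "[=\t]", perl = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed config line", call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  known <- names(formals(run_config))
  if (!all(keys %in% known))
    stop("unknown config key(s): ",
         paste(setdiff(keys, known), collapse = ", "), call. = FALSE)
  args <- stats::setNames(as.list(vals), keys)
  if ("k_values" %in% keys)
    args$k_values <- as.numeric(strsplit(args$k_values, ",")[[1]])
  for (k in setdiff(keys, "k_values")) args[[k]] <- as.numeric(args[[k]])
  do.call(run_config, args)
}
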