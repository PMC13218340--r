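#' @title Genomic position-based grouping schemes
#' @description Hierarchical partitions of miRNAs by chromosomal
#'   location: (a) chromosome, (b) chromosome + strand, (c) chromosome +
#'   strand + arm, and refinements of (c) obtained by chunking large
#'   groups into adjacent blocks of at most `k` members. Groups that
#'   would be empty never materialize, and single-miRNA groups are merged
#'   into their nearest neighboring group so every scheme built from at
#'   least two miRNAs has minimum group size >= 2.
#' @name grouping-schemes
NULL

CHROM_ORDER <- c(as.character(1:22), "X", "Y")

new_grouping_scheme <- function(assignment, groups, level, k = NA_integer_) {
  structure(list(assignment = assignment, groups = groups,
                 level = level, k = k),
            class = "grouping_scheme")
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat(sprintf("<grouping_scheme> level=%s%s: %d miRNAs in %d groups\n",
              x$level, if (is.na(x$k)) "" else sprintf(" (k=%d)", x$k),
              length(x$assignment), length(x$groups)))
  invisible(x)
}

validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  members <- unlist(scheme$groups, use.names = FALSE)
  if (anyDuplicated(members) ||
      !setequal(members, names(scheme$assignment)))
    stop("scheme is not a partition", call. = FALSE)
  if (any(lengths(scheme$groups) == 0L))
    stop("empty group in scheme", call. = FALSE)
  ok <- vapply(names(scheme$groups), function(g)
    all(scheme$assignment[scheme$groups[[g]]] == g), logical(1))
  if (!all(ok)) stop("assignment/groups mismatch", call. = FALSE)
  invisible(scheme)
}

chrom_index <- function(chrom) {
  ix <- match(chrom, CHROM_ORDER)
  ix[is.na(ix)] <- length(CHROM_ORDER) + 1L  # unknown labels sort last
  ix
}

group_key <- function(ann, level) {
  switch(level,
         chrom = ann$chrom,
         chrom_strand = paste(ann$chrom, ann$strand, sep = ":"),
         chrom_strand_arm = paste(ann$chrom, ann$strand, ann$arm, sep = ":"),
         stop("unknown level: ", level, call. = FALSE))
}

order_members <- function(ids, ann) {
  ix <- match(ids, ann$mirna_id)
  ids[order(ann$start[ix], ids)]
}

groups_from_assignment <- function(assignment, ann) {
  gs <- split(names(assignment), assignment)
  lapply(gs, order_members, ann = ann)
}

#' Build a position-based grouping scheme
#'
#' Groups miRNAs by the keys of the requested level; empty keys never
#' materialize, and singleton groups are merged via
#' [merge_singletons()]. Group member lists are ordered by ascending
#' start coordinate (ties by id).
#'
#' @param annotation data.frame of annotation records (`mirna_id`,
#'   `chrom`, `strand`, `arm`, `start`), one per tested miRNA.
#' @param level `"chrom"`, `"chrom_strand"` or `"chrom_strand_arm"`
#'   (schemes (a), (b), (c)).
#' @return A `grouping_scheme`.
#' @export
build_scheme <- function(annotation,
                         level = c("chrom", "chrom_strand",
                                   "chrom_strand_arm")) {
  level <- match.arg(level)
  ann <- validate_annotation(annotation)
  assignment <- stats::setNames(group_key(ann, level), ann$mirna_id)
  scheme <- new_grouping_scheme(assignment,
                                groups_from_assignment(assignment, ann),
                                level)
  merge_singletons(scheme, ann)
}

#' Merge single-miRNA groups into their nearest neighboring group
#'
#' Applied iteratively until no singleton remains. Each singleton joins
#' the group minimizing, lexicographically, (tier, distance, group id):
#' tier 0 for a same-chromosome same-strand candidate, 1 for same
#' chromosome with a strand mismatch, and 1 + chromosome-index distance
#' (order 1..22, X, Y) otherwise; distance is the minimum absolute start
#' difference between the singleton and any candidate member.
#'
#' @param scheme a `grouping_scheme`.
#' @param annotation the annotation used to build it.
#' @return A `grouping_scheme` with minimum group size >= 2 whenever at
#'   least two miRNAs exist.
#' @export
merge_singletons <- function(scheme, annotation) {
  validate_scheme(scheme)
  ann <- validate_annotation(annotation)
  if (length(scheme$assignment) == 1L)
    stop("cannot merge: only one miRNA in total", call. = FALSE)
  assignment <- scheme$assignment
  repeat {
    sizes <- table(assignment)
    singles <- sort(names(sizes)[sizes == 1L])
    if (length(singles) == 0L) break
    gid <- singles[[1L]]
    mid <- names(assignment)[assignment == gid]
    a <- ann[ann$mirna_id == mid, ]
    cand_gids <- sort(setdiff(unique(assignment), gid))
    best <- NULL
    for (cg in cand_gids) {
      members <- ann[ann$mirna_id %in%
                       names(assignment)[assignment == cg], ]
      tier_m <- ifelse(members$chrom == a$chrom,
                       ifelse(members$strand == a$strand, 0, 1),
                       1 + abs(chrom_index(members$chrom) -
                                 chrom_index(a$chrom)))
      dist_m <- abs(members$start - a$start)
      ord <- order(tier_m, dist_m)[1L]
      score <- c(tier_m[ord], dist_m[ord])
      if (is.null(best) || score[1] < best$score[1] ||
          (score[1] == best$score[1] && score[2] < best$score[2]))
        best <- list(gid = cg, score = score)
    }
    assignment[mid] <- best$gid
  }
  validate_scheme(new_grouping_scheme(
    assignment, groups_from_assignment(assignment, ann),
    scheme$level, scheme$k))
}

#' Refine a scheme by a maximum group size k
#'
#' Every group with more than `k` members is chunked, in ascending start
#' order, into consecutive blocks of size `k` with a smaller final
#' block; a final block of size 1 is merged back into the preceding
#' block (which may then have `k + 1` members). Groups of size <= `k`
#' are unchanged.
#'
#' @param scheme_c the scheme to refine (normally level
#'   `chrom_strand_arm`).
#' @param k maximum group size, integer >= 2.
#' @return A `grouping_scheme` of level `"refined"` carrying `k`.
#' @export
split_scheme <- function(scheme_c, k) {
  validate_scheme(scheme_c)
  if (!is.numeric(k) || length(k) != 1L || k != floor(k) || k < 2)
    stop("`k` must be an integer >= 2", call. = FALSE)
  k <- as.integer(k)
  groups <- list()
  for (gid in names(scheme_c$groups)) {
    members <- scheme_c$groups[[gid]]  # already start-ordered
    n <- length(members)
    if (n <= k) {
      groups[[gid]] <- members
      next
    }
    blocks <- split(members, ceiling(seq_len(n) / k))
    nb <- length(blocks)
    if (length(blocks[[nb]]) == 1L) {
      blocks[[nb - 1L]] <- c(blocks[[nb - 1L]], blocks[[nb]])
      blocks[[nb]] <- NULL
    }
    for (b in seq_along(blocks))
      groups[[sprintf("%s.%02d", gid, b)]] <- blocks[[b]]
  }
  assignment <- stats::setNames(
    rep(names(groups), lengths(groups)),
    unlist(groups, use.names = FALSE))
  assignment <- assignment[names(scheme_c$assignment)]
  validate_scheme(new_grouping_scheme(assignment, groups, "refined", k))
}

#' Build the full family of grouping schemes
#'
#' Returns schemes (a), (b), (c) followed by the refinements of (c) for
#' each `k` (descending).
#'
#' @inheritParams build_scheme
#' @param k_values maximum group sizes, descending (default 25, 23, ...,
#'   5); may be empty.
#' @return Named list of `grouping_scheme`s (`a`, `b`, `c`, `k25`, ...).
#' @export
scheme_family <- function(annotation, k_values = seq(25L, 5L, by = -2L)) {
  if (length(k_values) > 1L && is.unsorted(rev(k_values)))
    stop("`k_values` must be sorted descending", call. = FALSE)
  fam <- list(a = build_scheme(annotation, "chrom"),
              b = build_scheme(annotation, "chrom_strand"),
              c = build_scheme(annotation, "chrom_strand_arm"))
  for (k in k_values)
    fam[[sprintf("k%d", k)]] <- split_scheme(fam$c, k)
  fam
}

#' Summarize a grouping scheme
#'
#' @param scheme a `grouping_scheme`.
#' @return List with `n_groups`, `size_histogram` (named count per
#'   size), `min_size`, `max_size`.
#' @export
scheme_summary <- function(scheme) {
  validate_scheme(scheme)
  sizes <- lengths(scheme$groups)
  list(n_groups = length(sizes),
       size_histogram = table(sizes),
       min_size = min(sizes), max_size = max(sizes))
}
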