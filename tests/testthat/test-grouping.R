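# Position-based grouping schemes: construction, singleton merging,
# k-refinement, family properties.

test_that("scheme levels project the annotation keys, merging singletons", {
  ann <- data.frame(
    mirna_id = paste0("m", 1:6),
    chrom = c("1", "1", "1", "1", "2", "2"),
    strand = c("+", "+", "+", "-", "+", "+"),
    arm = c("p", "p", "p", "p", "q", "q"),
    start = c(1000L, 2000L, 3000L, 1500L, 100L, 900L),
    stringsAsFactors = FALSE)

  sb <- build_scheme(ann, "chrom_strand")
  expect_setequal(unname(sort(lengths(sb$groups))), c(2, 4))
  # the chr1 minus-strand singleton joined the chr1 plus-strand group
  expect_identical(unname(sb$assignment["m4"]), unname(sb$assignment["m1"]))

  sa <- build_scheme(ann, "chrom")
  expect_equal(sort(unname(lengths(sa$groups))), c(2, 4))
  expect_setequal(sa$groups[["1"]], paste0("m", 1:4))

  # all miRNAs on one chromosome, strand and arm: one group at every level
  one_cell <- ann
  one_cell$chrom <- "1"; one_cell$strand <- "+"; one_cell$arm <- "p"
  for (lev in c("chrom", "chrom_strand", "chrom_strand_arm")) {
    sc <- build_scheme(one_cell, lev)
    expect_equal(length(sc$groups), 1L)
  }
})

test_that("group members are ordered by ascending start coordinate", {
  ann <- toy_annotation()
  sc <- build_scheme(ann, "chrom")
  for (g in sc$groups) {
    starts <- ann$start[match(g, ann$mirna_id)]
    expect_true(!is.unsorted(starts))
  }
})

test_that("singleton merging prefers the same-chromosome tier over a
           closer coordinate on another chromosome", {
  ann <- data.frame(
    mirna_id = c("s", "a1", "a2", "b1", "b2"),
    chrom = c("1", "1", "1", "2", "2"),
    strand = c("-", "+", "+", "+", "+"),
    arm = c("p", "p", "p", "p", "p"),
    start = c(1000L, 1200L, 2000L, 1050L, 1100L),
    stringsAsFactors = FALSE)
  sc <- build_scheme(ann, "chrom_strand")
  # chr2 group is nearer in coordinates (1050 vs 1200) but loses the tier
  expect_identical(unname(sc$assignment["s"]), unname(sc$assignment["a1"]))
})

test_that("two singletons merge into one group of two", {
  ann <- data.frame(mirna_id = c("x", "y"), chrom = c("1", "2"),
                    strand = c("+", "-"), arm = c("p", "q"),
                    start = c(10L, 20L), stringsAsFactors = FALSE)
  sc <- build_scheme(ann, "chrom_strand_arm")
  expect_equal(length(sc$groups), 1L)
  expect_setequal(sc$groups[[1]], c("x", "y"))
  expect_error(build_scheme(ann[1, ], "chrom"), "2 miRNAs|one miRNA")
})

test_that("k-splitting chunks by start order and absorbs a singleton tail", {
  ann <- data.frame(
    mirna_id = paste0("m", 1:9),
    chrom = c(rep("1", 7), "2", "2"),
    strand = "+", arm = "q",
    start = c(70L, 10L, 30L, 50L, 20L, 60L, 40L, 5L, 6L),
    stringsAsFactors = FALSE)
  sc <- build_scheme(ann, "chrom_strand_arm")
  s3 <- split_scheme(sc, 3)
  sizes <- sort(unname(lengths(s3$groups)))
  expect_identical(sizes, c(2L, 3L, 4L))  # 7 -> [3, 3, 1] -> [3, 4]
  # first chunk holds the three lowest coordinates
  chunk1 <- s3$groups[[grep("\\.01$", names(s3$groups))[1]]]
  expect_setequal(chunk1, c("m2", "m5", "m3"))

  # 7 with k = 6 -> [6, 1] -> singleton absorbed -> one group of 7 (= k + 1)
  s6 <- split_scheme(sc, 6)
  expect_identical(sort(unname(lengths(s6$groups))), c(2L, 7L))
  expect_error(split_scheme(sc, 1), "k")

  # exact division: 6 -> [3, 3]
  ann6 <- ann[1:6, ]; ann6$chrom <- "1"
  sc6 <- build_scheme(ann6, "chrom_strand_arm")
  expect_identical(sort(unname(lengths(split_scheme(sc6, 3)$groups))),
                   c(3L, 3L))
  # size <= k: unchanged
  expect_identical(split_scheme(sc6, 10)$groups, sc6$groups)
})

test_that("scheme family is ordered a, b, c, then descending k", {
  ann <- toy_annotation()
  fam <- scheme_family(ann, k_values = c(4L, 2L))
  expect_identical(names(fam), c("a", "b", "c", "k4", "k2"))
  expect_error(scheme_family(ann, k_values = c(2L, 4L)), "descending")
  fam_abc <- scheme_family(ann, k_values = integer(0))
  expect_identical(names(fam_abc), c("a", "b", "c"))
  # a large k that splits nothing reproduces scheme (c)
  expect_identical(scheme_family(ann, 25L)$k25$groups, fam$c$groups)
})

test_that("every scheme is a partition with minimum group size >= 2 and
           the group count never decreases with refinement", {
  set.seed(41)
  pars <- simulation_params(n_mirnas = 200, seed = 41)
  ann <- generate_annotation(pars)
  fam <- scheme_family(ann, k_values = seq(25L, 5L, by = -2L))
  n_groups <- vapply(fam, function(s) length(s$groups), integer(1))
  for (s in fam) {
    members <- sort(unlist(s$groups, use.names = FALSE))
    expect_identical(members, sort(ann$mirna_id))     # partition
    expect_gte(min(lengths(s$groups)), 2L)            # no singletons
  }
  expect_true(all(diff(n_groups) >= 0))               # a -> b -> c -> finer
})

test_that("grouping is deterministic", {
  set.seed(43)
  pars <- simulation_params(n_mirnas = 150, seed = 43)
  ann <- generate_annotation(pars)
  f1 <- scheme_family(ann, c(9L, 5L))
  f2 <- scheme_family(ann, c(9L, 5L))
  expect_identical(f1, f2)
})

test_that("scheme summaries count groups and sizes", {
  ann <- toy_annotation()
  sc <- build_scheme(ann, "chrom")
  ss <- scheme_summary(sc)
  expect_equal(ss$n_groups, length(sc$groups))
  expect_equal(sum(ss$size_histogram), ss$n_groups)
  expect_equal(ss$min_size, min(lengths(sc$groups)))
  expect_equal(ss$max_size, max(lengths(sc$groups)))
})
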