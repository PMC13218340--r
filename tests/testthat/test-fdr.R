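# Step-up procedures, null-proportion estimators, grouped methods.

test_that("BH step-up matches hand traces, boundary ties, and p.adjust", {
  r <- bh_stepup(c(a = 0.001, b = 0.02, c = 0.03, d = 0.2), alpha = 0.05)
  expect_setequal(r$rejected, c("a", "b", "c"))
  expect_identical(r$k_star, 3L)

  expect_length(bh_stepup(rep(1, 5), 0.05)$rejected, 0L)

  tie <- bh_stepup(c(x = 0.04, y = 0.04), alpha = 0.05)
  expect_setequal(tie$rejected, c("x", "y"))

  # independent route: BH rejections == adjusted p-values below alpha
  set.seed(7)
  for (i in 1:25) {
    p <- random_pvalues(40)
    mine <- bh_stepup(p, 0.05)$rejected
    ref <- names(p)[stats::p.adjust(p, "BH") <= 0.05]
    expect_setequal(mine, ref)
  }
})

test_that("step-up k* equals brute-force enumeration for n <= 12", {
  set.seed(11)
  for (i in 1:500) {
    n <- sample(1:12, 1)
    p <- round(stats::runif(n), sample(1:3, 1))  # rounding induces ties
    alpha <- stats::runif(1, 0.01, 0.3)
    expect_identical(bh_stepup(stats::setNames(p, seq_len(n)),
                               alpha)$k_star,
                     oracle_stepup_k(p, alpha))
  }
})

test_that("TST null-proportion estimate follows the two-stage count", {
  expect_equal(tst_pi0(c(0.001, 0.2, 0.7, 0.9), 0.05), 0.75)
  expect_equal(tst_pi0(rep(1, 4), 0.05), 1)
  expect_equal(tst_pi0(c(1e-6, 1e-6), 0.05), 0)
})

test_that("LSL estimate finds the first slope increase and clips at n_g", {
  expect_equal(lsl_pi0(c(0.001, 0.002, 0.003, 0.004, 0.005, 0.6)), 0.5)
  expect_equal(lsl_pi0(rep(1, 4)), 1)
  expect_equal(lsl_pi0(c(0.1, 0.2, 0.3, 0.9)), 1)
  # p-values equal to 1 create infinite slopes without error
  expect_equal(lsl_pi0(c(0.2, 1, 1)), 1)
})

test_that("tau-censored Storey estimate is clipped to [epsilon, 1]", {
  expect_equal(storey_q(c(0.01, 0.02, 0.03, 0.04)), 0.1)
  expect_equal(storey_q(c(0.01, 0.2, 0.6, 0.8)), 1)
  expect_equal(storey_q(c(0.6, 0.7, 0.8, 0.9)), 1)
  expect_equal(storey_q(c(0.01, 0.2, 0.6, 0.8), tau = 0.5, epsilon = 0.4),
               1)
  expect_error(storey_q(c(0.5), tau = 1.5), "tau")
})

test_that("TST-GBH two-group hand trace rejects exactly the critical group", {
  p <- stats::setNames(c(0.001, 0.002, 0.003, 0.04, 0.2, 0.5, 0.8, 0.9),
                       paste0("h", 1:8))
  groups <- rep(c("A", "B"), each = 4)
  r <- gbh(p, groups, alpha = 0.05, estimator = "tst")
  expect_setequal(r$rejected, paste0("h", 1:4))
  expect_equal(unname(r$pi0_by_group[c("A", "B")]), c(0, 1))
  expect_equal(r$pi0_overall, 0.5)
  expect_equal(sum(r$weighted_p == 0), 4)
  expect_equal(sum(is.infinite(r$weighted_p)), 4)
})

test_that("SABHA two-group hand trace gives k_hat = 3", {
  p <- stats::setNames(c(0.001, 0.01, 0.02, 0.6, 0.3, 0.55, 0.7, 0.9),
                       paste0("h", 1:8))
  groups <- rep(c("A", "B"), each = 4)
  r <- sabha(p, groups, alpha = 0.05)
  expect_equal(unname(r$pi0_by_group[c("A", "B")]), c(0.5, 1))
  expect_identical(r$k_star, 3L)
  expect_setequal(r$rejected, c("h1", "h2", "h3"))
})

test_that("degenerate grouped inputs reject nothing", {
  p <- stats::setNames(rep(1, 6), paste0("h", 1:6))
  g <- rep(c("A", "B"), 3)
  expect_length(gbh(p, g, 0.05, "tst")$rejected, 0L)
  expect_length(gbh(p, g, 0.05, "lsl")$rejected, 0L)
  expect_length(sabha(p, g, 0.05)$rejected, 0L)
})

test_that("SABHA with unit weights in every group equals plain BH", {
  set.seed(3)
  for (i in 1:20) {
    p <- random_pvalues(30, frac_small = 0)  # uniform: q_hat ~ 1 mostly
    g <- rep(c("A", "B", "C"), each = 10)
    r <- sabha(p, g, 0.05, tau = 0.5, epsilon = 1)  # epsilon=1 forces q=1
    expect_setequal(r$rejected, bh_stepup(p, 0.05)$rejected)
  }
})

test_that("single-group grouped procedures equal their classical
           adaptive-BH counterparts on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    p <- random_pvalues(n)
    alpha <- sample(c(0.05, 0.1, 0.2), 1)
    one <- rep("all", n)
    expect_setequal(gbh(p, one, alpha, "tst")$rejected,
                    oracle_tst_bh(p, alpha))
    expect_setequal(gbh(p, one, alpha, "lsl")$rejected,
                    oracle_lsl_bh(p, alpha))
    expect_setequal(sabha(p, one, alpha)$rejected,
                    oracle_storey_bh(p, alpha))
    # adaptive_unigroup is the same reduction by construction
    expect_setequal(adaptive_unigroup(p, alpha, "tst")$rejected,
                    oracle_tst_bh(p, alpha))
    expect_setequal(adaptive_unigroup(p, alpha, "lsl")$rejected,
                    oracle_lsl_bh(p, alpha))
    expect_setequal(adaptive_unigroup(p, alpha, "storey")$rejected,
                    oracle_storey_bh(p, alpha))
  }
})

test_that("within-group rejection is monotone in the p-value", {
  set.seed(23)
  for (i in 1:50) {
    p <- random_pvalues(36)
    g <- rep(sprintf("g%d", 1:6), each = 6)
    for (fit in list(gbh(p, g, 0.1, "tst"), gbh(p, g, 0.1, "lsl"),
                     sabha(p, g, 0.1))) {
      for (grp in unique(g)) {
        ids <- names(p)[g == grp]
        rej <- ids %in% fit$rejected
        if (any(rej))
          expect_true(all(p[ids][rej] <= min(p[ids][!rej], Inf)))
      }
    }
  }
})

test_that("rejection sets grow with alpha (BH; SABHA at fixed weights)", {
  set.seed(31)
  for (i in 1:30) {
    p <- random_pvalues(25)
    alphas <- c(0.01, 0.05, 0.1, 0.2)
    prev_bh <- character(0)
    for (a in alphas) {
      cur <- bh_stepup(p, a)$rejected
      expect_true(all(prev_bh %in% cur))
      prev_bh <- cur
    }
    g <- rep(c("A", "B"), length.out = 25)
    # fix weights by fixing epsilon=1 (q=1 throughout): SABHA == BH path
    prev_s <- character(0)
    for (a in alphas) {
      cur <- sabha(p, g, a, epsilon = 1)$rejected
      expect_true(all(prev_s %in% cur))
      prev_s <- cur
    }
  }
})

test_that("grouped rejection sets need not contain the BH set", {
  # a group whose LSL estimate is 1 gets infinite weighted p-values, so a
  # globally tiny p-value in it can be lost by LSL-GBH while BH keeps it
  p <- stats::setNames(c(1e-6, 0.9, 0.95, 1,
                         0.001, 0.002, 0.003, 0.2, 0.4, 0.6),
                       paste0("h", 1:10))
  g <- rep(c("A", "B"), c(4, 6))
  bh_set <- bh_stepup(p, 0.05)$rejected
  lsl_set <- gbh(p, g, 0.05, "lsl")$rejected
  expect_true("h1" %in% bh_set)
  expect_false("h1" %in% lsl_set)
  expect_false(all(bh_set %in% lsl_set))
})

test_that("p-values exactly 0 and 1 are legal everywhere", {
  p <- stats::setNames(c(0, 0.5, 1, 1), paste0("h", 1:4))
  g <- c("A", "A", "B", "B")
  expect_no_error(gbh(p, g, 0.05, "tst"))
  expect_no_error(gbh(p, g, 0.05, "lsl"))
  expect_no_error(sabha(p, g, 0.05))
  expect_true("h1" %in% gbh(p, g, 0.05, "tst")$rejected)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(bh_stepup(numeric(0)), "empty")
  expect_error(bh_stepup(c(0.1, NA)), "finite")
  expect_error(bh_stepup(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(gbh(c(a = 0.1, b = 0.2), groups = "A"), "one label")
})
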