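# Independent oracle implementations used to cross-check the package's
# procedures. These are written directly from the classical sorted-threshold
# statements of each procedure and share no code with R/.

# Brute-force step-up: largest k in 0..n such that the k-th smallest value
# satisfies v_(k) <= k * level / n.
oracle_stepup_k <- function(v, level, n = length(v)) {
  vs <- sort(v)
  best <- 0L
  for (k in seq_along(vs)) if (vs[k] <= k * level / n) best <- k
  best
}

# Two-stage adaptive BH (Benjamini-Krieger-Yekutieli): stage-1 BH at
# alpha' = alpha/(1+alpha); with r1 rejections, stage-2 BH with critical
# values k * alpha' / (n - r1).
oracle_tst_bh <- function(p, alpha) {
  n <- length(p)
  ap <- alpha / (1 + alpha)
  r1 <- oracle_stepup_k(p, ap)
  if (r1 == 0L) return(character(0))
  if (r1 == n) return(names(p))
  n0 <- n - r1
  ps <- sort(p)
  k2 <- 0L
  for (k in seq_len(n)) if (ps[k] <= k * ap / n0) k2 <- k
  if (k2 == 0L) character(0) else names(p)[p <= ps[k2]]
}

# LSL adaptive BH: LSL null-count estimate, then BH with critical values
# k * alpha / n0_hat. Shares the grouped-weighting convention that an
# all-null estimate (n0_hat = n) rejects nothing: an estimated null
# proportion of 1 gives such hypotheses infinite weighted p-values.
oracle_lsl_bh <- function(p, alpha) {
  n <- length(p)
  ps <- sort(p)
  l <- ifelse(ps == 1, Inf, (n + 1 - seq_len(n)) / (1 - ps))
  n0 <- n
  for (i in seq_len(n)[-1]) {
    if (is.finite(l[i]) && l[i] > l[i - 1]) { n0 <- min(floor(l[i]) + 1, n); break }
    if (is.infinite(l[i]) && is.finite(l[i - 1])) { n0 <- n; break }
  }
  if (n0 >= n) return(character(0))
  k2 <- 0L
  for (k in seq_len(n)) if (ps[k] <= k * alpha / n0) k2 <- k
  if (k2 == 0L) character(0) else names(p)[p <= ps[k2]]
}

# Storey's tau-censored adaptive BH with the epsilon floor: BH with critical
# values k * alpha / (n * q_hat).
oracle_storey_bh <- function(p, alpha, tau = 0.5, epsilon = 0.1) {
  n <- length(p)
  q <- min(1, max(epsilon, sum(p > tau) / (n * (1 - tau))))
  ps <- sort(p)
  k2 <- 0L
  for (k in seq_len(n)) if (ps[k] <= k * alpha / (n * q)) k2 <- k
  if (k2 == 0L) character(0) else names(p)[p <= ps[k2]]
}

# Exhaustive control-study oracle: detection frequency of each hypothesis
# over all balanced assignments of 8 hypotheses into two groups of 4.
oracle_control_freq_8 <- function(p, method_fun) {
  ids <- names(p)
  subsets <- utils::combn(8L, 4L)
  hits <- stats::setNames(numeric(8), ids)
  for (j in seq_len(ncol(subsets))) {
    groups <- rep("B", 8)
    groups[subsets[, j]] <- "A"
    rej <- method_fun(p, groups)
    hits[rej] <- hits[rej] + 1
  }
  hits / ncol(subsets)
}

# Small deterministic annotation fixture: chr1 +p dense cluster, chr1 -p
# singleton candidate material, chr2 +q pair, etc.
toy_annotation <- function() {
  data.frame(
    mirna_id = sprintf("m%02d", 1:12),
    chrom = c("1", "1", "1", "1", "2", "2", "2", "3", "3", "3", "3", "4"),
    strand = c("+", "+", "+", "-", "+", "+", "-", "+", "+", "+", "+", "-"),
    arm = c("p", "p", "p", "p", "q", "q", "q", "q", "q", "q", "q", "p"),
    start = c(1000L, 2000L, 3000L, 1500L, 100L, 900L, 5000L,
              10L, 20L, 30L, 40L, 7000L),
    stringsAsFactors = FALSE)
}

random_pvalues <- function(n, frac_small = 0.3) {
  p <- stats::runif(n)
  small <- stats::runif(n) < frac_small
  p[small] <- stats::rbeta(sum(small), 0.15, 1)
  stats::setNames(p, sprintf("h%03d", seq_len(n)))
}
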