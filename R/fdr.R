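#' @title Multiple-testing procedures for grouped hypotheses
#' @description Step-up FDR control: the Benjamini-Hochberg (BH)
#'   procedure, per-group null-proportion estimators (two-stage step-up
#'   TST, least-slope LSL, tau-censored Storey), the group-adaptive BH
#'   procedures TST-GBH and LSL-GBH, and group SABHA. All procedures
#'   operate on a vector of raw p-values plus an optional group label per
#'   hypothesis, and return an `fdr_result` object.
#' @name fdr-procedures
NULL

new_fdr_result <- function(method, alpha, rejected, pi0_by_group,
                           pi0_overall, weighted_p, k_star, threshold) {
  structure(
    list(method = method, alpha = alpha, rejected = rejected,
         pi0_by_group = pi0_by_group, pi0_overall = pi0_overall,
         weighted_p = weighted_p, k_star = k_star, threshold = threshold),
    class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> method=%s alpha=%g rejections=%d threshold=%g\n",
              x$method, x$alpha, x$k_star, x$threshold))
  invisible(x)
}

check_pvalues <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  if (is.null(names(p))) names(p) <- as.character(seq_along(p))
  if (anyDuplicated(names(p))) stop("duplicate hypothesis ids", call. = FALSE)
  p
}

check_groups <- function(p, groups) {
  if (length(groups) != length(p))
    stop("`groups` must have one label per p-value", call. = FALSE)
  if (anyNA(groups)) stop("missing group labels", call. = FALSE)
  as.character(groups)
}

## Generic step-up on (possibly weighted, possibly infinite) p-values:
## k* = max{ k : v_(k) <= k * level / n_eff }.  Returns k* and the realized
## threshold k* * level / n_eff; ties at the boundary are all below the
## threshold by maximality of k*.
stepup_kstar <- function(v, level, n_eff = length(v)) {
  vs <- sort(v)
  crit <- seq_along(vs) * level / n_eff
  ok <- which(vs <= crit)
  k_star <- if (length(ok)) max(ok) else 0L
  threshold <- if (k_star > 0L) k_star * level / n_eff else 0
  list(k_star = as.integer(k_star), threshold = threshold)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Rejects the \eqn{k^*} smallest p-values, where
#' \eqn{k^* = \max\{k : p_{(k)} \le k\alpha/n\}} (0 if the condition never
#' holds). Hypotheses tied at the realized threshold are all rejected.
#'
#' @param p numeric vector of raw p-values in \[0, 1\]; names are used as
#'   hypothesis ids (defaults to positional ids).
#' @param alpha FDR control level in (0, 1).
#' @return An `fdr_result` with the rejection set, `k_star` and the
#'   realized p-value `threshold`.
#' @examples
#' bh_stepup(c(a = 0.001, b = 0.02, c = 0.03, d = 0.2), alpha = 0.05)
#' @export
bh_stepup <- function(p, alpha = 0.05) {
  p <- check_pvalues(p)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  su <- stepup_kstar(p, alpha)
  rejected <- names(p)[p <= su$threshold & su$k_star > 0L]
  new_fdr_result("bh", alpha, rejected,
                 pi0_by_group = NULL, pi0_overall = NA_real_,
                 weighted_p = p, k_star = su$k_star,
                 threshold = su$threshold)
}

#' Two-stage step-up (TST) null-proportion estimate
#'
#' First-pass BH within the group at the reduced level
#' \eqn{\alpha' = \alpha/(1+\alpha)}; with `r` rejections the estimate is
#' \eqn{(n_g - r)/n_g}.
#'
#' @param p_group p-values of one group.
#' @param alpha nominal FDR level (the reduction to \eqn{\alpha'} is
#'   internal).
#' @return Estimated null proportion in \[0, 1\].
#' @export
tst_pi0 <- function(p_group, alpha = 0.05) {
  p_group <- check_pvalues(p_group)
  alpha_prime <- alpha / (1 + alpha)
  r <- stepup_kstar(p_group, alpha_prime)$k_star
  (length(p_group) - r) / length(p_group)
}

#' Least-slope (LSL) null-proportion estimate
#'
#' With p-values sorted ascending, computes the slope sequence
#' \eqn{l_i = (n_g + 1 - i)/(1 - p_{(i)})} (\eqn{+\infty} when
#' \eqn{p_{(i)} = 1}) and stops at the first \eqn{i \ge 2} with
#' \eqn{l_i > l_{i-1}}; the null count is
#' \eqn{\min(\lfloor l_i \rfloor + 1, n_g)}, or \eqn{n_g} if the sequence
#' never increases. Comparisons between two infinite slopes are not
#' increases.
#'
#' @inheritParams tst_pi0
#' @return Estimated null proportion in \[0, 1\].
#' @export
lsl_pi0 <- function(p_group) {
  p_group <- check_pvalues(p_group)
  n <- length(p_group)
  ps <- sort(p_group)
  l <- ifelse(ps == 1, Inf, (n + 1 - seq_len(n)) / (1 - ps))
  n0 <- n
  if (n >= 2L) {
    inc <- which(l[-1L] > l[-n])  # Inf > Inf is FALSE, as required
    if (length(inc)) {
      i <- inc[1L] + 1L
      n0 <- min(floor(l[i]) + 1, n)
    }
  }
  n0 / n
}

#' Tau-censored Storey null-proportion estimate
#'
#' \eqn{\hat q = \min(1, \max(\epsilon, \#\{p > \tau\} / (n_g(1-\tau))))}:
#' the Storey estimator censored at `tau` and clipped to
#' \eqn{[\epsilon, 1]}.
#'
#' @inheritParams tst_pi0
#' @param tau censoring threshold in (0, 1).
#' @param epsilon lower clip in (0, 1\].
#' @return Estimate in \[`epsilon`, 1\].
#' @export
storey_q <- function(p_group, tau = 0.5, epsilon = 0.1) {
  p_group <- check_pvalues(p_group)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("`tau` must be in (0, 1)", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 ||
      epsilon > 1)
    stop("`epsilon` must be in (0, 1]", call. = FALSE)
  raw <- sum(p_group > tau) / (length(p_group) * (1 - tau))
  min(1, max(epsilon, raw))
}

#' Group-adaptive Benjamini-Hochberg procedures (TST-GBH, LSL-GBH)
#'
#' Estimates the null proportion \eqn{\hat\pi_g} within each group (TST at
#' the reduced level \eqn{\alpha' = \alpha/(1+\alpha)}, or LSL), forms
#' weighted p-values
#' \eqn{p^w_i = p_i\,\hat\pi_{g(i)}/(1-\hat\pi_{g(i)})} (\eqn{+\infty}
#' when \eqn{\hat\pi_g = 1}, 0 when \eqn{\hat\pi_g = 0}), and applies the
#' BH step-up to the pooled weighted p-values at the effective level
#' \eqn{\alpha_{base}/(1-\hat\pi_0)} with
#' \eqn{\hat\pi_0 = \sum_g n_g\hat\pi_g/n}, where \eqn{\alpha_{base}} is
#' \eqn{\alpha'} for TST and \eqn{\alpha} for LSL. If \eqn{\hat\pi_0 = 1}
#' nothing is rejected. With a single group the procedure reduces exactly
#' to the two-stage adaptive BH (TST) or the LSL adaptive BH.
#'
#' @inheritParams bh_stepup
#' @param groups group label per hypothesis (coerced to character).
#' @param estimator `"tst"` or `"lsl"`.
#' @return An `fdr_result` with per-group estimates in `pi0_by_group`.
#' @export
gbh <- function(p, groups, alpha = 0.05, estimator = c("tst", "lsl")) {
  p <- check_pvalues(p)
  groups <- check_groups(p, groups)
  estimator <- match.arg(estimator)
  stopifnot(alpha > 0, alpha < 1)
  alpha_prime <- alpha / (1 + alpha)
  alpha_base <- if (estimator == "tst") alpha_prime else alpha

  idx_by_g <- split(seq_along(p), groups)
  pi0_g <- vapply(idx_by_g, function(ix) {
    if (estimator == "tst") tst_pi0(p[ix], alpha) else lsl_pi0(p[ix])
  }, numeric(1))

  n <- length(p)
  n_g <- lengths(idx_by_g)
  pi0_overall <- sum(n_g * pi0_g) / n

  w <- pi0_g[groups]
  weighted_p <- ifelse(w >= 1, Inf, ifelse(w <= 0, 0, p * w / (1 - w)))
  names(weighted_p) <- names(p)

  method <- paste0(estimator, "_gbh")
  if (pi0_overall >= 1) {
    return(new_fdr_result(method, alpha, character(0), pi0_g, pi0_overall,
                          weighted_p, 0L, 0))
  }
  level <- alpha_base / (1 - pi0_overall)
  su <- stepup_kstar(weighted_p, level)
  rejected <- names(p)[weighted_p <= su$threshold & su$k_star > 0L]
  new_fdr_result(method, alpha, rejected, pi0_g, pi0_overall,
                 weighted_p, su$k_star, su$threshold)
}

#' Group SABHA (structure-adaptive BH with per-group censored weights)
#'
#' Per group, \eqn{\hat q_g} is the tau-censored Storey estimate clipped
#' to \eqn{[\epsilon, 1]}; the procedure rejects
#' \eqn{\{i : \hat q_{g(i)} p_i \le \hat k\alpha/n\}} where
#' \eqn{\hat k = \max\{k : \#\{i : \hat q_{g(i)} p_i \le k\alpha/n\} \ge k\}}.
#'
#' @inheritParams gbh
#' @param tau censoring threshold (default 0.5).
#' @param epsilon lower clip on the per-group null proportion (default
#'   0.1).
#' @param tau_cap if `TRUE`, additionally require \eqn{p_i \le \tau} for
#'   rejection; off by default (the cap is not binding at conventional
#'   levels).
#' @return An `fdr_result`; `pi0_by_group` holds the \eqn{\hat q_g}.
#' @export
sabha <- function(p, groups, alpha = 0.05, tau = 0.5, epsilon = 0.1,
                  tau_cap = FALSE) {
  p <- check_pvalues(p)
  groups <- check_groups(p, groups)
  stopifnot(alpha > 0, alpha < 1)
  idx_by_g <- split(seq_along(p), groups)
  q_g <- vapply(idx_by_g, function(ix) storey_q(p[ix], tau, epsilon),
                numeric(1))
  weighted_p <- q_g[groups] * p
  names(weighted_p) <- names(p)
  n <- length(p)
  su <- stepup_kstar(weighted_p, alpha, n)
  sel <- weighted_p <= su$threshold & su$k_star > 0L
  if (tau_cap) sel <- sel & p <= tau
  rejected <- names(p)[sel]
  new_fdr_result("sabha", alpha, rejected, q_g,
                 pi0_overall = sum(lengths(idx_by_g) * q_g) / n,
                 weighted_p = weighted_p, k_star = su$k_star,
                 threshold = su$threshold)
}

#' Single-group (uni-group) adaptive BH variants
#'
#' Runs the corresponding grouped procedure with one group containing all
#' hypotheses: `"tst"` reduces TST-GBH to the two-stage adaptive BH,
#' `"lsl"` reduces LSL-GBH to the LSL adaptive BH, and `"storey"` reduces
#' group SABHA to Storey's tau-censored adaptive BH.
#'
#' @inheritParams sabha
#' @param variant `"storey"`, `"tst"` or `"lsl"`.
#' @return An `fdr_result`.
#' @export
adaptive_unigroup <- function(p, alpha = 0.05,
                              variant = c("storey", "tst", "lsl"),
                              tau = 0.5, epsilon = 0.1) {
  variant <- match.arg(variant)
  p <- check_pvalues(p)
  one <- rep("all", length(p))
  if (variant == "storey") sabha(p, one, alpha, tau, epsilon)
  else gbh(p, one, alpha, estimator = variant)
}
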