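#' @title Intra- and inter-group correlation diagnostics
#' @description Under the exchangeable random-effects model
#'   \eqn{z_{j,i} = \mu_i + a_j + b_{j,g(i)} + e_{j,i}} (patient j, miRNA
#'   i, group g(i); independent components with variances
#'   \eqn{\sigma_a^2, \sigma_b^2, \sigma_e^2}), any two miRNAs in the
#'   same group have correlation
#'   \eqn{\rho_{intra} = (\sigma_a^2+\sigma_b^2)/(\sigma_a^2+\sigma_b^2+\sigma_e^2)}
#'   and two miRNAs in different groups
#'   \eqn{\rho_{inter} = \sigma_a^2/(\sigma_a^2+\sigma_b^2+\sigma_e^2)},
#'   constant across groups. The moment estimator below averages pairwise
#'   Pearson correlations over within- and between-group miRNA pairs.
#' @name group-association
NULL

#' Estimate the constant intra- and inter-group correlations
#'
#' Pairwise Pearson correlations of per-patient delta-delta-Ct profiles
#' (pairwise-complete observations; pairs sharing fewer than 3 patients,
#' or with a constant profile, are skipped) are averaged separately over
#' all within-group and all between-group miRNA pairs. Per-miRNA mean
#' shifts are absorbed by the centering inside the correlation.
#'
#' @param ddct patients x miRNAs delta-delta-Ct matrix.
#' @param scheme a `grouping_scheme` over the columns of `ddct`.
#' @return List with `rho_intra`, `rho_inter`, `n_intra_pairs`,
#'   `n_inter_pairs`.
#' @export
estimate_correlations <- function(ddct, scheme) {
  stopifnot(is.matrix(ddct), !is.null(colnames(ddct)))
  validate_scheme(scheme)
  ids <- colnames(ddct)
  if (!all(ids %in% names(scheme$assignment)))
    stop("scheme does not cover all miRNAs", call. = FALSE)
  if (nrow(ddct) < 3L) stop("need >= 3 patients", call. = FALSE)
  p <- ncol(ddct)
  if (p < 2L) stop("need >= 2 miRNAs", call. = FALSE)

  suppressWarnings(
    R <- stats::cor(ddct, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(ddct))
  R[shared < 3L] <- NA_real_

  g <- scheme$assignment[ids]
  same <- outer(g, g, `==`)
  upper <- upper.tri(R)
  intra <- R[upper & same]
  inter <- R[upper & !same]
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (length(intra) == 0L || length(inter) == 0L)
    stop("no usable miRNA pairs for correlation estimation", call. = FALSE)
  list(rho_intra = mean(intra), rho_inter = mean(inter),
       n_intra_pairs = length(intra), n_inter_pairs = length(inter))
}
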