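# qPCR validation arithmetic: ChIP fold enrichment by signal over
# background and delta-delta-Ct expression fold change.

#' ChIP fold enrichment from Ct values (signal over background)
#'
#' `fold = efficiency^(ct_igg - ct_antibody)`; the IgG control maps to
#' fold 1.  Vectorized; invariant to adding a constant to every Ct value.
#'
#' @param ct_antibody,ct_igg Ct values (PCR cycles), finite.
#' @param efficiency Amplification efficiency per cycle (2 = perfect
#'   doubling).
#' @return Fold enrichment over the IgG background.
#' @export
#' @examples
#' chip_fold_enrichment(28, 30)  # 4
#' chip_fold_enrichment(31, 30)  # 0.5
chip_fold_enrichment <- function(ct_antibody, ct_igg, efficiency = 2) {
  if (any(!is.finite(ct_antibody))) stop("non-finite antibody Ct")
  if (any(!is.finite(ct_igg))) stop("missing or non-finite IgG control Ct")
  stopifnot(efficiency > 1)
  efficiency^(ct_igg - ct_antibody)
}

#' Expression fold change by delta-delta-Ct
#'
#' `ddCt = (ct_target_kd - ct_ref_kd) - (ct_target_mock - ct_ref_mock)`;
#' `fold = efficiency^(-ddCt)`.  Expression is normalized to the
#' reference gene and the mock control maps to fold 1.
#'
#' @param ct_target_kd,ct_ref_kd Target and reference-gene Ct in the
#'   knockdown sample.
#' @param ct_target_mock,ct_ref_mock The same in the mock control.
#' @param efficiency Amplification efficiency per cycle.
#' @return Fold change in expression relative to mock.
#' @export
#' @examples
#' expression_fold_change(24, 20, 25, 20)  # ddCt = -1 -> fold 2
expression_fold_change <- function(ct_target_kd, ct_ref_kd,
                                   ct_target_mock, ct_ref_mock,
                                   efficiency = 2) {
  cts <- c(ct_target_kd, ct_ref_kd, ct_target_mock, ct_ref_mock)
  if (any(!is.finite(cts))) stop("missing or non-finite Ct value")
  stopifnot(efficiency > 1)
  ddct <- (ct_target_kd - ct_ref_kd) - (ct_target_mock - ct_ref_mock)
  efficiency^(-ddct)
}

#' Replicate-aware expression fold change with an SD range
#'
#' Replicate Ct values are averaged before folding; the replicate SD of
#' the per-replicate ddCt propagates to the fold range
#' `[eff^(-ddCt - sd), eff^(-ddCt + sd)]`.
#'
#' @param ct_target_kd,ct_ref_kd,ct_target_mock,ct_ref_mock Numeric
#'   vectors of replicate Ct values (equal length).
#' @param efficiency Amplification efficiency per cycle.
#' @return List with `fold`, `fold_low`, `fold_high`, `ddct`, `sd`.
#' @export
expression_fold_change_replicates <- function(ct_target_kd, ct_ref_kd,
                                              ct_target_mock, ct_ref_mock,
                                              efficiency = 2) {
  n <- length(ct_target_kd)
  stopifnot(n == length(ct_ref_kd), n == length(ct_target_mock),
            n == length(ct_ref_mock), n >= 1L)
  ddct_rep <- (ct_target_kd - ct_ref_kd) - (ct_target_mock - ct_ref_mock)
  ddct <- mean(ddct_rep)
  s <- if (n > 1L) sd(ddct_rep) else 0
  list(fold = efficiency^(-ddct),
       fold_low = efficiency^(-ddct - s),
       fold_high = efficiency^(-ddct + s),
       ddct = ddct, sd = s)
}
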