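#' Filter thresholds for the DNM detection cascade
#'
#' Defaults are the site-specific and trio-level thresholds of the detection
#' pipeline: sites fail if QD < 2.0, FS > 20.0, MQ < 40.0,
#' MQRankSum outside (-2.0, 4.0), ReadPosRankSum outside (-3.0, 3.0) or
#' SOR > 3.0; trio-level retention requires both parents homozygous
#' reference with zero alternate-allele depth, a heterozygous offspring,
#' GQ > 70 in all three individuals, per-sample depth strictly between 0.5x
#' and 2x that sample's mean individual depth, and offspring allelic balance
#' within `[ab_min, ab_max]` (inclusive by default; whether the published
#' bounds are inclusive is not stated, so it is configurable). GQ and DP
#' comparisons are strict inequalities, exactly as printed.
#'
#' @param qd_min,fs_max,mq_min Site-quality bounds (QD, FS, MQ).
#' @param mqrs_min,mqrs_max MQRankSum pass range (exclusive fail outside).
#' @param rprs_min,rprs_max ReadPosRankSum pass range.
#' @param sor_max SOR upper bound.
#' @param gq_min Genotype-quality bound; samples must have GQ strictly
#'   greater than this.
#' @param dp_low_mult,dp_high_mult Depth window multipliers: a sample passes
#'   with `dp > dp_low_mult * mean_depth` and `dp < dp_high_mult * mean_depth`
#'   against its own mean individual depth.
#' @param ab_min,ab_max Offspring allelic-balance window,
#'   AB = AD_alt / (AD_ref + AD_alt).
#' @param ab_inclusive Whether the AB window bounds are inclusive.
#' @param min_scaffold_len Minimum scaffold length (bp) for positions to
#'   enter mean-depth and callability computations.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(qd_min = 2.0, fs_max = 20.0, mq_min = 40.0,
                              mqrs_min = -2.0, mqrs_max = 4.0,
                              rprs_min = -3.0, rprs_max = 3.0,
                              sor_max = 3.0, gq_min = 70,
                              dp_low_mult = 0.5, dp_high_mult = 2.0,
                              ab_min = 0.3, ab_max = 0.7,
                              ab_inclusive = TRUE,
                              min_scaffold_len = 10000) {
  if (mqrs_min >= mqrs_max) stop("MQRankSum window must be ordered")
  if (rprs_min >= rprs_max) stop("ReadPosRankSum window must be ordered")
  if (dp_low_mult >= dp_high_mult) stop("depth window must be ordered")
  if (ab_min > ab_max) stop("allelic-balance window must be ordered")
  structure(list(
    qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
    mqrs_min = mqrs_min, mqrs_max = mqrs_max,
    rprs_min = rprs_min, rprs_max = rprs_max,
    sor_max = sor_max, gq_min = gq_min,
    dp_low_mult = dp_low_mult, dp_high_mult = dp_high_mult,
    ab_min = ab_min, ab_max = ab_max, ab_inclusive = ab_inclusive,
    min_scaffold_len = min_scaffold_len
  ), class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("DNM filter thresholds\n")
  cat(sprintf("  site: QD >= %g, FS <= %g, MQ >= %g, MQRankSum (%g, %g),\n",
              x$qd_min, x$fs_max, x$mq_min, x$mqrs_min, x$mqrs_max))
  cat(sprintf("        ReadPosRankSum (%g, %g), SOR <= %g\n",
              x$rprs_min, x$rprs_max, x$sor_max))
  cat(sprintf("  trio: GQ > %g, DP in (%g, %g) x mean depth, AB %s%g, %g%s\n",
              x$gq_min, x$dp_low_mult, x$dp_high_mult,
              if (x$ab_inclusive) "[" else "(", x$ab_min, x$ab_max,
              if (x$ab_inclusive) "]" else ")"))
  invisible(x)
}

#' Allelic balance of a genotype call
#'
#' AB = AD_alt / (AD_ref + AD_alt); NA when total allelic depth is zero.
#'
#' @param ad_ref,ad_alt Reference and alternate allelic depths.
#' @return Numeric vector of allelic balances.
#' @export
allelic_balance <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(tot > 0, ad_alt / tot, NA_real_)
}

ab_in_window <- function(ab, thresholds) {
  if (thresholds$ab_inclusive) {
    ab >= thresholds$ab_min & ab <= thresholds$ab_max
  } else {
    ab > thresholds$ab_min & ab < thresholds$ab_max
  }
}

dp_in_window <- function(dp, mean_depth, thresholds) {
  dp > thresholds$dp_low_mult * mean_depth &
    dp < thresholds$dp_high_mult * mean_depth
}
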