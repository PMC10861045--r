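# Diploid genotype codes used throughout the package:
#   0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#   NA = missing / no data.

GT_HOMREF <- 0L
GT_HET <- 1L
GT_HOMALT <- 2L

#' Genotype log10-likelihoods under a binomial read-error model
#'
#' For a biallelic site with `ad_ref` reference-supporting and `ad_alt`
#' alternate-supporting reads, the probability that a single read shows the
#' alternate allele is `error` for a hom-ref genotype, 1/2 for a het and
#' `1 - error` for a hom-alt genotype. Reads are treated as independent
#' Bernoulli draws, so each genotype likelihood is a binomial probability.
#'
#' @param ad_ref,ad_alt Integer vectors of reference and alternate read depths.
#' @param error Per-read probability that a read from a homozygous genotype
#'   shows the other allele. An exact 0 gives hard zero likelihoods to any
#'   genotype contradicted by a single read.
#' @return A numeric matrix with one row per site and columns
#'   `hom_ref`, `het`, `hom_alt` of log10 likelihoods.
#' @export
genotype_likelihoods <- function(ad_ref, ad_alt, error = 0.005) {
  stopifnot(length(ad_ref) == length(ad_alt))
  if (any(ad_ref < 0 | ad_alt < 0, na.rm = TRUE)) {
    stop("allelic depths must be non-negative")
  }
  if (error > 0 && error < 1) {
    le <- log10(error)
    l1e <- log10(1 - error)
    out <- matrix(nrow = length(ad_ref), ncol = 3L,
                  dimnames = list(NULL, c("hom_ref", "het", "hom_alt")))
    out[, 1L] <- ad_alt * le + ad_ref * l1e
    out[, 2L] <- (ad_alt + ad_ref) * log10(0.5)
    out[, 3L] <- ad_alt * l1e + ad_ref * le
  } else {
    # convention 0 * log10(0) = 0 so zero-probability outcomes only
    # penalise genotypes actually contradicted by reads
    term <- function(count, pr) {
      res <- count * log10(pr)
      res[count == 0] <- 0
      res
    }
    p <- c(error, 0.5, 1 - error)
    out <- vapply(p, function(pr) {
      term(ad_alt, pr) + term(ad_ref, 1 - pr)
    }, numeric(length(ad_ref)))
    out <- matrix(out, ncol = 3L,
                  dimnames = list(NULL, c("hom_ref", "het", "hom_alt")))
  }
  out
}

#' Maximum-likelihood genotype call with Phred-scaled quality
#'
#' Calls the genotype with the highest likelihood under
#' [genotype_likelihoods()] and reports GQ as the Phred-scaled gap between
#' the best and second-best genotype likelihood, capped at `gq_cap`
#' (mirroring common caller semantics). Sites with zero total depth are
#' returned as missing with GQ 0.
#'
#' @inheritParams genotype_likelihoods
#' @param gq_cap Upper cap on GQ (default 99).
#' @return A list with integer vectors `gt` (0/1/2, NA for no data) and `gq`.
#' @export
call_genotype <- function(ad_ref, ad_alt, error = 0.005, gq_cap = 99L) {
  gl <- genotype_likelihoods(ad_ref, ad_alt, error)
  n <- length(ad_ref)
  a <- gl[, 1L]
  b <- gl[, 2L]
  c3 <- gl[, 3L]
  top <- pmax(a, b, c3)
  second <- pmax(pmin(a, b), pmin(pmax(a, b), c3))
  gt <- integer(n) # ties resolve to the first (lowest) genotype code
  not_a <- !(a >= b & a >= c3)
  gt[not_a & b >= c3] <- 1L
  gt[not_a & b < c3] <- 2L
  gq <- as.integer(round(pmin(10 * (top - second), gq_cap)))
  nodata <- (ad_ref + ad_alt) == 0L
  gt[nodata] <- NA_integer_
  gq[nodata] <- 0L
  list(gt = gt, gq = gq)
}

#' Convert genotype codes to VCF GT strings and back
#'
#' @param gt Integer genotype codes (0/1/2, NA).
#' @return Character vector of unphased VCF genotypes.
#' @keywords internal
gt_to_string <- function(gt) {
  out <- c("0/0", "0/1", "1/1")[gt + 1L]
  out[is.na(gt)] <- "./."
  out
}

#' @keywords internal
string_to_gt <- function(s) {
  s <- sub("\\|", "/", s)
  out <- rep(NA_integer_, length(s))
  out[s == "0/0"] <- 0L
  out[s %in% c("0/1", "1/0")] <- 1L
  out[s == "1/1"] <- 2L
  out
}
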