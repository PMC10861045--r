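# Genetic diversity, effective-size estimators and trajectory summaries,
# census size from survey tables with bootstrap, and Ne/Nc ratios.

#' Pairwise nucleotide diversity from called genotypes
#'
#' Unbiased sample heterozygosity averaged over the assayed genome: for a
#' biallelic site with alternate-allele frequency `p` over `m` sampled
#' alleles, the per-site value is `2 p (1 - p) * m / (m - 1)` (the
#' probability two alleles drawn without replacement differ), summed over
#' polymorphic sites and divided by the total number of assayed sites
#' (including monomorphic ones). Multi-allelic sites are excluded and
#' their count reported as an attribute.
#'
#' @param genotypes Integer matrix of alternate-allele counts
#'   (individuals x sites; 0/1/2, NA for missing). An optional
#'   `multiallelic` logical attribute or argument marks excluded sites.
#' @param n_sites_total Total assayed sites (>= number of columns).
#' @param multiallelic Optional logical vector marking multi-allelic sites
#'   (excluded from the sum, counted in the attribute).
#' @return Nucleotide diversity `pi` with attribute `n_multiallelic`.
#' @examples
#' g <- rbind(c(0L), c(2L)) # one site, genotypes 0/0 and 1/1
#' pairwise_pi(g, n_sites_total = 1) # 2 * 0.25 * 4/3 = 2/3
#' @export
pairwise_pi <- function(genotypes, n_sites_total,
                        multiallelic = NULL) {
  if (n_sites_total <= 0) stop("n_sites_total must be positive")
  if (!is.matrix(genotypes)) genotypes <- matrix(genotypes, ncol = 1)
  if (nrow(genotypes) < 2) stop("need >= 2 individuals")
  keep <- rep(TRUE, ncol(genotypes))
  n_multi <- 0L
  if (!is.null(multiallelic)) {
    keep <- !multiallelic
    n_multi <- sum(multiallelic)
  }
  g <- genotypes[, keep, drop = FALSE]
  m <- 2 * colSums(!is.na(g)) # sampled alleles per site
  ac <- colSums(g, na.rm = TRUE)
  p <- ifelse(m > 0, ac / m, 0)
  site_h <- ifelse(m > 1, 2 * p * (1 - p) * m / (m - 1), 0)
  out <- sum(site_h) / n_sites_total
  attr(out, "n_multiallelic") <- n_multi
  out
}

#' Parental genotype matrix of a simulated cohort
#'
#' Stacks the parents of every family into one individuals-by-sites
#' genotype matrix over the union of variant positions (parents are
#' hom-ref at other families' sites), ready for [pairwise_pi()].
#'
#' @param cohort A `trio_cohort` (truth genotypes, not calls).
#' @return Integer matrix (2 x n_families rows).
#' @export
parental_genotypes <- function(cohort) {
  all_pos <- sort(unique(unlist(lapply(cohort$families, `[[`, "pos"))))
  fams <- cohort$families
  out <- matrix(0L, nrow = 2 * length(fams), ncol = length(all_pos))
  rn <- character(2 * length(fams))
  for (f in seq_along(fams)) {
    fam <- fams[[f]]
    idx <- match(fam$pos, all_pos)
    out[2 * f - 1, idx] <- fam$hap[, 1] + fam$hap[, 2]
    out[2 * f, idx] <- fam$hap[, 3] + fam$hap[, 4]
    rn[2 * f - 1] <- paste0(names(fams)[f], "_mother")
    rn[2 * f] <- paste0(names(fams)[f], "_father")
  }
  rownames(out) <- rn
  out
}

#' Equilibrium effective population size
#'
#' Under mutation-drift equilibrium, `Ne = pi / (4 * mu)`.
#'
#' @param pi Nucleotide diversity.
#' @param mu Per-site per-generation mutation rate (> 0).
#' @return Effective population size.
#' @examples
#' equilibrium_ne(0.0108, 9.13e-9) # ~295,728
#' @export
equilibrium_ne <- function(pi, mu) {
  if (any(mu <= 0)) stop("mu must be positive")
  pi / (4 * mu)
}

#' Windowed harmonic or arithmetic mean of an Ne trajectory
#'
#' The harmonic mean — `k / sum(1 / Ne_i)` over the `k` in-window points —
#' is the drift-relevant long-term average of a fluctuating population
#' (dominated by its minima); the arithmetic mean is used for recent
#' LD-based trajectories.
#'
#' @param trajectory A `data.frame(time, ne)` (see [read_trajectory()]).
#' @param window Numeric length-2 inclusive time window.
#' @param kind `"harmonic"` or `"arithmetic"`.
#' @return The summary Ne over the window.
#' @examples
#' tr <- data.frame(time = c(1, 2), ne = c(100, 400))
#' trajectory_mean(tr, c(0, 10), "harmonic")   # 160
#' trajectory_mean(tr, c(0, 10), "arithmetic") # 250
#' @export
trajectory_mean <- function(trajectory, window,
                            kind = c("harmonic", "arithmetic")) {
  kind <- match.arg(kind)
  stopifnot(length(window) == 2, window[1] <= window[2])
  ne <- trajectory$ne[trajectory$time >= window[1] &
                        trajectory$time <= window[2]]
  if (!length(ne)) stop("no trajectory points inside the window")
  if (kind == "harmonic") {
    length(ne) / sum(1 / ne)
  } else {
    mean(ne)
  }
}

#' Convert manta-tow counts to a swim-count-equivalent density
#'
#' Deterministic regression prediction of density (individuals per km^2)
#' from mean per-tow counts. The default coefficients are a documented
#' placeholder (linear through the origin with unit slope per standard tow
#' area); supply calibrated coefficients for real survey programmes. In
#' stochastic mode, lognormal prediction noise with standard deviation
#' `sigma / sqrt(n_tows)` is added, so dispersion decreases with the
#' number of tows.
#'
#' @param tow_counts Numeric vector of per-tow counts.
#' @param coefficients Named vector with `intercept` and `slope`.
#' @param n_tows Number of tows (defaults to `length(tow_counts)`).
#' @param tow_area_km2 Effective area surveyed per tow.
#' @param stochastic Add prediction noise.
#' @param sigma Lognormal sdlog of the noise at one tow.
#' @param seed Seed used in stochastic mode.
#' @return Predicted density (individuals per km^2).
#' @export
manta_to_density <- function(tow_counts,
                             coefficients = c(intercept = 0, slope = 1),
                             n_tows = length(tow_counts),
                             tow_area_km2 = 1,
                             stochastic = FALSE, sigma = 0.3,
                             seed = NULL) {
  if (!all(c("intercept", "slope") %in% names(coefficients))) {
    stop("coefficients must contain 'intercept' and 'slope'")
  }
  if (n_tows < 1) stop("n_tows must be >= 1")
  dens <- coefficients[["intercept"]] +
    coefficients[["slope"]] * mean(tow_counts) / tow_area_km2
  if (stochastic) {
    if (!is.null(seed)) set.seed(seed)
    dens <- dens * stats::rlnorm(1, meanlog = 0,
                                 sdlog = sigma / sqrt(n_tows))
  }
  max(dens, 0)
}

#' Bootstrap census population size from reef surveys
#'
#' For each monitored year: the annual mean of reef-level densities, a 95%
#' confidence interval from `n_boot` bootstrap pseudo-samples of the
#' monitored reefs (resampled with replacement at the same roster size),
#' and the census size Nc = density x habitat area for the mean and both
#' confidence limits. Across years, the harmonic means of the annual 2.5th
#' and 97.5th percentile Nc series give long-run census bounds.
#'
#' @param survey A `data.frame(reef, year, density)` with density in
#'   individuals per km^2.
#' @param habitat_area_km2 Total habitat surface area (default 14,199).
#' @param n_boot Bootstrap pseudo-samples per year (default 500).
#' @param seed Seed.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `nc_estimate`: `per_year` data frame
#'   (year, n_reefs, mean_density, density_lo, density_hi, nc_mean, nc_lo,
#'   nc_hi), `harmonic_lo`, `harmonic_hi`, `habitat_area_km2`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_nc <- function(survey, habitat_area_km2 = 14199, n_boot = 500,
                         seed = 1L, conf = 0.95) {
  stopifnot(all(c("reef", "year", "density") %in% names(survey)))
  alpha <- (1 - conf) / 2
  years <- sort(unique(survey$year))
  set.seed(seed)
  rows <- list()
  for (y in years) {
    dens <- survey$density[survey$year == y]
    dens <- sort(dens[!is.na(dens)]) # roster order never matters
    n <- length(dens)
    if (n == 0) {
      warning("year ", y, " has no monitored reefs; skipped")
      next
    }
    boot_means <- vapply(seq_len(n_boot), function(b) {
      mean(dens[sample.int(n, replace = TRUE)])
    }, numeric(1))
    qs <- unname(stats::quantile(boot_means, c(alpha, 1 - alpha)))
    rows[[length(rows) + 1]] <- data.frame(
      year = y, n_reefs = n, mean_density = mean(dens),
      density_lo = qs[1], density_hi = qs[2],
      nc_mean = mean(dens) * habitat_area_km2,
      nc_lo = qs[1] * habitat_area_km2,
      nc_hi = qs[2] * habitat_area_km2
    )
  }
  per_year <- do.call(rbind, rows)
  if (is.null(per_year)) stop("no monitored years in survey")
  harm <- function(x) length(x) / sum(1 / x)
  structure(list(
    per_year = per_year,
    harmonic_lo = harm(per_year$nc_lo),
    harmonic_hi = harm(per_year$nc_hi),
    habitat_area_km2 = habitat_area_km2,
    n_boot = n_boot, seed = seed
  ), class = "nc_estimate")
}

#' @export
print.nc_estimate <- function(x, ...) {
  cat(sprintf(
    "Census size over %d years x %s km^2: harmonic 95%% bounds %.3g - %.3g\n",
    nrow(x$per_year), format(x$habitat_area_km2, big.mark = ","),
    x$harmonic_lo, x$harmonic_hi))
  invisible(x)
}

#' Ne/Nc ratio table
#'
#' Ratios of each effective-size estimate against each census-size bound,
#' reported to two significant figures.
#'
#' @param ne Named numeric vector of Ne values.
#' @param nc Named numeric vector of Nc bounds (> 0).
#' @return A numeric matrix (Ne rows x Nc columns) of ratios.
#' @examples
#' ne_nc_ratios(c(recent = 67755), c(hi = 14.3e6, lo = 6.7e6))
#' @export
ne_nc_ratios <- function(ne, nc) {
  if (any(nc <= 0)) stop("Nc bounds must be positive")
  signif(outer(ne, nc, "/"), 2)
}
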