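#' Simulation configuration for synthetic trio cohorts
#'
#' Bundles every tunable of the synthetic-data generator. Defaults reproduce
#' the study design the package targets: seven biparental families with two
#' offspring each (14 mother-father-offspring trios), parental heterozygosity
#' pi = 0.0108, a true germline mutation rate of 9.13e-9 per site per
#' generation, a sibling-sharing (mosaicism) fraction of 0.19, ~60X mean
#' depth with negative-binomial dispersion and a transition:transversion
#' weight of 47/16 (so the simulated spectrum converges to ti/tv = 2.94).
#'
#' @param genome_length Haploid genome length in bp (one scaffold).
#' @param n_families Number of biparental families.
#' @param offspring_per_family Offspring (siblings) per family.
#' @param pi_true Per-site probability that a parent is heterozygous
#'   (infinite-sites, biallelic). Must be in `[0, 1)`.
#' @param mu_true True per-site per-generation mutation rate; the expected
#'   number of de novo mutations per offspring is `2 * genome_length * mu_true`.
#' @param share_fraction Expected fraction of de novo mutation instances that
#'   are mosaic events shared by both siblings of a family, in `[0, 1]`.
#' @param mean_depth Mean sequencing depth per site per individual.
#' @param depth_dispersion Negative-binomial overdispersion of depth: the
#'   per-site depth variance is `mean_depth + depth_dispersion * mean_depth^2`.
#'   0 gives Poisson depth.
#' @param base_error_rate Per-read probability that a read from a homozygous
#'   genotype shows the other allele.
#' @param titv_weight Odds of drawing a transition (vs a transversion) when
#'   placing a de novo mutation; must be positive.
#' @param artifact_rate Fraction of variant sites whose site-quality
#'   annotations (QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR) are flipped
#'   into a failing region of the site filters; 0 disables artifact injection.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(genome_length = 1e5, seed = 1)
#' cfg$mu_true
#' @export
sim_config <- function(genome_length = 1e7,
                       n_families = 7L,
                       offspring_per_family = 2L,
                       pi_true = 0.0108,
                       mu_true = 9.13e-9,
                       share_fraction = 0.19,
                       mean_depth = 60,
                       depth_dispersion = 0.03,
                       base_error_rate = 0.001,
                       titv_weight = 47 / 16,
                       artifact_rate = 0,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.double(genome_length),
    n_families = as.integer(n_families),
    offspring_per_family = as.integer(offspring_per_family),
    pi_true = pi_true,
    mu_true = mu_true,
    share_fraction = share_fraction,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    base_error_rate = base_error_rate,
    titv_weight = titv_weight,
    artifact_rate = artifact_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length < 1) stop("genome_length must be >= 1")
  if (cfg$n_families < 1) stop("n_families must be >= 1")
  if (cfg$offspring_per_family < 1) stop("offspring_per_family must be >= 1")
  if (cfg$pi_true < 0 || cfg$pi_true >= 1) {
    stop("pi_true must be in [0, 1)")
  }
  if (cfg$mu_true < 0) stop("mu_true must be >= 0")
  if (cfg$share_fraction < 0 || cfg$share_fraction > 1) {
    stop("share_fraction must be in [0, 1]")
  }
  if (cfg$mean_depth <= 0) stop("mean_depth must be > 0")
  if (cfg$depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  if (cfg$base_error_rate < 0 || cfg$base_error_rate >= 1) {
    stop("base_error_rate must be in [0, 1)")
  }
  if (cfg$titv_weight <= 0) stop("titv_weight must be > 0")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    stop("artifact_rate must be in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Trio cohort simulation config\n")
  cat(sprintf("  genome: %s bp, %d families x %d offspring (%d trios)\n",
              format(x$genome_length, big.mark = ","), x$n_families,
              x$offspring_per_family, x$n_families * x$offspring_per_family))
  cat(sprintf("  pi = %g, mu = %g, shared fraction = %g\n",
              x$pi_true, x$mu_true, x$share_fraction))
  cat(sprintf("  depth %gX (dispersion %g), error %g, ti/tv weight %.3f\n",
              x$mean_depth, x$depth_dispersion, x$base_error_rate,
              x$titv_weight))
  invisible(x)
}
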