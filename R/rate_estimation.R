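# Callable-site counting, false-negative-rate estimation by spike-in
# simulation, and the per-trio / cohort mutation-rate estimator
#   mu = (nb_DNM - nb_FP) / (2 * C * (1 - FNR)).

#' Count callable sites in a per-site record table
#'
#' A position is callable iff both parents are called homozygous reference
#' and all three individuals pass the GQ and DP filters (GQ strictly above
#' `gq_min`; DP strictly inside each sample's own depth window). This is
#' the denominator condition of the mutation-rate estimator, applied to
#' BP-resolution-style records.
#'
#' @param records Wide trio record table (variant and/or invariant rows).
#' @param thresholds A [filter_thresholds()].
#' @param mean_depths Named per-sample mean depths.
#' @return Integer count of callable positions.
#' @export
count_callable_sites <- function(records, thresholds, mean_depths) {
  ok <- records$mother_gt %in% 0L & records$father_gt %in% 0L &
    records$mother_gq > thresholds$gq_min &
    records$father_gq > thresholds$gq_min &
    records$offspring_gq > thresholds$gq_min &
    dp_in_window(records$mother_dp, mean_depths[["mother"]], thresholds) &
    dp_in_window(records$father_dp, mean_depths[["father"]], thresholds) &
    dp_in_window(records$offspring_dp, mean_depths[["offspring"]],
                 thresholds)
  ok[is.na(ok)] <- FALSE
  sum(ok)
}

#' Estimate genome-wide callable sites for a simulated trio
#'
#' Explicitly simulated (variant) positions are counted exactly with
#' [count_callable_sites()]; the vast invariant remainder of the genome is
#' exchangeable under the read model, so its callable fraction is measured
#' on `n_sample` freshly simulated invariant hom-ref positions and scaled
#' to the remaining genome length. This is the package's scaling design
#' for BP-resolution callability at genome sizes where materialising every
#' position is pointless.
#'
#' @param cohort A `trio_cohort` with read evidence.
#' @param trio_id Trio id.
#' @param thresholds A [filter_thresholds()].
#' @param n_sample Number of invariant positions to sample.
#' @param seed Seed for the invariant-site sample.
#' @param records Optional precomputed [trio_records()] table for the trio
#'   (avoids rebuilding it).
#' @return A list with `c_sites` (estimated C), `frac_invariant`,
#'   `callable_variant`, and the `mean_depths` used.
#' @export
estimate_trio_callable <- function(cohort, trio_id,
                                   thresholds = filter_thresholds(),
                                   n_sample = 2e4,
                                   seed = cohort$config$seed + 4L,
                                   records = NULL) {
  recs <- if (is.null(records)) trio_records(cohort, trio_id) else records
  mean_depths <- c(mother = mean(recs$mother_dp),
                   father = mean(recs$father_dp),
                   offspring = mean(recs$offspring_dp))
  callable_variant <- count_callable_sites(recs, thresholds, mean_depths)
  set.seed(seed)
  cfg <- cohort$config
  inv <- replicate(3, simulate_sample_evidence(rep(0L, n_sample), cfg),
                   simplify = FALSE)
  pass <- inv[[1]]$gt %in% 0L & inv[[2]]$gt %in% 0L &
    inv[[1]]$gq > thresholds$gq_min & inv[[2]]$gq > thresholds$gq_min &
    inv[[3]]$gq > thresholds$gq_min &
    dp_in_window(inv[[1]]$dp, mean_depths[["mother"]], thresholds) &
    dp_in_window(inv[[2]]$dp, mean_depths[["father"]], thresholds) &
    dp_in_window(inv[[3]]$dp, mean_depths[["offspring"]], thresholds)
  frac <- mean(pass)
  n_explicit <- nrow(recs)
  c_sites <- (cfg$genome_length - n_explicit) * frac + callable_variant
  list(c_sites = c_sites, frac_invariant = frac,
       callable_variant = callable_variant, mean_depths = mean_depths)
}

#' Estimate the false-negative rate by spike-in simulation
#'
#' Simulates `n_spikes` true heterozygous de novo sites under the read
#' model (offspring `AD_alt ~ Binomial(DP, 1/2)`, parents hom-ref with
#' error-rate alternate reads, DP from the depth model, GQ from the
#' genotype-likelihood model) and measures the fraction rejected by the
#' candidate-level detection rules *conditional on* the GQ/DP callability
#' rules — callability losses are already absorbed into the callable-site
#' count C, so including them here would correct twice.
#'
#' Components (all switchable):
#' \describe{
#'   \item{detect}{offspring called het and both parents called hom-ref}
#'   \item{parent_ad}{zero alternate reads in both parents}
#'   \item{gq}{GQ strictly above `gq_min` in all three (callability rule)}
#'   \item{dp}{depth strictly inside the window in all three (callability
#'     rule; the window is anchored at `mean_depth`)}
#'   \item{ab}{offspring allelic balance inside the AB window}
#' }
#'
#' @param thresholds A [filter_thresholds()].
#' @param mean_depth,depth_dispersion,error_rate Read-model parameters.
#' @param n_spikes Number of spiked sites (must be positive).
#' @param seed Seed.
#' @param components Character vector of enabled components.
#' @param fixed_dp Optional fixed depth for all individuals (overrides the
#'   depth model; used for exact-oracle checks).
#' @return A list with `fnr`, its Monte-Carlo standard error `se`,
#'   `n_callable` and the components used.
#' @export
estimate_fnr <- function(thresholds = filter_thresholds(),
                         mean_depth = 60, depth_dispersion = 0.03,
                         error_rate = 0.001, n_spikes = 1e5, seed = 1L,
                         components = c("detect", "parent_ad", "gq", "dp",
                                        "ab"),
                         fixed_dp = NULL) {
  if (n_spikes < 1) stop("n_spikes must be positive")
  set.seed(seed)
  draw_dp <- function() {
    if (is.null(fixed_dp)) {
      draw_depth(n_spikes, mean_depth, depth_dispersion)
    } else {
      rep(as.integer(fixed_dp), n_spikes)
    }
  }
  sim_member <- function(true_het) {
    dp <- draw_dp()
    p <- if (true_het) 0.5 else error_rate
    ad_alt <- stats::rbinom(n_spikes, dp, p)
    call <- call_genotype(dp - ad_alt, ad_alt, error = error_rate)
    list(dp = dp, ad_alt = ad_alt, gt = call$gt, gq = call$gq)
  }
  mo <- sim_member(FALSE)
  fa <- sim_member(FALSE)
  off <- sim_member(TRUE)
  callable <- rep(TRUE, n_spikes)
  if ("gq" %in% components) {
    callable <- callable & mo$gq > thresholds$gq_min &
      fa$gq > thresholds$gq_min & off$gq > thresholds$gq_min
  }
  if ("dp" %in% components) {
    callable <- callable &
      dp_in_window(mo$dp, mean_depth, thresholds) &
      dp_in_window(fa$dp, mean_depth, thresholds) &
      dp_in_window(off$dp, mean_depth, thresholds)
  }
  detected <- callable
  if ("detect" %in% components) {
    detected <- detected & off$gt %in% 1L & mo$gt %in% 0L & fa$gt %in% 0L
  }
  if ("parent_ad" %in% components) {
    detected <- detected & mo$ad_alt == 0 & fa$ad_alt == 0
  }
  if ("ab" %in% components) {
    ab <- allelic_balance(off$dp - off$ad_alt, off$ad_alt)
    in_ab <- ab_in_window(ab, thresholds)
    in_ab[is.na(in_ab)] <- FALSE
    detected <- detected & in_ab
  }
  n_callable <- sum(callable)
  if (n_callable == 0) stop("no spiked site passed the callability rules")
  fnr <- 1 - sum(detected) / n_callable
  list(fnr = fnr, se = sqrt(fnr * (1 - fnr) / n_callable),
       n_callable = n_callable, components = components)
}

#' Per-trio germline mutation rate
#'
#' The corrected per-generation estimator
#' `mu = (nb_dnm - nb_fp) / (2 * c_sites * (1 - fnr))`: validated DNM
#' count (candidates minus false positives) over twice the callable sites,
#' inflated for the false-negative rate.
#'
#' @param nb_dnm Number of candidate DNMs entering validation.
#' @param nb_fp Number of those classed false positive.
#' @param c_sites Callable sites C (> 0).
#' @param fnr False-negative rate, in `[0, 1)`.
#' @return Per-site per-generation mutation rate (vectorised).
#' @examples
#' trio_mutation_rate(5, 1, 2.0e8, 0.084) # 1.0917e-08
#' @export
trio_mutation_rate <- function(nb_dnm, nb_fp, c_sites, fnr) {
  if (any(c_sites <= 0)) stop("c_sites must be positive")
  if (any(fnr < 0 | fnr >= 1)) stop("fnr must be in [0, 1)")
  if (any(nb_fp > nb_dnm)) stop("nb_fp cannot exceed nb_dnm")
  if (any(nb_dnm < 0 | nb_fp < 0)) stop("counts must be non-negative")
  (nb_dnm - nb_fp) / (2 * c_sites * (1 - fnr))
}

#' Cohort mean mutation rate with confidence interval
#'
#' Arithmetic mean of per-trio rates with a 95% percentile bootstrap over
#' trios (default) and a Welch/Student t-interval for comparison. The
#' bootstrap resamples whole trios with replacement, holding the seed
#' fixed; trio order does not affect the result.
#'
#' @param mu Numeric vector of per-trio mutation rates (>= 2 trios).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Seed for the bootstrap.
#' @param method `"bootstrap"` (percentile) or `"t"`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `cohort_rate`: `mean`, `ci` (chosen method),
#'   `boot_ci`, `t_ci`, `per_trio`, `n_boot`, `seed`, `method`.
#' @export
cohort_rate_and_ci <- function(mu, n_boot = 10000, seed = 1L,
                               method = c("bootstrap", "t"), conf = 0.95) {
  method <- match.arg(method)
  if (length(mu) < 2) stop("need at least 2 trios for a confidence interval")
  mu_sorted <- sort(mu) # exchangeable: order never matters
  m <- mean(mu_sorted)
  alpha <- (1 - conf) / 2
  set.seed(seed)
  boot_means <- vapply(seq_len(n_boot), function(i) {
    mean(mu_sorted[sample.int(length(mu_sorted), replace = TRUE)])
  }, numeric(1))
  boot_ci <- unname(stats::quantile(boot_means, c(alpha, 1 - alpha)))
  s <- stats::sd(mu_sorted)
  t_ci <- if (s == 0) {
    c(m, m)
  } else {
    m + stats::qt(c(alpha, 1 - alpha), df = length(mu_sorted) - 1) *
      s / sqrt(length(mu_sorted))
  }
  structure(list(
    mean = m,
    ci = if (method == "bootstrap") boot_ci else t_ci,
    boot_ci = boot_ci, t_ci = t_ci, per_trio = mu,
    n_boot = n_boot, seed = seed, method = method, conf = conf
  ), class = "cohort_rate")
}

#' @export
print.cohort_rate <- function(x, ...) {
  cat(sprintf("Cohort mutation rate: mean %.3g, %g%% CI (%s) [%.3g, %.3g]\n",
              x$mean, 100 * x$conf, x$method, x$ci[1], x$ci[2]))
  invisible(x)
}

#' End-to-end mutation-rate estimate for a simulated cohort
#'
#' Runs the DNM-calling cascade on every trio, estimates per-trio callable
#' sites (exact over explicit sites, sampled over the invariant genome), a
#' cohort-wide spike-in FNR, per-trio rates and the cohort mean with CI.
#'
#' @param cohort A `trio_cohort` with read evidence.
#' @param thresholds A [filter_thresholds()].
#' @param n_boot Bootstrap replicates for the cohort CI.
#' @param n_callable_sample Invariant positions sampled per trio for C.
#' @param n_fnr_spikes Spike-in count for the FNR.
#' @param population Optional population variant table.
#' @param curation A [curation_config()].
#' @return A list with `per_trio` (trio, nb_dnm, nb_fp, c_sites, fnr, mu),
#'   `cohort` (a `cohort_rate`), `fnr` and per-trio callsets' tallies.
#' @export
estimate_cohort_rate <- function(cohort,
                                 thresholds = filter_thresholds(),
                                 n_boot = 10000,
                                 n_callable_sample = 2e4,
                                 n_fnr_spikes = 5e4,
                                 population = NULL,
                                 curation = curation_config()) {
  cfg <- cohort$config
  ped <- cohort$pedigree
  fnr_est <- estimate_fnr(
    thresholds, mean_depth = cfg$mean_depth,
    depth_dispersion = cfg$depth_dispersion,
    error_rate = cfg$base_error_rate,
    n_spikes = n_fnr_spikes, seed = cfg$seed + 5L
  )
  per_trio <- vector("list", nrow(ped))
  tallies <- vector("list", nrow(ped))
  validated <- vector("list", nrow(ped))
  for (i in seq_len(nrow(ped))) {
    trio <- ped$trio_id[i]
    recs <- trio_records(cohort, trio)
    fam <- cohort$families[[ped$family[i]]]
    sib_gt <- NULL
    if (!is.na(ped$sibling[i])) {
      sib_role <- sub(paste0(ped$family[i], "_"), "", ped$sibling[i])
      sib_gt <- data.frame(chrom = SIM_CHROM, pos = fam$pos,
                           gt = fam$gt[, sib_role],
                           stringsAsFactors = FALSE)
    }
    cal <- estimate_trio_callable(cohort, trio, thresholds,
                                  n_sample = n_callable_sample,
                                  seed = cfg$seed + 6L + i,
                                  records = recs)
    cs <- call_trio_dnms(recs, thresholds, mean_depths = cal$mean_depths,
                         population = population, curation = curation,
                         sibling_gt = sib_gt)
    mu <- trio_mutation_rate(cs$nb_dnm, cs$nb_fp, cal$c_sites, fnr_est$fnr)
    per_trio[[i]] <- data.frame(
      trio = trio, nb_dnm = cs$nb_dnm, nb_fp = cs$nb_fp,
      c_sites = cal$c_sites, fnr = fnr_est$fnr, mu = mu,
      stringsAsFactors = FALSE
    )
    tl <- cs$tally
    tl$trio <- trio
    tallies[[i]] <- tl
    if (nrow(cs$validated)) {
      v <- cs$validated
      v$trio_id <- trio
      validated[[i]] <- v
    }
  }
  per_trio <- do.call(rbind, per_trio)
  cohort_est <- cohort_rate_and_ci(per_trio$mu, n_boot = n_boot,
                                   seed = cfg$seed + 99L)
  list(per_trio = per_trio, cohort = cohort_est, fnr = fnr_est,
       tally = do.call(rbind, tallies),
       validated = do.call(rbind, validated))
}
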