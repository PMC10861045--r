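# Synthetic trio cohorts: sparse infinite-sites simulation. Only variant
# sites (parental heterozygous positions and planted de novo mutations) are
# materialised; invariant hom-ref sites are exchangeable and are sampled on
# demand for callability estimation (see estimate_trio_callable).

SIM_CHROM <- "scaffold_1"
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
STAT_NAMES <- c("qd", "fs", "mq", "mqranksum", "readposranksum", "sor")

#' Simulate true parental diploid genomes
#'
#' Each parent is heterozygous at a site independently with probability
#' `pi_true` (infinite-sites, biallelic: a reference base plus exactly one
#' alternate base per segregating site). Only heterozygous positions are
#' stored; every unlisted position is homozygous reference.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `parental_genomes`: a list with `config`,
#'   `pedigree` and per-family tables of variant positions, ref/alt bases
#'   and parental haplotypes (0 = ref, 1 = alt).
#' @export
simulate_parental_genomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$genome_length
  ped <- make_pedigree(config$n_families, config$offspring_per_family)
  families <- vector("list", config$n_families)
  names(families) <- paste0("f", seq_len(config$n_families))
  for (f in seq_len(config$n_families)) {
    pos_m <- draw_het_positions(L, config$pi_true)
    pos_f <- draw_het_positions(L, config$pi_true)
    pos <- sort(unique(c(pos_m, pos_f)))
    n <- length(pos)
    hap <- matrix(0L, nrow = n, ncol = 4,
                  dimnames = list(NULL, c("mother_1", "mother_2",
                                          "father_1", "father_2")))
    im <- match(pos_m, pos)
    hap[cbind(im, sample(1:2, length(im), replace = TRUE))] <- 1L
    ifa <- match(pos_f, pos)
    hap[cbind(ifa, 2L + sample(1:2, length(ifa), replace = TRUE))] <- 1L
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- draw_alt_alleles(ref, config$titv_weight)
    families[[f]] <- list(pos = pos, ref = ref, alt = alt, hap = hap)
  }
  structure(list(config = config, pedigree = ped, families = families),
            class = "parental_genomes")
}

draw_het_positions <- function(L, pi_true) {
  if (pi_true == 0) return(integer(0))
  n <- stats::rbinom(1, size = L, prob = pi_true)
  if (n == 0) return(integer(0))
  sort(sample.int(L, n, useHash = TRUE))
}

# Draw one alternate base per site: a transition with odds `titv_weight`
# against a transversion, transversion partners equiprobable.
TRANSVERSION_1 <- c(A = "C", C = "A", G = "C", T = "A")
TRANSVERSION_2 <- c(A = "T", C = "G", G = "T", T = "G")

draw_alt_alleles <- function(ref, titv_weight) {
  n <- length(ref)
  if (n == 0) return(character(0))
  is_ti <- stats::runif(n) < titv_weight / (1 + titv_weight)
  tv <- ifelse(stats::runif(n) < 0.5, TRANSVERSION_1[ref],
               TRANSVERSION_2[ref])
  unname(ifelse(is_ti, TRANSITION[ref], tv))
}

make_pedigree <- function(n_families, offspring_per_family) {
  fam <- paste0("f", rep(seq_len(n_families), each = offspring_per_family))
  oix <- rep(seq_len(offspring_per_family), times = n_families)
  offspring <- paste0(fam, "_off", oix)
  sibling <- if (offspring_per_family == 2) {
    paste0(fam, "_off", 3L - oix)
  } else {
    rep(NA_character_, length(fam))
  }
  data.frame(
    family = fam,
    trio_id = offspring,
    mother = paste0(fam, "_mother"),
    father = paste0(fam, "_father"),
    offspring = offspring,
    sibling = sibling,
    stringsAsFactors = FALSE
  )
}

#' Transmit parental alleles and plant de novo mutations
#'
#' Each offspring inherits one uniformly chosen allele per parent per site
#' (sites are unlinked). De novo mutations (DNMs) are planted at positions
#' where both parents are homozygous reference. Per offspring, private DNMs
#' are Poisson with mean `(1 - share_fraction) * 2 * L * mu_true`; per
#' family, mosaic DNM events shared identically by both siblings (same
#' position, allele and parental haplotype) are Poisson with mean
#' `share_fraction * 2 * L * mu_true`, so the expected DNM count per
#' offspring is `2 * L * mu_true` and the expected fraction of DNM
#' instances shared between siblings is `share_fraction`.
#'
#' @param parents A `parental_genomes` object.
#' @param config The [sim_config()] used to generate `parents`.
#' @return An object of class `trio_cohort` holding per-family site tables,
#'   haplotypes for all family members, and a `truth` data frame of planted
#'   DNMs (offspring, chrom, pos, ref, alt, origin, shared).
#' @export
transmit_and_mutate <- function(parents, config = parents$config) {
  stopifnot(inherits(parents, "parental_genomes"))
  set.seed(config$seed + 1L)
  L <- config$genome_length
  k <- config$offspring_per_family
  m_dnm <- 2 * L * config$mu_true
  truth_list <- list()
  families <- parents$families
  for (f in seq_along(families)) {
    fam <- families[[f]]
    fam_id <- names(families)[f]
    n <- length(fam$pos)
    off_names <- as.vector(t(outer(paste0(fam_id, "_off", seq_len(k)),
                                   c("_m", "_p"), paste0)))
    off_hap <- matrix(0L, nrow = n, ncol = 2 * k,
                      dimnames = list(NULL, off_names))
    for (o in seq_len(k)) {
      pick_m <- 1L + (stats::runif(n) < 0.5)
      pick_f <- 1L + (stats::runif(n) < 0.5)
      if (n > 0) {
        off_hap[, 2 * o - 1] <- fam$hap[cbind(seq_len(n), pick_m)]
        off_hap[, 2 * o] <- fam$hap[cbind(seq_len(n), pick_f + 2L)]
      }
    }
    # planted DNMs: shared mosaic events plus per-offspring private events
    n_shared <- stats::rpois(1, config$share_fraction * m_dnm)
    n_priv <- stats::rpois(k, (1 - config$share_fraction) * m_dnm)
    n_events <- n_shared + sum(n_priv)
    if (n_events > 0) {
      dnm_pos <- draw_new_positions(L, n_events, exclude = fam$pos)
      dnm_ref <- sample(c("A", "C", "G", "T"), n_events, replace = TRUE)
      dnm_alt <- draw_alt_alleles(dnm_ref, config$titv_weight)
      dnm_origin <- sample(c("maternal", "paternal"), n_events,
                           replace = TRUE)
      owner <- c(rep(0L, n_shared),
                 rep(seq_len(k), times = n_priv)) # 0 = shared by all sibs
      add_hap <- matrix(0L, nrow = n_events, ncol = 2 * k,
                        dimnames = list(NULL, off_names))
      for (i in seq_len(n_events)) {
        slot <- if (dnm_origin[i] == "maternal") 1L else 2L
        targets <- if (owner[i] == 0L) seq_len(k) else owner[i]
        add_hap[i, 2 * (targets - 1) + slot] <- 1L
      }
      ord <- order(c(fam$pos, dnm_pos))
      fam$pos <- c(fam$pos, dnm_pos)[ord]
      fam$ref <- c(fam$ref, dnm_ref)[ord]
      fam$alt <- c(fam$alt, dnm_alt)[ord]
      fam$hap <- rbind(fam$hap, matrix(0L, n_events, 4))[ord, , drop = FALSE]
      off_hap <- rbind(off_hap, add_hap)[ord, , drop = FALSE]
      tr <- do.call(rbind, lapply(seq_len(n_events), function(i) {
        targets <- if (owner[i] == 0L) seq_len(k) else owner[i]
        data.frame(
          family = fam_id,
          offspring = paste0(fam_id, "_off", targets),
          chrom = SIM_CHROM,
          pos = dnm_pos[i],
          ref = dnm_ref[i],
          alt = dnm_alt[i],
          origin = dnm_origin[i],
          shared = owner[i] == 0L,
          stringsAsFactors = FALSE
        )
      }))
      truth_list[[fam_id]] <- tr
    }
    fam$off_hap <- off_hap
    families[[f]] <- fam
  }
  truth <- if (length(truth_list)) {
    out <- do.call(rbind, truth_list)
    rownames(out) <- NULL
    out
  } else {
    data.frame(family = character(0), offspring = character(0),
               chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), origin = character(0),
               shared = logical(0), stringsAsFactors = FALSE)
  }
  structure(list(config = config, pedigree = parents$pedigree,
                 families = families, truth = truth),
            class = "trio_cohort")
}

draw_new_positions <- function(L, n, exclude) {
  pos <- integer(0)
  while (length(pos) < n) {
    cand <- ceiling(stats::runif(n - length(pos)) * L)
    cand <- setdiff(unique(cand), c(exclude, pos))
    pos <- c(pos, cand)
  }
  pos[seq_len(n)]
}

#' Simulate read-level evidence for a trio cohort
#'
#' Draws per-site per-sample total depth (negative binomial with mean
#' `mean_depth` and variance `mean_depth + depth_dispersion * mean_depth^2`;
#' Poisson when `depth_dispersion = 0`), alternate-allele depth (binomial
#' with success probability `base_error_rate` for hom-ref genotypes, 1/2
#' for hets and `1 - base_error_rate` for hom-alt), and calls genotypes
#' with [call_genotype()]. Site-quality annotations (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum, SOR) are drawn from Gaussian nulls centred well inside
#' the pass region of the default site filters; a fraction `artifact_rate`
#' of sites has one annotation flipped into a failing region.
#'
#' @param cohort A `trio_cohort` from [transmit_and_mutate()].
#' @param config The [sim_config()] used to generate the cohort.
#' @return The cohort with per-family evidence matrices `dp`, `ad_alt`,
#'   `gt`, `gq` (columns mother, father, off1, ...) and a site-annotation
#'   matrix `stats`.
#' @export
simulate_reads <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "trio_cohort"))
  set.seed(config$seed + 2L)
  k <- config$offspring_per_family
  sample_roles <- c("mother", "father", paste0("off", seq_len(k)))
  for (f in seq_along(cohort$families)) {
    fam <- cohort$families[[f]]
    n <- length(fam$pos)
    geno <- matrix(0L, nrow = n, ncol = length(sample_roles),
                   dimnames = list(NULL, sample_roles))
    geno[, 1L] <- fam$hap[, 1] + fam$hap[, 2]
    geno[, 2L] <- fam$hap[, 3] + fam$hap[, 4]
    for (o in seq_len(k)) {
      geno[, 2L + o] <- fam$off_hap[, 2 * o - 1] + fam$off_hap[, 2 * o]
    }
    dp <- ad_alt <- gt <- gq <- matrix(
      NA_integer_, nrow = n, ncol = length(sample_roles),
      dimnames = list(NULL, sample_roles))
    for (s in seq_along(sample_roles)) {
      ev <- simulate_sample_evidence(geno[, s], config)
      dp[, s] <- ev$dp
      ad_alt[, s] <- ev$ad_alt
      gt[, s] <- ev$gt
      gq[, s] <- ev$gq
    }
    fam$dp <- dp
    fam$ad_alt <- ad_alt
    fam$gt <- gt
    fam$gq <- gq
    fam$stats <- draw_site_stats(n, config$artifact_rate)
    cohort$families[[f]] <- fam
  }
  cohort$has_reads <- TRUE
  cohort
}

# Evidence for one sample over a vector of true genotype codes.
simulate_sample_evidence <- function(geno, config) {
  n <- length(geno)
  dp <- draw_depth(n, config$mean_depth, config$depth_dispersion)
  p_alt <- c(config$base_error_rate, 0.5, 1 - config$base_error_rate)[geno + 1L]
  ad_alt <- stats::rbinom(n, size = dp, prob = p_alt)
  call <- call_genotype(dp - ad_alt, ad_alt, error = config$base_error_rate)
  list(dp = dp, ad_alt = ad_alt, gt = call$gt, gq = call$gq)
}

draw_depth <- function(n, mean_depth, dispersion) {
  if (dispersion == 0) {
    stats::rpois(n, mean_depth)
  } else {
    stats::rnbinom(n, size = 1 / dispersion, mu = mean_depth)
  }
}

# Site-quality nulls sit >= 6 standard deviations inside every default
# filter threshold so clean sites essentially never fail the site filters.
draw_site_stats <- function(n, artifact_rate = 0) {
  stats <- cbind(
    qd = stats::rnorm(n, 20, 3),
    fs = pmax(0, stats::rnorm(n, 5, 2.5)),
    mq = stats::rnorm(n, 60, 3),
    mqranksum = stats::rnorm(n, 1, 0.5),
    readposranksum = stats::rnorm(n, 0, 0.5),
    sor = pmax(0, stats::rnorm(n, 1, 0.3))
  )
  if (artifact_rate > 0 && n > 0) {
    bad <- which(stats::runif(n) < artifact_rate)
    if (length(bad)) {
      fail_values <- c(qd = 1.0, fs = 30, mq = 30, mqranksum = 5,
                       readposranksum = 4, sor = 4)
      which_stat <- sample(seq_along(fail_values), length(bad),
                           replace = TRUE)
      stats[cbind(bad, which_stat)] <- fail_values[which_stat]
    }
  }
  stats
}

#' Simulate a complete trio cohort
#'
#' Convenience wrapper chaining [simulate_parental_genomes()],
#' [transmit_and_mutate()] and [simulate_reads()].
#'
#' @param config A [sim_config()].
#' @return A `trio_cohort` with truth and read evidence.
#' @examples
#' cohort <- simulate_trio_cohort(sim_config(genome_length = 5e4,
#'                                           mu_true = 2e-5, seed = 7))
#' nrow(cohort$truth)
#' @export
simulate_trio_cohort <- function(config = sim_config()) {
  simulate_reads(transmit_and_mutate(simulate_parental_genomes(config)))
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("Trio cohort: %d families, %d trios, %s planted DNM instances\n",
              length(x$families), nrow(x$pedigree), nrow(x$truth)))
  invisible(x)
}

#' Site records for one trio
#'
#' Flattens the family-level evidence into the wide per-site record table
#' consumed by the DNM-calling cascade: one row per explicitly simulated
#' site with site annotations and per-role genotype evidence
#' (`<role>_gt`, `<role>_ad_ref`, `<role>_ad_alt`, `<role>_dp`,
#' `<role>_gq` for mother, father and offspring).
#'
#' @param cohort A `trio_cohort` with read evidence.
#' @param trio_id A trio id from `cohort$pedigree$trio_id`.
#' @return A `data.frame` of site records in coordinate order.
#' @export
trio_records <- function(cohort, trio_id) {
  stopifnot(isTRUE(cohort$has_reads))
  ped <- cohort$pedigree[cohort$pedigree$trio_id == trio_id, , drop = FALSE]
  if (nrow(ped) != 1) stop("unknown trio id: ", trio_id)
  fam <- cohort$families[[ped$family]]
  off_role <- sub(paste0(ped$family, "_"), "", ped$offspring)
  roles <- c(mother = "mother", father = "father", offspring = off_role)
  cols <- list(
    chrom = rep(SIM_CHROM, length(fam$pos)),
    pos = fam$pos,
    ref = fam$ref,
    alt = fam$alt
  )
  for (st in colnames(fam$stats)) cols[[st]] <- fam$stats[, st]
  for (r in names(roles)) {
    s <- roles[[r]]
    cols[[paste0(r, "_gt")]] <- fam$gt[, s]
    cols[[paste0(r, "_ad_ref")]] <- fam$dp[, s] - fam$ad_alt[, s]
    cols[[paste0(r, "_ad_alt")]] <- fam$ad_alt[, s]
    cols[[paste0(r, "_dp")]] <- fam$dp[, s]
    cols[[paste0(r, "_gq")]] <- fam$gq[, s]
  }
  out <- cols
  attr(out, "row.names") <- .set_row_names(length(cols$pos))
  class(out) <- "data.frame"
  out
}
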