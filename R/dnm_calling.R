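# The DNM detection cascade: site filters -> Mendelian-violation candidates
# -> trio-level filters (parental AD = 0, GQ, DP window, allelic balance)
# -> independent genotype-likelihood recall -> population polymorphism
# screen -> automated curation heuristics.

SITE_FILTER_NAMES <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")

#' Apply site-quality filters to variant records
#'
#' A record fails if any enabled inequality triggers: QD below `qd_min`,
#' FS above `fs_max`, MQ below `mq_min`, MQRankSum outside
#' `(mqrs_min, mqrs_max)`, ReadPosRankSum outside `(rprs_min, rprs_max)`,
#' or SOR above `sor_max`. Missing annotations pass (caller convention);
#' missingness is auditable from the record itself.
#'
#' @param records Wide record table with columns `qd`, `fs`, `mq`,
#'   `mqranksum`, `readposranksum`, `sor`.
#' @param thresholds A [filter_thresholds()] object.
#' @param enabled Character vector of enabled filters (subset of
#'   QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR).
#' @return A list with logical `pass` and character `reasons`
#'   (";"-separated names of triggered filters, "" when passing).
#' @export
apply_site_filters <- function(records, thresholds = filter_thresholds(),
                               enabled = SITE_FILTER_NAMES) {
  n <- nrow(records)
  fails <- matrix(FALSE, n, length(SITE_FILTER_NAMES),
                  dimnames = list(NULL, SITE_FILTER_NAMES))
  chk <- function(x, bad) !is.na(x) & bad
  if ("QD" %in% enabled) {
    fails[, "QD"] <- chk(records$qd, records$qd < thresholds$qd_min)
  }
  if ("FS" %in% enabled) {
    fails[, "FS"] <- chk(records$fs, records$fs > thresholds$fs_max)
  }
  if ("MQ" %in% enabled) {
    fails[, "MQ"] <- chk(records$mq, records$mq < thresholds$mq_min)
  }
  if ("MQRankSum" %in% enabled) {
    fails[, "MQRankSum"] <- chk(records$mqranksum,
                                records$mqranksum < thresholds$mqrs_min |
                                  records$mqranksum > thresholds$mqrs_max)
  }
  if ("ReadPosRankSum" %in% enabled) {
    fails[, "ReadPosRankSum"] <-
      chk(records$readposranksum,
          records$readposranksum < thresholds$rprs_min |
            records$readposranksum > thresholds$rprs_max)
  }
  if ("SOR" %in% enabled) {
    fails[, "SOR"] <- chk(records$sor, records$sor > thresholds$sor_max)
  }
  pass <- rowSums(fails) == 0
  reasons <- character(n)
  bad <- which(!pass)
  if (length(bad)) {
    reasons[bad] <- apply(fails[bad, , drop = FALSE], 1, function(r) {
      paste(SITE_FILTER_NAMES[r], collapse = ";")
    })
  }
  list(pass = pass, reasons = reasons)
}

#' Detect Mendelian-violation candidates in trio records
#'
#' Emits candidate records where an offspring allele occurs in neither
#' parental called genotype. The canonical de novo configuration (both
#' parents hom-ref, offspring het) is flagged; other violations (e.g.
#' offspring hom-alt with hom-ref parents) are recorded as non-canonical.
#' Records with any missing genotype are never candidates.
#'
#' @param records Wide trio record table (site filters typically applied
#'   upstream; this function is purely a genotype-configuration scan).
#' @return The candidate subset of `records` with an added logical column
#'   `canonical`.
#' @export
detect_mendelian_violations <- function(records) {
  out <- records[mendelian_violation_mask(records), , drop = FALSE]
  out$canonical <- out$mother_gt == 0L & out$father_gt == 0L &
    out$offspring_gt == 1L
  rownames(out) <- NULL
  out
}

# Logical mask of Mendelian-violation rows (offspring allele present in
# neither parental called genotype), computed without copying the table.
mendelian_violation_mask <- function(records) {
  m <- records$mother_gt
  f <- records$father_gt
  o <- records$offspring_gt
  has_alt <- !is.na(o) & o >= 1
  has_ref <- !is.na(o) & o <= 1
  m_alt <- !is.na(m) & m >= 1
  f_alt <- !is.na(f) & f >= 1
  m_ref <- !is.na(m) & m <= 1
  f_ref <- !is.na(f) & f <= 1
  complete <- !is.na(m) & !is.na(f) & !is.na(o) & !is.na(records$alt)
  complete & ((has_alt & !m_alt & !f_alt) | (has_ref & !m_ref & !f_ref))
}

#' Trio-level candidate filter
#'
#' Retains a candidate iff: both parents are called hom-ref with zero
#' alternate allelic depth (AD = 0), the offspring is called het, all three
#' individuals have GQ strictly above `gq_min`, each individual's depth is
#' strictly inside its own `(dp_low_mult, dp_high_mult) x mean depth`
#' window, and the offspring allelic balance lies in the AB window.
#'
#' @param candidates Candidate record table.
#' @param thresholds A [filter_thresholds()].
#' @param mean_depths Named numeric vector with per-sample mean depths
#'   (`mother`, `father`, `offspring`).
#' @return A list with logical `retain` and character `reasons`.
#' @export
trio_candidate_filter <- function(candidates, thresholds, mean_depths) {
  stopifnot(all(c("mother", "father", "offspring") %in% names(mean_depths)))
  n <- nrow(candidates)
  checks <- list(
    not_canonical_config =
      !(candidates$mother_gt %in% 0L) | !(candidates$father_gt %in% 0L) |
      !(candidates$offspring_gt %in% 1L),
    parental_alt_reads =
      candidates$mother_ad_alt > 0 | candidates$father_ad_alt > 0,
    GQ = candidates$mother_gq <= thresholds$gq_min |
      candidates$father_gq <= thresholds$gq_min |
      candidates$offspring_gq <= thresholds$gq_min,
    DP = !dp_in_window(candidates$mother_dp, mean_depths[["mother"]],
                       thresholds) |
      !dp_in_window(candidates$father_dp, mean_depths[["father"]],
                    thresholds) |
      !dp_in_window(candidates$offspring_dp, mean_depths[["offspring"]],
                    thresholds),
    AB = !ab_in_window(
      allelic_balance(candidates$offspring_ad_ref,
                      candidates$offspring_ad_alt), thresholds)
  )
  fails <- vapply(checks, function(x) {
    x[is.na(x)] <- TRUE
    x
  }, logical(n))
  fails <- matrix(fails, nrow = n, dimnames = list(NULL, names(checks)))
  retain <- rowSums(fails) == 0
  reasons <- character(n)
  bad <- which(!retain)
  if (length(bad)) {
    reasons[bad] <- apply(fails[bad, , drop = FALSE], 1, function(r) {
      paste(names(checks)[r], collapse = ";")
    })
  }
  list(retain = retain, reasons = reasons)
}

#' Independent genotype-likelihood recall of candidate sites
#'
#' Re-genotypes the trio from raw allelic depths with the internal
#' binomial genotype-likelihood caller (an in-package stand-in for
#' concordance between two independent callers: the recall is concordant
#' iff the re-called genotypes reproduce the de novo configuration
#' hom-ref / hom-ref / het). Candidates with zero depth in any individual
#' are discordant with reason `no_data`.
#'
#' @param candidates Candidate record table.
#' @param error Recall caller error rate (default 0.005).
#' @return A list with logical `concordant` and character `reasons`.
#' @export
independent_recall <- function(candidates, error = 0.005) {
  n <- nrow(candidates)
  recall <- lapply(c("mother", "father", "offspring"), function(role) {
    call_genotype(candidates[[paste0(role, "_ad_ref")]],
                  candidates[[paste0(role, "_ad_alt")]], error = error)$gt
  })
  names(recall) <- c("mother", "father", "offspring")
  no_data <- candidates$mother_dp == 0 | candidates$father_dp == 0 |
    candidates$offspring_dp == 0
  ok <- !no_data &
    recall$mother %in% 0L & recall$father %in% 0L &
    recall$offspring %in% 1L
  reasons <- character(n)
  reasons[no_data] <- "no_data"
  mismatch <- !ok & !no_data
  reasons[mismatch] <- "recall_genotype_mismatch"
  list(concordant = ok, reasons = reasons)
}

#' Screen candidates against population polymorphism
#'
#' Flags a candidate as a known segregating variant iff the population
#' table contains the same position with the same alternate allele
#' (positional-only matching available by flag).
#'
#' @param candidates Candidate record table.
#' @param population A `data.frame(chrom, pos, alt)` of population variants
#'   (e.g. read from a population VCF or allele-count TSV).
#' @param match_alt Require the alternate allele to match (default TRUE).
#' @return Logical vector: TRUE where the candidate is present in the
#'   population table (to be classed false positive).
#' @export
population_screen <- function(candidates, population, match_alt = TRUE) {
  if (is.null(population) || nrow(population) == 0) {
    return(rep(FALSE, nrow(candidates)))
  }
  if (match_alt) {
    key <- paste(candidates$chrom, candidates$pos, candidates$alt)
    pop_key <- paste(population$chrom, population$pos, population$alt)
  } else {
    key <- paste(candidates$chrom, candidates$pos)
    pop_key <- paste(population$chrom, population$pos)
  }
  key %in% pop_key
}

#' Curation heuristic configuration
#'
#' Automated proxies for visual curation of candidate DNMs. Each criterion
#' is individually switchable:
#' \describe{
#'   \item{parental_raw_ad}{any raw parental alternate read at the site}
#'   \item{spacing}{distance to the nearest other candidate (or supplied
#'     known variant) below `min_spacing` bp}
#'   \item{density}{more than `max_per_window` candidates within a
#'     `window_bp` window}
#'   \item{sibling}{sibling called genotype contradicting the candidate
#'     (hom-alt sibling at a het candidate site)}
#'   \item{stat_bias}{extreme strand/position bias
#'     (`|MQRankSum| > mqrs_abs_max` or `SOR > sor_bias_max`)}
#'   \item{depth}{offspring depth anomaly outside
#'     `(dp_lo_mult, dp_hi_mult) x mean depth`}
#' }
#'
#' @param parental_raw_ad,spacing,density,sibling,stat_bias,depth Logical
#'   switches.
#' @param min_spacing,window_bp,max_per_window,mqrs_abs_max,sor_bias_max,dp_hi_mult,dp_lo_mult
#'   Numeric knobs.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(parental_raw_ad = TRUE, spacing = TRUE,
                            density = TRUE, sibling = TRUE,
                            stat_bias = TRUE, depth = TRUE,
                            min_spacing = 10, window_bp = 100,
                            max_per_window = 2, mqrs_abs_max = 8,
                            sor_bias_max = 6, dp_hi_mult = 3,
                            dp_lo_mult = 0.25) {
  structure(as.list(environment()), class = "curation_config")
}

#' Apply curation heuristics to surviving candidates
#'
#' @param candidates Candidate record table (typically survivors of the
#'   earlier stages).
#' @param mean_depths Named per-sample mean depths (for the depth-anomaly
#'   criterion).
#' @param config A [curation_config()].
#' @param all_candidate_pos Optional `data.frame(chrom, pos)` of *all*
#'   Mendelian-violation candidates in the trio, used by the spacing and
#'   density criteria; defaults to the candidates themselves.
#' @param known_variants Optional `data.frame(chrom, pos)` of additional
#'   positions (e.g. indels) for the spacing criterion.
#' @param sibling_gt Optional integer vector (aligned with `candidates`)
#'   of the sibling's called genotype at each candidate site.
#' @param raw_parent_ad Optional numeric vector of raw parental alternate
#'   read counts from unfiltered evidence; defaults to the candidates' own
#'   parental AD fields.
#' @return A list with logical `pass`, a logical matrix `criteria`
#'   (TRUE = criterion failed) and character `reasons`.
#' @export
curation_heuristics <- function(candidates, mean_depths,
                                config = curation_config(),
                                all_candidate_pos = NULL,
                                known_variants = NULL,
                                sibling_gt = NULL,
                                raw_parent_ad = NULL) {
  n <- nrow(candidates)
  crit <- matrix(FALSE, n, 6,
                 dimnames = list(NULL, c("parental_raw_ad", "spacing",
                                         "density", "sibling", "stat_bias",
                                         "depth")))
  if (config$parental_raw_ad) {
    raw <- if (is.null(raw_parent_ad)) {
      candidates$mother_ad_alt + candidates$father_ad_alt
    } else {
      raw_parent_ad
    }
    crit[, "parental_raw_ad"] <- raw > 0
  }
  neighbour_pos <- if (is.null(all_candidate_pos)) {
    candidates[c("chrom", "pos")]
  } else {
    all_candidate_pos[c("chrom", "pos")]
  }
  if (!is.null(known_variants)) {
    neighbour_pos <- rbind(neighbour_pos, known_variants[c("chrom", "pos")])
  }
  if (config$spacing || config$density) {
    for (i in seq_len(n)) {
      same <- neighbour_pos$chrom == candidates$chrom[i]
      d <- abs(neighbour_pos$pos[same] - candidates$pos[i])
      d_other <- d[d > 0]
      if (config$spacing && length(d_other) &&
          min(d_other) < config$min_spacing) {
        crit[i, "spacing"] <- TRUE
      }
      if (config$density &&
          sum(d <= config$window_bp / 2) > config$max_per_window) {
        crit[i, "density"] <- TRUE
      }
    }
  }
  if (config$sibling && !is.null(sibling_gt)) {
    crit[, "sibling"] <- !is.na(sibling_gt) & sibling_gt == 2L
  }
  if (config$stat_bias) {
    crit[, "stat_bias"] <-
      (!is.na(candidates$mqranksum) &
         abs(candidates$mqranksum) > config$mqrs_abs_max) |
      (!is.na(candidates$sor) & candidates$sor > config$sor_bias_max)
  }
  if (config$depth) {
    md <- mean_depths[["offspring"]]
    crit[, "depth"] <- candidates$offspring_dp > config$dp_hi_mult * md |
      candidates$offspring_dp < config$dp_lo_mult * md
  }
  pass <- rowSums(crit) == 0
  reasons <- character(n)
  bad <- which(!pass)
  if (length(bad)) {
    reasons[bad] <- apply(crit[bad, , drop = FALSE], 1, function(r) {
      paste(colnames(crit)[r], collapse = ";")
    })
  }
  list(pass = pass, criteria = crit, reasons = reasons)
}

#' Run the full DNM-calling cascade on one trio
#'
#' Chains [apply_site_filters()], [detect_mendelian_violations()],
#' [trio_candidate_filter()], [independent_recall()],
#' [population_screen()] and [curation_heuristics()], recording per-stage
#' provenance for every candidate and per-stage tallies. Candidates
#' rejected after the trio-level filter (recall, population screen or
#' curation) are classed `false_positive`; survivors are `validated`.
#' Non-canonical violations are recorded but never validated.
#'
#' @param records Wide trio record table.
#' @param thresholds A [filter_thresholds()].
#' @param mean_depths Named per-sample mean depths; computed from `records`
#'   when `NULL`.
#' @param population Optional population variant table for
#'   [population_screen()].
#' @param curation A [curation_config()].
#' @param sibling_gt Optional sibling called-genotype lookup,
#'   `data.frame(chrom, pos, gt)`.
#' @param recall_error Error rate of the independent recall caller.
#' @return A list of class `dnm_callset`: `candidates` (with provenance
#'   columns `stage_*`, `class`), `validated`, `tally`
#'   (stage, entering, rejected) and `nb_dnm` / `nb_fp` counts for the
#'   rate estimator.
#' @export
call_trio_dnms <- function(records, thresholds = filter_thresholds(),
                           mean_depths = NULL, population = NULL,
                           curation = curation_config(),
                           sibling_gt = NULL, recall_error = 0.005) {
  if (is.null(mean_depths)) {
    mean_depths <- c(
      mother = mean_individual_depth(records, "mother"),
      father = mean_individual_depth(records, "father"),
      offspring = mean_individual_depth(records, "offspring")
    )
  }
  site <- apply_site_filters(records, thresholds)
  cands <- records[site$pass & mendelian_violation_mask(records), ,
                   drop = FALSE]
  cands$canonical <- cands$mother_gt == 0L & cands$father_gt == 0L &
    cands$offspring_gt == 1L
  rownames(cands) <- NULL
  n0 <- nrow(cands)
  if (n0 == 0) {
    empty <- cands
    empty$class <- character(0)
    return(structure(list(
      candidates = empty, validated = empty,
      tally = data.frame(stage = c("mendelian", "trio_filter", "recall",
                                   "population", "curation"),
                         entering = c(0L, 0L, 0L, 0L, 0L),
                         rejected = c(0L, 0L, 0L, 0L, 0L)),
      nb_dnm = 0L, nb_fp = 0L, mean_depths = mean_depths
    ), class = "dnm_callset"))
  }
  cands$stage_site <- "pass"
  trio <- trio_candidate_filter(cands, thresholds, mean_depths)
  cands$stage_trio <- ifelse(trio$retain, "pass",
                             paste0("fail:", trio$reasons))
  surv <- trio$retain
  cands$class <- ifelse(surv, "candidate", "rejected")

  idx <- which(surv)
  sub <- cands[idx, , drop = FALSE]
  recall <- independent_recall(sub, error = recall_error)
  cands$stage_recall <- NA_character_
  cands$stage_recall[idx] <- ifelse(recall$concordant, "pass",
                                    paste0("fail:", recall$reasons))
  cands$class[idx[!recall$concordant]] <- "false_positive"

  idx2 <- idx[recall$concordant]
  pop_hit <- population_screen(cands[idx2, , drop = FALSE], population)
  cands$stage_population <- NA_character_
  cands$stage_population[idx2] <- ifelse(pop_hit, "fail:population_variant",
                                         "pass")
  cands$class[idx2[pop_hit]] <- "false_positive"

  idx3 <- idx2[!pop_hit]
  sib <- NULL
  if (!is.null(sibling_gt)) {
    key <- paste(cands$chrom[idx3], cands$pos[idx3])
    sib <- sibling_gt$gt[match(key, paste(sibling_gt$chrom, sibling_gt$pos))]
  }
  cur <- curation_heuristics(
    cands[idx3, , drop = FALSE], mean_depths, config = curation,
    all_candidate_pos = cands[c("chrom", "pos")], sibling_gt = sib
  )
  cands$stage_curation <- NA_character_
  cands$stage_curation[idx3] <- ifelse(cur$pass, "pass",
                                       paste0("fail:", cur$reasons))
  cands$class[idx3[!cur$pass]] <- "false_positive"
  cands$class[idx3[cur$pass]] <- "validated"

  tally <- data.frame(
    stage = c("mendelian", "trio_filter", "recall", "population",
              "curation"),
    entering = c(n0, n0, length(idx), length(idx2), length(idx3)),
    rejected = c(0L, n0 - length(idx), sum(!recall$concordant),
                 sum(pop_hit), sum(!cur$pass))
  )
  validated <- cands[cands$class == "validated", , drop = FALSE]
  structure(list(
    candidates = cands, validated = validated, tally = tally,
    nb_dnm = length(idx), nb_fp = length(idx) - nrow(validated),
    mean_depths = mean_depths
  ), class = "dnm_callset")
}

#' @export
print.dnm_callset <- function(x, ...) {
  cat(sprintf(
    "DNM callset: %d Mendelian-violation candidates, %d pass trio filter, %d validated\n",
    x$tally$entering[1], x$nb_dnm, nrow(x$validated)))
  invisible(x)
}

#' Sibling-shared DNMs among validated calls
#'
#' A DNM instance is shared iff the identical (chrom, pos, alt) is
#' validated in both siblings of a family. The shared fraction is the
#' number of shared DNM instances over all validated DNM instances.
#'
#' @param validated A `data.frame` of validated DNMs with columns
#'   `trio_id`, `chrom`, `pos`, `alt`.
#' @param pedigree Trio table with `trio_id` and `sibling` columns.
#' @return A list with `n_shared`, `n_total`, `fraction` and the shared
#'   subset `shared`.
#' @export
count_shared_sibling_dnms <- function(validated, pedigree) {
  n_total <- nrow(validated)
  if (n_total == 0) {
    return(list(n_shared = 0L, n_total = 0L, fraction = 0,
                shared = validated))
  }
  sib_of <- stats::setNames(pedigree$sibling, pedigree$trio_id)
  key <- paste(validated$trio_id, validated$chrom, validated$pos,
               validated$alt)
  sib_key <- paste(sib_of[validated$trio_id], validated$chrom,
                   validated$pos, validated$alt)
  is_shared <- sib_key %in% key
  list(n_shared = sum(is_shared), n_total = n_total,
       fraction = sum(is_shared) / n_total,
       shared = validated[is_shared, , drop = FALSE])
}

#' Per-stage and cumulative false-positive rates
#'
#' For stage tallies (per trio): the per-stage FP rate is
#' rejected / entering, and the cumulative rate is the total rejected
#' across stages over the initial candidate count. Both the pooled
#' convention (totals across trios) and the mean of per-trio rates are
#' reported, since the two differ whenever trios are unbalanced.
#' Rates with a zero denominator are undefined and reported as `NA`.
#'
#' @param tallies A `data.frame(trio, stage, entering, rejected)`; stages
#'   are taken in their order of first appearance.
#' @return A list with `per_stage` (stage, pooled_rate, mean_trio_rate),
#'   `cumulative_pooled`, `cumulative_mean_trio` and the per-trio
#'   cumulative rates.
#' @export
false_positive_rates <- function(tallies) {
  stopifnot(all(c("trio", "stage", "entering", "rejected") %in%
                  names(tallies)))
  stages <- unique(tallies$stage)
  rate <- function(rej, ent) if (sum(ent) > 0) sum(rej) / sum(ent) else NA_real_
  per_stage <- do.call(rbind, lapply(stages, function(s) {
    sub <- tallies[tallies$stage == s, , drop = FALSE]
    trio_rates <- ifelse(sub$entering > 0, sub$rejected / sub$entering,
                         NA_real_)
    data.frame(stage = s,
               pooled_rate = rate(sub$rejected, sub$entering),
               mean_trio_rate = mean(trio_rates, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  per_stage$mean_trio_rate[is.nan(per_stage$mean_trio_rate)] <- NA_real_
  per_trio <- vapply(split(tallies, tallies$trio), function(sub) {
    init <- sub$entering[match(stages[1], sub$stage)]
    if (is.na(init) || init == 0) NA_real_ else sum(sub$rejected) / init
  }, numeric(1))
  init_total <- sum(tallies$entering[tallies$stage == stages[1]])
  list(
    per_stage = per_stage,
    cumulative_pooled = if (init_total > 0) {
      sum(tallies$rejected) / init_total
    } else {
      NA_real_
    },
    cumulative_mean_trio = if (all(is.na(per_trio))) {
      NA_real_
    } else {
      mean(per_trio, na.rm = TRUE)
    },
    per_trio = per_trio
  )
}
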