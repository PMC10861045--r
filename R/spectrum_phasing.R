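# Mutation-spectrum classification, CpG context, read-back parent-of-origin
# phasing, paternal:maternal ratio (alpha), functional annotation and the
# associated group tests.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Classify single-base mutations as transitions or transversions, with CpG flag
#'
#' A transition exchanges purines (A<->G) or pyrimidines (C<->T); every
#' other single-base change is a transversion. By default a site is flagged
#' CpG iff the mutated base is the cytosine of a CpG dinucleotide on either
#' strand, i.e. ref C followed by G, or ref G preceded by C (the standard
#' dinucleotide-context reading). `cpg_mode = "literal"` instead flags
#' every mutation from a C regardless of context, an alternative reading
#' retained behind this flag.
#'
#' @param ref,alt Single reference and alternate bases (vectorised).
#' @param context Trinucleotide context strings centred on the site
#'   (e.g. `"ACG"`); `NA` yields `cpg = NA` in context mode.
#' @param cpg_mode `"context"` (default) or `"literal"`.
#' @return A `data.frame(class, cpg)` with `class` in
#'   `{"transition", "transversion"}`.
#' @examples
#' classify_mutation("A", "G", "TAG")$class # transition
#' classify_mutation("C", "A", "ACG")       # transversion at a CpG
#' @export
classify_mutation <- function(ref, alt, context = NA_character_,
                              cpg_mode = c("context", "literal")) {
  cpg_mode <- match.arg(cpg_mode)
  ref <- toupper(ref)
  alt <- toupper(alt)
  bases <- c(PURINES, PYRIMIDINES)
  if (any(!ref %in% bases) || any(!alt %in% bases)) {
    stop("ref and alt must be single A/C/G/T bases")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  transition <- (ref %in% PURINES & alt %in% PURINES) |
    (ref %in% PYRIMIDINES & alt %in% PYRIMIDINES)
  context <- toupper(context)
  if (length(context) == 1 && length(ref) > 1) {
    context <- rep(context, length(ref))
  }
  cpg <- if (cpg_mode == "literal") {
    ref == "C"
  } else {
    ifelse(is.na(context), NA,
           (ref == "C" & substr(context, 3, 3) == "G") |
             (ref == "G" & substr(context, 1, 1) == "C"))
  }
  data.frame(class = ifelse(transition, "transition", "transversion"),
             cpg = cpg, stringsAsFactors = FALSE)
}

#' Transition:transversion ratio
#'
#' @param class Character vector of `"transition"` / `"transversion"`
#'   labels (e.g. from [classify_mutation()]).
#' @return The ratio of transition to transversion counts (`Inf` with no
#'   transversions, `NaN` when both counts are zero).
#' @export
titv_ratio <- function(class) {
  sum(class == "transition") / sum(class == "transversion")
}

#' Informative heterozygous sites for read-back phasing
#'
#' A nearby offspring-het site is informative when exactly one parent can
#' have contributed a given allele: if the father is called hom-ref and
#' the mother carries the alternate allele, an offspring read bearing the
#' alternate must be maternal (and a read bearing the reference paternal),
#' and symmetrically.
#'
#' @param records Wide trio record table with `ref`/`alt` bases.
#' @return A `data.frame(chrom, pos, allele, parent)`; one row per
#'   attributable (site, allele) pair.
#' @export
informative_sites <- function(records) {
  het <- !is.na(records$offspring_gt) & records$offspring_gt == 1L &
    !is.na(records$alt)
  rec <- records[het, , drop = FALSE]
  out <- list()
  m <- rec$mother_gt
  f <- rec$father_gt
  # father cannot donate alt, mother can: alt -> mother, ref -> father
  a <- !is.na(f) & f == 0L & !is.na(m) & m >= 1L
  if (any(a)) {
    out[[length(out) + 1]] <- data.frame(
      chrom = rep(rec$chrom[a], 2), pos = rep(rec$pos[a], 2),
      allele = c(rec$alt[a], rec$ref[a]),
      parent = rep(c("maternal", "paternal"), each = sum(a)),
      stringsAsFactors = FALSE)
  }
  b <- !is.na(m) & m == 0L & !is.na(f) & f >= 1L
  if (any(b)) {
    out[[length(out) + 1]] <- data.frame(
      chrom = rep(rec$chrom[b], 2), pos = rep(rec$pos[b], 2),
      allele = c(rec$alt[b], rec$ref[b]),
      parent = rep(c("paternal", "maternal"), each = sum(b)),
      stringsAsFactors = FALSE)
  }
  # hom-alt x hom-ref: both offspring alleles fully determined
  c1 <- !is.na(m) & m == 2L & !is.na(f) & f == 0L
  if (any(c1)) {
    out[[length(out) + 1]] <- data.frame(
      chrom = rep(rec$chrom[c1], 2), pos = rep(rec$pos[c1], 2),
      allele = c(rec$alt[c1], rec$ref[c1]),
      parent = rep(c("maternal", "paternal"), each = sum(c1)),
      stringsAsFactors = FALSE)
  }
  c2 <- !is.na(f) & f == 2L & !is.na(m) & m == 0L
  if (any(c2)) {
    out[[length(out) + 1]] <- data.frame(
      chrom = rep(rec$chrom[c2], 2), pos = rep(rec$pos[c2], 2),
      allele = c(rec$alt[c2], rec$ref[c2]),
      parent = rep(c("paternal", "maternal"), each = sum(c2)),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      allele = character(0), parent = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # remove duplicated attributions (e.g. hom-alt cases emitted twice)
  res[!duplicated(res[c("chrom", "pos", "allele")]), , drop = FALSE]
}

#' Read-back phasing of a single DNM
#'
#' A parental origin is assigned iff at least one fragment links the DNM
#' alternate allele to an allele attributable to exactly one parent, and
#' no fragment links it to the other parent. Conflicting fragments (or the
#' absence of any informative co-covered site) yield `"unknown"` — the
#' assignment is never taken by majority vote.
#'
#' @param dnm A list or one-row data frame with `chrom`, `pos`, `alt`.
#' @param fragments A `data.frame(fragment_id, chrom, pos, allele)` of
#'   read-fragment observations (one row per covered site per fragment).
#' @param informative An informative-site table from [informative_sites()].
#' @return One of `"maternal"`, `"paternal"`, `"unknown"`.
#' @export
readback_phase <- function(dnm, fragments, informative) {
  carrier <- fragments$fragment_id[
    fragments$chrom == dnm$chrom & fragments$pos == dnm$pos &
      fragments$allele == dnm$alt]
  if (!length(carrier)) return("unknown")
  obs <- fragments[fragments$fragment_id %in% carrier &
                     !(fragments$pos == dnm$pos &
                         fragments$chrom == dnm$chrom), , drop = FALSE]
  if (!nrow(obs)) return("unknown")
  hit <- merge(obs, informative, by = c("chrom", "pos", "allele"))
  parents <- unique(hit$parent)
  if (length(parents) == 1) parents else "unknown"
}

#' Phase every validated DNM of a trio
#'
#' @param dnms A `data.frame(chrom, pos, alt)` of DNMs.
#' @param fragments Fragment observations (see [readback_phase()]).
#' @param informative Informative-site table.
#' @return Character vector of origins aligned with `dnms`.
#' @export
phase_dnms <- function(dnms, fragments, informative) {
  vapply(seq_len(nrow(dnms)), function(i) {
    readback_phase(dnms[i, , drop = FALSE], fragments, informative)
  }, character(1))
}

#' Simulate read fragments spanning planted DNMs
#'
#' Generates synthetic sequencing fragments from the true offspring
#' haplotypes around each planted DNM: fragments from the DNM-carrying
#' haplotype bear the alternate allele plus that haplotype's alleles at
#' covered variant sites; fragments from the homologous haplotype bear the
#' reference. This is the minimal read-level object read-back phasing
#' needs (no full FASTQ/BAM simulation).
#'
#' @param cohort A `trio_cohort`.
#' @param fragment_length Fragment span in bp.
#' @param n_fragments Fragments per haplotype per DNM.
#' @param seed Seed.
#' @return A `data.frame(fragment_id, offspring, chrom, pos, allele)`.
#' @export
simulate_read_fragments <- function(cohort, fragment_length = 500,
                                    n_fragments = 4,
                                    seed = cohort$config$seed + 7L) {
  set.seed(seed)
  truth <- cohort$truth
  out <- list()
  frag_counter <- 0L
  for (i in seq_len(nrow(truth))) {
    fam <- cohort$families[[truth$family[i]]]
    hap_cols <- paste0(truth$offspring[i], c("_m", "_p"))
    carrier_col <- if (truth$origin[i] == "maternal") {
      hap_cols[1]
    } else {
      hap_cols[2]
    }
    for (hap in hap_cols) {
      for (j in seq_len(n_fragments)) {
        start <- truth$pos[i] -
          sample.int(fragment_length, 1) + 1L
        end <- start + fragment_length - 1L
        covered <- which(fam$pos >= start & fam$pos <= end)
        if (!length(covered)) next
        hvals <- fam$off_hap[covered, hap]
        alleles <- ifelse(hvals == 1L, fam$alt[covered], fam$ref[covered])
        # the maternal haplotype carries maternal alleles; the DNM sits on
        # `carrier_col` by construction of transmit_and_mutate()
        frag_counter <- frag_counter + 1L
        out[[length(out) + 1]] <- data.frame(
          fragment_id = paste0("frag", frag_counter),
          offspring = truth$offspring[i],
          chrom = truth$chrom[i],
          pos = fam$pos[covered],
          allele = alleles,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(fragment_id = character(0), offspring = character(0),
                      chrom = character(0), pos = integer(0),
                      allele = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paternal:maternal contribution ratio (alpha) and its test
#'
#' `alpha` is the total paternal over total maternal phased DNM count. The
#' default test is a Welch two-sample t-test comparing the per-trio
#' paternal and maternal count vectors; a one-sample t-test of per-trio
#' paternal fractions against 1/2 is available as an alternative framing.
#'
#' @param counts A `data.frame(trio, maternal, paternal)` of per-trio
#'   phased DNM counts (>= 2 trios).
#' @param method `"welch"` (two-sample) or `"one_sample"`.
#' @return A list with `alpha`, `p_value`, `statistic`, `method`.
#' @examples
#' # cohort totals of 26 paternal vs 27 maternal give alpha = 0.96
#' @export
alpha_and_test <- function(counts, method = c("welch", "one_sample")) {
  method <- match.arg(method)
  stopifnot(all(c("maternal", "paternal") %in% names(counts)))
  if (nrow(counts) < 2) stop("need phased counts for at least 2 trios")
  tot_m <- sum(counts$maternal)
  tot_p <- sum(counts$paternal)
  alpha <- if (tot_m == 0) {
    warning("no maternally phased DNMs; alpha undefined")
    NA_real_
  } else {
    tot_p / tot_m
  }
  if (method == "welch") {
    if (stats::sd(counts$paternal) == 0 && stats::sd(counts$maternal) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(counts$paternal, counts$maternal)
    }
  } else {
    frac <- counts$paternal / (counts$paternal + counts$maternal)
    frac <- frac[is.finite(frac)]
    if (stats::sd(frac) == 0) {
      degenerate_p <- if (isTRUE(all.equal(frac[1], 0.5))) 1 else 0
      tt <- list(statistic = c(t = if (degenerate_p == 1) 0 else Inf),
                 p.value = degenerate_p)
    } else {
      tt <- stats::t.test(frac, mu = 0.5)
    }
  }
  list(alpha = alpha, p_value = tt$p.value,
       statistic = unname(tt$statistic), method = method)
}

#' Annotate DNMs against gene models
#'
#' Assigns each DNM a genomic category with precedence
#' CDS > UTR > intron > intergenic; coding changes are resolved to
#' `missense` / `synonymous` (or `other` for stop gain/loss) by mutating
#' the codon in the spliced CDS and translating with the standard code.
#'
#' @param dnms A `data.frame(chrom, pos, ref, alt)`.
#' @param models Gene models from [read_gff_models()].
#' @param reference A `Biostrings::DNAStringSet` or FASTA path.
#' @return Character vector of categories:
#'   `missense`, `synonymous`, `UTR`, `intron`, `intergenic`, `other`.
#' @export
annotate_dnms <- function(dnms, models, reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub(" .*", "", names(reference))
  }
  vapply(seq_len(nrow(dnms)), function(i) {
    annotate_one_dnm(dnms[i, , drop = FALSE], models, reference)
  }, character(1))
}

annotate_one_dnm <- function(dnm, models, reference) {
  if (!dnm$chrom %in% names(reference)) {
    stop("scaffold absent from reference: ", dnm$chrom)
  }
  on_chrom <- models[models$chrom == dnm$chrom, , drop = FALSE]
  hits <- on_chrom[on_chrom$start <= dnm$pos & on_chrom$end >= dnm$pos, ,
                   drop = FALSE]
  if (any(hits$type == "CDS")) {
    cds_hit <- hits[hits$type == "CDS", , drop = FALSE][1, ]
    return(coding_effect(dnm, models, cds_hit, reference))
  }
  if (any(hits$type %in% c("five_prime_UTR", "three_prime_UTR", "UTR"))) {
    return("UTR")
  }
  if (any(hits$type == "exon")) return("UTR") # exonic non-CDS
  if (any(hits$type %in% c("gene", "mRNA"))) return("intron")
  "intergenic"
}

coding_effect <- function(dnm, models, cds_hit, reference) {
  cds_set <- models[models$type == "CDS" & models$parent %in% cds_hit$parent,
                    , drop = FALSE]
  minus <- identical(cds_hit$strand, "-")
  cds_set <- cds_set[order(cds_set$start, decreasing = minus), , drop = FALSE]
  chrom_seq <- reference[[dnm$chrom]]
  pieces <- lapply(seq_len(nrow(cds_set)), function(j) {
    s <- Biostrings::subseq(chrom_seq, cds_set$start[j], cds_set$end[j])
    if (minus) Biostrings::reverseComplement(s) else s
  })
  cds_seq <- do.call(Biostrings::xscat, pieces)
  # offset of the mutated base within the spliced CDS (1-based)
  offset <- 0L
  for (j in seq_len(nrow(cds_set))) {
    if (dnm$pos >= cds_set$start[j] && dnm$pos <= cds_set$end[j]) {
      offset <- offset + if (minus) {
        cds_set$end[j] - dnm$pos + 1L
      } else {
        dnm$pos - cds_set$start[j] + 1L
      }
      break
    }
    offset <- offset + (cds_set$end[j] - cds_set$start[j] + 1L)
  }
  alt_base <- if (minus) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(dnm$alt)))
  } else {
    dnm$alt
  }
  codon_idx <- (offset - 1L) %/% 3L
  codon_start <- codon_idx * 3L + 1L
  if (codon_start + 2L > length(cds_seq)) return("other") # truncated model
  codon <- as.character(Biostrings::subseq(cds_seq, codon_start,
                                           codon_start + 2L))
  within <- offset - codon_start + 1L
  mut_codon <- codon
  substr(mut_codon, within, within) <- alt_base
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[mut_codon]]
  if (is.null(aa_ref) || is.null(aa_alt)) return("other")
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_alt == "*" || aa_ref == "*") return("other")
  "missense"
}

#' Annotation-category enrichment test
#'
#' Two-sided exact binomial test per category of the observed DNM count
#' against `n_total * fraction`, with Benjamini-Hochberg adjustment across
#' categories. Fractions are the callable-genome composition and must sum
#' to 1 (tolerance 1e-6).
#'
#' @param observed Named integer vector of per-category DNM counts.
#' @param fractions Named numeric vector of genome fractions (same names).
#' @return A `data.frame(category, observed, expected, p, p_adj)`.
#' @export
enrichment_test <- function(observed, fractions) {
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("category fractions must sum to 1")
  }
  if (!all(names(observed) %in% names(fractions))) {
    stop("every observed category needs a genome fraction")
  }
  n_total <- sum(observed)
  p <- vapply(names(observed), function(cat) {
    stats::binom.test(observed[[cat]], n_total, fractions[[cat]],
                      alternative = "two.sided")$p.value
  }, numeric(1))
  data.frame(
    category = names(observed),
    observed = as.integer(observed),
    expected = n_total * fractions[names(observed)],
    p = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' One-way ANOVA of per-trio mutation rates by family
#'
#' Tests whether family grouping explains between-trio variance in the
#' per-trio rates. Degenerate inputs with zero total variance return
#' F = 0, p = 1.
#'
#' @param rates A `data.frame(trio, family, mu)` with at least two
#'   families of at least two trios each.
#' @return A list with `f_statistic`, `p_value` and the fitted `aov`
#'   object (`NULL` in the degenerate case).
#' @export
family_grouping_test <- function(rates) {
  stopifnot(all(c("family", "mu") %in% names(rates)))
  tab <- table(rates$family)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 families with >= 2 trios each")
  }
  if (stats::var(rates$mu) == 0) {
    return(list(f_statistic = 0, p_value = 1, fit = NULL))
  }
  fit <- stats::aov(mu ~ factor(family), data = rates)
  s <- summary(fit)[[1]]
  list(f_statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
       fit = fit)
}

#' Mutation-spectrum summary for a set of validated DNMs
#'
#' @param dnms A `data.frame` with `ref`, `alt` and optionally `context`,
#'   `origin` (maternal/paternal/unknown) and `category` columns.
#' @return A list with transition/transversion counts, `titv`, CpG count
#'   and fraction, per-category annotation counts, phase counts and
#'   `alpha`.
#' @export
spectrum_summary <- function(dnms) {
  cls <- classify_mutation(dnms$ref, dnms$alt,
                           context = if ("context" %in% names(dnms)) {
                             dnms$context
                           } else {
                             NA_character_
                           })
  n_ti <- sum(cls$class == "transition")
  n_tv <- sum(cls$class == "transversion")
  phases <- if ("origin" %in% names(dnms)) {
    table(factor(dnms$origin,
                 levels = c("maternal", "paternal", "unknown")))
  } else {
    NULL
  }
  alpha <- if (!is.null(phases) && phases[["maternal"]] > 0) {
    phases[["paternal"]] / phases[["maternal"]]
  } else {
    NA_real_
  }
  list(
    n = nrow(dnms),
    transitions = n_ti,
    transversions = n_tv,
    titv = n_ti / n_tv,
    cpg_count = sum(cls$cpg, na.rm = TRUE),
    cpg_fraction = sum(cls$cpg, na.rm = TRUE) / nrow(dnms),
    categories = if ("category" %in% names(dnms)) {
      table(dnms$category)
    } else {
      NULL
    },
    phases = phases,
    alpha = alpha
  )
}
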