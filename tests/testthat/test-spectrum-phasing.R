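# Mutation spectrum, CpG context, read-back phasing, alpha and the tests.

test_that("transitions and transversions classify exhaustively", {
  expect_identical(classify_mutation("A", "G")$class, "transition")
  expect_identical(classify_mutation("C", "T")$class, "transition")
  expect_identical(classify_mutation("C", "A")$class, "transversion")
  # every possible single-base change is exactly one of the two classes
  bases <- c("A", "C", "G", "T")
  for (r in bases) for (a in setdiff(bases, r)) {
    cls <- classify_mutation(r, a)$class
    expect_true(cls %in% c("transition", "transversion"))
  }
  expect_error(classify_mutation("A", "A"), "differ")
  expect_error(classify_mutation("N", "A"), "single")
})

test_that("CpG context flags the C of a CpG dinucleotide on either strand", {
  expect_true(classify_mutation("C", "A", "ACG")$cpg)   # C followed by G
  expect_true(classify_mutation("G", "A", "CGT")$cpg)   # reverse strand
  expect_false(classify_mutation("C", "A", "ACT")$cpg)
  expect_true(is.na(classify_mutation("C", "A")$cpg))
  # literal mode: any change from a C
  expect_true(classify_mutation("C", "A", "ACT",
                                cpg_mode = "literal")$cpg)
  expect_false(classify_mutation("G", "A", "CGT",
                                 cpg_mode = "literal")$cpg)
})

test_that("47 transitions to 16 transversions give ti/tv 2.94", {
  class <- c(rep("transition", 47), rep("transversion", 16))
  expect_equal(round(titv_ratio(class), 2), 2.94)
})

test_that("read-back phasing follows fragments to a unique parent", {
  informative <- data.frame(
    chrom = "s1", pos = c(500L, 500L),
    allele = c("T", "A"), parent = c("maternal", "paternal"))
  dnm <- list(chrom = "s1", pos = 1000L, alt = "G")
  # fragment links DNM alt to the maternal-only allele
  frag_m <- data.frame(fragment_id = "fr1", chrom = "s1",
                       pos = c(1000L, 500L), allele = c("G", "T"))
  expect_identical(readback_phase(dnm, frag_m, informative), "maternal")
  # no informative site covered: unknown
  frag_lonely <- data.frame(fragment_id = "fr2", chrom = "s1",
                            pos = 1000L, allele = "G")
  expect_identical(readback_phase(dnm, frag_lonely, informative), "unknown")
  # conflicting fragments: unknown, never majority vote
  frag_conflict <- rbind(
    frag_m,
    data.frame(fragment_id = c("fr3", "fr3", "fr4", "fr4"),
               chrom = "s1", pos = c(1000L, 500L, 1000L, 500L),
               allele = c("G", "A", "G", "A")))
  expect_identical(readback_phase(dnm, frag_conflict, informative),
                   "unknown")
  # fragments not carrying the DNM alternate contribute nothing
  frag_ref <- data.frame(fragment_id = "fr5", chrom = "s1",
                         pos = c(1000L, 500L), allele = c("A", "A"))
  expect_identical(readback_phase(dnm, frag_ref, informative), "unknown")
})

test_that("adding span resolves unknowns without flipping assignments", {
  informative <- data.frame(
    chrom = "s1", pos = c(500L, 500L, 2000L, 2000L),
    allele = c("T", "A", "C", "G"),
    parent = c("maternal", "paternal", "maternal", "paternal"))
  dnm <- list(chrom = "s1", pos = 1000L, alt = "G")
  short_frag <- data.frame(fragment_id = "fr1", chrom = "s1",
                           pos = c(1000L, 500L), allele = c("G", "T"))
  long_frag <- rbind(short_frag,
                     data.frame(fragment_id = "fr1", chrom = "s1",
                                pos = 2000L, allele = "C"))
  expect_identical(readback_phase(dnm, short_frag, informative), "maternal")
  expect_identical(readback_phase(dnm, long_frag, informative), "maternal")
})

test_that("phasing on simulated fragments recovers every recorded origin", {
  co <- simulate_trio_cohort(
    sim_config(genome_length = 5e4, mu_true = 4e-5, pi_true = 0.01,
               seed = 3))
  frags <- simulate_read_fragments(co, fragment_length = 2000,
                                   n_fragments = 6)
  tru <- co$truth
  expect_gt(nrow(tru), 20)
  phased <- character(nrow(tru))
  for (i in seq_len(nrow(tru))) {
    recs <- trio_records(co, tru$offspring[i])
    info <- informative_sites(recs)
    fr <- frags[frags$offspring == tru$offspring[i], ]
    phased[i] <- readback_phase(
      list(chrom = tru$chrom[i], pos = tru$pos[i], alt = tru$alt[i]),
      fr, info)
  }
  resolved <- phased != "unknown"
  expect_true(all(phased[resolved] == tru$origin[resolved]))
  expect_gt(mean(resolved), 0.8)
})

test_that("alpha and the Welch test behave on totals and degenerate input", {
  counts <- data.frame(
    trio = paste0("t", 1:14),
    maternal = c(3, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1),
    paternal = c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1))
  expect_identical(sum(counts$maternal), 27)
  expect_identical(sum(counts$paternal), 26)
  res <- alpha_and_test(counts)
  expect_equal(round(res$alpha, 2), 0.96)
  expect_gt(res$p_value, 0.5) # nearly identical vectors
  # identical vectors: t = 0, p = 1
  same <- data.frame(maternal = c(2, 3, 4), paternal = c(2, 3, 4))
  res2 <- alpha_and_test(same)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  # zero maternal total: alpha undefined with a warning
  none <- data.frame(maternal = c(0, 0), paternal = c(2, 3))
  expect_warning(res3 <- alpha_and_test(none), "alpha undefined")
  expect_true(is.na(res3$alpha))
  # one-sample framing also runs
  res4 <- alpha_and_test(counts, method = "one_sample")
  expect_gt(res4$p_value, 0.05)
})

test_that("annotation resolves codon effects and feature precedence", {
  fa <- withr::local_tempfile(fileext = ".fa")
  # layout: 1-4 intergenic, gene 5-40, CDS 8-16 (ATG GCT GGG), the rest
  # of the gene intronic/UTR
  writeLines(c(">s1",
               paste0("AAAA", "TTT", "ATGGCTGGG", "CCCCCCCCCCCCCCCCCCCCCCCC",
                      "AAAA")), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\tx\tgene\t5\t40\t.\t+\t.\tID=g1",
               "s1\tx\tmRNA\t5\t40\t.\t+\t.\tID=m1;Parent=g1",
               "s1\tx\texon\t5\t16\t.\t+\t.\tID=e1;Parent=m1",
               "s1\tx\tfive_prime_UTR\t5\t7\t.\t+\t.\tID=u1;Parent=m1",
               "s1\tx\tCDS\t8\t16\t.\t+\t0\tID=c1;Parent=m1"), gff)
  models <- read_gff_models(gff)
  dnms <- data.frame(
    chrom = "s1",
    pos = c(13L, 11L, 2L, 20L, 6L),
    ref = c("T", "G", "A", "C", "T"),
    alt = c("C", "C", "G", "T", "A"))
  # pos 13 is codon GCT position 3: GCT -> GCC, Ala -> Ala (synonymous)
  # pos 11 is codon GCT position 1: GCT -> CCT, Ala -> Pro (missense)
  res <- annotate_dnms(dnms, models, fa)
  expect_identical(res,
                   c("synonymous", "missense", "intergenic", "intron",
                     "UTR"))
  expect_error(
    annotate_dnms(data.frame(chrom = "nope", pos = 1L, ref = "A",
                             alt = "G"), models, fa),
    "absent")
})

test_that("minus-strand codons are annotated through the reverse complement", {
  fa <- withr::local_tempfile(fileext = ".fa")
  # minus-strand CDS 5..13; genomic CAT CAG CCA -> transcript TGG CTG ATG
  # read 13->5: revcomp of CATCAGCCA = TGGCTGATG
  writeLines(c(">s1", paste0("AAAA", "CATCAGCCA", "AAAA")), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\tx\tgene\t5\t13\t.\t-\t.\tID=g1",
               "s1\tx\tmRNA\t5\t13\t.\t-\t.\tID=m1;Parent=g1",
               "s1\tx\tCDS\t5\t13\t.\t-\t0\tID=c1;Parent=m1"), gff)
  models <- read_gff_models(gff)
  # genomic pos 6 (A) is transcript position 8 in codon CTG (Leu);
  # A->G genomic means T->C on the transcript: CTG -> CCG (Pro): missense
  res <- annotate_dnms(data.frame(chrom = "s1", pos = 6L, ref = "A",
                                  alt = "G"), models, fa)
  expect_identical(res, "missense")
})

test_that("enrichment test matches binomial tails and adjusts across categories", {
  # observed exactly at expectation: p essentially 1 everywhere
  fr <- c(intron = 0.4, intergenic = 0.5, cds = 0.1)
  obs <- c(intron = 40L, intergenic = 50L, cds = 10L)
  res <- enrichment_test(obs, fr)
  expect_true(all(res$p >= 0.99))
  # strong concentration: tiny adjusted p
  obs2 <- c(intron = 63L, intergenic = 0L, cds = 0L)
  fr2 <- c(intron = 0.01, intergenic = 0.89, cds = 0.10)
  res2 <- enrichment_test(obs2, fr2)
  expect_lt(res2$p_adj[res2$category == "intron"], 1e-6)
  # single category of fraction 1: p = 1
  res3 <- enrichment_test(c(all = 63L), c(all = 1))
  expect_equal(res3$p, 1)
  expect_error(enrichment_test(obs, fr * 0.9), "sum to 1")
})

test_that("family ANOVA separates real grouping and handles degeneracy", {
  # all rates identical: F = 0, p = 1
  flat <- data.frame(trio = paste0("t", 1:8),
                     family = rep(paste0("f", 1:4), each = 2),
                     mu = rep(5e-9, 8))
  res <- family_grouping_test(flat)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  # two families with disjoint ranges and tiny within-variance
  sep <- data.frame(trio = paste0("t", 1:8),
                    family = rep(c("a", "b"), each = 4),
                    mu = c(1, 1.01, 1.02, 1.03, 9, 9.01, 9.02, 9.03) * 1e-9)
  expect_lt(family_grouping_test(sep)$p_value, 0.01)
  expect_error(family_grouping_test(flat[1:3, ]), "families")
  # permuted labels under the null give non-extreme p most of the time
  set.seed(9)
  ps <- replicate(50, {
    perm <- flat
    perm$mu <- rnorm(8, 5e-9, 1e-9)
    perm$family <- sample(perm$family)
    family_grouping_test(perm)$p_value
  })
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(min(ps), 0)
})

test_that("spectrum summary aggregates counts, phases and alpha", {
  dnms <- data.frame(
    ref = c(rep("A", 4), "C"), alt = c(rep("G", 4), "A"),
    context = c(rep("AAG", 4), "ACG"),
    origin = c("maternal", "paternal", "paternal", "unknown", "maternal"))
  s <- spectrum_summary(dnms)
  expect_identical(s$transitions, 4L)
  expect_identical(s$transversions, 1L)
  expect_equal(s$titv, 4)
  expect_identical(s$cpg_count, 1L)
  expect_identical(as.integer(s$phases[c("maternal", "paternal",
                                         "unknown")]),
                   c(2L, 2L, 1L))
  expect_equal(s$alpha, 1)
  expect_identical(s$transitions + s$transversions, s$n)
})
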