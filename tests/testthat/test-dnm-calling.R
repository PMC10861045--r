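# The DNM detection cascade, stage by stage and end to end.

test_that("site filters fail on each printed threshold and pass interior points", {
  th <- filter_thresholds()
  cases <- list(
    list(rec = make_record(qd = 1.9), reason = "QD"),
    list(rec = make_record(fs = 25), reason = "FS"),
    list(rec = make_record(mq = 35), reason = "MQ"),
    list(rec = make_record(mqranksum = -2.5), reason = "MQRankSum"),
    list(rec = make_record(mqranksum = 4.5), reason = "MQRankSum"),
    list(rec = make_record(readposranksum = 3.5), reason = "ReadPosRankSum"),
    list(rec = make_record(sor = 3.5), reason = "SOR")
  )
  for (cs in cases) {
    res <- apply_site_filters(cs$rec, th)
    expect_false(res$pass)
    expect_match(res$reasons, cs$reason)
  }
  interior <- apply_site_filters(
    make_record(qd = 10, fs = 1, mq = 60, mqranksum = 0,
                readposranksum = 0, sor = 1), th)
  expect_true(interior$pass)
  expect_identical(interior$reasons, "")
  # boundary values sit exactly on the printed thresholds and pass
  expect_true(apply_site_filters(make_record(qd = 2.0, sor = 3.0), th)$pass)
})

test_that("missing site annotations pass the site filters", {
  res <- apply_site_filters(make_record(mqranksum = NA_real_))
  expect_true(res$pass)
})

test_that("all triggered site-filter reasons are listed together", {
  res <- apply_site_filters(make_record(qd = 1, sor = 5))
  expect_identical(res$reasons, "QD;SOR")
})

test_that("Mendelian-violation detection follows the allele-novelty rule", {
  # canonical DNM pattern
  c1 <- detect_mendelian_violations(
    make_record(mother_gt = 0L, father_gt = 0L, offspring_gt = 1L))
  expect_identical(nrow(c1), 1L)
  expect_true(c1$canonical)
  # allele 1 present in the father: no violation
  c2 <- detect_mendelian_violations(
    make_record(mother_gt = 0L, father_gt = 1L, offspring_gt = 1L))
  expect_identical(nrow(c2), 0L)
  # both offspring alleles novel: flagged non-canonical
  c3 <- detect_mendelian_violations(
    make_record(mother_gt = 0L, father_gt = 0L, offspring_gt = 2L))
  expect_identical(nrow(c3), 1L)
  expect_false(c3$canonical)
  # reference allele novel: hom-alt parents, het offspring
  c4 <- detect_mendelian_violations(
    make_record(mother_gt = 2L, father_gt = 2L, offspring_gt = 1L))
  expect_identical(nrow(c4), 1L)
  # missing genotype: never a candidate
  c5 <- detect_mendelian_violations(
    make_record(mother_gt = NA_integer_, father_gt = 0L,
                offspring_gt = 1L))
  expect_identical(nrow(c5), 0L)
})

test_that("trio-level filter enforces AD=0, GQ, DP and AB rules", {
  th <- filter_thresholds()
  # a single parental alternate read rejects
  r <- trio_candidate_filter(
    make_record(father_ad_ref = 30L, father_ad_alt = 1L), th,
    nominal_depths)
  expect_false(r$retain)
  expect_match(r$reasons, "parental_alt_reads")
  # AB exactly 0.30 is retained under the inclusive window
  r2 <- trio_candidate_filter(
    make_record(offspring_ad_ref = 42L, offspring_ad_alt = 18L), th,
    nominal_depths)
  expect_true(r2$retain)
  # ... and rejected under the exclusive reading
  th_excl <- filter_thresholds(ab_inclusive = FALSE)
  r3 <- trio_candidate_filter(
    make_record(offspring_ad_ref = 42L, offspring_ad_alt = 18L), th_excl,
    nominal_depths)
  expect_false(r3$retain)
  expect_match(r3$reasons, "AB")
  # GQ = 70 fails the strict inequality
  r4 <- trio_candidate_filter(make_record(offspring_gq = 70L), th,
                              nominal_depths)
  expect_false(r4$retain)
  expect_match(r4$reasons, "GQ")
  # DP exactly at the window edge fails (strict), inside passes
  r5 <- trio_candidate_filter(make_record(mother_dp = 30L), th,
                              nominal_depths)
  expect_false(r5$retain)
  expect_match(r5$reasons, "DP")
  r6 <- trio_candidate_filter(make_record(mother_dp = 31L), th,
                              nominal_depths)
  expect_true(r6$retain)
})

test_that("independent recall reproduces or contradicts the DNM configuration", {
  ok <- independent_recall(make_record())
  expect_true(ok$concordant)
  # offspring 59 ref / 1 alt reads: recall says hom-ref
  bad <- independent_recall(
    make_record(offspring_ad_ref = 59L, offspring_ad_alt = 1L))
  expect_false(bad$concordant)
  expect_identical(bad$reasons, "recall_genotype_mismatch")
  # zero-depth parent: no data
  nd <- independent_recall(
    make_record(mother_dp = 0L, mother_ad_ref = 0L, mother_ad_alt = 0L))
  expect_false(nd$concordant)
  expect_identical(nd$reasons, "no_data")
})

test_that("population screen matches position and alternate allele", {
  cand <- make_record()
  pop <- data.frame(chrom = "scaffold_1", pos = 1000L, alt = "G")
  expect_true(population_screen(cand, pop))
  expect_false(population_screen(cand, pop[0, ]))
  pop_other_alt <- data.frame(chrom = "scaffold_1", pos = 1000L, alt = "T")
  expect_false(population_screen(cand, pop_other_alt))
  expect_true(population_screen(cand, pop_other_alt, match_alt = FALSE))
})

test_that("curation heuristics: spacing, clustering and clean passes", {
  two_close <- make_records(make_record(), make_record())
  two_close$pos <- c(1000L, 1005L)
  res <- curation_heuristics(two_close, nominal_depths)
  expect_false(any(res$pass))
  expect_true(all(res$criteria[, "spacing"]))
  clean <- make_record()
  res2 <- curation_heuristics(clean, nominal_depths)
  expect_true(res2$pass)
  # raw parental evidence criterion
  res3 <- curation_heuristics(clean, nominal_depths,
                              raw_parent_ad = 2)
  expect_false(res3$pass)
  expect_match(res3$reasons, "parental_raw_ad")
  # density: three candidates within 100 bp
  three <- make_records(make_record(), make_record(), make_record())
  three$pos <- c(1000L, 1020L, 1040L)
  res4 <- curation_heuristics(three, nominal_depths)
  expect_true(all(res4$criteria[, "density"]))
  # each criterion is switchable
  res5 <- curation_heuristics(three, nominal_depths,
                              config = curation_config(spacing = FALSE,
                                                       density = FALSE))
  expect_true(all(res5$pass))
  # sibling hom-alt contradiction
  res6 <- curation_heuristics(clean, nominal_depths, sibling_gt = 2L)
  expect_false(res6$pass)
  expect_match(res6$reasons, "sibling")
})

test_that("shared sibling DNMs count identical validated sites", {
  ped <- data.frame(trio_id = c("o1", "o2"), sibling = c("o2", "o1"))
  validated <- data.frame(
    trio_id = c(rep("o1", 32), rep("o2", 31)),
    chrom = "s1",
    pos = c(1:32, 1:6, 101:125),
    alt = "G", stringsAsFactors = FALSE)
  res <- count_shared_sibling_dnms(validated, ped)
  expect_identical(res$n_total, 63L)
  expect_identical(res$n_shared, 12L) # 6 sites seen in both siblings
  expect_equal(round(100 * res$fraction, 1), 19.0)
  # same position but different alternate allele never counts as shared
  validated2 <- data.frame(trio_id = c("o1", "o2"), chrom = "s1",
                           pos = c(1L, 1L), alt = c("G", "T"))
  expect_identical(count_shared_sibling_dnms(validated2, ped)$n_shared, 0L)
  # boundary: everything shared
  validated3 <- data.frame(trio_id = c("o1", "o2"), chrom = "s1",
                           pos = c(1L, 1L), alt = "G")
  expect_equal(count_shared_sibling_dnms(validated3, ped)$fraction, 1)
})

test_that("false-positive rates combine per-stage and cumulative conventions", {
  tallies <- data.frame(
    trio = "t1",
    stage = c("mendelian", "recall", "curation"),
    entering = c(246L, 246L, 141L),
    rejected = c(0L, 105L, 78L))
  res <- false_positive_rates(tallies)
  expect_equal(res$cumulative_pooled, 183 / 246)
  expect_equal(
    res$per_stage$pooled_rate[res$per_stage$stage == "recall"], 105 / 246)
  expect_equal(
    res$per_stage$pooled_rate[res$per_stage$stage == "curation"], 78 / 141)
  # zero rejections give all-zero rates
  none <- data.frame(trio = "t1", stage = c("a", "b"),
                     entering = c(10L, 10L), rejected = c(0L, 0L))
  res2 <- false_positive_rates(none)
  expect_true(all(res2$per_stage$pooled_rate == 0))
  expect_equal(res2$cumulative_pooled, 0)
  # everything rejected at stage 1: later stages undefined
  all1 <- data.frame(trio = "t1", stage = c("a", "b"),
                     entering = c(5L, 0L), rejected = c(5L, 0L))
  res3 <- false_positive_rates(all1)
  expect_equal(res3$per_stage$pooled_rate[1], 1)
  expect_true(is.na(res3$per_stage$pooled_rate[2]))
})

test_that("the cascade is deterministic and monotone non-increasing", {
  co <- small_cohort()
  recs <- trio_records(co, "f1_off1")
  a <- call_trio_dnms(recs)
  b <- call_trio_dnms(recs)
  expect_identical(a$candidates, b$candidates)
  expect_identical(a$tally, b$tally)
  n_remaining <- a$tally$entering - a$tally$rejected
  expect_true(all(diff(a$tally$entering) <= 0))
  expect_true(all(n_remaining >= nrow(a$validated)))
})

test_that("noiseless cohorts are called with perfect sensitivity and specificity", {
  co <- simulate_trio_cohort(
    sim_config(genome_length = 2e5, mu_true = 2e-5, pi_true = 0.01,
               mean_depth = 100, depth_dispersion = 0,
               base_error_rate = 0, seed = 6))
  th <- filter_thresholds()
  for (i in seq_len(nrow(co$pedigree))) {
    trio <- co$pedigree$trio_id[i]
    recs <- trio_records(co, trio)
    md <- c(mother = mean(recs$mother_dp), father = mean(recs$father_dp),
            offspring = mean(recs$offspring_dp))
    cs <- call_trio_dnms(recs, th, mean_depths = md)
    tr <- co$truth[co$truth$offspring == trio, ]
    # every planted DNM whose site passes the callability rules validates;
    # the curation proximity proxies are deterministic functions of
    # position and also apply to pairs of true DNMs, so mirror them here
    callable <- vapply(tr$pos, function(p) {
      row <- recs[recs$pos == p, ]
      count_callable_sites(row, th, md) == 1
    }, logical(1))
    spaced <- vapply(tr$pos, function(p) {
      d <- abs(tr$pos - p)
      min_other <- suppressWarnings(min(d[d > 0]))
      min_other >= 10 && sum(d <= 50) <= 2
    }, logical(1))
    expected <- tr$pos[callable & spaced]
    expect_setequal(cs$validated$pos, expected)
    # no inherited (parental) variant is ever validated
    fam <- co$families[[co$pedigree$family[i]]]
    parental <- fam$pos[fam$hap[, 1] + fam$hap[, 2] +
                          fam$hap[, 3] + fam$hap[, 4] > 0]
    expect_length(intersect(cs$validated$pos, parental), 0)
    # any non-validated candidate carries a logged reason
    rejected <- cs$candidates[cs$candidates$class != "validated", ]
    if (nrow(rejected)) {
      has_reason <- grepl("fail:", paste(rejected$stage_trio,
                                         rejected$stage_recall,
                                         rejected$stage_population,
                                         rejected$stage_curation))
      expect_true(all(has_reason))
    }
  }
})

test_that("population screening flags planted population variants end to end", {
  co <- small_cohort()
  recs <- trio_records(co, "f2_off1")
  cs0 <- call_trio_dnms(recs)
  if (nrow(cs0$validated) > 0) {
    pop <- cs0$validated[1, c("chrom", "pos", "alt")]
    cs1 <- call_trio_dnms(recs, population = pop)
    expect_identical(nrow(cs1$validated), nrow(cs0$validated) - 1L)
    expect_identical(cs1$tally$rejected[cs1$tally$stage == "population"], 1L)
  }
})
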