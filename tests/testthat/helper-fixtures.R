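# Shared fixtures: hand-built trio records and a small cached cohort.

# One wide trio record with every field at an interior (passing) value;
# override any field by name.
make_record <- function(...) {
  rec <- data.frame(
    chrom = "scaffold_1", pos = 1000L, ref = "A", alt = "G",
    qd = 10, fs = 1, mq = 60, mqranksum = 0, readposranksum = 0, sor = 1,
    mother_gt = 0L, mother_ad_ref = 60L, mother_ad_alt = 0L,
    mother_dp = 60L, mother_gq = 99L,
    father_gt = 0L, father_ad_ref = 60L, father_ad_alt = 0L,
    father_dp = 60L, father_gq = 99L,
    offspring_gt = 1L, offspring_ad_ref = 30L, offspring_ad_alt = 30L,
    offspring_dp = 60L, offspring_gq = 99L,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_records <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$pos <- seq(1000L, by = 1000L, length.out = nrow(out))
  out
}

nominal_depths <- c(mother = 60, father = 60, offspring = 60)

# Small cohort with a dense mutation rate so every module has DNMs to work
# with; cached across tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_trio_cohort(
        sim_config(genome_length = 1e5, mu_true = 2e-5, pi_true = 0.01,
                   seed = 42)
      )
    }
    cache
  }
})
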