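# VCF 4.2 emission and reading for trio site records. Coordinates are
# 1-based inclusive in VCF, matching the internal `pos` column; interval
# containers (callable masks, BED) are 0-based half-open.

INFO_KEYS <- c(qd = "QD", fs = "FS", mq = "MQ", mqranksum = "MQRankSum",
               readposranksum = "ReadPosRankSum", sor = "SOR")

#' Write a trio site-record table as a VCF file
#'
#' Emits VCF 4.2 with per-sample `GT:AD:DP:GQ` and the site annotations
#' QD, FS, MQ, MQRankSum, ReadPosRankSum and SOR in INFO. Missing
#' annotations are omitted from INFO (VCF missing semantics); invariant
#' records (no `alt`) are written with ALT ".".
#'
#' @param records A wide trio record table (see [trio_records()]).
#' @param path Output `.vcf` path (a `.gz` suffix writes gzip).
#' @param sample_names Named character vector mapping roles
#'   `mother`, `father`, `offspring` to VCF sample ids.
#' @param contigs Named numeric vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_site_records <- function(records, path,
                               sample_names = c(mother = "mother",
                                                father = "father",
                                                offspring = "offspring"),
                               contigs = NULL) {
  stopifnot(all(c("mother", "father", "offspring") %in% names(sample_names)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triomu",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs))
    },
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            INFO_KEYS, INFO_KEYS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names[["mother"]], sample_names[["father"]],
            sample_names[["offspring"]]), collapse = "\t")
  )
  n <- nrow(records)
  if (n == 0) {
    con <- vcf_connection(path)
    on.exit(close(con))
    writeLines(header, con)
    return(invisible(path))
  }
  info <- rep("", n)
  for (col in names(INFO_KEYS)) {
    val <- records[[col]]
    piece <- ifelse(is.na(val), NA_character_,
                    paste0(INFO_KEYS[[col]], "=", formatC(val, digits = 10,
                                                          format = "g")))
    info <- ifelse(is.na(piece), info,
                   ifelse(info == "", piece, paste(info, piece, sep = ";")))
  }
  info[info == ""] <- "."
  fmt_sample <- function(role) {
    gt <- gt_to_string(records[[paste0(role, "_gt")]])
    sprintf("%s:%d,%d:%d:%d", gt,
            records[[paste0(role, "_ad_ref")]],
            records[[paste0(role, "_ad_alt")]],
            records[[paste0(role, "_dp")]],
            records[[paste0(role, "_gq")]])
  }
  alt <- records$alt
  alt[is.na(alt)] <- "."
  body <- paste(records$chrom, records$pos, ".", records$ref, alt, ".", ".",
                info, "GT:AD:DP:GQ", fmt_sample("mother"),
                fmt_sample("father"), fmt_sample("offspring"), sep = "\t")
  con <- vcf_connection(path)
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

vcf_connection <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Write one VCF per trio of a simulated cohort
#'
#' @param cohort A `trio_cohort` with read evidence.
#' @param dir Output directory (created if needed).
#' @param gzip Write gzip-compressed files.
#' @return Named character vector of written paths (one per trio).
#' @export
emit_trio_vcf <- function(cohort, dir, gzip = FALSE) {
  stopifnot(isTRUE(cohort$has_reads))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ped <- cohort$pedigree
  paths <- character(nrow(ped))
  names(paths) <- ped$trio_id
  for (i in seq_len(nrow(ped))) {
    recs <- trio_records(cohort, ped$trio_id[i])
    path <- file.path(dir, paste0(ped$trio_id[i], ".vcf",
                                  if (gzip) ".gz" else ""))
    write_site_records(
      recs, path,
      sample_names = c(mother = ped$mother[i], father = ped$father[i],
                       offspring = ped$offspring[i]),
      contigs = stats::setNames(cohort$config$genome_length, SIM_CHROM)
    )
    paths[i] <- path
  }
  invisible(paths)
}

#' Read a trio VCF into a wide site-record table
#'
#' Parses a VCF (via \pkg{vcfR}) and maps the three pedigree samples onto
#' the `mother`/`father`/`offspring` roles of the wide record layout used
#' throughout the package. Missing INFO annotations are preserved as `NA`,
#' never coerced to zero.
#'
#' @param path VCF path (plain or gzip).
#' @param samples Named character vector with elements `mother`, `father`
#'   and `offspring` giving the VCF sample ids, or a single pedigree row
#'   from [read_pedigree()].
#' @return A wide record `data.frame` in coordinate order.
#' @export
read_trio_vcf <- function(path, samples) {
  if (is.data.frame(samples)) {
    stopifnot(nrow(samples) == 1)
    samples <- c(mother = samples$mother, father = samples$father,
                 offspring = samples$offspring)
  }
  stopifnot(all(c("mother", "father", "offspring") %in% names(samples)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(vcf@gt)[-1]
  missing <- setdiff(unname(samples[c("mother", "father", "offspring")]),
                     have)
  if (length(missing)) {
    stop("sample(s) missing from VCF header: ",
         paste(missing, collapse = ", "))
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  alt[alt == "."] <- NA_character_
  out <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = alt,
    stringsAsFactors = FALSE
  )
  for (col in names(INFO_KEYS)) {
    out[[col]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = INFO_KEYS[[col]])))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  for (role in c("mother", "father", "offspring")) {
    s <- samples[[role]]
    ad_parts <- strsplit(ad[, s], ",", fixed = TRUE)
    out[[paste0(role, "_gt")]] <- string_to_gt(gt[, s])
    out[[paste0(role, "_ad_ref")]] <-
      as.integer(vapply(ad_parts, `[`, character(1), 1L))
    out[[paste0(role, "_ad_alt")]] <-
      as.integer(vapply(ad_parts, function(p) {
        if (length(p) >= 2) p[2] else "0"
      }, character(1)))
    out[[paste0(role, "_dp")]] <- as.integer(dp[, s])
    out[[paste0(role, "_gq")]] <- as.integer(gq[, s])
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write the planted-truth table of a simulated cohort as TSV
#'
#' @param cohort A `trio_cohort`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(cohort, path) {
  utils::write.table(cohort$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Materialise the simulated reference sequence as FASTA
#'
#' Reconstructs a reference sequence consistent with the cohort's variant
#' reference bases (all other positions drawn uniformly from ACGT under the
#' cohort seed). Intended for small demonstration genomes where annotation
#' or CpG context is needed.
#'
#' @param cohort A `trio_cohort`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(cohort, path) {
  L <- cohort$config$genome_length
  if (L > 5e6) stop("reference materialisation is for small genomes (<= 5 Mb)")
  set.seed(cohort$config$seed + 3L)
  seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  for (fam in cohort$families) {
    seq[fam$pos] <- fam$ref
  }
  dna <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(dna) <- SIM_CHROM
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
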