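# Readers and writers for pedigrees, gene models, survey tables, Ne
# trajectories and callable masks.

#' Read a 6-column PED pedigree into trio rows
#'
#' Standard PED layout (family, individual, father, mother, sex, phenotype;
#' whitespace-separated, `0` for founder parents). Each genotyped offspring
#' (both parents non-zero) yields one trio row; full siblings are linked.
#'
#' @param path PED file path.
#' @return A `data.frame` with columns `family`, `trio_id`, `mother`,
#'   `father`, `offspring`, `sibling`.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 6)
  if (length(bad)) {
    stop("malformed PED line(s): ", paste(bad, collapse = ", "))
  }
  ped <- as.data.frame(do.call(rbind, lapply(fields, `[`, 1:6)),
                       stringsAsFactors = FALSE)
  names(ped) <- c("family", "id", "father", "mother", "sex", "phenotype")
  kids <- ped[ped$father != "0" & ped$mother != "0", , drop = FALSE]
  if (nrow(kids) == 0) stop("no offspring rows (non-founder) in pedigree")
  sibling <- vapply(seq_len(nrow(kids)), function(i) {
    sibs <- kids$id[kids$family == kids$family[i] &
                      kids$father == kids$father[i] &
                      kids$mother == kids$mother[i] &
                      kids$id != kids$id[i]]
    if (length(sibs)) sibs[1] else NA_character_
  }, character(1))
  data.frame(
    family = kids$family,
    trio_id = kids$id,
    mother = kids$mother,
    father = kids$father,
    offspring = kids$id,
    sibling = sibling,
    stringsAsFactors = FALSE
  )
}

#' Write a cohort pedigree in 6-column PED format
#'
#' @param pedigree A trio table as in `cohort$pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  founders <- unique(c(pedigree$mother, pedigree$father))
  fam_of <- c(stats::setNames(pedigree$family, pedigree$mother),
              stats::setNames(pedigree$family, pedigree$father))
  rows <- c(
    sprintf("%s\t%s\t0\t0\t0\t0", fam_of[founders], founders),
    sprintf("%s\t%s\t%s\t%s\t0\t0", pedigree$family, pedigree$offspring,
            pedigree$father, pedigree$mother)
  )
  writeLines(rows, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses GFF3 (via `ape::read.gff`) and keeps gene/mRNA/exon/CDS/UTR
#' features with their `ID` and `Parent` attributes, as needed for DNM
#' annotation.
#'
#' @param path GFF3 path.
#' @return A `data.frame` with columns `chrom`, `type`, `start`, `end`
#'   (1-based inclusive), `strand`, `phase`, `id`, `parent`.
#' @export
read_gff_models <- function(path) {
  gff <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  keep <- c("gene", "mRNA", "exon", "CDS",
            "five_prime_UTR", "three_prime_UTR", "UTR")
  gff <- gff[gff$type %in% keep, , drop = FALSE]
  attr_field <- function(attr, key) {
    m <- regexec(paste0("(?:^|;)", key, "=([^;]*)"), attr)
    vapply(regmatches(attr, m), function(g) {
      if (length(g) >= 2) g[2] else NA_character_
    }, character(1))
  }
  data.frame(
    chrom = as.character(gff$seqid),
    type = as.character(gff$type),
    start = gff$start,
    end = gff$end,
    strand = as.character(gff$strand),
    phase = suppressWarnings(as.integer(as.character(gff$phase))),
    id = attr_field(as.character(gff$attributes), "ID"),
    parent = attr_field(as.character(gff$attributes), "Parent"),
    stringsAsFactors = FALSE
  )
}

#' Read a reef survey table
#'
#' Expects a CSV with at least `reef`, `year` and `density` columns
#' (density in individuals per km^2); extra columns (e.g. manta-tow counts)
#' are preserved.
#'
#' @param path CSV path.
#' @return A `data.frame`; reef-year pairs must be unique.
#' @export
read_survey <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("reef", "year")
  if (!all(needed %in% names(out))) {
    stop("survey table must have 'reef' and 'year' columns")
  }
  if (anyDuplicated(out[c("reef", "year")])) {
    stop("duplicate reef-year records in survey table")
  }
  if ("density" %in% names(out) && any(out$density < 0, na.rm = TRUE)) {
    stop("negative densities in survey table")
  }
  out
}

#' Read an effective-size trajectory table
#'
#' Tab-separated table of (time, Ne) pairs, e.g. exported from coalescent
#' or linkage-disequilibrium based inference. Times may be generations or
#' years; they are kept as given and must be strictly increasing after
#' sorting (ties are an error). Ne must be positive.
#'
#' @param path TSV path with columns `time` and `ne` (header required).
#' @param source Optional label (e.g. "coalescent" or "ld") stored as an
#'   attribute.
#' @return A `data.frame(time, ne)` ordered by time.
#' @export
read_trajectory <- function(path, source = NA_character_) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time", "ne") %in% names(out))) {
    stop("trajectory table must have 'time' and 'ne' columns")
  }
  out <- out[order(out$time), c("time", "ne")]
  if (anyDuplicated(out$time)) stop("trajectory times must be unique")
  if (any(out$ne <= 0)) stop("Ne values must be positive")
  rownames(out) <- NULL
  attr(out, "source") <- source
  out
}

#' Mean individual depth over sufficiently long scaffolds
#'
#' Arithmetic mean of per-site depth for one trio role, restricted to
#' positions on scaffolds of at least `min_scaffold_len` bp — the anchor of
#' the per-sample depth-window filters.
#'
#' @param records Wide trio record table.
#' @param role One of `"mother"`, `"father"`, `"offspring"`.
#' @param scaffold_lengths Named vector of scaffold lengths; scaffolds
#'   absent from it are excluded. `NULL` treats every scaffold as passing.
#' @param min_scaffold_len Minimum qualifying scaffold length (bp).
#' @return The mean depth (numeric scalar).
#' @export
mean_individual_depth <- function(records, role,
                                  scaffold_lengths = NULL,
                                  min_scaffold_len = 10000) {
  col <- paste0(role, "_dp")
  if (!col %in% names(records)) stop("unknown role: ", role)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(scaffold_lengths)) {
    len <- scaffold_lengths[records$chrom]
    keep <- !is.na(len) & len >= min_scaffold_len
  }
  dp <- records[[col]][keep]
  dp <- dp[!is.na(dp)]
  if (length(dp) == 0) {
    stop("no positions on scaffolds >= ", min_scaffold_len, " bp")
  }
  mean(dp)
}

#' Callable mask: sorted, non-overlapping genomic intervals
#'
#' Intervals are 0-based half-open; overlapping or book-ended input
#' intervals are merged. The total callable length `C` is the summed
#' interval length.
#'
#' @param intervals A `data.frame(chrom, start, end)`.
#' @return An object of class `callable_mask` with a `total` attribute.
#' @export
callable_mask <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end < intervals$start)) stop("end < start interval")
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  merged <- list()
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    starts <- iv$start
    ends <- iv$end
    keep_s <- starts[1]
    keep_e <- ends[1]
    out_s <- out_e <- numeric(0)
    for (i in seq_len(nrow(iv))[-1]) {
      if (starts[i] <= keep_e) {
        keep_e <- max(keep_e, ends[i])
      } else {
        out_s <- c(out_s, keep_s)
        out_e <- c(out_e, keep_e)
        keep_s <- starts[i]
        keep_e <- ends[i]
      }
    }
    merged[[chr]] <- data.frame(chrom = chr, start = c(out_s, keep_s),
                                end = c(out_e, keep_e),
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  structure(out, class = c("callable_mask", "data.frame"),
            total = sum(out$end - out$start))
}

#' Total callable length of a mask
#' @param mask A `callable_mask`.
#' @return Total interval length (numeric scalar).
#' @export
mask_total <- function(mask) attr(mask, "total")

#' Write / read a callable mask as BED
#'
#' BED is 0-based half-open, matching the internal interval convention.
#'
#' @param mask A `callable_mask`.
#' @param path BED path.
#' @return `path` (write) or a `callable_mask` (read).
#' @export
write_bed <- function(mask, path) {
  utils::write.table(data.frame(mask$chrom, mask$start, mask$end), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  callable_mask(data.frame(chrom = bed[[1]], start = bed[[2]],
                           end = bed[[3]], stringsAsFactors = FALSE))
}
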