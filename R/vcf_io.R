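#' Read diploid genotypes from a VCF file
#'
#' Parses a VCF v4.x file into a [geno()] container. Phased (`|`) and unphased
#' (`/`) separators are treated identically; half-calls (`./1`) and `./.` are
#' recorded as missing. Multiallelic records are kept and flagged — the dosage
#' counts copies of the *first* alternate allele — so that the QC filter can
#' account for them explicitly rather than losing them at parse time.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param mapped_chroms Optional character vector naming the assembled
#'   chromosomes; any other contig is flagged unmapped in `sites$is_mapped`.
#'   `NULL` (default) marks every contig as mapped.
#' @return A [geno()] object. The `sites` tibble carries `chrom`, `pos`, `id`,
#'   `ref`, `alt`, `is_indel`, `is_multiallelic` and `is_mapped`.
#' @export
read_vcf <- function(path, mapped_chroms = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) stop("malformed VCF header in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2) {
    stop("VCF has no genotype (GT) columns", call. = FALSE)
  }
  samples <- colnames(gt_raw)[-1]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, samples))
  gt[gt == "."] <- NA
  gtc <- gsub("|", "/", gt, fixed = TRUE)
  known <- is.na(gtc) | gtc %in% c(
    "0/0", "0/1", "1/0", "1/1", "./.", "./0", "0/.", "./1", "1/.",
    "0/2", "2/0", "1/2", "2/1", "2/2", "./2", "2/.", "0/3", "3/0",
    "1/3", "3/1", "2/3", "3/2", "3/3"
  )
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop(sprintf("non-diploid or malformed GT '%s' at record %d (%s:%s), sample %s",
                 gt[bad[1], bad[2]], bad[1], fix[bad[1], "CHROM"],
                 fix[bad[1], "POS"], samples[bad[2]]), call. = FALSE)
  }
  half <- grepl(".", gtc, fixed = TRUE)
  gtc[half] <- NA
  a1 <- substr(gtc, 1, 1)
  a2 <- substr(gtc, 3, 3)
  dos <- matrix((a1 == "1") + (a2 == "1"), nrow = nrow(fix))
  dos[is.na(gtc)] <- NA
  chrom <- unname(fix[, "CHROM"])
  sites <- tibble::tibble(
    chrom = chrom,
    pos = as.integer(fix[, "POS"]),
    id = ifelse(fix[, "ID"] %in% c(".", NA), NA_character_, fix[, "ID"]),
    ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"])
  )
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  sites$is_indel <- nchar(sites$ref) > 1L |
    vapply(alts, function(a) any(nchar(a) != 1L), logical(1))
  sites$is_multiallelic <- lengths(alts) > 1L
  sites$is_mapped <- if (is.null(mapped_chroms)) TRUE else chrom %in% mapped_chroms
  geno(sites, dos, samples)
}

#' Write a geno object to a VCF v4.2 file
#'
#' Emits a deterministic plain-text VCF: dosage 0 becomes `0/0`, 1 becomes
#' `0/1`, 2 becomes `1/1`, missing becomes `./.`. When `chrom_sizes` is given,
#' a `##contig` header line is written for every chromosome in it.
#'
#' @param g A [geno()] object.
#' @param path Output file path.
#' @param chrom_sizes Optional tibble from [read_chrom_sizes()] (columns
#'   `chrom`, `length`) used for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, chrom_sizes = NULL) {
  stopifnot(inherits(g, "geno"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=divscan",
    if (!is.null(chrom_sizes)) {
      sprintf("##contig=<ID=%s,length=%d>", chrom_sizes$chrom,
              as.integer(chrom_sizes$length))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  gt <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L], nrow = n_sites(g))
  gt[is.na(gt)] <- "./."
  body <- if (n_sites(g)) {
    paste(g$sites$chrom, g$sites$pos,
          ifelse(is.na(g$sites$id), ".", g$sites$id),
          g$sites$ref, g$sites$alt, ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column TSV (sample id, population label); a header line is detected and
#' skipped when its second field is one of `population`, `pop`, `label` or
#' `subspecies`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample` and `population`.
#' @export
read_population_map <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(sample = character(), population = character()))
  }
  if (ncol(raw) < 2) stop("population map needs two columns", call. = FALSE)
  if (tolower(raw[[2]][1]) %in% c("population", "pop", "label", "subspecies")) {
    raw <- raw[-1, , drop = FALSE]
  }
  out <- tibble::tibble(sample = raw[[1]], population = raw[[2]])
  if (anyDuplicated(out$sample)) {
    stop("duplicated sample id(s) in population map: ",
         paste(unique(out$sample[duplicated(out$sample)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(out$population) | out$population == "")) {
    stop("empty population label in map", call. = FALSE)
  }
  out
}

#' Look up the population of samples, failing on absent ids
#'
#' @param pop_map Tibble from [read_population_map()].
#' @param samples Character vector of sample ids.
#' @return Character vector of population labels.
#' @export
population_of <- function(pop_map, samples) {
  idx <- match(samples, pop_map$sample)
  if (anyNA(idx)) {
    stop("sample(s) absent from population map: ",
         paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  pop_map$population[idx]
}

#' Read chromosome sizes from a two-column TSV or a FASTA index
#'
#' Accepts either a `name<TAB>length` table or a samtools `.fai` index (in
#' which case the first two columns are used).
#'
#' @param path Path to the sizes file.
#' @return A tibble with columns `chrom` and `length` (bp).
#' @export
read_chrom_sizes <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(raw) < 2) stop("chromosome sizes need two columns", call. = FALSE)
  if (suppressWarnings(is.na(as.numeric(raw[[2]][1])))) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) stop("no chromosome rows in ", path, call. = FALSE)
  len <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(len) || any(len != floor(len))) {
    stop("non-integer chromosome length in ", path, call. = FALSE)
  }
  if (any(len <= 0)) stop("chromosome length must be > 0", call. = FALSE)
  if (anyDuplicated(raw[[1]])) stop("duplicated chromosome name", call. = FALSE)
  tibble::tibble(chrom = raw[[1]], length = as.numeric(len))
}

#' Read gene or QTL intervals from BED or GFF3
#'
#' Coordinates are normalised to the package-wide 1-based inclusive
#' convention: BED (0-based half-open) start positions are shifted by +1;
#' GFF3 is already 1-based inclusive. For GFF3 input only features of type
#' `gff3_feature` (default `"gene"`) are kept. For BED input an optional 5th
#' column is read as the QTL trait label.
#'
#' @param path Path to the interval file.
#' @param format `"bed"`, `"gff3"`, or `"auto"` (by file extension).
#' @param kind Interval kind recorded in the output, `"gene"` or `"qtl"`.
#' @param gff3_feature GFF3 feature type to retain.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `kind`,
#'   `trait` (NA unless supplied).
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3"),
                           kind = c("gene", "qtl"), gff3_feature = "gene") {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols(.default = "c"), progress = FALSE)
    if (ncol(raw) < 3) stop("BED needs at least 3 columns", call. = FALSE)
    out <- tibble::tibble(
      chrom = raw[[1]],
      start = as.numeric(raw[[2]]) + 1,
      end = as.numeric(raw[[3]]),
      name = if (ncol(raw) >= 4) raw[[4]] else NA_character_,
      kind = kind,
      trait = if (ncol(raw) >= 5) raw[[5]] else NA_character_
    )
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) == gff3_feature
    gr <- gr[keep]
    nm <- if (!is.null(gr$Name)) as.character(gr$Name) else
      if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    out <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = as.numeric(GenomicRanges::start(gr)),
      end = as.numeric(GenomicRanges::end(gr)),
      name = nm,
      kind = kind,
      trait = if (!is.null(gr$trait)) as.character(gr$trait) else NA_character_
    )
  }
  if (any(out$start > out$end)) {
    stop("interval with start > end after normalisation in ", path, call. = FALSE)
  }
  out
}
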