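#' Read a reference genome from FASTA
#'
#' Loads a (multi-)chromosome FASTA file into a [Biostrings::DNAStringSet],
#' uppercasing all residues and validating that only `A`, `C`, `G`, `T`, `N`
#' occur and that chromosome names are unique.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome, uppercase.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' genome <- read_genome_fasta(fa)
#' chrom_lengths(genome)
#' @export
read_genome_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1, file.exists(path))
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  # drop description after first whitespace, as aligners do
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    dup <- unique(names(genome)[duplicated(names(genome))])
    stop("duplicated chromosome name(s) in FASTA: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  bad <- which(vapply(
    as.character(genome),
    function(s) grepl("[^ACGTN]", s),
    logical(1)
  ))
  if (length(bad)) {
    stop("non-ACGTN characters in FASTA record(s): ",
         paste(names(genome)[bad], collapse = ", "), call. = FALSE)
  }
  genome
}

#' Write a genome to FASTA
#'
#' @param genome Named `DNAStringSet` (or named character vector of sequences).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = width)
  invisible(path)
}

# Accept a named character vector or DNAStringSet
as_genome <- function(genome) {
  if (is.character(genome)) {
    stopifnot(!is.null(names(genome)))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Chromosome lengths of a genome
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @return A tibble with columns `chrom` and `length` (bp), in FASTA order.
#' @export
chrom_lengths <- function(genome) {
  genome <- as_genome(genome)
  tibble::tibble(chrom = names(genome), length = Biostrings::width(genome))
}

#' Read InDel calls for one sample from a single-sample VCF
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeps only records where the
#' reference and alternate alleles differ in length (InDels), and splits
#' multi-allelic records into one row per called ALT allele. Records whose
#' genotype does not carry a given ALT allele contribute no row for that
#' allele. SNP records (equal-length alleles) are dropped and counted.
#'
#' A site absent from the file is interpreted downstream as reference
#' genotype for this sample; gVCF-style reference blocks are not supported.
#'
#' @param path Path to a single-sample VCF (plain text or bgzip).
#' @param sample_id Sample identifier; defaults to the VCF sample column name.
#' @param group Group label to attach (e.g. `"indica"` / `"javanica"`).
#' @param min_qual Optional QUAL threshold; records below it are dropped.
#'   Default `NULL` (no filtering).
#' @return A tibble with columns `sample_id`, `group`, `chrom`, `pos`
#'   (1-based anchor), `ref`, `alt`, `gt`, `multiallelic`, `length`
#'   (signed bp: insertions positive). Attribute `n_snps_dropped` records
#'   how many equal-length allele records were discarded.
#' @export
read_indel_vcf <- function(path, sample_id = NULL, group = NA_character_,
                           min_qual = NULL) {
  stopifnot(file.exists(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_mat <- vcf@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2) {
    stop("VCF '", path, "' has no genotype (GT) column", call. = FALSE)
  }
  if (ncol(gt_mat) > 2) {
    stop("VCF '", path, "' has ", ncol(gt_mat) - 1,
         " sample columns; provide one file per sample ",
         "(see split_multisample_vcf())", call. = FALSE)
  }
  if (!all(grepl("(^|:)GT($|:)", gt_mat[, "FORMAT"]))) {
    stop("VCF '", path, "' is missing the GT field in FORMAT", call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- colnames(gt_mat)[2]

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]

  rec <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    gt = unname(gt)
  )
  if (!is.null(min_qual)) {
    rec <- dplyr::filter(rec, is.na(.data$qual) | .data$qual >= min_qual)
  }

  # one row per ALT allele, keeping only alleles present in the genotype
  rec <- rec |>
    dplyr::mutate(row_id = dplyr::row_number()) |>
    tidyr::separate_rows("alt", sep = ",") |>
    dplyr::group_by(.data$row_id) |>
    dplyr::mutate(
      allele_idx = dplyr::row_number(),
      multiallelic = dplyr::n() > 1L
    ) |>
    dplyr::ungroup()

  called <- purrr::map2_lgl(rec$gt, rec$allele_idx, gt_carries_allele)
  rec <- rec[called, , drop = FALSE]

  is_indel <- nchar(rec$ref) != nchar(rec$alt)
  n_snps <- sum(!is_indel)
  rec <- rec[is_indel, , drop = FALSE]

  out <- tibble::tibble(
    sample_id = sample_id,
    group = group,
    chrom = rec$chrom,
    pos = rec$pos,
    ref = rec$ref,
    alt = rec$alt,
    gt = rec$gt,
    multiallelic = rec$multiallelic,
    length = nchar(rec$alt) - nchar(rec$ref)
  )
  attr(out, "n_snps_dropped") <- n_snps
  out
}

# Does a GT string (e.g. "0/1", "1|1", ".") carry ALT allele number `idx`?
gt_carries_allele <- function(gt, idx) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(FALSE)
  alleles <- strsplit(gsub("\\|", "/", gt), "/")[[1]]
  any(alleles == as.character(idx))
}

# Is the genotype homozygous for ALT allele `idx`?
gt_homozygous_alt <- function(gt, idx) {
  if (is.na(gt)) return(FALSE)
  alleles <- strsplit(gsub("\\|", "/", gt), "/")[[1]]
  length(alleles) > 0 && all(alleles == as.character(idx))
}

#' Read per-sample VCFs for a whole cohort
#'
#' @param paths Character vector of single-sample VCF paths.
#' @param sample_ids Sample ids, one per path (default: VCF column names).
#' @param groups Group label per sample (recycled if length 1).
#' @param ... Passed to [read_indel_vcf()].
#' @return One long tibble of calls, rows from all samples.
#' @export
read_cohort_vcfs <- function(paths, sample_ids = NULL, groups = NA_character_, ...) {
  stopifnot(length(paths) >= 1)
  if (is.null(sample_ids)) sample_ids <- rep(list(NULL), length(paths))
  groups <- rep_len(groups, length(paths))
  purrr::pmap(
    list(paths, sample_ids, groups),
    function(p, s, g) read_indel_vcf(p, sample_id = s, group = g, ...)
  ) |>
    purrr::list_rbind()
}

#' Split a merged multi-sample VCF into per-sample call tibbles
#'
#' Convenience path for cohorts delivered as one merged VCF; the canonical
#' input remains one single-sample VCF per accession.
#'
#' @param path Multi-sample VCF path.
#' @param groups Named character vector mapping sample id to group label.
#' @return Long tibble of calls for all samples (as [read_cohort_vcfs()]).
#' @export
split_multisample_vcf <- function(path, groups = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_mat <- vcf@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2) {
    stop("VCF '", path, "' has no genotype columns", call. = FALSE)
  }
  samples <- colnames(gt_mat)[-1]
  tmp <- tempfile(fileext = ".dir")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  purrr::map(samples, function(s) {
    f <- file.path(tmp, paste0(s, ".vcf"))
    write_vcf_lines(
      f, sample_id = s,
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      qual = fix$QUAL, gt = sub(":.*$", "", gt_mat[, s])
    )
    g <- if (is.null(groups)) NA_character_ else unname(groups[s])
    read_indel_vcf(f, sample_id = s, group = g)
  }) |>
    purrr::list_rbind()
}

# Minimal VCF 4.2 writer for our own records (plain text, deterministic).
write_vcf_lines <- function(path, sample_id, chrom, pos, ref, alt,
                            qual = ".", gt = "1/1", contigs = NULL) {
  qual <- rep_len(as.character(qual), length(chrom))
  gt <- rep_len(gt, length(chrom))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=indelmarker",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contigs)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                contigs$chrom, contigs$length))
  }
  header <- c(header, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", sample_id, sep = "\t"))
  ord <- order(chrom, pos)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.\tGT\t%s",
                  chrom[ord], pos[ord], ref[ord], alt[ord], qual[ord], gt[ord])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a designed-marker table to TSV
#'
#' Columns: `marker_name`, `chromosome`, `position_1based`, `indel_length`,
#' `forward_primer`, `reverse_primer`, `product_size_ref`,
#' `product_size_alt`, `tm_f`, `tm_r`, `classification`. Coordinates are
#' 1-based, as in all user-facing tables.
#'
#' @param markers Marker tibble (from the design/e-PCR stages).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  stopifnot(nrow(markers) > 0)
  out <- tibble::tibble(
    marker_name = markers$marker_name %||% NA_character_,
    chromosome = markers$chrom,
    position_1based = markers$pos,
    indel_length = markers$length,
    forward_primer = markers$forward,
    reverse_primer = markers$reverse,
    product_size_ref = markers$product_size_ref,
    product_size_alt = markers$product_size_alt,
    tm_f = round(markers$tm_f, 2),
    tm_r = round(markers$tm_r, 2),
    classification = markers$classification %||% NA_character_
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a marker table written by [write_marker_table()]
#'
#' @param path TSV path.
#' @return Tibble in the internal marker column layout.
#' @export
read_marker_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    marker_name = as.character(x$marker_name),
    chrom = as.character(x$chromosome),
    pos = as.integer(x$position_1based),
    length = as.integer(x$indel_length),
    forward = x$forward_primer,
    reverse = x$reverse_primer,
    product_size_ref = as.integer(x$product_size_ref),
    product_size_alt = as.integer(x$product_size_alt),
    tm_f = x$tm_f,
    tm_r = x$tm_r,
    classification = as.character(x$classification)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
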