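#' Normalize InDel calls against a reference genome
#'
#' Left-aligns and parsimony-trims each insertion/deletion so that identical
#' events called at different anchors by different samples collapse to one
#' identity key `(chrom, pos, ref, alt)`. The representation kept is the
#' leftmost equivalent one with a single shared anchor base (VCF
#' convention). Normalization is idempotent.
#'
#' @param calls Tibble of calls with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` (any extra columns are preserved).
#' @param genome Reference genome (`DNAStringSet` or named character).
#' @return `calls` with `pos`, `ref`, `alt`, `length` rewritten to the
#'   normalized representation and a `normalized` column set to `TRUE`.
#' @export
normalize_indels <- function(calls, genome) {
  genome <- as_genome(genome)
  if (nrow(calls) == 0) {
    return(dplyr::mutate(calls, normalized = logical(0)))
  }
  missing_chr <- setdiff(unique(calls$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) not in reference: ", paste(missing_chr, collapse = ", "),
         call. = FALSE)
  }
  seqs <- setNames(as.character(genome), names(genome))
  norm <- purrr::pmap(
    list(calls$chrom, calls$pos, calls$ref, calls$alt),
    function(chrom, pos, ref, alt) normalize_one(chrom, pos, ref, alt, seqs[[chrom]])
  )
  calls$pos <- vapply(norm, `[[`, integer(1), "pos")
  calls$ref <- vapply(norm, `[[`, character(1), "ref")
  calls$alt <- vapply(norm, `[[`, character(1), "alt")
  calls$length <- nchar(calls$alt) - nchar(calls$ref)
  calls$normalized <- TRUE
  calls
}

# Left-align + trim a single variant; `seq` is the chromosome string.
normalize_one <- function(chrom, pos, ref, alt, seq) {
  if (nchar(ref) == nchar(alt)) {
    stop("not an InDel at ", chrom, ":", pos, " (", ref, ">", alt,
         "): alleles have equal length", call. = FALSE)
  }
  obs <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref)) {
    stop("REF allele mismatch at ", chrom, ":", pos, ": VCF says '", ref,
         "', reference has '", obs, "'", call. = FALSE)
  }
  last <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    if (nchar(ref) > 1 && nchar(alt) > 1 && last(ref) == last(alt)) {
      ref <- substr(ref, 1, nchar(ref) - 1L)
      alt <- substr(alt, 1, nchar(alt) - 1L)
    } else if (last(ref) == last(alt)) {
      if (pos == 1L) break
      pos <- pos - 1L
      b <- substr(seq, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else {
      break
    }
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Build the group-common InDel catalog for one group
#'
#' An InDel belongs to the group-common set when its exact normalized allele
#' is called in every member of the group. By default a heterozygous call
#' counts as presence (`require_homozygous = TRUE` restricts to homozygous
#' ALT genotypes).
#'
#' @param calls Long tibble of normalized calls for one group (columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `gt`; a `group` column is
#'   used as the label if `group` is `NULL`).
#' @param group Group label; default taken from the `group` column.
#' @param require_homozygous Count only homozygous ALT genotypes as presence.
#' @return A `group_catalog`: list with `group`, `members`, `common`
#'   (tibble of group-common variants), `presence` (logical variant x
#'   sample matrix over all variants seen in the group), and `union`
#'   (all variants seen in any member, with per-variant carrier counts).
#' @export
group_common <- function(calls, group = NULL, require_homozygous = FALSE) {
  if (is.null(group)) {
    group <- unique(calls$group)
    group <- group[!is.na(group)]
  }
  if (length(group) != 1) {
    stop("calls must carry exactly one group label (got: ",
         paste(group, collapse = ", "), ")", call. = FALSE)
  }
  calls <- dplyr::filter(calls, is.na(.data$group) | .data$group == .env$group)
  members <- sort(unique(calls$sample_id))
  if (length(members) == 0) stop("empty group '", group, "'", call. = FALSE)
  if (!isTRUE(all(calls$normalized))) {
    stop("calls must be normalized first (see normalize_indels())", call. = FALSE)
  }
  if (require_homozygous) {
    hom <- vapply(calls$gt, function(g) gt_homozygous_alt(g, idx_from_gt(g)),
                  logical(1))
    calls <- calls[hom, , drop = FALSE]
  }
  calls <- dplyr::mutate(calls, key = variant_key(.data$chrom, .data$pos,
                                                  .data$ref, .data$alt))
  uni <- calls |>
    dplyr::distinct(.data$key, .data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$sample_id) |>
    dplyr::count(.data$key, .data$chrom, .data$pos, .data$ref, .data$alt,
                 name = "n_samples") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)

  presence <- matrix(FALSE, nrow = nrow(uni), ncol = length(members),
                     dimnames = list(uni$key, members))
  idx <- cbind(match(calls$key, uni$key), match(calls$sample_id, members))
  presence[idx] <- TRUE

  common <- uni |>
    dplyr::filter(.data$n_samples == length(members)) |>
    dplyr::mutate(length = nchar(.data$alt) - nchar(.data$ref)) |>
    dplyr::select("chrom", "pos", "ref", "alt", "length", "key")

  structure(
    list(group = group, members = members, common = common,
         presence = presence, union = uni),
    class = "group_catalog"
  )
}

# best-effort allele index for require_homozygous mode: single-allele rows
# produced by read_indel_vcf carry gt like "1/1" or "0/1"; the carried index
# is whatever non-zero allele appears.
idx_from_gt <- function(g) {
  a <- strsplit(gsub("\\|", "/", g), "/")[[1]]
  a <- a[a != "0" & a != "."]
  if (length(a) == 0) return("0")
  a[[1]]
}

#' @export
print.group_catalog <- function(x, ...) {
  cat("<group_catalog> group '", x$group, "': ", length(x$members),
      " samples, ", nrow(x$union), " distinct InDels, ",
      nrow(x$common), " group-common\n", sep = "")
  invisible(x)
}

#' @rdname group_common
#' @param x A `group_catalog`.
#' @param ... Unused.
#' @export
tidy.group_catalog <- function(x, ...) {
  dplyr::mutate(x$common, group = x$group, .before = 1)
}

#' @rdname group_common
#' @export
glance.group_catalog <- function(x, ...) {
  tibble::tibble(
    group = x$group,
    n_samples = length(x$members),
    n_indels_union = nrow(x$union),
    n_common = nrow(x$common)
  )
}

#' Select subspecies-specific InDels
#'
#' A variant is specific to the target group when (i) it is group-common in
#' the target group, (ii) its length exceeds `min_len` bp (strictly), and
#' (iii) no sample of the other group carries the identical normalized
#' allele — every other-group sample then carries a different allele at the
#' locus, whether that is the reference allele or a different ALT. Which
#' condition held is recorded per variant in `rule_trace`.
#'
#' @param catalog_target `group_catalog` of the group the markers should
#'   type (e.g. javanica).
#' @param catalog_other `group_catalog` of the contrasting group.
#' @param min_len Strict minimum |InDel length| in bp (default 10: only
#'   InDels larger than 10 bp are kept, so a 10 bp event is excluded).
#' @return Tibble of specific variants (`chrom`, `pos`, `ref`, `alt`,
#'   `length`, `key`, `rule_trace`) with attributes `target_group`,
#'   `other_group`, `min_len`.
#' @export
specific_indels <- function(catalog_target, catalog_other, min_len = 10) {
  stopifnot(inherits(catalog_target, "group_catalog"),
            inherits(catalog_other, "group_catalog"))
  cand <- dplyr::filter(catalog_target$common, abs(.data$length) > min_len)
  other_keys <- catalog_other$union$key
  cand <- dplyr::filter(cand, !(.data$key %in% other_keys))
  other_loci <- paste(catalog_other$union$chrom, catalog_other$union$pos, sep = ":")
  cand <- dplyr::mutate(
    cand,
    rule_trace = dplyr::if_else(
      paste(.data$chrom, .data$pos, sep = ":") %in% other_loci,
      "other_group_different_alt",
      "other_group_reference"
    )
  )
  attr(cand, "target_group") <- catalog_target$group
  attr(cand, "other_group") <- catalog_other$group
  attr(cand, "min_len") <- min_len
  cand
}

#' Genome-wide InDel density table
#'
#' Counts variants per chromosome and per fixed-size window. Windows are
#' half-open `[k*w, (k+1)*w)` on 0-based coordinates (so 1-based position
#' 100,000 falls in the first 100-kb window); the last window is truncated
#' at the chromosome end. Chromosome densities are counts per Mb.
#'
#' @param variants Tibble with `chrom` and `pos` (1-based) columns; rows are
#'   counted as-is (deduplicate first if needed).
#' @param chrom_lengths Tibble with `chrom`, `length` (bp), e.g. from
#'   [chrom_lengths()]; must cover every chromosome in `variants`.
#' @param window Window size in bp (default 100,000).
#' @return An `indel_density` object: list with `per_chromosome`
#'   (`chrom`, `n`, `length_mb`, `density`), `windows` (`chrom`, `start`,
#'   `end` 1-based inclusive, `n`; includes empty windows), and `window`.
#' @export
density_table <- function(variants, chrom_lengths, window = 100000) {
  stopifnot(window > 0)
  missing_chr <- setdiff(unique(variants$chrom), chrom_lengths$chrom)
  if (length(missing_chr)) {
    stop("chromosome(s) missing from chrom_lengths: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  len <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  if (nrow(variants)) {
    beyond <- variants$pos > len[variants$chrom] | variants$pos < 1
    if (any(beyond)) {
      i <- which(beyond)[1]
      stop("variant at ", variants$chrom[i], ":", variants$pos[i],
           " lies outside the chromosome (length ",
           len[variants$chrom[i]], ")", call. = FALSE)
    }
  }

  windows <- chrom_lengths |>
    dplyr::rowwise() |>
    dplyr::reframe(
      chrom = .data$chrom,
      start = seq(1L, .data$length, by = as.integer(window)),
      end = pmin(.data$start + as.integer(window) - 1L, .data$length)
    )
  counts <- variants |>
    dplyr::mutate(start = (floor((.data$pos - 1) / window) * window) + 1L) |>
    dplyr::count(.data$chrom, .data$start)
  windows <- windows |>
    dplyr::left_join(counts, by = c("chrom", "start")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))

  per_chrom <- chrom_lengths |>
    dplyr::left_join(
      dplyr::count(variants, .data$chrom),
      by = "chrom"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      length_mb = .data$length / 1e6,
      density = .data$n / .data$length_mb
    ) |>
    dplyr::select("chrom", "n", "length_mb", "density")

  structure(
    list(per_chromosome = per_chrom, windows = windows, window = window),
    class = "indel_density"
  )
}

#' @export
print.indel_density <- function(x, ...) {
  cat("<indel_density> window =", format(x$window, big.mark = ","), "bp\n")
  out <- dplyr::mutate(x$per_chromosome, density = round(.data$density, 2))
  print(out)
  invisible(x)
}

#' @rdname density_table
#' @param x An `indel_density` object.
#' @param ... Unused.
#' @export
tidy.indel_density <- function(x, ...) x$windows

#' @rdname density_table
#' @export
glance.indel_density <- function(x, ...) {
  dplyr::mutate(x$per_chromosome, density = round(.data$density, 2))
}

#' Write density tables to TSV (densities rounded to 2 decimals)
#'
#' @param x An `indel_density` object.
#' @param per_chromosome_path,windows_path Output paths (either may be NULL).
#' @return `x`, invisibly.
#' @export
write_density_table <- function(x, per_chromosome_path = NULL, windows_path = NULL) {
  stopifnot(inherits(x, "indel_density"))
  if (!is.null(per_chromosome_path)) {
    readr::write_tsv(glance(x), per_chromosome_path)
  }
  if (!is.null(windows_path)) readr::write_tsv(x$windows, windows_path)
  invisible(x)
}

#' Per-chromosome between-group catalog difference
#'
#' Counts, per chromosome, the loci at which the two groups' common
#' genotypes differ: the symmetric difference of the two group-common
#' variant sets (allele-exact keys). The mean over chromosomes is reported
#' alongside.
#'
#' @param catalog_a,catalog_b `group_catalog` objects.
#' @return Tibble `chrom`, `n_diff` with attribute `mean_per_chromosome`.
#' @export
between_group_diff <- function(catalog_a, catalog_b) {
  stopifnot(inherits(catalog_a, "group_catalog"),
            inherits(catalog_b, "group_catalog"))
  a <- catalog_a$common
  b <- catalog_b$common
  sym <- dplyr::bind_rows(
    dplyr::anti_join(a, b, by = "key"),
    dplyr::anti_join(b, a, by = "key")
  )
  out <- sym |>
    dplyr::count(.data$chrom, name = "n_diff") |>
    dplyr::arrange(.data$chrom)
  chroms <- sort(unique(c(a$chrom, b$chrom, out$chrom)))
  out <- tibble::tibble(chrom = chroms) |>
    dplyr::left_join(out, by = "chrom") |>
    dplyr::mutate(n_diff = dplyr::coalesce(.data$n_diff, 0L))
  attr(out, "mean_per_chromosome") <- mean(out$n_diff)
  out
}
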