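#' In-silico PCR on a sequence
#'
#' Predicts amplicons from exact primer matches: every site where the
#' forward primer matches the plus strand, paired with every downstream
#' site where the reverse primer matches the minus strand (i.e. its
#' reverse complement matches the plus strand, starting after the forward
#' site ends), gives a product of size at most `max_product`. Matching is
#' exact (0 mismatches); `N` in the sequence never matches a primer base.
#'
#' @param forward,reverse Primer sequences (5'->3').
#' @param sequence Subject sequence (character or `DNAString`); may
#'   contain `N`.
#' @param max_product Maximum product size reported (bp).
#' @return Tibble of amplicons: `start`, `end` (1-based inclusive on the
#'   subject), `size`. Zero rows when no product.
#' @export
insilico_pcr <- function(forward, reverse, sequence, max_product = 2000) {
  sequence <- toupper(as.character(sequence))
  subj <- Biostrings::DNAString(sequence)
  f_len <- nchar(forward)
  r_len <- nchar(reverse)
  f_starts <- Biostrings::start(Biostrings::matchPattern(toupper(forward), subj))
  r_starts <- Biostrings::start(
    Biostrings::matchPattern(reverse_complement(toupper(reverse)), subj)
  )
  if (length(f_starts) == 0 || length(r_starts) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), size = integer()))
  }
  grid <- tidyr::expand_grid(f = f_starts, r = r_starts)
  grid <- dplyr::filter(grid, .data$r >= .data$f + f_len)
  grid$size <- grid$r + r_len - grid$f
  grid <- dplyr::filter(grid, .data$size <= max_product)
  tibble::tibble(
    start = as.integer(grid$f),
    end = as.integer(grid$r + r_len - 1L),
    size = as.integer(grid$size)
  ) |>
    dplyr::arrange(.data$start, .data$end)
}

# Apply the variant to its flanking template (ref -> alt allele sequence).
alt_template <- function(template_row) {
  paste0(template_row$left_flank, template_row$alt, template_row$right_flank)
}

#' Predict per-allele amplicon sizes for a designed marker
#'
#' Runs [insilico_pcr()] on the reference-allele template and on the
#' template with the variant applied. A marker is flagged `failed` when
#' either allele yields zero or more than one product.
#'
#' @param pair One-row tibble from [design_pair()] (columns `forward`,
#'   `reverse`).
#' @param template Matching row of [extract_flanks()] output.
#' @param max_product Passed to [insilico_pcr()].
#' @return Tibble `size_ref`, `size_alt`, `status` (`"ok"`/`"failed"`).
#' @export
predict_allele_sizes <- function(pair, template, max_product = 2000) {
  ref_amp <- insilico_pcr(pair$forward, pair$reverse, template$template,
                          max_product)
  alt_amp <- insilico_pcr(pair$forward, pair$reverse, alt_template(template),
                          max_product)
  if (nrow(ref_amp) != 1 || nrow(alt_amp) != 1) {
    return(tibble::tibble(
      size_ref = if (nrow(ref_amp) == 1) ref_amp$size else NA_integer_,
      size_alt = if (nrow(alt_amp) == 1) alt_amp$size else NA_integer_,
      status = "failed"
    ))
  }
  tibble::tibble(size_ref = ref_amp$size, size_alt = alt_amp$size,
                 status = "ok")
}

#' Virtual gel model
#'
#' Minimum band-size difference a gel can separate, and the largest size it
#' resolves. Defaults: 10 bp on 6 % polyacrylamide, 20 bp on 4 % agarose
#' (configurable; the separation thresholds are this package's operational
#' stand-ins — electrophoretic mobility is not modelled).
#'
#' @param type `"page"` or `"agarose"`.
#' @param min_diff Minimum resolvable size difference (bp); default by
#'   `type`.
#' @param max_size Largest band size resolved (bp).
#' @return A `gel_model` list.
#' @export
gel_model <- function(type = c("page", "agarose"), min_diff = NULL,
                      max_size = 1000) {
  type <- match.arg(type)
  if (is.null(min_diff)) min_diff <- if (type == "page") 10 else 20
  stopifnot(min_diff > 0, max_size > 0)
  structure(list(type = type, min_diff = min_diff, max_size = max_size),
            class = "gel_model")
}

#' Are two band sizes separable on a gel?
#'
#' @param size_a,size_b Band sizes (bp, vectors recycled).
#' @param gel A [gel_model()].
#' @return Logical: `TRUE` iff `|size_a - size_b| >= min_diff` and both
#'   sizes are at most `max_size`.
#' @export
resolvable <- function(size_a, size_b, gel = gel_model()) {
  stopifnot(all(size_a > 0), all(size_b > 0))
  abs(size_a - size_b) >= gel$min_diff &
    size_a <= gel$max_size & size_b <= gel$max_size
}

#' Classify one marker from per-variety band sets
#'
#' Outcomes mirror marker validation on a gel: `failed` (some variety gives
#' no product), `monomorphic` (identical bands everywhere),
#' `discriminating_biallelic` / `discriminating_multiallelic` (the band-set
#' partition separates the two groups perfectly, with exactly two / more
#' than two distinct band sets), `polymorphic_nondiscriminating`
#' (polymorphic but groups overlap).
#'
#' @param band_sets Named list: variety -> numeric vector of band sizes
#'   (possibly empty = no amplification).
#' @param groups Named character vector: variety -> group label (must cover
#'   every variety).
#' @return Classification string.
#' @export
classify_marker <- function(band_sets, groups) {
  varieties <- names(band_sets)
  if (is.null(varieties) || !all(varieties %in% names(groups))) {
    missing <- setdiff(varieties, names(groups))
    stop("group label missing for variety: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(vapply(band_sets, length, integer(1)) == 0)) return("failed")
  sig <- vapply(band_sets, function(s) paste(sort(unique(s)), collapse = ","),
                character(1))
  if (length(unique(sig)) == 1) return("monomorphic")
  g <- groups[varieties]
  sets_by_group <- split(sig, g)
  if (length(sets_by_group) != 2) {
    stop("classification needs exactly two groups, got ",
         length(sets_by_group), call. = FALSE)
  }
  if (length(intersect(unique(sets_by_group[[1]]),
                       unique(sets_by_group[[2]]))) == 0) {
    if (length(unique(sig)) == 2) "discriminating_biallelic"
    else "discriminating_multiallelic"
  } else {
    "polymorphic_nondiscriminating"
  }
}

# natural chromosome order: non-digit prefix, then numeric suffix
natural_chrom_order <- function(chroms) {
  u <- unique(chroms)
  prefix <- sub("[0-9]+$", "", u)
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", u)))
  u[order(prefix, num, u)]
}

#' Assign IJ marker names by genomic position
#'
#' Sorts markers by chromosome (natural order, or the supplied order of
#' appearance in the reference) then position, and names them `IJ` plus a
#' zero-padded ordinal ("IJ" from Indica/Javanica, the two groups the
#' markers separate). Idempotent and deterministic.
#'
#' @param markers Marker tibble with `chrom`, `pos`.
#' @param chrom_order Optional chromosome ordering (e.g. FASTA order);
#'   default natural sort.
#' @return `markers` sorted, with a `marker_name` column.
#' @export
assign_ij_names <- function(markers, chrom_order = NULL) {
  if (anyDuplicated(markers[, c("chrom", "pos")])) {
    d <- markers[duplicated(markers[, c("chrom", "pos")]), c("chrom", "pos")]
    stop("duplicate marker position(s): ",
         paste(d$chrom, d$pos, sep = ":", collapse = ", "), call. = FALSE)
  }
  if (is.null(chrom_order)) chrom_order <- natural_chrom_order(markers$chrom)
  ord <- order(match(markers$chrom, chrom_order), markers$pos)
  markers <- markers[ord, ]
  width <- nchar(as.character(nrow(markers)))
  markers$marker_name <- paste0("IJ", formatC(seq_len(nrow(markers)),
                                              width = width, flag = "0"))
  markers
}

#' Physical map of markers along chromosomes
#'
#' @param markers Named marker tibble (`marker_name`, `chrom`, `pos`).
#' @param chrom_lengths Tibble `chrom`, `length` (every chromosome is
#'   reported, empty ones with count 0).
#' @return A `physical_map`: list with `markers` (positionally ordered) and
#'   `counts` (`chrom`, `n`, `length`).
#' @export
physical_map <- function(markers, chrom_lengths) {
  chrom_order <- chrom_lengths$chrom
  ord <- order(match(markers$chrom, chrom_order), markers$pos)
  m <- markers[ord, c("marker_name", "chrom", "pos")]
  counts <- chrom_lengths |>
    dplyr::left_join(dplyr::count(m, .data$chrom), by = "chrom") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::select("chrom", "n", "length")
  structure(list(markers = m, counts = counts), class = "physical_map")
}

#' @export
print.physical_map <- function(x, ...) {
  cat("<physical_map>", nrow(x$markers), "markers on",
      nrow(x$counts), "chromosomes\n")
  print(x$counts)
  invisible(x)
}

#' @rdname physical_map
#' @param x A `physical_map`.
#' @param ... Unused.
#' @export
tidy.physical_map <- function(x, ...) x$markers

#' Annotate markers with nearby genes from a GFF3 file
#'
#' Lists gene identifiers whose annotated span lies within `window` bp of
#' each marker position (an explicit operational stand-in for "tightly
#' linked" genes).
#'
#' @param markers Marker tibble with `chrom`, `pos`.
#' @param gff Path to a GFF3 file (read with \pkg{rtracklayer}).
#' @param window Linking window in bp (default 50,000).
#' @return `markers` with a `linked_genes` column (comma-separated IDs or
#'   `NA`).
#' @export
annotate_linked_genes <- function(markers, gff, window = 50000) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("annotate_linked_genes() requires the rtracklayer package",
         call. = FALSE)
  }
  gr <- rtracklayer::import(gff)
  genes <- as.data.frame(gr)
  genes <- genes[genes$type == "gene", , drop = FALSE]
  id_col <- intersect(c("ID", "gene_id", "Name"), names(genes))[1]
  if (is.na(id_col)) stop("no gene identifier attribute in GFF3", call. = FALSE)
  markers$linked_genes <- vapply(seq_len(nrow(markers)), function(i) {
    hit <- genes$seqnames == markers$chrom[i] &
      genes$start <= markers$pos[i] + window &
      genes$end >= markers$pos[i] - window
    if (!any(hit)) return(NA_character_)
    paste(genes[[id_col]][hit], collapse = ",")
  }, character(1))
  markers
}
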