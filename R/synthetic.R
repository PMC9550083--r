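#' Design of a synthetic two-group cohort
#'
#' Describes a fully seeded cohort emulating a resequencing panel of two
#' subspecies groups (default 10 + 10 accessions) with planted InDel
#' classes:
#' \describe{
#'   \item{group_specific}{present homozygous in every target-group sample,
#'     absent from the other group; length drawn from `indel_length_range`
#'     (default 11–60 bp, i.e. marker-eligible).}
#'   \item{shared}{group-common in *both* groups (present in all samples).}
#'   \item{private}{present in exactly one sample (count is the total over
#'     the cohort).}
#'   \item{sub_threshold}{same genotype pattern as group_specific but with
#'     length at most 10 bp, so the size filter must remove them.}
#' }
#' Planted sites are at least `min_spacing` bp apart (default 500) so
#' 200-nt flanking templates never collide.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_per_group Samples per group.
#' @param groups Two group labels; the second is the target (marker) group.
#' @param n_group_specific,n_shared,n_private,n_sub_threshold Planted counts
#'   per class.
#' @param indel_length_range Length range (bp) for marker-eligible classes.
#' @param sub_threshold_length_range Length range for sub-threshold InDels.
#' @param gc_content Target GC fraction of the reference.
#' @param min_spacing Minimum distance between planted sites (bp).
#' @param heterozygous Plant 0/1 genotypes instead of 1/1 (off by default;
#'   inbred rice varieties are effectively homozygous).
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_chromosomes = 3,
                          chrom_length = 200000,
                          n_per_group = 10,
                          groups = c("indica", "javanica"),
                          n_group_specific = 200,
                          n_shared = 100,
                          n_private = 50,
                          n_sub_threshold = 30,
                          indel_length_range = c(11, 60),
                          sub_threshold_length_range = c(1, 10),
                          gc_content = 0.44,
                          min_spacing = 500,
                          heterozygous = FALSE,
                          seed = 1) {
  stopifnot(
    n_chromosomes >= 1, chrom_length >= 1000, n_per_group >= 2,
    length(groups) == 2, !anyDuplicated(groups),
    n_group_specific >= 0, n_shared >= 0, n_private >= 0, n_sub_threshold >= 0,
    indel_length_range[1] > 0, diff(indel_length_range) >= 0,
    sub_threshold_length_range[1] > 0, sub_threshold_length_range[2] <= 10,
    gc_content > 0, gc_content < 1, min_spacing >= 1
  )
  design <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_per_group = as.integer(n_per_group),
    groups = groups,
    n_group_specific = as.integer(n_group_specific),
    n_shared = as.integer(n_shared),
    n_private = as.integer(n_private),
    n_sub_threshold = as.integer(n_sub_threshold),
    indel_length_range = as.integer(indel_length_range),
    sub_threshold_length_range = as.integer(sub_threshold_length_range),
    gc_content = gc_content,
    min_spacing = as.integer(min_spacing),
    heterozygous = isTRUE(heterozygous),
    seed = as.integer(seed)
  )
  check_capacity(design)
  structure(design, class = "cohort_design")
}

# margin from chromosome ends: full 200-nt flank + widest planted event
# + slack for the deletion-anchor nudge in make_variant()
plant_margin <- function(design) 200L + max(design$indel_length_range) + 40L

n_planted <- function(design) {
  design$n_group_specific + design$n_shared + design$n_private +
    design$n_sub_threshold
}

check_capacity <- function(design) {
  usable <- design$chrom_length - 2L * plant_margin(design)
  capacity <- design$n_chromosomes * (usable %/% design$min_spacing + 1L)
  if (usable <= 0 || capacity < n_planted(design)) {
    stop("chrom_length ", design$chrom_length, " is too short for ",
         n_planted(design), " planted variants at spacing ",
         design$min_spacing, call. = FALSE)
  }
  invisible(design)
}

#' Generate the synthetic reference genome
#'
#' Deterministic for a fixed `design$seed`; per-chromosome GC fraction falls
#' within about 2 percentage points of `design$gc_content` at the default
#' chromosome length.
#'
#' @param design A [cohort_design()].
#' @return Named `DNAStringSet` of `n_chromosomes` chromosomes
#'   (`chr1`, `chr2`, ...).
#' @export
generate_reference <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  check_capacity(design)
  gc <- design$gc_content
  withr::with_seed(design$seed, {
    seqs <- vapply(seq_len(design$n_chromosomes), function(i) {
      paste(sample(c("A", "C", "G", "T"), design$chrom_length, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(design$n_chromosomes))
  genome
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Positions per chromosome: evenly spread slots with bounded jitter, so
# adjacent sites always keep >= min_spacing.
plant_positions <- function(design) {
  v <- n_planted(design)
  margin <- plant_margin(design)
  per_chrom <- diff(c(0, round(seq_len(design$n_chromosomes) * v /
                                 design$n_chromosomes)))
  purrr::map2(paste0("chr", seq_len(design$n_chromosomes)), per_chrom,
    function(chrom, k) {
      if (k == 0) return(tibble::tibble(chrom = character(), pos = integer()))
      usable <- design$chrom_length - 2 * margin
      step <- usable / k
      if (step < design$min_spacing) {
        stop("chrom_length too short for ", v, " planted variants", call. = FALSE)
      }
      jit_max <- floor((step - design$min_spacing) / 2)
      jitter <- if (jit_max > 0) sample(-jit_max:jit_max, k, replace = TRUE) else 0L
      tibble::tibble(
        chrom = chrom,
        pos = as.integer(margin + round((seq_len(k) - 0.5) * step) + jitter)
      )
    }) |>
    purrr::list_rbind()
}

# Build one planted variant at (chrom, pos); alleles are constructed so the
# VCF representation is already left-aligned and parsimonious.
make_variant <- function(seq, pos, len) {
  anchor <- substr(seq, pos, pos)
  if (stats::runif(1) < 0.5) {  # insertion
    ins <- random_bases(len)
    while (substr(ins, len, len) == anchor) {
      ins <- paste0(substr(ins, 1, len - 1), random_bases(1))
    }
    list(pos = pos, ref = anchor, alt = paste0(anchor, ins))
  } else {                      # deletion; nudge right until unambiguous
    for (p in pos:(pos + 25L)) {
      a <- substr(seq, p, p)
      if (substr(seq, p + len, p + len) != a) {
        return(list(pos = p, ref = substr(seq, p, p + len), alt = a))
      }
    }
    # pathological run of one base: fall back to an insertion
    ins <- random_bases(len)
    while (substr(ins, len, len) == anchor) {
      ins <- paste0(substr(ins, 1, len - 1), random_bases(1))
    }
    list(pos = pos, ref = anchor, alt = paste0(anchor, ins))
  }
}

#' Plant the cohort's variants and build the truth table
#'
#' Places all planted classes on the reference at mutually spaced sites and
#' assigns carriers: `group_specific` and `sub_threshold` variants to every
#' target-group sample, `shared` to all samples, `private` to exactly one
#' sample. Genotypes are homozygous ALT (`1/1`) unless
#' `design$heterozygous`.
#'
#' @param reference Genome from [generate_reference()] (same design).
#' @param design The [cohort_design()].
#' @return List with `calls` (long tibble: one row per sample x carried
#'   variant, VCF-style fields), `truth` (one row per planted variant:
#'   `chrom`, `pos`, `ref`, `alt`, `length`, `class`, `eligible`),
#'   `samples` (tibble `sample_id`, `group`) and `design`.
#' @export
plant_cohort <- function(reference, design) {
  stopifnot(inherits(design, "cohort_design"))
  reference <- as_genome(reference)
  seqs <- setNames(as.character(reference), names(reference))
  samples <- tibble::tibble(
    sample_id = c(sprintf("%s_%02d", design$groups[1], seq_len(design$n_per_group)),
                  sprintf("%s_%02d", design$groups[2], seq_len(design$n_per_group))),
    group = rep(design$groups, each = design$n_per_group)
  )
  target <- design$groups[2]

  truth <- withr::with_seed(design$seed + 1L, {
    sites <- plant_positions(design)
    classes <- sample(rep(
      c("group_specific", "shared", "private", "sub_threshold"),
      times = c(design$n_group_specific, design$n_shared,
                design$n_private, design$n_sub_threshold)
    ))
    lens <- ifelse(
      classes == "sub_threshold",
      sample(seq(design$sub_threshold_length_range[1],
                 design$sub_threshold_length_range[2]),
             length(classes), replace = TRUE),
      sample(seq(design$indel_length_range[1], design$indel_length_range[2]),
             length(classes), replace = TRUE)
    )
    vars <- purrr::pmap(
      list(sites$chrom, sites$pos, lens),
      function(chrom, pos, len) {
        v <- make_variant(seqs[[chrom]], pos, len)
        tibble::tibble(chrom = chrom, pos = v$pos, ref = v$ref, alt = v$alt)
      }
    ) |> purrr::list_rbind()
    carrier <- sample(samples$sample_id, nrow(vars), replace = TRUE)
    dplyr::mutate(vars,
      class = classes,
      length = nchar(.data$alt) - nchar(.data$ref),
      private_carrier = dplyr::if_else(.data$class == "private", carrier,
                                       NA_character_)
    )
  })
  truth <- dplyr::mutate(
    truth,
    eligible = .data$class == "group_specific" & abs(.data$length) > 10
  )

  planted_gt <- if (design$heterozygous) "0/1" else "1/1"
  carriers_of <- function(class, private_carrier) {
    switch(class,
      group_specific = ,
      sub_threshold = samples$sample_id[samples$group == target],
      shared = samples$sample_id,
      private = private_carrier
    )
  }
  calls <- truth |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      sample_id = carriers_of(.data$class, .data$private_carrier),
      chrom = .data$chrom, pos = .data$pos, ref = .data$ref, alt = .data$alt,
      length = .data$length
    ) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::mutate(gt = planted_gt, multiallelic = FALSE) |>
    dplyr::select("sample_id", "group", "chrom", "pos", "ref", "alt",
                  "gt", "multiallelic", "length") |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos)

  list(
    calls = calls,
    truth = dplyr::select(truth, "chrom", "pos", "ref", "alt", "length",
                          "class", "eligible"),
    samples = samples,
    design = design
  )
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_reference()] + [plant_cohort()].
#'
#' @param design A [cohort_design()].
#' @return As [plant_cohort()], plus a `reference` element.
#' @export
simulate_cohort <- function(design = cohort_design()) {
  reference <- generate_reference(design)
  cohort <- plant_cohort(reference, design)
  cohort$reference <- reference
  cohort
}

#' Write a cohort to standard files
#'
#' Emits `reference.fa`, one plain-text VCF 4.2 per sample under `vcf/`,
#' `truth.tsv` and `samples.tsv`.
#'
#' @param cohort From [simulate_cohort()] / [plant_cohort()].
#' @param dir Output directory (created if needed).
#' @return Tibble of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  ref_path <- file.path(dir, "reference.fa")
  write_genome_fasta(cohort$reference, ref_path)
  contigs <- chrom_lengths(cohort$reference)
  vcf_paths <- purrr::map_chr(cohort$samples$sample_id, function(s) {
    x <- dplyr::filter(cohort$calls, .data$sample_id == s)
    p <- file.path(dir, "vcf", paste0(s, ".vcf"))
    write_vcf_lines(p, sample_id = s, chrom = x$chrom, pos = x$pos,
                    ref = x$ref, alt = x$alt, gt = x$gt, contigs = contigs)
    p
  })
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(cohort$truth, truth_path)
  samples_path <- file.path(dir, "samples.tsv")
  readr::write_tsv(cohort$samples, samples_path)
  invisible(tibble::tibble(
    file = c("reference", "truth", "samples", cohort$samples$sample_id),
    path = c(ref_path, truth_path, samples_path, vcf_paths)
  ))
}

#' Simulate a scored band matrix for a marker panel
#'
#' Emulates gel scoring: entry 1 when the variety carries the target-group
#' (javanica-type) allele at the marker's InDel, 0 otherwise; a fraction
#' `dropout_rate` of entries is set to missing at random.
#'
#' @param markers Marker tibble with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `marker_name`) — must be designed on this cohort.
#' @param cohort From [simulate_cohort()].
#' @param dropout_rate Fraction of entries set missing (default 0).
#' @param seed Seed for the dropout draw.
#' @return A `band_matrix` tibble: `variety`, `group`, then one 0/1/NA
#'   column per marker.
#' @export
simulate_band_matrix <- function(markers, cohort, dropout_rate = 0, seed = 1) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  mkey <- variant_key(markers$chrom, markers$pos, markers$ref, markers$alt)
  tkey <- variant_key(cohort$truth$chrom, cohort$truth$pos,
                      cohort$truth$ref, cohort$truth$alt)
  if (!all(mkey %in% tkey)) {
    stop("marker(s) not locatable in this cohort: ",
         paste(utils::head(mkey[!mkey %in% tkey], 3), collapse = ", "),
         call. = FALSE)
  }
  names <- if ("marker_name" %in% names(markers) &&
               !anyNA(markers$marker_name)) {
    markers$marker_name
  } else {
    mkey
  }
  ckey <- variant_key(cohort$calls$chrom, cohort$calls$pos,
                      cohort$calls$ref, cohort$calls$alt)
  carried <- paste(cohort$calls$sample_id, ckey)
  mat <- outer(cohort$samples$sample_id, mkey,
               function(s, k) as.integer(paste(s, k) %in% carried))
  dimnames(mat) <- list(cohort$samples$sample_id, names)
  if (dropout_rate > 0) {
    withr::with_seed(seed, {
      drop <- stats::runif(length(mat)) < dropout_rate
    })
    mat[drop] <- NA_integer_
  }
  new_band_matrix(
    tibble::as_tibble(mat) |>
      dplyr::mutate(variety = cohort$samples$sample_id,
                    group = cohort$samples$group,
                    .before = 1)
  )
}
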