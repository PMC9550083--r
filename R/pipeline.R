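with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full marker-development pipeline in memory
#'
#' Executes the method end to end: normalize InDel calls, build per-group
#' common catalogs, select target-group-specific InDels larger than
#' `min_indel_len` bp, extract flanking templates, design genome-unique
#' primer pairs, predict per-allele amplicons by in-silico PCR, classify
#' each marker against the cohort on a virtual gel, and name the
#' discriminating markers `IJ1..IJn` by genomic position. Counts at every
#' filter stage are collected in `stage_counts`.
#'
#' @param reference Reference genome (`DNAStringSet` or named character).
#' @param calls Long tibble of per-sample InDel calls (from
#'   [read_cohort_vcfs()] or [plant_cohort()]); must carry `group` labels
#'   for exactly two groups.
#' @param target_group Group the markers should type (default: the second
#'   group label encountered).
#' @param constraints A [design_constraints()].
#' @param gel A [gel_model()].
#' @param min_indel_len Strict minimum |InDel length| (bp) for marker
#'   candidates.
#' @param flank Flank width for templates (nt).
#' @param max_product In-silico PCR size cap (bp).
#' @param window Density window size (bp).
#' @param keep_only_discriminating Keep only discriminating markers in the
#'   final named panel.
#' @param out_dir If non-NULL, write all intermediate and final TSVs there.
#' @return An `indel_pipeline` object; see [tidy.indel_pipeline()].
#' @export
run_indel_pipeline <- function(reference, calls, target_group = NULL,
                               constraints = design_constraints(),
                               gel = gel_model(),
                               min_indel_len = 10, flank = 200,
                               max_product = 2000, window = 100000,
                               keep_only_discriminating = TRUE,
                               out_dir = NULL) {
  reference <- as_genome(reference)
  groups <- unique(calls$group)
  groups <- groups[!is.na(groups)]
  if (length(groups) != 2) {
    stop("calls must carry exactly two group labels, got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  if (is.null(target_group)) target_group <- groups[2]
  other_group <- setdiff(groups, target_group)
  if (length(other_group) != 1 || !(target_group %in% groups)) {
    stop("target_group must be one of: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }

  n_input <- nrow(calls)
  calls <- with_stage("normalize", normalize_indels(calls, reference))
  n_distinct <- dplyr::n_distinct(
    variant_key(calls$chrom, calls$pos, calls$ref, calls$alt))

  cat_target <- with_stage("catalog", group_common(
    dplyr::filter(calls, .data$group == target_group)))
  cat_other <- with_stage("catalog", group_common(
    dplyr::filter(calls, .data$group == other_group)))

  specific_all <- with_stage("specific", specific_indels(
    cat_target, cat_other, min_len = 0))
  specific <- with_stage("specific", specific_indels(
    cat_target, cat_other, min_len = min_indel_len))

  lens <- chrom_lengths(reference)
  density_target <- with_stage("density", density_table(
    cat_target$common, lens, window = window))
  density_other <- with_stage("density", density_table(
    cat_other$common, lens, window = window))
  group_diff <- with_stage("density", between_group_diff(cat_target, cat_other))

  templates <- with_stage("flanks", extract_flanks(specific, reference,
                                                   flank = flank))
  designable <- dplyr::filter(templates, .data$designable)

  designed <- with_stage("design", design_primers(designable, reference,
                                                  constraints))
  pairs <- dplyr::filter(designed, .data$status == "ok")

  epcr <- with_stage("epcr", epcr_classify(
    pairs, templates, calls, target_group, other_group, gel, max_product))

  markers <- epcr$markers
  discriminating <- dplyr::filter(
    markers, startsWith(.data$classification, "discriminating"))
  final <- if (keep_only_discriminating) discriminating else markers
  if (nrow(final)) {
    final <- assign_ij_names(final, chrom_order = names(reference))
  } else {
    final$marker_name <- character(0)
  }
  pmap <- physical_map(final, lens)

  stage_counts <- tibble::tibble(
    stage = c("input_records", "distinct_indels",
              paste0("common_", target_group), "specific",
              paste0("specific_gt", min_indel_len, "bp"),
              "designable_templates", "primer_pairs", "epcr_ok",
              "discriminating"),
    n = c(n_input, n_distinct, nrow(cat_target$common), nrow(specific_all),
          nrow(specific), nrow(designable), nrow(pairs),
          sum(markers$epcr_status == "ok"), nrow(discriminating))
  )

  res <- structure(
    list(
      stage_counts = stage_counts,
      markers = final,
      all_markers = markers,
      designed = designed,
      specific = specific,
      catalogs = setNames(list(cat_target, cat_other),
                          c(target_group, other_group)),
      density = setNames(list(density_target, density_other),
                         c(target_group, other_group)),
      between_group = group_diff,
      physical_map = pmap,
      target_group = target_group,
      other_group = other_group,
      classification_counts = dplyr::count(markers, .data$classification)
    ),
    class = "indel_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Predict per-allele sizes and classify every designed pair on the cohort.
epcr_classify <- function(pairs, templates, calls, target_group, other_group,
                          gel, max_product) {
  samples <- calls |>
    dplyr::distinct(.data$sample_id, .data$group)
  groups <- setNames(samples$group, samples$sample_id)
  carried <- paste(
    calls$sample_id,
    variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  )
  het <- setNames(
    grepl("0", gsub("\\|", "/", calls$gt)) & grepl("[1-9]", calls$gt),
    carried
  )
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    tpl <- templates[templates$chrom == p$chrom & templates$pos == p$pos &
                     templates$alt == p$alt, ][1, ]
    sizes <- predict_allele_sizes(p, tpl, max_product)
    out <- dplyr::bind_cols(
      p, tibble::tibble(size_ref = sizes$size_ref, size_alt = sizes$size_alt,
                        epcr_status = sizes$status)
    )
    if (sizes$status != "ok") {
      out$classification <- "failed"
      return(out)
    }
    key <- variant_key(p$chrom, p$pos, p$ref, p$alt)
    band_sets <- lapply(samples$sample_id, function(s) {
      id <- paste(s, key)
      if (id %in% names(het)) {
        if (het[[id]]) c(sizes$size_ref, sizes$size_alt) else sizes$size_alt
      } else {
        sizes$size_ref
      }
    })
    names(band_sets) <- samples$sample_id
    cls <- classify_marker(band_sets, groups)
    if (startsWith(cls, "discriminating") &&
        !resolvable(sizes$size_ref, sizes$size_alt, gel)) {
      cls <- "monomorphic"  # alleles co-migrate on this gel
    }
    out$classification <- cls
    out
  })
  markers <- if (length(rows)) purrr::list_rbind(rows) else
    dplyr::mutate(pairs[0, ], size_ref = integer(), size_alt = integer(),
                  epcr_status = character(), classification = character())
  list(markers = markers)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(res$stage_counts, p("stage_counts.tsv"))
  for (g in names(res$catalogs)) {
    readr::write_tsv(tidy(res$catalogs[[g]]), p(paste0("common_", g, ".tsv")))
    write_density_table(res$density[[g]],
                        p(paste0("density_", g, ".tsv")),
                        p(paste0("density_windows_", g, ".tsv")))
  }
  readr::write_tsv(res$specific, p("specific_indels.tsv"))
  readr::write_tsv(res$between_group, p("between_group_diff.tsv"))
  if (nrow(res$markers)) write_marker_table(res$markers, p("markers.tsv"))
  readr::write_tsv(res$physical_map$counts, p("physical_map_counts.tsv"))
  readr::write_tsv(res$physical_map$markers, p("physical_map.tsv"))
  readr::write_tsv(res$classification_counts, p("classification_counts.tsv"))
  invisible(out_dir)
}

#' @export
print.indel_pipeline <- function(x, ...) {
  cat("<indel_pipeline> target group '", x$target_group, "'\n", sep = "")
  print(x$stage_counts, n = Inf)
  invisible(x)
}

#' Tidy / glance methods for pipeline results
#'
#' `tidy()` returns the per-stage filter counts; `glance()` a one-row
#' summary.
#'
#' @param x An `indel_pipeline`.
#' @param ... Unused.
#' @export
tidy.indel_pipeline <- function(x, ...) x$stage_counts

#' @rdname tidy.indel_pipeline
#' @export
glance.indel_pipeline <- function(x, ...) {
  n <- setNames(x$stage_counts$n, x$stage_counts$stage)
  tibble::tibble(
    target_group = x$target_group,
    n_specific = unname(n[grep("^specific_gt", names(n))]),
    n_pairs = unname(n[["primer_pairs"]]),
    n_discriminating = unname(n[["discriminating"]]),
    n_markers_named = nrow(x$markers)
  )
}

#' Pipeline configuration from files
#'
#' Reads a YAML (or flat `key: value`) configuration describing a
#' file-based run: reference FASTA, a directory of single-sample VCFs, a
#' sample table mapping VCF/sample to group, optional GFF3, output
#' directory and any scalar overrides of the design constraints and gel
#' model.
#'
#' @param path YAML config path.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}

#' Run the pipeline from a file-based configuration
#'
#' @param config Path to a YAML config, or the list from
#'   [read_pipeline_config()]. Recognized keys: `reference` (FASTA),
#'   `vcf_dir`, `samples` (TSV with `sample_id`, `group`), `target_group`,
#'   `out_dir`, `min_indel_len`, `flank`, `window`, `gff`,
#'   `gel` (list), `constraints` (list of [design_constraints()]
#'   arguments).
#' @return An `indel_pipeline` object.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (k in c("reference", "vcf_dir", "samples")) {
    if (is.null(config[[k]])) stop("config is missing '", k, "'", call. = FALSE)
  }
  reference <- with_stage("genome", read_genome_fasta(config$reference))
  samples <- readr::read_tsv(config$samples, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  if (any(table(samples$group) < 2)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  vcfs <- file.path(config$vcf_dir, paste0(samples$sample_id, ".vcf"))
  missing <- !file.exists(vcfs)
  if (all(missing)) {
    stop("pipeline stage 'catalog': no VCF files found in ",
         config$vcf_dir, call. = FALSE)
  }
  if (any(missing)) {
    stop("missing VCF for sample(s): ",
         paste(samples$sample_id[missing], collapse = ", "), call. = FALSE)
  }
  calls <- with_stage("catalog", read_cohort_vcfs(
    vcfs, sample_ids = as.list(samples$sample_id), groups = samples$group,
    min_qual = config$min_qual))
  constraints <- do.call(design_constraints,
                         config$constraints %||% list())
  gel <- do.call(gel_model, config$gel %||% list())
  res <- run_indel_pipeline(
    reference, calls,
    target_group = config$target_group,
    constraints = constraints, gel = gel,
    min_indel_len = config$min_indel_len %||% 10,
    flank = config$flank %||% 200,
    window = config$window %||% 100000,
    keep_only_discriminating = config$keep_only_discriminating %||% TRUE,
    out_dir = config$out_dir
  )
  if (!is.null(config$gff) && nrow(res$markers)) {
    res$markers <- annotate_linked_genes(res$markers, config$gff,
                                         window = config$link_window %||% 50000)
  }
  res
}
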