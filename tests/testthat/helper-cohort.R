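# Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small cohort: fast, exercises every class
small_design <- function(seed = 7) {
  cohort_design(
    n_chromosomes = 2, chrom_length = 60000, n_per_group = 3,
    n_group_specific = 12, n_shared = 6, n_private = 4, n_sub_threshold = 4,
    seed = seed
  )
}

small_cohort <- function() memo("small_cohort", simulate_cohort(small_design()))

small_pipeline <- function() {
  memo("small_pipeline", {
    cohort <- small_cohort()
    run_indel_pipeline(cohort$reference, cohort$calls,
                       target_group = "javanica")
  })
}

# the full study-condition cohort (2 x 10 samples, 200/100/50/30 planted)
full_cohort <- function() memo("full_cohort", simulate_cohort(cohort_design(seed = 1)))

full_pipeline <- function() {
  memo("full_pipeline", {
    cohort <- full_cohort()
    dir <- file.path(tempdir(), "full_pipeline_run1")
    run_indel_pipeline(cohort$reference, cohort$calls,
                       target_group = "javanica", out_dir = dir)
  })
}

full_pipeline_dir <- function() {
  full_pipeline()
  file.path(tempdir(), "full_pipeline_run1")
}

# random toy genome as named character vector (also used for oracle scans)
random_genome <- function(n_chrom = 2, len = 20000, seed = 11, gc = 0.5) {
  withr::with_seed(seed, {
    s <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
  })
  names(s) <- paste0("chr", seq_len(n_chrom))
  s
}

# random flanking templates over a genome, for design-oracle comparisons
random_templates <- function(genome_strings, n, flank = 100, seed = 3) {
  withr::with_seed(seed, {
    chroms <- sample(names(genome_strings), n, replace = TRUE)
    purrr::map2(chroms, seq_len(n), function(ch, i) {
      s <- genome_strings[[ch]]
      pos <- sample(seq(flank + 80, nchar(s) - flank - 80), 1)
      len <- sample(11:40, 1)
      ref <- substr(s, pos, pos + len)
      tibble::tibble(
        chrom = ch, pos = pos, ref = ref, alt = substr(ref, 1, 1),
        left_flank = substr(s, pos - flank, pos - 1),
        right_flank = substr(s, pos + nchar(ref), pos + nchar(ref) + flank - 1),
        template = substr(s, pos - flank, pos + nchar(ref) + flank - 1),
        template_start = pos - flank,
        truncated = FALSE, designable = TRUE
      )
    })
  })
}

# tiny normalized call-set tibble builder for direct catalog tests
make_calls <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"gt" %in% names(df)) df$gt <- "1/1"
  df$multiallelic <- FALSE
  df$length <- nchar(df$alt) - nchar(df$ref)
  df$normalized <- TRUE
  df
}
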