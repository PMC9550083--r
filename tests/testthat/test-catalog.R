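test_that("normalization left-aligns to the brute-force minimum position", {
  # homopolymer context around position 100: ...GT AAAA C...
  seq <- paste0(
    strrep("ACGT", 24), "GT", "AAAA", "C",
    strrep("TGCA", 24)
  )
  genome <- c(chr1 = seq)
  # insertion of AA called at the right edge of the A-tract (pos 103, REF=T?)
  # use an equivalent right-shifted representation of inserting AA into the
  # tract and check both paths agree with the oracle
  pos <- 102L  # the "A" tract spans 99..102? locate it explicitly
  tract_start <- as.integer(regexpr("GTAAAAC", seq)) + 2L
  v <- list(chrom = "chr1", pos = tract_start + 2L,
            ref = "A", alt = "AAA")  # insertion inside the tract
  norm <- normalize_indels(make_calls(tibble::as_tibble(v)), genome)
  oracle <- oracle_normalize(seq, v$pos, v$ref, v$alt)
  expect_equal(norm$pos, oracle$pos)
  expect_equal(norm$ref, oracle$ref)
  expect_equal(norm$alt, oracle$alt)
  # left-aligned: anchor is the base before the tract
  expect_equal(norm$pos, tract_start - 1L)

  # already-normalized input is a fixed point
  norm2 <- normalize_indels(norm[, c("chrom", "pos", "ref", "alt", "gt",
                                     "multiallelic", "length", "normalized")],
                            genome)
  expect_equal(norm2$pos, norm$pos)
  expect_equal(norm2$ref, norm$ref)
  expect_equal(norm2$alt, norm$alt)
})

test_that("normalization matches the enumeration oracle on random indels", {
  g <- random_genome(n_chrom = 1, len = 4000, seed = 21)
  seq <- g[[1]]
  withr::with_seed(31, {
    for (i in 1:25) {
      pos <- sample(300:3500, 1)
      len <- sample(1:12, 1)
      if (runif(1) < 0.5) {
        ref <- substr(seq, pos, pos)
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = ""))
      } else {
        ref <- substr(seq, pos, pos + len)
        alt <- substr(seq, pos, pos)
      }
      # denormalize: extend both alleles with the next reference base
      nb <- substr(seq, pos + nchar(ref), pos + nchar(ref))
      calls <- make_calls(tibble::tibble(chrom = "chr1", pos = pos,
                                         ref = paste0(ref, nb),
                                         alt = paste0(alt, nb)))
      norm <- normalize_indels(calls, g)
      oracle <- oracle_normalize(seq, pos, paste0(ref, nb), paste0(alt, nb))
      expect_equal(norm$pos, oracle$pos)
      expect_equal(norm$ref, oracle$ref)
      expect_equal(norm$alt, oracle$alt)
    }
  })
})

test_that("normalization rejects non-indels and REF mismatches", {
  genome <- c(chr1 = "ACGTACGTACGT")
  expect_error(
    normalize_indels(make_calls(tibble::tibble(
      chrom = "chr1", pos = 2L, ref = "CGTA", alt = "CGTT")), genome),
    "equal length"
  )
  expect_error(
    normalize_indels(make_calls(tibble::tibble(
      chrom = "chr1", pos = 2L, ref = "GG", alt = "G")), genome),
    "mismatch"
  )
})

test_that("group-common requires presence in every member", {
  calls <- make_calls(tibble::tibble(
    sample_id = c(paste0("s", 1:10), paste0("s", 1:9)),
    group = "g",
    chrom = "chr1",
    pos = c(rep(100L, 10), rep(900L, 9)),
    ref = "A",
    alt = "ATTTTTTTTTTT"
  ))
  cat <- group_common(calls, group = "g")
  expect_equal(cat$common$pos, 100L)
  expect_equal(nrow(cat$union), 2L)
  expect_equal(dim(cat$presence), c(2L, 10L))
  expect_error(group_common(calls[0, ], group = "g"), "empty group")
})

test_that("synthetic target-group common set equals all planted target classes", {
  cohort <- small_cohort()
  d <- cohort$design
  calls <- normalize_indels(cohort$calls, cohort$reference)
  cat_b <- group_common(dplyr::filter(calls, group == "javanica"))
  expect_equal(nrow(cat_b$common),
               d$n_group_specific + d$n_shared + d$n_sub_threshold)
})

test_that("group_common and specific_indels match a brute-force presence scan", {
  withr::with_seed(17, {
    for (rep in 1:3) {
      n_var <- 40; n_a <- 4; n_b <- 5
      keys <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), n_var, replace = TRUE),
        pos = sample(seq(1000, 99000, by = 40), n_var),
        ref = "A",
        alt = paste0("A", vapply(sample(c(5, 12, 20), n_var, TRUE),
                                 function(k) strrep("T", k), character(1)))
      )
      pres_a <- matrix(runif(n_var * n_a) < 0.6, n_var, n_a)
      pres_b <- matrix(runif(n_var * n_b) < 0.6, n_var, n_b)
      long <- function(pres, grp) {
        idx <- which(pres, arr.ind = TRUE)
        make_calls(dplyr::bind_cols(
          keys[idx[, 1], ],
          tibble::tibble(sample_id = paste0(grp, idx[, 2]), group = grp)
        ))
      }
      calls_a <- long(pres_a, "a"); calls_b <- long(pres_b, "b")
      cat_a <- group_common(calls_a, "a"); cat_b <- group_common(calls_b, "b")

      k <- paste(keys$chrom, keys$pos, keys$ref, keys$alt, sep = ":")
      expect_setequal(cat_a$common$key, k[rowSums(pres_a) == n_a])
      expect_setequal(cat_b$common$key, k[rowSums(pres_b) == n_b])

      spec <- specific_indels(cat_b, cat_a, min_len = 10)
      brute <- k[rowSums(pres_b) == n_b & rowSums(pres_a) == 0 &
                   nchar(keys$alt) - 1 > 10]
      expect_setequal(spec$key, brute)

      # mutual specific sets are disjoint
      spec_ab <- specific_indels(cat_a, cat_b, min_len = 10)
      expect_length(intersect(spec$key, spec_ab$key), 0)

      # shrinking a group can only grow its common set
      sub <- group_common(
        dplyr::filter(calls_b, sample_id %in% c("b1", "b2")), "b")
      expect_true(all(cat_b$common$key %in% sub$common$key))
    }
  })
})

test_that("the size filter is strictly 'larger than 10 bp'", {
  mk <- function(len, pos) tibble::tibble(
    chrom = "chr1", pos = pos, ref = "A", alt = paste0("A", strrep("T", len)),
    sample_id = c("t1", "t2"), group = "t"
  )
  calls_t <- make_calls(dplyr::bind_rows(
    mk(10, 100L),   # exactly 10: excluded
    mk(11, 900L)    # 11: included
  ))
  calls_o <- make_calls(tibble::tibble(
    chrom = "chr1", pos = 5000L, ref = "AT", alt = "A",
    sample_id = c("o1", "o2"), group = "o"
  ))
  spec <- specific_indels(group_common(calls_t, "t"),
                          group_common(calls_o, "o"))
  expect_equal(spec$pos, 900L)
  expect_equal(spec$length, 11L)
  expect_equal(spec$rule_trace, "other_group_reference")
})

test_that("an identical allele in the other group disqualifies the locus", {
  both <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A",
                         alt = paste0("A", strrep("G", 15)))
  calls_t <- make_calls(dplyr::bind_rows(both, both) |>
    dplyr::mutate(sample_id = c("t1", "t2"), group = "t"))
  # other group: one sample has the same allele
  calls_o <- make_calls(both |>
    dplyr::mutate(sample_id = "o1", group = "o"))
  calls_o2 <- make_calls(tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = paste0("A", strrep("C", 12)),
    sample_id = "o2", group = "o"))
  spec <- specific_indels(group_common(calls_t, "t"),
                          group_common(dplyr::bind_rows(calls_o, calls_o2), "o"))
  expect_equal(nrow(spec), 0)

  # different-length ALT in the other group still qualifies the locus
  spec2 <- specific_indels(group_common(calls_t, "t"),
                           group_common(calls_o2, "o"))
  expect_equal(nrow(spec2), 1)
  expect_equal(spec2$rule_trace, "other_group_different_alt")
})

test_that("density tables respect window bookkeeping", {
  lens <- tibble::tibble(chrom = "chr1", length = 500000L)
  v <- tibble::tibble(chrom = "chr1", pos = as.integer(seq(5000, 495000,
                                                           length.out = 50)))
  dt <- density_table(v, lens)
  expect_equal(dt$per_chromosome$density, 100)
  expect_equal(nrow(dt$windows), 5)
  expect_equal(sum(dt$windows$n), 50)

  # empty set
  dt0 <- density_table(v[0, ], lens)
  expect_true(all(dt0$windows$n == 0))
  expect_equal(dt0$per_chromosome$n, 0L)

  # 1-based position 100,000 falls in the first window (half-open, 0-based)
  dt1 <- density_table(tibble::tibble(chrom = "chr1", pos = 100000L), lens)
  expect_equal(dt1$windows$n, c(1L, 0L, 0L, 0L, 0L))
  dt2 <- density_table(tibble::tibble(chrom = "chr1", pos = 100001L), lens)
  expect_equal(dt2$windows$n, c(0L, 1L, 0L, 0L, 0L))

  expect_error(density_table(tibble::tibble(chrom = "chr1", pos = 500001L),
                             lens), "outside")
})

test_that("density invariants hold on a synthetic run", {
  res <- small_pipeline()
  for (g in names(res$density)) {
    dt <- res$density[[g]]
    per_win <- tapply(dt$windows$n, dt$windows$chrom, sum)
    per_chr <- setNames(dt$per_chromosome$n, dt$per_chromosome$chrom)
    expect_equal(as.integer(per_win[names(per_chr)]), unname(per_chr))
    expect_equal(dt$per_chromosome$density,
                 dt$per_chromosome$n / dt$per_chromosome$length_mb)
  }
})

test_that("between-group difference is the per-chromosome symmetric difference", {
  mk_cat <- function(positions, alt, grp) {
    calls <- make_calls(tibble::tibble(
      chrom = "chr1", pos = positions, ref = "A", alt = alt,
      sample_id = "x1", group = grp
    ))
    calls <- dplyr::bind_rows(calls, dplyr::mutate(calls, sample_id = "x2"))
    group_common(calls, grp)
  }
  a <- mk_cat(c(100L, 200L, 300L), "ATTTTTTTTTTT", "a")
  b <- mk_cat(c(1000L, 2000L, 3000L, 4000L), "ATTTTTTTTTTT", "b")
  d <- between_group_diff(a, b)
  expect_equal(sum(d$n_diff), 7L)
  expect_equal(attr(between_group_diff(a, a), "mean_per_chromosome"), 0)

  # synthetic cohort: symmetric difference = planted specifics + sub-threshold
  cohort <- small_cohort()
  calls <- normalize_indels(cohort$calls, cohort$reference)
  cat_i <- group_common(dplyr::filter(calls, group == "indica"))
  cat_j <- group_common(dplyr::filter(calls, group == "javanica"))
  dd <- between_group_diff(cat_i, cat_j)
  expected <- sum(cohort$truth$class %in% c("group_specific", "sub_threshold"))
  expect_equal(sum(dd$n_diff), expected)
})
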