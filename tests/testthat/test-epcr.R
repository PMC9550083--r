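test_that("in-silico PCR finds constructed amplicons", {
  f <- "ACGGTCAGGTCAATCGGATCA"
  r <- "TGACCTGGTAACCGTAGGCAT"
  spacer <- strrep("CATG", 25)  # 100 nt
  tpl <- paste0("GGGG", f, spacer, oracle_revcomp(r), "TTTT")
  amp <- insilico_pcr(f, r, tpl)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$size, nchar(f) + 100 + nchar(r))
  expect_equal(amp$start, 5L)

  # no reverse site -> no product
  expect_equal(nrow(insilico_pcr(f, r, paste0("GG", f, spacer))), 0)

  # duplicated forward site upstream -> two amplicons, matches the oracle
  tpl2 <- paste0(f, strrep("GTCA", 10), f, spacer, oracle_revcomp(r))
  amp2 <- insilico_pcr(f, r, tpl2)
  expect_equal(nrow(amp2), 2)
  o <- oracle_pcr(f, r, tpl2)
  expect_equal(amp2$start, o$start[order(o$start)])
  expect_equal(amp2$size, o$size[order(o$start)])

  # size cap applies
  expect_equal(nrow(insilico_pcr(f, r, tpl, max_product = 100)), 0)
})

test_that("in-silico PCR agrees with the naive scan on random sequences", {
  withr::with_seed(41, {
    for (i in 1:5) {
      s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
      f <- substr(s, 100, 119)
      r <- oracle_revcomp(substr(s, 700, 721))
      amp <- insilico_pcr(f, r, s)
      o <- oracle_pcr(f, r, s)
      expect_equal(nrow(amp), nrow(o))
      if (nrow(o)) {
        oo <- o[order(o$start, o$size), ]
        expect_equal(amp$size, oo$size)
      }
    }
  })
})

test_that("allele size prediction follows the InDel length exactly", {
  res <- small_pipeline()
  m <- res$all_markers
  ok <- m[m$epcr_status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_equal(abs(ok$size_ref - ok$size_alt), abs(ok$length))
  expect_equal(ok$size_ref, ok$product_size_ref)

  # arithmetic on constructed cases: deletion shrinks, insertion grows
  g <- random_genome(1, 4000, seed = 51)
  seq <- g[[1]]
  del <- tibble::tibble(chrom = "chr1", pos = 2000L,
                        ref = substr(seq, 2000, 2020),
                        alt = substr(seq, 2000, 2000))
  tpl <- extract_flanks(del, g, flank = 200)
  pair <- design_pair(as.list(tpl[1, ]), design_constraints(), g)
  skip_if(is.null(pair), "no pair on this fixture")
  sz <- predict_allele_sizes(pair, tpl[1, ])
  expect_equal(sz$status, "ok")
  expect_equal(sz$size_ref - sz$size_alt, 20L)
})

test_that("gel resolvability applies threshold and size cap", {
  page <- gel_model("page")
  expect_true(resolvable(250, 230, page))
  expect_false(resolvable(250, 245, page))
  expect_true(resolvable(250, 240, page))   # boundary: diff == 10
  expect_false(resolvable(1200, 1100, page))  # beyond max_size
  agarose <- gel_model("agarose")
  expect_false(resolvable(250, 235, agarose))
  expect_true(resolvable(250, 229, agarose))
})

test_that("marker classification covers all outcome categories", {
  groups <- c(i1 = "ind", i2 = "ind", i3 = "ind",
              j1 = "jav", j2 = "jav", j3 = "jav")
  bs <- function(...) {
    x <- list(...)
    names(x) <- names(groups)
    x
  }
  # perfect biallelic split
  expect_equal(classify_marker(bs(250, 250, 250, 230, 230, 230), groups),
               "discriminating_biallelic")
  # three band sets, still group-separating
  expect_equal(classify_marker(bs(250, 250, 260, 230, 230, 230), groups),
               "discriminating_multiallelic")
  # identical everywhere
  expect_equal(classify_marker(bs(250, 250, 250, 250, 250, 250), groups),
               "monomorphic")
  # polymorphic but overlapping groups
  expect_equal(classify_marker(bs(250, 230, 250, 230, 230, 230), groups),
               "polymorphic_nondiscriminating")
  # any empty band set fails the marker
  expect_equal(classify_marker(bs(250, numeric(0), 250, 230, 230, 230),
                               groups), "failed")
  # heterozygous two-band profiles are their own band set
  expect_equal(classify_marker(bs(250, 250, 250, c(230, 250), c(230, 250),
                                  c(230, 250)), groups),
               "discriminating_biallelic")
  expect_error(classify_marker(list(x1 = 250), groups), "group label")
})

test_that("IJ names follow (chromosome, position) order and are stable", {
  m <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(500L, 100L, 50L)
  )
  named <- assign_ij_names(m)
  expect_equal(named$marker_name, c("IJ1", "IJ2", "IJ3"))
  expect_equal(named$pos, c(100L, 500L, 50L))
  # idempotent
  expect_equal(assign_ij_names(named)$marker_name, named$marker_name)
  # single marker
  expect_equal(assign_ij_names(m[1, ])$marker_name, "IJ1")
  # natural chromosome order: chr2 before chr10
  m2 <- tibble::tibble(chrom = c("chr10", "chr2"), pos = c(1L, 1L))
  expect_equal(assign_ij_names(m2)$chrom, c("chr2", "chr10"))
  # zero-padding keeps ordinals sortable
  m3 <- tibble::tibble(chrom = "chr1", pos = seq(100L, 1190L, by = 10L))
  n3 <- assign_ij_names(m3)
  expect_equal(n3$marker_name[1], "IJ001")
  expect_equal(n3$marker_name[110], "IJ110")
  expect_error(assign_ij_names(tibble::tibble(chrom = c("chr1", "chr1"),
                                              pos = c(5L, 5L))),
               "duplicate")
})

test_that("physical map conserves counts and positional order", {
  res <- small_pipeline()
  cohort <- small_cohort()
  pm <- res$physical_map
  expect_equal(sum(pm$counts$n), nrow(res$markers))
  expect_equal(nrow(pm$counts), length(cohort$reference))
  ord <- order(match(pm$markers$chrom, pm$counts$chrom), pm$markers$pos)
  expect_equal(ord, seq_len(nrow(pm$markers)))

  # an empty chromosome is still reported, with count 0
  lens <- tibble::tibble(chrom = c("chr1", "chrEmpty"),
                         length = c(1000L, 1000L))
  pm2 <- physical_map(
    tibble::tibble(marker_name = "IJ1", chrom = "chr1", pos = 10L), lens)
  expect_equal(pm2$counts$n, c(1L, 0L))
})

test_that("GFF3 gene annotation links markers within the window", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=geneA",
    "chr1\ttest\tgene\t90000\t95000\t.\t-\t.\tID=geneB"
  ), gff)
  m <- tibble::tibble(chrom = "chr1", pos = c(2500L, 60000L))
  ann <- annotate_linked_genes(m, gff, window = 50000)
  expect_equal(ann$linked_genes, c("geneA", "geneB"))
  ann2 <- annotate_linked_genes(m, gff, window = 1000)
  expect_true(is.na(ann2$linked_genes[2]))
})
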