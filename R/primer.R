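#' Primer design constraints
#'
#' Container for every tunable of the primer-design stage. Defaults follow
#' the marker-development protocol this package implements: primer length
#' 18–25 nt (optimum 21), melting temperature 55–63 °C (optimum 58),
#' GC 40–60 %, reference-allele product 150–300 bp, and exact genome
#' uniqueness (a primer must occur exactly once in the reference, counting
#' both strands).
#'
#' The pair penalty minimized by [design_pair()] is
#' `w_tm * (|Tm_f - tm_opt| + |Tm_r - tm_opt|) +
#'  w_len * (|len_f - len_opt| + |len_r - len_opt|) +
#'  w_product * |product_ref - product_opt|`.
#'
#' @param len_range,len_opt Primer length range and optimum (nt).
#' @param tm_range,tm_opt Melting-temperature range and optimum (°C).
#' @param gc_range GC-fraction range.
#' @param product_range Allowed reference-allele amplicon size (bp).
#' @param product_opt Amplicon size optimum (default mid-range, 225 bp).
#' @param max_pair_tm_diff Maximum |Tm_f − Tm_r| (°C).
#' @param max_genome_hits Required exact genome occurrence count (1).
#' @param tm_method `"santalucia"` (nearest-neighbor) or `"wallace"`.
#' @param na_mM Monovalent cation concentration (mM) for the NN model.
#' @param primer_nM Primer strand concentration (nM) for the NN model.
#' @param weights Penalty weights `c(tm=, len=, product=)` in 1/°C, 1/nt,
#'   1/bp.
#' @param dimer_check Apply the minimal 3'-end cross/self-complementarity
#'   filter.
#' @param dimer_k 3'-terminal k-mer length for the dimer filter.
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(len_range = c(18L, 25L), len_opt = 21L,
                               tm_range = c(55, 63), tm_opt = 58,
                               gc_range = c(0.40, 0.60),
                               product_range = c(150L, 300L),
                               product_opt = 225L,
                               max_pair_tm_diff = 3,
                               max_genome_hits = 1L,
                               tm_method = c("santalucia", "wallace"),
                               na_mM = 50, primer_nM = 50,
                               weights = c(tm = 1, len = 0.5, product = 0.02),
                               dimer_check = TRUE, dimer_k = 4L) {
  tm_method <- match.arg(tm_method)
  stopifnot(
    len_range[1] <= len_range[2],
    len_opt >= len_range[1], len_opt <= len_range[2],
    tm_range[1] <= tm_range[2], tm_opt >= tm_range[1], tm_opt <= tm_range[2],
    gc_range[1] <= gc_range[2],
    product_range[1] <= product_range[2],
    product_opt >= product_range[1], product_opt <= product_range[2],
    max_pair_tm_diff > 0, max_genome_hits >= 1,
    all(c("tm", "len", "product") %in% names(weights))
  )
  structure(
    list(len_range = as.integer(len_range), len_opt = as.integer(len_opt),
         tm_range = tm_range, tm_opt = tm_opt, gc_range = gc_range,
         product_range = as.integer(product_range),
         product_opt = as.integer(product_opt),
         max_pair_tm_diff = max_pair_tm_diff,
         max_genome_hits = as.integer(max_genome_hits),
         tm_method = tm_method, na_mM = na_mM, primer_nM = primer_nM,
         weights = weights, dimer_check = isTRUE(dimer_check),
         dimer_k = as.integer(dimer_k)),
    class = "design_constraints"
  )
}

#' Extract flanking templates around InDels
#'
#' For each variant, takes `flank` nt of reference sequence on both sides
#' of the InDel site; the template is `left flank + REF allele + right
#' flank` and is an exact substring of the reference. Templates truncated
#' by a chromosome end are flagged; a template with either flank shorter
#' than 150 nt is marked undesignable.
#'
#' @param variants Tibble of normalized variants (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param genome Reference genome.
#' @param flank Flank width in nt (default 200).
#' @return Input tibble plus `left_flank`, `right_flank`, `template`,
#'   `template_start` (1-based), `truncated`, `designable`.
#' @export
extract_flanks <- function(variants, genome, flank = 200) {
  genome <- as_genome(genome)
  missing_chr <- setdiff(unique(variants$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) not in reference: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  seqs <- setNames(as.character(genome), names(genome))
  lens <- setNames(nchar(seqs), names(seqs))
  left_start <- pmax(1L, variants$pos - as.integer(flank))
  ref_end <- variants$pos + nchar(variants$ref) - 1L
  right_end <- pmin(lens[variants$chrom], ref_end + as.integer(flank))
  left <- substr(seqs[variants$chrom], left_start, variants$pos - 1L)
  right <- substr(seqs[variants$chrom], ref_end + 1L, right_end)
  site <- substr(seqs[variants$chrom], variants$pos, ref_end)
  bad <- site != variants$ref
  if (any(bad)) {
    i <- which(bad)[1]
    stop("REF allele mismatch at ", variants$chrom[i], ":", variants$pos[i],
         "; normalize against this reference first", call. = FALSE)
  }
  dplyr::mutate(
    variants,
    left_flank = unname(left),
    right_flank = unname(right),
    template = paste0(left, variants$ref, right),
    template_start = as.integer(left_start),
    truncated = nchar(left) < flank | nchar(right) < flank,
    designable = nchar(left) >= 150 & nchar(right) >= 150
  )
}

#' GC fraction of DNA sequences
#'
#' `(#G + #C) / length`; `N` and other ambiguity codes count toward the
#' denominator only. Candidates containing `N` are rejected upstream of
#' design; here they simply yield a value.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of GC fractions.
#' @examples gc_fraction(c("ATGC", "AAAA", "GCGC"))
#' @export
gc_fraction <- function(seq) {
  stopifnot(all(nchar(seq) > 0))
  vapply(strsplit(toupper(seq), ""), function(b) mean(b %in% c("G", "C")),
         numeric(1))
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# Enthalpy kcal/mol, entropy cal/(mol K), 5'->3' dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Duplex initiation per terminal base
INIT_DH <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
INIT_DS <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)
GAS_R <- 1.987  # cal/(mol K)

#' Primer melting temperature
#'
#' Default is the nearest-neighbor model with the SantaLucia (1998) unified
#' parameter set, entropy salt correction `0.368 (N-1) ln[Na+]`, 50 mM
#' monovalent cations and 50 nM primer strand concentration:
#' `Tm = 1000 dH / (dS_salt + R ln C) - 273.15`. The Wallace rule
#' (`2(A+T) + 4(G+C)`) is available as a simple closed-form mode for short
#' oligos.
#'
#' @param seq Character vector of ACGT sequences (10–40 nt for the NN
#'   model).
#' @param method `"santalucia"` or `"wallace"`.
#' @param na_mM Monovalent cation concentration in mM.
#' @param primer_nM Primer strand concentration in nM.
#' @return Numeric vector of Tm in °C.
#' @examples melting_temperature("ACGTACGTACGTAC", method = "wallace")
#' @export
melting_temperature <- function(seq, method = c("santalucia", "wallace"),
                                na_mM = 50, primer_nM = 50) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) {
    stop("melting_temperature: sequences must contain only A/C/G/T",
         call. = FALSE)
  }
  if (method == "wallace") {
    bases <- strsplit(seq, "")
    return(vapply(bases, function(b) {
      2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
    }, numeric(1)))
  }
  n <- nchar(seq)
  if (any(n < 10 | n > 40)) {
    stop("nearest-neighbor Tm expects sequences of 10-40 nt", call. = FALSE)
  }
  vapply(seq, function(s) {
    b <- strsplit(s, "")[[1]]
    di <- paste0(head(b, -1), tail(b, -1))
    dh <- sum(NN_DH[di]) + INIT_DH[[b[1]]] + INIT_DH[[b[length(b)]]]
    ds <- sum(NN_DS[di]) + INIT_DS[[b[1]]] + INIT_DS[[b[length(b)]]]
    ds <- ds + 0.368 * (length(b) - 1) * log(na_mM / 1000)
    1000 * dh / (ds + GAS_R * log(primer_nM * 1e-9)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Reverse complement
#' @param seq Character vector of DNA sequences.
#' @return Character vector.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Exact genome occurrence count of primers
#'
#' Number of exact, full-length occurrences of each primer on either strand
#' of the whole reference. A usable primer must occur exactly once.
#'
#' @param primers Character vector of ACGT primers.
#' @param genome Reference genome.
#' @return Integer vector of hit counts.
#' @export
specificity_hits <- function(primers, genome) {
  genome <- as_genome(genome)
  if (any(grepl("[^ACGT]", toupper(primers)))) {
    stop("primers must be ACGT-only", call. = FALSE)
  }
  vapply(toupper(primers), function(p) {
    fwd <- sum(Biostrings::vcountPattern(p, genome))
    rev <- sum(Biostrings::vcountPattern(reverse_complement(p), genome))
    as.integer(fwd + rev)
  }, integer(1), USE.NAMES = FALSE)
}

# All candidate primers (start, len, tm, gc) over one flank sequence via
# cumulative NN sums: O(1) per candidate after an O(L) pass.
enumerate_candidates <- function(flank, constraints) {
  L <- nchar(flank)
  if (L < constraints$len_range[1]) {
    return(tibble::tibble(start = integer(), len = integer(),
                          tm = numeric(), gc = numeric()))
  }
  b <- strsplit(flank, "")[[1]]
  valid <- b %in% c("A", "C", "G", "T")
  di <- paste0(head(b, -1), tail(b, -1))
  dh_steps <- unname(NN_DH[di]); dh_steps[is.na(dh_steps)] <- 0
  ds_steps <- unname(NN_DS[di]); ds_steps[is.na(ds_steps)] <- 0
  cdh <- c(0, cumsum(dh_steps))
  cds <- c(0, cumsum(ds_steps))
  cgc <- c(0, cumsum(b %in% c("G", "C")))
  cbad <- c(0, cumsum(!valid))
  rln_c <- GAS_R * log(constraints$primer_nM * 1e-9)
  ln_na <- log(constraints$na_mM / 1000)
  wallace <- constraints$tm_method == "wallace"

  out <- purrr::map(seq(constraints$len_range[1], constraints$len_range[2]),
    function(len) {
      if (L < len) return(NULL)
      a <- seq_len(L - len + 1L)
      has_bad <- (cbad[a + len] - cbad[a]) > 0
      gc_n <- cgc[a + len] - cgc[a]
      if (wallace) {
        tm <- 2 * (len - gc_n) + 4 * gc_n
      } else {
        first <- b[a]; last <- b[a + len - 1L]
        dh <- cdh[a + len - 1L] - cdh[a] + INIT_DH[first] + INIT_DH[last]
        ds <- cds[a + len - 1L] - cds[a] + INIT_DS[first] + INIT_DS[last] +
          0.368 * (len - 1) * ln_na
        tm <- 1000 * dh / (ds + rln_c) - 273.15
      }
      tibble::tibble(start = a, len = len, tm = unname(tm),
                     gc = gc_n / len)[!has_bad, ]
    })
  purrr::list_rbind(out)
}

filter_candidates <- function(cand, constraints) {
  dplyr::filter(
    cand,
    .data$tm >= constraints$tm_range[1], .data$tm <= constraints$tm_range[2],
    .data$gc >= constraints$gc_range[1], .data$gc <= constraints$gc_range[2]
  )
}

# 3'-end cross-complementarity: TRUE when the 3'-terminal k-mer of `a` can
# anneal to the 3'-terminal k-mer of `b` (a >> b extension-competent dimer).
dimer_3prime <- function(a, b, k = 4) {
  tail_a <- substr(a, nchar(a) - k + 1, nchar(a))
  tail_b <- substr(b, nchar(b) - k + 1, nchar(b))
  reverse_complement(tail_a) == tail_b
}

#' Design the optimal primer pair for one flanking template
#'
#' Enumerates every candidate forward primer in the left flank and every
#' candidate reverse primer (reverse complement of a right-flank
#' substring), filters by length, Tm, GC, pair Tm difference, the 3'-end
#' dimer filter, reference-product size range and exact genome uniqueness,
#' and returns the surviving pair with the smallest penalty (see
#' [design_constraints()]). Ties break by leftmost forward start, then
#' shortest product. Returns `NULL` when no pair survives.
#'
#' Genome-uniqueness is checked lazily in penalty order (with per-primer
#' caching), so the returned pair is the global optimum among fully valid
#' pairs without testing every candidate against the genome.
#'
#' @param template One row of [extract_flanks()] output (as list/row).
#' @param constraints A [design_constraints()].
#' @param genome Reference genome (for uniqueness screening).
#' @param hit_cache Optional environment used to cache per-primer genome
#'   hit counts across calls.
#' @return A one-row tibble (`forward`, `reverse`, `f_start`, `r_start`
#'   template coordinates, `f_len`, `r_len`, `tm_f`, `tm_r`, `gc_f`,
#'   `gc_r`, `product_size_ref`, `product_size_alt`, `penalty`) or `NULL`.
#' @export
design_pair <- function(template, constraints = design_constraints(),
                        genome, hit_cache = NULL) {
  if (isFALSE(template$designable)) return(NULL)
  left <- template$left_flank
  right <- template$right_flank
  site_len <- nchar(template$ref)
  lf <- nchar(left)
  indel_len <- nchar(template$alt) - nchar(template$ref)

  f_cand <- filter_candidates(enumerate_candidates(left, constraints), constraints)
  r_cand <- filter_candidates(enumerate_candidates(right, constraints), constraints)
  if (nrow(f_cand) == 0 || nrow(r_cand) == 0) return(NULL)

  # template coordinates: forward starts; reverse binding-site end
  f_start <- f_cand$start
  r_end <- lf + site_len + r_cand$start + r_cand$len - 1L

  # pair grid
  grid <- tidyr::expand_grid(fi = seq_len(nrow(f_cand)),
                             ri = seq_len(nrow(r_cand)))
  grid$product <- r_end[grid$ri] - f_start[grid$fi] + 1L
  grid <- grid[grid$product >= constraints$product_range[1] &
               grid$product <= constraints$product_range[2], ]
  if (nrow(grid) == 0) return(NULL)
  tm_d <- abs(f_cand$tm[grid$fi] - r_cand$tm[grid$ri])
  grid <- grid[tm_d <= constraints$max_pair_tm_diff, ]
  if (nrow(grid) == 0) return(NULL)

  w <- constraints$weights
  pen <- w[["tm"]] * (abs(f_cand$tm[grid$fi] - constraints$tm_opt) +
                      abs(r_cand$tm[grid$ri] - constraints$tm_opt)) +
    w[["len"]] * (abs(f_cand$len[grid$fi] - constraints$len_opt) +
                  abs(r_cand$len[grid$ri] - constraints$len_opt)) +
    w[["product"]] * abs(grid$product - constraints$product_opt)
  ord <- order(pen, f_cand$start[grid$fi], grid$product)

  if (is.null(hit_cache)) hit_cache <- new.env(parent = emptyenv())
  primer_seq_f <- function(i) substr(left, f_cand$start[i],
                                     f_cand$start[i] + f_cand$len[i] - 1L)
  primer_seq_r <- function(i) reverse_complement(
    substr(right, r_cand$start[i], r_cand$start[i] + r_cand$len[i] - 1L))
  hits_of <- function(p) {
    if (is.null(hit_cache[[p]])) hit_cache[[p]] <- specificity_hits(p, genome)
    hit_cache[[p]]
  }

  for (k in ord) {
    fi <- grid$fi[k]; ri <- grid$ri[k]
    fseq <- primer_seq_f(fi); rseq <- primer_seq_r(ri)
    if (constraints$dimer_check) {
      kk <- constraints$dimer_k
      if (dimer_3prime(fseq, rseq, kk) || dimer_3prime(fseq, fseq, kk) ||
          dimer_3prime(rseq, rseq, kk)) next
    }
    if (hits_of(fseq) != constraints$max_genome_hits) next
    if (hits_of(rseq) != constraints$max_genome_hits) next
    return(tibble::tibble(
      forward = fseq, reverse = rseq,
      f_start = f_cand$start[fi],
      r_start = lf + site_len + r_cand$start[ri],
      f_len = f_cand$len[fi], r_len = r_cand$len[ri],
      tm_f = f_cand$tm[fi], tm_r = r_cand$tm[ri],
      gc_f = f_cand$gc[fi], gc_r = r_cand$gc[ri],
      product_size_ref = grid$product[k],
      product_size_alt = grid$product[k] + indel_len,
      penalty = pen[k]
    ))
  }
  NULL
}

#' Design primer pairs for a set of flanking templates
#'
#' Runs [design_pair()] on every template and collects results into a
#' marker table; templates where no pair survives are kept with
#' `status = "no_pair"` (design failure is a counted outcome, not an
#' error).
#'
#' @param templates Output of [extract_flanks()].
#' @param genome Reference genome.
#' @param constraints A [design_constraints()].
#' @return Tibble: variant columns + primer columns + `status`
#'   (`"ok"`, `"no_pair"`, `"undesignable"`).
#' @export
design_primers <- function(templates, genome,
                           constraints = design_constraints()) {
  genome <- as_genome(genome)
  cache <- new.env(parent = emptyenv())
  rows <- purrr::map(seq_len(nrow(templates)), function(i) {
    tpl <- as.list(templates[i, ])
    base <- tibble::tibble(
      chrom = tpl$chrom, pos = tpl$pos, ref = tpl$ref, alt = tpl$alt,
      length = nchar(tpl$alt) - nchar(tpl$ref),
      template_start = tpl$template_start
    )
    if (isFALSE(tpl$designable)) {
      return(dplyr::mutate(base, status = "undesignable"))
    }
    pair <- design_pair(tpl, constraints, genome, hit_cache = cache)
    if (is.null(pair)) return(dplyr::mutate(base, status = "no_pair"))
    dplyr::bind_cols(base, pair, tibble::tibble(status = "ok"))
  })
  purrr::list_rbind(rows)
}
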