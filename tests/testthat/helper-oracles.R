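# Independent oracles: simple loop/scan implementations used only to check
# the package's vectorized/optimized code paths.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

# Nearest-neighbor Tm, plain per-dinucleotide loop (SantaLucia 1998 unified
# set, entropy salt correction, Tm = 1000 dH / (dS + R ln C) - 273.15).
oracle_tm <- function(seq, na_molar = 0.05, conc = 50e-9) {
  dh_tab <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
              TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
              GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
              CC = -8.0)
  ds_tab <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
              TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
              GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              CC = -19.9)
  b <- strsplit(toupper(seq), "")[[1]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(b) - 1)) {
    di <- paste0(b[i], b[i + 1])
    dh <- dh + dh_tab[[di]]
    ds <- ds + ds_tab[[di]]
  }
  for (end in c(b[1], b[length(b)])) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (length(b) - 1) * log(na_molar)
  1000 * dh / (ds + 1.987 * log(conc)) - 273.15
}

# Exact full-length occurrences of `pattern` on the plus strand of one
# string, naive O(n*m) sliding window.
oracle_scan <- function(pattern, subject) {
  n <- nchar(subject); m <- nchar(pattern)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1)) {
    if (substr(subject, i, i + m - 1) == pattern) hits <- c(hits, i)
  }
  hits
}

# Both-strand exact hit count over a genome given as named character vector.
oracle_hits <- function(primer, genome_strings) {
  sum(vapply(genome_strings, function(s) {
    length(oracle_scan(primer, s)) +
      length(oracle_scan(oracle_revcomp(primer), s))
  }, numeric(1)))
}

# Naive all-pairs in-silico PCR: forward site strictly upstream of the
# reverse binding site, size capped.
oracle_pcr <- function(forward, reverse, sequence, max_product = 2000) {
  f <- oracle_scan(toupper(forward), toupper(sequence))
  r <- oracle_scan(oracle_revcomp(reverse), toupper(sequence))
  out <- list()
  for (fs in f) {
    for (rs in r) {
      if (rs >= fs + nchar(forward)) {
        size <- rs + nchar(reverse) - fs
        if (size <= max_product) out[[length(out) + 1]] <- c(fs, size)
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), size = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], size = m[, 2])
}

# Exhaustive primer-pair enumeration: every substring pair, full filters,
# lazy naive uniqueness check in penalty order. Returns the optimum penalty
# (NA when nothing survives).
oracle_best_penalty <- function(left, right, site_len, indel_len,
                                genome_strings, cns) {
  enum <- function(flank) {
    out <- list()
    for (len in cns$len_range[1]:cns$len_range[2]) {
      if (nchar(flank) < len) next
      for (a in seq_len(nchar(flank) - len + 1)) {
        s <- substr(flank, a, a + len - 1)
        if (grepl("[^ACGT]", s)) next
        gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / len
        if (gc < cns$gc_range[1] || gc > cns$gc_range[2]) next
        tm <- oracle_tm(s, cns$na_mM / 1000, cns$primer_nM * 1e-9)
        if (tm < cns$tm_range[1] || tm > cns$tm_range[2]) next
        out[[length(out) + 1]] <- list(start = a, len = len, seq = s, tm = tm)
      }
    }
    out
  }
  dimer <- function(a, b, k) {
    ta <- substr(a, nchar(a) - k + 1, nchar(a))
    tb <- substr(b, nchar(b) - k + 1, nchar(b))
    oracle_revcomp(ta) == tb
  }
  fc <- enum(left); rc <- enum(right)
  lf <- nchar(left)
  pairs <- list()
  for (f in fc) {
    for (r in rc) {
      prod <- (lf + site_len + r$start + r$len - 1) - f$start + 1
      if (prod < cns$product_range[1] || prod > cns$product_range[2]) next
      if (abs(f$tm - r$tm) > cns$max_pair_tm_diff) next
      rseq <- oracle_revcomp(r$seq)
      if (cns$dimer_check &&
          (dimer(f$seq, rseq, cns$dimer_k) || dimer(f$seq, f$seq, cns$dimer_k) ||
           dimer(rseq, rseq, cns$dimer_k))) next
      pen <- cns$weights[["tm"]] * (abs(f$tm - cns$tm_opt) + abs(r$tm - cns$tm_opt)) +
        cns$weights[["len"]] * (abs(f$len - cns$len_opt) + abs(r$len - cns$len_opt)) +
        cns$weights[["product"]] * abs(prod - cns$product_opt)
      pairs[[length(pairs) + 1]] <- list(pen = pen, fseq = f$seq, rseq = rseq)
    }
  }
  if (!length(pairs)) return(NA_real_)
  ord <- order(vapply(pairs, `[[`, numeric(1), "pen"))
  for (k in ord) {
    p <- pairs[[k]]
    if (oracle_hits(p$fseq, genome_strings) == 1 &&
        oracle_hits(p$rseq, genome_strings) == 1) {
      return(p$pen)
    }
  }
  NA_real_
}

# Naive UPGMA returning the cophenetic (merge-height) matrix; average
# linkage with explicit cluster-size weighting.
oracle_upgma_cophenetic <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  clusters <- as.list(labs)
  size <- rep(1, n)
  dm <- d
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bmin <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (dm[i, j] < bmin) { bmin <- dm[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- bmin
    }
    # merge j into i with average linkage
    for (k in active) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        (size[i] * dm[i, k] + size[j] * dm[j, k]) / (size[i] + size[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  coph
}

# Brute-force left-alignment: enumerate all equivalent (pos, ref, alt)
# parsimonious triples by reconstructing the alternate haplotype, take the
# minimum position.
oracle_normalize <- function(seq, pos, ref, alt) {
  apply_var <- function(p, r, a) {
    paste0(substr(seq, 1, p - 1), a, substr(seq, p + nchar(r), nchar(seq)))
  }
  target <- apply_var(pos, ref, alt)
  delta <- nchar(alt) - nchar(ref)
  best <- NULL
  for (p in max(1, pos - 100):(pos + nchar(ref))) {
    for (rl in 1:(nchar(ref) + 2)) {
      r2 <- substr(seq, p, p + rl - 1)
      if (nchar(r2) < rl) next
      al <- rl + delta
      if (al < 1) next
      a2 <- substr(target, p, p + al - 1)
      if (nchar(a2) < al) next
      if (apply_var(p, r2, a2) != target) next
      # parsimony: neither a shared trailing base (right-trimmable) nor a
      # shared leading base with both alleles longer than 1 (front-trimmable)
      if (rl > 1 && al > 1 &&
          substr(r2, rl, rl) == substr(a2, al, al)) next
      if (rl > 1 && al > 1 &&
          substr(r2, 1, 1) == substr(a2, 1, 1)) next
      cand <- list(pos = p, ref = r2, alt = a2)
      if (is.null(best) || p < best$pos) best <- cand
    }
  }
  best
}
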