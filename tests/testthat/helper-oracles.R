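# Independent brute-force oracles. These deliberately re-derive results with
# plain loops and explicit rule application, staying independent of the
# package's vectorized implementations.

# Classification oracle: per-barcode growth rates against the control,
# labels applied literally from the stated rules.
oracle_classify <- function(counts, replicates, control, T_weeks,
                            min_count = 2, pseudo_reads = 0.5) {
  keep <- character(0)
  for (bc in rownames(counts)) {
    vals <- counts[bc, c(replicates, control)]
    if (any(vals >= min_count)) keep <- c(keep, bc)
  }
  counts <- counts[keep, , drop = FALSE]
  col_sum <- colSums(counts)
  out <- NULL
  for (bc in rownames(counts)) {
    r_by_rep <- numeric(0)
    det_by_rep <- logical(0)
    for (rp in replicates) {
      fR <- counts[bc, rp] / col_sum[rp]
      f0 <- counts[bc, control] / col_sum[control]
      if (fR == 0) fR <- pseudo_reads / col_sum[rp]
      if (f0 == 0) f0 <- pseudo_reads / col_sum[control]
      r_by_rep[rp] <- log(fR / f0) / T_weeks
      det_by_rep[rp] <- counts[bc, rp] > 0
    }
    n_pos <- sum(r_by_rep > 0 & det_by_rep)
    for (rp in replicates) {
      label <- if (!det_by_rep[rp]) "excluded"
        else if (r_by_rep[rp] > 0 && n_pos >= 2) "preexisting"
        else if (r_by_rep[rp] > 0) "denovo"
        else "sensitive"
      out <- rbind(out, data.frame(barcode = bc, replicate = rp,
                                   r = unname(r_by_rep[rp]), label = label,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# Hamming distance by explicit character comparison.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# VAF enrichment oracle: literal rule application per variant.
oracle_enrichment <- function(tab, fold = 2,
                              replicates = c("RepA", "RepB", "RepC")) {
  sharing <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v0 <- tab$vaf_initial[i]
    if (v0 == 0) v0 <- 1 / (2 * max(tab$depth_initial[i], 1))
    dmso <- tab$vaf_DMSO[i] >= fold * v0
    hits <- character(0)
    for (rp in replicates) {
      if (tab[[paste0("vaf_", rp)]][i] >= fold * v0 && !dmso)
        hits <- c(hits, rp)
    }
    sharing[i] <- if (length(hits) == length(replicates)) "conserved"
      else if (length(hits) == 1) paste0("private:", hits)
      else "none"
  }
  sharing
}

# Consensus oracle: exhaustive enumeration of pairs and triples of calls
# from distinct replicates, maximal support only.
oracle_consensus <- function(calls, replicates, control = "DMSO",
                             min_rec = 0.5) {
  rc <- calls[calls$sample %in% replicates, , drop = FALSE]
  ctl <- calls[calls$sample == control, , drop = FALSE]
  recip <- function(i, j) {
    ov <- min(rc$end[i], rc$end[j]) - max(rc$start[i], rc$start[j]) + 1
    if (ov <= 0) return(0)
    min(ov / (rc$end[i] - rc$start[i] + 1), ov / (rc$end[j] - rc$start[j] + 1))
  }
  compat <- function(i, j) {
    rc$sample[i] != rc$sample[j] && rc$chrom[i] == rc$chrom[j] &&
      rc$status[i] == rc$status[j] && recip(i, j) >= min_rec
  }
  ctl_hit <- function(chrom, status, s, e) {
    any(ctl$chrom == chrom & ctl$status == status &
          ctl$start <= e & ctl$end >= s)
  }
  n <- nrow(rc)
  res <- NULL
  pairs <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (compat(i, j)) pairs[[length(pairs) + 1]] <- c(i, j)
  triples <- list()
  for (p in pairs) for (k in seq_len(n)) {
    if (k %in% p) next
    if (k < max(p)) next   # enumerate each triple once, k largest
    if (compat(p[1], k) && compat(p[2], k))
      triples[[length(triples) + 1]] <- sort(c(p, k))
  }
  triples <- unique(triples)
  emit <- function(members) {
    s <- max(rc$start[members]); e <- min(rc$end[members])
    if (s > e) return(NULL)
    chrom <- rc$chrom[members[1]]; status <- rc$status[members[1]]
    if (ctl_hit(chrom, status, s, e)) return(NULL)
    data.frame(chrom = chrom, start = s, end = e, status = status,
               support = paste(sort(unique(rc$sample[members])),
                               collapse = ","),
               n_support = length(unique(rc$sample[members])),
               stringsAsFactors = FALSE)
  }
  for (t in triples) res <- rbind(res, emit(t))
  in_triple <- function(p) any(vapply(triples, function(t)
    all(p %in% t), TRUE))
  for (p in pairs) if (!length(triples) || !in_triple(p))
    res <- rbind(res, emit(p))
  if (is.null(res)) return(data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    status = character(0), support = character(0),
    n_support = integer(0), stringsAsFactors = FALSE))
  res <- unique(res)
  res[order(res$chrom, res$start, res$end, res$status), , drop = FALSE]
}

# Canonical form for comparing consensus tables.
canon_consensus <- function(df) {
  df <- df[order(df$chrom, df$start, df$end, df$status, df$support), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "status", "support", "n_support")]
}

# Random count table for classifier fuzzing.
random_count_table <- function(n_barcodes, seed) {
  set.seed(seed)
  n <- sample.int(n_barcodes, 1)
  m <- matrix(stats::rpois(n * 5, lambda = sample(c(0.5, 2, 10), 1)),
              nrow = n,
              dimnames = list(sprintf("bc%03d", seq_len(n)),
                              c("initial", "DMSO", "RepA", "RepB", "RepC")))
  storage.mode(m) <- "integer"
  m
}

# Random segment call set for consensus fuzzing: few chroms and a coarse
# coordinate grid so overlaps and ties actually occur.
random_segments <- function(seed, n_max = 30) {
  set.seed(seed)
  n <- sample(5:n_max, 1)
  start <- sample(seq(1, 2e6, by = 1e5), n, replace = TRUE)
  len <- sample(seq(1e5, 1.5e6, by = 1e5), n, replace = TRUE)
  data.frame(
    sample = sample(c("RepA", "RepB", "RepC", "DMSO"), n, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start, end = start + len,
    copy_number = sample(1:5, n, replace = TRUE),
    status = sample(c("gain", "loss"), n, replace = TRUE),
    p_value = stats::runif(n, 0, 0.04),
    stringsAsFactors = FALSE)
}
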