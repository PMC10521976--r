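# Whole-exome post-filters applied to externally produced variant and
# copy-number tables: coverage/target gating, per-replicate two-fold VAF
# enrichment with control exclusion, and multi-replicate CNA consensus.

VARIANT_SAMPLES <- c("initial", "DMSO", "RepA", "RepB", "RepC")

.gr_from_intervals <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end))
}

#' Read a BED file of intervals
#'
#' Parses BED3+ (chrom, start, end, optional name) and converts the on-disk
#' 0-based half-open coordinates to the 1-based inclusive convention used
#' internally. Malformed lines abort with their line number.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` (if present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 which(nf < 3L)[1L]))
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
  if (length(bad))
    stop(sprintf("malformed BED line %d: bad coordinates", bad[1L]))
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                    start = start + 1, end = end,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- vapply(parts, `[[`, "", 4L)
  out
}

#' Coverage and target-region filter for variant tables
#'
#' Retains a variant iff its depth is at least `min_depth` in every sample
#' and its position falls inside one of the capture-panel target intervals.
#'
#' @param table Variant data.frame with `chrom`, `pos` and `depth_<sample>`
#'   columns for the five samples (see [simulate_variant_table()] or
#'   [read_variant_table()]).
#' @param targets Target intervals: data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive, e.g. from [read_bed()]), or `NULL` to skip the
#'   positional test.
#' @param min_depth Minimum per-sample depth (default 10).
#' @param samples Sample names whose depths are checked.
#' @return The filtered variant data.frame.
#' @export
coverage_filter <- function(table, targets = NULL, min_depth = 10L,
                            samples = VARIANT_SAMPLES) {
  depth_cols <- paste0("depth_", samples)
  missing <- setdiff(depth_cols, names(table))
  if (length(missing))
    stop("missing depth column(s): ", paste(missing, collapse = ", "))
  ok_depth <- rowSums(as.matrix(table[, depth_cols]) >= min_depth) ==
    length(depth_cols)
  ok_pos <- rep(TRUE, nrow(table))
  if (!is.null(targets) && nrow(table)) {
    pos_gr <- GenomicRanges::GRanges(table$chrom,
                                     IRanges::IRanges(table$pos, table$pos))
    ok_pos <- IRanges::overlapsAny(pos_gr, .gr_from_intervals(targets))
  }
  table[ok_depth & ok_pos, , drop = FALSE]
}

#' Per-replicate two-fold VAF enrichment with control exclusion
#'
#' For each variant and each treated replicate, flags the replicate as
#' enriched when its VAF is at least `fold` times the initial line's VAF and
#' the DMSO control is NOT similarly enriched (so drift that also appears in
#' the vehicle control never counts as drug-selected). A variant enriched in
#' all replicates is labelled `conserved`, in exactly one `private:<Rep>`,
#' otherwise `none`.
#'
#' When the initial VAF is 0 the fold ratio is undefined; the initial VAF is
#' then floored at half a read, `1 / (2 * depth_initial)`, recorded in the
#' `vaf_initial_eff` output column.
#'
#' @param table Coverage-filtered variant data.frame with `vaf_<sample>` and
#'   `depth_<sample>` columns.
#' @param fold Enrichment factor (default 2).
#' @param replicates Treated replicate names.
#' @return data.frame with the variant key columns, per-replicate
#'   `enriched_<Rep>` logicals, `vaf_initial_eff`, and `sharing` in
#'   {"conserved", "private:<Rep>", "none"}.
#' @export
vaf_enrichment <- function(table, fold = 2,
                           replicates = c("RepA", "RepB", "RepC")) {
  if (!nrow(table))
    return(cbind(table[, intersect(c("chrom", "pos", "ref", "alt"),
                                   names(table)), drop = FALSE],
                 data.frame(sharing = character(0))))
  v0 <- table$vaf_initial
  floor0 <- 1 / (2 * pmax(table$depth_initial, 1L))
  v0_eff <- ifelse(v0 == 0, floor0, v0)
  dmso_hit <- table$vaf_DMSO >= fold * v0_eff
  flags <- sapply(replicates, function(r)
    table[[paste0("vaf_", r)]] >= fold * v0_eff & !dmso_hit)
  flags <- matrix(flags, nrow = nrow(table),
                  dimnames = list(NULL, replicates))
  n_enr <- rowSums(flags)
  sharing <- rep("none", nrow(table))
  sharing[n_enr == length(replicates)] <- "conserved"
  one <- which(n_enr == 1L)
  if (length(one))
    sharing[one] <- paste0("private:",
                           replicates[apply(flags[one, , drop = FALSE], 1L,
                                            which)])
  out <- table[, intersect(c("chrom", "pos", "ref", "alt"), names(table)),
               drop = FALSE]
  colnames(flags) <- paste0("enriched_", replicates)
  cbind(out, flags, vaf_initial_eff = v0_eff, sharing = sharing)
}

#' Keep significant copy-number segment calls
#'
#' Retains calls with `p_value < alpha` (strict inequality, so p = 0.05 is
#' removed at the default threshold).
#'
#' @param calls Segment data.frame with a `p_value` column.
#' @param alpha Significance level (default 0.05).
#' @return The filtered data.frame.
#' @export
significant_cna_filter <- function(calls, alpha = 0.05) {
  if (!"p_value" %in% names(calls) ||
      (nrow(calls) && anyNA(calls$p_value)))
    stop("every segment call needs a p_value")
  calls[calls$p_value < alpha, , drop = FALSE]
}

# reciprocal overlap of two 1-based inclusive intervals
.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1)))
}

#' Multi-replicate copy-number consensus
#'
#' Identifies genomic regions altered concordantly across replicates but not
#' in the control: a consensus region is the intersection of significant
#' same-direction calls from at least `min_replicates` distinct replicates
#' that mutually overlap at reciprocal overlap >= `min_reciprocal_overlap`,
#' provided no significant same-direction call from the control overlaps the
#' region. Supporting call sets are maximal (a two-replicate consensus is not
#' reported separately when the same calls belong to a three-replicate one).
#'
#' @param calls Significance-filtered segment data.frame with columns
#'   `sample`, `chrom`, `start`, `end`, `status` ("gain"/"loss"), `p_value`.
#' @param replicates Treated replicate sample names; names absent from
#'   `calls` produce a warning and contribute no calls.
#' @param control Control sample name (default "DMSO").
#' @param min_replicates Minimum distinct supporting replicates (default 2).
#' @param min_reciprocal_overlap Pairwise reciprocal-overlap threshold
#'   (default 0.5).
#' @return data.frame: `chrom`, `start`, `end`, `status`, `support`
#'   (comma-separated replicate names), `n_support`.
#' @export
cna_consensus <- function(calls, replicates = c("RepA", "RepB", "RepC"),
                          control = "DMSO", min_replicates = 2L,
                          min_reciprocal_overlap = 0.5) {
  absent <- setdiff(replicates, unique(calls$sample))
  if (length(absent))
    warning("no calls for replicate(s): ", paste(absent, collapse = ", "))
  rep_calls <- calls[calls$sample %in% replicates, , drop = FALSE]
  ctl_calls <- calls[calls$sample == control, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), status = character(0),
                      support = character(0), n_support = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(rep_calls) < min_replicates) return(empty)

  out <- list()
  for (chrom in unique(rep_calls$chrom)) {
    for (status in c("gain", "loss")) {
      cc <- rep_calls[rep_calls$chrom == chrom & rep_calls$status == status,
                      , drop = FALSE]
      if (nrow(cc) < min_replicates) next
      n <- nrow(cc)
      # compatibility graph: edges between calls from distinct replicates
      # with sufficient reciprocal overlap
      adj <- matrix(FALSE, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (cc$sample[i] == cc$sample[j]) next
        ro <- .reciprocal_overlap(cc$start[i], cc$end[i],
                                  cc$start[j], cc$end[j])
        adj[i, j] <- adj[j, i] <- ro >= min_reciprocal_overlap
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      cliques <- igraph::max_cliques(g, min = min_replicates)
      for (cl in cliques) {
        members <- as.integer(cl)
        reps <- sort(unique(cc$sample[members]))
        if (length(reps) < min_replicates) next
        region_start <- max(cc$start[members])
        region_end <- min(cc$end[members])
        if (region_start > region_end) next
        # control exclusion: any overlapping same-direction significant call
        ctl <- ctl_calls[ctl_calls$chrom == chrom &
                           ctl_calls$status == status, , drop = FALSE]
        if (nrow(ctl) &&
            any(ctl$start <= region_end & ctl$end >= region_start)) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = region_start, end = region_end,
          status = status, support = paste(reps, collapse = ","),
          n_support = length(reps), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start, res$end, res$status), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate consensus segments with overlapping genes
#'
#' @param segments data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param genes Gene intervals: data.frame with `chrom`, `start`, `end`,
#'   `name` (e.g. from [read_bed()]).
#' @return `segments` with an added `genes` column: comma-separated names of
#'   intersecting genes in genomic order ("" when none).
#' @export
annotate_genes <- function(segments, genes) {
  if (!nrow(segments)) { segments$genes <- character(0); return(segments) }
  seg_gr <- .gr_from_intervals(segments)
  gene_gr <- .gr_from_intervals(genes)
  hits <- GenomicRanges::findOverlaps(seg_gr, gene_gr)
  ann <- rep("", nrow(segments))
  if (length(hits)) {
    byseg <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (q in names(byseg)) {
      g <- byseg[[q]]
      g <- g[order(genes$start[g])]
      ann[as.integer(q)] <- paste(genes$name[g], collapse = ",")
    }
  }
  segments$genes <- ann
  segments
}

#' Read a per-sample variant table
#'
#' Accepts either a TSV with the documented columns (`chrom`, `pos`, `ref`,
#' `alt`, `depth_<sample>`, `vaf_<sample>`) or a VCF, from which per-sample
#' depth and VAF are derived from the genotype `AD` (allelic depths) field:
#' depth = sum(AD), VAF = AD[alt] / depth. VCF sample names must match the
#' expected sample set.
#'
#' @param path `.tsv`/`.txt` or `.vcf`/`.vcf.gz` file.
#' @param samples Expected sample names.
#' @return Variant data.frame in the internal layout.
#' @export
read_variant_table <- function(path, samples = VARIANT_SAMPLES) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading VCF requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    ad <- VariantAnnotation::geno(vcf)$AD
    if (is.null(ad)) stop("VCF lacks the AD genotype field")
    missing <- setdiff(samples, colnames(ad))
    if (length(missing))
      stop("VCF lacks sample(s): ", paste(missing, collapse = ", "))
    rr <- SummarizedExperiment::rowRanges(vcf)
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) as.character(a)[1L], ""),
      stringsAsFactors = FALSE)
    for (s in samples) {
      adl <- ad[, s]
      depth <- vapply(adl, sum, 0)
      altd <- vapply(adl, function(v) if (length(v) >= 2L) v[2L] else 0, 0)
      out[[paste0("depth_", s)]] <- as.integer(depth)
      out[[paste0("vaf_", s)]] <- ifelse(depth > 0, altd / depth, 0)
    }
    out
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "pos", paste0("depth_", samples),
              paste0("vaf_", samples))
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop("variant table lacks column(s): ",
           paste(missing, collapse = ", "))
    df
  }
}
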