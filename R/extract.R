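# Barcode extraction: purely positional trimming of paired amplicon reads.
# The barcode occupies a fixed window in each mate (after a constant flank),
# so extraction is headcrop-then-crop with no adapter scanning or alignment.

#' Read-level quality filter
#'
#' A read is kept iff its mean Phred quality is at least
#' `layout$min_mean_phred`; the boundary is inclusive (mean exactly at the
#' threshold keeps the read). Vectorized over reads.
#'
#' @param qualities Character vector of FASTQ quality strings (Phred+33 by
#'   default; see [read_layout()]).
#' @param layout A [read_layout()].
#' @return Logical vector: `TRUE` = keep.
#' @examples
#' quality_filter(c(strrep("I", 10), strrep("+", 10)))  # Q40 kept, Q10 dropped
#' @export
quality_filter <- function(qualities, layout = read_layout()) {
  n <- nchar(qualities)
  if (!length(qualities)) return(logical(0))
  keep <- rep(FALSE, length(qualities))
  nz <- n > 0L
  if (any(nz)) {
    bytes <- as.integer(charToRaw(paste(qualities[nz], collapse = "")))
    sums <- rowsum(bytes, rep.int(seq_len(sum(nz)), n[nz]))
    means <- as.vector(sums) / n[nz] - layout$phred_offset
    keep[nz] <- means >= layout$min_mean_phred
  }
  keep
}

#' Trim a read to its barcode window
#'
#' Applies headcrop-then-crop: removes the constant prefix
#' (`fwd_headcrop`/`rev_headcrop` bases depending on orientation), then keeps
#' the first `window_len` bases. For the default layout the forward window is
#' read bases 21-68 and the reverse window bases 80-127 (1-based inclusive).
#' Reads too short to contain the full window yield `NA`.
#'
#' @param reads Character vector of read sequences.
#' @param orientation `"forward"` or `"reverse"`.
#' @param layout A [read_layout()].
#' @return Character vector of `window_len`-nt windows (`NA` where the read
#'   was too short).
#' @export
trim_window <- function(reads, orientation = c("forward", "reverse"),
                        layout = read_layout()) {
  orientation <- match.arg(orientation)
  crop <- if (orientation == "forward") layout$fwd_headcrop
          else layout$rev_headcrop
  start <- crop + 1L
  end <- crop + layout$window_len
  out <- substr(reads, start, end)
  out[nchar(reads) < end] <- NA_character_
  out
}

.read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  list(id = names(ss),
       seq = as.character(ss),
       qual = as.character(S4Vectors::mcols(ss)$qualities))
}

# FASTQ ids: strip mate suffix (/1, /2) and anything after whitespace
.core_id <- function(ids) sub("/[12]$", "", sub("[ \t].*$", "", ids))

#' Extract paired barcode windows from FASTQ files
#'
#' Streams a synchronized pair of FASTQ files (optionally gzipped) and emits
#' one forward window per passing R1 read and one reverse window per passing
#' R2 read. Each read is quality-filtered independently (mean Phred >=
#' `layout$min_mean_phred`) and then trimmed positionally with
#' [trim_window()]; the two mates of a pair are counted independently
#' downstream, mirroring counting of forward and reverse directions.
#'
#' @param fastq_r1,fastq_r2 Paths to the R1/R2 FASTQ files. Read ids (after
#'   stripping mate suffixes) must match pairwise; a desynchronized pair
#'   aborts with the first mismatching id.
#' @param layout A [read_layout()].
#' @return An object of class `window_set`: list with `windows` (data.frame:
#'   `read_id`, `orientation`, `sequence`) and `report` (per-orientation
#'   totals and drop counts with reasons).
#' @export
extract_pairs <- function(fastq_r1, fastq_r2, layout = read_layout()) {
  r1 <- .read_fastq(fastq_r1)
  r2 <- .read_fastq(fastq_r2)
  if (length(r1$id) != length(r2$id))
    stop(sprintf("paired FASTQ files differ in length (%d vs %d reads)",
                 length(r1$id), length(r2$id)))
  id1 <- .core_id(r1$id); id2 <- .core_id(r2$id)
  mism <- which(id1 != id2)
  if (length(mism))
    stop(sprintf(
      "desynchronized pair files: record %d has id '%s' in R1 but '%s' in R2",
      mism[1L], id1[mism[1L]], id2[mism[1L]]))

  one <- function(rd, ids, orientation) {
    n <- length(ids)
    malformed <- nchar(rd$qual) != nchar(rd$seq)
    keep_q <- quality_filter(rd$qual, layout) & !malformed
    win <- trim_window(rd$seq, orientation, layout)
    short <- is.na(win)
    keep <- keep_q & !short
    list(df = data.frame(read_id = ids[keep],
                         orientation = orientation,
                         sequence = win[keep],
                         stringsAsFactors = FALSE),
         report = list(total = n,
                       kept = sum(keep),
                       dropped_malformed = sum(malformed),
                       dropped_quality = sum(!keep_q & !malformed),
                       dropped_short = sum(short & keep_q)))
  }
  fwd <- one(r1, id1, "forward")
  rev <- one(r2, id2, "reverse")
  structure(list(
    windows = rbind(fwd$df, rev$df),
    report = list(forward = fwd$report, reverse = rev$report)),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  r <- x$report
  cat("Extracted barcode windows\n")
  for (o in names(r))
    cat(sprintf("  %s: %d reads, %d kept, %d quality-dropped, %d too short\n",
                o, r[[o]]$total, r[[o]]$kept, r[[o]]$dropped_quality,
                r[[o]]$dropped_short))
  invisible(x)
}
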