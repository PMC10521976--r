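# Barcode counting: direct exact (or unique Hamming-1) matching of extracted
# 48-nt windows against the reference library. Forward windows are compared
# to the library sequences, reverse windows to their reverse complements, and
# the two orientations of a pair are counted independently by default.

.revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Lookup environment mapping every Hamming-1 neighbour of every library
# barcode to the barcode's index, with ambiguous neighbours (reachable from
# two different barcodes) mapped to NA. Exact sequences are handled
# separately, so neighbours that collide with a true library sequence defer
# to the exact match.
.neighbour_map <- function(seqs) {
  nb <- .hamming1_neighbours(seqs)
  o <- order(nb$seq)
  s <- nb$seq[o]; i <- nb$idx[o]
  first <- !duplicated(s)
  runs <- cumsum(first)
  # ambiguous: a run (identical neighbour sequence) containing two distinct
  # barcode indices; within a sorted run it suffices to test adjacent pairs
  n <- length(s)
  adj <- c(FALSE, s[-1L] == s[-n] & i[-1L] != i[-n])
  amb <- rowsum(as.integer(adj), runs) > 0L
  idx <- i[first]
  idx[amb] <- NA_integer_
  list(seq = s[first], idx = idx)
}

#' Match barcode windows against a library
#'
#' Forward windows are compared with the library sequences, reverse windows
#' with their reverse complements. An exact match always wins; with
#' `max_mismatch = 1` a window with no exact hit is assigned to the unique
#' library barcode at Hamming distance 1, and windows equidistant from two or
#' more barcodes stay unmatched. Unmatched is a value, not an error.
#'
#' @param sequences Character vector of extracted windows.
#' @param orientation `"forward"`/`"reverse"`, length 1 or per window.
#' @param library A `barcode_library`.
#' @param max_mismatch 0 (exact only) or 1.
#' @return Character vector of barcode ids, `NA` where unmatched; attribute
#'   `"status"` holds `"matched"`, `"unmatched"` or `"ambiguous"` per window.
#' @export
match_window <- function(sequences, orientation = "forward", library,
                         max_mismatch = 0L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  lib_seq <- unname(unclass(library))
  lib_ids <- names(library)
  if (length(orientation) == 1L)
    orientation <- rep(orientation, length(sequences))
  ref_fwd <- lib_seq
  ref_rev <- .revcomp(lib_seq)

  idx <- integer(length(sequences)); idx[] <- NA_integer_
  status <- rep("unmatched", length(sequences))
  for (ori in c("forward", "reverse")) {
    sel <- orientation == ori
    if (!any(sel)) next
    ref <- if (ori == "forward") ref_fwd else ref_rev
    hit <- match(sequences[sel], ref)
    idx[sel] <- hit
    if (max_mismatch == 1L) {
      miss <- sel & is.na(idx)
      if (any(miss)) {
        nm <- .neighbour_map(ref)
        pos <- match(sequences[miss], nm$seq)
        found <- !is.na(pos)
        nidx <- nm$idx[pos[found]]
        miss_i <- which(miss)
        idx[miss_i[found]] <- nidx
        status[miss_i[found][is.na(nidx)]] <- "ambiguous"
      }
    }
  }
  status[!is.na(idx)] <- "matched"
  out <- lib_ids[idx]
  attr(out, "status") <- status
  out
}

#' Count matched windows for one sample
#'
#' Each matched window contributes one count to its barcode, so an error-free
#' read pair contributes two (its forward and its reverse window), matching
#' counting of both read directions. With `strict_pair = TRUE` a read id is
#' counted once, and only when its forward and reverse windows map to the
#' same barcode.
#'
#' When `max_mismatch = 1`, the library's minimum pairwise Hamming distance
#' is checked first; if any two barcodes are closer than 3, correction is
#' disabled with a warning (a one-error read could otherwise be assigned to
#' the wrong barcode).
#'
#' @param windows A `window_set` from [extract_pairs()], or its `windows`
#'   data.frame.
#' @param library A `barcode_library`.
#' @param max_mismatch 0 or 1.
#' @param strict_pair Count read pairs once, requiring orientation agreement.
#' @return List with `counts` (named integer vector over library ids with
#'   nonzero counts) and `report` (total / matched / unmatched / ambiguous
#'   window tallies; `matched + unmatched + ambiguous == total`).
#' @export
count_sample <- function(windows, library, max_mismatch = 0L,
                         strict_pair = FALSE) {
  if (inherits(windows, "window_set")) windows <- windows$windows
  stopifnot(all(c("orientation", "sequence") %in% names(windows)))
  if (max_mismatch == 1L && !library_min_dist_ok(library)) {
    warning("library pairwise Hamming distance < 3; disabling mismatch correction")
    max_mismatch <- 0L
  }
  ids <- match_window(windows$sequence, windows$orientation, library,
                      max_mismatch)
  status <- attr(ids, "status")
  if (strict_pair) {
    df <- data.frame(read_id = windows$read_id,
                     orientation = windows$orientation,
                     bc = as.vector(ids), stringsAsFactors = FALSE)
    fwd <- df[df$orientation == "forward", ]
    rev <- df[df$orientation == "reverse", ]
    m <- merge(fwd, rev, by = "read_id")
    agree <- !is.na(m$bc.x) & !is.na(m$bc.y) & m$bc.x == m$bc.y
    counted <- m$bc.x[agree]
  } else {
    counted <- ids[!is.na(ids)]
  }
  counts <- table(counted)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       report = list(total = length(status),
                     matched = sum(status == "matched"),
                     unmatched = sum(status == "unmatched"),
                     ambiguous = sum(status == "ambiguous")))
}

#' Assemble per-sample counts into a barcode x sample count table
#'
#' Takes the union of barcodes seen in any sample, fills missing cells with
#' zero, and orders rows lexicographically by barcode id so the table is
#' deterministic regardless of input order.
#'
#' @param sample_counts Named list: sample name -> named integer vector (the
#'   `counts` element of [count_sample()] output, or the list itself).
#' @return Integer matrix, barcodes x samples.
#' @export
assemble_count_table <- function(sample_counts) {
  if (anyDuplicated(names(sample_counts)))
    stop("duplicate sample names: ",
         paste(names(sample_counts)[duplicated(names(sample_counts))],
               collapse = ", "))
  sample_counts <- lapply(sample_counts, function(x)
    if (is.list(x) && !is.null(x$counts)) x$counts else x)
  all_bc <- sort(unique(unlist(lapply(sample_counts, names))))
  tab <- matrix(0L, nrow = length(all_bc), ncol = length(sample_counts),
                dimnames = list(all_bc, names(sample_counts)))
  for (s in names(sample_counts)) {
    v <- sample_counts[[s]]
    if (length(v)) tab[names(v), s] <- as.integer(v)
  }
  tab
}

#' Read / write a count table as TSV
#'
#' The on-disk format is a tab-separated table whose first column (`barcode`)
#' holds barcode ids and whose remaining columns are samples.
#'
#' @param path TSV path.
#' @return `read_count_table`: integer matrix. `write_count_table`: `path`,
#'   invisibly.
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_count_table
#' @param counts Integer count matrix.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(barcode = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
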