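# Barcode reference library: named set of unique fixed-length DNA barcodes.

#' Generate a random barcode reference library
#'
#' Draws `n` distinct random DNA sequences of length `width` and names them
#' `bc000001`, `bc000002`, ... . This stands in for a commercial lentiviral
#' barcode library: real libraries (~10^6 barcodes of 48 nt) are proprietary
#' sequence sets, but for simulation only the fixed length and mutual
#' distinctness matter. Random 48-mers are, with overwhelming probability,
#' pairwise far apart in Hamming distance, which is what makes single-mismatch
#' correction safe (see [count_sample()]).
#'
#' @param n Number of barcodes.
#' @param width Barcode length in nt (default 48).
#' @param seed Integer seed; the library is deterministic given the seed.
#' @return A `barcode_library`: named character vector of uppercase ACGT
#'   sequences.
#' @examples
#' lib <- generate_barcode_library(10, seed = 1)
#' nchar(lib)
#' @export
generate_barcode_library <- function(n, width = 48L, seed = 1L) {
  stopifnot(n >= 1, width >= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  repeat {
    m <- matrix(sample(bases, n * width, replace = TRUE), nrow = n)
    seqs <- apply(m, 1L, paste0, collapse = "")
    if (!anyDuplicated(seqs)) break
  }
  names(seqs) <- sprintf("bc%06d", seq_len(n))
  class(seqs) <- "barcode_library"
  seqs
}

#' Load a barcode library from FASTA
#'
#' Reads a FASTA file of reference barcodes and validates it: record ids must
#' be unique, sequences must be unique, strictly A/C/G/T and all of one fixed
#' length.
#'
#' @param fasta Path to a FASTA file.
#' @param width Expected barcode length (default 48).
#' @return A `barcode_library` (named character vector).
#' @export
load_library <- function(fasta, width = 48L) {
  ss <- Biostrings::readDNAStringSet(fasta)
  ids <- names(ss)
  if (anyDuplicated(ids))
    stop("duplicate barcode ids in library: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- Biostrings::width(ss)
  if (any(widths != width)) {
    bad <- which(widths != width)[1L]
    stop(sprintf("barcode '%s' has length %d, expected %d",
                 ids[bad], widths[bad], width))
  }
  seqs <- toupper(as.character(ss))
  if (any(grepl("[^ACGT]", seqs))) {
    bad <- which(grepl("[^ACGT]", seqs))[1L]
    stop(sprintf("barcode '%s' contains non-ACGT characters", ids[bad]))
  }
  if (anyDuplicated(seqs)) {
    dups <- seqs[duplicated(seqs) | duplicated(seqs, fromLast = TRUE)]
    stop("duplicate barcode sequences in library; offending ids: ",
         paste(names(seqs)[seqs %in% dups], collapse = ", "))
  }
  names(seqs) <- ids
  class(seqs) <- "barcode_library"
  seqs
}

#' Write a barcode library to FASTA
#'
#' @param library A `barcode_library` or named character vector.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  ss <- Biostrings::DNAStringSet(unclass(library))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# All single-substitution neighbours of each sequence (Hamming distance 1).
# Returns a data.frame (seq, idx) with 3 * width rows per input sequence.
.hamming1_neighbours <- function(seqs) {
  width <- nchar(seqs[1L])
  bases <- c("A", "C", "G", "T")
  out_seq <- vector("list", width * 3L)
  out_idx <- vector("list", width * 3L)
  k <- 0L
  for (pos in seq_len(width)) {
    cur <- substr(seqs, pos, pos)
    for (b in bases) {
      mut <- seqs
      substr(mut, pos, pos) <- b
      keep <- cur != b
      k <- k + 1L
      out_seq[[k]] <- mut[keep]
      out_idx[[k]] <- which(keep)
    }
  }
  data.frame(seq = unlist(out_seq), idx = unlist(out_idx),
             stringsAsFactors = FALSE)
}

#' Check the minimum pairwise Hamming distance of a library
#'
#' Single-mismatch correction is only safe when no two library barcodes are
#' within Hamming distance 2 of each other (otherwise a one-error read could
#' sit within distance 1 of two references). Two equal-length sequences are at
#' distance <= 2 exactly when their Hamming-1 balls intersect, so the check
#' hashes every barcode's distance-<=1 ball and looks for collisions between
#' different barcodes.
#'
#' @param library A `barcode_library`.
#' @return `TRUE` if all pairwise distances are >= 3, else `FALSE`.
#' @export
library_min_dist_ok <- function(library) {
  seqs <- unname(unclass(library))
  nb <- .hamming1_neighbours(seqs)
  ball_seq <- c(seqs, nb$seq)
  ball_idx <- c(seq_along(seqs), nb$idx)
  o <- order(ball_seq)
  ball_seq <- ball_seq[o]; ball_idx <- ball_idx[o]
  same <- ball_seq[-1L] == ball_seq[-length(ball_seq)]
  diff_bc <- ball_idx[-1L] != ball_idx[-length(ball_idx)]
  !any(same & diff_bc)
}
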