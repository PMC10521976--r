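# Amplicon geometry of the barcode cassette.
#
# A 48-nt barcode sits behind a 20-nt constant flank on the forward read and
# behind a 79-nt constant flank on the reverse read; both reads are 150 nt.
# Only the flank lengths matter for extraction (trimming is positional); the
# flank sequences themselves are arbitrary package constants used by the
# simulator.

FWD_FLANK <- "AAAACTCCATGTGTAACTCC"
REV_FLANK <- "GGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATC"
FILLER_BASE <- "A"
READ_LEN <- 150L

#' Positional read layout for barcode extraction
#'
#' Describes where the 48-nt barcode window sits in each mate of a read pair
#' and the quality threshold applied before extraction. Defaults correspond to
#' a cassette with a 20-nt constant prefix on the forward read and a 79-nt
#' constant prefix on the reverse read, so the forward window is bases 21-68
#' and the reverse window bases 80-127 (1-based, inclusive).
#'
#' @param fwd_headcrop Bases removed from the start of forward reads (default 20).
#' @param rev_headcrop Bases removed from the start of reverse reads (default 79).
#' @param window_len Length of the retained barcode window (default 48; must
#'   match the library barcode length).
#' @param min_mean_phred Reads whose mean Phred quality falls below this value
#'   are dropped (default 20; the boundary is inclusive — mean exactly 20 keeps
#'   the read).
#' @param phred_offset ASCII offset of the quality encoding (default 33).
#' @return An object of class `read_layout`.
#' @examples
#' read_layout()
#' @export
read_layout <- function(fwd_headcrop = 20L, rev_headcrop = 79L,
                        window_len = 48L, min_mean_phred = 20,
                        phred_offset = 33L) {
  stopifnot(fwd_headcrop >= 0, rev_headcrop >= 0, window_len > 0)
  structure(list(
    fwd_headcrop = as.integer(fwd_headcrop),
    rev_headcrop = as.integer(rev_headcrop),
    window_len = as.integer(window_len),
    min_mean_phred = min_mean_phred,
    phred_offset = as.integer(phred_offset)
  ), class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat("Barcode read layout\n")
  cat(sprintf("  forward window: bases %d-%d (headcrop %d, crop %d)\n",
              x$fwd_headcrop + 1L, x$fwd_headcrop + x$window_len,
              x$fwd_headcrop, x$window_len))
  cat(sprintf("  reverse window: bases %d-%d (headcrop %d, crop %d)\n",
              x$rev_headcrop + 1L, x$rev_headcrop + x$window_len,
              x$rev_headcrop, x$window_len))
  cat(sprintf("  min mean Phred: %g (offset %d)\n",
              x$min_mean_phred, x$phred_offset))
  invisible(x)
}
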