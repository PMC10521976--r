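# Synthetic-data generator emulating a barcoded spheroid selection experiment:
# a founder population infected at low MOI (so each clone carries one barcode),
# split into one initial sample, one DMSO control and three drug-treated
# replicates, selected for T weeks and sequenced as a barcode amplicon.

TREATED_REPS <- c("RepA", "RepB", "RepC")
SIM_SAMPLES <- c("initial", "DMSO", TREATED_REPS)

#' Configuration for a clone-selection simulation
#'
#' Captures the experimental design being emulated: `n_clones` founder clones
#' (each with a distinct barcode drawn from a library of `library_size`), a
#' fraction `frac_preexisting` of clones resistant before any drug exposure
#' (shared across replicates), and a per-replicate probability `p_denovo` that
#' a drug-sensitive clone acquires resistance privately in one treated
#' replicate. Selection acts multiplicatively for `T_weeks` weeks: resistant
#' clones grow at `fitness_resistant` per week, sensitive clones decline at
#' `fitness_sensitive` (negative) per week, and the DMSO control drifts with
#' mean-zero log-normal noise of total log-scale standard deviation
#' `fitness_dmso` (kept small so neutral drift does not flip growth-rate
#' signs at default sequencing depth).
#'
#' Defaults are desk-scale: 1,000 founder clones, 5% pre-existing
#' resistance, 1% per-replicate de novo acquisition, +/-0.3 per-week fitness
#' and T = 4 weeks (the short-arm schedule; use `T_weeks = 16` for a long
#' selection arm).
#'
#' @param n_clones Number of founder clones.
#' @param library_size Number of distinct barcodes in the reference library
#'   (>= `n_clones`; real libraries have ~10^6, tests use 10^3-10^4).
#' @param frac_preexisting Fraction of clones resistant prior to treatment.
#' @param p_denovo Per-replicate probability that a sensitive clone acquires
#'   private resistance.
#' @param fitness_resistant Per-week log growth advantage of resistant clones
#'   under drug (positive).
#' @param fitness_sensitive Per-week log growth rate of sensitive clones under
#'   drug (negative).
#' @param fitness_dmso Log-scale standard deviation of the control's total
#'   multiplicative drift over the selection (mean zero).
#' @param T_weeks Duration of selection in weeks (16 for the long arm, 4 for
#'   the short arm).
#' @param depth Sequencing reads per sample.
#' @param error_rate Per-base substitution probability in emitted reads.
#' @param seed Integer seed; all downstream simulation is deterministic
#'   given the config.
#' @return An object of class `clone_sim_config`.
#' @export
clone_sim_config <- function(n_clones = 1000L, library_size = 10000L,
                             frac_preexisting = 0.05, p_denovo = 0.01,
                             fitness_resistant = 0.3,
                             fitness_sensitive = -0.3,
                             fitness_dmso = 0.1, T_weeks = 4,
                             depth = 1e6, error_rate = 0, seed = 1L) {
  stopifnot(n_clones >= 1, library_size >= 1,
            frac_preexisting >= 0, frac_preexisting <= 1,
            p_denovo >= 0, p_denovo <= 1,
            T_weeks > 0, depth > 0, error_rate >= 0, error_rate < 1)
  if (n_clones > library_size)
    stop("n_clones (", n_clones, ") exceeds library_size (", library_size,
         "): each founder clone must carry a distinct barcode")
  structure(list(
    n_clones = as.integer(n_clones), library_size = as.integer(library_size),
    frac_preexisting = frac_preexisting, p_denovo = p_denovo,
    fitness_resistant = fitness_resistant,
    fitness_sensitive = fitness_sensitive,
    fitness_dmso = fitness_dmso, T_weeks = T_weeks,
    depth = depth, error_rate = error_rate, seed = as.integer(seed)
  ), class = "clone_sim_config")
}

#' Simulate a barcoded clone population under drug selection
#'
#' Plants ground-truth resistance labels and evolves clone abundances
#' deterministically from them. Each clone receives an initial abundance
#' (log-normal, reflecting unequal founder expansion), a resistance status
#' (pre-existing with probability `frac_preexisting`; otherwise possibly a
#' private de novo acquisition in one treated replicate with per-replicate
#' probability `p_denovo`), and then grows or shrinks exponentially for
#' `T_weeks`: the abundance of clone i in treated replicate j is
#' `initial * exp(fitness_ij * T_weeks)`, with resistant fitness in every
#' replicate for pre-existing clones, in exactly the private replicate for de
#' novo clones, and sensitive fitness otherwise. DMSO abundances drift
#' multiplicatively with mean-zero log-normal noise of standard deviation
#' `fitness_dmso`.
#'
#' If a sensitive clone draws de novo acquisition in more than one replicate,
#' one is kept at random, preserving the invariant that de novo resistance is
#' private to a single replicate.
#'
#' @param config A [clone_sim_config()].
#' @param library Optional `barcode_library` to draw barcodes from; by default
#'   one of `config$library_size` barcodes is generated from `config$seed`.
#' @return A `clone_population`: list with `barcode_ids`, `abundance` (matrix
#'   clone x sample over initial, DMSO, RepA, RepB, RepC), `true_class`
#'   (character matrix clone x treated replicate with values "preexisting",
#'   "denovo", "sensitive"), `library`, and `config`.
#' @examples
#' pop <- simulate_population(clone_sim_config(n_clones = 50, seed = 7))
#' table(pop$true_class[, "RepA"])
#' @export
simulate_population <- function(config, library = NULL) {
  stopifnot(inherits(config, "clone_sim_config"))
  if (is.null(library))
    library <- generate_barcode_library(config$library_size,
                                        seed = config$seed)
  if (config$n_clones > length(library))
    stop("n_clones exceeds the size of the supplied library")
  set.seed(config$seed)
  n <- config$n_clones
  ids <- sample(names(library), n)

  a0 <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)

  pre <- stats::runif(n) < config$frac_preexisting
  denovo_rep <- rep(NA_character_, n)
  sens <- which(!pre)
  if (length(sens)) {
    draws <- matrix(stats::runif(length(sens) * length(TREATED_REPS)) <
                      config$p_denovo,
                    nrow = length(sens))
    for (k in seq_along(sens)) {
      hit <- which(draws[k, ])
      if (length(hit) > 1L) hit <- sample(hit, 1L)
      if (length(hit) == 1L) denovo_rep[sens[k]] <- TREATED_REPS[hit]
    }
  }

  true_class <- matrix("sensitive", nrow = n, ncol = length(TREATED_REPS),
                       dimnames = list(ids, TREATED_REPS))
  true_class[pre, ] <- "preexisting"
  for (j in seq_along(TREATED_REPS)) {
    priv <- !is.na(denovo_rep) & denovo_rep == TREATED_REPS[j]
    true_class[priv, j] <- "denovo"
  }

  fit <- matrix(config$fitness_sensitive, nrow = n,
                ncol = length(TREATED_REPS))
  fit[true_class %in% c("preexisting", "denovo")] <- config$fitness_resistant

  ab <- matrix(0, nrow = n, ncol = length(SIM_SAMPLES),
               dimnames = list(ids, SIM_SAMPLES))
  ab[, "initial"] <- a0
  drift <- stats::rnorm(n, 0, config$fitness_dmso)
  ab[, "DMSO"] <- a0 * exp(drift)
  for (j in seq_along(TREATED_REPS))
    ab[, TREATED_REPS[j]] <- a0 * exp(fit[, j] * config$T_weeks)

  structure(list(barcode_ids = ids, abundance = ab, true_class = true_class,
                 library = library, config = config),
            class = "clone_population")
}

#' @export
print.clone_population <- function(x, ...) {
  cls <- x$true_class
  n_pre <- sum(cls[, 1L] == "preexisting")
  n_dn <- sum(apply(cls == "denovo", 1L, any))
  cat(sprintf(
    "Simulated clone population: %d clones (%d pre-existing, %d de novo, %d sensitive)\n",
    nrow(cls), n_pre, n_dn, nrow(cls) - n_pre - n_dn))
  cat("samples:", paste(colnames(x$abundance), collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth labels of a simulated population in long form
#'
#' @param pop A `clone_population`.
#' @return data.frame with columns `barcode`, `replicate`, `true_class`.
#' @export
truth_labels <- function(pop) {
  stopifnot(inherits(pop, "clone_population"))
  cls <- pop$true_class
  data.frame(
    barcode = rep(rownames(cls), times = ncol(cls)),
    replicate = rep(colnames(cls), each = nrow(cls)),
    true_class = as.vector(cls),
    stringsAsFactors = FALSE)
}

#' Draw sequencing read counts from clone abundances
#'
#' Models sequencing as multinomial sampling: for each sample, `depth` reads
#' are allocated to barcodes with probabilities proportional to their
#' abundances, so column sums equal `depth` exactly.
#'
#' @param pop A `clone_population` (or a nonnegative abundance matrix with
#'   clones as rows and samples as columns).
#' @param depth Reads per sample (positive integer).
#' @param seed Integer seed.
#' @return Integer count matrix, barcode x sample.
#' @export
sample_counts <- function(pop, depth, seed = 1L) {
  ab <- if (inherits(pop, "clone_population")) pop$abundance else pop
  stopifnot(is.matrix(ab), all(ab >= 0))
  if (depth <= 0) stop("depth must be a positive integer")
  depth <- as.integer(depth)
  if (any(colSums(ab) <= 0)) stop("every sample needs total abundance > 0")
  set.seed(seed)
  counts <- matrix(0L, nrow(ab), ncol(ab), dimnames = dimnames(ab))
  for (j in seq_len(ncol(ab)))
    counts[, j] <- as.integer(stats::rmultinom(1L, depth, ab[, j]))
  counts
}

# Inject i.i.d. substitution errors into a character vector of reads.
.inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  width <- nchar(reads[1L])
  raw <- charToRaw(paste(reads, collapse = ""))
  n_bases <- length(raw)
  n_err <- stats::rbinom(1L, n_bases, error_rate)
  if (n_err == 0L) return(reads)
  pos <- sample.int(n_bases, n_err)
  bases <- charToRaw("ACGT")
  for (p in pos) {
    alt <- bases[bases != raw[p]]
    raw[p] <- alt[sample.int(3L, 1L)]
  }
  big <- rawToChar(raw)
  substring(big, seq(1L, n_bases, by = width),
            seq(width, n_bases, by = width))
}

#' Emit paired FASTQ files for counted barcodes
#'
#' Writes one R1/R2 FASTQ pair per sample. Each forward read is the 20-nt
#' constant flank, the 48-nt barcode, then neutral filler to 150 nt; each
#' reverse read is the 79-nt constant flank, the reverse complement of the
#' barcode, then filler to 150 nt — matching the positional layout that
#' [extract_pairs()] undoes. Substitution errors are injected i.i.d. at
#' `error_rate` over the full read; qualities are constant Q40 by default so
#' no read fails quality filtering unless `qual_char` is lowered. Read ids
#' embed the source barcode (`<sample>_<serial>:<barcode>`), preserving
#' per-read ground truth through extraction.
#'
#' @param counts Integer count matrix (barcode x sample) or named vector for a
#'   single sample.
#' @param library `barcode_library` containing every counted barcode.
#' @param dir Output directory (created if needed).
#' @param layout A [read_layout()]; flank lengths are taken from it.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param gzip Write gzip-compressed FASTQ (default FALSE).
#' @param qual_char Single quality character applied to every base
#'   (default "I", Phred 40).
#' @return Named list per sample with elements `r1` and `r2` (file paths).
#' @export
emit_fastq <- function(counts, library, dir, layout = read_layout(),
                       error_rate = 0, seed = 1L, gzip = FALSE,
                       qual_char = "I") {
  if (is.vector(counts)) counts <- cbind(sample1 = counts)
  stopifnot(is.matrix(counts))
  unknown <- setdiff(rownames(counts), names(library))
  if (length(unknown))
    stop("barcode ids absent from library: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  fwd_flank <- substr(FWD_FLANK, 1L, layout$fwd_headcrop)
  rev_flank <- substr(REV_FLANK, 1L, layout$rev_headcrop)
  w <- layout$window_len
  fill1 <- strrep(FILLER_BASE, READ_LEN - layout$fwd_headcrop - w)
  fill2 <- strrep(FILLER_BASE, READ_LEN - layout$rev_headcrop - w)

  out <- list()
  for (s in colnames(counts)) {
    cnt <- stats::setNames(as.vector(counts[, s]), rownames(counts))
    cnt <- cnt[cnt > 0]
    bc <- rep(names(cnt), times = cnt)
    if (length(bc)) bc <- sample(bc)        # shuffle read order
    seqs <- unname(unclass(library)[bc])
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
    r1 <- .inject_errors(paste0(fwd_flank, seqs, fill1), error_rate)
    r2 <- .inject_errors(paste0(rev_flank, rc, fill2), error_rate)

    # read id carries the source barcode so simulated reads keep per-read
    # ground truth through extraction
    ids <- sprintf("%s_%06d:%s", s, seq_along(r1), bc)
    qual <- strrep(qual_char, READ_LEN)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    f1 <- file.path(dir, paste0(s, "_R1", ext))
    f2 <- file.path(dir, paste0(s, "_R2", ext))
    .write_fastq(ids, r1, qual, f1, mate = 1L)
    .write_fastq(ids, r2, qual, f2, mate = 2L)
    out[[s]] <- list(r1 = f1, r2 = f2)
  }
  out
}

.write_fastq <- function(ids, seqs, qual, path, mate) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (!length(ids)) { writeLines(character(0), con); return(invisible(path)) }
  rec <- paste0("@", ids, "/", mate, "\n", seqs, "\n+\n", qual)
  writeLines(rec, con)
  invisible(path)
}

#' Simulate a per-sample variant table with planted VAF enrichment
#'
#' Builds a toy whole-exome variant table over the five samples (initial,
#' DMSO, RepA/B/C) with planted truth for the two-fold VAF enrichment filter:
#' `n_enriched_conserved` variants are >= 2x enriched over the initial line in
#' all three treated replicates (but not in DMSO), `n_enriched_private`
#' variants in exactly one replicate, `n_lowcov` variants carry a sub-10-read
#' depth in one sample (so the coverage filter removes them), and the
#' remainder are unenriched background.
#'
#' @param n_variants Total variants.
#' @param n_enriched_conserved Planted conserved-enriched variants.
#' @param n_enriched_private Planted private-enriched variants.
#' @param depth_range Length-2 integer range for sequencing depths.
#' @param seed Integer seed.
#' @param n_lowcov Variants planted to fail the 10-read coverage filter.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth_<sample>` and `vaf_<sample>` for the five samples, and a
#'   `truth` column in {"conserved", "private:<Rep>", "none", "lowcov"}.
#' @export
simulate_variant_table <- function(n_variants, n_enriched_conserved,
                                   n_enriched_private,
                                   depth_range = c(10L, 200L), seed = 1L,
                                   n_lowcov = 0L) {
  if (n_enriched_conserved + n_enriched_private + n_lowcov > n_variants)
    stop("planted variants exceed n_variants")
  set.seed(seed)
  n <- n_variants
  samples <- SIM_SAMPLES
  bases <- c("A", "C", "G", "T")
  tab <- data.frame(
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n),
    ref = sample(bases, n, replace = TRUE),
    stringsAsFactors = FALSE)
  tab$alt <- vapply(tab$ref, function(r) sample(setdiff(bases, r), 1L), "")
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL

  for (s in samples)
    tab[[paste0("depth_", s)]] <-
      sample(seq(depth_range[1L], depth_range[2L]), n, replace = TRUE)

  # background: VAF close to the initial value everywhere (< 2x, no dropout
  # of the DMSO condition)
  v0 <- stats::runif(n, 0.08, 0.2)
  tab$vaf_initial <- round(v0, 4)
  for (s in samples[-1L])
    tab[[paste0("vaf_", s)]] <- round(v0 * stats::runif(n, 0.6, 1.6), 4)

  truth <- rep("none", n)
  idx <- sample.int(n)          # random, non-overlapping planting slots
  used <- 0L
  take <- function(k) { s <- idx[used + seq_len(k)]; used <<- used + k; s }

  cons <- take(n_enriched_conserved)
  for (i in cons) {
    for (r in TREATED_REPS)
      tab[i, paste0("vaf_", r)] <-
        round(min(1, tab$vaf_initial[i] * stats::runif(1L, 2.2, 3.5)), 4)
    tab[i, "vaf_DMSO"] <- round(tab$vaf_initial[i] * stats::runif(1L, 0.7, 1.5), 4)
  }
  truth[cons] <- "conserved"

  priv <- take(n_enriched_private)
  priv_rep <- sample(TREATED_REPS, length(priv), replace = TRUE)
  for (k in seq_along(priv)) {
    i <- priv[k]
    for (r in TREATED_REPS) {
      mult <- if (r == priv_rep[k]) stats::runif(1L, 2.2, 3.5)
              else stats::runif(1L, 0.5, 1.5)
      tab[i, paste0("vaf_", r)] <- round(min(1, tab$vaf_initial[i] * mult), 4)
    }
    tab[i, "vaf_DMSO"] <- round(tab$vaf_initial[i] * stats::runif(1L, 0.7, 1.5), 4)
  }
  truth[priv] <- paste0("private:", priv_rep)

  low <- take(n_lowcov)
  low_sample <- sample(samples, length(low), replace = TRUE)
  for (k in seq_along(low))
    tab[low[k], paste0("depth_", low_sample[k])] <- sample(0:9, 1L)
  truth[low] <- "lowcov"

  tab$truth <- truth
  tab
}

#' Simulate a normalized dose-response curve
#'
#' Generates percent-of-control viabilities from the three-parameter
#' normalized log-inhibitor model `Y = 100 / (1 + 10^(X - log_ic50))` with
#' `X = log10(concentration)`, plus Gaussian noise.
#'
#' @param log_ic50 True log10 IC50 (same log-units as the concentrations).
#' @param concentrations Positive concentrations; at least 4 distinct values
#'   spanning the IC50.
#' @param noise_sd Gaussian noise standard deviation in percentage points
#'   (default 5).
#' @param seed Integer seed.
#' @return data.frame with columns `concentration` and `response`.
#' @export
simulate_dose_response <- function(log_ic50, concentrations, noise_sd = 5,
                                   seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  x <- log10(concentrations)
  if (length(unique(concentrations)) < 4L)
    stop("need at least 4 distinct concentrations")
  if (min(x) >= log_ic50 || max(x) <= log_ic50)
    stop("concentrations must span the IC50")
  set.seed(seed)
  y <- 100 / (1 + 10^(x - log_ic50)) +
    stats::rnorm(length(x), 0, noise_sd)
  data.frame(concentration = concentrations, response = y)
}

#' Simulate copy-number segment calls with a planted consensus
#'
#' Generates Control-FREEC-style significant/non-significant segment calls
#' across the treated replicates and the DMSO control, planting
#' `n_consensus` regions that are significantly and concordantly altered in
#' at least `min_replicates` replicates while absent from the control.
#'
#' @param n_consensus Planted consensus regions.
#' @param n_noise Additional random single-replicate or non-significant calls.
#' @param min_replicates Replicates supporting each planted region (2 or 3).
#' @param seed Integer seed.
#' @return list with `calls` (data.frame: sample, chrom, start, end,
#'   copy_number, status, p_value) and `truth` (data.frame of planted
#'   regions: chrom, start, end, status, n_support).
#' @export
simulate_segments <- function(n_consensus = 2L, n_noise = 10L,
                              min_replicates = 2L, seed = 1L) {
  set.seed(seed)
  mk <- function(sample, chrom, start, end, status, p, cn) {
    data.frame(sample = sample, chrom = chrom, start = start, end = end,
               copy_number = cn, status = status, p_value = p,
               stringsAsFactors = FALSE)
  }
  calls <- list(); truth <- list()
  for (i in seq_len(n_consensus)) {
    chrom <- paste0("chr", sample(1:22, 1L))
    start <- sample.int(5e7, 1L); len <- sample(5e5:5e6, 1L)
    status <- sample(c("gain", "loss"), 1L)
    reps <- sample(TREATED_REPS, max(2L, min_replicates))
    for (r in reps) {
      jit <- sample(0:round(len * 0.2), 2L, replace = TRUE)
      calls[[length(calls) + 1L]] <-
        mk(r, chrom, start + jit[1L], start + len - jit[2L], status,
           stats::runif(1L, 1e-6, 0.04),
           if (status == "gain") sample(3:5, 1L) else 1L)
    }
    truth[[length(truth) + 1L]] <-
      data.frame(chrom = chrom, start = start, end = start + len,
                 status = status, n_support = length(reps),
                 stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_noise)) {
    s <- sample(c(TREATED_REPS, "DMSO"), 1L)
    start <- sample.int(5e7, 1L) + 1e8      # away from planted regions
    calls[[length(calls) + 1L]] <-
      mk(s, paste0("chr", sample(1:22, 1L)), start,
         start + sample(1e5:2e6, 1L), sample(c("gain", "loss"), 1L),
         stats::runif(1L, 0, 1), sample(1:5, 1L))
  }
  list(calls = do.call(rbind, calls),
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}
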