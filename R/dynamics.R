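# Core statistic: per-barcode growth rates and the pre-existing / de novo /
# sensitive classification.
#
# For barcode i in treated replicate R, the per-week growth rate is
#     r = (1/T) * log(f_R / f_0)
# where f_R is the barcode's read frequency in the replicate, f_0 its
# frequency in the matched DMSO control and T the number of weeks between
# first treatment and harvest. Barcodes with a positive growth rate in at
# least two replicates are pre-existing resistant, positive in exactly one
# replicate de novo resistant, and negative growth rates are sensitive.

#' Low-count barcode filter
#'
#' Removes a barcode iff its count is below `min_count` in every treated
#' (resistant) sample AND in the control; a single sample at or above the
#' threshold rescues the row.
#'
#' @param counts Integer count matrix (barcodes x samples).
#' @param resistant_samples Names of treated replicate columns.
#' @param control_sample Name of the DMSO control column.
#' @param min_count Threshold (default 2).
#' @return The filtered count matrix (rows retained unchanged).
#' @examples
#' m <- rbind(low = c(RepA = 1L, RepB = 0L, DMSO = 1L),
#'            ok  = c(RepA = 2L, RepB = 0L, DMSO = 0L))
#' filter_low_count(m, c("RepA", "RepB"), "DMSO")
#' @export
filter_low_count <- function(counts, resistant_samples, control_sample,
                             min_count = 2L) {
  need <- c(resistant_samples, control_sample)
  missing <- setdiff(need, colnames(counts))
  if (length(missing))
    stop("unknown sample name(s): ", paste(missing, collapse = ", "))
  sub <- counts[, need, drop = FALSE]
  drop <- rowSums(sub >= min_count) == 0L
  counts[!drop, , drop = FALSE]
}

#' Convert counts to within-sample frequencies
#'
#' Divides each column by its sum, so every column sums to 1 over the
#' retained barcodes.
#'
#' @param counts Nonnegative count matrix.
#' @return Numeric matrix of frequencies.
#' @export
to_frequencies <- function(counts) {
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero))
    stop("all-zero count column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2L, cs, "/")
}

#' Per-week clonal growth rate
#'
#' Computes `r = (1/T) * log((f_R + p_R) / (f_0 + p_0))`, the per-week
#' log-ratio of a barcode's frequency in a treated replicate to its frequency
#' in the control. Pseudo-frequencies are added only where the corresponding
#' input is exactly zero (the formula is undefined at f_0 = 0, where de novo
#' barcodes typically sit), so results for barcodes observed on both sides
#' are identical with or without pseudocounts. Natural log by default;
#' classification depends only on the sign of r, which is base-invariant.
#'
#' @param f_R Frequencies in the treated replicate (vectorized).
#' @param f_0 Frequencies in the control.
#' @param T_weeks Selection time in weeks (> 0).
#' @param pseudo Pseudo-frequency (or length-2 vector `c(p_R, p_0)`) applied
#'   to zero entries only; default 0 (zeros then give +/-Inf).
#' @param log_base Logarithm base (default `exp(1)`).
#' @return Numeric vector of growth rates (per week).
#' @examples
#' growth_rate(0.02, 0.01, T_weeks = 4)   # log(2)/4
#' @export
growth_rate <- function(f_R, f_0, T_weeks, pseudo = 0, log_base = exp(1)) {
  if (T_weeks <= 0) stop("T_weeks must be > 0")
  if (any(f_R < 0) || any(f_0 < 0)) stop("frequencies must be nonnegative")
  pseudo <- rep(pseudo, length.out = 2L)
  num <- f_R + ifelse(f_R == 0, pseudo[1L], 0)
  den <- f_0 + ifelse(f_0 == 0, pseudo[2L], 0)
  log(num / den, base = log_base) / T_weeks
}

#' Classify barcodes as pre-existing, de novo, or sensitive
#'
#' The main analysis entry point. Starting from a raw count table it (i)
#' removes barcodes below the low-count threshold in all treated samples and
#' the control, (ii) converts counts to within-sample frequencies, (iii)
#' computes each barcode's per-week growth rate in every treated replicate
#' against the DMSO control, and (iv) labels every detected barcode-replicate
#' pair: positive growth rate in >= 2 replicates = "preexisting", positive in
#' exactly one = "denovo", non-positive = "sensitive". Pairs where the
#' barcode has zero reads in that replicate are labelled "excluded" (the
#' barcode is not detected there and contributes nothing to that replicate's
#' class shares).
#'
#' Zero frequencies on either side of the ratio receive a pseudo-frequency of
#' `pseudo_reads` reads divided by the corresponding column's read sum, so
#' growth rates are finite even for barcodes absent from the control.
#'
#' `detect_rule` controls how "detected in at least two replicates" is read:
#' `"positive_growth"` (default) requires a positive growth rate in >= 2
#' replicates before calling a barcode pre-existing; `"nonzero_count"` only
#' requires presence (nonzero reads) in >= 2 replicates.
#'
#' @param counts Integer count matrix (barcodes x samples).
#' @param replicates Treated replicate column names.
#' @param control DMSO control column name.
#' @param T_weeks Selection time in weeks.
#' @param min_count Low-count filter threshold (default 2).
#' @param pseudo_reads Pseudocount in read units applied to zero frequencies
#'   (default 0.5).
#' @param detect_rule `"positive_growth"` or `"nonzero_count"`.
#' @param log_base Log base for growth rates.
#' @return An object of class `clone_dynamics`: list with `records`
#'   (data.frame: `barcode`, `replicate`, `r`, `detected`, `label`),
#'   `summary` (per-replicate class shares in percent), `freq`, `counts`
#'   (filtered), and the call parameters.
#' @examples
#' cnt <- rbind(bc1 = c(initial = 50L, DMSO = 40L, RepA = 90L, RepB = 80L, RepC = 10L),
#'              bc2 = c(initial = 50L, DMSO = 60L, RepA = 10L, RepB = 20L, RepC = 90L))
#' fit <- classify_barcodes(cnt, c("RepA", "RepB", "RepC"), "DMSO", T_weeks = 4)
#' fit$records
#' @export
classify_barcodes <- function(counts, replicates, control, T_weeks,
                              min_count = 2L, pseudo_reads = 0.5,
                              detect_rule = c("positive_growth",
                                              "nonzero_count"),
                              log_base = exp(1)) {
  detect_rule <- match.arg(detect_rule)
  counts <- filter_low_count(counts, replicates, control, min_count)
  if (nrow(counts) == 0L) stop("no barcodes survive the low-count filter")
  # frequencies over the columns entering the growth-rate ratio; other
  # samples (initial, medium) are carried in $counts for reporting only
  freq <- to_frequencies(counts[, c(control, replicates), drop = FALSE])
  col_sums <- colSums(counts)

  n <- nrow(freq)
  r_mat <- matrix(NA_real_, n, length(replicates),
                  dimnames = list(rownames(freq), replicates))
  det <- matrix(FALSE, n, length(replicates),
                dimnames = dimnames(r_mat))
  f0 <- freq[, control]
  p0 <- pseudo_reads / col_sums[control]
  for (j in seq_along(replicates)) {
    rep_j <- replicates[j]
    fR <- freq[, rep_j]
    pR <- pseudo_reads / col_sums[rep_j]
    r_mat[, j] <- growth_rate(fR, f0, T_weeks, pseudo = c(pR, p0),
                              log_base = log_base)
    det[, j] <- fR > 0
  }

  pos <- det & r_mat > 0
  n_basis <- if (detect_rule == "positive_growth") rowSums(pos)
             else rowSums(det)

  label <- matrix("excluded", n, length(replicates),
                  dimnames = dimnames(r_mat))
  for (j in seq_along(replicates)) {
    lab <- ifelse(pos[, j],
                  ifelse(n_basis >= 2L, "preexisting", "denovo"),
                  "sensitive")
    lab[!det[, j]] <- "excluded"
    label[, j] <- lab
  }

  records <- data.frame(
    barcode = rep(rownames(freq), times = length(replicates)),
    replicate = rep(replicates, each = n),
    r = as.vector(r_mat),
    detected = as.vector(det),
    label = as.vector(label),
    stringsAsFactors = FALSE)

  obj <- structure(list(
    records = records, freq = freq, counts = counts,
    replicates = replicates, control = control, T_weeks = T_weeks,
    min_count = min_count, pseudo_reads = pseudo_reads,
    detect_rule = detect_rule), class = "clone_dynamics")
  obj$summary <- class_frequency_summary(obj)
  obj
}

#' Read-frequency-weighted class shares per replicate
#'
#' For each treated replicate, sums the replicate-column frequencies of the
#' barcodes in each class, renormalizes over classified (detected) barcodes,
#' and reports percentages. The three shares sum to 100.
#'
#' @param x A `clone_dynamics` object, or a records data.frame (then `freq`
#'   must be supplied).
#' @param freq Frequency matrix (barcodes x samples) when `x` is a
#'   data.frame.
#' @return data.frame: `replicate`, `preexisting`, `denovo`, `sensitive`
#'   (percent).
#' @export
class_frequency_summary <- function(x, freq = NULL) {
  if (inherits(x, "clone_dynamics")) {
    records <- x$records; freq <- x$freq
  } else records <- x
  stopifnot(!is.null(freq))
  classes <- c("preexisting", "denovo", "sensitive")
  reps <- unique(records$replicate)
  out <- lapply(reps, function(rp) {
    rec <- records[records$replicate == rp & records$label != "excluded", ]
    w <- freq[rec$barcode, rp]
    tot <- sum(w)
    shares <- vapply(classes,
                     function(cl) 100 * sum(w[rec$label == cl]) / tot, 0)
    data.frame(replicate = rp, t(shares), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out) <- c("replicate", classes)
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 against planted truth
#'
#' Compares predicted labels with ground-truth labels per class, pooled over
#' replicates and also per replicate. Only detected (classified)
#' barcode-replicate pairs enter the confusion matrix. F1 is 0 when both
#' precision and recall are undefined or 0.
#'
#' @param records Records data.frame from [classify_barcodes()] (or the
#'   `clone_dynamics` object).
#' @param truth data.frame with `barcode`, `replicate`, `true_class`
#'   (as produced by [truth_labels()]); must cover all classified barcodes.
#' @return data.frame: `replicate` ("all" = pooled), `class`, `precision`,
#'   `recall`, `f1`, `n_true`, `n_pred`.
#' @export
recovery_metrics <- function(records, truth) {
  if (inherits(records, "clone_dynamics")) records <- records$records
  rec <- records[records$label != "excluded", ]
  key <- function(d) paste(d$barcode, d$replicate)
  m <- match(key(rec), key(truth))
  if (anyNA(m))
    stop("truth labels missing for ", sum(is.na(m)),
         " classified barcode-replicate pair(s)")
  rec$true_class <- truth$true_class[m]

  one <- function(d, rp) {
    do.call(rbind, lapply(c("preexisting", "denovo", "sensitive"),
      function(cl) {
        tp <- sum(d$label == cl & d$true_class == cl)
        fp <- sum(d$label == cl & d$true_class != cl)
        fn <- sum(d$label != cl & d$true_class == cl)
        prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
        recl <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
        f1 <- if (!is.na(prec) && !is.na(recl) && prec + recl > 0)
          2 * prec * recl / (prec + recl) else 0
        data.frame(replicate = rp, class = cl, precision = prec,
                   recall = recl, f1 = f1, n_true = tp + fn,
                   n_pred = tp + fp, stringsAsFactors = FALSE)
      }))
  }
  out <- one(rec, "all")
  for (rp in unique(rec$replicate))
    out <- rbind(out, one(rec[rec$replicate == rp, ], rp))
  rownames(out) <- NULL
  out
}

#' @export
print.clone_dynamics <- function(x, ...) {
  cat(sprintf(
    "Clonal dynamics classification (%d barcodes, T = %g weeks, control = %s)\n",
    nrow(x$freq), x$T_weeks, x$control))
  tab <- table(x$records$label[x$records$label != "excluded"],
               x$records$replicate)
  print(tab)
  cat("\nRead-frequency-weighted class shares (%):\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
summary.clone_dynamics <- function(object, ...) {
  rec <- object$records
  cls <- c("preexisting", "denovo", "sensitive")
  uniq <- lapply(object$replicates, function(rp)
    vapply(cls, function(cl)
      sum(rec$replicate == rp & rec$label == cl), 0L))
  un <- do.call(rbind, uniq)
  rownames(un) <- object$replicates
  structure(list(shares = object$summary, unique_counts = un,
                 T_weeks = object$T_weeks, detect_rule = object$detect_rule),
            class = "summary.clone_dynamics")
}

#' @export
print.summary.clone_dynamics <- function(x, ...) {
  cat(sprintf("Selection time: %g weeks; detection rule: %s\n\n",
              x$T_weeks, x$detect_rule))
  cat("Unique barcodes per class:\n")
  print(x$unique_counts)
  cat("\nRead-frequency-weighted shares (%):\n")
  print(x$shares, digits = 4)
  invisible(x)
}

#' Stacked class-share bar plot
#'
#' Draws one stacked bar per treated replicate showing the
#' read-frequency-weighted share of pre-existing, de novo, and sensitive
#' barcodes.
#'
#' @param x A `clone_dynamics` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.clone_dynamics <- function(x, ...) {
  sm <- x$summary
  m <- t(as.matrix(sm[, c("preexisting", "denovo", "sensitive")]))
  colnames(m) <- sm$replicate
  graphics::barplot(m, col = c("#E69F00", "#6B8E23", "#5B9BD5"),
                    legend.text = rownames(m),
                    ylab = "share of reads (%)", ...)
  invisible(x)
}
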