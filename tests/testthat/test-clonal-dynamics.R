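# Growth rates and the pre-existing / de novo / sensitive classifier.

reps <- c("RepA", "RepB", "RepC")

test_that("low-count filter drops rows below threshold everywhere", {
  m <- rbind(
    drop    = c(initial = 9L, DMSO = 1L, RepA = 1L, RepB = 0L, RepC = 1L),
    rescued = c(initial = 0L, DMSO = 0L, RepA = 2L, RepB = 0L, RepC = 0L),
    control = c(initial = 0L, DMSO = 5L, RepA = 0L, RepB = 0L, RepC = 0L))
  out <- filter_low_count(m, reps, "DMSO")
  expect_identical(rownames(out), c("rescued", "control"))
  # the initial column never rescues a row
  expect_false("drop" %in% rownames(out))
  expect_error(filter_low_count(m, c("RepA", "RepX"), "DMSO"),
               "unknown sample.*RepX")
})

test_that("frequencies are column-normalized and scale-invariant", {
  m <- cbind(s1 = c(a = 3L, b = 1L))
  f <- to_frequencies(m)
  expect_equal(unname(f[, 1]), c(0.75, 0.25))
  expect_equal(to_frequencies(m * 17L), f)
  single <- cbind(s = c(only = 5L))
  expect_equal(unname(to_frequencies(single)[1, 1]), 1)
  expect_error(to_frequencies(cbind(s1 = c(a = 0L))), "all-zero.*s1")
})

test_that("growth rate matches its closed form and sign convention", {
  expect_equal(growth_rate(0.02, 0.01, 4), log(2) / 4)
  expect_equal(growth_rate(0.005, 0.01, 16), log(0.5) / 16)
  expect_lt(growth_rate(0.005, 0.01, 16), 0)
  expect_equal(growth_rate(0.3, 0.3, 7), 0)
  expect_error(growth_rate(0.1, 0.1, 0), "T_weeks")
  expect_error(growth_rate(-0.1, 0.1, 1), "nonnegative")
  # log base only rescales, never changes sign
  expect_equal(growth_rate(0.02, 0.01, 4, log_base = 2), 1 / 4)
  # pseudocounts touch only zero entries
  expect_equal(growth_rate(0.02, 0.01, 4, pseudo = 0.123), log(2) / 4)
  expect_equal(growth_rate(0, 0.01, 4, pseudo = c(0.001, 0.5)),
               log(0.001 / 0.01) / 4)
})

# count table engineered so growth-rate signs are known by construction:
# column sums are equal, so frequency ratios equal count ratios
engineered_counts <- function() {
  rbind(
    both_up  = c(initial = 10L, DMSO = 10L, RepA = 40L, RepB = 30L, RepC = 2L),
    one_up   = c(initial = 10L, DMSO = 10L, RepA = 2L,  RepB = 5L,  RepC = 50L),
    all_down = c(initial = 30L, DMSO = 40L, RepA = 18L, RepB = 25L, RepC = 8L),
    filler   = c(initial = 50L, DMSO = 40L, RepA = 40L, RepB = 40L, RepC = 40L))
}

test_that("classifier applies the stated rules per replicate", {
  cnt <- engineered_counts()
  expect_equal(unname(colSums(cnt[, c("DMSO", reps)])), rep(100L, 4))
  fit <- classify_barcodes(cnt, reps, "DMSO", T_weeks = 4)
  rec <- fit$records
  lab <- function(bc, rp) rec$label[rec$barcode == bc & rec$replicate == rp]
  # positive r in RepA & RepB => pre-existing there, sensitive in RepC
  expect_equal(lab("both_up", "RepA"), "preexisting")
  expect_equal(lab("both_up", "RepB"), "preexisting")
  expect_equal(lab("both_up", "RepC"), "sensitive")
  # positive r only in RepC => de novo there
  expect_equal(lab("one_up", "RepC"), "denovo")
  expect_equal(lab("one_up", "RepA"), "sensitive")
  # negative r everywhere => sensitive
  expect_true(all(rec$label[rec$barcode == "all_down"] == "sensitive"))
  # mutual exclusivity and exhaustiveness over detected pairs
  expect_true(all(rec$label %in%
                    c("preexisting", "denovo", "sensitive", "excluded")))
  expect_true(all(rec$detected == (rec$label != "excluded")))
  # sign coherence
  expect_true(all(rec$r[rec$label %in% c("preexisting", "denovo")] > 0))
  expect_true(all(rec$r[rec$label == "sensitive"] <= 0))
})

test_that("pseudocounts leave doubly-observed barcodes untouched", {
  cnt <- engineered_counts()
  f1 <- classify_barcodes(cnt, reps, "DMSO", 4, pseudo_reads = 0.5)
  f2 <- classify_barcodes(cnt, reps, "DMSO", 4, pseudo_reads = 1e-6)
  expect_equal(f1$records$r, f2$records$r)   # no zero counts anywhere
})

test_that("class shares are frequency-weighted and sum to 100", {
  cnt <- engineered_counts()
  fit <- classify_barcodes(cnt, reps, "DMSO", 4)
  sm <- fit$summary
  expect_equal(rowSums(sm[, c("preexisting", "denovo", "sensitive")]),
               rep(100, 3), tolerance = 1e-10, ignore_attr = TRUE)
  # RepA: preexisting = both_up only, 40 reads of 100
  expect_equal(sm$preexisting[sm$replicate == "RepA"], 40)
  expect_equal(sm$denovo[sm$replicate == "RepC"], 50)
})

test_that("classifier agrees with the brute-force oracle on random tables", {
  for (seed in 1:60) {
    cnt <- random_count_table(30, seed)
    flt <- tryCatch(filter_low_count(cnt, reps, "DMSO"), error = function(e) NULL)
    if (is.null(flt) || nrow(flt) == 0 ||
        any(colSums(flt[, c(reps, "DMSO"), drop = FALSE]) == 0)) next
    fit <- classify_barcodes(cnt, reps, "DMSO", 4)
    orc <- oracle_classify(cnt, reps, "DMSO", 4)
    got <- fit$records[order(fit$records$barcode, fit$records$replicate),
                       c("barcode", "replicate", "r", "label")]
    want <- orc[order(orc$barcode, orc$replicate), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("nonzero-count detection rule is selectable", {
  # barcode present in two replicates but growing only in one
  cnt <- rbind(
    x = c(initial = 10L, DMSO = 10L, RepA = 40L, RepB = 5L, RepC = 0L),
    f = c(initial = 90L, DMSO = 90L, RepA = 60L, RepB = 95L, RepC = 100L))
  strict <- classify_barcodes(cnt, reps, "DMSO", 4,
                              detect_rule = "positive_growth")
  loose <- classify_barcodes(cnt, reps, "DMSO", 4,
                             detect_rule = "nonzero_count")
  lab <- function(fit, bc, rp)
    fit$records$label[fit$records$barcode == bc & fit$records$replicate == rp]
  expect_equal(lab(strict, "x", "RepA"), "denovo")
  expect_equal(lab(loose, "x", "RepA"), "preexisting")
  expect_equal(lab(strict, "x", "RepC"), "excluded")
})

test_that("recovery metrics behave at the identity and adversarial poles", {
  rec <- data.frame(
    barcode = rep(c("a", "b", "c"), each = 3),
    replicate = rep(reps, 3),
    r = 1, detected = TRUE,
    label = rep(c("preexisting", "denovo", "sensitive"), each = 3),
    stringsAsFactors = FALSE)
  truth <- rec[, c("barcode", "replicate")]
  truth$true_class <- rec$label
  m <- recovery_metrics(rec, truth)
  expect_true(all(m$f1 == 1))

  flipped <- rec
  flipped$label <- ifelse(rec$label == "preexisting", "sensitive",
                          ifelse(rec$label == "sensitive", "preexisting",
                                 rec$label))
  mf <- recovery_metrics(flipped, truth)
  expect_equal(mf$recall[mf$replicate == "all" &
                           mf$class == "preexisting"], 0)

  expect_error(recovery_metrics(rec, truth[-1, ]), "missing")
})

test_that("random labels on balanced truth give chance-level F1", {
  set.seed(99)
  n <- 3000
  cls <- c("preexisting", "denovo", "sensitive")
  rec <- data.frame(
    barcode = sprintf("b%04d", seq_len(n)), replicate = "RepA",
    r = 1, detected = TRUE,
    label = sample(cls, n, replace = TRUE), stringsAsFactors = FALSE)
  truth <- data.frame(barcode = rec$barcode, replicate = "RepA",
                      true_class = sample(cls, n, replace = TRUE),
                      stringsAsFactors = FALSE)
  m <- recovery_metrics(rec, truth)
  expect_true(all(abs(m$f1[m$replicate == "all"] - 1 / 3) < 0.05))
})
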