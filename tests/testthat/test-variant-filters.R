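# Whole-exome post-filters: coverage gating, VAF enrichment, CNA consensus.

mk_variant <- function(pos, depths, vafs, chrom = "chr1") {
  samples <- c("initial", "DMSO", "RepA", "RepB", "RepC")
  row <- data.frame(chrom = chrom, pos = pos, ref = "G", alt = "A",
                    stringsAsFactors = FALSE)
  for (i in seq_along(samples)) {
    row[[paste0("depth_", samples[i])]] <- depths[i]
    row[[paste0("vaf_", samples[i])]] <- vafs[i]
  }
  row
}

test_that("coverage filter requires min depth in every sample and a target hit", {
  targets <- data.frame(chrom = "chr1", start = 100, end = 200)
  inside <- mk_variant(150, c(12, 15, 20, 11, 30), rep(0.1, 5))
  low <- mk_variant(160, c(12, 9, 20, 11, 30), rep(0.1, 5))
  outside <- mk_variant(500, c(50, 50, 50, 50, 50), rep(0.1, 5))
  tab <- rbind(inside, low, outside)
  out <- coverage_filter(tab, targets)
  expect_equal(out$pos, 150)
  out2 <- coverage_filter(tab, targets = NULL)
  expect_equal(out2$pos, c(150, 500))
})

test_that("BED parsing converts coordinates and flags malformed lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tpanel1", "chr2\t0\t50\tpanel2"), path)
  bed <- read_bed(path)
  expect_equal(bed$start, c(100, 1))   # 0-based half-open -> 1-based inclusive
  expect_equal(bed$end, c(200, 50))
  writeLines(c("chr1\t99\t200", "chr1\tnot_a_number\t5"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t99"), path)
  expect_error(read_bed(path), "line 1")
})

test_that("VAF enrichment follows the two-fold rule with control exclusion", {
  tab <- rbind(
    # enriched in all three replicates, DMSO quiet -> conserved
    mk_variant(1, rep(100, 5), c(0.10, 0.11, 0.25, 0.22, 0.30)),
    # DMSO also >= 2x -> not enriched anywhere
    mk_variant(2, rep(100, 5), c(0.10, 0.25, 0.30, 0.30, 0.30)),
    # enriched only in RepA -> private
    mk_variant(3, rep(100, 5), c(0.10, 0.09, 0.25, 0.05, 0.08)))
  res <- vaf_enrichment(tab)
  expect_equal(res$sharing, c("conserved", "none", "private:RepA"))
  expect_identical(res$sharing, oracle_enrichment(tab))
  # boundary: exactly 2x counts as enriched (rule is >=)
  boundary <- mk_variant(4, rep(100, 5), c(0.10, 0.10, 0.20, 0.30, 0.25))
  expect_equal(vaf_enrichment(boundary)$sharing, "conserved")
})

test_that("zero initial VAF is floored at half a read", {
  tab <- mk_variant(1, c(50, 100, 100, 100, 100), c(0, 0.001, 0.3, 0.3, 0.3))
  res <- vaf_enrichment(tab)
  expect_equal(res$vaf_initial_eff, 1 / 100)   # 1 / (2 * 50)
  expect_equal(res$sharing, "conserved")       # 0.3 >= 2 * 0.01, DMSO 0.001 quiet
  expect_identical(res$sharing, oracle_enrichment(tab))
})

test_that("planted enrichment truth is recovered exactly", {
  tab <- simulate_variant_table(20, 2, 3, seed = 7)
  res <- vaf_enrichment(tab)
  expect_identical(res$sharing[tab$truth == "conserved"],
                   rep("conserved", 2))
  expect_identical(res$sharing[grepl("^private", tab$truth)],
                   sub("^private:", "private:",
                       tab$truth[grepl("^private", tab$truth)]))
  expect_true(all(res$sharing[tab$truth == "none"] == "none"))
  # nothing planted -> nothing flagged
  tab0 <- simulate_variant_table(15, 0, 0, seed = 8)
  expect_true(all(vaf_enrichment(tab0)$sharing == "none"))
})

test_that("coverage and enrichment filters compose order-invariantly", {
  tab <- simulate_variant_table(40, 3, 3, seed = 9, n_lowcov = 5)
  seq_res <- vaf_enrichment(coverage_filter(tab, NULL))
  depth_ok <- rowSums(as.matrix(
    tab[, grep("^depth_", names(tab))]) >= 10) == 5
  joint <- vaf_enrichment(tab[depth_ok, , drop = FALSE])
  expect_identical(seq_res, joint)
})

test_that("significance filter uses a strict inequality", {
  calls <- data.frame(sample = "RepA", chrom = "chr1", start = 1,
                      end = 10, copy_number = 3, status = "gain",
                      p_value = c(0.049, 0.05, 0.001))
  out <- significant_cna_filter(calls)
  expect_equal(out$p_value, c(0.049, 0.001))
  expect_equal(nrow(significant_cna_filter(calls[0, ])), 0)
  calls$p_value <- NULL
  expect_error(significant_cna_filter(calls), "p_value")
})

test_that("consensus requires two same-direction replicates absent in DMSO", {
  mk <- function(sample, start, end, status = "gain", chrom = "chr19")
    data.frame(sample = sample, chrom = chrom, start = start, end = end,
               copy_number = 3, status = status, p_value = 0.01,
               stringsAsFactors = FALSE)
  cc <- function(...) suppressWarnings(cna_consensus(...))
  # identical gain in RepB and RepC, nothing in DMSO
  calls <- rbind(mk("RepB", 1, 1e6), mk("RepC", 1, 1e6))
  res <- cc(calls)
  expect_equal(nrow(res), 1)
  expect_equal(res$support, "RepB,RepC")
  expect_equal(c(res$start, res$end), c(1, 1e6))

  # single replicate: below min_replicates
  expect_equal(nrow(cc(mk("RepA", 1, 1e6))), 0)

  # same-direction overlapping DMSO call vetoes the region
  veto <- rbind(mk("RepA", 1, 1e6), mk("RepB", 1, 1e6),
                mk("DMSO", 5e5, 2e6))
  expect_equal(nrow(cc(veto)), 0)
  # opposite-direction DMSO call does not veto
  noveto <- rbind(mk("RepA", 1, 1e6), mk("RepB", 1, 1e6),
                  mk("DMSO", 5e5, 2e6, status = "loss"))
  expect_equal(nrow(cc(noveto)), 1)

  # gains never pair with losses
  mixed <- rbind(mk("RepA", 1, 1e6), mk("RepB", 1, 1e6, status = "loss"))
  expect_equal(nrow(cc(mixed)), 0)

  # support is maximal: a triple reports once with all three replicates
  triple <- rbind(mk("RepA", 1, 1e6), mk("RepB", 1, 1e6), mk("RepC", 1, 1e6))
  res3 <- cc(triple)
  expect_equal(nrow(res3), 1)
  expect_equal(res3$n_support, 3)

  expect_warning(cna_consensus(calls, replicates = c("RepB", "RepC", "RepZ")),
                 "RepZ")
})

test_that("reciprocal overlap threshold is monotone", {
  mk <- function(sample, start, end)
    data.frame(sample = sample, chrom = "chr2", start = start, end = end,
               copy_number = 3, status = "gain", p_value = 0.01,
               stringsAsFactors = FALSE)
  # 60% reciprocal overlap
  calls <- rbind(mk("RepA", 1, 100), mk("RepB", 41, 140))
  strictr <- suppressWarnings(cna_consensus(calls, min_reciprocal_overlap = 0.7))
  lax <- suppressWarnings(cna_consensus(calls, min_reciprocal_overlap = 0.5))
  expect_equal(nrow(strictr), 0)
  expect_equal(nrow(lax), 1)
  expect_equal(c(lax$start, lax$end), c(41, 100))
  for (seed in 1:20) {
    calls <- random_segments(seed)
    hi <- suppressWarnings(cna_consensus(calls, min_reciprocal_overlap = 0.8))
    lo <- suppressWarnings(cna_consensus(calls, min_reciprocal_overlap = 0.4))
    # every high-threshold consensus persists at the lower threshold,
    # possibly absorbed into a clique with wider support
    for (i in seq_len(nrow(hi))) {
      sup <- strsplit(hi$support[i], ",")[[1]]
      match_found <- any(vapply(seq_len(nrow(lo)), function(j) {
        lo$chrom[j] == hi$chrom[i] && lo$status[j] == hi$status[i] &&
          all(sup %in% strsplit(lo$support[j], ",")[[1]])
      }, TRUE))
      expect_true(match_found)
    }
  }
})

test_that("consensus agrees with exhaustive enumeration on random sets", {
  for (seed in 1:40) {
    calls <- random_segments(seed)
    got <- canon_consensus(suppressWarnings(cna_consensus(calls)))
    want <- canon_consensus(
      oracle_consensus(calls, c("RepA", "RepB", "RepC")))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("gene annotation intersects segments in genomic order", {
  genes <- data.frame(chrom = "chr1",
                      start = c(100, 300, 500, 700, 900),
                      end = c(150, 350, 550, 750, 950),
                      name = paste0("G", 1:5))
  segs <- data.frame(chrom = "chr1", start = c(120, 160, 320),
                     end = c(130, 170, 760))
  ann <- annotate_genes(segs, genes)
  expect_equal(ann$genes, c("G1", "", "G2,G3,G4"))
})
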