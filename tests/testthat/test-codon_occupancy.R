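make_offsets <- function(lengths = c(21L, 29L), offset = 12L) {
  data.table::data.table(length = lengths, offset = offset)
}

test_that("site assignment follows the floor-division arithmetic", {
  seq <- paste0(strrep("A", 10), "ATG", "GGT", "AAA", "CCC", "GTT", "TAA",
                strrep("C", 40))
  ts <- transcript_set(c(tx1 = seq),
                       data.frame(transcript_id = "tx1", cds_start = 10,
                                  cds_end = 28))
  lib <- sample_library(data.frame(transcript_id = "tx1", start = 1L,
                                   length = 29L), "s1", "WT", 1L, ts)
  asg <- assign_sites(lib, ts, make_offsets(), c(21L, 29L))
  expect_identical(asg$p_index, 1L)   # P-site nt 13 -> codon 1
  expect_identical(asg$a_index, 2L)
  expect_identical(asg$p_codon, "GGT")
  expect_identical(asg$a_codon, "AAA")
})

test_that("reads whose A-site would pass the stop codon are excluded", {
  ts <- toy_transcripts()   # 5 codons, cds_start 12; P index max admitted 3
  lib <- sample_library(data.frame(
    transcript_id = "tx1",
    # P-site nt = start + 12; P indices: 3 (stop in A-site, kept),
    # 4 (P-site on the stop codon, dropped), 0 (start codon, kept)
    start = c(9L, 12L, 0L), length = 21L), "s1", "WT", 1L)
  asg <- assign_sites(lib, ts, make_offsets(21L), 21L)
  expect_identical(asg$p_index, c(3L, 0L))
  expect_identical(asg$a_codon[1], "TAA")
  expect_identical(attr(asg, "n_out_of_bounds"), 1L)
})

test_that("assignment requires an offset for every admitted length", {
  ts <- toy_transcripts()
  lib <- sample_library(data.frame(transcript_id = "tx1", start = 0L,
                                   length = 21L), "s1", "WT", 1L)
  expect_error(assign_sites(lib, ts, make_offsets(21L), c(21L, 29L)), "29")
})

test_that("assigned indices equal simulator ground truth on jitter-free data", {
  cfg <- small_sim_config(n_reads = 5000L, jitter_prob = 0,
                          open_length_dist = c("21" = 1),
                          occupied_length_dist = c("29" = 1))
  ts <- simulate_transcriptome(cfg, 2)
  sim <- simulate_library(ts, cfg, "WT", 1L, 5)
  asg <- assign_sites(sim$library, ts, make_offsets(), c(21L, 29L))
  expect_identical(nrow(asg), nrow(sim$truth))
  expect_identical(asg$p_index, sim$truth$p_index)
  expect_identical(asg$a_index, sim$truth$a_index)
})

test_that("codon counting spans 64 codons and conserves totals per stratum", {
  ts <- toy_transcripts()
  asg <- data.table::data.table(
    sample_id = "s1", transcript_id = "tx1", length = 21L,
    p_index = c(0L, 0L, 2L), a_index = c(1L, 1L, 3L),
    p_codon = c("ATG", "ATG", "AAA"), a_codon = c("GGT", "GGT", "AAA"))
  cnt <- count_site_codons(asg)
  expect_identical(cnt[site == "A" & codon == "GGT", count], 2L)
  expect_identical(cnt[site == "A" & codon == "AAA", count], 1L)
  per_stratum <- cnt[, .(n = sum(count), rows = .N), by = .(site, length)]
  expect_true(all(per_stratum$n == 3L))
  expect_true(all(per_stratum$rows == 64L))
})

test_that("normalization divides by the stratum total and flags empty strata", {
  codons <- all_codons()
  cnt <- data.table::CJ(sample_id = "s1", site = c("A", "P"), length = 21L,
                        codon = codons)
  cnt[, count := 0L]
  cnt[site == "A" & codon == "GGT", count := 30L]
  cnt[site == "A" & codon == "AAA", count := 70L]
  occ <- normalize_frequencies(cnt)
  expect_equal(occ[site == "A" & codon == "GGT", freq], 0.30)
  expect_equal(occ[, sum(freq), by = .(site, length)]$V1, 1,
               tolerance = 1e-12)
  expect_false(any(is.na(occ$freq)))
  empty <- attr(occ, "empty_strata")
  expect_identical(empty$site, "P")
})

test_that("condition aggregation averages replicate frequencies", {
  occ <- data.table::data.table(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    site = "A", length = 21L, codon = rep(c("GGT", "AAA"), 3),
    count = 1L, freq = c(0.02, 0.98, 0.04, 0.96, 0.03, 0.97))
  design <- data.frame(sample_id = c("s1", "s2", "s3"), condition = "WT")
  m <- aggregate_condition(occ, design)
  expect_equal(m[codon == "GGT", freq], 0.03)
  expect_identical(m$n_replicates, c(3L, 3L))
  expect_equal(m[, sum(freq)], 1)
  # single replicate is the identity
  m1 <- aggregate_condition(occ[sample_id == "s1"],
                            design[design$sample_id == "s1", , drop = FALSE])
  expect_equal(m1[codon == "GGT", freq], 0.02)
  expect_error(aggregate_condition(occ, design[1:2, ]), "s3")
})

test_that("pooled-count aggregation renormalizes summed counts", {
  occ <- data.table::data.table(
    sample_id = rep(c("s1", "s2"), each = 2),
    site = "A", length = 21L, codon = rep(c("GGT", "AAA"), 2),
    count = c(10L, 90L, 30L, 70L), freq = c(0.1, 0.9, 0.3, 0.7))
  design <- data.frame(sample_id = c("s1", "s2"), condition = "WT")
  m <- aggregate_condition(occ, design, method = "pooled_counts")
  expect_equal(m[codon == "GGT", freq], 40 / 200)
  expect_equal(m[, sum(freq)], 1)
})

test_that("condition comparison computes ratios, differences and flags", {
  mk <- function(freqs, condition) data.table::data.table(
    condition = condition, site = "A", length = 21L,
    codon = names(freqs), freq = as.numeric(freqs), n_replicates = 3L)
  a <- mk(c(GGT = 0.04, AAA = 0.46, CCC = 0.50, TTT = 0.00), "mut")
  b <- mk(c(GGT = 0.02, AAA = 0.48, CCC = 0.50, TTT = 0.00), "wt")
  rt <- compare_conditions(a, b, "A", 21L, codon_group = "GGT")
  expect_equal(rt[codon == "GGT", ratio], 2.0)
  expect_equal(rt[codon == "GGT", diff], 0.02)
  expect_true(rt[codon == "TTT", undefined])
  expect_true(is.na(rt[codon == "TTT", ratio]))
  # sorted descending with undefined last
  expect_identical(rt$codon[1], "GGT")
  expect_identical(rt$codon[nrow(rt)], "TTT")
  expect_equal(attr(rt, "group_summary")$mean_ratio, 2.0)
  # identical tables give unit ratios and zero differences
  rt0 <- compare_conditions(a, a, "A", 21L)
  expect_equal(rt0[undefined == FALSE, ratio], rep(1, 3))
  expect_equal(rt0$diff, rep(0, 4))
  expect_error(compare_conditions(a, b, "P", 21L), "site P")
})

test_that("rank_codon_shifts returns the top ratios in order", {
  rt <- data.table::data.table(
    site = "A", length = 21L, codon = c("GGT", "GGC", "AAA", "TTT"),
    freq_a = c(0.4, 0.3, 0.2, 0), freq_b = c(0.1, 0.2, 0.2, 0),
    ratio = c(4, 1.5, 1, NA), diff = c(0.3, 0.1, 0, 0),
    undefined = c(FALSE, FALSE, FALSE, TRUE))
  top <- rank_codon_shifts(rt, 2L)
  expect_identical(top$codon, c("GGT", "GGC"))
  expect_error(rank_codon_shifts(rt, 0L), "top_k")
})

test_that("an injected glycine pause is found by the ranking", {
  gly <- codon_family("G")
  cfg <- gly_pause_config(n_reads = 5e4L, n_transcripts = 10L,
                          cds_codons = 150L)
  ts <- simulate_transcriptome(cfg, 3)
  libs <- data.table::rbindlist(lapply(1:2, function(i)
    simulate_library(ts, cfg, c("WT", "G240R")[i], 1L, 100 + i)$library))
  off <- make_offsets()
  occ <- normalize_frequencies(count_site_codons(
    assign_sites(libs, ts, off, c(21L, 29L))))
  design <- unique(libs[, .(sample_id, condition)])
  m <- aggregate_condition(occ, design)
  rt <- compare_conditions(m[condition == "G240R"], m[condition == "WT"],
                           "A", 21L, codon_group = gly)
  expect_setequal(rank_codon_shifts(rt, 4L)$codon, gly)
})
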