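#' Assign P- and A-site codons to footprints
#'
#' For each read of an admitted length L the P-site nucleotide is
#' `5' end + offset(L)` and the P-site codon index is
#' `floor((P-site nt - cds_start) / 3)` — floor division, so out-of-frame
#' reads are assigned to the codon containing the P-site nucleotide rather
#' than rejected (periodicity is enforced upstream by length selection).
#' Reads are kept iff the P-site index lies in `[0, n_codons - 2]`: the
#' P-site is always a sense codon, the A-site (`P + 1`) may be any codon
#' including the stop. Reads of non-admitted lengths are skipped.
#'
#' @param library a [sample_library()].
#' @param transcripts a [transcript_set()].
#' @param offsets offset table from [infer_psite_offsets()]; must cover
#'   every admitted length.
#' @param lengths admitted read lengths.
#' @return data.table `sample_id`, `transcript_id`, `length`, `p_index`,
#'   `a_index`, `p_codon`, `a_codon`; the number of reads excluded by the
#'   site-bounds rule is attached as attribute `"n_out_of_bounds"`.
#' @export
assign_sites <- function(library, transcripts, offsets, lengths) {
  lengths <- sort(as.integer(lengths))
  offs <- psite_offset(offsets, lengths)   # errors if any length missing
  lib <- with_cds(library, transcripts)[length %in% lengths]
  lib[, offset := offs[match(length, lengths)]]
  lib[, p_index := (start + offset - cds_start) %/% 3L]
  n0 <- nrow(lib)
  lib <- lib[p_index >= 0L & p_index <= n_codons - 2L]
  lib[, a_index := p_index + 1L]
  # per-transcript codon lookup
  lib[, `:=`(
    p_codon = codon_at(transcripts, transcript_id[1], p_index),
    a_codon = codon_at(transcripts, transcript_id[1], a_index)
  ), by = transcript_id]
  out <- lib[, .(sample_id, transcript_id, length, p_index, a_index,
                 p_codon, a_codon)]
  setattr(out, "n_out_of_bounds", n0 - nrow(out))
  out[]
}

#' Count codons by sample, site and read length
#'
#' Exact integer counts over all 64 codons (zeros included) for both the
#' A- and the P-site. Stop codons can only be counted in the A-site; their
#' P-site rows are structurally zero.
#'
#' @param assignments output of [assign_sites()].
#' @return data.table `sample_id`, `site`, `length`, `codon`, `count`, with
#'   64 codon rows per (sample, site, length) stratum.
#' @export
count_site_codons <- function(assignments) {
  a <- as.data.table(assignments)
  cnt <- rbindlist(list(
    a[, .(count = .N), by = .(sample_id, length, codon = a_codon)][, site := "A"],
    a[, .(count = .N), by = .(sample_id, length, codon = p_codon)][, site := "P"]
  ))
  full <- CJ(sample_id = unique(a$sample_id), site = c("A", "P"),
             length = unique(a$length), codon = all_codons())
  cnt <- cnt[full, on = c("sample_id", "site", "length", "codon")]
  cnt[is.na(count), count := 0L]
  setcolorder(cnt, c("sample_id", "site", "length", "codon", "count"))
  setorder(cnt, sample_id, site, length, codon)
  cnt[]
}

#' Normalize codon counts to per-stratum frequencies
#'
#' Within each (sample, site, read length) stratum, each codon's count is
#' divided by the stratum total — the normalization "by the sum of all reads
#' for a given read length, site and sample". Strata with zero reads are
#' excluded (never divided) and reported via attribute `"empty_strata"`.
#'
#' @param counts output of [count_site_codons()].
#' @return occupancy table: data.table `sample_id`, `site`, `length`,
#'   `codon`, `count`, `freq`.
#' @export
normalize_frequencies <- function(counts) {
  cnt <- copy(as.data.table(counts))
  cnt[, total := sum(count), by = .(sample_id, site, length)]
  empty <- unique(cnt[total == 0L, .(sample_id, site, length)])
  cnt <- cnt[total > 0L]
  cnt[, freq := count / total]
  cnt[, total := NULL]
  setattr(cnt, "empty_strata", empty[])
  cnt[]
}

#' Average per-replicate frequencies within conditions
#'
#' Default aggregation is the arithmetic mean of the per-replicate frequency
#' vectors per (condition, site, length, codon) — frequency means over
#' triplicates. `method = "pooled_counts"` instead sums raw counts across
#' replicates and renormalizes, an alternative reading of
#' sum-then-average aggregation; both keep each stratum summing to 1.
#'
#' @param occupancy per-sample occupancy table from
#'   [normalize_frequencies()].
#' @param design data.frame `sample_id`, `condition` covering every sample.
#' @param method `"mean_frequency"` (default) or `"pooled_counts"`.
#' @return condition-level occupancy table: data.table `condition`, `site`,
#'   `length`, `codon`, `freq`, `n_replicates`.
#' @export
aggregate_condition <- function(occupancy, design,
                                method = c("mean_frequency", "pooled_counts")) {
  method <- match.arg(method)
  occ <- as.data.table(occupancy)
  des <- as.data.table(design)
  unmapped <- setdiff(unique(occ$sample_id), des$sample_id)
  if (length(unmapped))
    stop("sample(s) not mapped to a condition: ",
         paste(unmapped, collapse = ", "))
  occ <- merge(occ, des[, .(sample_id, condition)], by = "sample_id")
  if (method == "mean_frequency") {
    out <- occ[, .(freq = mean(freq), n_replicates = .N),
               by = .(condition, site, length, codon)]
  } else {
    out <- occ[, .(count = sum(count), n_replicates = .N),
               by = .(condition, site, length, codon)]
    out[, freq := count / sum(count), by = .(condition, site, length)]
    out[, count := NULL]
  }
  setorder(out, condition, site, length, codon)
  out[]
}

#' Compare condition-mean codon frequencies in one stratum
#'
#' Per codon, the ratio `freq_a / freq_b` and difference `freq_a - freq_b`
#' of the two condition means in the requested (site, read length) stratum,
#' sorted by descending ratio. Ratios with a zero denominator are flagged
#' undefined (`NA`), never epsilon-padded. If `codon_group` is given (e.g.
#' the glycine family), the group's mean per-codon ratio is attached as
#' attribute `"group_summary"`.
#'
#' @param mean_a,mean_b condition-level occupancy tables (one condition
#'   each) from [aggregate_condition()]; numerator first (e.g. mutant).
#' @param site `"A"` or `"P"`.
#' @param length read length of the stratum (nt).
#' @param codon_group optional codon group to summarize.
#' @return ratio table: data.table `site`, `length`, `codon`, `freq_a`,
#'   `freq_b`, `ratio`, `diff`, `undefined`.
#' @export
compare_conditions <- function(mean_a, mean_b, site, length,
                               codon_group = NULL) {
  pick <- function(tab, who) {
    t <- as.data.table(tab)
    s <- site; L <- as.integer(length)
    t <- t[t$site == s & t$length == L]
    if (nrow(t) == 0L)
      stop("stratum (site ", s, ", length ", L, ") missing from ", who)
    t[, .(codon, freq)]
  }
  a <- pick(mean_a, "mean_a"); b <- pick(mean_b, "mean_b")
  rt <- merge(a, b, by = "codon", suffixes = c("_a", "_b"))
  rt[, `:=`(site = site, length = as.integer(length))]
  rt[, undefined := freq_b == 0]
  rt[, ratio := fifelse(undefined, NA_real_, freq_a / freq_b)]
  rt[, diff := freq_a - freq_b]
  setnames(rt, c("freq_a", "freq_b"), c("freq_a", "freq_b"))
  setcolorder(rt, c("site", "length", "codon", "freq_a", "freq_b",
                    "ratio", "diff", "undefined"))
  setorder(rt, -ratio, na.last = TRUE)
  if (!is.null(codon_group)) {
    g <- rt[codon %in% codon_group & !undefined]
    setattr(rt, "group_summary", list(
      codons = sort(codon_group),
      mean_ratio = if (nrow(g)) mean(g$ratio) else NA_real_,
      mean_diff = if (nrow(g)) mean(g$diff) else NA_real_
    ))
  }
  rt[]
}

#' Rank codons by between-condition frequency shift
#'
#' @param ratios ratio table from [compare_conditions()].
#' @param top_k number of codons to return (>= 1).
#' @return the `top_k` rows with the largest defined ratios, sorted
#'   descending.
#' @export
rank_codon_shifts <- function(ratios, top_k) {
  if (top_k < 1) stop("top_k must be >= 1")
  rt <- as.data.table(ratios)[undefined == FALSE]
  setorder(rt, -ratio)
  head(rt, top_k)
}
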