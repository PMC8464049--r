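# Shared fixture builders. Everything is generated in code; no data files.

# One transcript with a hand-readable CDS: 12 nt UTR5, ATG GGT AAA CCC TAA,
# 10 nt UTR3. cds_start = 12, cds_end = 27, 5 codons.
toy_transcripts <- function() {
  seq <- paste0("ACGTACGTACGT", "ATG", "GGT", "AAA", "CCC", "TAA",
                "GTGTGTGTGT")
  transcript_set(c(tx1 = seq),
                 data.frame(transcript_id = "tx1", cds_start = 12,
                            cds_end = 27))
}

# Small simulator config for fast tests; scenario knobs via ...
small_sim_config <- function(n_reads = 2e4, ...) {
  sim_config(n_transcripts = 8L, cds_codons = 120L, n_reads = n_reads, ...)
}

# The glycine-shortage scenario of the main analysis: rare glycine codons
# (family usage 0.01) and a 2x open-state dwell multiplier in the mutant.
gly_pause_config <- function(n_reads = 2e4, factor = 2, usage_mass = 0.01,
                             ...) {
  sim_config(
    codon_usage = codon_usage_with_family(codon_family("G"), usage_mass),
    pause_factors = pause_factors("G240R", "open", codon_family("G"), factor),
    n_reads = n_reads, ...)
}

wt_mut_design <- function(n_rep = 3L) {
  data.frame(condition = rep(c("WT", "G240R"), each = n_rep),
             replicate = rep(seq_len(n_rep), 2L))
}

# Brute-force site-frequency oracle, independent of the package internals:
# walks every P-site position of every transcript with plain substring
# arithmetic and accumulates dwell weights per codon. Jitter-free.
brute_force_site_freqs <- function(transcripts, p_open, state,
                                   factors = NULL, start_enrichment = 1) {
  acc_a <- setNames(numeric(64), all_codons())
  acc_p <- setNames(numeric(64), all_codons())
  prior <- if (state == "open") p_open else 1 - p_open
  for (id in transcript_ids(transcripts)) {
    seq <- transcripts$sequences[[id]]
    cs <- transcripts$cds[transcript_id == id, cds_start]
    ce <- transcripts$cds[transcript_id == id, cds_end]
    n <- (ce - cs) / 3
    for (p in 0:(n - 2)) {
      pc <- substr(seq, cs + 3 * p + 1, cs + 3 * p + 3)
      ac <- substr(seq, cs + 3 * (p + 1) + 1, cs + 3 * (p + 1) + 3)
      f <- if (!is.null(factors) && ac %in% names(factors)) factors[[ac]] else 1
      w <- prior * f * if (p == 0) start_enrichment else 1
      acc_a[ac] <- acc_a[ac] + w
      acc_p[pc] <- acc_p[pc] + w
    }
  }
  list(A = acc_a / sum(acc_a), P = acc_p / sum(acc_p))
}
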