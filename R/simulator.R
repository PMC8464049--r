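#' Configuration for the two-state footprint simulator
#'
#' The simulator draws ribosome footprints under an explicit two-state codon
#' dwell-time model. Each sampled ribosome sits with a sense codon in its
#' P-site and the next codon (possibly the stop) in its A-site, and is in one
#' of two states: `open` (pre-accommodation, no tRNA in the A-site, short
#' footprints) or `occupied` (post-accommodation, long footprints). A
#' position/state pair is sampled with probability proportional to
#' `state prior x dwell multiplier of the A-site codon x start-codon
#' enrichment`, so codons whose decoding is slow accumulate proportionally
#' more footprints — the mechanism by which tRNA shortage becomes measurable.
#'
#' @param n_transcripts number of transcripts.
#' @param cds_codons sense codons per CDS, excluding start and stop.
#' @param utr5_len,utr3_len UTR lengths in nt (must leave room for the P-site
#'   offset and the longest footprint).
#' @param codon_usage probability vector over the 61 sense codons (default
#'   uniform); see [codon_usage_with_family()].
#' @param p_open prior probability that a sampled ribosome is in the open-A
#'   state (default 0.4, which yields a clearly bimodal length histogram).
#' @param open_length_dist probability vector over footprint lengths
#'   20--22 nt, mode 21 (pre-accommodation footprints).
#' @param occupied_length_dist probability vector over lengths 27--30 nt,
#'   mode 29 (post-accommodation footprints).
#' @param psite_offset_truth named vector (`open`, `occupied`): nt from the
#'   footprint 5' end to the first nt of the P-site codon (default 12).
#' @param jitter_prob probability that a 5' end shifts by 1 nt (split evenly
#'   between -1 and +1; default 0.1, giving ~90% in-frame reads).
#' @param start_enrichment dwell multiplier for the position with the start
#'   codon in the P-site (default 5), emulating the initiation-site pileup
#'   seen in ribosome profiling metagenes; it is what makes the start-codon
#'   metagene peak (and hence offset calibration) well defined.
#' @param pause_factors data.frame `condition`, `state`, `codon`, `factor`
#'   of dwell multipliers (>= 0); omitted combinations default to 1. See
#'   [pause_factors()].
#' @param n_reads footprints per sample, before size selection.
#' @param size_window c(min, max) retained fragment lengths in nt
#'   (default 15--35, the library size-selection window).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 50L,
                       cds_codons = 300L,
                       utr5_len = 50L,
                       utr3_len = 50L,
                       codon_usage = codon_usage_uniform(),
                       p_open = 0.4,
                       open_length_dist = c("20" = 0.15, "21" = 0.70, "22" = 0.15),
                       occupied_length_dist = c("27" = 0.10, "28" = 0.20,
                                                "29" = 0.55, "30" = 0.15),
                       psite_offset_truth = c(open = 12L, occupied = 12L),
                       jitter_prob = 0.1,
                       start_enrichment = 5,
                       pause_factors = NULL,
                       n_reads = 1e5,
                       size_window = c(15L, 35L)) {
  stopifnot(n_transcripts >= 1, cds_codons >= 2,
            utr5_len >= 0, utr3_len >= 0,
            p_open >= 0, p_open <= 1,
            jitter_prob >= 0, jitter_prob <= 1,
            start_enrichment >= 0, n_reads >= 1,
            length(size_window) == 2, size_window[1] <= size_window[2])
  check_prob_vector(codon_usage, "codon_usage")
  if (any(names(codon_usage) %in% stop_codons() & codon_usage > 0))
    stop("codon_usage assigns mass to stop codon(s)")
  if (!setequal(names(codon_usage), sense_codons()))
    stop("codon_usage must be named over the 61 sense codons")
  check_prob_vector(open_length_dist, "open_length_dist")
  check_prob_vector(occupied_length_dist, "occupied_length_dist")
  stopifnot(all(c("open", "occupied") %in% names(psite_offset_truth)))
  if (!is.null(pause_factors)) {
    pause_factors <- as.data.table(pause_factors)
    stopifnot(all(c("condition", "state", "codon", "factor") %in%
                    names(pause_factors)))
    if (any(pause_factors$factor < 0)) stop("pause factors must be >= 0")
    if (!all(pause_factors$state %in% c("open", "occupied")))
      stop("pause factor states must be 'open' or 'occupied'")
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    cds_codons = as.integer(cds_codons),
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    codon_usage = codon_usage[sense_codons()],
    p_open = p_open,
    open_length_dist = open_length_dist,
    occupied_length_dist = occupied_length_dist,
    psite_offset_truth = vapply(psite_offset_truth[c("open", "occupied")],
                                as.integer, integer(1)),
    jitter_prob = jitter_prob,
    start_enrichment = start_enrichment,
    pause_factors = pause_factors,
    n_reads = as.integer(n_reads),
    size_window = as.integer(size_window)
  ), class = "sim_config")
}

check_prob_vector <- function(p, what) {
  if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(what, " must be a named non-negative vector summing to 1")
  invisible(p)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_transcripts, "transcripts x", x$cds_codons,
      "sense codons;", x$n_reads, "reads/sample; p_open =", x$p_open, "\n")
  if (!is.null(x$pause_factors)) {
    cat("pause factors:\n")
    print(x$pause_factors)
  }
  invisible(x)
}

#' Declare condition-specific dwell multipliers
#'
#' Convenience constructor for the `pause_factors` table of [sim_config()].
#' Rows from several calls can be combined with `rbind()`. A multiplier of 2
#' on the open state of the glycine family, for instance, makes ribosomes
#' dwell twice as long pre-accommodation at glycine codons in that condition.
#'
#' @param condition condition label the multiplier applies to.
#' @param state `"open"` or `"occupied"`.
#' @param codons codons receiving the multiplier.
#' @param factor dwell multiplier (>= 0).
#' @return data.table with columns `condition`, `state`, `codon`, `factor`.
#' @export
pause_factors <- function(condition, state, codons, factor) {
  data.table(condition = condition, state = state, codon = codons,
             factor = factor)
}

#' Simulate a transcriptome
#'
#' Each transcript is `UTR5 + ATG + cds_codons sense codons (i.i.d. from
#' codon_usage) + TAA + UTR3`; UTR bases are uniform. Deterministic given
#' the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a [transcript_set()].
#' @export
simulate_transcriptome <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  b <- c("A", "C", "G", "T")
  ids <- sprintf("tx%04d", seq_len(config$n_transcripts))
  seqs <- vapply(ids, function(id) {
    utr5 <- paste(sample(b, config$utr5_len, replace = TRUE), collapse = "")
    cds <- paste(sample(names(config$codon_usage), config$cds_codons,
                        replace = TRUE, prob = config$codon_usage),
                 collapse = "")
    utr3 <- paste(sample(b, config$utr3_len, replace = TRUE), collapse = "")
    paste0(utr5, "ATG", cds, "TAA", utr3)
  }, character(1))
  cds <- data.table(transcript_id = ids,
                    cds_start = config$utr5_len,
                    cds_end = config$utr5_len + 3L * (config$cds_codons + 2L))
  transcript_set(seqs, cds)
}

# Candidate elongation positions: one row per (transcript, P-site codon
# index p), p in 0..(n_codons - 2), so the A-site (p + 1) may be any codon
# including the stop but the P-site is always a sense codon.
candidate_positions <- function(transcripts) {
  cds <- transcripts$cds
  rbindlist(lapply(seq_len(nrow(cds)), function(i) {
    n <- cds$n_codons[i]
    cv <- transcripts$codons[[cds$transcript_id[i]]]
    data.table(transcript_id = cds$transcript_id[i],
               p_index = 0:(n - 2L),
               p_codon = cv[1:(n - 1L)],
               a_codon = cv[2:n],
               cds_start = cds$cds_start[i],
               tx_len = cds$tx_len[i])
  }))
}

# Joint (position, state) sampling weights for one condition:
# prior(state) * pause factor(condition, state, A-site codon) *
# start-codon enrichment at p = 0.
state_weights <- function(transcripts, config, condition) {
  cand <- candidate_positions(transcripts)
  w <- rbindlist(list(
    copy(cand)[, `:=`(state = "open", prior = config$p_open)],
    copy(cand)[, `:=`(state = "occupied", prior = 1 - config$p_open)]
  ))
  w[, factor := 1]
  pf <- config$pause_factors
  if (!is.null(pf)) {
    cond <- condition
    pf <- pf[pf$condition == cond]
    if (nrow(pf)) {
      w[pf, factor := i.factor, on = c("state", a_codon = "codon")]
    }
  }
  w[, weight := prior * factor * fifelse(p_index == 0L,
                                         config$start_enrichment, 1)]
  w
}

#' Simulate one footprint library with ground truth
#'
#' Samples `n_reads` (position, state) pairs with probability proportional to
#' the dwell weights, draws the footprint length from the state-conditional
#' length distribution, places the 5' end at
#' `P-site codon start - psite_offset_truth[state]`, applies 1-nt jitter,
#' and resamples any read that would fall outside its transcript. Reads of
#' non-modal length additionally shift their 5' end by a binomial split of
#' the length difference between the two footprint ends (nuclease trimming
#' heterogeneity), so only the modal lengths — 21 nt open, 29 nt occupied
#' under the defaults — retain single-frame 5' ends and survive periodicity
#' selection, as in real libraries where only those lengths are analyzed.
#'
#' @param transcripts a [transcript_set()].
#' @param config a [sim_config()].
#' @param condition condition label (selects pause factors).
#' @param replicate replicate number.
#' @param seed integer seed.
#' @param sample_id sample label (default `condition_repN`).
#' @return list with `library` (a [sample_library()]) and `truth`
#'   (data.table: `read_id`, `transcript_id`, `state`, `p_index`, `a_index`,
#'   `start_prejitter`, `jitter`).
#' @export
simulate_library <- function(transcripts, config, condition, replicate, seed,
                             sample_id = sprintf("%s_rep%d", condition,
                                                 replicate)) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  cw <- state_weights(transcripts, config, condition)
  if (all(cw$weight == 0)) stop("all dwell weights are zero")
  offs <- config$psite_offset_truth
  modal <- c(open = modal_length(config$open_length_dist),
             occupied = modal_length(config$occupied_length_dist))
  draw <- function(m) {
    idx <- sample.int(nrow(cw), m, replace = TRUE, prob = cw$weight)
    d <- cw[idx, .(transcript_id, p_index, cds_start, tx_len, state)]
    d[, length := 0L]
    is_open <- d$state == "open"
    if (any(is_open))
      d[is_open, length := sample_lengths(config$open_length_dist, sum(is_open))]
    if (any(!is_open))
      d[!is_open, length := sample_lengths(config$occupied_length_dist,
                                           sum(!is_open))]
    # non-modal lengths: the extra trimming/extension relative to the modal
    # footprint is split binomially between the 5' and 3' ends, so only the
    # modal lengths carry a clean single-frame 5' end
    d[, delta := length - modal[state]]
    d[, end_shift5 := 0L]
    het <- d$delta != 0L
    if (any(het))
      d[het, end_shift5 := -sign(delta) *
          stats::rbinom(sum(het), abs(delta), 0.5)]
    u <- runif(m)
    d[, jitter := fifelse(u < config$jitter_prob / 2, -1L,
                          fifelse(u < config$jitter_prob, 1L, 0L))]
    d[, start_prejitter := cds_start + 3L * p_index - offs[state] + end_shift5]
    d[, start := start_prejitter + jitter]
    d
  }
  d <- draw(config$n_reads)
  repeat {
    bad <- which(d$start < 0L | d$start + d$length > d$tx_len)
    if (!length(bad)) break
    repl <- draw(length(bad))
    for (col in names(d)) set(d, i = bad, j = col, value = repl[[col]])
  }
  d[, read_id := seq_len(.N)]
  lib <- sample_library(d[, .(transcript_id, start, length)],
                        sample_id, condition, replicate, transcripts)
  truth <- d[, .(read_id, transcript_id, state, p_index,
                 a_index = p_index + 1L, start_prejitter, end_shift5, jitter)]
  list(library = lib, truth = truth)
}

sample_lengths <- function(dist, m) {
  as.integer(names(dist))[sample.int(length(dist), m, replace = TRUE,
                                     prob = dist)]
}

modal_length <- function(dist) as.integer(names(dist))[which.max(dist)]

#' Apply fragment size selection
#'
#' Keeps reads with `min_len <= length <= max_len` (both inclusive),
#' preserving order; the number of removed reads is reported with a message.
#'
#' @param library a [sample_library()].
#' @param min_len,max_len window bounds in nt.
#' @return filtered library.
#' @export
size_select <- function(library, min_len = 15L, max_len = 35L) {
  stopifnot(min_len <= max_len)
  keep <- library$length >= min_len & library$length <= max_len
  message("size_select: removed ", sum(!keep), " of ", length(keep),
          " read(s) outside [", min_len, ", ", max_len, "] nt")
  library[keep]
}

#' Analytic expected site frequencies under a simulator configuration
#'
#' Closed-form oracle for the occupancy statistic: enumerates every candidate
#' (position, state) pair of the transcriptome with its dwell weight, applies
#' the 1-nt jitter model analytically (a -1 nt shift moves the assigned
#' P-site codon one codon upstream under floor-division assignment; reads
#' jittered upstream of codon 0 are excluded, as in [assign_sites()]), and
#' normalizes within each (site, read length) stratum. For state s, codon c
#' with coverage-weighted A-site usage u_c and dwell multiplier f_c the
#' jitter-free A-site frequency is `f_c u_c / sum(f u)`; length strata mix
#' states through the state-conditional length distributions. The per-length
#' values are exact for the modal lengths (the strata periodicity selection
#' admits); non-modal lengths carry an extra 5'-end trimming shift the
#' jitter adjustment does not model.
#'
#' @param config a [sim_config()].
#' @param transcripts the [transcript_set()] the libraries are drawn from.
#' @param condition condition label.
#' @param apply_jitter include the jitter adjustment (default TRUE; FALSE
#'   gives the frequencies of the true, pre-jitter site codons).
#' @return data.table `site` (`A`/`P`), `length`, `codon`, `freq`, spanning
#'   all 64 codons per stratum; per-state frequencies are attached as
#'   attribute `"state_freqs"`.
#' @export
expected_site_frequencies <- function(config, transcripts, condition,
                                      apply_jitter = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cw <- state_weights(transcripts, config, condition)
  j <- if (apply_jitter) config$jitter_prob else 0
  # jitter outcomes: -1 shifts the assigned codon upstream; 0 and +1 keep it
  shifted <- copy(cw)
  shifted[, weight := weight * (j / 2)]
  # p -> p - 1: drop p = 0 (assigned index would be negative -> excluded)
  shifted <- shifted[p_index > 0L]
  prev <- candidate_prev_codons(transcripts)
  shifted[prev, `:=`(p_codon = i.prev_p, a_codon = i.prev_a),
          on = c("transcript_id", "p_index")]
  unshifted <- copy(cw)[, weight := weight * (1 - j / 2)]
  contrib <- rbindlist(list(unshifted, shifted), use.names = TRUE)
  # aggregate per state x codon for both sites
  agg_site <- function(col, site) {
    x <- contrib[, .(w = sum(weight)), by = .(state, codon = get(col))]
    x[, site := site]
    x
  }
  agg <- rbindlist(list(agg_site("a_codon", "A"), agg_site("p_codon", "P")))
  tot <- agg[, .(tot = sum(w)), by = .(state, site)]
  agg[tot, freq := w / i.tot, on = c("state", "site")]
  full <- CJ(state = c("open", "occupied"), site = c("A", "P"),
             codon = all_codons())
  agg <- agg[full, on = c("state", "site", "codon")]
  agg[is.na(freq), freq := 0]
  # mix states into length strata
  state_mass <- contrib[, .(mass = sum(weight)), by = state]
  ldists <- list(open = config$open_length_dist,
                 occupied = config$occupied_length_dist)
  lw <- rbindlist(lapply(names(ldists), function(s) {
    data.table(state = s, length = as.integer(names(ldists[[s]])),
               p_len = as.numeric(ldists[[s]]))
  }))
  lw[state_mass, mass := i.mass, on = "state"]
  lw[, w_len := p_len * mass]
  out <- agg[lw, on = "state", allow.cartesian = TRUE]
  out <- out[, .(freq = sum(freq * w_len) / sum(w_len)),
             by = .(site, length, codon)]
  setorder(out, site, length, codon)
  state_freqs <- agg[, .(state, site, codon, freq)]
  setattr(out, "state_freqs", state_freqs[])
  out[]
}

# codons one position upstream: for p >= 1, the assigned P/A codons after a
# -1 nt jitter are those of position p - 1
candidate_prev_codons <- function(transcripts) {
  cand <- candidate_positions(transcripts)
  cand[, .(transcript_id, p_index = p_index + 1L,
           prev_p = p_codon, prev_a = a_codon)]
}
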