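#' Footprint length histogram of CDS-mapped reads
#'
#' Counts reads per footprint length and characterizes the bimodality of the
#' distribution by the modal length within a low window (<= 24 nt,
#' pre-accommodation footprints) and a high window (>= 25 nt,
#' post-accommodation footprints). With `cds_only = TRUE` (the default) only
#' reads whose 5' end lies within `[cds_start - 30, cds_end)` are counted,
#' the operational definition of "CDS-mapped" used throughout.
#'
#' @param library a [sample_library()] (may contain several samples).
#' @param transcripts a [transcript_set()].
#' @param cds_only restrict to CDS-mapped reads.
#' @param low_max,high_min boundaries of the low/high mode windows (nt).
#' @return data.table `sample_id`, `length`, `count`, `fraction`; modes per
#'   sample attached as attribute `"modes"` (`NA` where a window is empty).
#' @export
length_histogram <- function(library, transcripts, cds_only = TRUE,
                             low_max = 24L, high_min = 25L) {
  lib <- with_cds(library, transcripts)
  if (cds_only)
    lib <- lib[start >= cds_start - 30L & start < cds_end]
  hist <- lib[, .(count = .N), by = .(sample_id, length)]
  hist[, fraction := count / sum(count), by = sample_id]
  setorder(hist, sample_id, length)
  modes <- hist[, .(
    low_mode = mode_in_window(length, count, length <= low_max),
    high_mode = mode_in_window(length, count, length >= high_min)
  ), by = sample_id]
  setattr(hist, "modes", modes[])
  hist[]
}

mode_in_window <- function(length, count, in_win) {
  if (!any(in_win)) return(NA_integer_)
  length[in_win][which.max(count[in_win])]
}

# annotate alignments with their transcript's CDS columns, preserving
# row order (downstream ground-truth comparisons rely on it)
with_cds <- function(library, transcripts) {
  lib <- copy(as.data.table(library))
  validate_alignments(lib, transcripts)
  idx <- match(lib$transcript_id, transcripts$cds$transcript_id)
  lib[, `:=`(cds_start = transcripts$cds$cds_start[idx],
             cds_end = transcripts$cds$cds_end[idx],
             tx_len = transcripts$cds$tx_len[idx],
             n_codons = transcripts$cds$n_codons[idx])]
  lib
}

#' Start-codon metagene profile
#'
#' Aggregates footprint 5' ends relative to the annotated start codon
#' (position 0 = first nt of the AUG) over all transcripts, for reads of one
#' length. The pre-accommodation and post-accommodation footprint
#' populations both peak at minus the P-site offset.
#'
#' @param library a [sample_library()].
#' @param transcripts a [transcript_set()].
#' @param read_length footprint length to profile (nt).
#' @param window `c(from, to)` window of relative positions.
#' @return data.table `rel_pos`, `count` covering the full window
#'   (zero-filled).
#' @export
metagene_start_profile <- function(library, transcripts, read_length,
                                   window = c(-40L, 60L)) {
  stopifnot(window[1] < 0, window[2] > 0)
  lib <- with_cds(library, transcripts)[length == read_length]
  lib[, rel_pos := start - cds_start]
  prof <- lib[rel_pos >= window[1] & rel_pos <= window[2],
              .(count = .N), by = rel_pos]
  grid <- data.table(rel_pos = window[1]:window[2])
  prof <- prof[grid, on = "rel_pos"]
  prof[is.na(count), count := 0L]
  setorder(prof, rel_pos)
  prof[]
}

#' Infer per-length P-site offsets from start-codon metagenes
#'
#' For each requested read length L the offset is the candidate o in
#' `[6, L - 6]` maximizing the metagene count at relative position -o —
#' footprints whose 5' end sits o nt upstream of start codons have the AUG
#' in their P-site. Ties break toward the smallest offset. Lengths with
#' fewer than `min_reads` reads starting in `[cds_start - 40, cds_start)`
#' are omitted with a warning; downstream lookups of omitted lengths fail.
#'
#' @param library a [sample_library()] (samples are pooled).
#' @param transcripts a [transcript_set()].
#' @param lengths read lengths to calibrate.
#' @param min_reads minimum upstream-window reads per length (default 200).
#' @return offset table: data.table `length`, `offset`, `n_upstream`.
#' @export
infer_psite_offsets <- function(library, transcripts, lengths,
                                min_reads = 200L) {
  lib <- with_cds(library, transcripts)
  lib[, rel_pos := start - cds_start]
  up <- lib[rel_pos >= -40L & rel_pos <= -1L]
  rows <- lapply(sort(unique(as.integer(lengths))), function(L) {
    upL <- up[length == L]
    if (nrow(upL) < min_reads) {
      warning("length ", L, " nt: only ", nrow(upL),
              " read(s) in the upstream window (< ", min_reads,
              "); omitted from offset table", call. = FALSE)
      return(NULL)
    }
    cand <- 6L:(L - 6L)
    cnt <- vapply(cand, function(o) sum(upL$rel_pos == -o), integer(1))
    data.table(length = L, offset = cand[which.max(cnt)],
               n_upstream = nrow(upL))
  })
  rbindlist(rows)
}

#' Look up a P-site offset
#'
#' @param offsets an offset table from [infer_psite_offsets()].
#' @param lengths read length(s) to look up.
#' @return integer offsets.
#' @export
psite_offset <- function(offsets, lengths) {
  idx <- match(as.integer(lengths), offsets$length)
  if (anyNA(idx))
    stop("no P-site offset for read length(s): ",
         paste(unique(lengths[is.na(idx)]), collapse = ", "))
  offsets$offset[idx]
}

#' Reading-frame fractions of inferred P-site positions
#'
#' Per (sample, read length), the fractions of CDS-internal reads whose
#' inferred P-site nucleotide (`5' end + offset`) falls in frame 0/1/2
#' relative to `cds_start`. Dominance of one frame is the 3-nt periodicity
#' hallmark of genuine ribosome footprints. Lengths absent from the offset
#' table use the raw 5' end and are flagged (`offset_used = NA`).
#'
#' @param library a [sample_library()].
#' @param transcripts a [transcript_set()].
#' @param offsets offset table from [infer_psite_offsets()].
#' @return data.table `sample_id`, `length`, `n_reads`, `frame0`, `frame1`,
#'   `frame2`, `offset_used`.
#' @export
frame_fractions <- function(library, transcripts, offsets) {
  lib <- with_cds(library, transcripts)
  off <- as.data.table(offsets)
  idx <- match(lib$length, off$length)
  lib[, offset_used := if (nrow(off)) off$offset[idx] else NA_integer_]
  lib[, psite := start + fifelse(is.na(offset_used), 0L, offset_used)]
  lib <- lib[psite >= cds_start & psite < cds_end]
  lib[, frame := (psite - cds_start) %% 3L]
  ft <- lib[, .(
    n_reads = .N,
    frame0 = mean(frame == 0L),
    frame1 = mean(frame == 1L),
    frame2 = mean(frame == 2L),
    offset_used = offset_used[1]
  ), by = .(sample_id, length)]
  setorder(ft, sample_id, length)
  ft[]
}

#' Select read lengths with strong 3-nt periodicity
#'
#' Returns the lengths whose maximal frame fraction reaches
#' `dominance_threshold` in every sample — the lengths admitted to codon
#' occupancy analysis. An explicit `override` (e.g. `c(21, 29)`) bypasses
#' selection.
#'
#' @param frames frame table from [frame_fractions()].
#' @param dominance_threshold minimal dominant-frame fraction
#'   (0.34 < threshold <= 1; default 0.6).
#' @param override explicit length set bypassing selection.
#' @return sorted integer vector of selected lengths.
#' @export
select_periodic_lengths <- function(frames, dominance_threshold = 0.6,
                                    override = NULL) {
  if (!is.null(override)) return(sort(as.integer(override)))
  stopifnot(dominance_threshold > 0.34, dominance_threshold <= 1)
  ft <- as.data.table(frames)
  ft[, max_frac := pmax(frame0, frame1, frame2)]
  sel <- ft[, .(ok = all(max_frac >= dominance_threshold) &
                  .N == length(unique(frames$sample_id))),
            by = length][ok == TRUE, sort(length)]
  if (!length(sel))
    stop("no read length passes the periodicity threshold (",
         dominance_threshold, "); lower the threshold or pass an explicit ",
         "length override")
  sel
}
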