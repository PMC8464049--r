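#' Configuration for an end-to-end pipeline run
#'
#' Two input modes. Simulation mode (`sim` given): the transcriptome and the
#' per-sample footprint libraries are generated under `sim` for every row of
#' `design` (`condition`, `replicate`), with per-sample seeds derived from
#' `seed`. File mode: `fasta`/`cds_table` give the transcripts and `design`
#' must also carry a `path` column (and optionally `format`) naming one
#' alignment file per sample.
#'
#' @param design data.frame with `condition` and `replicate` (file mode:
#'   plus `path`, optionally `format` and `sample_id`).
#' @param sim a [sim_config()] for simulation mode, else `NULL`.
#' @param fasta,cds_table transcript inputs for file mode.
#' @param condition_a,condition_b numerator and denominator conditions of
#'   the comparison (default: first and second condition of `design`).
#' @param lengths explicit admitted read lengths, bypassing periodicity
#'   selection (`NULL` = select automatically).
#' @param dominance_threshold periodicity dominance threshold for
#'   [select_periodic_lengths()].
#' @param size_window fragment size-selection window (nt).
#' @param metagene_window start-codon metagene window.
#' @param min_reads_offset minimum upstream reads for offset inference.
#' @param codon_group codon group summarized in every comparison (default
#'   the glycine family).
#' @param aggregate_method replicate aggregation, see
#'   [aggregate_condition()].
#' @param outdir output directory (`NULL` = no files written).
#' @param seed master seed for simulation mode.
#' @return object of class `run_config`.
#' @export
run_config <- function(design,
                       sim = NULL, fasta = NULL, cds_table = NULL,
                       condition_a = NULL, condition_b = NULL,
                       lengths = NULL, dominance_threshold = 0.6,
                       size_window = c(15L, 35L),
                       metagene_window = c(-40L, 60L),
                       min_reads_offset = 200L,
                       codon_group = codon_family("G"),
                       aggregate_method = "mean_frequency",
                       outdir = NULL, seed = 1L) {
  design <- as.data.table(design)
  stopifnot(all(c("condition", "replicate") %in% names(design)))
  if (anyDuplicated(design[, .(condition, replicate)]))
    stop("(condition, replicate) pairs must be unique")
  if (!"sample_id" %in% names(design))
    design[, sample_id := sprintf("%s_rep%d", condition,
                                  as.integer(replicate))]
  if (is.null(sim)) {
    if (is.null(fasta) || is.null(cds_table) || !"path" %in% names(design))
      stop("file mode needs fasta, cds_table and a design 'path' column")
    missing <- design$path[!file.exists(design$path)]
    if (length(missing))
      stop("alignment file(s) not found: ", paste(missing, collapse = ", "))
  }
  conds <- unique(design$condition)
  condition_a <- condition_a %||% conds[pmin(2L, length(conds))]
  condition_b <- condition_b %||% conds[1L]
  structure(list(
    design = design[], sim = sim, fasta = fasta, cds_table = cds_table,
    condition_a = condition_a, condition_b = condition_b,
    lengths = lengths, dominance_threshold = dominance_threshold,
    size_window = as.integer(size_window),
    metagene_window = as.integer(metagene_window),
    min_reads_offset = min_reads_offset,
    codon_group = codon_group,
    aggregate_method = aggregate_method,
    outdir = outdir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full simulate/load -> QC -> occupancy -> compare pipeline
#'
#' Executes, in order: input acquisition (simulation or file loading),
#' fragment size selection, CDS-mapped length histograms, P-site offset
#' inference on the pooled library, per-sample frame fractions, periodic
#' length selection, site assignment, codon counting, per-stratum
#' normalization, replicate aggregation, and the condition comparison for
#' every (site, admitted length) stratum. Identical inputs, config and seed
#' give identical outputs. When `config$outdir` is set, all tables are
#' written as TSV plus a machine-readable `summary.json` and the effective
#' config as `config.yaml`; on error a marker file `INCOMPLETE` is left in
#' the output directory.
#'
#' @param config a [run_config()].
#' @return (invisibly) object of class `ribopause_run`: list with
#'   `transcripts`, `histogram`, `offsets`, `frames`, `selected_lengths`,
#'   `occupancy`, `condition_means`, `ratios` (one ratio table per
#'   site x length), `group_ratios`, `accounting`, `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    file.create(file.path(config$outdir, "INCOMPLETE"))
  }
  res <- pipeline_stages(config)
  if (!is.null(config$outdir)) {
    write_pipeline_outputs(res, config)
    unlink(file.path(config$outdir, "INCOMPLETE"))
  }
  invisible(res)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

pipeline_stages <- function(config) {
  design <- config$design
  # -- inputs ---------------------------------------------------------------
  if (!is.null(config$sim)) {
    inputs <- stage("simulate", {
      transcripts <- simulate_transcriptome(config$sim, config$seed)
      libs <- lapply(seq_len(nrow(design)), function(i) {
        simulate_library(transcripts, config$sim,
                         condition = design$condition[i],
                         replicate = design$replicate[i],
                         seed = config$seed + 1000L * i,
                         sample_id = design$sample_id[i])$library
      })
      list(transcripts = transcripts, library = rbindlist(libs))
    })
  } else {
    inputs <- stage("load", {
      transcripts <- read_transcripts(config$fasta, config$cds_table)
      libs <- lapply(seq_len(nrow(design)), function(i) {
        fmt <- if ("format" %in% names(design)) design$format[i] else "tsv"
        read_alignments(design$path[i], format = fmt,
                        sample_id = design$sample_id[i],
                        condition = design$condition[i],
                        replicate = design$replicate[i],
                        transcripts = transcripts)
      })
      list(transcripts = transcripts, library = rbindlist(libs))
    })
  }
  transcripts <- inputs$transcripts
  lib0 <- inputs$library
  n_input <- lib0[, .(input = .N), by = sample_id]

  # -- size selection -------------------------------------------------------
  lib <- stage("size_select", suppressMessages(
    size_select(lib0, config$size_window[1], config$size_window[2])))
  n_sized <- lib[, .(sized = .N), by = sample_id]

  # -- QC and calibration ---------------------------------------------------
  histo <- stage("length_histogram", length_histogram(lib, transcripts))
  cand_lengths <- config$lengths %||% histo[, sort(unique(length))]
  offsets <- stage("infer_psite_offsets", suppressWarnings(
    infer_psite_offsets(lib, transcripts, cand_lengths,
                        min_reads = config$min_reads_offset)))
  frames <- stage("frame_fractions",
                  frame_fractions(lib, transcripts, offsets))
  selected <- stage("select_periodic_lengths", select_periodic_lengths(
    frames[length %in% offsets$length],
    dominance_threshold = config$dominance_threshold,
    override = config$lengths))

  # -- occupancy ------------------------------------------------------------
  assignments <- stage("assign_sites",
                       assign_sites(lib, transcripts, offsets, selected))
  n_admit <- assignments[, .(admitted = .N), by = sample_id]
  counts <- stage("count_site_codons", count_site_codons(assignments))
  occupancy <- stage("normalize_frequencies", normalize_frequencies(counts))
  means <- stage("aggregate_condition", aggregate_condition(
    occupancy, design[, .(sample_id, condition)],
    method = config$aggregate_method))

  # -- comparison -----------------------------------------------------------
  mean_a <- means[condition == config$condition_a]
  mean_b <- means[condition == config$condition_b]
  ratios <- list()
  group_rows <- list()
  for (s in c("A", "P")) for (L in selected) {
    rt <- stage("compare_conditions", compare_conditions(
      mean_a, mean_b, site = s, length = L,
      codon_group = config$codon_group))
    key <- sprintf("%s_%d", s, L)
    ratios[[key]] <- rt
    gs <- attr(rt, "group_summary")
    group_rows[[key]] <- data.table(site = s, length = L,
                                    group_mean_ratio = gs$mean_ratio,
                                    group_mean_diff = gs$mean_diff)
  }
  group_ratios <- rbindlist(group_rows)

  # -- read accounting ------------------------------------------------------
  not_admitted_len <- merge(n_sized,
    lib[length %in% selected, .(in_sel = .N), by = sample_id],
    by = "sample_id", all.x = TRUE)
  not_admitted_len[is.na(in_sel), in_sel := 0L]
  acct_in <- merge(merge(n_input, n_sized, by = "sample_id"),
                   merge(not_admitted_len[, .(sample_id, in_sel)], n_admit,
                         by = "sample_id", all = TRUE), by = "sample_id")
  acct_in[is.na(admitted), admitted := 0L]
  accounting <- stage("read_accounting", read_accounting(acct_in))

  summary <- list(
    selected_lengths = selected,
    condition_a = config$condition_a, condition_b = config$condition_b,
    codon_group = sort(config$codon_group),
    offsets = as.data.frame(offsets),
    group_ratios = as.data.frame(group_ratios),
    accounting = as.data.frame(accounting),
    length_modes = as.data.frame(attr(histo, "modes"))
  )
  structure(list(
    transcripts = transcripts, library = lib, histogram = histo,
    offsets = offsets, frames = frames, selected_lengths = selected,
    assignments = assignments, counts = counts, occupancy = occupancy,
    condition_means = means, ratios = ratios, group_ratios = group_ratios,
    accounting = accounting, summary = summary
  ), class = "ribopause_run")
}

#' Per-sample read accounting across pipeline filters
#'
#' Turns per-stage survivor counts into an explicit accounting table in
#' which every read discarded at any filter is attributed to exactly one
#' rule and counts are monotone non-increasing downstream. Violations of
#' either property are errors, so conservation is checked, not assumed.
#'
#' @param stage_counts data.table `sample_id`, `input`, `sized`, `in_sel`,
#'   `admitted` (reads surviving input, size selection, length admission and
#'   site-bounds filtering, respectively).
#' @return data.table `sample_id`, `stage`, `reads_in`, `removed`,
#'   `reads_out` with stages `size_selection`, `length_admission`,
#'   `site_bounds`.
#' @export
read_accounting <- function(stage_counts) {
  sc <- as.data.table(stage_counts)
  long <- sc[, {
    ins <- c(input, sized, in_sel)
    outs <- c(sized, in_sel, admitted)
    .(stage = c("size_selection", "length_admission", "site_bounds"),
      reads_in = ins, removed = ins - outs, reads_out = outs)
  }, by = sample_id]
  if (any(long$removed < 0))
    stop("read counts increased downstream — accounting violated")
  chk <- long[, .(ok = reads_out[3] + sum(removed) == reads_in[1]),
              by = sample_id]
  if (!all(chk$ok))
    stop("read accounting does not balance")
  long[]
}

#' @export
print.ribopause_run <- function(x, ...) {
  cat("ribopause_run: lengths {",
      paste(x$selected_lengths, collapse = ", "), "} selected\n", sep = "")
  cat("codon-group mean ratios (",
      paste(x$summary$codon_group, collapse = "/"), "):\n", sep = "")
  print(x$group_ratios)
  invisible(x)
}

write_pipeline_outputs <- function(res, config) {
  out <- config$outdir
  fwrite(res$histogram, file.path(out, "length_histogram.tsv"), sep = "\t")
  fwrite(res$offsets, file.path(out, "offset_table.tsv"), sep = "\t")
  fwrite(res$frames, file.path(out, "frame_table.tsv"), sep = "\t")
  fwrite(res$counts, file.path(out, "codon_counts.tsv"), sep = "\t")
  fwrite(res$occupancy, file.path(out, "codon_frequencies.tsv"), sep = "\t")
  fwrite(res$condition_means, file.path(out, "condition_means.tsv"),
         sep = "\t")
  for (key in names(res$ratios))
    fwrite(res$ratios[[key]], file.path(out, sprintf("ratios_%s.tsv", key)),
           sep = "\t")
  fwrite(res$group_ratios, file.path(out, "group_ratios.tsv"), sep = "\t")
  fwrite(res$accounting, file.path(out, "read_accounting.tsv"), sep = "\t")
  jsonlite::write_json(res$summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg <- config
  cfg$design <- as.data.frame(cfg$design)
  cfg$sim <- if (!is.null(cfg$sim)) {
    s <- unclass(cfg$sim)
    s$codon_usage <- as.list(s$codon_usage)
    s$pause_factors <- if (!is.null(s$pause_factors))
      as.data.frame(s$pause_factors)
    s
  }
  yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))
  invisible(NULL)
}
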