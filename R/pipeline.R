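# Pipeline entry points behind the command-line tool: scan (detect +
# aggregate + reports), extract (locate + window + verify), stats (genotype
# table -> panel statistics), simulate (synthetic fixtures). Logging is
# machine-parsable key=value lines; runs with identical config and inputs
# produce byte-identical outputs.

log_info <- function(step, ..., quiet = FALSE) {
  if (quiet) return(invisible())
  kv <- c(...)
  inform(paste0(step, " ", paste(names(kv), unname(kv), sep = "=",
                                 collapse = " ")))
}

#' Load a YAML run configuration
#'
#' Reads a small declarative config (any subset of `input`, `out_dir`, `k`,
#' `min_obs`, `merge_revcomp`, `min_flank`, `window`, `seed`, and per-unit
#' thresholds `min_mono` ... `min_hexa`) and merges it over defaults.
#'
#' @param path YAML file path.
#' @return A named list of run parameters.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- ssr_thresholds()
  nm <- c(min_mono = "1", min_di = "2", min_tri = "3", min_tetra = "4",
          min_penta = "5", min_hexa = "6")
  for (key in names(nm)) {
    if (!is.null(cfg[[key]])) th[[nm[[key]]]] <- as.integer(cfg[[key]])
  }
  defaults <- list(k = 10, min_obs = NULL, merge_revcomp = FALSE,
                   min_flank = 50, window = c(100, 300), seed = 1)
  utils::modifyList(c(defaults, list(thresholds = th)),
                    cfg[setdiff(names(cfg), names(nm))])
}

#' Run the scan stage: detect, aggregate, report
#'
#' Reads the (merged) transcript FASTA input, finds SSR runs, aggregates them
#' under flank keys, and writes `FindStr.result.detail` (all loci),
#' `FindStr.result` (potentially polymorphic loci), and `motif_summary.tsv`
#' into `out_dir`. An empty input produces empty outputs and a warning.
#'
#' @param input FASTA path(s) (multiple paths are concatenated) or a named
#'   sequence vector.
#' @param out_dir Output directory (created if needed).
#' @inheritParams aggregate_loci
#' @param header Write header lines on the report files? Default `FALSE`.
#' @param quiet Suppress log lines.
#' @return Invisibly, a list: `hits`, `records`, `motif_summary`, `paths`.
#' @export
run_scan <- function(input, out_dir, k = 10, thresholds = ssr_thresholds(),
                     min_obs = NULL, merge_revcomp = FALSE, header = FALSE,
                     quiet = FALSE) {
  seqs <- as_sequences(input)
  if (length(seqs) == 0) warn("input contains no transcripts")
  hits <- scan_ssrs(seqs, thresholds)
  records <- aggregate_loci(hits, seqs, k = k, min_obs = min_obs,
                            merge_revcomp = merge_revcomp)
  skipped <- attr(records, "skipped")
  if (!is.null(skipped) && nrow(skipped) > 0) {
    warn(paste0("hits skipped at key building: ",
                paste(skipped$skip_reason, skipped$n_hits, sep = "=",
                      collapse = ", ")))
  }
  motif_summary <- summarize_motifs(hits)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_locus_reports(records, file.path(out_dir, "FindStr.result.detail"),
                        file.path(out_dir, "FindStr.result"), header = header),
    motifs = file.path(out_dir, "motif_summary.tsv")
  )
  readr::write_tsv(as_tibble(motif_summary), paths[["motifs"]])
  log_info("scan", transcripts = length(seqs), hits = nrow(hits),
           loci = nrow(records), polymorphic = sum(records$polymorphic),
           quiet = quiet)
  invisible(list(hits = hits, records = records,
                 motif_summary = motif_summary, paths = paths))
}

#' Run the extraction stage: locate, window, verify
#'
#' For each selected locus (by default every potentially polymorphic record),
#' relocates the key in the transcripts, extracts candidate amplicon windows,
#' verifies them, and writes `candidates.fasta` (record ids
#' `locus|transcript|repeats=n`) plus `verification.tsv`.
#'
#' @param input Transcript FASTA path(s) or named sequence vector.
#' @param records Locus records ([aggregate_loci()]) or the path of a report
#'   file written by [write_locus_reports()] (then `k` is required to re-split
#'   its keys).
#' @param out_dir Output directory.
#' @inheritParams extract_verify
#' @param quiet Suppress log lines.
#' @return Invisibly, the [extract_verify()] result plus output paths.
#' @export
run_extract <- function(input, records, out_dir, k = NULL, min_flank = 50,
                        window = c(100, 300), thresholds = ssr_thresholds(),
                        quiet = FALSE) {
  if (is.character(records) && length(records) == 1 && file.exists(records)) {
    if (is.null(k)) abort("reading a report file requires the flank length k")
    records <- read_locus_report(records, k = k) |>
      mutate(locus_id = sprintf("locus%04d", row_number()))
  }
  k <- k %||% attr(records, "k")
  res <- extract_verify(records, input, k = k, min_flank = min_flank,
                        window = window, thresholds = thresholds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(out_dir, "candidates.fasta")
  report <- file.path(out_dir, "verification.tsv")
  write_candidate_fasta(res$candidates, fasta)
  readr::write_tsv(res$verification, report)
  log_info("extract", loci = nrow(records),
           windows = sum(res$candidates$status == "ok"),
           verified = sum(res$verification$flank_length_ok &
                            res$verification$consistency_ok),
           quiet = quiet)
  invisible(c(res, list(paths = c(fasta = fasta, report = report))))
}

#' Run the statistics stage
#'
#' Computes the marker-validation statistics table. The input may be a
#' genotype table (columns `locus_id`, `individual_id`, `allele1`, `allele2`)
#' — then per-locus statistics are computed first — or an already per-locus
#' statistics table (columns `locus`/`locus_id`, `n`, `na`, `fm`, `pic`),
#' e.g. a published panel, which is summarized as-is. Writes
#' `marker_stats.tsv` (per-locus rows, 4-decimal values, plus a `Mean` row)
#' and `summary.tsv` when `out_dir` is given.
#'
#' @param input A file path (TSV/CSV, sniffed by header) or a tibble.
#' @param out_dir Optional output directory.
#' @param format `"tsv"` or `"csv"` for file input.
#' @param quiet Suppress log lines.
#' @return A list: `stats` (per-locus tibble), `summary` (one row,
#'   [summarize_loci()]).
#' @export
run_stats <- function(input, out_dir = NULL, format = c("tsv", "csv"),
                      quiet = FALSE) {
  format <- match.arg(format)
  if (is.character(input)) {
    hdr <- strsplit(readr::read_lines(input, n_max = 1),
                    if (format == "csv") "," else "\t")[[1]]
    if (all(c("individual_id", "allele1") %in% hdr)) {
      stats <- marker_stats(read_genotype_table(input, format))
    } else if (all(c("n", "na", "fm", "pic") %in% hdr)) {
      reader <- if (format == "csv") readr::read_csv else readr::read_tsv
      stats <- reader(input, col_types = readr::cols()) |>
        dplyr::rename(dplyr::any_of(c(locus_id = "locus"))) |>
        filter(.data$locus_id != "Mean")
    } else {
      abort(paste0("unrecognized table schema in '", input,
                   "': need a genotype or per-locus statistics header"))
    }
  } else {
    stats <- input
  }
  summary <- summarize_loci(stats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_marker_stats(stats, file.path(out_dir, "marker_stats.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  }
  log_info("stats", loci = summary$n_loci, monomorphic = summary$n_monomorphic,
           pct_polymorphic = sprintf("%.2f", summary$pct_polymorphic),
           mean_pic = sprintf("%.4f", summary$mean_pic), quiet = quiet)
  list(stats = stats, summary = summary)
}

#' Run the simulation stage
#'
#' Writes a synthetic multi-sample transcript set with truth table to disk;
#' see [make_transcript_set()].
#'
#' @param out_dir Output directory.
#' @param seed Random seed.
#' @param ... Passed to [make_transcript_set()].
#' @param quiet Suppress log lines.
#' @return Invisibly, the [make_transcript_set()] result.
#' @export
run_simulate <- function(out_dir, seed = 1, ..., quiet = FALSE) {
  res <- make_transcript_set(seed = seed, dir = out_dir, ...)
  log_info("simulate", samples = length(res$samples),
           loci = nrow(res$truth), polymorphic = sum(res$truth$polymorphic),
           seed = seed, quiet = quiet)
  invisible(res)
}
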