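# Flank-keyed locus aggregation: the identity of a putative SSR locus across
# samples is the exact string left-flank + motif unit + right-flank; the
# repeat counts observed under one key are its polymorphism evidence.

#' Attach flanking-sequence locus keys to SSR hits
#'
#' For each hit, takes exactly `k` bases on each side of the repeat run and
#' forms the locus key `left_flank + motif + right_flank`. Hits whose
#' transcript cannot supply `k` bases on a side, or whose flank contains `N`,
#' are kept but marked with a `skip_reason` and never enter aggregation.
#'
#' @param hits Tibble of SSR hits ([scan_ssrs()]).
#' @param sequences The transcripts the hits came from (named character
#'   vector, `DNAStringSet`, or FASTA path(s)).
#' @param k Flank length per side (>= 1; values >= 8 recommended for key
#'   specificity, default 10).
#' @return `hits` plus columns `left_flank`, `right_flank`, `key`,
#'   `skip_reason` (`NA` when a key was built).
#' @export
build_locus_keys <- function(hits, sequences, k = 10) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("flank length k must be an integer >= 1")
  seqs <- as_sequences(sequences)
  unknown <- setdiff(unique(hits$seq_id), names(seqs))
  if (length(unknown) > 0) {
    abort(paste0("hits reference transcripts absent from `sequences`: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  s <- unname(seqs[hits$seq_id])
  len <- str_length(s)
  left <- ifelse(hits$start >= k, str_sub(s, hits$start - k + 1L, hits$start), NA)
  right <- ifelse(hits$end + k <= len, str_sub(s, hits$end + 1L, hits$end + k), NA)
  reason <- dplyr::case_when(
    hits$start < k ~ "left_flank_short",
    hits$end + k > len ~ "right_flank_short",
    str_detect(left, "N") | str_detect(right, "N") ~ "flank_contains_n",
    .default = NA_character_
  )
  hits |>
    mutate(
      left_flank = ifelse(is.na(reason), left, NA_character_),
      right_flank = ifelse(is.na(reason), right, NA_character_),
      key = ifelse(is.na(reason), paste0(left, .data$motif, right), NA_character_),
      skip_reason = reason
    )
}

#' Aggregate SSR observations into putative loci by exact flank key
#'
#' Builds flank keys for every hit and groups repeat-count observations under
#' identical keys across the merged dataset. A locus is flagged potentially
#' polymorphic when at least two distinct repeat counts were observed (and,
#' if `min_obs` is set, when it has at least that many observations). The
#' result is independent of input record order: observations are listed after
#' a deterministic sort by transcript id, run start, and unit length, and
#' records are sorted by key.
#'
#' @inheritParams build_locus_keys
#' @param min_obs Optional minimum number of observations for the polymorphic
#'   flag (default `NULL`: no filter; few input transcriptomes give too few
#'   repeat-count values for the flag to mean much).
#' @param merge_revcomp Merge each key with the reverse complement of its key
#'   string (off by default: matching is exact string identity, so loci
#'   assembled on opposite strands form separate records unless enabled).
#' @return A tibble of locus records (class `ssr_locus_records`): `locus_id`,
#'   `key`, `left_flank`, `motif`, `right_flank`, `motif_class`, `n_obs`,
#'   `seq_ids` (list), `repeats` (list), `n_distinct_repeats`, `polymorphic`.
#'   The flank length is kept in attribute `k`, skipped-hit tallies in
#'   attribute `skipped`.
#' @export
aggregate_loci <- function(hits, sequences, k = 10, min_obs = NULL,
                           merge_revcomp = FALSE) {
  keyed <- build_locus_keys(hits, sequences, k)
  skipped <- keyed |>
    filter(!is.na(.data$skip_reason)) |>
    dplyr::count(.data$skip_reason, name = "n_hits")
  kept <- keyed |>
    filter(is.na(.data$skip_reason)) |>
    mutate(unit_length = str_length(.data$motif)) |>
    arrange(.data$seq_id, .data$start, .data$unit_length)
  if (merge_revcomp && nrow(kept) > 0) {
    rc_key <- revcomp_chr(kept$key)
    flip <- rc_key < kept$key
    kept <- kept |>
      mutate(
        key = ifelse(flip, rc_key, .data$key),
        new_left = ifelse(flip, revcomp_chr(.data$right_flank), .data$left_flank),
        right_flank = ifelse(flip, revcomp_chr(.data$left_flank), .data$right_flank),
        left_flank = .data$new_left,
        motif = ifelse(flip, revcomp_chr(.data$motif), .data$motif),
        new_left = NULL
      )
  }
  records <- kept |>
    group_by(.data$key) |>
    summarise(
      left_flank = first(.data$left_flank),
      motif = first(.data$motif),
      right_flank = first(.data$right_flank),
      motif_class = first(.data$motif_class),
      n_obs = n(),
      seq_ids = list(.data$seq_id),
      n_distinct_repeats = n_distinct(.data$repeats),
      repeats = list(.data$repeats),
      .groups = "drop"
    ) |>
    mutate(
      polymorphic = .data$n_distinct_repeats >= 2L &
        (if (is.null(min_obs)) TRUE else .data$n_obs >= min_obs)
    ) |>
    dplyr::relocate("repeats", .before = "n_distinct_repeats") |>
    arrange(.data$key) |>
    mutate(locus_id = sprintf("locus%04d", row_number()), .before = 1)
  attr(records, "k") <- k
  attr(records, "skipped") <- skipped
  class(records) <- c("ssr_locus_records", class(records))
  records
}

#' Rank polymorphic locus candidates
#'
#' Orders the potentially polymorphic records so that loci showing many
#' different repeat numbers — the sites with relatively high expected
#' polymorphism — come first.
#'
#' @param records Locus records from [aggregate_loci()].
#' @return The polymorphic subset, sorted by number of distinct repeat counts
#'   (descending), then number of observations (descending), then key.
#' @export
rank_candidates <- function(records) {
  records |>
    filter(.data$polymorphic) |>
    arrange(desc(.data$n_distinct_repeats), desc(.data$n_obs), .data$key)
}

record_lines <- function(records) {
  paste(records$key, records$n_obs,
        map_chr(records$repeats, paste, collapse = ","), sep = "\t")
}

#' Write the two locus report files
#'
#' Writes the detail file (every aggregated locus) and the result file (the
#' potentially polymorphic subset). Both are tab-delimited with three
#' columns: the key string (flank + motif + flank), the total number of SSRs
#' observed at the locus, and the comma-separated repeat number of each
#' observation. No header by default.
#'
#' @param records Locus records from [aggregate_loci()].
#' @param detail_path,result_path Output paths (conventionally
#'   `FindStr.result.detail` and `FindStr.result`).
#' @param header Write a header line (`key  n_obs  repeats`)? Default `FALSE`.
#' @return Invisibly, the two paths.
#' @export
write_locus_reports <- function(records, detail_path, result_path,
                                header = FALSE) {
  hdr <- if (header) "key\tn_obs\trepeats" else character()
  readr::write_lines(c(hdr, record_lines(records)), detail_path)
  readr::write_lines(c(hdr, record_lines(filter(records, .data$polymorphic))),
                     result_path)
  invisible(c(detail = detail_path, result = result_path))
}

#' Read a locus report file
#'
#' Round-trips the three-column report written by [write_locus_reports()].
#' When the flank length `k` is supplied, the key is re-split into
#' `left_flank`, `motif`, `right_flank` (the motif length is
#' `nchar(key) - 2k`, so the split is unambiguous).
#'
#' @param path Report file path.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @param k Optional flank length used when the report was produced.
#' @return A tibble with `key`, `n_obs`, `repeats` (list of integer vectors),
#'   `n_distinct_repeats`, `polymorphic`, plus the key split if `k` is given.
#' @export
read_locus_report <- function(path, header = FALSE, k = NULL) {
  out <- readr::read_tsv(path, col_names = c("key", "n_obs", "repeats"),
                         skip = if (header) 1L else 0L,
                         col_types = readr::cols(.default = readr::col_character())) |>
    mutate(
      n_obs = as.integer(.data$n_obs),
      repeats = map(str_split(.data$repeats, ","), as.integer),
      n_distinct_repeats = map_int(.data$repeats, n_distinct),
      polymorphic = .data$n_distinct_repeats >= 2L
    )
  if (any(out$n_obs != map_int(out$repeats, length))) {
    abort(paste0("corrupt report '", path,
                 "': observation count disagrees with repeat list"))
  }
  if (!is.null(k)) {
    mlen <- str_length(out$key) - 2L * k
    if (any(mlen < 1L | mlen > 6L)) {
      abort("k inconsistent with key lengths in report")
    }
    out <- out |>
      mutate(
        left_flank = str_sub(.data$key, 1L, k),
        motif = str_sub(.data$key, k + 1L, k + mlen),
        right_flank = str_sub(.data$key, k + mlen + 1L, str_length(.data$key)),
        motif_class = canonical_motif_class(.data$motif)
      )
    attr(out, "k") <- as.integer(k)
  }
  out
}
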