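# Candidate extraction and verification: relocate a locus key in the
# transcript dataset, cut a primer-ready window around each occurrence, and
# check flank-length sufficiency and cross-sample flank consistency.

split_key <- function(key, k) {
  mlen <- str_length(key) - 2L * k
  if (any(mlen < 1L | mlen > 6L)) abort("key length inconsistent with flank length k")
  list(left = str_sub(key, 1L, k),
       motif = str_sub(key, k + 1L, k + mlen),
       right = str_sub(key, k + mlen + 1L, str_length(key)))
}

#' Locate a locus key in a transcript set
#'
#' Finds every exact occurrence of `left_flank` + at least `min_repeats`
#' tandem copies of `motif` + `right_flank` within individual transcripts
#' (records are never concatenated, so a key spanning a boundary does not
#' match). The repeat count actually present at each occurrence is reported;
#' it may differ from the aggregate record when new data are searched.
#'
#' @param sequences Transcripts (named character vector, `DNAStringSet`, or
#'   FASTA path(s)).
#' @param key Locus key string (`left_flank + motif + right_flank`).
#' @param k Flank length per side used to build the key.
#' @param min_repeats Minimum tandem copies required at a match; defaults to
#'   the detection threshold for the motif's unit length.
#' @param thresholds Threshold vector used for that default.
#' @return A tibble with one row per occurrence: `seq_id`, `start`, `end`
#'   (0-based half-open coordinates of the repeat run), `repeats`. Zero
#'   matches give an empty tibble (with a message).
#' @export
locate_key <- function(sequences, key, k, min_repeats = NULL,
                       thresholds = ssr_thresholds()) {
  seqs <- as_sequences(sequences)
  parts <- split_key(key, k)
  u <- str_length(parts$motif)
  min_repeats <- min_repeats %||% thresholds[[as.character(u)]]
  pat <- paste0(parts$left, "(?:", parts$motif, "){", min_repeats, ",}", parts$right)
  out <- imap(seqs, function(s, id) {
    loc <- str_locate_all(s, pat)[[1]]
    if (nrow(loc) == 0L) return(NULL)
    run_start <- loc[, "start"] - 1L + k            # 0-based run start
    run_end <- loc[, "end"] - k                     # 0-based half-open run end
    tibble(seq_id = id,
           start = as.integer(run_start),
           end = as.integer(run_end),
           repeats = as.integer((run_end - run_start) %/% u))
  }) |> list_rbind()
  if (is.null(out) || nrow(out) == 0L) {
    inform(paste0("no occurrence of key '", substr(key, 1, 20), "...' found"))
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  repeats = integer()))
  }
  out
}

#' Cut a candidate amplicon window around one SSR occurrence
#'
#' Chooses a window of `window[1]`-`window[2]` bases containing the repeat
#' run with at least `min_flank` bases of context on each side, expanding
#' symmetrically from the run and then extending toward the upper bound only
#' as the transcript allows. Returns a skip reason instead of a window when
#' the transcript cannot supply `min_flank` bases per side, or the run is too
#' long for both flanks to fit in the upper bound.
#'
#' @param sequence The transcript (single DNA string).
#' @param start,end 0-based half-open coordinates of the repeat run.
#' @param min_flank Minimum context per side inside the window (default 50,
#'   the primer-design sufficiency rule).
#' @param window Length-2 vector of window bounds (default `c(100, 300)`).
#' @return One-row tibble: `window_sequence`, `window_start` (0-based),
#'   `left_context_len`, `right_context_len`, `status` (`"ok"` or a reason;
#'   non-`"ok"` rows carry `NA` for the window fields).
#' @export
extract_window <- function(sequence, start, end, min_flank = 50,
                           window = c(100, 300)) {
  stopifnot(length(sequence) == 1L, end > start, length(window) == 2L)
  s <- str_to_upper(sequence)
  len <- str_length(s)
  run_len <- end - start
  failed <- function(reason) {
    tibble(window_sequence = NA_character_, window_start = NA_integer_,
           left_context_len = NA_integer_, right_context_len = NA_integer_,
           status = reason)
  }
  if (run_len + 2L * min_flank > window[2]) return(failed("run_too_long_for_window"))
  if (start < min_flank) return(failed("left_context_short"))
  if (len - end < min_flank) return(failed("right_context_short"))
  budget <- window[2] - run_len
  left_take <- min(start, budget %/% 2L)
  right_take <- min(len - end, budget - left_take)
  left_take <- min(start, budget - right_take)
  tibble(
    window_sequence = str_sub(s, start - left_take + 1L, end + right_take),
    window_start = as.integer(start - left_take),
    left_context_len = as.integer(left_take),
    right_context_len = as.integer(right_take),
    status = "ok"
  )
}

#' Extract candidate amplicons for a set of key occurrences
#'
#' Applies [extract_window()] to every match returned by [locate_key()].
#'
#' @param matches Tibble from [locate_key()].
#' @param sequences The transcripts searched.
#' @inheritParams extract_window
#' @return `matches` with the window columns of [extract_window()] appended;
#'   failed extractions keep their row with a non-`"ok"` `status`.
#' @export
extract_candidates <- function(matches, sequences, min_flank = 50,
                               window = c(100, 300)) {
  seqs <- as_sequences(sequences)
  windows <- pmap(list(matches$seq_id, matches$start, matches$end),
                  function(id, s0, e0) {
                    extract_window(seqs[[id]], s0, e0, min_flank, window)
                  }) |> list_rbind()
  if (nrow(matches) == 0L) {
    windows <- extract_window("ACGT", 0, 4)[0, ]
  }
  dplyr::bind_cols(matches, windows)
}

#' Verify a locus across its extracted candidate windows
#'
#' Two checks per locus. Flank length: every occurrence yielded a window with
#' at least the minimum context on each side. Consistency: excluding the
#' repeat run itself (a repeat-count difference is the signal, not an
#' inconsistency), the non-repeat context around the run must be identical
#' across windows wherever two windows both cover a position — left contexts
#' compared right-aligned against the run start, right contexts
#' left-aligned after the run end.
#'
#' @param candidates Tibble from [extract_candidates()] for one locus.
#' @param locus_id Optional label carried into the report.
#' @return One-row tibble: `locus_id`, `n_matches`, `n_windows`,
#'   `flank_length_ok`, `consistency_ok`, `notes`.
#' @export
verify_locus <- function(candidates, locus_id = NA_character_) {
  ok <- filter(candidates, .data$status == "ok")
  flank_ok <- nrow(candidates) > 0 && all(candidates$status == "ok")
  notes <- candidates |>
    filter(.data$status != "ok") |>
    (\(d) if (nrow(d) == 0) "" else
      paste(d$seq_id, d$status, sep = ":", collapse = ";"))()
  consistent <- TRUE
  if (nrow(ok) >= 2) {
    run_len <- ok$end - ok$start
    lefts <- str_sub(ok$window_sequence, 1L, ok$left_context_len)
    rights <- str_sub(ok$window_sequence, ok$left_context_len + run_len + 1L,
                      str_length(ok$window_sequence))
    # pairwise agreement on covered positions == every context matches the
    # longest one over its own length (suffix-aligned left, prefix-aligned right)
    ref_l <- lefts[which.max(str_length(lefts))]
    ref_r <- rights[which.max(str_length(rights))]
    left_ok <- all(map_lgl(lefts, function(x) {
      str_sub(ref_l, str_length(ref_l) - str_length(x) + 1L) == x
    }))
    right_ok <- all(map_lgl(rights, function(x) {
      str_sub(ref_r, 1L, str_length(x)) == x
    }))
    consistent <- left_ok && right_ok
  }
  tibble(locus_id = locus_id, n_matches = nrow(candidates),
         n_windows = nrow(ok), flank_length_ok = flank_ok,
         consistency_ok = consistent, notes = notes)
}

#' Locate, extract, and verify a set of locus records
#'
#' Runs the full verification stage for each (typically polymorphic) locus
#' record: relocate the key, cut candidate amplicon windows, verify flank
#' length and cross-sample consistency.
#'
#' @param records Locus records ([aggregate_loci()] or [read_locus_report()]
#'   with `k`), needing columns `locus_id` and `key`.
#' @param sequences The transcript dataset.
#' @param k Flank length used to build the keys; defaults to the records'
#'   `k` attribute.
#' @inheritParams extract_window
#' @inheritParams locate_key
#' @return A list with `candidates` (per-occurrence tibble, with a FASTA-ready
#'   `amplicon_id` of the form `locus|transcript|repeats=n` for successful
#'   windows) and `verification` (one row per locus from [verify_locus()]).
#' @export
extract_verify <- function(records, sequences, k = attr(records, "k"),
                           min_flank = 50, window = c(100, 300),
                           thresholds = ssr_thresholds()) {
  if (is.null(k)) abort("flank length k must be supplied or carried by `records`")
  seqs <- as_sequences(sequences)
  if (!"locus_id" %in% names(records)) {
    records$locus_id <- sprintf("locus%04d", seq_len(nrow(records)))
  }
  per_locus <- map2(records$locus_id, records$key, function(id, key) {
    cand <- locate_key(seqs, key, k, thresholds = thresholds) |>
      extract_candidates(seqs, min_flank, window) |>
      mutate(locus_id = id, .before = 1)
    list(cand = cand, report = verify_locus(cand, id))
  })
  candidates <- list_rbind(map(per_locus, "cand"))
  if (!is.null(candidates) && nrow(candidates) > 0) {
    candidates <- candidates |>
      mutate(amplicon_id = ifelse(
        .data$status == "ok",
        paste0(.data$locus_id, "|", .data$seq_id, "|repeats=", .data$repeats),
        NA_character_))
  }
  list(candidates = candidates, verification = list_rbind(map(per_locus, "report")))
}

#' Write candidate amplicons to FASTA
#'
#' @param candidates Candidate tibble from [extract_verify()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_candidate_fasta <- function(candidates, path) {
  ok <- filter(candidates, .data$status == "ok")
  set <- Biostrings::DNAStringSet(setNames(ok$window_sequence, ok$amplicon_id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
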