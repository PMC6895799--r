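# SSR detection: maximal tandem-repeat runs of 1-6 bp units under
# MISA-style minimum-repeat thresholds, with canonical motif classes.

#' Minimum repeat-count thresholds for SSR detection
#'
#' Builds the per-unit-length threshold vector used by [find_ssrs()]. The
#' defaults follow the MISA convention: a mononucleotide run must reach 10
#' repeats, a dinucleotide 6, and tri- to hexanucleotides 5.
#'
#' @param mono,di,tri,tetra,penta,hexa Minimum number of full tandem copies
#'   for each motif unit length (all integers >= 2).
#' @return A named integer vector with names `"1"` to `"6"`.
#' @examples
#' ssr_thresholds()
#' ssr_thresholds(di = 8)
#' @export
ssr_thresholds <- function(mono = 10L, di = 6L, tri = 5L, tetra = 5L,
                           penta = 5L, hexa = 5L) {
  th <- c(`1` = mono, `2` = di, `3` = tri, `4` = tetra, `5` = penta, `6` = hexa)
  th <- vapply(th, as.integer, integer(1))
  if (anyNA(th) || any(th < 2L)) {
    abort("all repeat thresholds must be integers >= 2")
  }
  th
}

# reverse complement of plain character DNA (A/C/G/T/N)
revcomp_chr <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# all cyclic rotations of a single motif
motif_rotations <- function(m) {
  u <- nchar(m)
  vapply(seq_len(u) - 1L,
         function(i) paste0(substr(m, i + 1L, u), substr(m, 1L, i)),
         character(1))
}

# a motif is primitive when it is not a whole-number power of a shorter unit
is_primitive_motif <- function(m) {
  u <- nchar(m)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && strrep(substr(m, 1L, d), u / d) == m) return(FALSE)
  }
  TRUE
}

#' Canonical strand/rotation class of a repeat motif
#'
#' A repeat unit, all of its cyclic rotations, and all rotations of its
#' reverse complement describe the same microsatellite, so motif tallies are
#' reported per equivalence class. The class label is `"X/Y"` where X and Y
#' are the lexicographically smallest rotations of the motif and of its
#' reverse complement, in alphabetical order, e.g. `"TA"` and `"AT"` both
#' map to `"AT/AT"`, `"CT"` and `"GA"` to `"AG/CT"`.
#'
#' @param motif Character vector of primitive repeat units (1-6 bp, A/C/G/T).
#' @return Character vector of class labels.
#' @examples
#' canonical_motif_class(c("TA", "CT", "TTA"))
#' @export
canonical_motif_class <- function(motif) {
  motif <- str_to_upper(motif)
  vapply(motif, function(m) {
    if (!grepl("^[ACGT]{1,6}$", m)) {
      abort(paste0("motif must be 1-6 bases over A/C/G/T, got '", m, "'"))
    }
    if (!is_primitive_motif(m)) {
      abort(paste0("motif '", m, "' is not primitive"))
    }
    a <- min(motif_rotations(m))
    b <- min(motif_rotations(revcomp_chr(m)))
    paste(sort(c(a, b)), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

# validate a DNA string, return it uppercased; error names the first bad position
validate_dna <- function(sequence, seq_id = "sequence") {
  s <- str_to_upper(sequence)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    abort(paste0("non-DNA character '", substr(s, bad, bad), "' at position ",
                 bad, " in ", seq_id))
  }
  s
}

#' Find maximal SSR runs in one transcript
#'
#' Scans a single DNA sequence for maximal tandem repeats of every primitive
#' unit length 1-6 that reach the minimum repeat count for their unit length.
#' Only full tandem copies count: a trailing partial copy is left to the
#' flank. Runs are maximal (they cannot be extended by a further full copy on
#' either side), a run reported for one unit length is never re-reported as a
#' power of a shorter unit, and runs never contain `N`. Overlapping runs of
#' different unit lengths that each pass their threshold are all reported;
#' for the degenerate case of identical spans the shorter unit wins.
#'
#' @param sequence A single DNA string (A/C/G/T/N, case-insensitive).
#' @param seq_id Identifier recorded in the output.
#' @param thresholds Named threshold vector from [ssr_thresholds()].
#' @return A tibble with one row per hit: `seq_id`, `motif` (unit as read on
#'   the input strand), `motif_class`, `repeats`, and 0-based half-open run
#'   coordinates `start`, `end`. Sorted by `start`.
#' @examples
#' find_ssrs(paste0("CC", strrep("A", 12), "GG"), "tx1")
#' @export
find_ssrs <- function(sequence, seq_id = "seq1", thresholds = ssr_thresholds()) {
  stopifnot(length(sequence) == 1L, length(seq_id) == 1L)
  if (!identical(sort(names(thresholds)), as.character(1:6))) {
    abort("thresholds must be named '1' through '6'; see ssr_thresholds()")
  }
  s <- validate_dna(sequence, seq_id)

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  per_unit <- map(1:6, function(u) {
    # zero-width lookahead: at every position, greedily capture a run of >= 2
    # full copies of a u-mer (N is excluded by the class, so runs can neither
    # contain nor cross an ambiguous base); a plain non-overlapping scan would
    # consume the first base of an adjacent region and shift its phase
    pat <- sprintf("(?=(([ACGT]{%d})\\2+))", u)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    pos <- attr(m, "capture.start")[, 1L]      # 1-based run start
    len <- attr(m, "capture.length")[, 1L]     # full copies only
    # keep the run anchored at its tandem region's start: the base before it
    # must not extend the region (trailing partial copies belong to the flank)
    maximal <- pos == 1L | chars[pmax(pos - 1L, 1L)] != chars[pos + u - 1L]
    reps <- len %/% u
    motif <- str_sub(s, pos, pos + u - 1L)
    keep <- maximal & reps >= thresholds[[as.character(u)]] &
      vapply(motif, is_primitive_motif, logical(1))
    if (!any(keep)) return(NULL)
    tibble(
      seq_id = seq_id,
      motif = motif[keep],
      repeats = as.integer(reps[keep]),
      start = as.integer(pos[keep] - 1L),
      end = as.integer(pos[keep] - 1L + reps[keep] * u),
      unit_length = u
    )
  })
  hits <- list_rbind(per_unit)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble(seq_id = character(), motif = character(),
                  motif_class = character(), repeats = integer(),
                  start = integer(), end = integer()))
  }
  hits |>
    arrange(.data$start, .data$end, .data$unit_length) |>
    # identical spans from two unit lengths: keep the shorter unit
    distinct(.data$start, .data$end, .keep_all = TRUE) |>
    mutate(motif_class = canonical_motif_class(.data$motif)) |>
    select("seq_id", "motif", "motif_class", "repeats", "start", "end")
}

# coerce FASTA paths / DNAStringSet / character vectors to named uppercase strings
as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) > 0 && all(file.exists(x))) {
    out <- read_transcripts(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    abort("sequences must be a named character vector, DNAStringSet, or FASTA path(s)")
  }
  if (length(out) == 0) return(setNames(character(), character()))
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    abort("every sequence must be named with a transcript identifier")
  }
  if (anyDuplicated(names(out))) {
    warn("duplicate transcript identifiers; making them unique")
    names(out) <- make.unique(names(out), sep = "_dup")
  }
  toupper(out)
}

#' Read transcript FASTA file(s)
#'
#' Reads one or more (multi-record, optionally wrapped) FASTA files and
#' returns the merged set of transcripts, emulating concatenation of
#' per-sample assemblies into one dataset. Record descriptions are truncated
#' at the first whitespace.
#'
#' @param paths Character vector of FASTA file paths.
#' @return A named uppercase character vector of sequences.
#' @export
read_transcripts <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input FASTA not found: ", paste(missing, collapse = ", ")))
  }
  sets <- map(paths, function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    out
  })
  out <- unlist(sets)
  if (is.null(out)) out <- character()
  toupper(out)
}

#' Scan a set of transcripts for SSRs
#'
#' Applies [find_ssrs()] to every transcript of a dataset.
#'
#' @param x Sequences: a named character vector, a
#'   `Biostrings::DNAStringSet`, or FASTA file path(s) (read and merged).
#' @inheritParams find_ssrs
#' @return A tibble of hits (see [find_ssrs()]), transcripts in input order.
#' @export
scan_ssrs <- function(x, thresholds = ssr_thresholds()) {
  seqs <- as_sequences(x)
  if (length(seqs) == 0L) return(find_ssrs("", "empty"))
  imap(seqs, function(s, id) find_ssrs(s, id, thresholds)) |> list_rbind()
}

#' Tally SSR hits by canonical motif class
#'
#' @param hits A tibble of SSR hits from [find_ssrs()] or [scan_ssrs()].
#' @return A tibble (class `ssr_motif_summary`) with columns `motif_class`,
#'   `unit_length`, `n`, sorted by unit length then descending count. Counts
#'   partition the hits.
#' @export
summarize_motifs <- function(hits) {
  out <- hits |>
    mutate(unit_length = str_length(.data$motif)) |>
    dplyr::count(.data$motif_class, .data$unit_length, name = "n") |>
    arrange(.data$unit_length, desc(.data$n), .data$motif_class)
  class(out) <- c("ssr_motif_summary", class(out))
  out
}
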