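# Independent oracles, deliberately implemented differently from the package:
# - brute_ssrs(): shift-compare/run-length SSR finder (the package scans with
#   a lookahead regex)
# - pic_loops(): double-loop evaluation of the PIC formula (the package uses
#   a closed-form rearrangement)

oracle_primitive <- function(m) {
  u <- nchar(m)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && paste(rep(substr(m, 1, d), u / d), collapse = "") == m) {
      return(FALSE)
    }
  }
  TRUE
}

# maximal tandem regions via x[i] == x[i+u] run-length encoding; a run is the
# full-copy prefix of each maximal region
brute_ssrs <- function(s, thresholds = ssr_thresholds()) {
  s <- toupper(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  rows <- list()
  for (u in 1:6) {
    if (L < 2L * u) next
    i <- seq_len(L - u)
    eq <- ch[i] == ch[i + u] & ch[i] != "N" & ch[i + u] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      region_start <- starts[j]
      region_len <- r$lengths[j] + u
      copies <- region_len %/% u
      if (copies < 2L) next
      motif <- substr(s, region_start, region_start + u - 1L)
      if (copies < thresholds[[as.character(u)]] || !oracle_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, repeats = copies,
        start = region_start - 1L,
        end = region_start - 1L + copies * u,
        u = u, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif = character(), repeats = integer(),
                      start = integer(), end = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$u), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out$u <- NULL
  rownames(out) <- NULL
  out
}

pic_loops <- function(p) {
  acc <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (j > i) acc <- acc - 2 * p[i]^2 * p[j]^2
    }
  }
  acc
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small planted dataset used across module tests
tiny_planted <- function(seed = 7, ...) make_transcript_set(seed = seed, ...)
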