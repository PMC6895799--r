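# Marker polymorphism statistics from fragment-length genotype tables:
# number of alleles (Na), major-allele frequency (FM), and polymorphism
# information content (PIC), per locus and summarized over the panel.

#' Allele frequencies at one locus
#'
#' Counts allele copies from diploid fragment-length calls (2 copies per
#' genotyped individual; an individual with a single detected peak is stored
#' as a homozygote) and converts to frequencies.
#'
#' @param genotypes Genotype tibble with columns `locus_id`, `individual_id`,
#'   `allele1`, `allele2` (fragment lengths; both `NA` = failed genotyping).
#' @param locus_id The locus to tabulate.
#' @return A tibble with `allele`, `count`, `freq` (descending frequency,
#'   ties by allele); frequencies sum to 1.
#' @export
allele_frequencies <- function(genotypes, locus_id) {
  g <- genotypes |>
    filter(.data$locus_id == !!locus_id, !is.na(.data$allele1), !is.na(.data$allele2))
  if (nrow(g) == 0L) abort(paste0("no data at locus ", locus_id))
  copies <- c(g$allele1, g$allele2)
  tab <- table(copies)
  tibble(allele = as.integer(names(tab)),
         count = as.integer(tab),
         freq = as.integer(tab) / length(copies)) |>
    arrange(desc(.data$freq), .data$allele)
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` for an allele-frequency
#' vector p. Zero for a monomorphic locus; always below the expected
#' heterozygosity `1 - sum(p_i^2)`. Values above 0.5 are conventionally
#' "highly informative", 0.25-0.5 "reasonably informative".
#'
#' @param p Numeric vector of allele frequencies (all > 0, summing to 1
#'   within 1e-9).
#' @return The PIC value in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))      # 0.375
#' pic(1)                # 0
#' @export
pic <- function(p) {
  if (any(p <= 0)) abort("allele frequencies must be positive")
  if (abs(sum(p) - 1) > 1e-9) abort("allele frequencies must sum to 1")
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Per-locus polymorphism statistics
#'
#' @inheritParams allele_frequencies
#' @return One-row tibble: `locus_id`, `n` (individuals successfully
#'   genotyped), `na` (number of distinct alleles), `fm` (major-allele
#'   frequency), `pic`.
#' @export
locus_stats <- function(genotypes, locus_id) {
  freqs <- allele_frequencies(genotypes, locus_id)
  n <- genotypes |>
    filter(.data$locus_id == !!locus_id, !is.na(.data$allele1),
           !is.na(.data$allele2)) |>
    nrow()
  tibble(locus_id = locus_id, n = n, na = nrow(freqs),
         fm = max(freqs$freq), pic = pic(freqs$freq))
}

#' Polymorphism statistics for every locus in a genotype table
#'
#' Runs [locus_stats()] across all loci. Loci with zero successfully
#' genotyped individuals are dropped with a warning. The result carries
#' class `ssr_marker_stats`, with [tidy()] (per-locus rows), [glance()]
#' (panel summary, see [summarize_loci()]), and [autoplot()] methods.
#'
#' @inheritParams allele_frequencies
#' @param motif_class Optional named character vector mapping `locus_id` to a
#'   canonical motif class, used by [pic_category_breakdown()] and plots.
#' @return A tibble of per-locus statistics (class `ssr_marker_stats`).
#' @export
marker_stats <- function(genotypes, motif_class = NULL) {
  loci <- unique(genotypes$locus_id)
  genotyped <- genotypes |>
    filter(!is.na(.data$allele1), !is.na(.data$allele2)) |>
    pull(.data$locus_id) |>
    unique()
  empty <- setdiff(loci, genotyped)
  if (length(empty) > 0) {
    warn(paste0("dropping loci with no successful genotypes: ",
                paste(empty, collapse = ", ")))
  }
  out <- map(intersect(loci, genotyped),
             function(l) locus_stats(genotypes, l)) |> list_rbind()
  if (!is.null(motif_class)) {
    out$motif_class <- unname(motif_class[as.character(out$locus_id)])
  }
  class(out) <- c("ssr_marker_stats", class(out))
  out
}

#' @export
tidy.ssr_marker_stats <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ssr_marker_stats")
  out
}

#' @export
glance.ssr_marker_stats <- function(x, ...) summarize_loci(x, ...)

#' Summarize a panel of per-locus statistics
#'
#' Arithmetic means of N, Na, FM and PIC over loci, the monomorphic count, the
#' percentage of polymorphic loci, and how many loci strictly exceed the
#' informativeness thresholds.
#'
#' @param stats Per-locus statistics: [marker_stats()] output, or any tibble
#'   with columns `n`, `na`, `fm`, `pic` (e.g. a published panel table).
#' @param informative,highly_informative PIC thresholds (defaults 0.25, 0.5);
#'   counts use strict `>`.
#' @return One-row tibble: `n_loci`, `mean_n`, `mean_na`, `mean_fm`,
#'   `mean_pic`, `n_monomorphic`, `pct_polymorphic`, `n_pic_gt_025`,
#'   `n_pic_gt_05`.
#' @export
summarize_loci <- function(stats, informative = 0.25, highly_informative = 0.5) {
  if (nrow(stats) == 0L) abort("need at least one locus")
  tibble(
    n_loci = nrow(stats),
    mean_n = mean(stats$n),
    mean_na = mean(stats$na),
    mean_fm = mean(stats$fm),
    mean_pic = mean(stats$pic),
    n_monomorphic = sum(stats$na == 1L),
    pct_polymorphic = 100 * mean(stats$na > 1L),
    n_pic_gt_025 = sum(stats$pic > informative),
    n_pic_gt_05 = sum(stats$pic > highly_informative)
  )
}

#' PIC band breakdown by motif class
#'
#' Splits loci into PIC bands `[0, 0.25]`, `(0.25, 0.5]`, `(0.5, 1)` and
#' reports per-motif-class percentages (summing to 100 within each class).
#' Classes with no loci are excluded.
#'
#' @param stats Per-locus statistics carrying a `motif_class` column.
#' @return Tibble: `motif_class`, `pic_band`, `n`, `pct`.
#' @export
pic_category_breakdown <- function(stats) {
  if (!"motif_class" %in% names(stats)) {
    abort("`stats` needs a motif_class column (see marker_stats(motif_class=))")
  }
  stats |>
    filter(!is.na(.data$motif_class)) |>
    mutate(pic_band = cut(.data$pic, breaks = c(0, 0.25, 0.5, 1),
                          labels = c("[0,0.25]", "(0.25,0.5]", "(0.5,1)"),
                          include.lowest = TRUE, right = TRUE)) |>
    dplyr::count(.data$motif_class, .data$pic_band, name = "n") |>
    complete(.data$motif_class, .data$pic_band, fill = list(n = 0L)) |>
    group_by(.data$motif_class) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$motif_class, .data$pic_band)
}

#' Read a fragment-length genotype table
#'
#' Expects a delimited file with header columns `locus_id`, `individual_id`,
#' `allele1`, `allele2` (fragment lengths in bases). An empty allele pair is
#' a failed genotyping; a single detected peak is treated as homozygous.
#'
#' @param path Input path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A genotype tibble suitable for [marker_stats()].
#' @export
read_genotype_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(
    locus_id = readr::col_character(),
    individual_id = readr::col_character(),
    allele1 = readr::col_integer(),
    allele2 = readr::col_integer()
  ), na = c("", "NA"))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed genotype table '", path, "' at line ",
                 probs$row[1] + 1L, ": ", probs$expected[1]))
  }
  out <- raw |>
    mutate(
      allele1 = dplyr::coalesce(.data$allele1, .data$allele2),
      allele2 = dplyr::coalesce(.data$allele2, .data$allele1)
    )
  bad <- which(!is.na(out$allele1) & out$allele1 <= 0 |
                 !is.na(out$allele2) & out$allele2 <= 0)
  if (length(bad) > 0) {
    abort(paste0("malformed genotype table '", path, "' at line ", bad[1] + 1L,
                 ": allele lengths must be positive"))
  }
  out
}

#' Write a marker-statistics table
#'
#' Tab-delimited per-locus rows (4-decimal FM and PIC) followed by a `Mean`
#' row, mirroring the conventional panel-validation layout.
#'
#' @param stats Per-locus statistics ([marker_stats()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_stats <- function(stats, path) {
  s <- summarize_loci(stats)
  lines <- c(
    "locus\tn\tna\tfm\tpic",
    sprintf("%s\t%d\t%d\t%.4f\t%.4f", stats$locus_id, stats$n, stats$na,
            stats$fm, stats$pic),
    sprintf("Mean\t%.4f\t%.4f\t%.4f\t%.4f", s$mean_n, s$mean_na, s$mean_fm,
            s$mean_pic)
  )
  readr::write_lines(lines, path)
  invisible(path)
}
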