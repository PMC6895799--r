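fixture_path <- function() {
  system.file("extdata", "pea_aphid_52loci.tsv", package = "ssrmine",
              mustWork = TRUE)
}

test_that("allele frequencies count diploid gene copies", {
  g <- tibble::tibble(
    locus_id = "L1",
    individual_id = c("i1", "i2", "i3", "i4"),
    allele1 = c(120L, 120L, 120L, 120L),
    allele2 = c(120L, 120L, 120L, 120L))
  f <- allele_frequencies(g, "L1")
  expect_equal(f$allele, 120L)
  expect_equal(f$freq, 1)

  g2 <- tibble::tibble(locus_id = "L1", individual_id = c("i1", "i2"),
                       allele1 = c(120L, 120L), allele2 = c(124L, 120L))
  f2 <- allele_frequencies(g2, "L1")
  expect_equal(f2$freq[f2$allele == 120], 0.75)
  expect_equal(f2$freq[f2$allele == 124], 0.25)
  expect_equal(sum(f2$freq), 1)

  g3 <- tibble::tibble(locus_id = "L1", individual_id = "i1",
                       allele1 = NA_integer_, allele2 = NA_integer_)
  expect_error(allele_frequencies(g3, "L1"), "no data at locus")
})

test_that("pic matches its analytic values and the loop oracle", {
  expect_identical(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(c(0.5, 0.25, 0.25)), 0.5546875, tolerance = 1e-15)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  expect_error(pic(c(1.2, -0.2)), "positive")

  set.seed(51)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    p <- as.vector(stats::rgamma(k, 1)); p <- p / sum(p)
    expect_equal(pic(p), pic_loops(p), tolerance = 1e-12)
    # PIC never exceeds expected heterozygosity
    expect_lte(pic(p), 1 - sum(p^2))
    expect_true(pic(p) >= 0 && pic(p) < 1)
  }
})

test_that("equal frequencies maximize PIC for a fixed allele number", {
  set.seed(52)
  for (k in 2:6) {
    best <- pic(rep(1 / k, k))
    for (i in 1:40) {
      p <- as.vector(stats::rgamma(k, 1)); p <- p / sum(p)
      expect_lte(pic(p), best + 1e-12)
    }
  }
})

test_that("locus_stats assembles N, Na, FM and PIC", {
  g <- tibble::tibble(
    locus_id = "L1",
    individual_id = sprintf("i%02d", 1:16),
    allele1 = rep(208L, 16), allele2 = rep(208L, 16))
  st <- locus_stats(g, "L1")
  expect_equal(st$n, 16L)
  expect_equal(st$na, 1L)
  expect_equal(st$fm, 1)
  expect_identical(st$pic, 0)

  g2 <- tibble::tibble(locus_id = "L2", individual_id = sprintf("i%02d", 1:10),
                       allele1 = 100L, allele2 = 104L)
  st2 <- locus_stats(g2, "L2")
  expect_equal(st2$fm, 0.5)
  expect_equal(st2$pic, 0.375)
})

test_that("simulated tables recover their generating frequencies", {
  p_true <- c(`100` = 0.5, `104` = 0.3, `108` = 0.2)
  gt <- make_genotype_table(list(LA = p_true), n_individuals = 500, seed = 3)
  f <- allele_frequencies(gt$genotypes, "LA")
  # 1000 gene copies: allow ~3.5 binomial standard errors
  for (a in names(p_true)) {
    se <- sqrt(p_true[[a]] * (1 - p_true[[a]]) / 1000)
    expect_lt(abs(f$freq[f$allele == as.integer(a)] - p_true[[a]]), 3.5 * se)
  }
  st <- locus_stats(gt$genotypes, "LA")
  expect_equal(st$n, 500L)
  expect_equal(st$na, 3L)
  expect_equal(st$pic, pic_loops(f$freq))
})

test_that("panel summary reproduces the published 52-locus validation table", {
  stats <- readr::read_tsv(fixture_path(), show_col_types = FALSE)
  s <- summarize_loci(stats)
  expect_equal(s$n_loci, 52L)
  expect_equal(round(s$mean_n, 4), 15.2115)
  expect_equal(round(s$mean_na, 4), 5.3462)
  expect_equal(round(s$mean_fm, 4), 0.4966)
  expect_equal(round(s$mean_pic, 4), 0.5751)
  expect_equal(s$n_monomorphic, 4L)
  expect_gt(s$pct_polymorphic, 92)
  expect_equal(s$n_pic_gt_025, 44L)
  expect_equal(s$n_pic_gt_05, 38L)
})

test_that("summary of a single monomorphic locus is degenerate", {
  one <- tibble::tibble(n = 16L, na = 1L, fm = 1, pic = 0)
  s <- summarize_loci(one)
  expect_equal(s$pct_polymorphic, 0)
  expect_equal(s$mean_pic, 0)
  expect_error(summarize_loci(one[0, ]), "at least one locus")
})

test_that("PIC bands split per motif class and sum to 100", {
  stats <- tibble::tibble(
    locus_id = as.character(1:6),
    n = 10L, na = c(1L, 3L, 4L, 5L, 2L, 6L),
    fm = 0.5,
    pic = c(0.1, 0.3, 0.6, 0.7, 0.25, 0.5),
    motif_class = c(rep("AT/AT", 4), "AG/CT", "AG/CT"))
  bd <- pic_category_breakdown(stats)
  at <- bd[bd$motif_class == "AT/AT", ]
  expect_equal(at$pct, c(25, 25, 50))
  expect_equal(sum(at$n), 4L)
  ag <- bd[bd$motif_class == "AG/CT", ]
  # 0.25 and 0.5 land in the closed upper ends of the lower bands
  expect_equal(ag$pct, c(50, 50, 0))
  expect_equal(as.vector(tapply(bd$pct, bd$motif_class, sum)), c(100, 100))
  # classes absent from the data are excluded
  expect_false("AAT/ATT" %in% bd$motif_class)
  # brute-force tally agreement
  for (cl in unique(stats$motif_class)) {
    p <- stats$pic[stats$motif_class == cl]
    expect_equal(sum(bd$n[bd$motif_class == cl & bd$pic_band == "(0.5,1)"]),
                 sum(p > 0.5))
  }
})

test_that("marker_stats handles multiple loci, dropout, and accessors", {
  freqs <- list(
    L1 = c(`100` = 0.5, `104` = 0.5),
    L2 = c(`200` = 1),
    L3 = c(`150` = 0.4, `153` = 0.4, `156` = 0.2))
  gt <- make_genotype_table(freqs, n_individuals = 60, missing_rate = 0.15,
                            seed = 9)
  st <- marker_stats(gt$genotypes,
                     motif_class = c(L1 = "AT/AT", L2 = "AG/CT", L3 = "AAT/ATT"))
  expect_s3_class(st, "ssr_marker_stats")
  expect_equal(nrow(st), 3L)
  expect_true(all(st$n < 60))
  expect_identical(st$pic[st$locus_id == "L2"], 0)
  expect_equal(glance(st), summarize_loci(st))
  expect_false(inherits(tidy(st), "ssr_marker_stats"))

  # total dropout at one locus is dropped with a warning
  gt2 <- make_genotype_table(freqs["L1"], n_individuals = 5,
                             missing_rate = 1, seed = 2)
  expect_error(locus_stats(gt2$genotypes, "L1"), "no data at locus")
  both <- dplyr::bind_rows(gt$genotypes,
                           dplyr::mutate(gt2$genotypes, locus_id = "L9"))
  expect_warning(marker_stats(both), "no successful genotypes")
})

test_that("genotype tables round-trip through the reader conventions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c(
    "locus_id\tindividual_id\tallele1\tallele2",
    "L1\ti1\t120\t124",
    "L1\ti2\t120\t",      # single peak -> homozygous
    "L1\ti3\t\t",         # failed genotyping
    "L2\ti1\t200\t200"), path)
  g <- read_genotype_table(path)
  expect_equal(g$allele2[2], 120L)
  expect_true(is.na(g$allele1[3]) && is.na(g$allele2[3]))
  st <- locus_stats(g, "L1")
  expect_equal(st$n, 2L)
  expect_equal(st$fm, 0.75)

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("locus_id\tindividual_id\tallele1\tallele2",
                       "L1\ti1\t120\t-4"), bad)
  expect_error(read_genotype_table(bad), "positive")

  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(c("locus_id,individual_id,allele1,allele2",
                       "L1,i1,120,124"), csv)
  expect_equal(nrow(read_genotype_table(csv, format = "csv")), 1L)
})
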