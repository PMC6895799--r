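make_flanked <- function(left, motif, reps, right) {
  paste0(left, strrep(motif, reps), right)
}

# context that cannot extend an AT/AAT repeat region at the junction
guarded_dna <- function(n, side = c("left", "right")) {
  side <- match.arg(side)
  core <- random_dna_str(n - 1)
  if (side == "left") paste0(core, "C") else paste0("C", core)
}

test_that("locus keys take exactly k bases per side and skip short flanks", {
  set.seed(3)
  left <- guarded_dna(10, "left")
  right <- guarded_dna(10, "right")
  s <- c(tx = make_flanked(left, "AT", 7, right))
  hits <- scan_ssrs(s)
  keyed <- build_locus_keys(hits, s, k = 10)
  expect_true(is.na(keyed$skip_reason))
  expect_equal(keyed$key, paste0(left, "AT", right))
  expect_equal(nchar(keyed$key), 2 * 10 + 2)

  # insufficient left flank: run starts 4 bases into the transcript
  s2 <- c(tx = make_flanked(substr(left, 7, 10), "AT", 7, right))
  keyed2 <- build_locus_keys(scan_ssrs(s2), s2, k = 10)
  expect_equal(keyed2$skip_reason, "left_flank_short")
  expect_true(is.na(keyed2$key))

  # N in a flank disqualifies the key
  left_n <- paste0(substr(left, 1, 5), "N", substr(left, 7, 10))
  s3 <- c(tx = make_flanked(left_n, "AT", 7, right))
  keyed3 <- build_locus_keys(scan_ssrs(s3), s3, k = 10)
  expect_equal(keyed3$skip_reason, "flank_contains_n")
})

test_that("identical flanks around different repeat counts share one key", {
  set.seed(4)
  left <- guarded_dna(30, "left")
  right <- guarded_dna(30, "right")
  s <- c(a = make_flanked(left, "AT", 7, right),
         b = make_flanked(left, "AT", 9, right))
  rec <- aggregate_loci(scan_ssrs(s), s, k = 10)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_obs, 2L)
  expect_equal(sort(rec$repeats[[1]]), c(7L, 9L))
  expect_true(rec$polymorphic)
})

test_that("aggregation counts, flags, and separates motifs correctly", {
  set.seed(5)
  left <- guarded_dna(20, "left"); right <- guarded_dna(20, "right")
  l2 <- guarded_dna(20, "left"); r2 <- guarded_dna(20, "right")
  s <- c(
    s1 = make_flanked(left, "AT", 7, right),
    s2 = make_flanked(left, "AT", 7, right),
    s3 = make_flanked(left, "AT", 9, right),
    s4 = make_flanked(left, "AT", 9, right),
    s5 = make_flanked(left, "AT", 8, right),
    c1 = make_flanked(l2, "AAT", 6, r2),
    c2 = make_flanked(l2, "AAT", 6, r2),
    c3 = make_flanked(l2, "AAT", 6, r2))
  rec <- aggregate_loci(scan_ssrs(s), s, k = 10)
  expect_equal(nrow(rec), 2L)
  at <- rec[rec$motif == "AT", ]
  expect_equal(at$n_obs, 5L)
  expect_equal(at$n_distinct_repeats, 3L)
  expect_true(at$polymorphic)
  aat <- rec[rec$motif == "AAT", ]
  expect_equal(aat$n_obs, 3L)
  expect_false(aat$polymorphic)

  # same flanks, different motif unit -> distinct records
  s6 <- c(x = make_flanked(left, "AT", 7, right),
          y = make_flanked(left, "AAT", 6, right))
  expect_equal(nrow(aggregate_loci(scan_ssrs(s6), s6, k = 10)), 2L)
})

test_that("every non-skipped hit contributes exactly one observation", {
  sim <- tiny_planted(seed = 13)
  hits <- scan_ssrs(sim$merged)
  keyed <- build_locus_keys(hits, sim$merged, k = 10)
  rec <- aggregate_loci(hits, sim$merged, k = 10)
  expect_equal(sum(rec$n_obs), sum(is.na(keyed$skip_reason)))
})

test_that("aggregation is invariant to input record order", {
  sim <- tiny_planted(seed = 17)
  seqs <- sim$merged
  rec1 <- aggregate_loci(scan_ssrs(seqs), seqs, k = 10)
  set.seed(1)
  shuffled <- seqs[sample(length(seqs))]
  rec2 <- aggregate_loci(scan_ssrs(shuffled), shuffled, k = 10)
  expect_equal(rec1, rec2, ignore_attr = TRUE)
})

test_that("a single flank mutation splits a locus into two records", {
  set.seed(6)
  left <- guarded_dna(25, "left"); right <- guarded_dna(25, "right")
  mut <- left
  substr(mut, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(left, 20, 20))[1]
  s <- c(a = make_flanked(left, "AT", 7, right),
         b = make_flanked(left, "AT", 9, right),
         c = make_flanked(mut, "AT", 9, right))
  rec <- aggregate_loci(scan_ssrs(s), s, k = 10)
  expect_equal(nrow(rec), 2L)
  expect_equal(sort(rec$n_obs), c(1L, 2L))
})

test_that("reverse-complement merging is off by default and merges when enabled", {
  set.seed(8)
  left <- guarded_dna(20, "left"); right <- paste0("C", random_dna_str(18), "G")
  fwd <- make_flanked(left, "AT", 7, right)
  rev <- paste(rev(strsplit(chartr("ACGT", "TGCA",
                                   make_flanked(left, "AT", 9, right)),
                            "")[[1]]), collapse = "")
  s <- c(a = fwd, b = rev)
  expect_equal(nrow(aggregate_loci(scan_ssrs(s), s, k = 10)), 2L)
  merged <- aggregate_loci(scan_ssrs(s), s, k = 10, merge_revcomp = TRUE)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_obs, 2L)
  expect_equal(sort(merged$repeats[[1]]), c(7L, 9L))
  expect_true(merged$polymorphic)
})

test_that("min_obs gates the polymorphic flag only when enabled", {
  set.seed(9)
  left <- guarded_dna(20, "left"); right <- guarded_dna(20, "right")
  s <- c(a = make_flanked(left, "AT", 7, right),
         b = make_flanked(left, "AT", 9, right))
  rec <- aggregate_loci(scan_ssrs(s), s, k = 10)
  expect_true(rec$polymorphic)
  rec2 <- aggregate_loci(scan_ssrs(s), s, k = 10, min_obs = 3)
  expect_false(rec2$polymorphic)
})

test_that("reports round-trip and the result file holds only polymorphic loci", {
  sim <- tiny_planted(seed = 19)
  rec <- aggregate_loci(scan_ssrs(sim$merged), sim$merged, k = 10)
  detail <- withr::local_tempfile(fileext = ".detail")
  result <- withr::local_tempfile(fileext = ".result")
  write_locus_reports(rec, detail, result)

  lines <- readr::read_lines(detail)
  expect_equal(length(lines), nrow(rec))
  expect_equal(length(readr::read_lines(result)), sum(rec$polymorphic))
  row <- strsplit(lines[1], "\t")[[1]]
  expect_equal(length(row), 3L)
  expect_equal(row[1], rec$key[1])
  expect_equal(as.integer(row[2]), rec$n_obs[1])
  expect_equal(row[3], paste(rec$repeats[[1]], collapse = ","))

  back <- read_locus_report(detail, k = 10)
  expect_equal(back$key, rec$key)
  expect_equal(back$n_obs, rec$n_obs)
  expect_equal(back$repeats, rec$repeats)
  expect_equal(back$polymorphic, rec$polymorphic)
  expect_equal(back$motif, rec$motif)
  expect_equal(back$left_flank, rec$left_flank)
})

test_that("candidates are ranked by distinct repeats, then observations, then key", {
  rec <- tibble::tibble(
    locus_id = c("a", "b", "c", "d"),
    key = c("CCC", "AAA", "BBB", "DDD"),
    n_obs = c(5L, 6L, 6L, 2L),
    n_distinct_repeats = c(4L, 2L, 3L, 2L),
    polymorphic = TRUE)
  ranked <- rank_candidates(rec)
  expect_equal(ranked$key, c("CCC", "BBB", "AAA", "DDD"))
  expect_equal(nrow(rank_candidates(rec[0, ])), 0L)
})
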