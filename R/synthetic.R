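# Synthetic fixtures with known truth: multi-sample transcript sets carrying
# planted SSR loci (flanking context generated once per locus and reused
# verbatim in every sample, repeat counts varying per sample), embedded among
# SSR-free background transcripts; and diploid fragment-length genotype
# tables drawn from stated allele-frequency vectors.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run the generator body under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# context free of SSRs above threshold, bounded retries
ssr_free_dna <- function(n, thresholds, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    if (nrow(find_ssrs(s, "bg", thresholds)) == 0L) return(s)
  }
  abort("could not generate SSR-free background sequence; relax thresholds")
}

default_motif_pool <- c("AT", "AG", "AC", "AAT", "AAG", "ATC", "ACC",
                        "AGG", "AAAT", "AATC")

#' Generate a multi-sample transcript set with planted SSR loci
#'
#' Builds `n_samples` synthetic de novo assemblies. Each planted locus gets a
#' motif, per-side context lengths, and a per-sample repeat-count vector; the
#' flanking context is generated once and embedded verbatim in every sample's
#' copy, so the locus carries one exact flank key across the dataset. Context
#' and background are rejection-sampled to contain no SSR run above the
#' detection thresholds, every planted run is verified to be detected exactly
#' as planted, and every locus key is verified to occur exactly once per
#' sample — so the scan/aggregate pipeline's truth is known by construction.
#'
#' Defaults emulate the intended use case: six samples (five or fewer
#' transcriptomes give too few repeat-count observations per locus), 20
#' planted loci of which 12 vary in repeat count across samples, and a
#' minority of loci with under 50 bases of context on one side (detectable
#' but failing the primer-design flank rule).
#'
#' @param n_samples Number of samples/assemblies (default 6).
#' @param n_loci,n_variable Planted loci and how many have variable repeat
#'   counts (defaults 20 and 12).
#' @param n_short_context How many loci get a sub-50-base context on one side
#'   (default 6, drawn from both variable and constant loci).
#' @param n_background SSR-free background transcripts per sample (default 30).
#' @param background_len Length range of background transcripts.
#' @param context_len Per-side context length range for full-context loci.
#' @param short_context_len Range for the short side of short-context loci.
#' @param k Flank-key length the truth table's keys are computed with.
#' @param thresholds Detection thresholds the planted repeats must satisfy.
#' @param motif_pool Motifs sampled for planted loci.
#' @param seed Random seed; output is deterministic given the seed.
#' @param dir Optional directory: writes `sample<i>.fasta`, `merged.fasta`,
#'   `truth.tsv`, and `config.yaml`.
#' @param max_tries Bounded retries for uniqueness/rejection sampling.
#' @return A list: `samples` (named list of named sequence vectors),
#'   `merged` (named vector, transcript ids prefixed by sample), `truth`
#'   (tibble: `locus_id`, `motif`, `motif_class`, `key`, `left_context_len`,
#'   `right_context_len`, `repeats` list-column of per-sample counts,
#'   `polymorphic`, `amplifiable`), and `params`.
#' @export
make_transcript_set <- function(n_samples = 6, n_loci = 20, n_variable = 12,
                                n_short_context = 6, n_background = 30,
                                background_len = c(300, 800),
                                context_len = c(60, 120),
                                short_context_len = c(25, 45),
                                k = 10, thresholds = ssr_thresholds(),
                                motif_pool = default_motif_pool,
                                seed = 1, dir = NULL, max_tries = 50) {
  stopifnot(n_variable <= n_loci, n_short_context <= n_loci, n_samples >= 1)
  with_seed(seed, {
    variable <- seq_len(n_loci) %in% sample.int(n_loci, n_variable)
    short_ctx <- seq_len(n_loci) %in% sample.int(n_loci, n_short_context)

    plant_one <- function(i) {
      motif <- sample(motif_pool, 1)
      u <- nchar(motif)
      base <- thresholds[[as.character(u)]] + sample(2:6, 1)
      if (variable[i]) {
        reps <- base + sample(0:4, n_samples, replace = TRUE)
        while (n_distinct(reps) < 2) {
          reps <- base + sample(0:4, n_samples, replace = TRUE)
        }
      } else {
        reps <- rep(base, n_samples)
      }
      lens <- sample(seq(context_len[1], context_len[2]), 2, replace = TRUE)
      if (short_ctx[i]) {
        side <- sample(1:2, 1)
        lens[side] <- sample(seq(short_context_len[1], short_context_len[2]), 1)
      }
      for (try in seq_len(max_tries)) {
        left <- ssr_free_dna(lens[1], thresholds)
        right <- ssr_free_dna(lens[2], thresholds)
        # planted run must be detected exactly as planted in every sample copy
        ok <- all(vapply(unique(reps), function(r) {
          tx <- paste0(left, strrep(motif, r), right)
          h <- find_ssrs(tx, "probe", thresholds)
          nrow(h) == 1L && h$motif == motif && h$repeats == r &&
            h$start == lens[1] && h$end == lens[1] + r * u
        }, logical(1)))
        if (ok) {
          return(tibble(
            locus_id = sprintf("locus%02d", i), motif = motif,
            motif_class = canonical_motif_class(motif),
            left_context = left, right_context = right,
            left_context_len = lens[1], right_context_len = lens[2],
            key = paste0(str_sub(left, -k), motif, str_sub(right, 1, k)),
            repeats = list(as.integer(reps)),
            polymorphic = n_distinct(reps) >= 2,
            amplifiable = all(lens >= 50) &&
              max(reps) * u + 100 <= 300
          ))
        }
      }
      abort("could not plant locus free of junction artifacts; widen motif_pool")
    }

    build <- function() {
      specs <- map(seq_len(n_loci), plant_one) |> list_rbind()
      samples <- map(seq_len(n_samples), function(g) {
        planted <- setNames(
          pmap(list(specs$left_context, specs$motif, specs$repeats,
                    specs$right_context),
               function(l, m, r, rr) paste0(l, strrep(m, r[g]), rr)) |>
            unlist(),
          paste0("s", g, "_", specs$locus_id))
        bg <- setNames(
          map_chr(seq_len(n_background), function(i) {
            ssr_free_dna(sample(seq(background_len[1], background_len[2]), 1),
                         thresholds)
          }),
          paste0("s", g, "_bg", sprintf("%03d", seq_len(n_background))))
        c(planted, bg)
      })
      names(samples) <- paste0("sample", seq_len(n_samples))
      list(specs = specs, samples = samples)
    }

    for (try in seq_len(max_tries)) {
      made <- build()
      merged <- unlist(unname(made$samples))
      # uniqueness: each key must occur exactly once per sample, on its own locus
      counts <- map_int(seq_len(n_loci), function(i) {
        m <- suppressMessages(
          locate_key(merged, made$specs$key[i], k, thresholds = thresholds))
        if (!all(grepl(paste0("_", made$specs$locus_id[i], "$"), m$seq_id))) {
          return(-1L)
        }
        nrow(m)
      })
      if (all(counts == n_samples)) break
      if (try == max_tries) abort("planted keys collide with background; retry budget exhausted")
    }

    truth <- made$specs |>
      select(-"left_context", -"right_context")
    out <- list(samples = made$samples, merged = merged, truth = truth,
                params = list(n_samples = n_samples, n_loci = n_loci,
                              n_variable = n_variable,
                              n_short_context = n_short_context,
                              n_background = n_background, k = k,
                              thresholds = as.list(thresholds), seed = seed))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      walk(names(out$samples), function(nm) {
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(out$samples[[nm]]),
          file.path(dir, paste0(nm, ".fasta")), width = 70L)
      })
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$merged),
                                  file.path(dir, "merged.fasta"), width = 70L)
      truth |>
        mutate(repeats = map_chr(.data$repeats, paste, collapse = ",")) |>
        readr::write_tsv(file.path(dir, "truth.tsv"))
      yaml::write_yaml(out$params, file.path(dir, "config.yaml"))
      out$dir <- dir
    }
    out
  })
}

#' Simulate a fragment-length genotype table from known allele frequencies
#'
#' Draws independent diploid genotypes per individual and locus from stated
#' allele-frequency vectors, with optional per-call dropout, emulating the
#' capillary-electrophoresis genotype tables the marker statistics consume.
#'
#' @param freqs Named list (by locus id) of named numeric vectors: names are
#'   allele fragment lengths, values are frequencies summing to 1.
#' @param n_individuals Individuals per locus (default 25).
#' @param missing_rate Probability a (locus, individual) call fails entirely
#'   (default 0).
#' @param seed Random seed.
#' @return A list: `genotypes` (tibble `locus_id`, `individual_id`,
#'   `allele1`, `allele2`, failed calls `NA`) and `true_freqs` (tibble
#'   `locus_id`, `allele`, `freq`).
#' @export
make_genotype_table <- function(freqs, n_individuals = 25, missing_rate = 0,
                                seed = 1) {
  stopifnot(is.list(freqs), length(freqs) > 0, !is.null(names(freqs)))
  bad <- names(freqs)[map_lgl(freqs, function(p) abs(sum(p) - 1) > 1e-9)]
  if (length(bad) > 0) {
    abort(paste0("allele frequencies must sum to 1 at: ",
                 paste(bad, collapse = ", ")))
  }
  ids <- sprintf("ind%03d", seq_len(n_individuals))
  with_seed(seed, {
    genotypes <- imap(freqs, function(p, locus) {
      alleles <- as.integer(names(p))
      a1 <- alleles[sample.int(length(p), n_individuals, replace = TRUE, prob = p)]
      a2 <- alleles[sample.int(length(p), n_individuals, replace = TRUE, prob = p)]
      miss <- runif(n_individuals) < missing_rate
      tibble(locus_id = locus, individual_id = ids,
             allele1 = ifelse(miss, NA_integer_, a1),
             allele2 = ifelse(miss, NA_integer_, a2))
    }) |> list_rbind()
    true_freqs <- imap(freqs, function(p, locus) {
      tibble(locus_id = locus, allele = as.integer(names(p)), freq = unname(p))
    }) |> list_rbind()
    list(genotypes = genotypes, true_freqs = true_freqs)
  })
}
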