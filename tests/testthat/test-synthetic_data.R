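small_cfg <- function(seed = 5L, ...) {
  synth_config(seed = seed, n_replicons = 1L, replicon_lengths = 80000L, n_genes = 35L,
               tss_counts = c(mTSS = 8L, lmTSS = 3L, pmTSS = 3L, seTSS = 3L,
                              asTSS = 3L, sTSS = 3L),
               promoters = list(sigma = "RpoD", consensus35 = "TTGACA",
                                consensus10 = "TATAAT",
                                spacer_range = c(16L, 18L),
                                n_seed = 2L, n_exact = 3L, n_sampled = 0L,
                                sample_min_score_frac = 0.8,
                                seed_mismatch = 1L),
               n_tfbs = 2L, ...)
}

test_that("generation is byte-identical for a fixed seed", {
  t1 <- simulate_tss_experiment(small_cfg())
  t2 <- simulate_tss_experiment(small_cfg())
  expect_identical(t1$genome$replicons, t2$genome$replicons)
  expect_identical(t1$tss, t2$tss)
  expect_identical(t1$reads, t2$reads)
  t3 <- simulate_tss_experiment(small_cfg(seed = 6L))
  expect_false(identical(t1$genome$replicons, t3$genome$replicons))
})

test_that("config validation catches impossible requests", {
  expect_error(synth_config(replicon_lengths = 1000L), ">= 5000")
  expect_error(synth_config(gc_content = 1.2), "gc_content")
  expect_error(synth_config(read_length_range = c(10L, 300L)),
               "read_length_range")
  expect_error(plant_features(synth_config(
    n_replicons = 1L, replicon_lengths = 20000L, n_genes = 8L,
    tss_counts = c(mTSS = 40L, lmTSS = 0L, pmTSS = 0L, seTSS = 0L,
                   asTSS = 0L, sTSS = 0L), promoters = NULL, n_tfbs = 0L)))
})

test_that("planted classes satisfy their geometry: sTSS and lmTSS contracts", {
  truth <- plant_features(small_cfg())
  genes <- truth$genes
  # every sTSS lies > 300 nt from any same-strand downstream start codon
  for (i in which(truth$tss$intended_class == "sTSS")) {
    t <- truth$tss[i, ]
    same <- genes[genes$strand == t$strand & genes$replicon == t$replicon, ]
    d <- if (t$strand == "+") same$start_codon_pos - t$pos
         else t$pos - same$start_codon_pos
    expect_true(min(d[d > 0]) > 300)
  }
  # every lmTSS sits on an ATG read in transcription direction
  for (i in which(truth$tss$intended_class == "lmTSS")) {
    t <- truth$tss[i, ]
    tri <- if (t$strand == "+")
      genome_seq(truth$genome, t$replicon, t$pos, t$pos + 2L, "+")
    else genome_seq(truth$genome, t$replicon, t$pos - 2L, t$pos, "-")
    expect_equal(tri, "ATG")
  }
  # planted promoters end 5-12 nt upstream of their TSS
  expect_true(all(truth$promoters$gap_to_tss >= 5 &
                    truth$promoters$gap_to_tss <= 12))
  # promoter elements are really in the sequence
  for (i in seq_len(nrow(truth$promoters))) {
    p <- truth$promoters[i, ]
    w35 <- nchar(p$seq35)
    got35 <- genome_seq(truth$genome, p$replicon, p$pos35,
                        p$pos35 + w35 - 1L, p$strand)
    got10 <- genome_seq(truth$genome, p$replicon, p$pos10,
                        p$pos10 + nchar(p$seq10) - 1L, p$strand)
    if (p$strand == "-") {
      # genomic start columns hold the element; orientation handled above
      expect_equal(got35, p$seq35)
      expect_equal(got10, p$seq10)
    } else {
      expect_equal(got35, p$seq35)
      expect_equal(got10, p$seq10)
    }
  }
})

test_that("the classifier confirms every unambiguous plant (rule oracle)", {
  truth <- plant_features(small_cfg())
  got <- vapply(seq_len(nrow(truth$tss)), function(i) {
    t <- truth$tss[i, ]
    len <- 100L
    row <- tibble::tibble(
      replicon = t$replicon, strand = t$strand, tss_pos = t$pos,
      end_pos = if (t$strand == "+") t$pos + len - 1L else t$pos - len + 1L)
    oracle_classify_one(row, truth$genes, truth$genome)
  }, character(1))
  expect_equal(got, truth$tss$intended_class)
})

test_that("read depths follow the configured model and honour jitter/noise", {
  cfg0 <- small_cfg(depth_dispersion = 0, jitter_rate = 0,
                    background_noise_rate = 0)
  truth <- plant_features(cfg0)
  reads <- simulate_read_starts(truth, cfg0)
  # noise 0: every read-start position is a planted TSS
  key <- unique(paste(reads$replicon, reads$strand, reads$five_prime_pos))
  tkey <- paste(truth$tss$replicon, truth$tss$strand, truth$tss$pos)
  expect_setequal(key, tkey)
  depth <- tapply(reads$count,
                  paste(reads$replicon, reads$strand, reads$five_prime_pos),
                  sum)
  # Poisson(100): all planted TSS comfortably exceed the 30-read threshold
  expect_true(all(depth >= 30))
  expect_lt(abs(mean(depth) - 100), 10)
  expect_true(all(reads$length >= 87 & reads$length <= 108))
  # zero planted TSS and zero noise -> empty read set
  t0 <- truth
  t0$tss <- truth$tss[0, ]
  expect_equal(nrow(simulate_read_starts(t0, cfg0)), 0L)

  # jitter produces satellite positions within 2 nt of deep TSS
  cfgj <- small_cfg(depth_dispersion = 0, jitter_rate = 0.1,
                    background_noise_rate = 0)
  rj <- simulate_read_starts(plant_features(cfgj), cfgj)
  off <- setdiff(paste(rj$replicon, rj$strand, rj$five_prime_pos), tkey)
  expect_gt(length(off), 0)
  sat_pos <- as.integer(sub(".* ", "", off))
  near <- vapply(sat_pos, function(p) {
    any(abs(truth$tss$pos - p) <= 2)
  }, logical(1))
  expect_true(all(near))

  # negative-binomial dropout: a realistic share of plants falls below 30
  # reads (pool several seeds so the 12% tail event is well sampled)
  dnb <- unlist(lapply(11:15, function(sd) {
    cfgnb <- small_cfg(seed = sd, depth_dispersion = 0.5, jitter_rate = 0,
                       background_noise_rate = 0)
    rnb <- simulate_read_starts(plant_features(cfgnb), cfgnb)
    tapply(rnb$count,
           paste(rnb$replicon, rnb$strand, rnb$five_prime_pos), sum)
  }))
  frac_drop <- mean(dnb < 30)
  # analytic NB tail: size = 1/dispersion = 2, mu = 100
  p_drop <- stats::pnbinom(29, size = 2, mu = 100)
  expect_gt(frac_drop, 0)
  expect_lt(abs(frac_drop - p_drop), 0.15)
})

test_that("experiment files round-trip through the writers", {
  withr::with_tempdir({
    truth <- simulate_tss_experiment(small_cfg())
    write_synth_experiment(truth, "exp")
    inputs <- load_inputs("exp/genome.fasta", "exp/genes.gff3",
                          "exp/reads.tsv")
    expect_identical(inputs$genome$replicons, truth$genome$replicons)
    expect_equal(nrow(inputs$genes), nrow(truth$genes))
    expect_equal(sum(inputs$reads$count), sum(truth$reads$count))
  })
})
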