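# Fixtures built in code at test time.

NTL <- c("A", "C", "G", "T")

rand_seq <- function(n, gc = 0.5) {
  paste(sample(NTL, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random non-overlapping genes with a clear margin from replicon ends
rand_genes <- function(n, L, rep_id = "chr", min_len = 300L, max_len = 900L,
                       margin = 400L) {
  genes <- list()
  pos <- margin
  for (i in seq_len(n)) {
    len <- sample(seq(min_len, max_len, by = 3L), 1)
    gap <- sample(100:600, 1)
    start <- pos + gap
    end <- start + len - 1L
    if (end > L - margin) break
    st <- sample(c("+", "-"), 1)
    genes[[i]] <- tibble::tibble(
      gene_id = sprintf("%s_g%03d", rep_id, i), replicon = rep_id,
      strand = st, start = start, end = end,
      start_codon_pos = if (st == "+") start else end,
      stop_codon_pos = if (st == "+") end else start
    )
    pos <- end
  }
  dplyr::bind_rows(genes)
}

# random read set with clusters near/below the coverage threshold and
# nearby positions exercising the merge rule
rand_reads <- function(L, rep_id = "chr", n_pos = 40, seed_cluster = TRUE) {
  pos <- sample(seq(150L, L - 150L), n_pos)
  rows <- lapply(pos, function(p) {
    st <- sample(c("+", "-"), 1)
    n <- sample(c(5L, 25L, 29L, 30L, 31L, 60L, 120L), 1)
    tibble::tibble(replicon = rep_id, strand = st, five_prime_pos = p,
                   length = sample(60:110, n, replace = TRUE),
                   unique = TRUE, mismatches_first3 = 0L, count = 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (seed_cluster) {
    # deliberate chains at distances 1, 2 and 3 around a few anchors
    anchors <- sample(seq(200L, L - 200L), 3)
    extra <- lapply(anchors, function(a) {
      st <- sample(c("+", "-"), 1)
      dplyr::bind_rows(lapply(c(0L, 2L, 3L, 4L), function(o) {
        tibble::tibble(replicon = rep_id, strand = st,
                       five_prime_pos = a + o,
                       length = sample(60:110, 35, replace = TRUE),
                       unique = TRUE, mismatches_first3 = 0L, count = 1L)
      }))
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(extra))
  }
  out
}

# coordinate mirror of a position on a replicon of length L
mirror_pos <- function(p, L) L - p + 1L

mirror_strand <- function(s) ifelse(s == "+", "-", "+")

mirror_genome <- function(genome) {
  tssmap::genome(
    setNames(tssmap::revcomp(genome$replicons), names(genome$replicons)),
    circular = unname(genome$circular)
  )
}

mirror_reads <- function(reads, lens) {
  out <- reads
  out$five_prime_pos <- mirror_pos(reads$five_prime_pos,
                                   unname(lens[reads$replicon]))
  out$strand <- mirror_strand(reads$strand)
  out
}

mirror_genes <- function(genes, lens) {
  L <- unname(lens[genes$replicon])
  tibble::tibble(
    gene_id = genes$gene_id, replicon = genes$replicon,
    strand = mirror_strand(genes$strand),
    start = mirror_pos(genes$end, L), end = mirror_pos(genes$start, L)
  ) |>
    dplyr::mutate(
      start_codon_pos = ifelse(strand == "+", start, end),
      stop_codon_pos = ifelse(strand == "+", end, start)
    )
}

# a moderately sized planted experiment reused by several expensive tests;
# built once per session
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 20260901L)
      cache <<- plant_features(cfg)
    }
    cache
  }
})

# one full pipeline run on the default fixture (clean reads), cached
default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- default_fixture()
      cfg <- pipeline_config(
        genome = truth$genome, genes = truth$genes,
        reads = clean_reads_for(truth),
        rbs = rbs_config(truth$config$anti_sd_tail),
        sigmas = list(
          RpoD = sigma_model("RpoD", w35 = 6L, w10 = 6L, spacer_min = 16L,
                             spacer_max = 18L),
          RpoE1 = sigma_model("RpoE1", mode = "string",
                              consensus = "GAAT-N18-GTCT")
        ),
        seeds = truth$seeds, operons = truth$operons, seed = 1L)
      cache <<- list(truth = truth, config = cfg,
                     run = suppressMessages(run_pipeline(cfg)))
    }
    cache
  }
})

clean_reads_for <- function(truth) {
  cfg <- truth$config
  cfg$depth_dispersion <- 0
  cfg$jitter_rate <- 0
  cfg$background_noise_rate <- 0
  simulate_read_starts(truth, cfg)
}
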