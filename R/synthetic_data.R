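# Synthetic genomes with planted truth: genes and operons, TSS of all six
# classes placed so each satisfies its class geometry unambiguously,
# promoter elements and Shine-Dalgarno leaders written into the sequence,
# gapped TF binding sites, and simulated read-start pileups.

#' Synthetic-experiment configuration
#'
#' Defaults emulate a small GC-rich multi-replicon bacterial genome with a
#' mix of single genes and operons, planted TSS of all six classes, promoter
#' instances 5-12 nt upstream of their TSS and read-start pileups of
#' negative-binomial depth (mean 100, dispersion 0.5, so sub-threshold
#' dropouts occur) with read lengths matching observed contig lengths
#' (87-108 nt).
#'
#' @param n_replicons Number of replicons.
#' @param replicon_lengths Lengths (nt, each >= 5000); recycled.
#' @param n_genes Total genes across replicons.
#' @param operon_fraction Fraction of genes that are non-lead operon members.
#' @param gc_content GC fraction of background sequence.
#' @param tss_counts Named integer vector of planted TSS per class
#'   (`mTSS`, `lmTSS`, `pmTSS`, `seTSS`, `asTSS`, `sTSS`).
#' @param read_depth_at_tss Mean reads sharing a planted 5' end.
#' @param depth_dispersion Negative-binomial dispersion (`var = mu + d*mu^2`);
#'   0 switches to Poisson depth.
#' @param jitter_rate Expected satellite reads within +/-1-2 nt, as a
#'   fraction of the TSS depth.
#' @param background_noise_rate Spurious read-start positions per kb per
#'   strand.
#' @param read_length_range Read length bounds (nt, within 50-200).
#' @param promoters `NULL` or a list: `sigma`, `consensus35`, `consensus10`,
#'   `spacer_range`, `n_seed` (planted with `seed_mismatch` mismatches; the
#'   seed set for profile searches), `n_exact` (exact-consensus instances),
#'   `n_sampled` (instances sampled from the seed-set PSSM at
#'   `sample_min_score_frac` of its maximal score), `seed_mismatch`.
#' @param anti_sd_tail 16S rRNA 3' tail (RNA, 5'->3') used to write
#'   Shine-Dalgarno leaders upstream of mTSS genes.
#' @param n_tfbs Planted gapped TF binding sites (box1 `TAA`, 7-nt spacer,
#'   box2 `TTAAC`) upstream of genes without planted TSS.
#' @param boundary_cases Also plant deliberately ambiguous TSS whose contig
#'   spans a gene and the next gene's upstream window (class-hierarchy
#'   exercises; intended class recorded in the truth set).
#' @param seed Integer seed; all outputs are deterministic given the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_replicons = 2L,
                         replicon_lengths = c(300000L, 200000L),
                         n_genes = 200L,
                         operon_fraction = 0.25,
                         gc_content = 0.6,
                         tss_counts = c(mTSS = 40L, lmTSS = 10L, pmTSS = 15L,
                                        seTSS = 30L, asTSS = 35L, sTSS = 10L),
                         read_depth_at_tss = 100,
                         depth_dispersion = 0.5,
                         jitter_rate = 0.05,
                         background_noise_rate = 0.5,
                         read_length_range = c(87L, 108L),
                         promoters = list(sigma = "RpoD",
                                          consensus35 = "TTGACA",
                                          consensus10 = "TATAAT",
                                          spacer_range = c(16L, 18L),
                                          n_seed = 5L, n_exact = 10L,
                                          n_sampled = 0L,
                                          sample_min_score_frac = 0.8,
                                          seed_mismatch = 1L),
                         anti_sd_tail = "ACCUCCUU",
                         n_tfbs = 5L,
                         boundary_cases = FALSE,
                         seed = 1L) {
  replicon_lengths <- rep_len(as.integer(replicon_lengths), n_replicons)
  if (any(replicon_lengths < 5000)) abort("replicon lengths must be >= 5000")
  if (gc_content <= 0 || gc_content >= 1) abort("gc_content must be in (0,1)")
  if (read_length_range[1] < 50 || read_length_range[2] > 200) {
    abort("read_length_range must lie within [50, 200]")
  }
  cls <- c("mTSS", "lmTSS", "pmTSS", "seTSS", "asTSS", "sTSS")
  tss_counts <- setNames(as.integer(tss_counts[cls]), cls)
  tss_counts[is.na(tss_counts)] <- 0L
  structure(list(n_replicons = as.integer(n_replicons),
                 replicon_lengths = replicon_lengths,
                 n_genes = as.integer(n_genes),
                 operon_fraction = operon_fraction,
                 gc_content = gc_content,
                 tss_counts = tss_counts,
                 read_depth_at_tss = read_depth_at_tss,
                 depth_dispersion = depth_dispersion,
                 jitter_rate = jitter_rate,
                 background_noise_rate = background_noise_rate,
                 read_length_range = as.integer(read_length_range),
                 promoters = promoters,
                 anti_sd_tail = toupper(gsub("T", "U", anti_sd_tail)),
                 n_tfbs = as.integer(n_tfbs),
                 boundary_cases = isTRUE(boundary_cases),
                 seed = as.integer(seed)),
            class = "synth_config")
}

random_dna <- function(n, gc) {
  sample(NT, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# stop-free random CDS interior (codons, excluding TAA/TAG/TGA)
random_cds <- function(n_codons, gc) {
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(random_dna(3L, gc), collapse = "")
      if (!cd %in% c("TAA", "TAG", "TGA")) break
    }
    out[i] <- cd
  }
  paste(out, collapse = "")
}

# substring replacement on a character genome sequence
splice_seq <- function(seq, start, replacement) {
  substr(seq, start, start + nchar(replacement) - 1L) <- replacement
  seq
}

# mutate `k` random positions of a word to a different base
mutate_word <- function(word, k) {
  ch <- strsplit(word, NULL)[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(NT, ch[p]), 1)
  paste(ch, collapse = "")
}

# layout constants (nt); the inter-unit gap leaves every planted feature
# >= 10 nt clear of its class boundaries
SYNTH_GAP <- 1000L
SYNTH_OPERON_GAP <- 80L

#' Plant genes, operons, TSS, promoters, SD leaders and TFBS
#'
#' Builds the genome sequence and annotation and a truth set in one pass.
#' Genes are laid out in transcription units separated by 1 kb gaps (80 nt
#' within operons), each unit on a random strand, with start codon ATG,
#' stop codon TAA, and a stop-free coding interior. Planted TSS are placed
#' so each satisfies its class geometry exactly and with >= 10 nt margin:
#' mTSS 20-54 nt upstream of a start codon, lmTSS on the start codon,
#' pmTSS 170-290 nt upstream (contig clear of all MTUs), seTSS/asTSS
#' mid-CDS in sense/antisense, sTSS 450 nt upstream of a same-strand start
#' codon. Promoter elements, Shine-Dalgarno leaders (reverse complement of
#' the anti-SD tail, ending 8 nt before mTSS start codons) and TF binding
#' sites are written into the sequence.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_truth`: `genome`, `genes`, `operons`,
#'   `tss` (with `intended_class`), `promoters`, `seeds` (promoter-seed
#'   tibble for profile searches), `sd_leaders`, `tfbs`, `config`.
#' @export
plant_features <- function(config) {
  set.seed(config$seed)
  n_rep <- config$n_replicons
  rep_ids <- paste0("rep", LETTERS[seq_len(n_rep)])
  lens <- setNames(config$replicon_lengths, rep_ids)
  seqs <- setNames(
    vapply(lens, function(L) paste(random_dna(L, config$gc_content),
                                   collapse = ""), character(1)),
    rep_ids)

  # --- transcription-unit layout -----------------------------------------
  per_rep <- pmax(1L, round(config$n_genes * lens / sum(lens)))
  per_rep[n_rep] <- config$n_genes - sum(per_rep[-n_rep])
  genes <- list()
  operons <- list()
  op_count <- 0L
  # operon_fraction bounds the fraction of genes that are non-lead members
  max_followers <- floor(config$operon_fraction * config$n_genes)
  n_followers <- 0L
  for (r in seq_len(n_rep)) {
    pos <- SYNTH_GAP
    placed <- 0L
    gi <- 0L
    while (placed < per_rep[r]) {
      remaining <- per_rep[r] - placed
      unit_size <- if (remaining >= 2 && n_followers + 1L <= max_followers &&
                       runif(1) < config$operon_fraction) {
        min(remaining, sample(2:3, 1), max_followers - n_followers + 1L)
      } else 1L
      st <- sample(c("+", "-"), 1)
      unit <- list()
      upos <- pos
      for (k in seq_len(unit_size)) {
        cds_codons <- sample(150:300, 1)          # 450-900 nt
        glen <- cds_codons * 3L
        gstart <- upos
        gend <- upos + glen - 1L
        if (gend + SYNTH_GAP > lens[r]) break
        gi <- gi + 1L
        unit[[k]] <- tibble(
          gene_id = sprintf("%s_g%03d", rep_ids[r], gi),
          replicon = rep_ids[r], strand = st,
          start = gstart, end = gend, cds_codons = cds_codons
        )
        upos <- gend + 1L + SYNTH_OPERON_GAP
      }
      if (length(unit) == 0) break
      unit <- list_rbind(unit)
      if (nrow(unit) > 1) {
        op_count <- op_count + 1L
        ord <- if (st == "+") seq_len(nrow(unit)) else rev(seq_len(nrow(unit)))
        operons[[op_count]] <- tibble(
          operon_id = sprintf("op%03d", op_count),
          gene_id = unit$gene_id[ord],
          position = seq_len(nrow(unit))
        )
      }
      genes[[length(genes) + 1L]] <- unit
      placed <- placed + nrow(unit)
      if (nrow(unit) > 1) n_followers <- n_followers + nrow(unit) - 1L
      pos <- max(unit$end) + 1L + SYNTH_GAP
      if (pos + 2000L > lens[r]) break
    }
    if (placed < per_rep[r]) {
      abort(sprintf(
        "replicon %s (%d nt) cannot fit the %d genes requested for it",
        rep_ids[r], lens[r], per_rep[r]))
    }
  }
  genes <- list_rbind(genes) |>
    mutate(start_codon_pos = if_else(.data$strand == "+", .data$start, .data$end),
           stop_codon_pos = if_else(.data$strand == "+", .data$end, .data$start))
  operons <- if (length(operons)) list_rbind(operons) else {
    tibble(operon_id = character(), gene_id = character(), position = integer())
  }

  # write gene sequences: ATG + stop-free interior + TAA, oriented
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    body <- paste0("ATG", random_cds(g$cds_codons - 2L, config$gc_content),
                   "TAA")
    if (g$strand == "-") body <- revcomp(body)
    seqs[[g$replicon]] <- splice_seq(seqs[[g$replicon]], g$start, body)
  }

  # --- host assignment ----------------------------------------------------
  # lead genes (operon position 1) and standalone genes host planted TSS;
  # one planted feature per host keeps every plant unambiguous
  followers <- operons$gene_id[operons$position > 1]
  hosts <- genes$gene_id[!genes$gene_id %in% followers]
  hosts <- sample(hosts)                 # random assignment order
  need <- sum(config$tss_counts) + config$n_tfbs +
    if (config$boundary_cases) 2L else 0L
  if (need > length(hosts)) {
    abort(sprintf("requested features (%d) exceed available host genes (%d)",
                  need, length(hosts)))
  }
  gene_row <- function(id) genes[genes$gene_id == id, ]

  truth <- list()
  host_i <- 0L
  take_host <- function() {
    host_i <<- host_i + 1L
    gene_row(hosts[host_i])
  }
  plant_tss <- function(class, pos, strand, replicon, gene_id,
                        utr5 = NA_integer_) {
    truth[[length(truth) + 1L]] <<- tibble(
      intended_class = class, replicon = replicon, strand = strand,
      pos = as.integer(pos), gene_id = gene_id, utr5_len = utr5
    )
  }

  for (class in names(config$tss_counts)) {
    for (k in seq_len(config$tss_counts[[class]])) {
      g <- take_host()
      plus <- g$strand == "+"
      sc <- g$start_codon_pos
      switch(class,
        mTSS = {
          d <- sample(20:54, 1)
          plant_tss("mTSS", if (plus) sc - d else sc + d, g$strand,
                    g$replicon, g$gene_id, utr5 = d)
        },
        lmTSS = plant_tss("lmTSS", sc, g$strand, g$replicon, g$gene_id,
                          utr5 = 0L),
        pmTSS = {
          d <- sample(170:290, 1)
          plant_tss("pmTSS", if (plus) sc - d else sc + d, g$strand,
                    g$replicon, g$gene_id)
        },
        seTSS = plant_tss("seTSS",
                          if (plus) g$start + 150L else g$end - 150L,
                          g$strand, g$replicon, g$gene_id),
        asTSS = plant_tss("asTSS",
                          if (plus) g$start + 150L else g$end - 150L,
                          if (plus) "-" else "+",
                          g$replicon, g$gene_id),
        sTSS = {
          d <- 450L
          plant_tss("sTSS", if (plus) sc - d else sc + d, g$strand,
                    g$replicon, NA_character_)
        }
      )
    }
  }

  if (config$boundary_cases && nrow(operons) > 0) {
    # contig spans the gap inside an operon and the next member's upstream
    # window: hierarchy resolves these to mTSS of the downstream member
    ops <- unique(operons$operon_id)
    for (op in head(ops, 2)) {
      mem <- operons$gene_id[operons$operon_id == op]
      g1 <- gene_row(mem[1]); g2 <- gene_row(mem[2])
      if (g1$strand == "+") {
        plant_tss("mTSS", g2$start - 60L, "+", g2$replicon, g2$gene_id,
                  utr5 = 60L)
      } else {
        plant_tss("mTSS", g2$end + 60L, "-", g2$replicon, g2$gene_id,
                  utr5 = 60L)
      }
    }
  }
  tss <- list_rbind(truth)

  # --- promoters ----------------------------------------------------------
  prom <- NULL
  seeds <- NULL
  pc <- config$promoters
  if (!is.null(pc)) {
    m_rows <- which(tss$intended_class == "mTSS")
    n_prom <- pc$n_seed + pc$n_exact + (pc$n_sampled %||% 0L)
    if (n_prom > length(m_rows)) {
      abort("not enough planted mTSS to carry the requested promoters")
    }
    pick <- m_rows[seq_len(n_prom)]
    kinds <- c(rep("seed", pc$n_seed), rep("exact", pc$n_exact),
               rep("sampled", pc$n_sampled %||% 0L))
    seed_seqs35 <- character(0)
    seed_seqs10 <- character(0)
    # seed elements carry mismatches so exact-consensus plants are distinct
    for (j in seq_len(pc$n_seed)) {
      seed_seqs35[j] <- mutate_word(pc$consensus35, pc$seed_mismatch %||% 1L)
      seed_seqs10[j] <- mutate_word(pc$consensus10, pc$seed_mismatch %||% 1L)
    }
    sampled35 <- sampled10 <- character(0)
    n_samp <- pc$n_sampled %||% 0L
    if (n_samp > 0) {
      p35 <- build_pssm(seed_seqs35, pseudocount = 1)
      p10 <- build_pssm(seed_seqs10, pseudocount = 1)
      sampled35 <- sample_pssm_words(p35, n_samp, pc$sample_min_score_frac)
      sampled10 <- sample_pssm_words(p10, n_samp, pc$sample_min_score_frac)
    }
    prom_rows <- list()
    for (j in seq_along(pick)) {
      t <- tss[pick[j], ]
      g <- gene_row(t$gene_id)
      s35 <- switch(kinds[j], seed = seed_seqs35[j], exact = pc$consensus35,
                    sampled = sampled35[j - pc$n_seed - pc$n_exact])
      s10 <- switch(kinds[j], seed = seed_seqs10[j], exact = pc$consensus10,
                    sampled = sampled10[j - pc$n_seed - pc$n_exact])
      gap <- sample(5:12, 1)
      sp <- sample(seq(pc$spacer_range[1], pc$spacer_range[2]), 1)
      w10 <- nchar(s10); w35 <- nchar(s35)
      if (t$strand == "+") {
        pos10 <- t$pos - gap - w10 + 1L
        pos35 <- pos10 - sp - w35
        block <- paste0(s35, substr(seqs[[t$replicon]],
                                    pos35 + w35, pos10 - 1L), s10)
        seqs[[t$replicon]] <- splice_seq(seqs[[t$replicon]], pos35, block)
      } else {
        pos10 <- t$pos + gap                       # genomic start of -10
        pos35 <- pos10 + w10 + sp                  # genomic start of -35
        block <- paste0(revcomp(s10),
                        substr(seqs[[t$replicon]], pos10 + w10, pos35 - 1L),
                        revcomp(s35))
        seqs[[t$replicon]] <- splice_seq(seqs[[t$replicon]], pos10, block)
      }
      prom_rows[[j]] <- tibble(
        sigma = pc$sigma, kind = kinds[j], replicon = t$replicon,
        strand = t$strand, seq35 = s35, seq10 = s10,
        pos35 = if (t$strand == "+") pos35 else pos35,
        pos10 = pos10, spacer = sp, gap_to_tss = gap, tss_pos = t$pos,
        gene_id = t$gene_id
      )
    }
    prom <- list_rbind(prom_rows)
    seeds <- prom |>
      filter(.data$kind == "seed") |>
      mutate(label = "model", tss_id = NA_character_) |>
      select("sigma", "seq35", "seq10", "label", "tss_id", "replicon",
             "strand", "pos35", "pos10")
  }

  # --- Shine-Dalgarno leaders for mTSS genes ------------------------------
  # the leader background is pyrimidine-rich (G-poor), as around real RBS:
  # a G/A-rich background would create competing anti-SD hybridisation
  # sites and make the planted RBS ambiguous
  sd_word <- revcomp(gsub("U", "T", config$anti_sd_tail))
  leader_bg <- function(n) {
    paste(sample(NT, n, replace = TRUE, prob = c(0.2, 0.3, 0.05, 0.45)),
          collapse = "")
  }
  sd_rows <- list()
  for (i in which(tss$intended_class == "mTSS" & !is.na(tss$gene_id))) {
    t <- tss[i, ]
    if (is.na(t$utr5_len) || t$utr5_len < nchar(sd_word) + 8L) next
    g <- gene_row(t$gene_id)
    d <- t$utr5_len
    if (g$strand == "+") {
      seqs[[g$replicon]] <- splice_seq(seqs[[g$replicon]],
                                       g$start_codon_pos - d, leader_bg(d))
    } else {
      seqs[[g$replicon]] <- splice_seq(seqs[[g$replicon]],
                                       g$start_codon_pos + 1L,
                                       revcomp(leader_bg(d)))
    }
    if (g$strand == "+") {
      s <- g$start_codon_pos - 8L - nchar(sd_word)
      seqs[[g$replicon]] <- splice_seq(seqs[[g$replicon]], s, sd_word)
      sd_rows[[length(sd_rows) + 1L]] <- tibble(
        gene_id = g$gene_id, replicon = g$replicon, strand = "+",
        start = s, end = s + nchar(sd_word) - 1L, tss_pos = t$pos)
    } else {
      s <- g$start_codon_pos + 9L
      seqs[[g$replicon]] <- splice_seq(seqs[[g$replicon]], s,
                                       revcomp(sd_word))
      sd_rows[[length(sd_rows) + 1L]] <- tibble(
        gene_id = g$gene_id, replicon = g$replicon, strand = "-",
        start = s, end = s + nchar(sd_word) - 1L, tss_pos = t$pos)
    }
  }
  sd_leaders <- if (length(sd_rows)) list_rbind(sd_rows) else {
    tibble(gene_id = character(), replicon = character(), strand = character(),
           start = integer(), end = integer(), tss_pos = integer())
  }

  # --- TF binding sites ---------------------------------------------------
  tfbs_rows <- list()
  for (k in seq_len(config$n_tfbs)) {
    g <- take_host()
    site <- paste0("TAA", paste(random_dna(7L, config$gc_content),
                                collapse = ""), "TTAAC")
    if (g$strand == "+") {
      s <- g$start - 80L
      seqs[[g$replicon]] <- splice_seq(seqs[[g$replicon]], s, site)
      tfbs_rows[[k]] <- tibble(gene_id = g$gene_id, replicon = g$replicon,
                               strand = "+", start = s,
                               end = s + nchar(site) - 1L, site = site)
    } else {
      s <- g$end + 80L - nchar(site) + 1L
      seqs[[g$replicon]] <- splice_seq(seqs[[g$replicon]], s, revcomp(site))
      tfbs_rows[[k]] <- tibble(gene_id = g$gene_id, replicon = g$replicon,
                               strand = "-", start = s,
                               end = s + nchar(site) - 1L, site = site)
    }
  }
  tfbs <- if (length(tfbs_rows)) list_rbind(tfbs_rows) else {
    tibble(gene_id = character(), replicon = character(), strand = character(),
           start = integer(), end = integer(), site = character())
  }

  structure(list(
    genome = genome(seqs, circular = TRUE),
    genes = select(genes, -"cds_codons"),
    operons = operons,
    tss = tss,
    promoters = prom,
    seeds = seeds,
    sd_leaders = sd_leaders,
    tfbs = tfbs,
    config = config
  ), class = "synth_truth")
}

# rejection-sample words from a PSSM with score >= frac * max score
sample_pssm_words <- function(pssm, n, frac) {
  mx <- sum(apply(pssm$log_odds, 2, max))
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      w <- vapply(seq_len(pssm$width), function(j) {
        sample(NT, 1, prob = pssm$probs[, j])
      }, character(1))
      sc <- sum(pssm$log_odds[cbind(match(w, NT), seq_len(pssm$width))])
      if (sc >= frac * mx) break
    }
    out[i] <- paste(w, collapse = "")
  }
  out
}

#' Simulate read starts for a planted truth set
#'
#' Every planted TSS receives a negative-binomial (or Poisson when the
#' dispersion is 0) number of reads sharing its 5' position, with read
#' lengths uniform in the configured range; satellite reads within 1-2 nt
#' appear at `jitter_rate` times the TSS depth; spurious background
#' read-start positions occur at `background_noise_rate` per kb per strand
#' with small Poisson counts, a fifth of them flagged non-unique or
#' 5'-mismatched so the read filters act.
#'
#' @param truth A `synth_truth` from [plant_features()].
#' @param config Defaults to `truth$config`.
#' @return Read tibble (aggregated rows with `count`), deterministic given
#'   the config seed.
#' @export
simulate_read_starts <- function(truth, config = truth$config) {
  set.seed(config$seed + 1001L)
  lens <- replicon_lengths(truth$genome)
  rl <- config$read_length_range
  rows <- list()
  emit <- function(replicon, strand, pos, n, unique = TRUE, mm = 0L,
                   min_len = rl[1], max_len = rl[2]) {
    if (n <= 0) return()
    lens_i <- sample(seq(min_len, max_len), n, replace = TRUE)
    agg <- table(lens_i)
    rows[[length(rows) + 1L]] <<- tibble(
      replicon = replicon, strand = strand, five_prime_pos = as.integer(pos),
      length = as.integer(names(agg)), unique = unique,
      mismatches_first3 = as.integer(mm), count = as.integer(agg)
    )
  }
  for (i in seq_len(nrow(truth$tss))) {
    t <- truth$tss[i, ]
    n <- if (config$depth_dispersion > 0) {
      rnbinom(1, size = 1 / config$depth_dispersion,
              mu = config$read_depth_at_tss)
    } else rpois(1, config$read_depth_at_tss)
    # clip read length so contigs never run off the replicon
    room <- if (t$strand == "+") lens[[t$replicon]] - t$pos else t$pos - 1L
    emit(t$replicon, t$strand, t$pos, n, max_len = min(rl[2], room + 1L))
    if (config$jitter_rate > 0 && n > 0) {
      nj <- rpois(1, config$jitter_rate * n)
      if (nj > 0) {
        offs <- sample(c(-2L, -1L, 1L, 2L), nj, replace = TRUE)
        for (o in unique(offs)) {
          emit(t$replicon, t$strand, t$pos + o, sum(offs == o))
        }
      }
    }
  }
  if (config$background_noise_rate > 0) {
    for (rep_id in names(lens)) {
      for (st in c("+", "-")) {
        n_pos <- rpois(1, config$background_noise_rate * lens[[rep_id]] / 1000)
        if (n_pos == 0) next
        pos <- sample(seq(rl[2] + 1L, lens[[rep_id]] - rl[2] - 1L), n_pos)
        cnt <- rpois(n_pos, 3) + 1L
        decoy <- runif(n_pos) < 0.2
        for (k in seq_len(n_pos)) {
          if (decoy[k]) {
            # exercised by the read filters: non-unique or 5'-mismatched
            if (runif(1) < 0.5) {
              emit(rep_id, st, pos[k], cnt[k], unique = FALSE)
            } else {
              emit(rep_id, st, pos[k], cnt[k], mm = 1L)
            }
          } else {
            emit(rep_id, st, pos[k], cnt[k])
          }
        }
      }
    }
  }
  out <- if (length(rows)) list_rbind(rows) else {
    tibble(replicon = character(), strand = character(),
           five_prime_pos = integer(), length = integer(), unique = logical(),
           mismatches_first3 = integer(), count = integer())
  }
  arrange(out, .data$replicon, .data$five_prime_pos, .data$strand,
          .data$length)
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: [plant_features()] plus [simulate_read_starts()].
#'
#' @param config A [synth_config()].
#' @return The `synth_truth` list with an added `reads` element.
#' @export
simulate_tss_experiment <- function(config = synth_config()) {
  truth <- plant_features(config)
  truth$reads <- simulate_read_starts(truth, config)
  truth
}

#' Write a synthetic experiment to files
#'
#' Writes `genome.fasta`, `genes.gff3`, `reads.tsv` and `truth.tsv` into a
#' directory.
#'
#' @param truth A `synth_truth` (with reads).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synth_experiment <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome_fasta(truth$genome, file.path(dir, "genome.fasta"))
  write_genes_gff3(truth$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(truth$reads, file.path(dir, "reads.tsv"))
  readr::write_tsv(truth$tss, file.path(dir, "truth.tsv"))
  invisible(dir)
}
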