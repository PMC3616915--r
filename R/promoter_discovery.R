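# Sigma-factor promoter prediction: -35/-10 element scanning with exact
# P-values, collinear chaining with spacer constraints, TSS association,
# exact seed extension, the iterative two-phase profile procedure, and the
# one-mismatch consensus string search for ECF sigma factors.

#' Describe a sigma-factor promoter model
#'
#' Profile-mode models carry element widths, a spacer range and the two
#' P-value cutoffs of the iterative search (0.005 in the stringent first
#' phase, 0.02 in the permissive second phase). String-mode models carry a
#' consensus pattern such as `"GAAT-N18-GTCT"` and a mismatch budget.
#' Promoters must end 5 to 12 nt upstream of a TSS in either mode.
#'
#' @param name Sigma factor name (e.g. `"RpoD"`, `"RpoE1"`).
#' @param mode `"profile"` or `"string"`.
#' @param w35,w10 Element widths (profile mode; the -24/-12 elements of
#'   sigma-54 models are handled identically).
#' @param spacer_min,spacer_max Spacer range, nucleotides strictly between
#'   the two elements.
#' @param tss_gap_min,tss_gap_max Allowed distance from the last promoter
#'   nucleotide to the TSS.
#' @param p_phase1,p_phase2 Element P-value cutoffs for the two phases.
#' @param consensus Consensus pattern `BOX1-N<k>-BOX2` (string mode). A fixed
#'   `N<k>` spacer may be widened with `spacer_min`/`spacer_max`.
#' @param max_mismatch Total mismatch budget across both boxes (string mode).
#' @return A list of class `sigma_model`.
#' @export
sigma_model <- function(name, mode = c("profile", "string"),
                        w35 = 6L, w10 = 7L,
                        spacer_min = 14L, spacer_max = 20L,
                        tss_gap_min = 5L, tss_gap_max = 12L,
                        p_phase1 = 0.005, p_phase2 = 0.02,
                        consensus = NULL, max_mismatch = 1L) {
  mode <- match.arg(mode)
  if (mode == "string") {
    if (is.null(consensus)) abort("string mode requires a consensus pattern")
    parsed <- parse_consensus(consensus)
    w35 <- nchar(parsed$box1)
    w10 <- nchar(parsed$box2)
    if (missing(spacer_min)) spacer_min <- parsed$spacer
    if (missing(spacer_max)) spacer_max <- parsed$spacer
  }
  if (spacer_min > spacer_max) abort("spacer_min must be <= spacer_max")
  structure(list(name = name, mode = mode, w35 = as.integer(w35),
                 w10 = as.integer(w10), spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 tss_gap_min = as.integer(tss_gap_min),
                 tss_gap_max = as.integer(tss_gap_max),
                 p_phase1 = p_phase1, p_phase2 = p_phase2,
                 consensus = consensus, max_mismatch = as.integer(max_mismatch)),
            class = "sigma_model")
}

parse_consensus <- function(pattern) {
  m <- regmatches(pattern,
                  regexec("^([ACGT]+)-N(\\d+)-([ACGT]+)$", toupper(pattern)))[[1]]
  if (length(m) != 4) {
    abort(paste0("malformed consensus pattern: ", pattern,
                 " (expected e.g. GAAT-N18-GTCT)"))
  }
  list(box1 = m[2], spacer = as.integer(m[3]), box2 = m[4])
}

#' Build a promoter-seed tibble
#'
#' @param sigma Sigma name.
#' @param seq35,seq10 Element sequences.
#' @param label Provenance: `"virtual"` (literature promoter without a
#'   matching TSS), `"model"` (with one), or a downstream discovery label.
#' @param tss_id Linked TSS id or `NA` (virtual seeds have none).
#' @param replicon,strand,pos35,pos10 Optional genomic anchoring (start of
#'   each element).
#' @return A seed tibble.
#' @export
promoter_seeds <- function(sigma, seq35, seq10, label = "model",
                           tss_id = NA_character_, replicon = NA_character_,
                           strand = NA_character_, pos35 = NA_integer_,
                           pos10 = NA_integer_) {
  tibble(sigma = sigma, seq35 = toupper(seq35), seq10 = toupper(seq10),
         label = label, tss_id = tss_id, replicon = replicon,
         strand = strand, pos35 = as.integer(pos35), pos10 = as.integer(pos10))
}

# all exact occurrences of a word on both strands, as element intervals
exact_occurrences <- function(genome, word) {
  w <- nchar(word)
  res <- list()
  for (rep_id in names(genome$replicons)) {
    seq_f <- genome$replicons[[rep_id]]
    for (st in c("+", "-")) {
      pat <- if (st == "+") word else revcomp(word)
      hits <- gregexpr(pat, seq_f, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      if (length(hits) == 0) next
      res[[length(res) + 1L]] <- tibble(
        replicon = rep_id, strand = st,
        start = as.integer(hits), end = as.integer(hits) + w - 1L
      )
    }
  }
  if (length(res)) list_rbind(res) else {
    tibble(replicon = character(), strand = character(),
           start = integer(), end = integer())
  }
}

# gap from the last (3'-most, in transcription direction) promoter
# nucleotide to a TSS: an element ending at t-5 has gap 5
gap_positions <- function(end10_start, end10_end, strand, gap) {
  if_else(strand == "+", end10_end + gap, end10_start - gap)
}

# associate chained element pairs with TSS / relaxed-contig 5' ends lying
# 5-12 nt downstream of the -10 element; returns one row per (pair, tss)
associate_pairs <- function(pairs, sigma, tss, relaxed = NULL) {
  anchors <- tibble(
    replicon = tss$replicon, strand = tss$strand, pos = tss$tss_pos,
    tss_id = if ("id" %in% names(tss)) tss$id else as.character(tss$tss_pos),
    tss_class = if ("tss_class" %in% names(tss)) tss$tss_class
                else NA_character_)
  if (!is.null(relaxed) && nrow(relaxed) > 0) {
    anchors <- bind_rows(anchors, tibble(
      replicon = relaxed$replicon, strand = relaxed$strand,
      pos = relaxed$five_prime_pos,
      tss_id = paste0("relaxed:", relaxed$id),
      tss_class = "relaxed_contig"
    ))
  }
  out <- list()
  for (gap in seq(sigma$tss_gap_min, sigma$tss_gap_max)) {
    tpos <- gap_positions(pairs$start10, pairs$end10, pairs$strand, gap)
    key <- paste(pairs$replicon, pairs$strand, tpos)
    akey <- paste(anchors$replicon, anchors$strand, anchors$pos)
    m <- match(key, akey)
    hit <- !is.na(m)
    if (!any(hit)) next
    add <- pairs[hit, , drop = FALSE]
    add$gap_to_tss <- gap
    add$tss_id <- anchors$tss_id[m[hit]]
    add$tss_class <- anchors$tss_class[m[hit]]
    out[[length(out) + 1L]] <- add
  }
  if (length(out)) list_rbind(out) else {
    pairs[0, ] |> mutate(gap_to_tss = integer(), tss_id = character(),
                         tss_class = character())
  }
}

#' Chain -35/-10 element hits and associate them with TSS
#'
#' Forms all collinear same-strand (-35, -10) pairs whose spacer (the number
#' of nucleotides strictly between the elements) lies within the model's
#' range, then keeps pairs whose -10 element ends 5 to 12 nt upstream of a
#' TSS or relaxed-contig 5' end. One row per (pair, anchor) association is
#' returned.
#'
#' @param hits35,hits10 Element hits from [scan_elements()].
#' @param sigma A [sigma_model()].
#' @param tss TSS tibble (`replicon`, `strand`, `tss_pos`, optionally `id`,
#'   `tss_class`).
#' @param relaxed Optional relaxed-contig tibble
#'   (see [relaxed_contigs_from_coverage()]).
#' @return Tibble of candidate promoter hits with element coordinates,
#'   P-values, spacer, `gap_to_tss`, `tss_id`, `tss_class`.
#' @export
chain_and_associate <- function(hits35, hits10, sigma, tss, relaxed = NULL) {
  pairs_out <- list()
  for (sp in seq(sigma$spacer_min, sigma$spacer_max)) {
    # + strand: -10 starts sp+1 after -35 ends; - strand mirrored
    off35 <- if_else(hits10$strand == "+",
                     hits10$start - sp - sigma$w35,
                     hits10$end + sp + 1L)
    key35 <- paste(hits35$replicon, hits35$strand, hits35$start)
    k <- paste(hits10$replicon, hits10$strand, off35)
    m <- match(k, key35)
    hit <- !is.na(m)
    if (!any(hit)) next
    h10 <- hits10[hit, , drop = FALSE]
    h35 <- hits35[m[hit], , drop = FALSE]
    pairs_out[[length(pairs_out) + 1L]] <- tibble(
      sigma = sigma$name,
      replicon = h10$replicon, strand = h10$strand,
      pos35 = h35$start, end35 = h35$end,
      start10 = h10$start, end10 = h10$end,
      spacer = sp,
      score35 = h35$score, score10 = h10$score,
      p35 = h35$pvalue, p10 = h10$pvalue
    )
  }
  pairs <- if (length(pairs_out)) list_rbind(pairs_out) else {
    tibble(sigma = character(), replicon = character(), strand = character(),
           pos35 = integer(), end35 = integer(), start10 = integer(),
           end10 = integer(), spacer = integer(), score35 = numeric(),
           score10 = numeric(), p35 = numeric(), p10 = numeric())
  }
  associate_pairs(pairs, sigma, tss, relaxed)
}

#' Extend promoter seeds by exact genomic matches
#'
#' Searches the genome for occurrences identical to the -35 and -10 elements
#' of each seed, at any spacer within the model's range, whose -10 element
#' ends 5 to 12 nt upstream of a TSS. New occurrences are added with label
#' `"extended_model"`; duplicates (same coordinates) are collapsed.
#'
#' @param seeds Seed tibble from [promoter_seeds()].
#' @param sigma A [sigma_model()].
#' @param genome A `tss_genome`.
#' @param tss TSS tibble.
#' @param relaxed Optional relaxed contigs.
#' @return `seeds` with any extended-model rows appended.
#' @export
extend_seed_exact <- function(seeds, sigma, genome, tss, relaxed = NULL) {
  added <- list()
  uniq <- distinct(seeds, .data$seq35, .data$seq10)
  for (i in seq_len(nrow(uniq))) {
    h35 <- exact_occurrences(genome, uniq$seq35[i])
    h10 <- exact_occurrences(genome, uniq$seq10[i])
    if (nrow(h35) == 0 || nrow(h10) == 0) next
    h35$score <- NA_real_; h35$pvalue <- NA_real_
    h10$score <- NA_real_; h10$pvalue <- NA_real_
    assoc <- chain_and_associate(h35, h10, sigma, tss, relaxed)
    if (nrow(assoc) == 0) next
    added[[length(added) + 1L]] <- tibble(
      sigma = sigma$name, seq35 = uniq$seq35[i], seq10 = uniq$seq10[i],
      label = "extended_model", tss_id = assoc$tss_id,
      replicon = assoc$replicon, strand = assoc$strand,
      pos35 = assoc$pos35, pos10 = assoc$start10
    )
  }
  if (length(added) == 0) return(seeds)
  new <- list_rbind(added) |>
    distinct(.data$replicon, .data$strand, .data$pos35, .data$pos10,
             .keep_all = TRUE)
  # do not re-add coordinates already present among anchored seeds
  if (any(!is.na(seeds$pos35))) {
    key <- paste(new$replicon, new$strand, new$pos35, new$pos10)
    old <- paste(seeds$replicon, seeds$strand, seeds$pos35, seeds$pos10)
    new <- new[!key %in% old, , drop = FALSE]
  }
  bind_rows(seeds, new)
}

# deduplicate per-(pair) candidates: keep the best association per promoter
# (preference: non-seTSS anchor, then smallest gap); record all anchors
dedup_candidates <- function(assoc) {
  if (nrow(assoc) == 0) {
    assoc$only_setss <- logical(0)
    return(assoc)
  }
  assoc |>
    group_by(.data$sigma, .data$replicon, .data$strand, .data$pos35,
             .data$start10) |>
    mutate(only_setss = all(.data$tss_class %in% "seTSS")) |>
    arrange(.data$tss_class %in% "seTSS", .data$gap_to_tss, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Run the iterative two-phase promoter search for one sigma factor
#'
#' The seed set is first extended by exact genomic matches of seed element
#' pairs near TSS. Phase 1 builds -35 and -10 PSSMs from the (extended) seed
#' elements with pseudocount 1 against the genome background, scans both
#' strands, chains collinear pairs, associates them with TSS / relaxed
#' contigs at 5-12 nt, and keeps candidates with both element P-values at
#' most `p_phase1` that are not associated exclusively with seTSS; survivors
#' are labelled `"new_initial"` and join the seed set. Phase 2 rebuilds the
#' PSSMs from the enlarged set and repeats the search with cutoff `p_phase2`
#' and all TSS classes admitted; additional promoters are labelled
#' `"second_search"`. The result is the deduplicated union (key: sigma,
#' strand, element coordinates) with provenance labels; anchored input seeds
#' are reported with their own labels.
#'
#' @param seeds Seed tibble (at least two usable element pairs).
#' @param sigma A profile-mode [sigma_model()].
#' @param genome A `tss_genome`.
#' @param tss TSS tibble (classified TSS recommended so the seTSS filter can
#'   act).
#' @param relaxed Optional relaxed contigs.
#' @param background Background nucleotide frequencies; defaults to the
#'   genome's composition.
#' @return Tibble of promoter hits with provenance labels. The fitted
#'   phase-2 PSSMs are attached as attributes `pssm35`/`pssm10`.
#' @export
run_two_phase <- function(seeds, sigma, genome, tss, relaxed = NULL,
                          background = NULL) {
  if (nrow(seeds) < 2) abort("need at least two seed promoters")
  if (sigma$mode != "profile") abort("run_two_phase needs a profile model")
  background <- background %||% genome_background(genome)

  seeds <- extend_seed_exact(seeds, sigma, genome, tss, relaxed)

  scan_chain <- function(seed_set, p_filter, drop_setss_only) {
    pssm35 <- with_score_distribution(
      build_pssm(seed_set$seq35, pseudocount = 1, background = background))
    pssm10 <- with_score_distribution(
      build_pssm(seed_set$seq10, pseudocount = 1, background = background))
    h35 <- scan_elements(genome, pssm35, sigma$p_phase2)
    h10 <- scan_elements(genome, pssm10, sigma$p_phase2)
    assoc <- chain_and_associate(h35, h10, sigma, tss, relaxed)
    cand <- dedup_candidates(assoc)
    cand <- cand[!is.na(cand$p35) & !is.na(cand$p10) &
                   cand$p35 <= p_filter & cand$p10 <= p_filter, , drop = FALSE]
    if (drop_setss_only) cand <- cand[!cand$only_setss, , drop = FALSE]
    list(cand = cand, pssm35 = pssm35, pssm10 = pssm10)
  }

  seed_keys <- paste(seeds$replicon, seeds$strand, seeds$pos35, seeds$pos10)

  ph1 <- scan_chain(seeds, sigma$p_phase1, drop_setss_only = TRUE)
  new1 <- ph1$cand
  new1 <- new1[!paste(new1$replicon, new1$strand, new1$pos35, new1$start10)
               %in% seed_keys, , drop = FALSE]
  new1$label <- "new_initial"

  seeds2 <- bind_rows(
    seeds,
    if (nrow(new1)) tibble(
      sigma = sigma$name,
      seq35 = promoter_element_seq(genome, new1, "35", sigma),
      seq10 = promoter_element_seq(genome, new1, "10", sigma),
      label = "new_initial", tss_id = new1$tss_id,
      replicon = new1$replicon, strand = new1$strand,
      pos35 = new1$pos35, pos10 = new1$start10
    )
  )

  ph2 <- scan_chain(seeds2, sigma$p_phase2, drop_setss_only = FALSE)
  seed2_keys <- paste(seeds2$replicon, seeds2$strand, seeds2$pos35, seeds2$pos10)
  new2 <- ph2$cand
  new2 <- new2[!paste(new2$replicon, new2$strand, new2$pos35, new2$start10)
               %in% seed2_keys, , drop = FALSE]
  new2$label <- "second_search"

  seed_rows <- seeds2 |>
    mutate(pos10 = .data$pos10) |>
    rename(start10 = "pos10") |>
    mutate(p35 = NA_real_, p10 = NA_real_, spacer = NA_integer_,
           gap_to_tss = NA_integer_, tss_class = NA_character_)
  cols <- c("sigma", "replicon", "strand", "pos35", "start10", "spacer",
            "p35", "p10", "tss_id", "tss_class", "gap_to_tss", "label")
  hits <- bind_rows(seed_rows[cols], new1[cols], new2[cols]) |>
    rename(pos10 = "start10")
  anchored <- !is.na(hits$pos35) & !is.na(hits$pos10) & !is.na(hits$replicon)
  hits <- bind_rows(
    hits[!anchored, , drop = FALSE],   # virtual seeds: no coordinates to key on
    hits[anchored, , drop = FALSE] |>
      distinct(.data$sigma, .data$strand, .data$replicon, .data$pos35,
               .data$pos10, .keep_all = TRUE)
  ) |>
    arrange(.data$replicon, .data$pos10, .data$strand)
  attr(hits, "pssm35") <- ph2$pssm35
  attr(hits, "pssm10") <- ph2$pssm10
  attr(hits, "phase1") <- new1
  hits
}

promoter_element_seq <- function(genome, hits, which, sigma) {
  vapply(seq_len(nrow(hits)), function(i) {
    if (which == "35") {
      s <- hits$pos35[i]; e <- hits$end35[i]
    } else {
      s <- hits$start10[i]; e <- hits$end10[i]
    }
    genome_seq(genome, hits$replicon[i], s, e, hits$strand[i])
  }, character(1))
}

#' Zero-order background frequencies of a genome
#'
#' @param genome A `tss_genome`.
#' @return Named numeric over A/C/G/T (N excluded).
#' @export
genome_background <- function(genome) {
  all_nt <- strsplit(paste(genome$replicons, collapse = ""), NULL)[[1]]
  tb <- table(factor(all_nt, levels = NT))
  as.numeric(tb) / sum(tb) -> fr
  setNames(fr, NT)
}

#' One-mismatch consensus string search for promoters
#'
#' Slides the model's `BOX1-N<spacer>-BOX2` consensus along both strands,
#' allowing at most `max_mismatch` mismatches in total across both boxes
#' (spacer positions are unconstrained, N in the genome never matches), and
#' keeps placements whose last nucleotide lies 5 to 12 nt upstream of a TSS.
#'
#' @param sigma A string-mode [sigma_model()].
#' @param genome A `tss_genome`.
#' @param tss TSS tibble.
#' @param relaxed Optional relaxed contigs.
#' @return Tibble of promoter hits (`pos35`/`pos10` hold the box starts,
#'   `n_mismatch` the total mismatches).
#' @export
string_promoter_search <- function(sigma, genome, tss, relaxed = NULL) {
  if (sigma$mode != "string") abort("string_promoter_search needs string mode")
  pat <- parse_consensus(sigma$consensus)
  out <- list()
  for (rep_id in names(genome$replicons)) {
    seq_f <- genome$replicons[[rep_id]]
    L <- nchar(seq_f)
    ch_f <- strsplit(seq_f, NULL)[[1]]
    ch_r <- strsplit(revcomp(seq_f), NULL)[[1]]
    for (st in c("+", "-")) {
      ch <- if (st == "+") ch_f else ch_r
      mm1 <- box_mismatches(ch, pat$box1)
      mm2 <- box_mismatches(ch, pat$box2)
      w1 <- nchar(pat$box1); w2 <- nchar(pat$box2)
      for (sp in seq(sigma$spacer_min, sigma$spacer_max)) {
        total_w <- w1 + sp + w2
        n <- L - total_w + 1L
        if (n < 1) next
        idx <- seq_len(n)
        mm <- mm1[idx] + mm2[idx + w1 + sp]
        hit <- which(!is.na(mm) & mm <= sigma$max_mismatch)
        if (length(hit) == 0) next
        if (st == "+") {
          pos35 <- hit
          pos10 <- hit + w1 + sp
          end10 <- pos10 + w2 - 1L
        } else {
          # index i on the revcomp: pattern occupies genomic
          # [L - i - total_w + 2, L - i + 1], box2 at the low end
          pos35 <- L - hit - w1 + 2L
          pos10 <- L - hit - w1 - sp - w2 + 2L
          end10 <- pos10 + w2 - 1L
        }
        out[[length(out) + 1L]] <- tibble(
          sigma = sigma$name, replicon = rep_id, strand = st,
          pos35 = pos35, end35 = pos35 + w1 - 1L,
          start10 = pos10, end10 = end10,
          spacer = sp, score35 = NA_real_, score10 = NA_real_,
          p35 = NA_real_, p10 = NA_real_,
          n_mismatch = mm[hit]
        )
      }
    }
  }
  pairs <- if (length(out)) list_rbind(out) else {
    tibble(sigma = character(), replicon = character(), strand = character(),
           pos35 = integer(), end35 = integer(), start10 = integer(),
           end10 = integer(), spacer = integer(), score35 = numeric(),
           score10 = numeric(), p35 = numeric(), p10 = numeric(),
           n_mismatch = integer())
  }
  assoc <- associate_pairs(pairs, sigma, tss, relaxed)
  if (nrow(assoc) == 0) {
    assoc$label <- character(0)
  } else {
    assoc <- assoc |>
      group_by(.data$sigma, .data$replicon, .data$strand, .data$pos35,
               .data$start10) |>
      arrange(.data$gap_to_tss, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
    assoc$label <- "string_search"
  }
  assoc |>
    rename(pos10 = "start10") |>
    arrange(.data$replicon, .data$pos10, .data$strand)
}

# per-position mismatch counts of a fixed box against a character vector;
# positions whose window would contain a non-ACGT base count it as mismatch,
# windows running off the end are NA
box_mismatches <- function(ch, box) {
  L <- length(ch)
  w <- nchar(box)
  n <- L - w + 1L
  if (n < 1) return(rep(NA_integer_, max(L, 0)))
  b <- strsplit(box, NULL)[[1]]
  mm <- integer(n)
  for (j in seq_len(w)) {
    cj <- ch[seq_len(n) + j - 1L]
    mm <- mm + as.integer(cj != b[j] | !cj %in% NT)
  }
  c(mm, rep(NA_integer_, L - n))
}

#' Report TSS with promoters from at least two sigma factors
#'
#' @param hit_sets Named list of promoter-hit tibbles (one per sigma model).
#' @return Tibble with one row per TSS claimed by two or more sigma factors:
#'   `tss_id`, `sigmas` (sorted, comma-separated), `n_sigma`. Symmetric in
#'   input order.
#' @export
cross_sigma_overlap <- function(hit_sets) {
  if (length(hit_sets) < 2) abort("need at least two hit sets")
  all_hits <- list_rbind(lapply(hit_sets, function(h) {
    h <- h[!is.na(h$tss_id) & !startsWith(h$tss_id %||% "", "relaxed:"), ]
    tibble(tss_id = h$tss_id, sigma = h$sigma)
  }))
  all_hits |>
    distinct(.data$tss_id, .data$sigma) |>
    group_by(.data$tss_id) |>
    summarise(sigmas = paste(sort(unique(.data$sigma)), collapse = ","),
              n_sigma = dplyr::n_distinct(.data$sigma), .groups = "drop") |>
    filter(.data$n_sigma >= 2) |>
    arrange(.data$tss_id)
}

#' Bar chart of promoter counts per sigma factor and provenance label
#'
#' @param hits A promoter-hit tibble (possibly several sigma factors bound
#'   together).
#' @return A ggplot.
#' @export
plot_promoter_provenance <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$sigma, fill = .data$label)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "promoters", fill = "provenance") +
    ggplot2::theme_minimal()
}
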