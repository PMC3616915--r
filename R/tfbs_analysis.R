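# Transcription-factor binding-site analysis: gapped-motif PSSM scanning of
# gene upstream regions, positional correlation of motif sites with TSS, and
# extraction of upstream sequences for de novo motif discovery.

#' Gapped-motif scan configuration
#'
#' Models a two-box binding motif with a fixed spacer (e.g. the CtrA box
#' TAA-N7-TTAAC). The PSSM is built from training-site sequences over the
#' informative box columns only; spacer columns are not scored.
#'
#' @param training_sites Character vector (>= 2) of training sites written as
#'   `BOX1 + spacer + BOX2` contiguous sequence, or `NULL` if `pssm` given.
#' @param box1_width,box2_width Box widths (nt).
#' @param spacer Fixed spacer length (nt).
#' @param pseudo_frequencies Pseudo-frequency mass added per position.
#' @param p_max P-value cutoff for reported hits.
#' @param upstream_window Upstream search window per gene (nt), truncated at
#'   the nearest annotated gene.
#' @param motif_name Label used in outputs.
#' @return A list of class `gapped_motif_config`.
#' @export
gapped_motif_config <- function(training_sites = NULL, box1_width = 3L,
                                spacer = 7L, box2_width = 5L,
                                pseudo_frequencies = 0.01, p_max = 1e-4,
                                upstream_window = 300L, motif_name = "motif") {
  stopifnot(p_max > 0, p_max < 1, spacer >= 0)
  if (!is.null(training_sites)) {
    need <- box1_width + spacer + box2_width
    if (length(training_sites) < 2) abort("need >= 2 training sites")
    if (any(nchar(training_sites) != need)) {
      abort(sprintf("training sites must be %d nt (box1+spacer+box2)", need))
    }
  }
  structure(list(training_sites = toupper(training_sites),
                 box1_width = as.integer(box1_width),
                 spacer = as.integer(spacer),
                 box2_width = as.integer(box2_width),
                 pseudo_frequencies = pseudo_frequencies,
                 p_max = p_max,
                 upstream_window = as.integer(upstream_window),
                 motif_name = motif_name),
            class = "gapped_motif_config")
}

# PSSM over the informative (box) columns with pseudo-frequency smoothing:
# f = (counts + pf * background) / (n + pf)
gapped_motif_pssm <- function(config, background) {
  sites <- config$training_sites
  w1 <- config$box1_width
  sp <- config$spacer
  w2 <- config$box2_width
  informative <- paste0(substr(sites, 1, w1),
                        substr(sites, w1 + sp + 1, w1 + sp + w2))
  pssm <- build_pssm(informative, pseudocount = 0, background = background)
  n <- length(sites)
  pf <- config$pseudo_frequencies
  probs <- sweep(pssm$counts, 1, pf * background, "+") / (n + pf)
  pssm$probs <- probs
  pssm$log_odds <- log(sweep(probs, 1, background, "/"))
  attr(pssm, ".dist") <- NULL
  pssm
}

# upstream window of each gene, truncated at the nearest annotated gene
gene_upstream_windows <- function(genes, genome, width) {
  lens <- replicon_lengths(genome)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    others <- genes[genes$replicon == g$replicon & genes$gene_id != g$gene_id, ]
    if (g$strand == "+") {
      lo <- g$start - width
      up_ends <- others$end[others$end < g$start]
      if (length(up_ends)) lo <- max(lo, max(up_ends) + 1L)
      lo <- max(1L, lo)
      hi <- g$start - 1L
    } else {
      hi <- g$end + width
      dn_starts <- others$start[others$start > g$end]
      if (length(dn_starts)) hi <- min(hi, min(dn_starts) - 1L)
      hi <- min(lens[[g$replicon]], hi)
      lo <- g$end + 1L
    }
    if (lo > hi) next
    out[[i]] <- tibble(gene_id = g$gene_id, replicon = g$replicon,
                       strand = g$strand, win_start = lo, win_end = hi)
  }
  list_rbind(out[!vapply(out, is.null, logical(1))])
}

#' Scan gene upstream regions for a gapped motif
#'
#' Builds the informative-column PSSM from the training sites and slides it
#' (box1, fixed spacer, box2) along the sense strand of each gene's upstream
#' window. Hits require a positive weight score, an exact P-value at most
#' `p_max`, and no overlap with any annotated gene.
#'
#' @param genome A `tss_genome`.
#' @param genes Annotated gene tibble.
#' @param config A [gapped_motif_config()].
#' @param background Background frequencies; default genome composition.
#' @return Tibble: `motif`, `replicon`, `strand`, `start`, `end` (full site
#'   including spacer), `score`, `pvalue`, `gene_id`.
#' @export
scan_gapped_motif <- function(genome, genes, config, background = NULL) {
  background <- background %||% genome_background(genome)
  pssm <- with_score_distribution(gapped_motif_pssm(config, background))
  w1 <- config$box1_width
  sp <- config$spacer
  w2 <- config$box2_width
  total_w <- w1 + sp + w2
  wins <- gene_upstream_windows(genes, genome, config$upstream_window)
  lo <- pssm$log_odds
  hits <- list()
  for (i in seq_len(nrow(wins))) {
    wn <- wins[i, ]
    if (wn$win_end - wn$win_start + 1L < total_w) next
    s <- genome_seq(genome, wn$replicon, wn$win_start, wn$win_end, wn$strand)
    ch <- strsplit(s, NULL)[[1]]
    enc <- match(ch, NT)
    nw <- length(enc) - total_w + 1L
    sc <- numeric(nw)
    bad <- logical(nw)
    idx <- seq_len(nw)
    for (j in seq_len(w1)) {
      e <- enc[idx + j - 1L]
      bad <- bad | is.na(e)
      e[is.na(e)] <- 1L
      sc <- sc + lo[cbind(e, j)]
    }
    for (j in seq_len(w2)) {
      e <- enc[idx + w1 + sp + j - 1L]
      bad <- bad | is.na(e)
      e[is.na(e)] <- 1L
      sc <- sc + lo[cbind(e, w1 + j)]
    }
    pv <- pssm_pvalue_lookup(pssm, sc)
    keep <- which(!bad & sc > 0 & pv <= config$p_max)
    if (length(keep) == 0) next
    # map window offsets back to genomic coordinates
    if (wn$strand == "+") {
      gs <- wn$win_start + keep - 1L
      ge <- gs + total_w - 1L
    } else {
      ge <- wn$win_end - keep + 1L
      gs <- ge - total_w + 1L
    }
    hits[[length(hits) + 1L]] <- tibble(
      motif = config$motif_name, replicon = wn$replicon, strand = wn$strand,
      start = gs, end = ge, score = sc[keep], pvalue = pv[keep],
      gene_id = wn$gene_id
    )
  }
  out <- if (length(hits)) list_rbind(hits) else {
    tibble(motif = character(), replicon = character(), strand = character(),
           start = integer(), end = integer(), score = numeric(),
           pvalue = numeric(), gene_id = character())
  }
  # no overlap with any annotated gene
  if (nrow(out)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      g <- genes[genes$replicon == out$replicon[i], , drop = FALSE]
      !any(out$start[i] <= g$end & g$start <= out$end[i])
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  arrange(out, .data$replicon, .data$start, .data$strand)
}

#' Correlate binding sites with TSS positions
#'
#' Categorises each site by the offset from its 3' end to the nearest
#' same-strand downstream TSS: within `overlap_offsets` nt upstream of a TSS
#' the site overlaps the -35 promoter element (`"-35-overlap"`); beyond that
#' it is `"farther-upstream"`; closer than the window, downstream of all TSS,
#' or without a same-strand TSS it is `"downstream/none"`.
#'
#' @param sites Tibble with `replicon`, `strand`, `start`, `end`.
#' @param classified Classified TSS tibble.
#' @param overlap_offsets Length-2 vector, offsets (nt) counted as -35
#'   overlap.
#' @return `sites` with `offset_to_tss`, `nearest_tss`, `category`; category
#'   counts as attribute `"category_counts"`.
#' @export
correlate_tfbs_with_tss <- function(sites, classified,
                                    overlap_offsets = c(22L, 25L)) {
  n <- nrow(sites)
  offset <- rep(NA_integer_, n)
  nearest <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    t <- classified[classified$replicon == sites$replicon[i] &
                      classified$strand == sites$strand[i], , drop = FALSE]
    if (nrow(t) == 0) next
    site3 <- if (sites$strand[i] == "+") sites$end[i] else sites$start[i]
    d <- if (sites$strand[i] == "+") t$tss_pos - site3 else site3 - t$tss_pos
    up <- which(d > 0)
    if (length(up) == 0) next
    j <- up[which.min(d[up])]
    offset[i] <- d[j]
    nearest[i] <- if ("id" %in% names(t)) t$id[j] else as.character(t$tss_pos[j])
  }
  category <- dplyr::case_when(
    !is.na(offset) & offset >= overlap_offsets[1] &
      offset <= overlap_offsets[2] ~ "-35-overlap",
    !is.na(offset) & offset > overlap_offsets[2] ~ "farther-upstream",
    TRUE ~ "downstream/none"
  )
  out <- sites
  out$offset_to_tss <- offset
  out$nearest_tss <- nearest
  out$category <- category
  attr(out, "category_counts") <- count(out, .data$category)
  out
}

#' Extract upstream sequences of high-coverage, promoter-less mRNA TSS
#'
#' For every mTSS/lmTSS with read coverage of at least `min_coverage` and no
#' promoter assignment, returns the `window`-nt same-strand sequence ending
#' 1 nt upstream of the TSS — the input set for external de novo motif
#' discovery (e.g. MEME with `-dna -mod anr -minw 18 -maxw 40 -minsites 10`).
#' Windows truncated by replicon edges are skipped with a warning.
#'
#' @param classified Classified TSS tibble.
#' @param promoter_hits Promoter-hit tibble (any sigma factors bound
#'   together) or `NULL`.
#' @param genome A `tss_genome`.
#' @param min_coverage Minimum TSS read count.
#' @param window Window width (nt).
#' @return Tibble `tss_id`, `replicon`, `strand`, `start`, `end`, `seq`.
#' @export
extract_unassigned_upstream <- function(classified, promoter_hits, genome,
                                        min_coverage = 300L, window = 40L) {
  assigned <- if (!is.null(promoter_hits)) {
    unique(promoter_hits$tss_id[!is.na(promoter_hits$tss_id)])
  } else character()
  cand <- classified[classified$tss_class %in% c("mTSS", "lmTSS") &
                       classified$read_count >= min_coverage &
                       !(classified$id %in% assigned), , drop = FALSE]
  lens <- replicon_lengths(genome)
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- cand$tss_pos[i]
    st <- cand$strand[i]
    L <- lens[[cand$replicon[i]]]
    if (st == "+") {
      s <- p - window; e <- p - 1L
    } else {
      s <- p + 1L; e <- p + window
    }
    if (s < 1L || e > L) {
      n_skipped <- n_skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- tibble(
      tss_id = cand$id[i], replicon = cand$replicon[i], strand = st,
      start = s, end = e,
      seq = genome_seq(genome, cand$replicon[i], s, e, st)
    )
  }
  if (n_skipped > 0) {
    warn(sprintf("%d window(s) truncated by replicon edges were skipped",
                 n_skipped))
  }
  if (length(out)) list_rbind(out) else {
    tibble(tss_id = character(), replicon = character(), strand = character(),
           start = integer(), end = integer(), seq = character())
  }
}

#' Write an upstream-sequence set as FASTA
#'
#' @param upstream Output of [extract_unassigned_upstream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_upstream_fasta <- function(upstream, path) {
  ss <- Biostrings::DNAStringSet(setNames(upstream$seq, upstream$tss_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
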