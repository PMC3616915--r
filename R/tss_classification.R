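# Minimal transcription unit (MTU) construction and hierarchical TSS
# classification into the six genomic-context categories, plus merging of
# antisense/intergenic TSS contigs into asRNA/sRNA features and summaries.

#' MTU configuration
#'
#' The minimal transcription unit of a gene is its CDS extended by fixed
#' minimal UTR margins: 14 nt of 5'-UTR (the minimal ribosome binding site)
#' and 20 nt of 3'-UTR (a minimal terminator hairpin). A 40-nt promoter
#' region lies immediately upstream of the MTU, so the "mRNA window" probed
#' by mTSS classification spans the 54 nt upstream of the start codon. TSS
#' further than 300 nt upstream of a start codon are no longer considered
#' putative mRNA TSS.
#'
#' @param utr5_len Minimal 5'-UTR length (nt).
#' @param utr3_len Minimal 3'-UTR length (nt).
#' @param promoter_len Promoter-region length (nt).
#' @param pm_max_dist Maximum TSS-to-start-codon distance for pmTSS (nt).
#' @return A list of class `mtu_config`; `m_window` is derived as
#'   `utr5_len + promoter_len`.
#' @export
mtu_config <- function(utr5_len = 14L, utr3_len = 20L, promoter_len = 40L,
                       pm_max_dist = 300L) {
  stopifnot(utr5_len > 0, utr3_len > 0, promoter_len > 0, pm_max_dist > 0)
  structure(list(utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 promoter_len = as.integer(promoter_len),
                 m_window = as.integer(utr5_len + promoter_len),
                 pm_max_dist = as.integer(pm_max_dist)),
            class = "mtu_config")
}

#' Build minimal transcription units for annotated genes
#'
#' For each gene the MTU span covers the CDS plus the fixed UTR margins in
#' transcription direction; the promoter window is the `promoter_len`-nt
#' block immediately upstream of the MTU, and the mRNA window (`win_start`,
#' `win_end`) is the `m_window` nt directly upstream of the start codon.
#' Windows are truncated at replicon ends and flagged.
#'
#' @param genes Gene tibble (see [read_genes_gff3()]).
#' @param genome A `tss_genome`.
#' @param config An [mtu_config()].
#' @return Tibble with one MTU per gene.
#' @export
build_mtus <- function(genes, genome, config = mtu_config()) {
  lens <- replicon_lengths(genome)
  L <- unname(lens[genes$replicon])
  plus <- genes$strand == "+"
  raw_span_start <- if_else(plus, genes$start - config$utr5_len,
                            genes$start - config$utr3_len)
  raw_span_end <- if_else(plus, genes$end + config$utr3_len,
                          genes$end + config$utr5_len)
  raw_prom_start <- if_else(plus, genes$start - config$m_window,
                            genes$end + config$utr5_len + 1L)
  raw_prom_end <- if_else(plus, genes$start - config$utr5_len - 1L,
                          genes$end + config$m_window)
  raw_win_start <- if_else(plus, genes$start - config$m_window, genes$end + 1L)
  raw_win_end <- if_else(plus, genes$start - 1L, genes$end + config$m_window)
  clamp <- function(x) pmin(pmax(x, 1L), L)
  tibble(
    gene_id = genes$gene_id,
    replicon = genes$replicon,
    strand = genes$strand,
    start_codon_pos = genes$start_codon_pos,
    stop_codon_pos = genes$stop_codon_pos,
    gene_start = genes$start,
    gene_end = genes$end,
    span_start = clamp(raw_span_start),
    span_end = clamp(raw_span_end),
    prom_start = clamp(raw_prom_start),
    prom_end = clamp(raw_prom_end),
    win_start = clamp(raw_win_start),
    win_end = clamp(raw_win_end),
    truncated = raw_span_start < 1L | raw_span_end > L |
      raw_prom_start < 1L | raw_prom_end > L
  )
}

# genome triplet at the TSS, read in transcription direction
tss_triplet <- function(genome, replicon, pos, strand) {
  L <- nchar(genome$replicons[[replicon]])
  if (strand == "+") {
    if (pos + 2L > L) return(NA_character_)
    genome_seq(genome, replicon, pos, pos + 2L, "+")
  } else {
    if (pos - 2L < 1L) return(NA_character_)
    genome_seq(genome, replicon, pos - 2L, pos, "-")
  }
}

overlaps <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2

#' Hierarchically classify TSS contigs
#'
#' Applies the six class rules in fixed precedence
#' `lmTSS > mTSS > seTSS > asTSS > pmTSS > sTSS`:
#' \describe{
#'   \item{lmTSS}{the TSS coincides with the first nucleotide of a
#'     same-strand ATG start codon (leaderless transcript; 5'-UTR length 0).}
#'   \item{mTSS}{the contig overlaps, in sense, the 54-nt window upstream of
#'     a start codon; the target is the gene with the nearest downstream
#'     start codon among qualifying windows. A TSS whose contig lies wholly
#'     upstream of a gene's promoter region also becomes an mTSS when a
#'     supplied leader contig for that gene starts at or upstream of the TSS.}
#'   \item{seTSS}{the TSS position falls inside a same-strand MTU.}
#'   \item{asTSS}{the contig overlaps an MTU in antisense orientation.}
#'   \item{pmTSS}{the contig overlaps no MTU on either strand and the TSS is
#'     at most `pm_max_dist` nt upstream, in sense, of a start codon.}
#'   \item{sTSS}{none of the above (trans-encoded sRNA in an intergenic
#'     region).}
#' }
#'
#' @param tss TSS contig tibble from [call_tss()] / [merge_tss()].
#' @param mtus MTU tibble from [build_mtus()].
#' @param genome A `tss_genome`.
#' @param leaders Optional tibble of prior mRNA-leader contigs with columns
#'   `replicon`, `strand`, `start`, `end` and `gene_id` (the MTU they belong
#'   to).
#' @param config An [mtu_config()].
#' @return `tss` with added columns `tss_class`, `target_feature`,
#'   `utr5_len` and `evidence`.
#' @export
classify_tss <- function(tss, mtus, genome, leaders = NULL,
                         config = mtu_config()) {
  validate_intervals(tss, genome, what = "TSS")
  n <- nrow(tss)
  cls <- character(n)
  target <- rep(NA_character_, n)
  utr5 <- rep(NA_integer_, n)
  evidence <- character(n)

  mtu_by_rep <- split(mtus, mtus$replicon)
  lead_by_rep <- if (!is.null(leaders)) split(leaders, leaders$replicon)

  for (i in seq_len(n)) {
    rep_id <- tss$replicon[i]
    st <- tss$strand[i]
    p <- tss$tss_pos[i]
    c1 <- min(tss$tss_pos[i], tss$end_pos[i])
    c2 <- max(tss$tss_pos[i], tss$end_pos[i])
    m <- mtu_by_rep[[rep_id]]
    if (is.null(m)) m <- mtus[0, ]
    same <- m[m$strand == st, , drop = FALSE]
    anti <- m[m$strand != st, , drop = FALSE]

    # (1) leaderless: TSS at the first nucleotide of an ATG start codon
    at_start <- same$start_codon_pos == p
    if (any(at_start) && identical(tss_triplet(genome, rep_id, p, st), "ATG")) {
      cls[i] <- "lmTSS"
      target[i] <- same$gene_id[which(at_start)[1]]
      utr5[i] <- 0L
      evidence[i] <- "tss_at_ATG"
      next
    }

    # (2) mRNA window overlap in sense
    hit <- overlaps(c1, c2, same$win_start, same$win_end)
    if (any(hit)) {
      cand <- same[hit, , drop = FALSE]
      d <- if (st == "+") cand$start_codon_pos - p else p - cand$start_codon_pos
      cand <- cand[d > 0, , drop = FALSE]
      d <- d[d > 0]
      if (length(d) > 0) {
        j <- which.min(d)
        cls[i] <- "mTSS"
        target[i] <- cand$gene_id[j]
        utr5[i] <- as.integer(d[j])
        evidence[i] <- "window_overlap"
        next
      }
    }
    # (2b) leader-contig rescue: contig wholly upstream of a promoter region,
    # with a prior leader for that MTU starting at or upstream of the TSS
    if (!is.null(leaders)) {
      ld <- lead_by_rep[[rep_id]]
      if (!is.null(ld) && nrow(same) > 0) {
        ld <- ld[ld$strand == st, , drop = FALSE]
        done <- FALSE
        for (k in seq_len(nrow(same))) {
          g <- same[k, ]
          upstream_of_prom <- if (st == "+") c2 < g$prom_start
                              else c1 > g$prom_end
          if (!upstream_of_prom) next
          lg <- ld[ld$gene_id == g$gene_id, , drop = FALSE]
          if (nrow(lg) == 0) next
          l5 <- if (st == "+") lg$start else lg$end
          starts_upstream <- if (st == "+") any(l5 <= p) else any(l5 >= p)
          if (starts_upstream) {
            cls[i] <- "mTSS"
            target[i] <- g$gene_id
            utr5[i] <- as.integer(
              if (st == "+") g$start_codon_pos - p else p - g$start_codon_pos
            )
            evidence[i] <- "leader_contig"
            done <- TRUE
            break
          }
        }
        if (done) next
      }
    }

    # (3) sense-internal: TSS point within a same-strand MTU
    inside <- same$span_start <= p & p <= same$span_end
    if (any(inside)) {
      cls[i] <- "seTSS"
      target[i] <- same$gene_id[which(inside)[1]]
      evidence[i] <- "tss_in_mtu"
      next
    }

    # (4) antisense: contig overlaps an MTU on the other strand
    as_hit <- overlaps(c1, c2, anti$span_start, anti$span_end)
    if (any(as_hit)) {
      ov <- pmin(c2, anti$span_end[as_hit]) - pmax(c1, anti$span_start[as_hit])
      cls[i] <- "asTSS"
      target[i] <- anti$gene_id[as_hit][which.max(ov)]
      evidence[i] <- "antisense_overlap"
      next
    }

    # (5)/(6): contig overlaps no MTU on either strand here (sense-MTU
    # overlap without containing the TSS point falls through to sTSS)
    sense_contig_overlap <- any(overlaps(c1, c2, same$span_start, same$span_end))
    d <- if (st == "+") same$start_codon_pos - p else p - same$start_codon_pos
    d <- d[d > 0]
    nearest <- if (length(d)) min(d) else Inf
    if (!sense_contig_overlap && nearest <= config$pm_max_dist) {
      cand <- same[(if (st == "+") same$start_codon_pos - p
                    else p - same$start_codon_pos) == nearest, , drop = FALSE]
      cls[i] <- "pmTSS"
      target[i] <- cand$gene_id[1]
      evidence[i] <- "within_300nt_upstream"
      next
    }
    cls[i] <- "sTSS"
    evidence[i] <- "intergenic"
    target[i] <- igr_id(mtu_by_rep[[rep_id]], rep_id, p)
  }
  out <- tss
  out$tss_class <- cls
  out$target_feature <- target
  out$utr5_len <- utr5
  out$evidence <- evidence
  out
}

# intergenic-region id: the flanking annotated genes by genomic position
igr_id <- function(mtus_rep, rep_id, pos) {
  if (is.null(mtus_rep) || nrow(mtus_rep) == 0) {
    return(paste0("IGR:", rep_id, ":.|."))
  }
  left <- mtus_rep[mtus_rep$gene_end < pos, , drop = FALSE]
  right <- mtus_rep[mtus_rep$gene_start > pos, , drop = FALSE]
  lg <- if (nrow(left)) left$gene_id[which.max(left$gene_end)] else "."
  rg <- if (nrow(right)) right$gene_id[which.min(right$gene_start)] else "."
  paste0("IGR:", rep_id, ":", lg, "|", rg)
}

#' Merge classified TSS contigs into sRNA and asRNA features
#'
#' Overlapping same-strand sTSS contigs form one trans-encoded sRNA;
#' overlapping asTSS contigs sharing a target gene form one cis-encoded
#' antisense RNA. asRNAs are annotated with the region of the target they
#' overlap (5'-UTR, CDS or 3'-UTR, using the MTU margins; the region with
#' the largest overlap wins, ties resolved 5'-UTR > CDS > 3'-UTR). Names are
#' assigned in genome order per replicon (`<prefix>_sRNA_n`,
#' `<prefix>_asRNA_n`).
#'
#' @param classified Output of [classify_tss()].
#' @param mtus MTU tibble (for asRNA region annotation).
#' @param config An [mtu_config()].
#' @param prefixes Optional replicon-to-prefix map as in [merge_tss()].
#' @return Tibble: `kind`, `id`, `replicon`, `strand`, `start`, `end`,
#'   `member_tss` (list), `n_members`, `target`, `overlap_region`.
#' @export
merge_rna_features <- function(classified, mtus, config = mtu_config(),
                               prefixes = NULL) {
  mk <- function(df, kind) {
    if (nrow(df) == 0) return(NULL)
    df$c1 <- pmin(df$tss_pos, df$end_pos)
    df$c2 <- pmax(df$tss_pos, df$end_pos)
    grp_keys <- if (kind == "asRNA") {
      paste(df$replicon, df$strand, df$target_feature)
    } else paste(df$replicon, df$strand)
    out <- list()
    for (key in unique(grp_keys)) {
      sub <- df[grp_keys == key, , drop = FALSE]
      sub <- sub[order(sub$c1), , drop = FALSE]
      # overlap chaining: new cluster when the next contig starts after the
      # running maximum end
      run_end <- cummax_shift(sub$c1, sub$c2)
      cl <- cumsum(c(TRUE, sub$c1[-1] > run_end))
      for (k in unique(cl)) {
        mem <- sub[cl == k, , drop = FALSE]
        out[[length(out) + 1L]] <- tibble(
          kind = kind,
          replicon = mem$replicon[1],
          strand = mem$strand[1],
          start = min(mem$c1),
          end = max(mem$c2),
          member_tss = list(mem$id),
          n_members = nrow(mem),
          target = if (kind == "asRNA") mem$target_feature[1]
                   else mem$target_feature[1]
        )
      }
    }
    list_rbind(out)
  }
  s <- mk(classified[classified$tss_class == "sTSS", , drop = FALSE], "sRNA")
  a <- mk(classified[classified$tss_class == "asTSS", , drop = FALSE], "asRNA")
  feats <- bind_rows(
    s %||% tibble(),
    a %||% tibble()
  )
  if (nrow(feats) == 0) {
    return(tibble(kind = character(), id = character(), replicon = character(),
                  strand = character(), start = integer(), end = integer(),
                  member_tss = list(), n_members = integer(),
                  target = character(), overlap_region = character()))
  }
  feats$overlap_region <- NA_character_
  is_as <- feats$kind == "asRNA"
  if (any(is_as)) {
    for (w in which(is_as)) {
      g <- mtus[match(feats$target[w], mtus$gene_id), ]
      if (is.na(g$gene_id[1])) next
      feats$overlap_region[w] <- asrna_region(
        feats$start[w], feats$end[w], g, config
      )
    }
  }
  feats <- feats |> arrange(.data$replicon, .data$start, .data$strand)
  feats |>
    group_by(.data$kind, .data$replicon) |>
    mutate(id = sprintf(
      "%s_%s_%d",
      if (!is.null(prefixes)) prefixes[[first(.data$replicon)]]
      else first(.data$replicon),
      first(.data$kind), row_number()
    )) |>
    ungroup() |>
    select("kind", "id", "replicon", "strand", "start", "end", "member_tss",
           "n_members", "target", "overlap_region")
}

cummax_shift <- function(c1, c2) {
  if (length(c2) <= 1) return(integer(0))
  cummax(c2)[-length(c2)]
}

asrna_region <- function(f1, f2, g, config) {
  if (g$strand == "+") {
    utr5 <- c(g$gene_start - config$utr5_len, g$gene_start - 1L)
    cds <- c(g$gene_start, g$gene_end)
    utr3 <- c(g$gene_end + 1L, g$gene_end + config$utr3_len)
  } else {
    utr5 <- c(g$gene_end + 1L, g$gene_end + config$utr5_len)
    cds <- c(g$gene_start, g$gene_end)
    utr3 <- c(g$gene_start - config$utr3_len, g$gene_start - 1L)
  }
  ov <- function(iv) max(0L, min(f2, iv[2]) - max(f1, iv[1]) + 1L)
  v <- c(`5'-UTR` = ov(utr5), CDS = ov(cds), `3'-UTR` = ov(utr3))
  if (all(v == 0)) return(NA_character_)
  names(v)[which.max(v)]
}

#' Summarize a TSS classification
#'
#' Computes per-class counts, the per-gene TSS-count histogram (1/2/3/4/>4),
#' the per-intergenic-region sRNA count histogram, the nucleotide composition
#' of the first three transcribed positions of mTSS/lmTSS transcripts, the
#' 5'-UTR length distribution of mTSS, per-replicon and per-strand
#' proportions, and (when operons are supplied) the operons whose lead gene
#' has an mTSS or lmTSS.
#'
#' @param classified Output of [classify_tss()].
#' @param features Output of [merge_rna_features()].
#' @param genome A `tss_genome`.
#' @param operons Optional tibble with `operon_id`, `gene_id`, `position`
#'   (1 = transcriptional start gene).
#' @return A list of class `tss_summary`.
#' @export
summarize_classification <- function(classified, features, genome,
                                     operons = NULL) {
  class_levels <- c("mTSS", "lmTSS", "pmTSS", "seTSS", "asTSS", "sTSS")
  class_counts <- classified |>
    count(tss_class = factor(.data$tss_class, levels = class_levels),
          .drop = FALSE) |>
    mutate(tss_class = as.character(.data$tss_class))

  histo <- function(x) {
    b <- cut(x, c(0.5, 1.5, 2.5, 3.5, 4.5, Inf),
             labels = c("1", "2", "3", "4", ">4"))
    tibble(n_tss = levels(b),
           n_features = as.integer(table(b)))
  }
  gene_tss <- classified |>
    filter(.data$tss_class %in% c("mTSS", "lmTSS")) |>
    count(.data$target_feature)
  per_gene_hist <- histo(gene_tss$n)

  igr_srna <- features |>
    filter(.data$kind == "sRNA", !is.na(.data$target)) |>
    count(.data$target)
  per_igr_hist <- histo(igr_srna$n)

  m <- classified[classified$tss_class %in% c("mTSS", "lmTSS"), , drop = FALSE]
  comp <- NULL
  if (nrow(m) > 0) {
    tri <- vapply(seq_len(nrow(m)), function(i) {
      tr <- tss_triplet(genome, m$replicon[i], m$tss_pos[i], m$strand[i])
      if (is.null(tr) || is.na(tr)) "NNN" else tr
    }, character(1))
    comp <- list_rbind(lapply(1:3, function(k) {
      nt <- substr(tri, k, k)
      tibble(position = paste0("+", k),
             nucleotide = c("A", "C", "G", "T"),
             fraction = as.numeric(
               table(factor(nt, levels = c("A", "C", "G", "T")))
             ) / length(nt))
    }))
  }

  utr5 <- classified$utr5_len[classified$tss_class == "mTSS"]
  operon_report <- NULL
  if (!is.null(operons)) {
    leads <- operons[operons$position == 1, , drop = FALSE]
    with_tss <- leads$gene_id %in%
      classified$target_feature[classified$tss_class %in% c("mTSS", "lmTSS")]
    operon_report <- tibble(operon_id = leads$operon_id,
                            lead_gene = leads$gene_id,
                            lead_gene_has_tss = with_tss)
  }

  structure(list(
    class_counts = class_counts,
    n_tss = nrow(classified),
    per_gene_hist = per_gene_hist,
    per_igr_hist = per_igr_hist,
    plus_site_composition = comp,
    utr5_lengths = utr5,
    utr5_mean = if (length(utr5)) mean(utr5) else NA_real_,
    per_replicon = count(classified, .data$replicon, .data$tss_class),
    per_strand = count(classified, .data$strand),
    operon_report = operon_report
  ), class = "tss_summary")
}

#' @export
print.tss_summary <- function(x, ...) {
  cat("<tss_summary> ", x$n_tss, " TSS\n", sep = "")
  print(x$class_counts)
  cat("mean mTSS 5'-UTR length:",
      round(x$utr5_mean, 1), "nt\n")
  invisible(x)
}

#' @describeIn summarize_classification Per-class counts as a tibble.
#' @param x A `tss_summary`.
#' @param ... Unused.
#' @method tidy tss_summary
#' @export
tidy.tss_summary <- function(x, ...) x$class_counts

#' @describeIn summarize_classification One-row overview.
#' @method glance tss_summary
#' @export
glance.tss_summary <- function(x, ...) {
  wide <- setNames(as.list(x$class_counts$n), x$class_counts$tss_class)
  as_tibble(c(list(n_tss = x$n_tss), wide,
              list(utr5_mean = x$utr5_mean)))
}
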