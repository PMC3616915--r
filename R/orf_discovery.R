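# TSS-guided ORF discovery: leaderless and Shine-Dalgarno candidates,
# ribosome-binding-site free energy against the 16S rRNA 3' tail, and
# new/reannotated status against the existing annotation.

#' RBS / ORF-discovery configuration
#'
#' The ribosome binding site is modelled as the energetically most favourable
#' ungapped hybridisation of the transcript leader with the 3' tail of the
#' 16S rRNA; a leader qualifies as an RBS when its minimum duplex free energy
#' is at most -3.4535 kcal/mol. Leaders must be at least 14 nt (the minimal
#' RBS length of the MTU model).
#'
#' @param anti_sd_tail 3' tail of the 16S rRNA, written 5' to 3' as RNA
#'   (no universal cross-species default; required).
#' @param energy_cutoff RBS free-energy cutoff (kcal/mol, negative).
#' @param min_leader_len Minimal leader length (nt).
#' @param min_helix_len Minimal contiguous helix length (base pairs).
#' @param min_orf_len Minimal ORF length, start to stop codon inclusive (nt).
#' @param max_scan Downstream search window from the TSS (nt).
#' @param sd_start_codons Start codons admitted for Shine-Dalgarno ORFs
#'   (leaderless ORFs are always ATG-only).
#' @return A list of class `rbs_config`.
#' @export
rbs_config <- function(anti_sd_tail, energy_cutoff = -3.4535,
                       min_leader_len = 14L, min_helix_len = 3L,
                       min_orf_len = 60L, max_scan = 3000L,
                       sd_start_codons = c("ATG", "GTG", "TTG")) {
  anti_sd_tail <- toupper(gsub("T", "U", anti_sd_tail))
  if (nchar(anti_sd_tail) < 8 || nchar(anti_sd_tail) > 20) {
    abort("anti_sd_tail must be 8-20 nt")
  }
  if (grepl("[^ACGU]", anti_sd_tail)) abort("anti_sd_tail must be RNA (ACGU)")
  if (energy_cutoff >= 0) abort("energy_cutoff must be negative")
  structure(list(anti_sd_tail = anti_sd_tail,
                 energy_cutoff = energy_cutoff,
                 min_leader_len = as.integer(min_leader_len),
                 min_helix_len = as.integer(min_helix_len),
                 min_orf_len = as.integer(min_orf_len),
                 max_scan = as.integer(max_scan),
                 sd_start_codons = toupper(sd_start_codons)),
            class = "rbs_config")
}

# --- nearest-neighbour RNA:RNA duplex energetics -------------------------
#
# Watson-Crick stack free energies (kcal/mol, 37 C) follow the standard
# nearest-neighbour set for RNA; any stack involving a G:U wobble pair is
# scored with a single flat value. A helix pays one duplex-initiation
# penalty plus the standard terminal penalty for each helix end closed by
# an A:U or G:U pair. Bulges, loops and dangling ends are not modelled.

RNA_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")
GU_STACK <- -0.50
DUPLEX_INIT <- 4.09
TERMINAL_AU <- 0.45
WEAK_PAIRS <- c("AU", "UA", "GU", "UG")

rna_stack_table <- local({
  E <- matrix(NA_real_, 6, 6, dimnames = list(RNA_PAIRS, RNA_PAIRS))
  set <- function(p1, p2, v) {
    E[p1, p2] <<- v
    # the same physical stack read from the other strand
    flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
    E[flip(p2), flip(p1)] <<- v
  }
  set("AU", "AU", -0.93); set("AU", "UA", -1.10); set("UA", "AU", -1.33)
  set("CG", "UA", -2.08); set("CG", "AU", -2.11); set("GC", "UA", -2.24)
  set("GC", "AU", -2.35); set("CG", "GC", -2.36); set("GC", "GC", -3.26)
  set("GC", "CG", -3.42)
  E[is.na(E)] <- GU_STACK   # every G:U-containing stack
  E
})

#' Minimum RBS hybridisation free energy of a leader sequence
#'
#' Considers every ungapped antiparallel alignment of the leader (converted
#' to RNA) against the anti-SD tail. Within an alignment, every contiguous
#' stretch of Watson-Crick or G:U pairs of at least `min_helix_len` base
#' pairs is a candidate helix, scored as the sum of its nearest-neighbour
#' stack energies plus one duplex-initiation term. The minimum over all
#' alignments and helices is returned; 0 when no qualifying helix exists.
#'
#' @param leader_seq Leader sequence (DNA or RNA, 5' to 3').
#' @param config An [rbs_config()].
#' @return Free energy in kcal/mol (<= 0).
#' @export
rbs_free_energy <- function(leader_seq, config) {
  leader <- strsplit(toupper(gsub("T", "U", leader_seq)), NULL)[[1]]
  if (length(leader) < config$min_leader_len) {
    abort(sprintf("leader shorter than min_leader_len (%d nt)",
                  config$min_leader_len))
  }
  tail_rev <- rev(strsplit(config$anti_sd_tail, NULL)[[1]])
  nl <- length(leader)
  nt_ <- length(tail_rev)
  minh <- config$min_helix_len
  rna <- c("A", "C", "G", "U")
  lidx <- match(leader, rna)
  tidx <- match(tail_rev, rna)
  # pair id (0 = no pair) for every (base, base) combination
  pair_id <- matrix(0L, 4, 4, dimnames = list(rna, rna))
  for (k in seq_along(RNA_PAIRS)) {
    pair_id[substr(RNA_PAIRS[k], 1, 1), substr(RNA_PAIRS[k], 2, 2)] <- k
  }
  is_weak <- RNA_PAIRS %in% WEAK_PAIRS

  # one row per alignment offset: leader position i pairs tail_rev position
  # t where i = offset + t
  noff <- nl + nt_ - 1L
  offs <- seq_len(noff) - nt_
  P <- matrix(0L, noff, nt_)
  for (t in seq_len(nt_)) {
    i <- offs + t
    ok <- i >= 1L & i <= nl
    P[ok, t] <- pair_id[cbind(lidx[i[ok]], tidx[t])]
  }
  # stack energies between consecutive paired positions
  S <- matrix(0, noff, max(nt_ - 1L, 1L))
  for (t in seq_len(nt_ - 1L)) {
    both <- P[, t] > 0L & P[, t + 1L] > 0L
    if (any(both)) {
      S[both, t] <- rna_stack_table[cbind(P[both, t], P[both, t + 1L])]
    }
  }
  row_cumsum <- function(m) {
    out <- matrix(0, nrow(m), ncol(m) + 1L)
    for (k in seq_len(ncol(m))) out[, k + 1L] <- out[, k] + m[, k]
    out
  }
  cumP <- row_cumsum(P > 0L)
  cumS <- row_cumsum(S)
  best <- 0
  # every contiguous fully-paired window of >= minh pairs is a helix
  for (a in seq_len(nt_ - minh + 1L)) {
    for (b in seq(a + minh - 1L, nt_)) {
      full <- (cumP[, b + 1L] - cumP[, a]) == (b - a + 1L)
      if (!any(full)) next
      e <- (cumS[full, b] - cumS[full, a]) + DUPLEX_INIT +
        TERMINAL_AU * (is_weak[P[full, a]] + is_weak[P[full, b]])
      m <- min(e)
      if (m < best) best <- m
    }
  }
  best
}

#' Enumerate candidate ORFs on a TSS transcript
#'
#' Scans the same strand downstream of the TSS (at most `max_scan` nt) for
#' ORFs — a start codon with an in-frame stop within the window and a length
#' of at least `min_orf_len` nt. A candidate starting exactly at the TSS with
#' an ATG is a leaderless candidate; one whose start codon lies at least
#' `min_leader_len` nt downstream of the TSS is a Shine-Dalgarno candidate
#' carrying its leader sequence (TSS up to the base before the start codon).
#' Starts 1 to `min_leader_len - 1` nt downstream are not candidates.
#'
#' @param tss One row of a TSS tibble (`replicon`, `strand`, `tss_pos`, and
#'   `id` if available).
#' @param genome A `tss_genome`.
#' @param config An [rbs_config()].
#' @return Tibble of candidates with genomic coordinates, `kind`
#'   (`"leaderless"`/`"sd"`), `leader_seq`, `leader_len`.
#' @export
enumerate_candidate_orfs <- function(tss, genome, config) {
  rep_id <- tss$replicon[1]
  st <- tss$strand[1]
  p <- tss$tss_pos[1]
  L <- nchar(genome$replicons[[rep_id]])
  span <- if (st == "+") c(p, min(L, p + config$max_scan - 1L))
          else c(max(1L, p - config$max_scan + 1L), p)
  txt <- genome_seq(genome, rep_id, span[1], span[2], st)  # 5'->3' transcript
  n <- nchar(txt)
  starts_all <- sort(unique(unlist(lapply(
    unique(c("ATG", config$sd_start_codons)),
    function(cd) {
      h <- gregexpr(cd, txt, fixed = TRUE)[[1]]
      as.integer(h[h > 0])
    }
  ))))
  stops <- sort(unique(unlist(lapply(c("TAA", "TAG", "TGA"), function(cd) {
    h <- gregexpr(cd, txt, fixed = TRUE)[[1]]
    as.integer(h[h > 0])
  }))))
  out <- list()
  for (s0 in starts_all) {
    codon <- substr(txt, s0, s0 + 2L)
    offset <- s0 - 1L                     # leader length in nt
    kind <- if (offset == 0L && codon == "ATG") "leaderless"
            else if (offset >= config$min_leader_len &&
                     codon %in% config$sd_start_codons) "sd"
            else next
    inframe <- stops[stops > s0 & (stops - s0) %% 3L == 0L]
    if (length(inframe) == 0) next       # no in-frame stop inside the window
    e0 <- min(inframe) + 2L
    if (e0 - s0 + 1L < config$min_orf_len) next
    # map transcript offsets back to genomic coordinates
    if (st == "+") {
      g_start <- span[1] + s0 - 1L
      g_stop <- span[1] + e0 - 1L
      gs <- g_start; ge <- g_stop
    } else {
      g_start <- span[2] - s0 + 1L
      g_stop <- span[2] - e0 + 1L
      gs <- g_stop; ge <- g_start
    }
    out[[length(out) + 1L]] <- tibble(
      tss_id = if ("id" %in% names(tss)) tss$id[1] else NA_character_,
      replicon = rep_id, strand = st,
      start = gs, end = ge,
      start_codon_pos = g_start, stop_codon_pos = g_stop,
      frame = (s0 - 1L) %% 3L,
      kind = kind,
      leader_len = offset,
      leader_seq = if (kind == "sd") substr(txt, 1L, offset) else NA_character_
    )
  }
  if (length(out)) list_rbind(out) else {
    tibble(tss_id = character(), replicon = character(), strand = character(),
           start = integer(), end = integer(), start_codon_pos = integer(),
           stop_codon_pos = integer(), frame = integer(), kind = character(),
           leader_len = integer(), leader_seq = character())
  }
}

#' Classify candidate ORFs against the annotation
#'
#' Shine-Dalgarno candidates first require an RBS (leader free energy at most
#' the cutoff); a candidate sharing its start or stop codon position with an
#' annotated gene is `reannotated`; one overlapping no annotated gene by more
#' than a start/stop codon (3 nt) is `new` and named `<prefix>_ORF_n` in
#' genome order per replicon; the rest are `discarded`. An optional
#' protein-homology table acts as an external keep-filter on new ORFs.
#'
#' @param candidates Output of [enumerate_candidate_orfs()] (rows for one or
#'   many TSS).
#' @param genes Annotated gene tibble.
#' @param config An [rbs_config()].
#' @param homology Optional tibble with columns `start_codon_pos`,
#'   `stop_codon_pos`, `strand`, `replicon` of candidates with accepted
#'   protein-homology support; when supplied, new ORFs without a matching row
#'   are discarded.
#' @param prefixes Optional replicon-to-prefix map.
#' @return `candidates` with `rbs_energy`, `status`, `name`.
#' @export
classify_orf <- function(candidates, genes, config, homology = NULL,
                         prefixes = NULL) {
  n <- nrow(candidates)
  rbs <- rep(NA_real_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    if (candidates$kind[i] == "sd") {
      rbs[i] <- rbs_free_energy(candidates$leader_seq[i], config)
      if (rbs[i] > config$energy_cutoff) {
        status[i] <- "discarded"
        next
      }
    }
    g_rep <- genes[genes$replicon == candidates$replicon[i], , drop = FALSE]
    same <- g_rep[g_rep$strand == candidates$strand[i], , drop = FALSE]
    shares <- any(same$start_codon_pos == candidates$start_codon_pos[i]) ||
      any(same$stop_codon_pos == candidates$stop_codon_pos[i])
    if (shares) {
      status[i] <- "reannotated"
      next
    }
    ov <- pmin(candidates$end[i], g_rep$end) -
      pmax(candidates$start[i], g_rep$start) + 1L
    status[i] <- if (all(ov <= 3L)) "new" else "discarded"
  }
  out <- candidates
  out$rbs_energy <- rbs
  out$status <- status
  if (!is.null(homology)) {
    key <- paste(out$replicon, out$strand, out$start_codon_pos,
                 out$stop_codon_pos)
    hkey <- paste(homology$replicon, homology$strand,
                  homology$start_codon_pos, homology$stop_codon_pos)
    out$status[out$status == "new" & !key %in% hkey] <- "discarded"
  }
  name_new_orfs(out, prefixes)
}

name_new_orfs <- function(out, prefixes = NULL) {
  out$name <- NA_character_
  new_rows <- which(out$status == "new")
  if (length(new_rows)) {
    ord <- new_rows[order(out$replicon[new_rows], out$start[new_rows])]
    per_rep <- stats::ave(seq_along(ord), out$replicon[ord], FUN = seq_along)
    out$name[ord] <- sprintf(
      "%s_ORF_%d",
      if (!is.null(prefixes)) unlist(prefixes[out$replicon[ord]])
      else out$replicon[ord],
      per_rep
    )
  }
  out
}

#' Discover ORFs for a set of classified TSS
#'
#' Runs [enumerate_candidate_orfs()] for every TSS and classifies the pooled
#' candidates, deduplicating identical ORFs reached from different TSS.
#'
#' @param tss Classified TSS tibble.
#' @param genome A `tss_genome`.
#' @param genes Annotated genes.
#' @param config An [rbs_config()].
#' @inheritParams classify_orf
#' @return ORF-call tibble.
#' @export
discover_orfs <- function(tss, genome, genes, config, homology = NULL,
                          prefixes = NULL) {
  cands <- list_rbind(lapply(seq_len(nrow(tss)), function(i) {
    enumerate_candidate_orfs(tss[i, ], genome, config)
  }))
  if (nrow(cands) == 0) {
    return(mutate(cands, rbs_energy = numeric(0), status = character(0),
                  name = character(0)))
  }
  # the same ORF reached from several TSS is judged per transcript (the
  # leaders differ); collapse to one row per ORF keeping the best outcome
  res <- classify_orf(cands, genes, config, homology)
  pri <- c(reannotated = 1L, new = 2L, discarded = 3L)
  res <- res |>
    arrange(.data$replicon, .data$strand, .data$start_codon_pos,
            .data$stop_codon_pos, pri[.data$status],
            .data$kind != "leaderless", .data$leader_len) |>
    distinct(.data$replicon, .data$strand, .data$start_codon_pos,
             .data$stop_codon_pos, .keep_all = TRUE)
  name_new_orfs(res, prefixes)
}
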