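# Independent brute-force oracles. These re-derive expected results by the
# most naive route available (explicit loops, union-find, exhaustive
# enumeration) and deliberately share no code with the implementation paths
# they check.

oracle_call_merge <- function(reads, config = tss_call_config()) {
  keep <- reads$length >= config$min_read_len &
    (!config$require_unique | reads$unique) &
    reads$mismatches_first3 <= config$max_mismatch_first3
  f <- reads[keep, , drop = FALSE]
  if (!"count" %in% names(f)) f$count <- 1L
  out <- list()
  for (rep_id in unique(f$replicon)) for (st in c("+", "-")) {
    sub <- f[f$replicon == rep_id & f$strand == st, , drop = FALSE]
    if (nrow(sub) == 0) next
    pos <- sort(unique(sub$five_prime_pos))
    cand <- t(vapply(pos, function(p) {
      r <- sub[sub$five_prime_pos == p, , drop = FALSE]
      ends <- if (st == "+") p + r$length - 1L else p - r$length + 1L
      c(p = p, n = sum(r$count),
        e = if (st == "+") max(ends) else min(ends))
    }, c(p = 0, n = 0, e = 0)))
    cand <- cand[cand[, "n"] >= config$min_reads_per_tss, , drop = FALSE]
    k <- nrow(cand)
    if (k == 0) next
    parent <- seq_len(k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (abs(cand[i, "p"] - cand[j, "p"]) < config$merge_distance_lt) {
        ri <- i; while (parent[ri] != ri) ri <- parent[ri]
        rj <- j; while (parent[rj] != rj) rj <- parent[rj]
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    root <- vapply(seq_len(k), function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }, integer(1))
    for (cl in unique(root)) {
      mem <- cand[root == cl, , drop = FALSE]
      best <- mem[mem[, "n"] == max(mem[, "n"]), , drop = FALSE]
      rep_pos <- if (st == "+") min(best[, "p"]) else max(best[, "p"])
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep_id, strand = st, tss_pos = rep_pos,
        end_pos = if (st == "+") max(mem[, "e"]) else min(mem[, "e"]),
        read_count = sum(mem[, "n"])
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(replicon = character(), strand = character(),
                      tss_pos = numeric(), end_pos = numeric(),
                      read_count = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$replicon, res$tss_pos, res$strand), , drop = FALSE]
}

# naive per-TSS evaluation of the six class definitions, then precedence
oracle_classify_one <- function(tss_row, genes, genome, cfg = mtu_config()) {
  p <- tss_row$tss_pos
  st <- tss_row$strand
  a <- min(tss_row$tss_pos, tss_row$end_pos)
  b <- max(tss_row$tss_pos, tss_row$end_pos)
  g <- genes[genes$replicon == tss_row$replicon, , drop = FALSE]
  seqrep <- genome$replicons[[tss_row$replicon]]

  lm <- FALSE; m <- FALSE; se <- FALSE; as_ <- FALSE
  any_mtu_overlap <- FALSE; pm_dist_ok <- FALSE
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    if (gi$strand == "+") {
      sc <- gi$start
      win <- c(gi$start - cfg$m_window, gi$start - 1L)
      span <- c(gi$start - cfg$utr5_len, gi$end + cfg$utr3_len)
      dist <- sc - p
    } else {
      sc <- gi$end
      win <- c(gi$end + 1L, gi$end + cfg$m_window)
      span <- c(gi$start - cfg$utr3_len, gi$end + cfg$utr5_len)
      dist <- p - sc
    }
    ctg_ov_win <- a <= win[2] && win[1] <= b
    ctg_ov_span <- a <= span[2] && span[1] <= b
    if (ctg_ov_span) any_mtu_overlap <- TRUE
    if (gi$strand == st) {
      if (sc == p) {
        tri <- if (st == "+") substr(seqrep, p, p + 2L) else
          chartr("ACGT", "TGCA",
                 paste(rev(strsplit(substr(seqrep, p - 2L, p), "")[[1]]),
                       collapse = ""))
        if (tri == "ATG") lm <- TRUE
      }
      if (ctg_ov_win && dist > 0) m <- TRUE
      if (span[1] <= p && p <= span[2]) se <- TRUE
      if (dist >= 1 && dist <= cfg$pm_max_dist) pm_dist_ok <- TRUE
    } else {
      if (ctg_ov_span) as_ <- TRUE
    }
  }
  if (lm) "lmTSS"
  else if (m) "mTSS"
  else if (se) "seTSS"
  else if (as_) "asTSS"
  else if (!any_mtu_overlap && pm_dist_ok) "pmTSS"
  else "sTSS"
}

# exhaustive enumeration of the PSSM score distribution tail
oracle_pssm_pvalue <- function(pssm, threshold) {
  w <- pssm$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    sc <- sc + pssm$log_odds[cbind(words[, j], j)]
    pr <- pr * pssm$background[words[, j]]
  }
  sum(pr[sc >= threshold - 1e-9])
}

# sliding-window consensus search with mismatch counting by char comparison
oracle_string_hits <- function(genome, box1, spacers, box2, max_mm) {
  hits <- list()
  for (rep_id in names(genome$replicons)) {
    fwd <- genome$replicons[[rep_id]]
    L <- nchar(fwd)
    for (st in c("+", "-")) {
      s <- if (st == "+") fwd else revcomp(fwd)
      for (sp in spacers) {
        tw <- nchar(box1) + sp + nchar(box2)
        for (i in seq_len(max(0L, L - tw + 1L))) {
          w1 <- substr(s, i, i + nchar(box1) - 1L)
          w2 <- substr(s, i + nchar(box1) + sp,
                       i + nchar(box1) + sp + nchar(box2) - 1L)
          mm <- sum(strsplit(w1, "")[[1]] != strsplit(box1, "")[[1]]) +
            sum(strsplit(w2, "")[[1]] != strsplit(box2, "")[[1]])
          if (grepl("N", w1) || grepl("N", w2)) mm <- Inf
          if (mm <= max_mm) {
            # genomic start of the full placement
            gs <- if (st == "+") i else L - (i + tw - 1L) + 1L
            hits[[length(hits) + 1L]] <- data.frame(
              replicon = rep_id, strand = st, gstart = gs, spacer = sp,
              mm = mm)
          }
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(replicon = character(), strand = character(),
                      gstart = integer(), spacer = integer(), mm = numeric()))
  }
  res <- do.call(rbind, hits)
  res[order(res$replicon, res$gstart, res$strand, res$spacer), , drop = FALSE]
}

# exhaustive (offset, helix start, helix end) enumeration of the RBS energy
oracle_rbs_energy <- function(leader, config) {
  stk <- tssmap:::rna_stack_table
  init <- tssmap:::DUPLEX_INIT
  term <- tssmap:::TERMINAL_AU
  weak <- tssmap:::WEAK_PAIRS
  pairs_ok <- rownames(stk)
  ld <- strsplit(chartr("Tt", "UU", toupper(leader)), "")[[1]]
  tl <- rev(strsplit(config$anti_sd_tail, "")[[1]])
  best <- 0
  for (off in -(length(tl)):(length(ld))) {
    for (i in seq_along(ld)) {
      for (j in i:length(ld)) {
        ti <- (i:j) - off
        if (any(ti < 1) || any(ti > length(tl))) next
        if (j - i + 1L < config$min_helix_len) next
        pr <- paste0(ld[i:j], tl[ti])
        if (!all(pr %in% pairs_ok)) next
        e <- init + term * ((pr[1] %in% weak) + (pr[length(pr)] %in% weak))
        for (k in seq_len(length(pr) - 1L)) e <- e + stk[pr[k], pr[k + 1L]]
        if (e < best) best <- e
      }
    }
  }
  best
}

oracle_compare_bins <- function(query, reference, horizon = 50L) {
  vapply(seq_len(nrow(query)), function(i) {
    r <- reference[reference$replicon == query$replicon[i] &
                     reference$strand == query$strand[i], , drop = FALSE]
    if (nrow(r) == 0) return("absent")
    d <- min(abs(r$tss_pos - query$tss_pos[i]))
    if (d > horizon) "absent"
    else if (d == 0) "exact"
    else if (d <= 4) "near"
    else "far"
  }, character(1))
}
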