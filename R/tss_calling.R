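# TSS calling: read filtering, contig assembly from shared 5' ends, merging
# of near-identical TSS, relaxed prior-data contigs, and TSS-set comparison.

#' TSS-calling configuration
#'
#' Defaults follow the read filters and coverage thresholds used for global
#' bacterial TSS mapping: reads of at least 18 nt mapping to a unique position
#' with no mismatches in their first three 5' bases; a TSS requires at least
#' 30 reads sharing a common 5' end; TSS closer than 3 nt are merged.
#'
#' @param min_read_len Minimum read length in nt.
#' @param require_unique Keep only uniquely mapping reads.
#' @param max_mismatch_first3 Maximum mismatches in the first three 5' bases.
#' @param min_reads_per_tss Minimum reads sharing a 5' end to call a TSS.
#' @param merge_distance_lt TSS closer than this (strictly) are merged.
#' @return A list of class `tss_call_config`.
#' @export
tss_call_config <- function(min_read_len = 18L, require_unique = TRUE,
                            max_mismatch_first3 = 0L, min_reads_per_tss = 30L,
                            merge_distance_lt = 3L) {
  stopifnot(min_read_len >= 1, max_mismatch_first3 >= 0,
            min_reads_per_tss >= 1, merge_distance_lt >= 1)
  structure(list(min_read_len = as.integer(min_read_len),
                 require_unique = isTRUE(require_unique),
                 max_mismatch_first3 = as.integer(max_mismatch_first3),
                 min_reads_per_tss = as.integer(min_reads_per_tss),
                 merge_distance_lt = as.integer(merge_distance_lt)),
            class = "tss_call_config")
}

#' Filter mapped reads before TSS calling
#'
#' Retains reads with `length >= min_read_len`, `unique == TRUE` (when
#' required) and `mismatches_first3 <= max_mismatch_first3`. The number of
#' reads dropped by each criterion (counting multiplicities in `count`) is
#' attached as attribute `"drop_report"`.
#'
#' @param reads Read tibble (see [read_read_starts()]).
#' @param config A [tss_call_config()].
#' @return Filtered read tibble with a `drop_report` attribute.
#' @export
filter_reads <- function(reads, config = tss_call_config()) {
  if (!"count" %in% names(reads)) reads$count <- 1L
  short <- reads$length < config$min_read_len
  nonuni <- config$require_unique & !reads$unique
  mm <- reads$mismatches_first3 > config$max_mismatch_first3
  kept <- !(short | nonuni | mm)
  report <- tibble(
    criterion = c("short", "non_unique", "mismatch_5prime", "kept"),
    n_reads = c(sum(reads$count[short]), sum(reads$count[nonuni & !short]),
                sum(reads$count[mm & !short & !nonuni]),
                sum(reads$count[kept]))
  )
  out <- reads[kept, , drop = FALSE]
  attr(out, "drop_report") <- report
  out
}

# strand-aware 3' end of a read: the furthest position in transcription
# direction from its 5' end
read_3prime <- function(five_prime_pos, length, strand) {
  if_else(strand == "+", five_prime_pos + length - 1L,
          five_prime_pos - length + 1L)
}

#' Assemble candidate TSS contigs from filtered reads
#'
#' Groups reads by (replicon, strand, 5' position). Each group is a candidate
#' TSS contig: its 5'-most position is the TSS, the 3' end of the longest
#' member read its end position. Candidates below `min_reads_per_tss` are
#' flagged, not silently dropped, so known TSS that fail the coverage cutoff
#' remain visible in a sub-threshold channel.
#'
#' @param reads Filtered read tibble.
#' @param config A [tss_call_config()].
#' @return Tibble of candidates: `replicon`, `strand`, `tss_pos`, `end_pos`,
#'   `read_count`, `above_threshold`.
#' @export
call_tss_contigs <- function(reads, config = tss_call_config()) {
  if (!"count" %in% names(reads)) reads$count <- 1L
  reads |>
    mutate(p3 = read_3prime(.data$five_prime_pos, .data$length, .data$strand)) |>
    group_by(.data$replicon, .data$strand, tss_pos = .data$five_prime_pos) |>
    summarise(
      end_pos = if (first(.data$strand) == "+") max(.data$p3) else min(.data$p3),
      read_count = sum(.data$count),
      .groups = "drop"
    ) |>
    mutate(above_threshold = .data$read_count >= config$min_reads_per_tss) |>
    arrange(.data$replicon, .data$tss_pos, .data$strand)
}

#' Merge TSS candidates closer than the merge distance
#'
#' Within a replicon and strand, transitive chains of above-threshold
#' candidates whose successive 5' positions differ by less than
#' `merge_distance_lt` collapse into a single TSS contig. The surviving
#' coordinate is the member with the highest read count (tie: the 5'-most
#' member); the read count is summed over members and the end position is the
#' furthest 3' extent. Ids are assigned in genome order per replicon using
#' `<prefix>_TSS_<nnnn>`.
#'
#' @param candidates Output of [call_tss_contigs()] (sub-threshold rows are
#'   ignored).
#' @param config A [tss_call_config()].
#' @param prefixes Optional named character vector mapping replicon id to an
#'   id prefix; defaults to the replicon id itself.
#' @return Tibble of TSS contigs: `id`, `replicon`, `strand`, `tss_pos`,
#'   `end_pos`, `read_count`, `n_members`, `merged_from` (list column of
#'   member position/count tibbles).
#' @export
merge_tss <- function(candidates, config = tss_call_config(),
                      prefixes = NULL) {
  cand <- if ("above_threshold" %in% names(candidates)) {
    candidates[candidates$above_threshold, , drop = FALSE]
  } else candidates
  cand <- cand |> arrange(.data$replicon, .data$strand, .data$tss_pos)
  merged <- cand |>
    group_by(.data$replicon, .data$strand) |>
    mutate(chain = cumsum(
      c(TRUE, diff(.data$tss_pos) >= config$merge_distance_lt)
    )) |>
    group_by(.data$replicon, .data$strand, .data$chain) |>
    summarise(
      merged_from = list(tibble(pos = tss_pos, count = read_count)),
      rep_pos = {
        best <- .data$tss_pos[.data$read_count == max(.data$read_count)]
        if (first(.data$strand) == "+") min(best) else max(best)
      },
      end_pos = if (first(.data$strand) == "+") max(.data$end_pos)
                else min(.data$end_pos),
      total_count = sum(.data$read_count),
      n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    select(-"chain") |>
    rename(tss_pos = "rep_pos", read_count = "total_count") |>
    arrange(.data$replicon, .data$tss_pos, .data$strand)
  merged |>
    group_by(.data$replicon) |>
    mutate(id = sprintf(
      "%s_TSS_%04d",
      if (!is.null(prefixes)) prefixes[[first(.data$replicon)]]
      else first(.data$replicon),
      row_number()
    )) |>
    ungroup() |>
    select("id", "replicon", "strand", "tss_pos", "end_pos", "read_count",
           "n_members", "merged_from")
}

#' Call TSS contigs from reads (filter, assemble, merge)
#'
#' Convenience wrapper chaining [filter_reads()], [call_tss_contigs()] and
#' [merge_tss()]. Sub-threshold candidates are attached as attribute
#' `"sub_threshold"`.
#'
#' @inheritParams merge_tss
#' @param reads Read tibble.
#' @return Merged TSS contig tibble.
#' @export
call_tss <- function(reads, config = tss_call_config(), prefixes = NULL) {
  filtered <- filter_reads(reads, config)
  cand <- call_tss_contigs(filtered, config)
  out <- merge_tss(cand, config, prefixes)
  attr(out, "sub_threshold") <- cand[!cand$above_threshold, , drop = FALSE]
  attr(out, "drop_report") <- attr(filtered, "drop_report")
  out
}

#' Relaxed contigs from prior coverage data
#'
#' Recovers short-RNA contigs from a prior read set under relaxed rules:
#' maximal runs of per-base coverage of at least `min_depth` on one strand,
#' with a length between `len_range[1]` and `len_range[2]` nt, retained only
#' when the run's 5' end coincides exactly with a called TSS position.
#'
#' @param prior_reads Read tibble of the prior data set.
#' @param tss TSS contig tibble (needs `replicon`, `strand`, `tss_pos`).
#' @param genome A `tss_genome` (bounds the coverage vectors).
#' @param min_depth Minimum continuous coverage.
#' @param len_range Length bounds (inclusive) in nt.
#' @param prefix Name prefix for retained contigs.
#' @return Tibble: `id`, `replicon`, `strand`, `start`, `end`,
#'   `five_prime_pos`, `max_depth`.
#' @export
relaxed_contigs_from_coverage <- function(prior_reads, tss, genome,
                                          min_depth = 5L,
                                          len_range = c(50L, 350L),
                                          prefix = "SmelXR") {
  if (!"count" %in% names(prior_reads)) prior_reads$count <- 1L
  lens <- replicon_lengths(genome)
  runs <- list()
  for (rep_id in unique(prior_reads$replicon)) {
    L <- lens[[rep_id]]
    for (st in c("+", "-")) {
      rd <- prior_reads[prior_reads$replicon == rep_id &
                          prior_reads$strand == st, , drop = FALSE]
      if (nrow(rd) == 0) next
      p3 <- read_3prime(rd$five_prime_pos, rd$length, rd$strand)
      lo <- pmax(1L, pmin(rd$five_prime_pos, p3))
      hi <- pmin(L, pmax(rd$five_prime_pos, p3))
      delta <- numeric(L + 1L)
      for (i in seq_along(lo)) {
        delta[lo[i]] <- delta[lo[i]] + rd$count[i]
        delta[hi[i] + 1L] <- delta[hi[i] + 1L] - rd$count[i]
      }
      cov <- cumsum(delta[seq_len(L)])
      ok <- cov >= min_depth
      if (!any(ok)) next
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      runs[[length(runs) + 1L]] <- tibble(
        replicon = rep_id, strand = st,
        start = starts[keep], end = ends[keep],
        max_depth = vapply(which(keep), function(k) {
          max(cov[starts[k]:ends[k]])
        }, numeric(1))
      )
    }
  }
  out <- if (length(runs)) list_rbind(runs) else {
    tibble(replicon = character(), strand = character(), start = integer(),
           end = integer(), max_depth = numeric())
  }
  out <- out |>
    mutate(
      len = .data$end - .data$start + 1L,
      five_prime_pos = if_else(.data$strand == "+", .data$start, .data$end)
    ) |>
    filter(.data$len >= len_range[1], .data$len <= len_range[2])
  key <- paste(out$replicon, out$strand, out$five_prime_pos)
  tss_key <- paste(tss$replicon, tss$strand, tss$tss_pos)
  out <- out[key %in% tss_key, , drop = FALSE] |>
    arrange(.data$replicon, .data$start, .data$strand) |>
    mutate(id = sprintf("%s%03d", prefix, row_number())) |>
    select("id", "replicon", "strand", "start", "end", "five_prime_pos",
           "max_depth")
  out
}

#' Compare a TSS set with a reference set
#'
#' Each query TSS is assigned to its nearest same-strand (and same-replicon)
#' reference position and binned by absolute distance: `exact` (0 nt),
#' `near` (1-4 nt), `far` (>= 5 nt, within the horizon) or `absent` (no
#' reference within `horizon` nt). Bin fractions over queries are attached as
#' attribute `"bin_fractions"`.
#'
#' @param query,reference Tibbles with `replicon`, `strand`, `tss_pos`.
#' @param horizon Maximum distance (nt) before a query counts as `absent`.
#' @return The query tibble with added `nearest_ref`, `distance`, `bin`.
#' @export
compare_tss_sets <- function(query, reference, horizon = 50L) {
  res <- query
  res$nearest_ref <- NA_integer_
  res$distance <- NA_integer_
  for (i in seq_len(nrow(query))) {
    refs <- reference$tss_pos[reference$replicon == query$replicon[i] &
                                reference$strand == query$strand[i]]
    if (length(refs) == 0) next
    d <- abs(refs - query$tss_pos[i])
    j <- which.min(d)
    res$nearest_ref[i] <- refs[j]
    res$distance[i] <- d[j]
  }
  res$bin <- dplyr::case_when(
    is.na(res$distance) | res$distance > horizon ~ "absent",
    res$distance == 0 ~ "exact",
    res$distance <= 4 ~ "near",
    TRUE ~ "far"
  )
  fr <- table(factor(res$bin, levels = c("exact", "near", "far", "absent")))
  attr(res, "bin_fractions") <-
    tibble(bin = names(fr),
           n = as.integer(fr),
           fraction = as.numeric(fr) / max(1L, nrow(res)))
  res
}
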