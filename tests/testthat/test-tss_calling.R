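mk_reads <- function(pos, n, strand = "+", len = 100L, rep_id = "chr",
                     unique = TRUE, mm = 0L) {
  tibble::tibble(replicon = rep_id, strand = strand, five_prime_pos = pos,
                 length = len, unique = unique, mismatches_first3 = mm,
                 count = n)
}

test_that("read filters drop short, multi-mapping and 5'-mismatched reads", {
  reads <- dplyr::bind_rows(
    mk_reads(100L, 1L, len = 17L),               # too short
    mk_reads(100L, 1L, len = 50L),               # kept
    mk_reads(100L, 1L, len = 18L),               # boundary: kept
    mk_reads(100L, 1L, unique = FALSE),          # non-unique
    mk_reads(100L, 1L, mm = 1L)                  # 5' mismatch
  )
  f <- filter_reads(reads)
  expect_equal(nrow(f), 2L)
  expect_true(all(f$length >= 18))
  rep <- attr(f, "drop_report")
  expect_equal(rep$n_reads[rep$criterion == "short"], 1L)
  expect_equal(rep$n_reads[rep$criterion == "non_unique"], 1L)
  expect_equal(rep$n_reads[rep$criterion == "mismatch_5prime"], 1L)
})

test_that("contig assembly needs 30 shared 5' ends; the longest read sets the 3' end", {
  reads <- dplyr::bind_rows(
    mk_reads(500L, 29L, len = 90L),
    mk_reads(500L, 1L, len = 100L),
    mk_reads(800L, 29L, len = 90L)               # below threshold
  )
  cand <- call_tss_contigs(reads)
  above <- cand[cand$above_threshold, ]
  expect_equal(nrow(above), 1L)
  expect_equal(above$tss_pos, 500L)
  expect_equal(above$end_pos, 599L)
  expect_equal(above$read_count, 30L)
  # sub-threshold channel keeps the rest
  expect_equal(cand$tss_pos[!cand$above_threshold], 800L)
})

test_that("minus-strand contigs extend towards lower coordinates", {
  cand <- call_tss_contigs(mk_reads(800L, 30L, strand = "-", len = 90L))
  expect_equal(cand$tss_pos, 800L)
  expect_equal(cand$end_pos, 711L)
})

test_that("TSS closer than 3 nt merge transitively; representative is read-weighted", {
  cand <- call_tss_contigs(dplyr::bind_rows(
    mk_reads(100L, 40L), mk_reads(102L, 35L),    # gap 2 -> merge
    mk_reads(200L, 30L), mk_reads(203L, 30L),    # gap 3 -> no merge
    mk_reads(300L, 30L), mk_reads(302L, 31L), mk_reads(304L, 30L) # chain
  ))
  merged <- merge_tss(cand)
  m1 <- merged[merged$tss_pos == 100L, ]
  expect_equal(m1$read_count, 75L)
  expect_equal(m1$n_members, 2L)
  expect_true(all(c(200L, 203L) %in% merged$tss_pos))
  chain <- merged[vapply(merged$merged_from,
                         function(x) 302L %in% x$pos, logical(1)), ]
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$n_members, 3L)
  expect_equal(chain$tss_pos, 302L)              # highest count wins
  expect_equal(chain$read_count, 91L)
})

test_that("merge tie-break picks the 5'-most member per strand", {
  plus <- merge_tss(call_tss_contigs(dplyr::bind_rows(
    mk_reads(100L, 40L), mk_reads(102L, 40L))))
  expect_equal(plus$tss_pos, 100L)
  minus <- merge_tss(call_tss_contigs(dplyr::bind_rows(
    mk_reads(100L, 40L, strand = "-"), mk_reads(102L, 40L, strand = "-"))))
  expect_equal(minus$tss_pos, 102L)              # 5'-most on minus = highest
})

test_that("ids are assigned per replicon in genome order", {
  reads <- dplyr::bind_rows(
    mk_reads(900L, 35L, rep_id = "pA"), mk_reads(100L, 35L, rep_id = "pA"),
    mk_reads(400L, 35L, rep_id = "chr"))
  tss <- call_tss(reads, prefixes = c(pA = "SMa", chr = "SMc"))
  expect_equal(tss$id[tss$replicon == "pA"],
               c("SMa_TSS_0001", "SMa_TSS_0002"))
  expect_equal(tss$tss_pos[tss$id == "SMa_TSS_0001"], 100L)
  expect_equal(tss$id[tss$replicon == "chr"], "SMc_TSS_0001")
})

test_that("read partition: contig counts plus sub-threshold equal filtered totals", {
  set.seed(77)
  reads <- rand_reads(10000, n_pos = 60)
  f <- filter_reads(reads)
  cand <- call_tss_contigs(f)
  expect_equal(sum(cand$read_count), sum(f$count))
  tss <- merge_tss(cand)
  sub <- cand[!cand$above_threshold, ]
  expect_equal(sum(tss$read_count) + sum(sub$read_count), sum(f$count))
})

test_that("caller matches the union-find oracle on random small replicons", {
  set.seed(1234)
  for (k in 1:8) {
    reads <- rand_reads(8000, n_pos = 45)
    got <- merge_tss(call_tss_contigs(filter_reads(reads)))
    want <- oracle_call_merge(reads)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$tss_pos, want$tss_pos)
    expect_equal(got$end_pos, want$end_pos)
    expect_equal(got$read_count, want$read_count)
    expect_equal(got$strand, want$strand)
  }
})

test_that("calling is strand-symmetric under coordinate mirroring", {
  set.seed(5150)
  L <- 9000L
  reads <- rand_reads(L, n_pos = 40)
  fwd <- merge_tss(call_tss_contigs(filter_reads(reads)))
  mir <- merge_tss(call_tss_contigs(filter_reads(
    mirror_reads(reads, c(chr = L)))))
  expect_equal(nrow(fwd), nrow(mir))
  key_f <- sort(paste(mirror_strand(fwd$strand), mirror_pos(fwd$tss_pos, L),
                      mirror_pos(fwd$end_pos, L)))
  key_m <- sort(paste(mir$strand, mir$tss_pos, mir$end_pos))
  expect_equal(key_m, key_f)
})

test_that("relaxed contigs require depth 5, length 50-350 and a TSS at the 5' end", {
  g <- genome(c(chr = rand_seq(3000)))
  tss <- tibble::tibble(replicon = "chr", strand = "+",
                        tss_pos = c(500L, 1500L, 2500L))
  pri <- function(pos, n, len) mk_reads(pos, n, len = len)
  prior <- dplyr::bind_rows(
    pri(500L, 5L, 120L),     # depth-5 run of 120 nt at a TSS -> kept
    pri(1500L, 5L, 49L),     # run of 49 nt -> too short
    pri(2500L, 5L, 351L),    # run of 351 nt -> too long
    pri(900L, 5L, 100L)      # no TSS at 5' end -> dropped
  )
  rc <- relaxed_contigs_from_coverage(prior, tss, g, prefix = "SmelXR")
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$five_prime_pos, 500L)
  expect_equal(rc$end - rc$start + 1L, 120L)
  expect_equal(rc$id, "SmelXR001")
})

test_that("TSS set comparison bins by distance with strict boundaries", {
  ref <- tibble::tibble(replicon = "chr", strand = "+",
                        tss_pos = c(100L, 300L, 600L, 900L))
  q <- tibble::tibble(replicon = "chr", strand = "+",
                      tss_pos = c(100L, 303L, 607L, 980L))
  got <- compare_tss_sets(q, ref)
  expect_equal(got$bin, c("exact", "near", "far", "absent"))
  fr <- attr(got, "bin_fractions")
  expect_equal(sum(fr$fraction), 1)
  # identical sets -> all exact
  expect_true(all(compare_tss_sets(ref, ref)$bin == "exact"))
})
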