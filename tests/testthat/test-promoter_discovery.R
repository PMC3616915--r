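test_that("chaining respects spacer ranges and the 5-12 nt TSS gap", {
  sig <- sigma_model("X", w35 = 6L, w10 = 6L, spacer_min = 14L,
                     spacer_max = 20L)
  h35 <- tibble::tibble(replicon = "chr", strand = "+", start = 100L,
                        end = 105L, score = 1, pvalue = 0.001)
  h10 <- tibble::tibble(replicon = "chr", strand = "+", start = 120L,
                        end = 125L, score = 1, pvalue = 0.001)
  tss_at <- function(p) tibble::tibble(id = "t", replicon = "chr",
                                       strand = "+", tss_pos = p)
  # spacer 14, TSS at 130 -> gap 5: retained
  got <- chain_and_associate(h35, h10, sig, tss_at(130L))
  expect_equal(nrow(got), 1L)
  expect_equal(got$spacer, 14L)
  expect_equal(got$gap_to_tss, 5L)
  # TSS at 138 -> gap 13: rejected
  expect_equal(nrow(chain_and_associate(h35, h10, sig, tss_at(138L))), 0L)
  # -35 downstream of -10 is never chained
  got3 <- chain_and_associate(h10, h35, sig, tss_at(130L))
  expect_equal(nrow(got3), 0L)
})

test_that("minus-strand chaining mirrors the plus-strand arithmetic", {
  sig <- sigma_model("X", w35 = 6L, w10 = 6L, spacer_min = 17L,
                     spacer_max = 17L)
  # on the minus strand the -35 element sits at higher coordinates
  h35 <- tibble::tibble(replicon = "chr", strand = "-", start = 200L,
                        end = 205L, score = 1, pvalue = 0.001)
  h10 <- tibble::tibble(replicon = "chr", strand = "-", start = 177L,
                        end = 182L, score = 1, pvalue = 0.001)
  tss <- tibble::tibble(id = "t", replicon = "chr", strand = "-",
                        tss_pos = 169L)   # element start 177, gap 8
  got <- chain_and_associate(h35, h10, sig, tss)
  expect_equal(nrow(got), 1L)
  expect_equal(got$gap_to_tss, 8L)
})

test_that("exact seed extension finds identical element pairs near TSS", {
  set.seed(60)
  s <- rand_seq(4000, gc = 0.5)
  e35 <- "TTGACA"; e10 <- "TATAAT"
  place <- function(s, pos10, gap, sp) {
    substr(s, pos10, pos10 + 5L) <- e10
    substr(s, pos10 - sp - 6L, pos10 - sp - 1L) <- e35
    s
  }
  s <- place(s, 1000L, 8L, 17L)    # the seed's own site, TSS at 1013
  s <- place(s, 2000L, 8L, 17L)    # a second identical site, TSS at 2013
  s <- place(s, 3000L, 8L, 17L)    # identical site with no TSS nearby
  g <- genome(c(chr = s))
  tss <- tibble::tibble(id = c("t1", "t2"), replicon = "chr", strand = "+",
                        tss_pos = c(1013L, 2013L))
  seeds <- promoter_seeds("X", e35, e10, label = "model", tss_id = "t1",
                          replicon = "chr", strand = "+", pos35 = 977L,
                          pos10 = 1000L)
  sig <- sigma_model("X", w35 = 6L, w10 = 6L, spacer_min = 14L,
                     spacer_max = 20L)
  ext <- extend_seed_exact(seeds, sig, g, tss)
  added <- ext[ext$label == "extended_model", ]
  expect_equal(nrow(added), 1L)
  expect_equal(added$pos10, 2000L)
  # virtual seed with no genomic occurrence leaves the set unchanged
  virt <- promoter_seeds("X", "ACACAC", "GTGTGT", label = "virtual")
  expect_equal(nrow(extend_seed_exact(virt, sig, g, tss)), 1L)
})

test_that("two-phase search is a fixed point when nothing new matches", {
  set.seed(61)
  s <- rand_seq(3000, gc = 0.5)
  g <- genome(c(chr = s))
  tss <- tibble::tibble(id = "t1", replicon = "chr", strand = "+",
                        tss_pos = 1013L, tss_class = "mTSS")
  seeds <- promoter_seeds("X", c("TTGACA", "TTGACC"), c("TATAAT", "TATACT"),
                          label = c("model", "virtual"))
  sig <- sigma_model("X", w35 = 6L, w10 = 6L, spacer_min = 16L,
                     spacer_max = 18L)
  out <- run_two_phase(seeds, sig, g, tss)
  expect_setequal(out$label, c("model", "virtual"))
  expect_error(run_two_phase(seeds[1, ], sig, g, tss), "two seed")
})

test_that("phase-1 drops seTSS-only candidates; phase 2 readmits them", {
  set.seed(62)
  s <- rand_seq(6000, gc = 0.5)
  e35 <- "TTGACA"; e10 <- "TATAAT"
  put <- function(s, pos10) {
    substr(s, pos10, pos10 + 5L) <- e10
    substr(s, pos10 - 17L - 6L, pos10 - 17L - 1L) <- e35
    s
  }
  s <- put(s, 1000L)   # near mTSS at 1013
  s <- put(s, 3000L)   # near seTSS at 3013
  g <- genome(c(chr = s))
  tss <- tibble::tibble(id = c("m", "se"), replicon = "chr", strand = "+",
                        tss_pos = c(1013L, 3013L),
                        tss_class = c("mTSS", "seTSS"))
  # seeds one mismatch away so plants are discovered, not extended
  seeds <- promoter_seeds("X", c("TTGACC", "TTGTCA"), c("TATACT", "TACAAT"),
                          label = "model")
  sig <- sigma_model("X", w35 = 6L, w10 = 6L, spacer_min = 16L,
                     spacer_max = 18L)
  out <- run_two_phase(seeds, sig, g, tss)
  p1 <- out[out$label == "new_initial", ]
  expect_true(1000L %in% p1$pos10)
  expect_false(3000L %in% p1$pos10)              # seTSS-only: held back
  p2 <- out[out$label == "second_search", ]
  expect_true(3000L %in% p2$pos10)               # readmitted in phase 2
})

test_that("string search honours the one-mismatch budget and spacer", {
  set.seed(63)
  s <- rand_seq(5000, gc = 0.6)
  consensus <- "GAAT-N18-GTCT"
  put <- function(s, pos, b1, b2) {
    substr(s, pos, pos + 3L) <- b1
    substr(s, pos + 4L + 18L, pos + 4L + 18L + 3L) <- b2
    s
  }
  s <- put(s, 1000L, "GAAT", "GTCT")   # exact; ends 1025, TSS 1033 gap 8
  s <- put(s, 2000L, "GACT", "GTCT")   # one mismatch
  s <- put(s, 3000L, "GACT", "GTCC")   # two mismatches -> no hit
  g <- genome(c(chr = s))
  tss <- tibble::tibble(id = paste0("t", 1:3), replicon = "chr",
                        strand = "+", tss_pos = c(1033L, 2033L, 3033L))
  sig <- sigma_model("RpoE1", mode = "string", consensus = consensus)
  hits <- string_promoter_search(sig, g, tss)
  expect_true(all(c(1000L, 2000L) %in% hits$pos35))
  expect_false(3000L %in% hits$pos35)
  expect_true(all(hits$gap_to_tss >= 5 & hits$gap_to_tss <= 12))
  # spacer outside the configured range finds nothing
  sig25 <- sigma_model("RpoE1", mode = "string", consensus = consensus,
                       spacer_min = 25L, spacer_max = 25L)
  expect_equal(nrow(string_promoter_search(sig25, g, tss)), 0L)
  expect_error(sigma_model("Bad", mode = "string", consensus = "GA-18-GT"),
               "malformed")
})

test_that("string search matches the sliding-window oracle on a 20 kb toy", {
  set.seed(64)
  L <- 20000L
  s <- rand_seq(L, gc = 0.55)
  substr(s, 5000L, 5003L) <- "TGTC"   # seed some near-matches
  g <- genome(c(chr = s))
  # every position is an anchor so the oracle needs no gap logic
  tss <- tibble::tibble(id = as.character(seq_len(L)), replicon = "chr",
                        strand = rep(c("+", "-"), length.out = L),
                        tss_pos = seq_len(L))
  tss <- dplyr::bind_rows(tss, dplyr::mutate(tss, strand = mirror_strand(strand)))
  for (cons in c("GAAT-N18-GTCT", "TGTCACA-N16-CGTC")) {
    sig <- sigma_model("E", mode = "string", consensus = cons)
    hits <- string_promoter_search(sig, g, tss)
    pat <- tssmap:::parse_consensus(cons)
    want <- oracle_string_hits(g, pat$box1, pat$spacer, pat$box2, 1L)
    got_key <- sort(paste(hits$strand,
                          ifelse(hits$strand == "+", hits$pos35,
                                 hits$pos10)))
    want_key <- sort(paste(want$strand, want$gstart))
    expect_equal(got_key, want_key)
  }
})

test_that("promoter recovery: planted consensus sites are found in phase 1", {
  fx <- default_pipeline()
  truth <- fx$truth
  out <- fx$run$promoters[fx$run$promoters$sigma == "RpoD", ]
  planted <- truth$promoters[truth$promoters$kind == "exact", ]
  new1 <- out[out$label == "new_initial", ]
  key <- paste(new1$replicon, new1$strand, new1$pos35, new1$pos10)
  pkey <- paste(planted$replicon, planted$strand, planted$pos35,
                planted$pos10)
  expect_true(all(pkey %in% key))
  # phase-1 survivors always remain in the final union
  expect_true(all(paste(new1$replicon, new1$strand, new1$pos35, new1$pos10)
                  %in% paste(out$replicon, out$strand, out$pos35, out$pos10)))
})

test_that("cross-sigma overlap reports TSS claimed by several factors", {
  a <- tibble::tibble(sigma = "RpoD", tss_id = c("t1", "t2"))
  b <- tibble::tibble(sigma = "RpoH1", tss_id = c("t2", "t3"))
  got <- cross_sigma_overlap(list(RpoD = a, RpoH1 = b))
  expect_equal(got$tss_id, "t2")
  expect_equal(got$sigmas, "RpoD,RpoH1")
  # symmetric in input order
  got2 <- cross_sigma_overlap(list(RpoH1 = b, RpoD = a))
  expect_equal(got2, got)
  # disjoint sets -> empty
  expect_equal(nrow(cross_sigma_overlap(list(
    a = a, b = dplyr::mutate(b, tss_id = c("x", "y"))))), 0L)
})
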