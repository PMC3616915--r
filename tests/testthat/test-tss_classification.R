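mk_tss <- function(pos, end, strand = "+", rep_id = "chr", id = "t1",
                   count = 50L) {
  tibble::tibble(id = id, replicon = rep_id, strand = strand,
                 tss_pos = pos, end_pos = end, read_count = count)
}

one_gene <- function(start, end, strand = "+", rep_id = "chr", id = "g1") {
  tibble::tibble(gene_id = id, replicon = rep_id, strand = strand,
                 start = start, end = end,
                 start_codon_pos = if (strand == "+") start else end,
                 stop_codon_pos = if (strand == "+") end else start)
}

# a genome with an ATG written at a gene start so lmTSS rules can fire
genome_with_gene <- function(gene, L = 3000L) {
  s <- rand_seq(L)
  body <- if (gene$strand == "+") "ATG" else "CAT"
  pos <- if (gene$strand == "+") gene$start else gene$end - 2L
  substr(s, pos, pos + 2L) <- body
  genome(setNames(s, gene$replicon))
}

test_that("MTU arithmetic follows the 14/20/40 margins on both strands", {
  g <- genome(c(chr = rand_seq(3000)))
  plus <- build_mtus(one_gene(1000L, 1500L), g)
  expect_equal(plus$span_start, 986L)
  expect_equal(plus$span_end, 1520L)
  expect_equal(plus$prom_start, 946L)
  expect_equal(plus$prom_end, 985L)
  expect_equal(c(plus$win_start, plus$win_end), c(946L, 999L))
  minus <- build_mtus(one_gene(1000L, 1500L, "-"), g)
  expect_equal(minus$span_start, 980L)
  expect_equal(minus$span_end, 1514L)
  expect_equal(minus$prom_start, 1515L)
  expect_equal(minus$prom_end, 1554L)
  expect_false(plus$truncated || minus$truncated)
})

test_that("MTUs truncate (with a flag) at replicon ends", {
  g <- genome(c(chr = rand_seq(600)))
  m <- build_mtus(one_gene(5L, 304L), g)
  expect_equal(m$span_start, 1L)
  expect_true(m$truncated)
})

test_that("each class rule fires on its canonical geometry", {
  gene <- one_gene(1000L, 1500L)
  g <- genome_with_gene(gene)
  mtus <- build_mtus(gene, g)
  cl <- function(tss) classify_tss(tss, mtus, g)$tss_class

  expect_equal(cl(mk_tss(1000L, 1090L)), "lmTSS")        # at the ATG
  expect_equal(cl(mk_tss(960L, 1050L)), "mTSS")          # overlaps 946-999
  expect_equal(classify_tss(mk_tss(960L, 1050L), mtus, g)$utr5_len, 40L)
  expect_equal(cl(mk_tss(1200L, 1290L)), "seTSS")        # inside the MTU
  expect_equal(cl(mk_tss(1290L, 1200L, strand = "-")), "asTSS")
  expect_equal(cl(mk_tss(750L, 840L)), "pmTSS")          # 250 nt upstream
  expect_equal(cl(mk_tss(300L, 390L)), "sTSS")           # 700 nt upstream
})

test_that("the pmTSS distance boundary at 300 nt is inclusive", {
  gene <- one_gene(1000L, 1500L)
  g <- genome_with_gene(gene)
  mtus <- build_mtus(gene, g)
  at300 <- classify_tss(mk_tss(700L, 790L), mtus, g)$tss_class
  at301 <- classify_tss(mk_tss(699L, 789L), mtus, g)$tss_class
  expect_equal(at300, "pmTSS")
  expect_equal(at301, "sTSS")
})

test_that("lmTSS requires the genomic triplet to be ATG", {
  gene <- one_gene(1000L, 1500L)
  s <- rand_seq(3000)
  substr(s, 1000, 1002) <- "GTG"                 # annotated non-ATG start
  g <- genome(c(chr = s))
  got <- classify_tss(mk_tss(1000L, 1090L), build_mtus(gene, g), g)
  expect_false(got$tss_class == "lmTSS")
  expect_equal(got$tss_class, "seTSS")           # TSS point is inside the MTU
})

test_that("mTSS targets the nearest downstream start codon among windows", {
  genes <- dplyr::bind_rows(one_gene(1000L, 1290L, id = "gA"),
                            one_gene(1320L, 1620L, id = "gB"))
  s <- rand_seq(3000); substr(s, 1000, 1002) <- "ATG"
  substr(s, 1320, 1322) <- "ATG"
  g <- genome(c(chr = s))
  mtus <- build_mtus(genes, g)
  # contig overlaps gA's window and reaches into gB's window; gA is nearer
  got <- classify_tss(mk_tss(970L, 1280L), mtus, g)
  expect_equal(got$tss_class, "mTSS")
  expect_equal(got$target_feature, "gA")
  expect_equal(got$utr5_len, 30L)
})

test_that("a leader contig can rescue a distant TSS into the mTSS class", {
  gene <- one_gene(1000L, 1500L)
  g <- genome_with_gene(gene)
  mtus <- build_mtus(gene, g)
  tss <- mk_tss(700L, 790L)                      # otherwise pmTSS
  leaders <- tibble::tibble(replicon = "chr", strand = "+", start = 650L,
                            end = 999L, gene_id = "g1")
  got <- classify_tss(tss, mtus, g, leaders = leaders)
  expect_equal(got$tss_class, "mTSS")
  expect_equal(got$evidence, "leader_contig")
  # leader starting downstream of the TSS does not rescue
  late <- leaders; late$start <- 750L
  expect_equal(classify_tss(tss, mtus, g, leaders = late)$tss_class, "pmTSS")
})

test_that("classification matches the naive rule oracle on random cases", {
  set.seed(2024)
  L <- 60000L
  genes <- rand_genes(50, L)
  s <- rand_seq(L)
  for (i in seq_len(nrow(genes))) {   # write real start codons
    if (genes$strand[i] == "+") substr(s, genes$start[i], genes$start[i] + 2) <- "ATG"
    else substr(s, genes$end[i] - 2, genes$end[i]) <- "CAT"
  }
  g <- genome(c(chr = s))
  mtus <- build_mtus(genes, g)
  n <- 300
  pos <- sample(seq(200L, L - 200L), n)
  len <- sample(87:108, n, replace = TRUE)
  st <- sample(c("+", "-"), n, replace = TRUE)
  tss <- tibble::tibble(
    id = paste0("t", seq_len(n)), replicon = "chr", strand = st,
    tss_pos = pos,
    end_pos = ifelse(st == "+", pos + len - 1L, pos - len + 1L),
    read_count = 50L)
  got <- classify_tss(tss, mtus, g)
  want <- vapply(seq_len(n), function(i) {
    oracle_classify_one(tss[i, ], genes, g)
  }, character(1))
  expect_equal(got$tss_class, want)
})

test_that("class assignment partitions the TSS set", {
  fx <- default_pipeline()
  cl <- fx$run$classified
  expect_equal(nrow(cl), nrow(fx$run$tss))
  expect_true(all(cl$tss_class %in%
                    c("mTSS", "lmTSS", "pmTSS", "seTSS", "asTSS", "sTSS")))
  expect_equal(sum(fx$run$summary$class_counts$n), nrow(cl))
})

test_that("overlapping sTSS/asTSS contigs merge into named RNA features", {
  gene <- one_gene(1000L, 1500L)
  g <- genome_with_gene(gene)
  mtus <- build_mtus(gene, g)
  tss <- dplyr::bind_rows(
    mk_tss(1290L, 1200L, strand = "-", id = "a1"),
    mk_tss(1270L, 1180L, strand = "-", id = "a2"),   # overlaps a1 -> one asRNA
    mk_tss(300L, 390L, id = "s1"),
    mk_tss(440L, 530L, id = "s2")                    # 50 nt apart -> separate
  )
  cl <- classify_tss(tss, mtus, g)
  expect_equal(cl$tss_class, c("asTSS", "asTSS", "sTSS", "sTSS"))
  fe <- merge_rna_features(cl, mtus)
  as_fe <- fe[fe$kind == "asRNA", ]
  expect_equal(nrow(as_fe), 1L)
  expect_equal(as_fe$n_members, 2L)
  expect_equal(as_fe$target, "g1")
  expect_equal(as_fe$overlap_region, "CDS")
  expect_equal(sum(fe$kind == "sRNA"), 2L)
  expect_match(fe$id[fe$kind == "sRNA"][1], "_sRNA_1$")
})

test_that("asRNA overlap regions honour the UTR margins", {
  gene <- one_gene(1000L, 1500L)
  g <- genome_with_gene(gene)
  mtus <- build_mtus(gene, g)
  # antisense contig covering only positions downstream of the stop, within +20
  tss <- mk_tss(1515L, 1505L, strand = "-", id = "x")
  cl <- classify_tss(tss, mtus, g)
  expect_equal(cl$tss_class, "asTSS")
  fe <- merge_rna_features(cl, mtus)
  expect_equal(fe$overlap_region, "3'-UTR")
  # antisense contig over the 5' margin
  tss5 <- mk_tss(995L, 988L, strand = "-", id = "y")
  fe5 <- merge_rna_features(classify_tss(tss5, mtus, g), mtus)
  expect_equal(fe5$overlap_region, "5'-UTR")
})

test_that("summaries report histograms, composition and UTR means", {
  gene <- one_gene(1000L, 1500L)
  s <- rand_seq(3000)
  substr(s, 1000, 1002) <- "ATG"
  substr(s, 960, 962) <- "AGC"                   # mTSS at 960 starts A,G,C
  substr(s, 904, 906) <- "ACT"
  g <- genome(c(chr = s))
  mtus <- build_mtus(gene, g)
  tss <- dplyr::bind_rows(
    mk_tss(960L, 1050L, id = "m1"),              # utr5 40
    mk_tss(904L, 994L, id = "m2")                # utr5 96
  )
  cl <- classify_tss(tss, mtus, g)
  expect_equal(sort(cl$utr5_len), c(40L, 96L))
  sm <- summarize_classification(cl, merge_rna_features(cl, mtus), g)
  expect_equal(sm$utr5_mean, 68)                 # (40 + 96) / 2
  comp <- sm$plus_site_composition
  expect_equal(comp$fraction[comp$position == "+1" & comp$nucleotide == "A"], 1)
  expect_equal(sum(comp$fraction[comp$position == "+2"]), 1)
  # per-gene histogram counts genes by TSS multiplicity
  gene_tss <- c(1, 1, 2, 5)
  fake <- tibble::tibble(
    id = paste0("t", 1:9), replicon = "chr", strand = "+",
    tss_pos = 1L, end_pos = 2L, read_count = 50L,
    tss_class = "mTSS",
    target_feature = rep(paste0("g", 1:4), gene_tss),
    utr5_len = 10L)
  sm2 <- summarize_classification(fake, merge_rna_features(fake, mtus), g)
  h <- setNames(sm2$per_gene_hist$n_features, sm2$per_gene_hist$n_tss)
  expect_equal(h[["1"]], 2L)
  expect_equal(h[["2"]], 1L)
  expect_equal(h[[">4"]], 1L)
})

test_that("classification commutes with genome mirroring", {
  set.seed(31)
  L <- 40000L
  genes <- rand_genes(25, L)
  s <- rand_seq(L)
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+") substr(s, genes$start[i], genes$start[i] + 2) <- "ATG"
    else substr(s, genes$end[i] - 2, genes$end[i]) <- "CAT"
  }
  g <- genome(c(chr = s))
  n <- 120
  pos <- sample(seq(200L, L - 200L), n)
  len <- sample(87:108, n, replace = TRUE)
  st <- sample(c("+", "-"), n, replace = TRUE)
  tss <- tibble::tibble(id = paste0("t", 1:n), replicon = "chr", strand = st,
                        tss_pos = pos,
                        end_pos = ifelse(st == "+", pos + len - 1L,
                                         pos - len + 1L),
                        read_count = 50L)
  fwd <- classify_tss(tss, build_mtus(genes, g), g)
  gm <- mirror_genome(g)
  genes_m <- mirror_genes(genes, c(chr = L))
  tss_m <- tss
  tss_m$strand <- mirror_strand(tss$strand)
  tss_m$tss_pos <- mirror_pos(tss$tss_pos, L)
  tss_m$end_pos <- mirror_pos(tss$end_pos, L)
  mir <- classify_tss(tss_m, build_mtus(genes_m, gm), gm)
  expect_equal(mir$tss_class, fwd$tss_class)
  expect_equal(mir$utr5_len, fwd$utr5_len)
})
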