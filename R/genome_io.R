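# Domain containers and readers/writers for the standard formats the
# pipeline touches. Internal coordinates are 1-based inclusive with explicit
# strand; BED half-open is converted at the boundary.

#' Construct a genome object from named sequences
#'
#' A genome is a set of named replicon sequences (chromosome and plasmids)
#' restricted to the A/C/G/T/N alphabet. The `circular` flag is carried as
#' metadata; interval arithmetic elsewhere in the package is linear, with
#' truncation at replicon ends.
#'
#' @param replicons Named character vector of nucleotide sequences.
#' @param circular Logical, recycled across replicons.
#' @return An object of class `tss_genome`: a list with elements `replicons`
#'   (named uppercase character vector) and `circular` (named logical).
#' @export
#' @examples
#' g <- genome(c(chr = "ACGTACGTAA"))
#' replicon_lengths(g)
genome <- function(replicons, circular = FALSE) {
  if (is.null(names(replicons)) || anyNA(names(replicons)) ||
      any(names(replicons) == "")) {
    abort("replicons must be a named character vector")
  }
  if (anyDuplicated(names(replicons))) abort("replicon ids must be unique")
  ids <- names(replicons)
  replicons <- setNames(toupper(as.character(replicons)), ids)
  if (any(nchar(replicons) == 0)) abort("replicon sequences must be non-empty")
  if (any(grepl("[^ACGTN]", replicons))) {
    abort("replicon sequences must use only A/C/G/T/N")
  }
  circular <- rep_len(as.logical(circular), length(replicons))
  structure(
    list(replicons = replicons,
         circular = setNames(circular, names(replicons))),
    class = "tss_genome"
  )
}

#' @export
print.tss_genome <- function(x, ...) {
  cat("<tss_genome> ", length(x$replicons), " replicon(s)\n", sep = "")
  for (id in names(x$replicons)) {
    cat("  ", id, ": ", nchar(x$replicons[[id]]), " nt",
        if (x$circular[[id]]) " (circular)" else "", "\n", sep = "")
  }
  invisible(x)
}

#' @rdname genome
#' @param x A `tss_genome`.
#' @export
replicon_lengths <- function(x) {
  stopifnot(inherits(x, "tss_genome"))
  setNames(nchar(x$replicons), names(x$replicons))
}

#' Reverse-complement a DNA string
#'
#' @param seq Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(seq, NULL),
    function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

#' Extract a strand-oriented subsequence from a genome
#'
#' Coordinates are 1-based inclusive genomic positions (`start <= end`);
#' for `strand = "-"` the reverse complement is returned so the result always
#' reads 5' to 3' on the requested strand.
#'
#' @param genome A `tss_genome`.
#' @param replicon Replicon id.
#' @param start,end 1-based inclusive genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A single character string.
#' @export
genome_seq <- function(genome, replicon, start, end, strand = "+") {
  stopifnot(inherits(genome, "tss_genome"))
  if (!replicon %in% names(genome$replicons)) {
    abort(paste0("unknown replicon: ", replicon))
  }
  seq <- genome$replicons[[replicon]]
  if (start < 1 || end > nchar(seq) || start > end) {
    abort(sprintf("coordinates %d-%d outside replicon %s (1-%d)",
                  start, end, replicon, nchar(seq)))
  }
  s <- substr(seq, start, end)
  if (strand == "-") revcomp(s) else s
}

#' Read a genome from FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @param circular Logical, recycled over records.
#' @return A `tss_genome`.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  genome(setNames(as.character(ss), ids), circular = circular)
}

#' Write a genome to FASTA
#'
#' @param genome A `tss_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$replicons)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Takes `gene` records (or `CDS` records when no `gene` records are present)
#' and returns one row per gene with the start/stop-codon positions implied by
#' the strand: on `+` the start codon begins at the interval start, on `-` it
#' begins at the interval end.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `tss_genome`; when given, records on unknown
#'   replicons or outside replicon bounds raise an error.
#' @return A tibble with columns `gene_id`, `replicon`, `strand`, `start`,
#'   `end`, `start_codon_pos`, `stop_codon_pos`.
#' @export
read_genes_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), replicon = character(),
                  strand = character(), start = integer(), end = integer(),
                  start_codon_pos = integer(), stop_codon_pos = integer()))
  }
  type <- as.character(gr$type)
  keep <- if (any(type == "gene")) type == "gene" else type == "CDS"
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) ids <- paste0("gene_", seq_along(gr))
  genes <- tibble(
    gene_id = as.character(ids),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) |>
    mutate(
      start_codon_pos = if_else(.data$strand == "+", .data$start, .data$end),
      stop_codon_pos = if_else(.data$strand == "+", .data$end, .data$start)
    )
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene records must carry strand + or -")
  }
  if (!is.null(genome)) validate_intervals(genes, genome, what = "gene")
  genes
}

#' Write gene models to GFF3
#'
#' @param genes Gene tibble as returned by [read_genes_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene",
    ID = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

validate_intervals <- function(df, genome, what = "record") {
  lens <- replicon_lengths(genome)
  bad <- !df$replicon %in% names(lens)
  if (any(bad)) {
    abort(sprintf("%s references unknown replicon(s): %s", what,
                  paste(unique(df$replicon[bad]), collapse = ", ")))
  }
  L <- lens[df$replicon]
  cols <- intersect(c("start", "end", "five_prime_pos", "tss_pos"), names(df))
  for (cl in cols) {
    v <- df[[cl]]
    if (any(v < 1 | v > L)) {
      abort(sprintf("%s has %s outside replicon bounds", what, cl))
    }
  }
  invisible(df)
}

#' Read mapped-read 5'-end records
#'
#' Accepts either BED6 (`chrom start end name score strand`, 0-based
#' half-open: the 5' end of a plus-strand read is `start + 1`, of a
#' minus-strand read `end`) or a tab-separated table with a header containing
#' at least `replicon`, `strand`, `five_prime_pos`, `length`. Optional table
#' columns: `unique` (default `TRUE`), `mismatches_first3` (default `0`) and
#' `count` (pre-aggregated rows; implies unique, mismatch-free reads).
#'
#' @param path Input path.
#' @param genome Optional `tss_genome` for coordinate validation.
#' @return A tibble with columns `replicon`, `strand`, `five_prime_pos`,
#'   `length`, `unique`, `mismatches_first3`, `count`.
#' @export
read_read_starts <- function(path, genome = NULL) {
  first <- readLines(path, n = 1L)
  reads <- if (grepl("five_prime_pos", first)) {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    df$unique <- if ("unique" %in% names(df)) as.logical(df$unique) else TRUE
    df$mismatches_first3 <-
      if ("mismatches_first3" %in% names(df)) df$mismatches_first3 else 0L
    df$count <- if ("count" %in% names(df)) df$count else 1L
    as_tibble(df[c("replicon", "strand", "five_prime_pos", "length",
                   "unique", "mismatches_first3", "count")])
  } else {
    bed <- read_bed(path)
    tibble(
      replicon = bed$replicon,
      strand = bed$strand,
      five_prime_pos = if_else(bed$strand == "+", bed$start, bed$end),
      length = bed$end - bed$start + 1L,
      unique = TRUE,
      mismatches_first3 = 0L,
      count = 1L
    )
  }
  if (any(!reads$strand %in% c("+", "-"))) abort("read strand must be + or -")
  if (any(reads$length < 1)) abort("read length must be >= 1")
  if (any(reads$mismatches_first3 < 0 | reads$mismatches_first3 > 3)) {
    abort("mismatches_first3 must be in 0..3")
  }
  if (!is.null(genome)) validate_intervals(reads, genome, what = "read")
  reads
}

#' Read a BED6 file into 1-based inclusive intervals
#'
#' @param path Path to a BED file (no header, >= 3 columns).
#' @return Tibble with `replicon`, `start`, `end` (1-based inclusive),
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) abort(paste0("malformed BED (need >= 3 columns): ", path))
  tibble(
    replicon = as.character(df[[1]]),
    start = as.integer(df[[2]]) + 1L,
    end = as.integer(df[[3]]),
    name = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_,
    score = if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_,
    strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+"
  )
}

#' Write 1-based inclusive intervals as BED6
#'
#' @param df Tibble with `replicon`, `start`, `end`, optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    df$replicon,
    df$start - 1L,
    df$end,
    if ("name" %in% names(df)) df$name else ".",
    if ("score" %in% names(df)) df$score else 0,
    if ("strand" %in% names(df)) df$strand else "+"
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load all pipeline inputs
#'
#' @param genome_path FASTA genome.
#' @param annotation_path GFF3 gene annotation.
#' @param reads_path Read-start table or BED (see [read_read_starts()]).
#' @param priors_path Optional BED of prior short-RNA contig reads.
#' @param circular Passed to [read_genome_fasta()].
#' @return A list with `genome`, `genes`, `reads`, `priors` (tibble or NULL).
#' @export
load_inputs <- function(genome_path, annotation_path, reads_path,
                        priors_path = NULL, circular = FALSE) {
  g <- read_genome_fasta(genome_path, circular = circular)
  list(
    genome = g,
    genes = read_genes_gff3(annotation_path, genome = g),
    reads = read_read_starts(reads_path, genome = g),
    priors = if (!is.null(priors_path)) read_read_starts(priors_path, genome = g)
  )
}

# deterministic output ordering used by all writers
order_features <- function(df, pos_col = "start") {
  df[order(df$replicon, df[[pos_col]], df$strand), , drop = FALSE]
}

gff3_escape <- function(x) gsub("([;=,&\t])", "", x)

write_gff3_features <- function(df, path, source = "tssmap") {
  # df: replicon, start, end, strand, type, id, plus optional attribute cols
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df) > 0) {
    df <- order_features(df)
    extra <- setdiff(names(df), c("replicon", "start", "end", "strand",
                                  "type", "id", "score"))
    attrs <- paste0("ID=", gff3_escape(df$id))
    for (cl in extra) {
      v <- df[[cl]]
      keep <- !is.na(v)
      add <- ifelse(keep, paste0(";", cl, "=", gff3_escape(as.character(v))), "")
      attrs <- paste0(attrs, add)
    }
    score <- if ("score" %in% names(df)) {
      ifelse(is.na(df$score), ".", format(df$score, trim = TRUE))
    } else "."
    writeLines(paste(df$replicon, source, df$type, df$start, df$end,
                     score, df$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Write pipeline results to an output directory
#'
#' Emits tab-separated tables (UTF-8, with headers) and GFF3 feature files for
#' the classified TSS, merged sRNA/asRNA features, promoter hits, ORF calls
#' and TFBS hits present in `results`. Output ordering is deterministic
#' (replicon, position, strand). Missing result elements are skipped.
#'
#' @param results A named list; recognised elements: `tss` (classified TSS
#'   tibble), `features` (RNA features), `promoters`, `orfs`, `tfbs`.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) abort(paste0("cannot create ", out_dir))
  }
  written <- character()
  wr_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$tss)) {
    tss <- order_features(as_tibble(results$tss), "tss_pos")
    tss_flat <- tss
    tss_flat$merged_from <- NULL
    wr_tsv(tss_flat, "tss.tsv")
    gff <- tibble(
      replicon = tss$replicon,
      start = pmin(tss$tss_pos, tss$end_pos),
      end = pmax(tss$tss_pos, tss$end_pos),
      strand = tss$strand, type = "TSS_contig", id = tss$id,
      score = tss$read_count
    )
    if ("tss_class" %in% names(tss)) gff$class <- tss$tss_class
    write_gff3_features(gff, file.path(out_dir, "tss.gff3"))
    written <- c(written, file.path(out_dir, "tss.gff3"))
  }
  if (!is.null(results$features) && is.data.frame(results$features)) {
    fe <- as_tibble(results$features)
    flat <- fe
    flat$member_tss <- vapply(fe$member_tss, paste, character(1), collapse = ",")
    wr_tsv(flat, "rna_features.tsv")
    gff <- tibble(replicon = fe$replicon, start = fe$start, end = fe$end,
                  strand = fe$strand,
                  type = ifelse(fe$kind == "sRNA", "ncRNA", "antisense_RNA"),
                  id = fe$id, target = fe$target)
    write_gff3_features(gff, file.path(out_dir, "rna_features.gff3"))
    written <- c(written, file.path(out_dir, "rna_features.gff3"))
  }
  if (!is.null(results$promoters)) {
    wr_tsv(order_features(as_tibble(results$promoters), "pos10"),
           "promoters.tsv")
  }
  if (!is.null(results$orfs)) {
    orfs <- as_tibble(results$orfs)
    wr_tsv(order_features(orfs, "start"), "orfs.tsv")
    gff <- tibble(replicon = orfs$replicon, start = orfs$start, end = orfs$end,
                  strand = orfs$strand, type = "ORF", id = orfs$name,
                  status = orfs$status, kind = orfs$kind)
    write_gff3_features(gff, file.path(out_dir, "orfs.gff3"))
    written <- c(written, file.path(out_dir, "orfs.gff3"))
  }
  if (!is.null(results$tfbs)) {
    wr_tsv(order_features(as_tibble(results$tfbs), "start"), "tfbs.tsv")
  }
  invisible(written)
}
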