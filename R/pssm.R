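# Position-specific scoring matrices with exact P-values.
#
# The P-value of a score threshold is the probability, under a zero-order
# background model with independent positions, that a random word of the
# matrix width scores at least the threshold. It is computed exactly by
# dynamic programming: the score distribution is built up position by
# position as a convolution over the (at most 4^w, in practice far fewer)
# attainable score sums, so no discretization grid is needed.

NT <- c("A", "C", "G", "T")

#' Build a position-specific scoring matrix
#'
#' Per-position nucleotide counts are smoothed with a pseudocount and turned
#' into log-odds (natural log) against a background nucleotide distribution.
#'
#' @param seqs Character vector of aligned, equal-length A/C/G/T sequences
#'   (at least one; promoter discovery requires two or more).
#' @param pseudocount Added to every count cell.
#' @param background Named numeric background frequencies over A/C/G/T;
#'   normalised internally.
#' @return An object of class `pssm` with elements `counts`, `probs`,
#'   `log_odds` (4 x width matrices, rows A/C/G/T), `width`, `background`,
#'   `pseudocount`.
#' @export
build_pssm <- function(seqs, pseudocount = 1,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(seqs) < 1) abort("need at least one sequence")
  w <- unique(nchar(seqs))
  if (length(w) != 1) abort("sequences must have equal length")
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGT]", seqs))) abort("sequences must be A/C/G/T only")
  background <- background[NT] / sum(background[NT])
  mat <- matrix(0L, 4, w, dimnames = list(NT, NULL))
  chars <- do.call(rbind, strsplit(seqs, NULL))
  for (j in seq_len(w)) {
    tb <- table(factor(chars[, j], levels = NT))
    mat[, j] <- as.integer(tb)
  }
  counts <- mat + pseudocount
  probs <- sweep(counts, 2, colSums(counts), "/")
  log_odds <- log(sweep(probs, 1, background, "/"))
  structure(list(counts = mat, probs = probs, log_odds = log_odds,
                 width = w, background = background,
                 pseudocount = pseudocount, n_seqs = length(seqs)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> width ", x$width, ", built from ", x$n_seqs, " sequence(s)\n",
      sep = "")
  cat("consensus: ", paste(NT[apply(x$log_odds, 2, which.max)], collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn build_pssm Long-format per-position frequencies and log-odds.
#' @param x A `pssm`.
#' @param ... Unused.
#' @method tidy pssm
#' @export
tidy.pssm <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$width), each = 4),
    nucleotide = rep(NT, x$width),
    count = as.vector(x$counts),
    prob = as.vector(x$probs),
    log_odds = as.vector(x$log_odds)
  )
}

#' @describeIn build_pssm One-row overview (width, information content).
#' @method glance pssm
#' @export
glance.pssm <- function(x, ...) {
  ic <- sum(x$probs * log2(sweep(x$probs, 1, x$background, "/")))
  tibble(width = x$width, n_seqs = x$n_seqs, information_content = ic,
         max_score = sum(apply(x$log_odds, 2, max)))
}

#' Exact score distribution of a PSSM under the background model
#'
#' @param pssm A `pssm`.
#' @return Tibble with columns `score` (descending), `prob`, `pvalue`
#'   (tail probability `P(S >= score)`).
#' @export
pssm_score_distribution <- function(pssm) {
  dist <- attr(pssm, ".dist")
  if (!is.null(dist)) return(dist)
  scores <- 0
  probs <- 1
  for (j in seq_len(pssm$width)) {
    s <- as.vector(outer(scores, pssm$log_odds[, j], "+"))
    p <- as.vector(outer(probs, pssm$background, "*"))
    # aggregate exactly equal sums without losing floating-point precision
    o <- order(s)
    s <- s[o]
    p <- p[o]
    grp <- cumsum(c(TRUE, diff(s) != 0))
    scores <- s[!duplicated(grp)]
    probs <- as.vector(rowsum(p, grp))
  }
  o <- order(scores, decreasing = TRUE)
  tibble(score = scores[o], prob = probs[o], pvalue = cumsum(probs[o]))
}

# cache the distribution inside the object (pssm objects are immutable)
with_score_distribution <- function(pssm) {
  if (is.null(attr(pssm, ".dist"))) {
    attr(pssm, ".dist") <- pssm_score_distribution(pssm)
  }
  pssm
}

#' Exact P-value for a PSSM score threshold
#'
#' @param pssm A `pssm`.
#' @param threshold Score threshold.
#' @return `P(score >= threshold)` for a random background word; 1 for
#'   `threshold = -Inf`.
#' @export
pssm_score_pvalue <- function(pssm, threshold) {
  d <- pssm_score_distribution(pssm)
  vapply(threshold, function(t) {
    keep <- d$score >= t - 1e-9
    if (!any(keep)) 0 else sum(d$prob[keep])
  }, numeric(1))
}

# minimal score whose tail P-value is <= p_max (Inf if none)
pssm_score_threshold <- function(pssm, p_max) {
  d <- pssm_score_distribution(pssm)
  ok <- d$pvalue <= p_max + 1e-12
  if (!any(ok)) Inf else min(d$score[ok])
}

# map a vector of scores to their exact tail P-values via the distribution
pssm_pvalue_lookup <- function(pssm, scores) {
  d <- pssm_score_distribution(pssm)
  # d$score descending; for each s, tail at the smallest attained score >= s
  idx <- findInterval(-(scores - 1e-9), -d$score)
  out <- rep(NA_real_, length(scores))
  out[idx >= 1] <- d$pvalue[idx[idx >= 1]]
  out[idx < 1] <- 0
  out
}

encode_nt <- function(seq) {
  match(strsplit(seq, NULL)[[1]], NT)   # N and others -> NA
}

# vectorized PSSM scores of every window of one encoded sequence strand;
# windows containing non-ACGT are NA
pssm_window_scores <- function(enc, lo) {
  w <- ncol(lo)
  L <- length(enc)
  nw <- L - w + 1L
  if (nw < 1) return(numeric(0))
  s <- numeric(nw)
  bad <- logical(nw)
  idx <- seq_len(nw)
  for (j in seq_len(w)) {
    e <- enc[idx + j - 1L]
    bad <- bad | is.na(e)
    e[is.na(e)] <- 1L
    s <- s + lo[cbind(e, j)]
  }
  s[bad] <- NA_real_
  s
}

#' Scan a genome for PSSM element hits
#'
#' Both strands of every replicon are scanned exhaustively; windows
#' containing N are skipped. A window is reported when its exact P-value is
#' at most `p_max`. Hits are reported as genomic intervals (`start <= end`)
#' with the element read 5' to 3' on `strand`.
#'
#' @param genome A `tss_genome`.
#' @param pssm A `pssm`.
#' @param p_max Element P-value cutoff in (0, 1].
#' @return Tibble: `replicon`, `strand`, `start`, `end`, `score`, `pvalue`.
#' @export
scan_elements <- function(genome, pssm, p_max) {
  stopifnot(p_max > 0, p_max <= 1)
  pssm <- with_score_distribution(pssm)
  thr <- pssm_score_threshold(pssm, p_max)
  w <- pssm$width
  lo <- pssm$log_odds
  res <- list()
  for (rep_id in names(genome$replicons)) {
    seq_f <- genome$replicons[[rep_id]]
    L <- nchar(seq_f)
    if (L < w) next
    enc_f <- match(strsplit(seq_f, NULL)[[1]], NT)
    enc_r <- rev(5L - enc_f)            # reverse complement in encoded space
    for (st in c("+", "-")) {
      enc <- if (st == "+") enc_f else enc_r
      s <- pssm_window_scores(enc, lo)
      hit <- which(!is.na(s) & s >= thr - 1e-9)
      if (length(hit) == 0) next
      if (st == "+") {
        start <- hit
        end <- hit + w - 1L
      } else {
        # position i on the revcomp corresponds to genomic [L-i-w+2, L-i+1]
        start <- L - hit - w + 2L
        end <- L - hit + 1L
      }
      res[[length(res) + 1L]] <- tibble(
        replicon = rep_id, strand = st, start = start, end = end,
        score = s[hit], pvalue = pssm_pvalue_lookup(pssm, s[hit])
      )
    }
  }
  out <- if (length(res)) list_rbind(res) else {
    tibble(replicon = character(), strand = character(), start = integer(),
           end = integer(), score = numeric(), pvalue = numeric())
  }
  arrange(out, .data$replicon, .data$start, .data$strand)
}

#' Information-content profile plot of a PSSM
#'
#' @param object A `pssm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pssm
#' @export
autoplot.pssm <- function(object, ...) {
  td <- tidy(object)
  td$ic <- td$prob * log2(td$prob / object$background[td$nucleotide])
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$position), y = .data$ic,
                                   fill = .data$nucleotide)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position", y = "information (bits)",
                  fill = "base") +
    ggplot2::theme_minimal()
}
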