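# End-to-end orchestration: call -> classify -> features -> orfs ->
# promoters -> tfbs -> report, with resumable intermediates and a
# machine-readable run report.

#' Assemble a pipeline configuration
#'
#' @param genome A `tss_genome`.
#' @param genes Gene tibble.
#' @param reads Read tibble.
#' @param priors Optional prior read set for relaxed contigs.
#' @param leaders Optional leader contigs for classification.
#' @param call A [tss_call_config()].
#' @param mtu An [mtu_config()].
#' @param rbs An [rbs_config()] or `NULL` to skip ORF discovery.
#' @param sigmas Named list of [sigma_model()]s (may be empty).
#' @param seeds Promoter-seed tibble (column `sigma` routes seeds to their
#'   model); required for profile-mode models.
#' @param tfbs A [gapped_motif_config()] or `NULL`.
#' @param operons Optional operon tibble.
#' @param prefixes Optional replicon-to-prefix map for feature names.
#' @param seed Integer; recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, genes, reads, priors = NULL,
                            leaders = NULL, call = tss_call_config(),
                            mtu = mtu_config(), rbs = NULL,
                            sigmas = list(), seeds = NULL, tfbs = NULL,
                            operons = NULL, prefixes = NULL, seed = 1L) {
  structure(list(genome = genome, genes = genes, reads = reads,
                 priors = priors, leaders = leaders, call = call, mtu = mtu,
                 rbs = rbs, sigmas = sigmas, seeds = seeds, tfbs = tfbs,
                 operons = operons, prefixes = prefixes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML names input paths (`genome`, `annotation`, `reads`, optional
#' `priors`) and parameter blocks (`call`, `mtu`, `rbs`, `sigmas`, `tfbs`);
#' every threshold of the analysis is surfaced here, nothing is hard-coded.
#' Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("genome", "annotation", "reads", "priors", "seeds", "call",
             "mtu", "rbs", "sigmas", "tfbs", "seed", "circular")
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    abort(paste0("unknown config keys: ", paste(extra, collapse = ", ")))
  }
  inputs <- load_inputs(y$genome, y$annotation, y$reads, y$priors,
                        circular = y$circular %||% FALSE)
  sigmas <- lapply(y$sigmas, function(s) do.call(sigma_model, s))
  names(sigmas) <- vapply(sigmas, function(s) s$name, character(1))
  seeds <- if (!is.null(y$seeds)) readr::read_tsv(y$seeds,
                                                  show_col_types = FALSE)
  pipeline_config(
    genome = inputs$genome, genes = inputs$genes, reads = inputs$reads,
    priors = inputs$priors,
    call = do.call(tss_call_config, y$call %||% list()),
    mtu = do.call(mtu_config, y$mtu %||% list()),
    rbs = if (!is.null(y$rbs)) do.call(rbs_config, y$rbs),
    sigmas = sigmas, seeds = seeds,
    tfbs = if (!is.null(y$tfbs)) do.call(gapped_motif_config, y$tfbs),
    seed = y$seed %||% 1L
  )
}

#' Run the full TSS-mapping pipeline
#'
#' Stages run in order: TSS calling, MTU classification, sRNA/asRNA feature
#' merging, ORF discovery, promoter prediction (two-phase profile search or
#' consensus string search per sigma model), TFBS scanning and upstream
#' extraction, then a run report with partition-checked counts. Precomputed
#' stage outputs may be supplied through `intermediates` to resume a run;
#' the pipeline is deterministic, so a resumed run equals a fresh one.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("call","classify","features","orfs","promoters","tfbs")`; later
#'   stages needing a skipped stage's output require it in `intermediates`.
#' @param intermediates Named list of precomputed outputs (`tss`,
#'   `classified`, `features`, ...).
#' @param out_dir Optional directory; when given, outputs and the JSON run
#'   report are written there.
#' @return A list of class `tssmap_run` with elements `tss`, `classified`,
#'   `features`, `relaxed`, `orfs`, `promoters`, `sigma_overlap`, `tfbs`,
#'   `upstream`, `summary`, `report`.
#' @export
run_pipeline <- function(config,
                         stages = c("call", "classify", "features", "orfs",
                                    "promoters", "tfbs"),
                         intermediates = list(), out_dir = NULL) {
  t0 <- Sys.time()
  res <- list()
  log_stage <- function(name, n) {
    inform(sprintf("[tssmap] %-10s %6d records", name, n))
  }

  if ("call" %in% stages) {
    res$tss <- call_tss(config$reads, config$call, config$prefixes)
  } else res$tss <- intermediates$tss %||% abort("no TSS available")
  log_stage("call", nrow(res$tss))

  res$relaxed <- if (!is.null(config$priors)) {
    relaxed_contigs_from_coverage(config$priors, res$tss, config$genome)
  }

  mtus <- build_mtus(config$genes, config$genome, config$mtu)
  if ("classify" %in% stages) {
    res$classified <- classify_tss(res$tss, mtus, config$genome,
                                   leaders = config$leaders,
                                   config = config$mtu)
  } else {
    res$classified <- intermediates$classified %||% abort("no classification")
  }
  log_stage("classify", nrow(res$classified))

  if ("features" %in% stages) {
    res$features <- merge_rna_features(res$classified, mtus, config$mtu,
                                       config$prefixes)
    log_stage("features", nrow(res$features))
  } else res$features <- intermediates$features

  if ("orfs" %in% stages && !is.null(config$rbs)) {
    orf_tss <- res$classified[
      res$classified$tss_class %in% c("mTSS", "lmTSS", "pmTSS", "sTSS"), ]
    res$orfs <- discover_orfs(orf_tss, config$genome, config$genes,
                              config$rbs, prefixes = config$prefixes)
    log_stage("orfs", nrow(res$orfs))
  } else res$orfs <- intermediates$orfs

  if ("promoters" %in% stages && length(config$sigmas)) {
    hit_sets <- list()
    for (nm in names(config$sigmas)) {
      sg <- config$sigmas[[nm]]
      hit_sets[[nm]] <- if (sg$mode == "string") {
        string_promoter_search(sg, config$genome, res$classified,
                               res$relaxed)
      } else {
        sd <- config$seeds[config$seeds$sigma == sg$name, , drop = FALSE]
        if (nrow(sd) < 2) {
          warn(sprintf("sigma %s skipped: fewer than 2 seed promoters", nm))
          NULL
        } else {
          run_two_phase(sd, sg, config$genome, res$classified, res$relaxed)
        }
      }
    }
    hit_sets <- hit_sets[!vapply(hit_sets, is.null, logical(1))]
    res$promoters <- if (length(hit_sets)) {
      list_rbind(lapply(hit_sets, as_tibble))
    }
    res$sigma_overlap <- if (length(hit_sets) >= 2) {
      cross_sigma_overlap(hit_sets)
    }
    log_stage("promoters", if (is.null(res$promoters)) 0L
              else nrow(res$promoters))
  } else res$promoters <- intermediates$promoters

  if ("tfbs" %in% stages && !is.null(config$tfbs)) {
    res$tfbs <- scan_gapped_motif(config$genome, config$genes, config$tfbs)
    res$tfbs <- correlate_tfbs_with_tss(res$tfbs, res$classified)
    log_stage("tfbs", nrow(res$tfbs))
  } else res$tfbs <- intermediates$tfbs

  res$upstream <- extract_unassigned_upstream(
    res$classified, res$promoters, config$genome)

  res$summary <- summarize_classification(res$classified, res$features %||%
                                            merge_rna_features(res$classified,
                                                               mtus,
                                                               config$mtu),
                                          config$genome, config$operons)

  class_counts <- setNames(res$summary$class_counts$n,
                           res$summary$class_counts$tss_class)
  report <- list(
    n_reads_in = sum(config$reads$count %||% rep(1, nrow(config$reads))),
    n_tss = nrow(res$tss),
    class_counts = as.list(class_counts),
    partition_ok = sum(class_counts) == nrow(res$classified),
    n_features = if (!is.null(res$features)) nrow(res$features) else NA,
    n_orfs_by_status = if (!is.null(res$orfs)) {
      as.list(table(res$orfs$status))
    },
    n_promoters_by_label = if (!is.null(res$promoters)) {
      as.list(table(paste(res$promoters$sigma, res$promoters$label)))
    },
    n_tfbs = if (!is.null(res$tfbs)) nrow(res$tfbs) else NA,
    seed = config$seed,
    config_hash = rlang::hash(strip_env(config)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  res$report <- report
  res <- structure(res, class = "tssmap_run")
  if (!is.null(out_dir)) {
    write_outputs(list(tss = res$classified, features = res$features,
                       promoters = res$promoters, orfs = res$orfs,
                       tfbs = res$tfbs), out_dir)
    rep_out <- report
    rep_out$elapsed_s <- NULL       # keep written outputs byte-reproducible
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

# configs are plain data; drop any environments so hashing is stable
strip_env <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) return(lapply(x, strip_env))
  x
}

#' @export
print.tssmap_run <- function(x, ...) {
  cat("<tssmap_run>\n")
  cat("  TSS called:      ", x$report$n_tss, "\n")
  cat("  classes:         ",
      paste(names(x$report$class_counts), unlist(x$report$class_counts),
            sep = "=", collapse = "  "), "\n")
  if (!is.null(x$orfs)) cat("  ORF calls:       ", nrow(x$orfs), "\n")
  if (!is.null(x$promoters)) cat("  promoter hits:   ", nrow(x$promoters), "\n")
  invisible(x)
}

#' @describeIn run_pipeline Classified TSS as a tibble.
#' @param x A `tssmap_run`.
#' @param ... Unused.
#' @method tidy tssmap_run
#' @export
tidy.tssmap_run <- function(x, ...) {
  out <- as_tibble(x$classified)
  out$merged_from <- NULL
  out
}

#' @describeIn run_pipeline One-row run overview.
#' @method glance tssmap_run
#' @export
glance.tssmap_run <- function(x, ...) {
  as_tibble(c(list(n_tss = x$report$n_tss), x$report$class_counts,
              list(n_promoters = if (is.null(x$promoters)) 0L
                   else nrow(x$promoters),
                   n_orfs = if (is.null(x$orfs)) 0L else nrow(x$orfs),
                   partition_ok = x$report$partition_ok)))
}

#' Class-count bar chart of a run or summary
#'
#' @param object A `tssmap_run` or `tss_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tss_summary
#' @export
autoplot.tss_summary <- function(object, ...) {
  ggplot2::ggplot(object$class_counts,
                  ggplot2::aes(x = .data$tss_class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "TSS") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tss_summary
#' @method autoplot tssmap_run
#' @export
autoplot.tssmap_run <- function(object, ...) autoplot(object$summary, ...)

#' Histogram of mTSS 5'-UTR lengths
#'
#' @param summary A `tss_summary`.
#' @param binwidth Histogram bin width (nt).
#' @return A ggplot.
#' @export
plot_utr5_distribution <- function(summary, binwidth = 10) {
  df <- tibble(utr5 = summary$utr5_lengths)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$utr5)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = summary$utr5_mean, linetype = 2) +
    ggplot2::labs(x = "5'-UTR length (nt)", y = "mTSS") +
    ggplot2::theme_minimal()
}
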