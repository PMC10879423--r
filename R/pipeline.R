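#' Default pipeline configuration
#'
#' Returns the configuration of the default simulated study: three unigene
#' sets (one CCS-like, two assembly-like), the TPM scan grid 0/1/5/10,
#' CD-HIT-style collapse at 0.90 identity, 100-bp shared blocks at 0.95
#' identity, 20-bp UTR-extension margin, 50-bp isoform gap, 100-residue
#' minimum ORF, WPGMA row clustering cut into 4 expression groups.
#'
#' @param seed integer seed used for the simulation.
#' @return a named list understood by \code{\link{run_pipeline}}.
#' @export
default_config <- function(seed = 42) {
  list(
    simulate = TRUE,
    seed = seed,
    n_genes = 120,
    thresholds = c(0, 1, 5, 10),
    tolerance = 0.25,
    rule = "max",
    identity_threshold = 0.90,
    k = 15,
    min_block = 100,
    min_identity = 0.95,
    margin = 20,
    min_isoform_gap = 50,
    min_aa = 100,
    linkage = "wpgma",
    k_cut = 4
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full unigene-set comparison pipeline
#'
#' Executes simulate (or load) -> per-set statistics -> TPM -> threshold
#' scan -> filter -> redundancy collapse -> ORF calling -> shared blocks ->
#' homology grouping and structural classification -> summary -> expression
#' clustering, and optionally writes a report bundle (per-set statistics
#' TSV, scan TSV, groups TSV, calls TSV, cluster labels TSV, summary JSON,
#' config YAML and a run log).
#'
#' @param config a configuration list (see \code{\link{default_config}}) or
#'   the path of a YAML file holding one. In non-simulate mode the list
#'   must carry \code{fasta} (named list of FASTA paths) and \code{counts}
#'   (named list of counts TSV paths) instead of \code{simulate = TRUE}.
#' @param out_dir optional output directory for the report bundle.
#' @param truth optional pre-built \code{sim_truth} with emitted sets and
#'   counts; overrides \code{config$simulate}.
#' @return invisibly, a list of class \code{"uniset_run"} with all stage
#'   results (\code{truth} in simulate mode, \code{set_stats},
#'   \code{scan}, \code{dedup}, \code{cds}, \code{groups}, \code{calls},
#'   \code{report}, \code{clusters}, \code{config}).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         truth = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)

  if (!is.null(truth)) {
    stopifnot(inherits(truth, "sim_truth"))
    if (is.null(truth$counts)) stop("truth lacks counts; run simulate_counts()")
    sets <- lapply(truth$sets, identity)
    counts <- truth$counts
  } else if (isTRUE(cfg$simulate)) {
    truth <- stage("simulate", simulate_study(seed = cfg$seed,
                                              n_genes = cfg$n_genes))
    sets <- lapply(truth$sets, identity)
    counts <- truth$counts
  } else {
    sets <- stage("load-fasta", {
      if (is.null(cfg$fasta)) stop("config$fasta missing")
      lapply(cfg$fasta, function(p) as_seqs(read_fasta(p)))
    })
    counts <- stage("load-counts", {
      if (is.null(cfg$counts)) stop("config$counts missing")
      lapply(cfg$counts, read_expression)
    })
  }
  log_lines <- c(
    sprintf("[config] seed=%s sets=%s", format(cfg$seed),
            paste(names(sets), collapse = ",")),
    sprintf("[config] %s", paste(sprintf("%s=%s",
      c("identity_threshold", "k", "min_block", "min_identity", "margin",
        "min_isoform_gap", "min_aa", "linkage", "k_cut"),
      c(cfg$identity_threshold, cfg$k, cfg$min_block, cfg$min_identity,
        cfg$margin, cfg$min_isoform_gap, cfg$min_aa, cfg$linkage,
        cfg$k_cut)), collapse = " ")))

  set_stats <- stage("stats", do.call(rbind, lapply(names(sets), function(s) {
    st <- length_stats(sets[[s]])
    data.frame(set_label = s, n = st$n, max_len = st$max_len,
               mean_len = st$mean_len, median_len = st$median_len,
               n50 = st$n50, gc_ratio = st$gc_ratio,
               stringsAsFactors = FALSE)
  })))

  tpm <- stage("tpm", lapply(names(sets), function(s) {
    compute_tpm(counts[[s]], nchar(sets[[s]]))
  }))
  names(tpm) <- names(sets)

  scan <- stage("scan", threshold_scan(sets, tpm, thresholds = cfg$thresholds,
                                       tolerance = cfg$tolerance,
                                       rule = cfg$rule))
  sel <- cfg[["threshold"]] %||% scan$selected_threshold
  if (is.na(sel)) {
    sel <- max(cfg$thresholds)
    log_lines <- c(log_lines, "[scan] no converging threshold; using max of grid")
  }
  log_lines <- c(log_lines, sprintf("[scan] selected threshold %s", sel))
  filtered <- lapply(names(sets), function(s) {
    sets[[s]][scan$survivors[[as.character(sel)]][[s]]]
  })
  names(filtered) <- names(sets)

  dedup <- stage("dedup", lapply(filtered, dedup_greedy,
                                 identity_threshold = cfg$identity_threshold,
                                 k = cfg$k))
  reps <- lapply(names(sets), function(s) filtered[[s]][dedup[[s]]$representatives])
  names(reps) <- names(sets)
  redundant <- unlist(lapply(dedup, `[[`, "redundant"))
  names(redundant) <- unlist(lapply(dedup, function(d) names(d$redundant)))
  redundant_sets <- rep(names(sets),
                        vapply(dedup, function(d) length(d$redundant), integer(1)))
  names(redundant_sets) <- names(redundant)

  cds <- stage("orf", do.call(rbind, lapply(names(reps), function(s) {
    predict_cds_set(reps[[s]], min_aa = cfg$min_aa)
  })))
  ## like the source study, members without a predictable CDS take no part
  ## in the structural comparison
  coding <- lapply(reps, function(x) x[names(x) %in% cds$unigene_id])
  log_lines <- c(log_lines, sprintf(
    "[orf] %d/%d representatives carry a CDS >= %d aa",
    sum(lengths(coding)), sum(lengths(reps)), cfg$min_aa))

  groups <- stage("blocks+groups",
                  build_groups(coding, k = cfg$k, min_block = cfg$min_block,
                               min_identity = cfg$min_identity,
                               anchor_set = names(sets)[1L]))
  calls <- stage("classify",
                 classify_members(groups, cds_calls = cds,
                                  margin = cfg$margin,
                                  min_isoform_gap = cfg$min_isoform_gap,
                                  redundant = redundant,
                                  redundant_sets = redundant_sets,
                                  k = cfg$k))
  report <- stage("summarize",
                  summarize_reconcile(groups, calls,
                                      min_isoform_gap = cfg$min_isoform_gap,
                                      k = cfg$k))

  clusters <- stage("exprclust", {
    z <- do.call(rbind, lapply(names(reps), function(s) {
      tpm[[s]][intersect(rownames(tpm[[s]]), names(coding[[s]])), ,
               drop = FALSE]
    }))
    z <- suppressWarnings(zscore_rows(z))
    tree <- hcluster(z, linkage = cfg$linkage)
    list(tree = tree, labels = cut_tree(tree, cfg$k_cut))
  })

  run <- structure(list(truth = truth, sets = sets, counts = counts,
                        tpm = tpm, set_stats = set_stats, scan = scan,
                        selected_threshold = sel, filtered = filtered,
                        dedup = dedup, cds = cds, groups = groups,
                        calls = calls, report = report, clusters = clusters,
                        config = cfg, log = log_lines),
                   class = "uniset_run")
  if (!is.null(out_dir)) write_bundle(run, out_dir)
  invisible(run)
}

write_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(run$set_stats, "set_stats.tsv")
  tsv(run$scan$table, "threshold_scan.tsv")
  tsv(run$scan$scores, "threshold_scores.tsv")
  tsv(run$groups$members, "groups.tsv")
  tsv(run$groups$blocks, "blocks.tsv")
  tsv(run$calls, "calls.tsv")
  tsv(run$cds, "cds_calls.tsv")
  tsv(data.frame(unigene_id = names(run$clusters$labels),
                 expr_group = run$clusters$labels), "expression_groups.tsv")
  summary <- list(selected_threshold = run$selected_threshold,
                  n_groups = run$report$n_groups,
                  per_set = run$report$per_set,
                  exclusive_isoforms = run$report$exclusive_isoforms)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  yaml::write_yaml(run$config, file.path(out_dir, "config.yaml"))
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  if (!is.null(run$truth)) {
    for (s in names(run$sets)) {
      write_fasta(run$sets[[s]], file.path(out_dir, paste0(s, ".fasta")))
      write_expression(run$counts[[s]],
                       file.path(out_dir, paste0(s, "_counts.tsv")))
    }
    write_ledger(run$truth$emissions, file.path(out_dir, "truth_ledger.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.uniset_run <- function(x, ...) {
  cat("unigene-set comparison run\n")
  print(x$set_stats, row.names = FALSE)
  cat("selected TPM threshold:", x$selected_threshold, "\n")
  print(x$report)
  invisible(x)
}
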