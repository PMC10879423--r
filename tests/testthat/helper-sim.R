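# The default simulated study (seed 42) feeds several recovery checks; it
# is computed once per test session and cached.

.sim_cache <- new.env(parent = emptyenv())

get_default_run <- function() {
  if (is.null(.sim_cache$run)) {
    .sim_cache$run <- run_pipeline(default_config(seed = 42))
  }
  .sim_cache$run
}

# planted set-exclusive isoform scenario: the second isoform of the ten most
# abundant two-isoform genes is forced into the hybrid set and kept out of
# the CCS-like and short-read sets; assembly capture is saturated and
# misassembly artifacts disabled so exclusivity is the only signal
plant_exclusive_scenario <- function(seed = 42, n_plant = 10) {
  truth <- simulate_truth(n_genes = 120, seed = seed)
  tx <- truth$transcripts
  iso_n <- table(tx$gene_id)
  two_iso <- names(iso_n)[iso_n == 2]
  gene_ab <- tapply(tx$abundance, tx$gene_id, sum)[two_iso]
  genes <- two_iso[order(-gene_ab)][seq_len(min(n_plant, length(two_iso)))]
  planted <- paste0(genes, ".i2")
  truth <- emit_ccs_set(truth, exclude_isoforms = planted)
  truth <- emit_assembly_set(truth, style = "hybrid", capture = 1e4,
                             chimera_rate = 0, concat_rate = 0,
                             redundancy_rate = 0, include_isoforms = planted)
  truth <- emit_assembly_set(truth, style = "shortread", capture = 1e4,
                             chimera_rate = 0, concat_rate = 0,
                             redundancy_rate = 0, exclude_isoforms = planted)
  truth <- simulate_counts(truth)
  list(truth = truth, planted = planted)
}

# recovery of representative-anchored UTR truncations from a pipeline run:
# for every CCS emission acting as a classification reference with a
# truncation of at least min_trunc bases, is there a member reporting the
# matching extension with evidence within +/- tol bases?
utr_recovery <- function(run, end, min_trunc = 40, tol = 14) {
  led <- run$truth$emissions
  calls <- run$calls
  refs <- unique(calls$ref_id[calls$call != "redundant" & !is.na(calls$ref_id)])
  ccs <- led[led$set_label == "ccs", ]
  tr <- ccs[ccs[[paste0("trunc", end)]] >= min_trunc &
            ccs$unigene_id %in% refs, ]
  ok <- vapply(seq_len(nrow(tr)), function(r) {
    id <- tr$unigene_id[r]
    tval <- tr[[paste0("trunc", end)]][r]
    sub <- calls[!is.na(calls$ref_id) & calls$ref_id == id &
                 calls$call == paste0("utr", end, "_extension"), ]
    ev <- if (end == 5) sub$ev_ext5 else sub$ev_ext3
    any(!is.na(ev) & abs(ev - tval) <= tol)
  }, logical(1))
  list(rate = mean(ok), n = length(ok))
}
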