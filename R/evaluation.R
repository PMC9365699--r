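#' Residual profiles straight from counts
#'
#' Convenience wrapper: [preprocess()] then [center_and_smooth()] (and
#' optionally [denoise()]).
#'
#' @param counts A [spot_counts()].
#' @param positions A `gene_positions` table.
#' @param reference_barcodes Reference set (`NULL` = unsupervised).
#' @param config An [inference_config()].
#' @param denoise_output Apply [denoise()] before returning (default
#'   `FALSE`).
#' @return A `sicnv_residuals`.
#' @export
infer_residuals <- function(counts, positions, reference_barcodes = NULL,
                            config = inference_config(),
                            denoise_output = FALSE) {
  res <- center_and_smooth(preprocess(counts, positions, config),
                           reference_barcodes, config)
  if (denoise_output) res <- denoise(res, config) else res
}

#' End-to-end synthetic benchmark
#'
#' Generates a synthetic tissue, treats spots whose majority genotype is the
#' founding diploid clone as "benign", selects a pure-benign reference,
#' infers residuals for the remaining (observation) spots, clusters them
#' into clones at the true clone number, and scores clone recovery
#' (adjusted Rand index) plus per-clone gene-category accuracy against the
#' rounded-average ground truth computed over the inferred clones.
#'
#' @param sim_config A [simulation_config()].
#' @param inf_config An [inference_config()].
#' @param k Number of clones to cut; default the true number of distinct
#'   majority-genotype labels among observation spots.
#' @return List with the tissue, counts, truth, reference barcodes,
#'   assignment, `recovery_score`, `clone_accuracies` (per inferred clone)
#'   and `mean_accuracy`.
#' @export
synthetic_benchmark <- function(sim_config = simulation_config(),
                                inf_config = inference_config(),
                                k = NULL) {
  tissue <- bin_cells_to_spots(simulate_tissue(sim_config))
  counts <- sample_expression(tissue)
  truth <- ground_truth_categories(tissue)
  positions <- simulated_gene_positions(sim_config)
  counts <- qc_filter_spots(counts, qc_config())
  bcs <- barcodes(counts)
  spot_clone <- truth$spot_clone[bcs]

  benign <- bcs[spot_clone == "clone1"]
  observed <- setdiff(bcs, benign)
  if (length(observed) < 2) {
    stop("fewer than 2 non-benign spots; no clonal structure to recover")
  }
  benign_counts <- spot_counts(counts$counts[benign, , drop = FALSE],
                               counts$section_of[benign])
  reference <- select_pure_reference(benign_counts, positions, inf_config)

  res <- infer_residuals(counts, positions, reference, inf_config)
  obs_res <- res
  obs_res$values <- res$values[observed, , drop = FALSE]
  dend <- cluster_spots(obs_res)
  truth_labels <- spot_clone[observed]
  if (is.null(k)) k <- length(unique(truth_labels))
  assignment <- assign_clones(dend, k = k)
  score <- clone_recovery_score(assignment, truth_labels)

  hmm <- hmm_states(res, groups = assignment$clone, config = inf_config)
  inferred_cat <- t(apply(hmm$states, 1, map_hmm_state_to_category))
  dimnames(inferred_cat) <- dimnames(hmm$states)
  truth_cat <- truth_categories_for_assignment(tissue, assignment$clone)
  shared_genes <- intersect(colnames(inferred_cat), colnames(truth_cat))
  accs <- vapply(rownames(inferred_cat), function(cl) {
    clone_accuracy(inferred_cat[cl, shared_genes], truth_cat[cl, shared_genes])
  }, 1)
  list(tissue = tissue, counts = counts, truth = truth,
       reference = reference, dendrogram = dend, assignment = assignment,
       truth_labels = truth_labels, recovery_score = score,
       hmm = hmm, clone_accuracies = accs, mean_accuracy = mean(accs),
       k = k)
}
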