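#' Inference configuration
#'
#' Numerical knobs of the siCNV core. Defaults follow the documented
#' defaults of expression-based CNV inference tools: genes with mean raw
#' count below `gene_mean_cutoff` are dropped, centred values are clipped to
#' `+/- max_centered_value`, profiles are smoothed with a pyramidal moving
#' average over `smoothing_window_genes` genes, denoising zeroes entries
#' within `denoise_sd_multiplier` reference standard deviations, and the HMM
#' decodes six states with Gaussian emissions centred at `log2` of
#' `hmm_state_levels` (relative copy levels; the third level must be 1 =
#' copy-neutral).
#'
#' @param gene_mean_cutoff Minimum mean raw count per gene (default 0.1).
#' @param max_centered_value Clip bound for centred values (default 3).
#' @param smoothing_window_genes Odd window width in genes (default 101).
#' @param denoise_sd_multiplier Denoise threshold in reference SDs (1.5).
#' @param hmm_state_levels Six increasing relative copy levels
#'   (default 0.01, 0.5, 1, 1.5, 2, 3); level 3 of the HMM (value 1) is
#'   copy-neutral.
#' @param hmm_transition_prob Cross-state transition probability (1e-6).
#' @param hmm_on_denoised Decode the HMM on denoised rather than raw
#'   residuals (default `FALSE`).
#' @param excluded_chromosomes Chromosomes removed before analysis
#'   (default `"chrM"`).
#' @return An `inference_config` list.
#' @export
inference_config <- function(gene_mean_cutoff = 0.1,
                             max_centered_value = 3,
                             smoothing_window_genes = 101,
                             denoise_sd_multiplier = 1.5,
                             hmm_state_levels = c(0.01, 0.5, 1, 1.5, 2, 3),
                             hmm_transition_prob = 1e-6,
                             hmm_on_denoised = FALSE,
                             excluded_chromosomes = "chrM") {
  stopifnot(gene_mean_cutoff >= 0,
            smoothing_window_genes >= 1,
            smoothing_window_genes %% 2 == 1,
            length(hmm_state_levels) == 6,
            all(diff(hmm_state_levels) > 0))
  if (abs(hmm_state_levels[3] - 1) > 1e-12) {
    stop("the third HMM state level must be 1 (copy-neutral)")
  }
  structure(list(gene_mean_cutoff = gene_mean_cutoff,
                 max_centered_value = max_centered_value,
                 smoothing_window_genes = smoothing_window_genes,
                 denoise_sd_multiplier = denoise_sd_multiplier,
                 hmm_state_levels = hmm_state_levels,
                 hmm_transition_prob = hmm_transition_prob,
                 hmm_on_denoised = hmm_on_denoised,
                 excluded_chromosomes = excluded_chromosomes),
            class = "inference_config")
}

#' Preprocess counts for CNV inference
#'
#' Restricts genes to those with a genome position (unmapped genes are
#' dropped with a warning) off the excluded chromosomes, removes genes whose
#' mean raw count across spots is below `gene_mean_cutoff`, scales every
#' spot to the median spot total, applies `log2(1 + x)` and orders columns
#' by genome rank.
#'
#' @param counts A [spot_counts()] (after QC).
#' @param positions A `gene_positions` table.
#' @param config An [inference_config()].
#' @return A `sicnv_expr` list: `expr` (dense spots x genes matrix) and
#'   `genes` (the surviving, genome-ordered position rows).
#' @export
preprocess <- function(counts, positions, config = inference_config()) {
  stopifnot(inherits(counts, "spot_counts"))
  positions <- positions[!(positions$chromosome %in% config$excluded_chromosomes), ,
                         drop = FALSE]
  unmapped <- setdiff(colnames(counts$counts), positions$gene_id)
  if (length(unmapped) > 0) {
    warning(length(unmapped), " gene(s) without genome position dropped")
  }
  shared <- intersect(positions$gene_id, colnames(counts$counts))
  if (length(shared) == 0) stop("no genes shared between counts and positions")
  m <- counts$counts[, shared, drop = FALSE]
  keep <- Matrix::colMeans(m) >= config$gene_mean_cutoff
  m <- m[, keep, drop = FALSE]
  genes <- positions[match(colnames(m), positions$gene_id), , drop = FALSE]
  ord <- order(genes$genome_rank)
  genes <- genes[ord, , drop = FALSE]
  m <- as.matrix(m[, ord, drop = FALSE])
  per_chrom <- table(genes$chromosome)
  if (all(per_chrom < config$smoothing_window_genes)) {
    stop("every chromosome has fewer than smoothing_window_genes (",
         config$smoothing_window_genes, ") surviving genes")
  }
  totals <- rowSums(m)
  m <- m * (stats::median(totals) / totals)
  structure(list(expr = log2(1 + m), genes = genes), class = "sicnv_expr")
}

pyramidal_weight_matrix <- function(n_genes, window) {
  k <- (window - 1) / 2
  W <- matrix(0, n_genes, n_genes)
  for (j in seq_len(n_genes)) {
    lo <- max(1, j - k); hi <- min(n_genes, j + k)
    w <- (k + 1) - abs((lo:hi) - j)
    W[lo:hi, j] <- w / sum(w)
  }
  W
}

#' Centre and smooth log-expression into residual profiles
#'
#' The siCNV signal: per-gene reference means are subtracted, values are
#' clipped, each chromosome is smoothed with a pyramidal (triangular)
#' weighted moving average whose weights renormalise at chromosome edges,
#' the per-spot median is subtracted, and per-gene reference means are
#' subtracted once more so that the reference is exactly centred.
#'
#' @param x A `sicnv_expr` from [preprocess()].
#' @param reference_barcodes Barcodes of the reference set; `NULL` means
#'   unsupervised (all spots are their own reference).
#' @param config An [inference_config()].
#' @return A `sicnv_residuals` list: `values` (spots x genes, log2 ratio to
#'   reference), `genes`, `reference_barcodes`.
#' @export
center_and_smooth <- function(x, reference_barcodes = NULL,
                              config = inference_config()) {
  stopifnot(inherits(x, "sicnv_expr"))
  expr <- x$expr
  if (is.null(reference_barcodes)) reference_barcodes <- rownames(expr)
  if (!all(reference_barcodes %in% rownames(expr))) {
    stop("reference barcodes missing from expression matrix")
  }
  if (length(reference_barcodes) == 0) stop("empty reference set")
  ref <- function(m) m[reference_barcodes, , drop = FALSE]

  v <- sweep(expr, 2, colMeans(ref(expr)))
  v <- pmin(pmax(v, -config$max_centered_value), config$max_centered_value)

  for (chrom in unique(x$genes$chromosome)) {
    cols <- which(x$genes$chromosome == chrom)
    if (length(cols) == 0) {
      warning("chromosome ", chrom, " has no genes; skipped")
      next
    }
    W <- pyramidal_weight_matrix(length(cols), config$smoothing_window_genes)
    v[, cols] <- v[, cols, drop = FALSE] %*% W
  }
  v <- sweep(v, 1, apply(v, 1, stats::median))
  v <- sweep(v, 2, colMeans(ref(v)))
  structure(list(values = v, genes = x$genes,
                 reference_barcodes = reference_barcodes),
            class = "sicnv_residuals")
}

#' Denoise residual profiles
#'
#' Entries with absolute value at most `denoise_sd_multiplier` times the
#' pooled standard deviation of the reference residuals are set to zero;
#' larger entries are kept unchanged. If the reference SD is zero the matrix
#' is returned unmodified with a warning.
#'
#' @param residuals A `sicnv_residuals`.
#' @param config An [inference_config()].
#' @return A `sicnv_residuals` with thresholded `values`.
#' @export
denoise <- function(residuals, config = inference_config()) {
  stopifnot(inherits(residuals, "sicnv_residuals"))
  refv <- residuals$values[residuals$reference_barcodes, , drop = FALSE]
  sigma <- stats::sd(as.vector(refv))
  if (!is.finite(sigma) || sigma == 0) {
    warning("reference residual SD is zero; denoising skipped")
    return(residuals)
  }
  v <- residuals$values
  v[abs(v) <= config$denoise_sd_multiplier * sigma] <- 0
  residuals$values <- v
  residuals
}

viterbi_gaussian <- function(obs, means, sigma, t_cross) {
  n <- length(obs); k <- length(means)
  loge <- -0.5 * outer(obs, means, "-")^2 / sigma^2
  logt <- matrix(log(t_cross), k, k)
  diag(logt) <- log(1 - (k - 1) * t_cross)
  delta <- matrix(-Inf, n, k)
  psi <- matrix(0L, n, k)
  delta[1, ] <- log(1 / k) + loge[1, ]
  if (n > 1) {
    for (i in 2:n) {
      cand <- delta[i - 1, ] + logt
      psi[i, ] <- max.col(t(cand), ties.method = "first")
      delta[i, ] <- cand[cbind(psi[i, ], seq_len(k))] + loge[i, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (i in (n - 1):1) path[i] <- psi[i + 1, path[i + 1]]
  path
}

#' Decode discrete copy states with a six-state HMM
#'
#' For each group (per-spot singletons by default, or clone memberships) the
#' per-gene mean residual sequence is decoded chromosome by chromosome with
#' exact Viterbi over six states. Emissions are Gaussian, centred at
#' `log2(hmm_state_levels)`, with a shared standard deviation estimated from
#' the pooled reference residuals; the self-transition probability is
#' `1 - 5 t` with cross transitions `t = hmm_transition_prob`. State 3 is
#' copy-neutral.
#'
#' @param residuals A `sicnv_residuals` (raw by default; set
#'   `hmm_on_denoised` in the config and pass denoised residuals to match).
#' @param groups `NULL` for per-spot decoding (mode `"cells"`), or a named
#'   vector/factor mapping barcodes to group labels (mode `"samples"`).
#' @param config An [inference_config()].
#' @return A `hmm_states` list: `states` (group x gene integer matrix in
#'   1..6), `genes`, `mode`.
#' @export
hmm_states <- function(residuals, groups = NULL, config = inference_config()) {
  stopifnot(inherits(residuals, "sicnv_residuals"))
  v <- residuals$values
  if (is.null(groups)) {
    mode <- "cells"
    profiles <- v
  } else {
    mode <- "samples"
    groups <- groups[!is.na(groups)]
    if (!all(names(groups) %in% rownames(v))) {
      stop("group barcodes missing from residual matrix")
    }
    labs <- sort(unique(as.character(groups)))
    profiles <- matrix(0, length(labs), ncol(v),
                       dimnames = list(labs, colnames(v)))
    for (lab in labs) {
      members <- names(groups)[as.character(groups) == lab]
      if (length(members) == 0) stop("group ", lab, " has no spots")
      profiles[lab, ] <- colMeans(v[members, , drop = FALSE])
    }
  }
  refv <- v[residuals$reference_barcodes, , drop = FALSE]
  sigma <- max(stats::sd(as.vector(refv)), 1e-6)
  means <- log2(config$hmm_state_levels)
  states <- matrix(3L, nrow(profiles), ncol(profiles),
                   dimnames = dimnames(profiles))
  for (chrom in unique(residuals$genes$chromosome)) {
    cols <- which(residuals$genes$chromosome == chrom)
    for (r in seq_len(nrow(profiles))) {
      states[r, cols] <- viterbi_gaussian(profiles[r, cols], means, sigma,
                                          config$hmm_transition_prob)
    }
  }
  structure(list(states = states, genes = residuals$genes, mode = mode),
            class = "hmm_states")
}

#' Call region-level events from HMM states
#'
#' Emits maximal runs of consecutive genes (genome order, within one
#' chromosome) sharing a non-neutral state as events, mirroring the
#' region-file dialect.
#'
#' @param hmm A `hmm_states` object.
#' @return Data frame: `group`, `chromosome`, `gene_start`, `gene_end`,
#'   `rank_start`, `rank_end`, `n_genes`, `state`, `direction`.
#' @export
call_region_events <- function(hmm) {
  stopifnot(inherits(hmm, "hmm_states"))
  out <- list()
  for (r in rownames(hmm$states)) {
    for (chrom in unique(hmm$genes$chromosome)) {
      cols <- which(hmm$genes$chromosome == chrom)
      s <- hmm$states[r, cols]
      rl <- rle(s)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      for (j in which(rl$values != 3L)) {
        i0 <- cols[starts[j]]; i1 <- cols[ends[j]]
        out[[length(out) + 1L]] <- data.frame(
          group = r, chromosome = chrom,
          gene_start = hmm$genes$gene_id[i0], gene_end = hmm$genes$gene_id[i1],
          rank_start = hmm$genes$genome_rank[i0],
          rank_end = hmm$genes$genome_rank[i1],
          n_genes = rl$lengths[j], state = rl$values[j],
          direction = if (rl$values[j] < 3) "loss" else "gain",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(group = character(), chromosome = character(),
                      gene_start = character(), gene_end = character(),
                      rank_start = integer(), rank_end = integer(),
                      n_genes = integer(), state = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write residuals as TSV (genes in genome order x spots)
#'
#' @param residuals A `sicnv_residuals`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_residuals <- function(residuals, path) {
  m <- t(residuals$values)
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
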