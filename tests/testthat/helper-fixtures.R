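# In-code fixture builders shared across the suite.

# tiny gene-position file: one row per gene, tab-separated, no header
write_positions_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

make_positions <- function(n_genes, chromosome = "chr1",
                           gene_ids = sprintf("g%04d", seq_len(n_genes))) {
  gene_positions(data.frame(gene_id = gene_ids, chromosome = chromosome,
                            start = seq_len(n_genes) * 1000,
                            stop = seq_len(n_genes) * 1000 + 500))
}

make_counts <- function(m, section = "S1") {
  if (is.null(rownames(m))) rownames(m) <- paste0("bc", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%04d", seq_len(ncol(m)))
  spot_counts(m, stats::setNames(rep(section, nrow(m)), rownames(m)))
}

# residual container without running the pipeline
make_residuals <- function(values, reference_barcodes = rownames(values),
                           chromosome = "chr1") {
  if (is.null(rownames(values))) rownames(values) <- paste0("bc", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("g%04d", seq_len(ncol(values)))
  structure(list(values = values,
                 genes = make_positions(ncol(values), chromosome,
                                        gene_ids = colnames(values)),
                 reference_barcodes = reference_barcodes),
            class = "sicnv_residuals")
}

make_hmm <- function(states, mode = "samples", chromosome = "chr1") {
  if (is.null(rownames(states))) rownames(states) <- paste0("r", seq_len(nrow(states)))
  if (is.null(colnames(states))) colnames(states) <- sprintf("g%04d", seq_len(ncol(states)))
  structure(list(states = states,
                 genes = make_positions(ncol(states), chromosome,
                                        gene_ids = colnames(states)),
                 mode = mode),
            class = "hmm_states")
}

# hand-built tissue: cells at given positions with given genotype rows
make_tissue <- function(xy, genotype_of_cell, genotypes, config) {
  cells <- data.frame(id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
                      parent = NA_integer_, genotype = genotype_of_cell,
                      alive = TRUE, birth_step = 0L)
  structure(list(cells = cells, genotypes = genotypes,
                 events = data.frame(), config = config),
            class = "synthetic_tissue")
}

# all set partitions of seq_len(n) as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (v in seq_len(next_max)) {
      recurse(c(labels, v), max(next_max, v + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# permutation-model oracle for the adjusted Rand index: the expected
# together-in-both pair count is averaged over every relabelling of one
# partition (this reproduces the hypergeometric expectation independently)
all_perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    cache[[key]] <<- perms(seq_len(n))
    cache[[key]]
  }
})

brute_force_ari <- function(a, b) {
  n <- length(a)
  p1 <- utils::combn(n, 2)[1, ]
  p2 <- utils::combn(n, 2)[2, ]
  co_a <- a[p1] == a[p2]
  s_obs <- sum(co_a & (b[p1] == b[p2]))
  s_perm <- vapply(all_perms(n), function(p) {
    bp <- b[p]
    sum(co_a & (bp[p1] == bp[p2]))
  }, 1)
  s_a <- sum(choose(table(a), 2))
  s_b <- sum(choose(table(b), 2))
  max_s <- (s_a + s_b) / 2
  exp_s <- mean(s_perm)
  if (max_s == exp_s) return(1)
  (s_obs - exp_s) / (max_s - exp_s)
}
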