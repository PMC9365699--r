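#' Map HMM states to copy-number categories
#'
#' States 1 and 2 are deletions, state 3 is neutral, states 4-6 are
#' amplifications.
#'
#' @param state Integer vector of states in 1..6.
#' @return Character vector in `{"deletion", "neutral", "amplification"}`.
#' @export
map_hmm_state_to_category <- function(state) {
  if (any(is.na(state)) || any(state < 1 | state > 6) ||
      any(state != round(state))) {
    stop("states must be integers in 1..6")
  }
  c("deletion", "deletion", "neutral",
    "amplification", "amplification", "amplification")[state]
}

#' Per-clone gene-category accuracy
#'
#' Fraction of genes whose inferred category (deletion/neutral/
#' amplification) equals the ground-truth category. Symmetric; 1 iff the
#' vectors are identical.
#'
#' @param inferred,truth Character vectors over the same gene universe.
#' @return Fraction in `[0, 1]`.
#' @export
clone_accuracy <- function(inferred, truth) {
  if (length(inferred) == 0 || length(truth) == 0) {
    stop("empty gene set")
  }
  if (length(inferred) != length(truth)) {
    stop("category vectors differ in length")
  }
  mean(inferred == truth)
}

#' Dual-threshold configuration for organ-wide event maps
#'
#' @param dataset_fraction A gene-level event must be present in at least
#'   this fraction of all spots (default 0.35).
#' @param section_fraction ... and in at least this fraction of the spots of
#'   the spot's own section (default 0.45).
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(dataset_fraction = 0.35, section_fraction = 0.45) {
  stopifnot(dataset_fraction >= 0, dataset_fraction <= 1,
            section_fraction >= 0, section_fraction <= 1)
  structure(list(dataset_fraction = dataset_fraction,
                 section_fraction = section_fraction),
            class = "threshold_config")
}

#' Organ-wide event-count map
#'
#' Counts per spot the gene-level events (non-neutral HMM states, decoded
#' per spot) that survive the dual threshold: a gene's event is retained for
#' a spot only if at least `dataset_fraction` of all spots carry a
#' non-neutral state at that gene and at least `section_fraction` of the
#' spots of that spot's section do. Comparisons are inclusive (`>=`).
#'
#' @param hmm A `hmm_states` decoded per spot (mode `"cells"`).
#' @param section_of Named character vector: barcode -> section label.
#' @param config A [threshold_config()].
#' @return Data frame: `barcode`, `section`, `event_count`.
#' @export
global_event_map <- function(hmm, section_of, config = threshold_config()) {
  stopifnot(inherits(hmm, "hmm_states"))
  bcs <- rownames(hmm$states)
  missing <- setdiff(bcs, names(section_of))
  if (length(missing) > 0) {
    stop("no section for barcode(s): ", paste(utils::head(missing), collapse = ", "))
  }
  sec <- section_of[bcs]
  ev <- hmm$states != 3L
  global_frac <- colMeans(ev)
  keep_global <- global_frac >= config$dataset_fraction
  counts <- numeric(length(bcs))
  for (s in unique(sec)) {
    rows <- which(sec == s)
    sec_frac <- colMeans(ev[rows, , drop = FALSE])
    keep <- keep_global & sec_frac >= config$section_fraction
    counts[rows] <- rowSums(ev[rows, keep, drop = FALSE])
  }
  data.frame(barcode = bcs, section = unname(sec), event_count = counts,
             stringsAsFactors = FALSE)
}

#' Sweep the dual-threshold grid
#'
#' Reproducible analog of the threshold-selection procedure: evaluates
#' retained-event totals over both fractions from 10% to 90% in 5%
#' increments.
#'
#' @inheritParams global_event_map
#' @param fractions Grid of fractions (default `seq(0.10, 0.90, 0.05)`).
#' @return Data frame: `dataset_fraction`, `section_fraction`,
#'   `total_events` (sum of per-spot retained counts).
#' @export
threshold_sweep <- function(hmm, section_of,
                            fractions = seq(0.10, 0.90, by = 0.05)) {
  grid <- expand.grid(dataset_fraction = fractions,
                      section_fraction = fractions)
  grid$total_events <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- threshold_config(grid$dataset_fraction[i], grid$section_fraction[i])
    sum(global_event_map(hmm, section_of, cfg)$event_count)
  }, 1)
  grid
}

#' Read a per-spot SNV count table
#'
#' TSV with columns barcode, chrom, pos, ref_count, alt_count.
#'
#' @param path TSV path (header expected).
#' @return Data frame with those columns plus `locus` (`chrom:pos`).
#' @export
read_snv_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  snv_counts(df)
}

#' Validate an SNV count table
#'
#' @param df Data frame with columns `barcode`, `chrom`, `pos`,
#'   `ref_count`, `alt_count`.
#' @return The validated data frame with a `locus` column.
#' @export
snv_counts <- function(df) {
  need <- c("barcode", "chrom", "pos", "ref_count", "alt_count")
  stopifnot(all(need %in% names(df)))
  if (any(df$ref_count < 0) || any(df$alt_count < 0)) {
    stop("allele counts must be non-negative")
  }
  df$locus <- paste0(df$chrom, ":", df$pos)
  if (anyDuplicated(df[, c("barcode", "locus")])) {
    stop("one row per (barcode, locus) required")
  }
  df
}

#' Clonal variant allele fractions
#'
#' Pools reference and alternative allele reads over the spots of each
#' clone. Reports both the alternate-allele fraction `alt / (ref + alt)`
#' (undefined and `NA` when no reads) and the raw `ref:alt` ratio, since
#' either convention may be wanted downstream.
#'
#' @param snv A validated [snv_counts()] data frame.
#' @param assignment A `clone_assignment` or named vector barcode -> clone.
#' @return Data frame: `clone`, `locus`, `ref`, `alt`, `alt_fraction`,
#'   `ref_alt_ratio`, `covered` (any reads).
#' @export
clonal_vaf <- function(snv, assignment) {
  a <- if (inherits(assignment, "clone_assignment")) assignment$clone else assignment
  unknown <- setdiff(unique(snv$barcode), names(a))
  if (length(unknown) > 0) {
    warning(length(unknown), " barcode(s) without clone assignment dropped")
    snv <- snv[snv$barcode %in% names(a), , drop = FALSE]
  }
  snv$clone <- a[snv$barcode]
  agg <- stats::aggregate(cbind(ref = ref_count, alt = alt_count) ~ clone + locus,
                          data = snv, FUN = sum)
  tot <- agg$ref + agg$alt
  agg$alt_fraction <- ifelse(tot > 0, agg$alt / tot, NA_real_)
  agg$ref_alt_ratio <- ifelse(agg$alt > 0, agg$ref / agg$alt, NA_real_)
  agg$covered <- tot > 0
  agg[order(agg$clone, agg$locus), ]
}

#' Spot coverage percentage per clone and locus
#'
#' Percentage of a clone's spots with at least one read (ref + alt > 0)
#' covering the locus, relative to all spots assigned to the clone.
#'
#' @inheritParams clonal_vaf
#' @return Data frame: `clone`, `locus`, `n_covered`, `n_spots`,
#'   `percentage`.
#' @export
spot_percentage <- function(snv, assignment) {
  a <- if (inherits(assignment, "clone_assignment")) assignment$clone else assignment
  clone_sizes <- table(a)
  if (any(clone_sizes == 0)) stop("empty clone in assignment")
  snv <- snv[snv$barcode %in% names(a), , drop = FALSE]
  snv$clone <- a[snv$barcode]
  covered <- snv[snv$ref_count + snv$alt_count > 0, , drop = FALSE]
  grid <- expand.grid(clone = names(clone_sizes), locus = unique(snv$locus),
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) return(data.frame(clone = character(), locus = character(),
                                         n_covered = integer(), n_spots = integer(),
                                         percentage = numeric()))
  key <- paste(covered$clone, covered$locus)
  n_cov <- vapply(paste(grid$clone, grid$locus),
                  function(k) sum(key == k), 1L, USE.NAMES = FALSE)
  grid$n_covered <- n_cov
  grid$n_spots <- as.integer(clone_sizes[grid$clone])
  grid$percentage <- 100 * grid$n_covered / grid$n_spots
  grid[order(grid$clone, grid$locus), ]
}
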