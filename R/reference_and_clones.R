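#' Select a "pure benign" reference set
#'
#' Replaces the manual inspection step with a quantitative rule: residuals
#' for the benign spots are computed unsupervised (reference = all benign
#' spots) and denoised, per-spot burden is the mean absolute residual, the
#' spots are clustered, and the returned set is the largest dendrogram node
#' whose members' median burden is at most the `burden_quantile` quantile of
#' all spot burdens. The returned set must contain at least 10% of the input
#' spots.
#'
#' @param benign_counts A [spot_counts()] restricted to benign-annotated
#'   spots (QC-filtered).
#' @param positions A `gene_positions` table.
#' @param config An [inference_config()].
#' @param burden_quantile Quantile of the burden distribution that the
#'   selected node's median burden may not exceed (default 0.5).
#' @return Character vector of reference barcodes.
#' @export
select_pure_reference <- function(benign_counts, positions,
                                  config = inference_config(),
                                  burden_quantile = 0.5) {
  stopifnot(burden_quantile > 0, burden_quantile < 1)
  expr <- preprocess(benign_counts, positions, config)
  res <- denoise(center_and_smooth(expr, NULL, config), config)
  burden <- rowMeans(abs(res$values))
  cutoff <- stats::quantile(burden, burden_quantile, names = FALSE)
  if (all(burden <= cutoff) || stats::sd(burden) == 0) {
    return(rownames(res$values))
  }
  dend <- cluster_spots(res)
  nodes <- dendrogram_nodes(dend)
  # the root is the whole input, not a subgroup, and its median burden equals
  # the cutoff by construction at the default quantile -- never a candidate
  nodes <- nodes[names(nodes) != as.character(nrow(dend$hclust$merge))]
  ok <- vapply(nodes, function(m) stats::median(burden[m]) <= cutoff, TRUE)
  sizes <- vapply(nodes, length, 1L)
  min_size <- ceiling(0.10 * nrow(res$values))
  usable <- ok & sizes >= min_size
  if (!any(usable)) {
    stop("no dendrogram node with median burden <= the ", burden_quantile,
         " quantile holds >= 10% of spots; choose a reference node manually")
  }
  nodes[[which(usable)[which.max(sizes[usable])]]]
}

#' Hierarchically cluster spots by residual profile
#'
#' Agglomerative clustering of genome-ordered residual rows (default Ward
#' linkage on Euclidean distance); deterministic given the input.
#'
#' @param residuals A `sicnv_residuals` (or a plain numeric matrix with
#'   barcode rownames).
#' @param linkage `hclust` method (default `"ward.D2"`).
#' @param metric `dist` method (default `"euclidean"`).
#' @return A `spot_dendrogram`: the `hclust` tree plus leaf barcodes.
#' @export
cluster_spots <- function(residuals, linkage = "ward.D2", metric = "euclidean") {
  v <- if (inherits(residuals, "sicnv_residuals")) residuals$values else residuals
  if (nrow(v) < 2) stop("need at least 2 spots to cluster")
  if (any(!is.finite(v))) stop("residual matrix contains non-finite values")
  hc <- stats::hclust(stats::dist(v, method = metric), method = linkage)
  structure(list(hclust = hc, barcodes = rownames(v)), class = "spot_dendrogram")
}

#' Enumerate dendrogram nodes
#'
#' Every internal node of the merge tree, as the set of its member barcodes.
#' Node ids follow `hclust` merge indices; leaves are included as singleton
#' nodes with negative ids.
#'
#' @param dend A `spot_dendrogram`.
#' @param include_leaves Also return singleton leaf nodes (default `TRUE`).
#' @return Named list: node id -> character vector of member barcodes.
#' @export
dendrogram_nodes <- function(dend, include_leaves = TRUE) {
  hc <- dend$hclust
  n <- length(dend$barcodes)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k) {
      if (k < 0) dend$barcodes[-k] else members[[k]]
    }))
  }
  names(members) <- as.character(seq_along(members))
  if (include_leaves) {
    leaves <- stats::setNames(as.list(dend$barcodes),
                              as.character(-seq_len(n)))
    members <- c(members, leaves)
  }
  members
}

#' Assign spots to clones
#'
#' Either cuts the tree into `k` clones or extracts explicit dendrogram
#' nodes. Clone labels `A`, `B`, ... are assigned in decreasing clone size;
#' clones with fewer than `min_display_spots` members are masked from
#' display (but retain their assignment).
#'
#' @param dend A `spot_dendrogram` from [cluster_spots()].
#' @param k Target number of clones (tree cut), or
#' @param nodes Character/integer vector of node ids (see
#'   [dendrogram_nodes()]); spots outside the selected nodes are left
#'   unassigned.
#' @param min_display_spots Display threshold (default 10).
#' @return A `clone_assignment` list: `clone` (named character vector
#'   barcode -> label), `sizes`, `display_mask`.
#' @export
assign_clones <- function(dend, k = NULL, nodes = NULL, min_display_spots = 10) {
  stopifnot(inherits(dend, "spot_dendrogram"))
  if (is.null(k) == is.null(nodes)) stop("supply exactly one of k or nodes")
  if (!is.null(k)) {
    cut <- stats::cutree(dend$hclust, k = k)
    groups <- split(dend$barcodes, cut)
  } else {
    all_nodes <- dendrogram_nodes(dend)
    missing <- setdiff(as.character(nodes), names(all_nodes))
    if (length(missing) > 0) stop("unknown node id(s): ", paste(missing, collapse = ", "))
    groups <- all_nodes[as.character(nodes)]
    flat <- unlist(groups)
    if (anyDuplicated(flat)) {
      stop("selected nodes overlap; shared barcodes: ",
           paste(unique(flat[duplicated(flat)]), collapse = ", "))
    }
  }
  ord <- order(-vapply(groups, length, 1L),
               vapply(groups, function(g) min(g), ""))
  groups <- groups[ord]
  labels <- make_clone_labels(length(groups))
  clone <- character(0)
  for (i in seq_along(groups)) {
    clone[groups[[i]]] <- labels[i]
  }
  sizes <- stats::setNames(vapply(groups, length, 1L), labels)
  structure(list(clone = clone, sizes = sizes,
                 display_mask = sizes >= min_display_spots),
            class = "clone_assignment")
}

make_clone_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else
    c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

#' Chance-adjusted clone recovery score
#'
#' Adjusted Rand index between an inferred clone assignment and ground-truth
#' labels over the same spots: 1 for identical partitions, about 0 for
#' chance agreement, negative for worse than chance.
#'
#' @param assignment A `clone_assignment` or a named vector barcode -> label.
#' @param truth Named vector barcode -> ground-truth label.
#' @return Numeric score in `[-1, 1]`.
#' @export
clone_recovery_score <- function(assignment, truth) {
  a <- if (inherits(assignment, "clone_assignment")) assignment$clone else assignment
  shared <- intersect(names(a), names(truth))
  if (length(shared) == 0) stop("assignment and truth share no barcodes")
  a <- a[shared]; b <- truth[shared]
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (s_ij - expected) / (max_index - expected)
}

#' Export a clone assignment as Loupe-importable CSV
#'
#' @param assignment A `clone_assignment`.
#' @param path Output CSV (`Barcode,Clone`).
#' @return `path`, invisibly.
#' @export
write_clone_assignment <- function(assignment, path) {
  utils::write.csv(data.frame(Barcode = names(assignment$clone),
                              Clone = unname(assignment$clone)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
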