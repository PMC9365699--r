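#' Branch length for a clone-tree edge
#'
#' Under sequential acquisition of copy-number events, the pixel length of
#' the edge from a parent to a descendant clone is
#' `100 * log2(|Z_child| - |Z_parent|) + 300`, where `Z` is a clone's event
#' set; the additive constant keeps single-event branches visible.
#'
#' @param parent_set,child_set Character vectors of event identifiers;
#'   `parent_set` must be a subset of `child_set` and the child must carry at
#'   least one additional event.
#' @return Branch length in pixels.
#' @export
branch_length <- function(parent_set, child_set) {
  if (!all(parent_set %in% child_set)) {
    stop("parent event set is not nested in the child event set")
  }
  d <- length(setdiff(child_set, parent_set))
  if (d < 1) {
    stop("degenerate edge: descendant carries no additional events")
  }
  100 * log2(d) + 300
}

#' Clone circle diameter
#'
#' A clone holding `s` spots is drawn with diameter `10 * log2(s)` pixels.
#' A single-spot clone gets diameter 0 (visually degenerate but legal).
#'
#' @param n_spots Number of spots assigned to the clone (>= 1).
#' @return Diameter in pixels.
#' @export
clone_diameter <- function(n_spots) {
  if (any(n_spots < 1)) stop("a clone must contain at least one spot")
  10 * log2(n_spots)
}

#' Build a clone tree from event sets
#'
#' Clones sharing copy-number events are assumed to share ancestry because
#' an event, once acquired, cannot revert. The tree is grown by recursive
#' maximal-shared-subset grouping: the root carries the empty event set; at
#' each level the clones sharing the largest common event intersection are
#' grouped under an ancestor bearing exactly that intersection (an observed
#' clone whose event set equals the intersection becomes the ancestor
#' itself); ties are broken by lexicographic event order. When spot
#' positions are supplied, an edge between two unobserved ancestors whose
#' subtree clones are not spatially proximate is flagged uncertain.
#'
#' @param event_sets Named list: clone label -> character vector of event
#'   ids. Sets must be distinct.
#' @param clone_sizes Optional named integer vector of spots per clone,
#'   used to compute node diameters via [clone_diameter()].
#' @param spot_positions Optional named list: clone label -> two-column
#'   matrix of spot coordinates.
#' @param proximity_threshold Maximum min inter-clone spot distance treated
#'   as proximate (default 4 array-pitch units of 100, i.e. 400).
#' @return A `clone_tree` list: `nodes` (data frame id, label, observed,
#'   n_events, n_spots, diameter_px) with an `events` list-column, and
#'   `edges` (parent, child, length_px, uncertain).
#' @export
build_clone_tree <- function(event_sets, clone_sizes = NULL,
                             spot_positions = NULL,
                             proximity_threshold = 400) {
  stopifnot(length(event_sets) >= 1, !is.null(names(event_sets)))
  event_sets <- lapply(event_sets, function(z) sort(unique(as.character(z))))
  keys <- vapply(event_sets, paste, "", collapse = "\r")
  if (anyDuplicated(keys)) {
    stop("duplicate event sets: ",
         paste(names(event_sets)[duplicated(keys) | duplicated(keys, fromLast = TRUE)],
               collapse = ", "))
  }

  nodes <- list()
  edges <- list()
  new_node <- function(events, clones) {
    id <- length(nodes) + 1L
    obs <- clones[vapply(event_sets[clones], setequal, TRUE, y = events)]
    label <- if (length(obs) == 1) obs else paste0("anc", id)
    nodes[[id]] <<- list(id = id, label = label, events = events,
                         observed = length(obs) == 1)
    id
  }
  set_string <- function(s) paste(sort(s), collapse = "\r")

  descend <- function(clones, parent_events, node_id) {
    remaining <- clones[!vapply(event_sets[clones], setequal, TRUE, y = parent_events)]
    repeat {
      if (length(remaining) == 0) return(invisible(NULL))
      if (length(remaining) == 1) {
        cl <- remaining
        cid <- new_node(event_sets[[cl]], cl)
        edges[[length(edges) + 1L]] <<- list(parent = node_id, child = cid,
                                             clones = cl)
        return(invisible(NULL))
      }
      best <- NULL
      for (i in seq_along(remaining)[-length(remaining)]) {
        for (j in (i + 1):length(remaining)) {
          I <- intersect(event_sets[[remaining[i]]], event_sets[[remaining[j]]])
          if (length(I) <= length(parent_events)) next
          if (is.null(best) || length(I) > length(best) ||
              (length(I) == length(best) && set_string(I) < set_string(best))) {
            best <- I
          }
        }
      }
      if (is.null(best)) {
        for (cl in remaining) {
          cid <- new_node(event_sets[[cl]], cl)
          descend(cl, event_sets[[cl]], cid)
          edges[[length(edges) + 1L]] <<- list(parent = node_id, child = cid,
                                               clones = cl)
        }
        return(invisible(NULL))
      }
      grp <- remaining[vapply(event_sets[remaining],
                              function(z) all(best %in% z), TRUE)]
      cid <- new_node(best, grp)
      descend(grp, best, cid)
      edges[[length(edges) + 1L]] <<- list(parent = node_id, child = cid,
                                           clones = grp)
      remaining <- setdiff(remaining, grp)
    }
  }

  root_id <- new_node(character(0), names(event_sets))
  descend(names(event_sets), character(0), root_id)

  node_df <- data.frame(
    id = vapply(nodes, `[[`, 1L, "id"),
    label = vapply(nodes, `[[`, "", "label"),
    observed = vapply(nodes, `[[`, TRUE, "observed"),
    n_events = vapply(nodes, function(n) length(n$events), 1L),
    stringsAsFactors = FALSE)
  node_df$events <- lapply(nodes, `[[`, "events")
  node_df$n_spots <- if (is.null(clone_sizes)) NA_integer_ else
    unname(clone_sizes[node_df$label])
  node_df$diameter_px <- NA_real_
  sized <- !is.na(node_df$n_spots) & node_df$n_spots >= 1
  node_df$diameter_px[sized] <- clone_diameter(node_df$n_spots[sized])

  edge_df <- data.frame(
    parent = vapply(edges, `[[`, 1L, "parent"),
    child = vapply(edges, `[[`, 1L, "child"),
    stringsAsFactors = FALSE)
  edge_df$length_px <- vapply(seq_len(nrow(edge_df)), function(i) {
    branch_length(nodes[[edge_df$parent[i]]]$events,
                  nodes[[edge_df$child[i]]]$events)
  }, 1)
  subtree_clones <- lapply(edges, `[[`, "clones")
  edge_df$uncertain <- FALSE
  if (!is.null(spot_positions)) {
    for (i in seq_len(nrow(edge_df))) {
      p <- edge_df$parent[i]; ch <- edge_df$child[i]
      if (nodes[[ch]]$observed || nodes[[p]]$observed) next
      sibs <- which(edge_df$parent == p & edge_df$child != ch)
      if (length(sibs) == 0) next
      own <- do.call(rbind, spot_positions[subtree_clones[[i]]])
      other <- do.call(rbind, spot_positions[unlist(subtree_clones[sibs])])
      if (is.null(own) || is.null(other)) next
      d <- min(sqrt(outer(own[, 1], other[, 1], "-")^2 +
                    outer(own[, 2], other[, 2], "-")^2))
      edge_df$uncertain[i] <- d > proximity_threshold
    }
  }
  structure(list(nodes = node_df, edges = edge_df), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d nodes (%d observed), %d edges\n",
              nrow(x$nodes), sum(x$nodes$observed), nrow(x$edges)))
  invisible(x)
}

#' Export a clone tree to Newick (+ JSON sidecar)
#'
#' Branch lengths are in pixels; internal (ancestor) nodes keep their
#' labels. The sidecar records each node's event list, diameter, ancestor
#' flag and the uncertain edges.
#'
#' @param tree A `clone_tree`.
#' @param newick_path Output Newick file.
#' @param json_path Optional sidecar path (default: newick path with
#'   `.json`).
#' @return `newick_path`, invisibly.
#' @export
write_clone_tree <- function(tree, newick_path,
                             json_path = paste0(newick_path, ".json")) {
  writeLines(paste0(newick_string(tree, tree$nodes$id[1]), ";"), newick_path)
  side <- list(
    nodes = lapply(seq_len(nrow(tree$nodes)), function(i) {
      list(label = tree$nodes$label[i],
           events = as.list(tree$nodes$events[[i]]),
           ancestor = !tree$nodes$observed[i],
           diameter_px = tree$nodes$diameter_px[i])
    }),
    uncertain_edges = lapply(which(tree$edges$uncertain), function(i) {
      list(parent = tree$nodes$label[tree$edges$parent[i]],
           child = tree$nodes$label[tree$edges$child[i]])
    }))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(newick_path)
}

newick_string <- function(tree, node_id) {
  kids <- tree$edges$child[tree$edges$parent == node_id]
  lab <- tree$nodes$label[node_id]
  if (length(kids) == 0) return(lab)
  parts <- vapply(kids, function(k) {
    len <- tree$edges$length_px[tree$edges$child == k]
    paste0(newick_string(tree, k), ":", format(len, digits = 15))
  }, "")
  paste0("(", paste(parts, collapse = ","), ")", lab)
}

hamming_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(m[i, ] != m[j, ])
  }
  stats::as.dist(d)
}

fitch_score <- function(tree, char_matrix) {
  tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_char <- ncol(char_matrix)
  masks <- matrix(0L, n_tip + tree$Nnode, n_char)
  masks[seq_len(n_tip), ] <-
    bitwShiftL(1L, char_matrix[tree$tip.label, , drop = FALSE] - 1L)
  score <- 0L
  done <- logical(n_tip + tree$Nnode)
  done[seq_len(n_tip)] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    if (!done[parent]) {
      masks[parent, ] <- masks[child, ]
      done[parent] <- TRUE
    } else {
      inter <- bitwAnd(masks[parent, ], masks[child, ])
      un <- bitwOr(masks[parent, ], masks[child, ])
      empty <- inter == 0L
      score <- score + sum(empty)
      masks[parent, ] <- ifelse(empty, un, inter)
    }
  }
  score
}

#' Maximum-parsimony clone tree from gene-level states
#'
#' Each gene is a multistate character (HMM states 1..6); genes without a
#' call are imputed to state 3 (diploid). For up to 8 clones every unrooted
#' topology is scored exhaustively by Fitch small parsimony and the minimum
#' is returned; for more clones a neighbour-joining start tree is refined by
#' nearest-neighbour-interchange hill climbing. The score is the total
#' number of state changes.
#'
#' @param state_matrix Clones x genes integer matrix of states in 1..6
#'   (`NA` allowed, imputed to 3); at least 3 clones.
#' @return A `parsimony_tree` list: `tree` (unrooted `phylo`), `score`,
#'   `method` (`"exhaustive"`, `"nni"`, or `"star"`).
#' @export
parsimony_tree <- function(state_matrix) {
  m <- as.matrix(state_matrix)
  if (nrow(m) < 3) stop("need at least 3 clones")
  if (is.null(rownames(m))) rownames(m) <- paste0("clone", seq_len(nrow(m)))
  m[is.na(m)] <- 3L
  storage.mode(m) <- "integer"
  if (any(m < 1L | m > 6L)) stop("states must lie in 1..6")
  if (all(apply(m, 2, function(col) length(unique(col)) == 1))) {
    warning("all clone profiles identical; returning star tree with score 0")
    star <- ape::stree(nrow(m), type = "star", tip.label = rownames(m))
    star$edge.length <- rep(0, nrow(star$edge))
    return(structure(list(tree = star, score = 0L, method = "star"),
                     class = "parsimony_tree"))
  }
  if (nrow(m) <= 8) {
    cands <- phangorn::allTrees(nrow(m), rooted = FALSE, tip.label = rownames(m))
    scores <- vapply(cands, fitch_score, 0L, char_matrix = m)
    best <- which.min(scores)
    return(structure(list(tree = cands[[best]], score = scores[best],
                          method = "exhaustive"),
                     class = "parsimony_tree"))
  }
  tree <- ape::unroot(ape::nj(hamming_dist(m)))
  tree$edge.length <- NULL
  score <- fitch_score(tree, m)
  repeat {
    nbrs <- phangorn::nni(tree)
    nscores <- vapply(nbrs, fitch_score, 0L, char_matrix = m)
    if (min(nscores) >= score) break
    best <- which.min(nscores)
    tree <- nbrs[[best]]
    score <- nscores[best]
  }
  structure(list(tree = tree, score = score, method = "nni"),
            class = "parsimony_tree")
}

#' Consensus clone event sets from HMM states
#'
#' Automates the merge of region-level HMM calls into per-clone event sets:
#' region events spanning at least `min_genes_per_event` genes become clone
#' events, and events on the same chromosome with the same direction are
#' unified into one event identity across clones when their gene spans
#' overlap at least `min_reciprocal_overlap` reciprocally.
#'
#' @param hmm A `hmm_states` object decoded per clone (mode `"samples"`).
#' @param min_genes_per_event Minimum event size in genes (default 20).
#' @param min_reciprocal_overlap Reciprocal span overlap required to share
#'   an identity (default 0.5).
#' @return Named list clone -> character vector of event ids (keys
#'   `chromosome:direction:index`), with the underlying region table in
#'   attribute `"events"`.
#' @export
consensus_events_from_states <- function(hmm, min_genes_per_event = 20,
                                         min_reciprocal_overlap = 0.5) {
  regions <- call_region_events(hmm)
  regions <- regions[regions$n_genes >= min_genes_per_event, , drop = FALSE]
  clones <- rownames(hmm$states)
  out <- stats::setNames(rep(list(character(0)), length(clones)), clones)
  if (nrow(regions) == 0) {
    attr(out, "events") <- regions
    return(out)
  }
  regions$event_id <- NA_character_
  for (grp in unique(paste(regions$chromosome, regions$direction))) {
    idx <- which(paste(regions$chromosome, regions$direction) == grp)
    comp <- seq_along(idx)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      ra <- regions[idx[a], ]; rb <- regions[idx[b], ]
      ov <- min(ra$rank_end, rb$rank_end) - max(ra$rank_start, rb$rank_start) + 1
      if (ov >= min_reciprocal_overlap * ra$n_genes &&
          ov >= min_reciprocal_overlap * rb$n_genes) {
        old <- comp[b]
        comp[comp == old] <- comp[a]
      }
    }
    starts <- vapply(unique(comp), function(cc) min(regions$rank_start[idx[comp == cc]]), 1)
    comp_rank <- match(comp, unique(comp)[order(starts)])
    regions$event_id[idx] <- paste0(regions$chromosome[idx], ":",
                                    regions$direction[idx], ":", comp_rank)
  }
  for (cl in clones) {
    out[[cl]] <- sort(unique(regions$event_id[regions$group == cl]))
  }
  attr(out, "events") <- regions
  out
}
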