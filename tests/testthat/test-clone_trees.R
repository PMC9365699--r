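test_that("branch lengths and clone diameters follow the printed formulas", {
  expect_equal(branch_length(character(0), "e1"), 300)        # one extra event
  expect_equal(branch_length("e1", c("e1", "e2", "e3")), 400) # 100*log2(2)+300
  expect_equal(branch_length(character(0), paste0("e", 1:8)), 600)
  expect_error(branch_length("e1", "e1"), "degenerate")
  expect_error(branch_length(c("e1", "e9"), c("e1", "e2")), "nested")

  expect_equal(clone_diameter(2), 10)
  expect_equal(clone_diameter(1024), 100)
  expect_equal(clone_diameter(1), 0)
  expect_error(clone_diameter(0), "at least one")
})

test_that("clone trees group by maximal shared event subsets", {
  # nesting chain: the observed empty-set clone becomes the root
  chain <- build_clone_tree(list(A = character(0), B = "e1", C = c("e1", "e2")))
  expect_equal(nrow(chain$nodes), 3)
  expect_true(all(chain$nodes$observed))
  expect_equal(chain$nodes$label[1], "A")
  labs <- chain$nodes$label
  expect_equal(chain$edges$length_px, c(300, 300))
  edge_pairs <- paste(labs[chain$edges$parent], labs[chain$edges$child])
  expect_setequal(edge_pairs, c("A B", "B C"))

  # shared event without an observed carrier -> unobserved ancestor
  pair <- build_clone_tree(list(B = c("e1", "e2"), C = c("e1", "e3")))
  anc <- pair$nodes[!pair$nodes$observed & pair$nodes$n_events > 0, ]
  expect_equal(nrow(anc), 1)
  expect_equal(anc$events[[1]], "e1")
  kids <- pair$edges$child[pair$edges$parent == anc$id]
  expect_setequal(pair$nodes$label[kids], c("B", "C"))

  # disjoint event sets attach directly to the root
  disj <- build_clone_tree(list(B = "e1", C = "e2"))
  root <- disj$nodes$id[disj$nodes$n_events == 0]
  expect_setequal(disj$nodes$label[disj$edges$child[disj$edges$parent == root]],
                  c("B", "C"))
  expect_equal(nrow(disj$nodes), 3)

  expect_error(build_clone_tree(list(A = c("e1", "e2"), B = c("e2", "e1"))),
               "duplicate")
})

test_that("no-reversal nesting holds on every edge for random event sets", {
  set.seed(17)
  universe <- paste0("e", 1:12)
  for (trial in 1:25) {
    sets <- list()
    repeat {
      sets <- lapply(seq_len(sample(2:6, 1)), function(i) {
        sort(sample(universe, sample(0:6, 1)))
      })
      names(sets) <- paste0("c", seq_along(sets))
      if (!anyDuplicated(vapply(sets, paste, "", collapse = "|"))) break
    }
    tree <- build_clone_tree(sets)
    for (i in seq_len(nrow(tree$edges))) {
      p_ev <- tree$nodes$events[[tree$edges$parent[i]]]
      c_ev <- tree$nodes$events[[tree$edges$child[i]]]
      expect_true(all(p_ev %in% c_ev))
      expect_gt(tree$edges$length_px[i], 0)
    }
  }
})

test_that("diameters and spatial uncertainty flags are attached", {
  sets <- list(B = c("e1", "e2"), C = c("e1", "e3"),
               D = c("e5", "e6"), E = c("e5", "e7"))
  sizes <- c(B = 2, C = 9, D = 1024, E = 1)
  far <- list(B = cbind(0, 0), C = cbind(10, 0),
              D = cbind(5000, 5000), E = cbind(5010, 5000))
  tree <- build_clone_tree(sets, clone_sizes = sizes, spot_positions = far,
                           proximity_threshold = 400)
  expect_equal(tree$nodes$diameter_px[tree$nodes$label == "B"], 10)
  expect_equal(tree$nodes$diameter_px[tree$nodes$label == "D"], 100)
  # the two unobserved ancestors hang far apart -> both root edges uncertain
  anc_edges <- which(!tree$nodes$observed[tree$edges$child] &
                     !tree$nodes$observed[tree$edges$parent])
  expect_true(any(tree$edges$uncertain[anc_edges]))
  # edges to observed clones are never flagged
  obs_edges <- which(tree$nodes$observed[tree$edges$child])
  expect_false(any(tree$edges$uncertain[obs_edges]))

  near <- lapply(far, function(m) m * 0.01)
  tree2 <- build_clone_tree(sets, spot_positions = near,
                            proximity_threshold = 400)
  expect_false(any(tree2$edges$uncertain))
})

test_that("Newick export round-trips topology and branch lengths", {
  sets <- list(B = c("e1", "e2"), C = c("e1", "e3", "e4"),
               D = c("e5", "e6"), E = c("e5", "e7"))
  tree <- build_clone_tree(sets)
  nwk <- tempfile(fileext = ".nwk")
  write_clone_tree(tree, nwk)
  ph <- ape::read.tree(nwk)
  expect_setequal(ph$tip.label, c("B", "C", "D", "E"))
  # every exported edge length is recovered exactly
  expect_setequal(round(ph$edge.length, 9), round(tree$edges$length_px, 9))
  # sibling structure: B with C, D with E
  pairs <- ape::prop.part(ph)
  expect_true(any(vapply(pairs, function(p)
    setequal(ph$tip.label[p], c("B", "C")) || setequal(ph$tip.label[p], c("D", "E")),
    TRUE)))
  side <- jsonlite::read_json(paste0(nwk, ".json"))
  expect_equal(length(side$nodes), nrow(tree$nodes))

  # JSON sidecar marks ancestors
  anc_flags <- vapply(side$nodes, function(n) n$ancestor, TRUE)
  expect_equal(sum(anc_flags), sum(!tree$nodes$observed))
})

test_that("Fitch scoring matches phangorn on arbitrary topologies", {
  set.seed(23)
  for (trial in 1:10) {
    n <- sample(4:9, 1)
    m <- matrix(sample(1:6, n * 8, replace = TRUE), n, 8,
                dimnames = list(paste0("t", 1:n), NULL))
    tree <- ape::rtree(n, tip.label = rownames(m), br = NULL)
    tree <- ape::unroot(tree)
    pd <- phangorn::phyDat(m, type = "USER", levels = 1:6)
    expect_equal(sicnv:::fitch_score(tree, m),
                 phangorn::parsimony(tree, pd))
  }
})

test_that("parsimony search finds the exhaustive optimum", {
  # 3 clones: a single unrooted topology; score must equal the oracle
  m3 <- matrix(c(1, 3, 6,  3, 3, 4,  2, 3, 3), 3, 3,
               dimnames = list(c("A", "B", "C"), NULL))
  pt <- parsimony_tree(m3)
  pd <- phangorn::phyDat(m3, type = "USER", levels = 1:6)
  expect_equal(pt$score, phangorn::parsimony(pt$tree, pd))

  # identical rows -> star tree with score 0
  expect_warning(star <- parsimony_tree(matrix(3, 4, 5,
                                               dimnames = list(LETTERS[1:4], NULL))),
                 "identical")
  expect_equal(star$score, 0)
  expect_equal(star$method, "star")

  # characters supporting ((A,B),(C,D)) pick that topology
  m4 <- matrix(c(4, 4, 3, 3,
                 6, 6, 3, 3,
                 3, 3, 2, 2,
                 3, 3, 1, 1), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  pt4 <- parsimony_tree(m4)
  want <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  expect_equal(phangorn::RF.dist(pt4$tree, want), 0)
  expect_equal(pt4$method, "exhaustive")

  expect_error(parsimony_tree(m3[1:2, ]), "at least 3")

  # > 8 clones goes through NJ + NNI and still scores correctly
  set.seed(31)
  m10 <- matrix(sample(1:6, 10 * 12, replace = TRUE), 10, 12,
                dimnames = list(paste0("c", 1:10), NULL))
  pt10 <- parsimony_tree(m10)
  expect_equal(pt10$method, "nni")
  pd10 <- phangorn::phyDat(m10, type = "USER", levels = 1:6)
  expect_equal(pt10$score, phangorn::parsimony(pt10$tree, pd10))
  # hill climbing cannot do worse than its NJ start
  nj0 <- ape::unroot(ape::nj(sicnv:::hamming_dist(m10)))
  expect_lte(pt10$score, sicnv:::fitch_score(nj0, m10))
})

test_that("consensus events unify by reciprocal overlap and filter small calls", {
  # clones with identical 30-gene gains share one identity
  st <- matrix(3L, 2, 100, dimnames = list(c("cA", "cB"), NULL))
  st[1, 11:40] <- 5L
  st[2, 11:40] <- 4L
  ev <- consensus_events_from_states(make_hmm(st))
  expect_equal(ev$cA, ev$cB)
  expect_length(ev$cA, 1)

  # overlap of ~10% -> two distinct identities
  st2 <- matrix(3L, 2, 100, dimnames = list(c("cA", "cB"), NULL))
  st2[1, 1:30] <- 5L
  st2[2, 28:57] <- 5L
  ev2 <- consensus_events_from_states(make_hmm(st2))
  expect_false(ev2$cA == ev2$cB)

  # 5-gene event is discarded at the default 20-gene threshold
  st3 <- matrix(3L, 1, 100, dimnames = list("cA", NULL))
  st3[1, 1:5] <- 6L
  expect_length(consensus_events_from_states(make_hmm(st3))$cA, 0)
})
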