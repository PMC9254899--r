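balanced4 <- function(comp_leaves, comp_nodes, labels = c("a", "b", "c", "d")) {
  # hand-built 4-leaf balanced tree: (a,b) at node 1, (c,d) at node 2,
  # root at node 3
  structure(list(merge = rbind(c(-1L, -2L), c(-3L, -4L), c(1L, 2L)),
                 height = c(1, 1.5, 4), labels = labels,
                 lcv_percent = NULL, alcv_angstrom = NULL,
                 completeness_nodes = comp_nodes,
                 completeness_leaves = comp_leaves),
            class = "ward_dendrogram")
}

test_that("LCV of the two-cubic-cell pair matches the face-diagonal formula", {
  v <- lcv(list(cubic10(), unit_cell(10.1, 10.1, 10.1, 90, 90, 90)))
  expect_equal(v$lcv_percent, 1.0, tolerance = 1e-9)
  expect_equal(v$alcv_angstrom, 0.1 * sqrt(2), tolerance = 1e-9)
  same <- lcv(list(cubic10(), cubic10()))
  expect_equal(same$lcv_percent, 0)
  expect_equal(same$alcv_angstrom, 0)
})

test_that("annotate_lcv fills nodes, is permutation-invariant, monotone", {
  set.seed(31)
  cells <- lapply(1:6, function(i)
    unit_cell(10 + i * 0.02, 10, 12, 90, 90, 90))
  names(cells) <- paste0("d", 1:6)
  D <- blend_cell_distance_matrix(cells)
  w <- annotate_lcv(ward_linkage(D), cells)
  expect_length(w$lcv_percent, 5L)
  expect_true(all(w$lcv_percent >= 0))
  # child LCV <= parent LCV (max over a subset)
  for (k in seq_len(5)) for (ch in w$merge[k, ])
    if (ch > 0) expect_lte(w$lcv_percent[ch], w$lcv_percent[k])
  # root LCV equals direct computation over all members
  expect_equal(w$lcv_percent[5], lcv(cells)$lcv_percent, tolerance = 1e-12)
  # permutation invariance of the root value
  perm <- c(4, 2, 6, 1, 3, 5)
  w2 <- annotate_lcv(ward_linkage(blend_cell_distance_matrix(cells[perm])),
                     cells[perm])
  expect_equal(w2$lcv_percent[5], w$lcv_percent[5], tolerance = 1e-12)
  expect_error(annotate_lcv(w, cells[-1]), "d1")
})

test_that("annotate_completeness unions members against a common lattice", {
  h1 <- sphere_subset("h1", cubic10(), "-1", 5, 1:8)
  h2 <- sphere_subset("h2", cubic10(), "-1", 5, 9:16)
  q1 <- sphere_subset("q1", cubic10(), "-1", 5, 1:4)
  sets <- list(h1 = h1, h2 = h2, q1 = q1)
  D <- matrix(c(0, 1, 8, 1, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(names(sets), names(sets)))
  w <- annotate_completeness(ward_linkage(D), sets, d_min = 5)
  # leaves equal their own completeness() (identical cells)
  expect_equal(unname(w$completeness_leaves),
               c(completeness(h1, 5), completeness(h2, 5),
                 completeness(q1, 5)))
  # disjoint half-spheres union to 1.0 at their parent
  expect_equal(w$completeness_nodes[1], 1.0)
  # parent completeness >= max of children
  expect_gte(w$completeness_nodes[2], max(w$completeness_nodes[1],
                                          w$completeness_leaves[3]))
  expect_error(annotate_completeness(ward_linkage(D), sets[-1], 5), "h1")
})

test_that("select_nonoverlapping picks minimal qualifying nodes", {
  # both pairs qualify: select the two pair nodes, not the root
  d <- balanced4(comp_leaves = rep(0.05, 4),
                 comp_nodes = c(0.12, 0.12, 0.20))
  sel <- select_nonoverlapping(d, 0.10)
  expect_setequal(sel$node_id, c(1L, 2L))
  expect_setequal(unlist(attr(sel, "members")), c("a", "b", "c", "d"))
  expect_length(attr(sel, "unassigned"), 0L)

  # only the root qualifies
  d2 <- balanced4(comp_leaves = rep(0.05, 4),
                  comp_nodes = c(0.09, 0.09, 0.12))
  sel2 <- select_nonoverlapping(d2, 0.10)
  expect_equal(sel2$node_id, 3L)
  expect_equal(sel2$size, 4L)

  # qualifying leaves are selectable as singletons
  d3 <- balanced4(comp_leaves = c(0.15, 0.05, 0.05, 0.05),
                  comp_nodes = c(0.2, 0.09, 0.3))
  sel3 <- select_nonoverlapping(d3, 0.10)
  expect_true(-1L %in% sel3$node_id)
  # leaf b is covered by no minimal qualifying node: node 1 has a
  # qualifying descendant (leaf a) and so is not minimal
  expect_true("b" %in% attr(sel3, "unassigned"))

  # member sets are pairwise disjoint in all cases
  for (s in list(sel, sel2, sel3)) {
    mem <- unlist(attr(s, "members"))
    expect_equal(anyDuplicated(mem), 0L)
  }
  expect_error(select_nonoverlapping(ward_linkage(matrix(0, 2, 2)), 0.1),
               "annotate")
})

test_that("newick and JSON exports round-trip the tree", {
  D <- as.matrix(dist(c(0, 1, 10)))
  rownames(D) <- colnames(D) <- c("A", "B", "C")
  w <- ward_linkage(D)
  nwk <- dendrogram_to_newick(w)
  expect_match(nwk, ";$")
  expect_equal(lengths(regmatches(nwk, gregexpr("[ABC]:", nwk))), 3L)
  # leaf branch lengths encode parent height minus child height
  expect_match(nwk, "A:1", fixed = TRUE)
  w2 <- dendrogram_from_json(dendrogram_to_json(w))
  expect_identical(w2[c("merge", "height", "labels")],
                   unclass(w)[c("merge", "height", "labels")])
  # annotations survive the round trip
  cells <- list(A = cubic10(), B = cubic10(),
                C = unit_cell(10.1, 10.1, 10.1, 90, 90, 90))
  wa <- annotate_lcv(w, cells)
  wa2 <- dendrogram_from_json(dendrogram_to_json(wa))
  expect_equal(wa2$lcv_percent, wa$lcv_percent)
  # newick internal labels carry LCV(aLCV)
  expect_match(dendrogram_to_newick(wa), "1.00(0.141)", fixed = TRUE)
})

test_that("cluster_report tabulates every internal node", {
  set.seed(3)
  cells <- lapply(1:5, function(i) unit_cell(10 + 0.01 * i, 11, 12, 90, 90, 90))
  names(cells) <- paste0("d", 1:5)
  w <- annotate_lcv(ward_linkage(blend_cell_distance_matrix(cells)), cells)
  rep <- cluster_report(w)
  expect_equal(nrow(rep), 4L)
  expect_equal(rep$size[4], 5L)
  expect_equal(sort(strsplit(rep$members[4], ",")[[1]]), names(cells))
})
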