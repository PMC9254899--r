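tri <- function(id, I) toy_merged(id, rbind(c(1, 0, 0), c(2, 0, 0),
                                            c(3, 0, 0)), I)

test_that("pearson_cc matches the direct formula on toy vectors", {
  expect_equal(pearson_cc(tri("a", c(1, 2, 3)), tri("b", c(1, 2, 3)))$cc, 1)
  expect_equal(pearson_cc(tri("a", c(1, 2, 3)), tri("b", c(3, 2, 1)))$cc, -1)
  r <- pearson_cc(tri("a", c(1, 2, 3)), tri("b", c(1, 2, 4)))
  expect_equal(r$cc, 3 / (sqrt(2) * sqrt(42 / 9)), tolerance = 1e-12)
  expect_equal(r$n_common, 3L)
  expect_equal(r$f_unmatched, 0)
})

test_that("cc is scale- and offset-invariant", {
  set.seed(13)
  I <- rexp(20)
  H <- cbind(1:20, 0, 0)
  a <- toy_merged("a", H, I)
  b <- toy_merged("b", H, 4.2 * I + 7)
  expect_equal(pearson_cc(a, b)$cc, 1, tolerance = 1e-12)
})

test_that("insufficient overlap and zero variance raise typed errors", {
  a <- toy_merged("a", rbind(c(1, 0, 0), c(2, 0, 0)), c(1, 2))
  b <- toy_merged("b", rbind(c(1, 0, 0), c(5, 0, 0)), c(1, 2))
  expect_error(pearson_cc(a, b), class = "serialmerge_insufficient_overlap")
  flat <- tri("f", c(2, 2, 2))
  expect_error(pearson_cc(flat, tri("b", c(1, 2, 3))),
               class = "serialmerge_undefined_cc")
  unmerged <- reflection_set("u", cubic10(), "-1",
                             data.frame(h = 1:3, k = 0, l = 0,
                                        intensity = 1:3, sigma = 1))
  expect_error(pearson_cc(unmerged, flat), "merged")
})

test_that("sfdist closed forms and monotonicity", {
  a <- tri("a", c(1, 2, 3))
  expect_equal(sfdist(a, a), 0, tolerance = 1e-6)
  expect_equal(sfdist(a, tri("b", c(3, 2, 1))), 2.0, tolerance = 1e-12)
  # cc = 0 with full overlap: chord sqrt(2)
  x <- c(1, 2, 3, 4); y <- c(1, -1, -1, 1)  # centred orthogonal pair
  a4 <- toy_merged("a4", cbind(1:4, 0, 0), x)
  b4 <- toy_merged("b4", cbind(1:4, 0, 0), y)
  expect_equal(pearson_cc(a4, b4)$cc, 0, tolerance = 1e-12)
  expect_equal(sfdist(a4, b4), sqrt(2), tolerance = 1e-12)
  # strictly decreasing in cc (full overlap, no penalty)
  ccs <- seq(-1, 1, by = 0.25)
  ds <- vapply(ccs, function(cc)
    serialmerge:::sfdist_from_cc(cc, 0, 1, 0.9, "chord"), 0)
  expect_true(all(diff(ds) < 0))
  # increasing in unmatched fraction at fixed cc, once activated
  fs <- seq(0.2, 0.9, by = 0.1)
  dp <- vapply(fs, function(f)
    serialmerge:::sfdist_from_cc(0.5, f, 1, 0.9, "chord"), 0)
  expect_true(all(diff(dp) > 0))
  # penalty inactive above the activation threshold
  expect_equal(serialmerge:::sfdist_from_cc(0.5, 0.05, 1, 0.9, "chord"),
               sqrt(2 * 0.5))
  # alternative base form
  expect_equal(serialmerge:::sfdist_from_cc(0.6, 0, 1, 0.9, "sine"),
               sqrt(1 - 0.36))
})

test_that("sfdist_matrix agrees with elementwise sfdist and permutes", {
  set.seed(77)
  ref <- generate_reference_intensities(cubic10(), "-1", 3, seed = 8)
  sets <- lapply(1:5, function(i) {
    w <- sample_wedge(ref, 0.7, 0.1, seed = 20 + i,
                      dataset_id = paste0("m", i))
    merge_sets(list(w))
  })
  D <- sfdist_matrix(sets)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D[i, j], sfdist(sets[[i]], sets[[j]]), tolerance = 1e-9)
  # identical pair at distance ~0
  D2 <- sfdist_matrix(list(sets[[1]], sets[[1]]))
  expect_equal(D2[1, 2], 0, tolerance = 1e-6)
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  Dp <- sfdist_matrix(sets[perm])
  expect_equal(matrix(Dp, 5, 5), matrix(D[perm, perm], 5, 5),
               tolerance = 1e-12)
})

test_that("uncomparable pairs receive the sentinel distance", {
  a <- sphere_subset("a", cubic10(), "-1", 5, 1:6)
  b <- sphere_subset("b", cubic10(), "-1", 5, 7:12)
  c3 <- sphere_subset("c", cubic10(), "-1", 5, c(1:3, 7:9), intensity = 1:6)
  D <- sfdist_matrix(list(a, b, c3), sentinel = 10)
  expect_equal(D[1, 2], 10)
  expect_true(nrow(attr(D, "failed_pairs")) >= 1)
})
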