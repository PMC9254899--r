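test_that("reference intensities cover the full ASU deterministically", {
  ref <- generate_reference_intensities(cubic10(), "mmm", 3, seed = 42)
  expect_true(ref$merged)
  expect_equal(completeness(ref, 3), 1.0)
  ref2 <- generate_reference_intensities(cubic10(), "mmm", 3, seed = 42)
  expect_identical(ref$observations, ref2$observations)
  ref3 <- generate_reference_intensities(cubic10(), "mmm", 3, seed = 43)
  expect_false(identical(ref$observations$intensity,
                         ref3$observations$intensity))
  # Wilson prior with unit mean: law-of-large-numbers bound
  n <- nrow(ref$observations)
  expect_lt(abs(mean(ref$observations$intensity) - 1), 3 / sqrt(n))
  expect_equal(ref$observations$sigma, 0.05 * ref$observations$intensity)
})

test_that("derive_form perturbs exactly the requested fraction", {
  ref <- generate_reference_intensities(cubic10(), "-1", 3, seed = 7)
  f0 <- derive_form(ref, form_spec("same", cubic10()), seed = 1)
  expect_identical(f0$observations$intensity, ref$observations$intensity)
  expect_equal(pearson_cc(f0, ref)$cc, 1)

  spec <- form_spec("all", cubic10(), intensity_shift_fraction = 1,
                    intensity_shift_scale = 3)
  f1 <- derive_form(ref, spec, seed = 2)
  expect_true(all(f1$observations$intensity > ref$observations$intensity))
  # perturbing every index with scale 3 leaves a clearly sub-unit cc
  expect_lt(pearson_cc(f1, ref)$cc, 0.99)
  # a partial shift decorrelates more strongly than the cc of a
  # matched unperturbed copy (which is exactly 1)
  expect_lt(pearson_cc(derive_form(ref, form_spec("half", cubic10(),
                                                  intensity_shift_fraction = 0.5,
                                                  intensity_shift_scale = 3),
                                   seed = 2), ref)$cc,
            pearson_cc(f0, ref)$cc)

  spec3 <- form_spec("some", cubic10(), intensity_shift_fraction = 0.3,
                     intensity_shift_scale = 2)
  f3 <- derive_form(ref, spec3, seed = 3)
  changed <- f3$observations$intensity != ref$observations$intensity
  expect_equal(sum(changed), as.integer(round(0.3 * nrow(ref$observations))))
})

test_that("two forms with distinct signatures are mutually farther than from reference", {
  ref <- generate_reference_intensities(cubic10(), "-1", 2, seed = 11)
  mk <- function(lab, seed) derive_form(ref, form_spec(lab, cubic10(),
                                                       intensity_shift_fraction = 0.3,
                                                       intensity_shift_scale = 2),
                                        seed = seed)
  fa <- mk("fa", 21); fb <- mk("fb", 22)
  expect_gt(sfdist(fa, fb), sfdist(fa, ref))
  expect_gt(sfdist(fa, fb), sfdist(fb, ref))
})

test_that("sample_wedge hits the completeness target and adds noise", {
  ref <- generate_reference_intensities(cubic10(), "-1", 2, seed = 19)
  n <- nrow(ref$observations)
  w <- sample_wedge(ref, 1.0, 0, seed = 1, dataset_id = "full")
  o <- order(w$observations$h, w$observations$k, w$observations$l)
  ro <- order(ref$observations$h, ref$observations$k, ref$observations$l)
  expect_equal(w$observations$intensity[o], ref$observations$intensity[ro])
  w2 <- sample_wedge(ref, 0.25, 0.05, seed = 2)
  expect_equal(completeness(merge_sets(list(w2)), 2), 0.25,
               tolerance = 1 / n + 1e-9)
  expect_error(sample_wedge(ref, 1e-9, 0, seed = 3), "no reflections")
  # coupon-collector style: ceiling(3/t) independent wedges exceed t
  t0 <- 0.25
  wedges <- lapply(seq_len(ceiling(3 / t0)), function(i)
    sample_wedge(ref, t0, 0, seed = 100 + i, dataset_id = paste0("w", i)))
  expect_gt(completeness(merge_sets(wedges), 2), t0)
})

test_that("generate_experiment shapes, labels and reproducibility", {
  forms <- list(form_spec("X", cubic10(), rep(0.01, 6)),
                form_spec("Y", unit_cell(10.2, 10.2, 10.2, 90, 90, 90),
                          rep(0.01, 6), 0.5, 2))
  e1 <- generate_experiment(forms, n_per_form = 5, laue_group = "mmm",
                            d_min = 3, seed = 77)
  expect_length(e1$sets, 10L)
  expect_equal(as.integer(table(e1$truth)), c(5L, 5L))
  expect_equal(nrow(e1$cells), 10L)
  e2 <- generate_experiment(forms, n_per_form = 5, laue_group = "mmm",
                            d_min = 3, seed = 77)
  expect_identical(e1$cells, e2$cells)
  expect_identical(lapply(e1$sets, `[[`, "observations"),
                   lapply(e2$sets, `[[`, "observations"))
  # per-form cell means concentrate around the form mean (CLT bound)
  forms2 <- list(form_spec("Z", cubic10(), rep(0.05, 6)))
  e3 <- generate_experiment(forms2, n_per_form = 100, laue_group = "mmm",
                            d_min = 4, seed = 99)
  expect_lt(abs(mean(e3$cells$a) - 10), 4 * 0.05 / sqrt(100))
  # all generated sets satisfy the container invariants
  expect_true(all(vapply(e3$sets, function(s)
    all(s$observations$sigma > 0), NA)))
})

test_that("experiments write and reload losslessly through the CSV/HKL files", {
  dir <- withr::local_tempdir()
  forms <- list(form_spec("X", cubic10(), rep(0.01, 6)))
  e <- generate_experiment(forms, n_per_form = 3, laue_group = "-1",
                           d_min = 3, seed = 5, out_dir = dir)
  expect_true(file.exists(file.path(dir, "cells.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "spec.yaml")))
  inp <- load_experiment_dir(dir, "-1")
  expect_setequal(names(inp$sets), names(e$sets))
  expect_equal(inp$truth, e$truth)
  # intensities survive to the fixed-point precision of HKL4
  id <- names(e$sets)[1]
  expect_equal(inp$sets[[id]]$observations$intensity,
               e$sets[[id]]$observations$intensity, tolerance = 0.005 + 1e-9)
})

test_that("the four-form preset encodes the intended degeneracy structure", {
  e <- preset_lysozyme_soaks(seed = 1, n_per_form = 2)
  expect_length(e$sets, 8L)
  f <- e$forms
  labs <- vapply(f, `[[`, "", "label")
  names(f) <- labs
  # N and B share a mean cell; G and GB share the expanded cell
  expect_equal(unclass(f$N$mean_cell), unclass(f$B$mean_cell))
  expect_equal(unclass(f$G$mean_cell), unclass(f$GB$mean_cell))
  expect_gt(f$G$mean_cell[1], f$N$mean_cell[1])
  # N carries no intensity signature; the others do
  expect_equal(f$N$intensity_shift_fraction, 0)
  expect_true(all(vapply(f[c("G", "B", "GB")], `[[`, 0,
                         "intensity_shift_fraction") > 0))
})
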