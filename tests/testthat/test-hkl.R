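test_that("HKL4 records parse per the fixed-width definition", {
  p <- withr::local_tempfile()
  writeLines(c("   1   2   3  100.00    5.00",
               "  -1  -2  -3   50.25    2.50",
               "   0   0   0    0.00    0.00",
               "   9   9   9  999.00    9.00"),  # after terminator: ignored
             p)
  s <- read_hkl(p, cubic10(), "-1")
  expect_equal(nrow(s$observations), 2L)
  expect_equal(s$observations$h, c(1L, -1L))
  expect_equal(s$observations$intensity, c(100, 50.25))
  expect_equal(s$observations$sigma, c(5, 2.5))
  expect_equal(s$dataset_id, sub("\\.[^.]*$", "", basename(p)))
})

test_that("write/read round-trip is the identity", {
  H <- rbind(c(1, 2, 3), c(-4, 0, 2), c(3, -3, 1))
  s <- toy_merged("rt", H, c(12.25, 0.75, 199.5), sigma = 0.25)
  p <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(s, p)
  expect_length(readLines(p), 4L)  # 3 records + terminator
  back <- read_hkl(p, s$cell, s$laue_group, merged = TRUE)
  expect_equal(back$observations, s$observations)
})

test_that("empty sets write a terminator-only file", {
  s <- reflection_set("empty", cubic10(), "-1",
                      data.frame(h = integer(0), k = integer(0),
                                 l = integer(0), intensity = numeric(0),
                                 sigma = numeric(0)), merged = TRUE)
  p <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(s, p)
  expect_identical(readLines(p), "   0   0   0    0.00    0.00")
  back <- read_hkl(p, cubic10(), "-1")
  expect_equal(nrow(back$observations), 0L)
})

test_that("malformed and empty files are rejected with context", {
  p <- withr::local_tempfile()
  writeLines(c("   1   2   3  100.00    5.00",
               "   1   2   x  100.00    5.00"), p)
  expect_error(read_hkl(p, cubic10(), "-1"), "line 2")
  p2 <- withr::local_tempfile()
  file.create(p2)
  expect_error(read_hkl(p2, cubic10(), "-1"), "empty")
  expect_error(read_hkl(file.path(tempdir(), "nope.hkl"), cubic10(), "-1"),
               "not found")
})

test_that("values exceeding the fixed-width columns raise overflow errors", {
  s <- toy_merged("ovf", rbind(c(1, 2, 3)), 1e6)
  p <- withr::local_tempfile(fileext = ".hkl")
  expect_error(write_hkl(s, p), "fixed-width")
  s2 <- reflection_set("ovf2", cubic10(), "-1",
                       data.frame(h = 10000, k = 2, l = 3,
                                  intensity = 1, sigma = 1))
  expect_error(write_hkl(s2, p), "fixed-width")
})

test_that("reflection_set enforces its invariants", {
  expect_error(reflection_set("x", cubic10(), "-1",
                              data.frame(h = 0, k = 0, l = 0,
                                         intensity = 1, sigma = 1)),
               "0,0,0")
  expect_error(reflection_set("x", cubic10(), "-1",
                              data.frame(h = 1, k = 0, l = 0,
                                         intensity = 1, sigma = 0)),
               "positive")
  # merged sets may not contain symmetry-duplicate indices
  expect_error(reflection_set("x", cubic10(), "-1",
                              data.frame(h = c(1, -1), k = c(2, -2),
                                         l = c(3, -3), intensity = 1,
                                         sigma = 1), merged = TRUE),
               "duplicate")
})
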