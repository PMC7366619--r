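test_that("read_curve parses the two-column dialect and canonicalizes", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.0 0.0", "0.1 2.0", "0.2 6.0", "0.3 14.0"), p)
  cv <- read_curve(p, units = "fraction")
  expect_s3_class(cv, "uc_curve")
  expect_equal(cv$strain, c(0, 0.1, 0.2, 0.3))
  expect_equal(cv$stress, c(0, 2, 6, 14))

  # header + percent units, comma and whitespace delimiters both accepted
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("strain,stress", "10,5.0", "20 12.0", "30,25.0", "33,30.0"), p2)
  cv2 <- read_curve(p2, dialect = "csv", units = "percent")
  expect_equal(cv2$strain, c(0.10, 0.20, 0.30, 0.33))

  # auto units: max strain > 1.5 means percent
  cv3 <- read_curve(p2, dialect = "csv")
  expect_equal(cv3$strain, cv2$strain)

  # duplicate strain rows collapse to the arithmetic mean of stress
  p4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.0 0.0", "0.1 2.0", "0.1 2.2", "0.2 6.0", "0.3 14.0"), p4)
  cv4 <- read_curve(p4, units = "fraction")
  expect_equal(cv4$strain, c(0, 0.1, 0.2, 0.3))
  expect_equal(cv4$stress[2], 2.1)
})

test_that("read_curve rejects malformed input with useful errors", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.0 0.0", "0.1 2.0", "0.2 oops", "0.3 14.0"), p)
  expect_error(read_curve(p), "line 3")

  writeLines(c("0.0 0.0", "0.1 2.0", "0.2 6.0"), p)
  expect_error(read_curve(p), "insufficient")

  # unloading segment: strain decreasing in file order
  writeLines(c("0.0 0.0", "0.2 6.0", "0.3 14.0", "0.1 2.0", "0.35 15"), p)
  expect_error(read_curve(p), "unloading|peak strain")

  expect_error(read_curve(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("write/read round trip is identity to 6 significant digits", {
  dir <- withr::local_tempdir()
  for (s in 1:15) {
    cv <- random_uc_curve(s)
    for (dialect in c("txt2col", "csv")) {
      p <- file.path(dir, paste0("c", s, ".", dialect))
      write_curve(cv, p, dialect = dialect)
      expect_curves_equal(read_curve(p, dialect = dialect), cv)
    }
  }
  # percent on output multiplies strain by 100 and reads back identically
  cv <- random_uc_curve(99)
  p <- file.path(dir, "pct.txt")
  write_curve(cv, p, units = "percent")
  raw <- read.table(p, header = TRUE)
  expect_equal(raw$strain, cv$strain * 100, tolerance = 1e-6)
  expect_curves_equal(read_curve(p, units = "percent"), cv)

  # canonicalization is idempotent: read(write(read(f))) == read(f)
  p2 <- file.path(dir, "again.txt")
  write_curve(read_curve(p, units = "percent"), p2)
  expect_curves_equal(read_curve(p2), read_curve(p, units = "percent"))

  # missing directories are created
  p3 <- file.path(dir, "new", "sub", "c.txt")
  write_curve(cv, p3)
  expect_true(file.exists(p3))
})

test_that("filename metadata pattern is parsed when sidecar args absent", {
  dir <- withr::local_tempdir()
  cv <- random_uc_curve(3)
  p <- file.path(dir, "ECOFLEX-0010_5_r01.txt")
  write_curve(cv, p)
  got <- read_curve(p)
  expect_equal(got$material, "ECOFLEX-0010")
  expect_equal(got$dilution_pct, 5)
  expect_equal(got$replicate_id, "r01")
})

test_that("load_replicates collects matching files deterministically", {
  dir <- withr::local_tempdir()
  for (i in 5:1) {  # write out of order; loading must be lexicographic
    cv <- random_uc_curve(i)
    write_curve(cv, file.path(dir, sprintf("ECOFLEX-0010_5_r%02d.txt", i)))
  }
  write_curve(random_uc_curve(9), file.path(dir, "ELASTOSIL-M4511_5_r01.txt"))

  st <- load_replicates(dir, "ECOFLEX-0010", 5)
  expect_s3_class(st, "replicate_set")
  expect_length(st, 5)
  ids <- vapply(st$curves, function(cv) cv$replicate_id, character(1))
  expect_equal(ids, sprintf("r%02d", 1:5))

  expect_error(load_replicates(dir, "NOSUCH", 5), "NOSUCH")

  # a corrupt replicate file is reported by name
  writeLines(c("0 0", "bad row", "0.2 2", "0.3 4"),
             file.path(dir, "ECOFLEX-0010_5_r99.txt"))
  expect_error(load_replicates(dir, "ECOFLEX-0010", 5), "r99")
})

test_that("replicate_set enforces shared mixture and unique ids", {
  a <- uc_curve(c(0, .1, .2, .3), c(0, 1, 2, 3), material = "A",
                dilution_pct = 5, replicate_id = "r1")
  b <- uc_curve(c(0, .1, .2, .3), c(0, 1, 2, 3), material = "B",
                dilution_pct = 5, replicate_id = "r2")
  expect_error(replicate_set(list(a, b)), "share")
  a2 <- a; a2$replicate_id <- "r1"
  expect_error(replicate_set(list(a, a2)), "unique")
  expect_silent(replicate_set(list(a)))
})
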