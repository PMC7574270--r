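test_that("DDVH files parse, validate and round-trip losslessly", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# patient_id=T1", "# structure=prostate_gland",
               "# bin_width_gy=0.1", "dose_gy,volume",
               "1.950,0.0", "2.050,10.0"), p)
  d <- read_ddvh(p)
  expect_s3_class(d, "ddvh")
  expect_equal(d$bin_centers, c(1.95, 2.05))
  expect_equal(d$volumes, c(0, 10))
  expect_identical(d$metadata$pruned_bins, 0L)

  # zero-dose bins are pruned with a warning
  writeLines(c("# bin_width_gy=0.1", "dose_gy,volume",
               "0.050,1.0", "0.150,2.0", "0.250,3.0"), p)
  expect_warning(dz <- read_ddvh(p), "pruned 1 zero-dose")
  expect_equal(dz$bin_centers, c(0.15, 0.25))

  # spacing break is a format error
  writeLines(c("# bin_width_gy=0.1", "dose_gy,volume",
               "1.0,1", "1.1,1", "1.3,1"), p)
  expect_error(read_ddvh(p), "spacing")

  # malformed header names the problem
  writeLines(c("dose,volume", "1.05,1"), p)
  expect_error(read_ddvh(p), "header")

  # round-trip at 1e-9
  set.seed(42)
  for (i in 1:5) {
    d0 <- random_ddvh(sample(5:200, 1))
    d0$metadata$patient_id <- "RT"
    write_ddvh(d0, p)
    d1 <- read_ddvh(p)
    expect_equal(d1$bin_centers, d0$bin_centers, tolerance = 1e-9)
    expect_equal(d1$volumes, d0$volumes, tolerance = 1e-9)
  }
  # row count matches bin count
  write_ddvh(ddvh(c(1.05, 1.15, 1.25), c(1, 2, 3)), p)
  expect_length(grep("^[0-9]", readLines(p)), 3L)
})

test_that("DDVH construction enforces its invariants", {
  expect_error(ddvh(c(1.05, 1.15), c(1, -1)), "non-negative")
  expect_error(ddvh(c(1.05, 1.15), c(0, 0)), "positive")
  expect_error(ddvh(c(1.15, 1.05), c(1, 1)), "increasing")
  expect_error(ddvh(c(1.05, 1.35), c(1, 1), bin_width = 0.1), "uniform")
  expect_error(write_ddvh(structure(list(volumes = 0), class = "ddvh"),
                          tempfile()), "zero total volume")
})

test_that("dose statistics match their definitions and oracles", {
  d <- ddvh(c(60.05, 60.15, 60.25, 60.35), c(0, 0, 5, 5))
  expect_equal(dose_min(d), 60.25)
  expect_equal(total_volume(d), 10)
  expect_equal(dose_min(uniform_ddvh(74.05)), 74.05)
  expect_equal(total_volume(ddvh(c(1.05, 1.15, 1.25), c(10, 20, 30))), 60)

  # D_f conventions
  u <- uniform_ddvh(70.05)
  expect_equal(dose_at_relative_volume(u, 0.98), 70.05)
  two <- ddvh(c(70, 74), c(5, 5), bin_width = 4)
  expect_equal(dose_at_relative_volume(two, 0.5), 72)  # 74 - half bin
  expect_error(dose_at_relative_volume(u, 0), "fraction")
  expect_error(dose_at_relative_volume(u, 1.2), "fraction")

  # property: linear-scan minimum oracle, D98 ordering, fraction-1 identity
  set.seed(7)
  for (i in 1:20) {
    d <- random_ddvh(sample(5:80, 1))
    pos <- d$bin_centers[d$volumes > 0]
    expect_equal(dose_min(d), min(pos))
    d98 <- dose_at_relative_volume(d, 0.98)
    expect_gte(d98, dose_min(d))
    expect_lte(d98, max(pos))
    expect_equal(dose_at_relative_volume(d, 1), dose_min(d))
    # cumulative-sum oracle: invert the interpolated reverse-cumulative DVH
    # independently (per-bin partial volumes + root finding)
    lo_e <- d$bin_centers - 0.05; hi_e <- d$bin_centers + 0.05
    v_ge <- function(D) sum(d$volumes * pmin(pmax((hi_e - D) / 0.1, 0), 1))
    target <- 0.98 * total_volume(d)
    root <- uniroot(function(D) v_ge(D) - target,
                    c(min(lo_e), max(hi_e)), tol = 1e-10)$root
    oracle <- min(max(root, dose_min(d)), max(pos))
    expect_equal(d98, oracle, tolerance = 1e-6)
  }
})

test_that("total_volume is invariant under zero-volume bin pruning", {
  d <- ddvh(seq(50.05, by = 0.1, length.out = 10),
            c(0, 0, 1, 2, 0, 3, 0, 0, 4, 0))
  keep <- d$volumes > 0
  pruned <- ddvh(d$bin_centers[keep], d$volumes[keep], dose_axis = "EQD2")
  expect_equal(total_volume(pruned), total_volume(d))
  expect_equal(dose_min(pruned), dose_min(d))
})

test_that("percent-volume files are flagged and kept on the 100 scale", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# bin_width_gy=0.1", "# volume_units=percent",
               "dose_gy,volume", "70.050,40", "70.150,60"), p)
  d <- read_ddvh(p)
  expect_identical(d$metadata$volume_units, "percent")
  expect_equal(total_volume(d), 100)
})

test_that("cohort manifests load, validate and round-trip", {
  dir <- withr::local_tempdir()
  co <- uniform_cohort(c(74.05, 70.05, 76.05), c(1, 0, 1))
  man <- write_cohort(co, dir)
  co2 <- load_cohort(man)
  expect_length(co2, 3L)
  expect_equal(responses(co2), responses(co))
  expect_equal(co2$patients[["P01"]]$structures$prostate_gland$bin_centers,
               74.05)

  # invalid response
  m <- read.csv(man, colClasses = "character")
  m$response[1] <- "2"
  bad <- file.path(dir, "bad.csv")
  write.csv(m, bad, row.names = FALSE, quote = FALSE)
  expect_error(load_cohort(bad), "response")

  # missing DVH file
  m <- read.csv(man, colClasses = "character")
  m$dvh_path[2] <- "nope.csv"
  write.csv(m, bad, row.names = FALSE, quote = FALSE)
  expect_error(load_cohort(bad), "missing DVH.*P02")

  # empty manifest
  write.csv(m[0, ], bad, row.names = FALSE, quote = FALSE)
  expect_error(load_cohort(bad), "non-empty")

  # duplicate ids rejected at construction
  p1 <- co$patients[[1]]
  expect_error(cohort(list(p1, p1)), "duplicate")
})
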