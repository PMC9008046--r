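make_set <- function(ne = 3, nc = 4, ns = 100, fs = 50, seed = 1,
                     labels = c("Fz", "Cz", "Pz", "Oz")[1:nc]) {
  set.seed(seed)
  epoch_set("sub1", array(rnorm(ne * nc * ns, sd = 20), c(ne, nc, ns)),
            labels, fs)
}

test_that("epoch_set enforces its invariants", {
  expect_error(epoch_set("s", matrix(0, 2, 2), c("a", "b"), 10), "3-d")
  expect_error(make_set(labels = c("Fz", "Fz", "Pz", "Oz")), "duplicate")
  x <- array(0, c(2, 2, 10)); x[1, 1, 1] <- NA
  expect_error(epoch_set("s", x, c("a", "b"), 10), "non-finite")
  expect_error(epoch_set("s", array(0, c(2, 2, 10)), c("a", "b"), -1),
               "fs")
})

test_that("EDF round-trip preserves the signal within 16-bit quantization", {
  x <- make_set(ne = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, path)
  y <- read_edf(path, epoch_seconds = dim(x$data)[3] / x$fs)
  expect_identical(y$channel_labels, x$channel_labels)
  expect_equal(y$fs, x$fs)
  expect_equal(dim(y$data), dim(x$data))
  qstep <- max(apply(x$data, 2, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(y$data - x$data)), 2 * qstep)
})

test_that("continuous EDF is segmented into exact epochs, trailing samples dropped", {
  # 20 s single-record recording at 200 Hz -> ten 2-s epochs
  set.seed(4)
  cont <- epoch_set("s20", array(rnorm(1 * 19 * 4000, sd = 15),
                                 c(1, 19, 4000)), montage_1020(), 200)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(cont, path)
  y <- read_edf(path, epoch_seconds = 2)
  expect_equal(dim(y$data), c(10, 19, 400))
  expect_identical(y$channel_labels, montage_1020())

  # 20.5 s -> same 10 epochs plus a logged drop of 100 samples
  cont2 <- epoch_set("s21", array(rnorm(1 * 19 * 4100, sd = 15),
                                  c(1, 19, 4100)), montage_1020(), 200)
  write_edf(cont2, path)
  expect_message(y2 <- read_edf(path, epoch_seconds = 2),
                 "dropping 100 trailing")
  expect_equal(dim(y2$data)[1], 10)
})

test_that("missing requested channel raises a named error", {
  x <- make_set()
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, path)
  expect_error(read_edf(path, epoch_seconds = 2, channels = c("Fz", "C3")),
               "missing channel.*C3")
})

test_that("channel order is canonicalized regardless of file order", {
  set.seed(9)
  shuffled <- sample(montage_1020())
  x <- epoch_set("s", array(rnorm(2 * 19 * 100, sd = 10),
                            c(2, 19, 100)), shuffled, 50)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, path)
  y <- read_edf(path, epoch_seconds = 2)
  expect_identical(y$channel_labels, montage_1020())
  i <- match("Cz", shuffled)
  expect_equal(y$data[, match("Cz", montage_1020()), ],
               x$data[, i, ], tolerance = 1e-2)
})

test_that("epoch-matrix round trip is bit exact and rejects bad content", {
  x <- make_set(ne = 2, nc = 3, ns = 37, labels = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_epoch_matrix(x, path)
  y <- read_epoch_matrix(path)
  expect_identical(y$data, x$data)
  expect_identical(y$channel_labels, x$channel_labels)
  expect_identical(y$fs, x$fs)
  expect_identical(y$subject_id, x$subject_id)

  # one NaN cell -> non-finite error
  lines <- readLines(path)
  lines[8] <- sub("^[^,]+", "NaN", lines[8])
  writeLines(lines, path)
  expect_error(read_epoch_matrix(path), "non-numeric|non-finite")

  # ragged row
  write_epoch_matrix(x, path)
  lines <- readLines(path)
  lines[8] <- paste0(lines[8], ",1.0")
  writeLines(lines, path)
  expect_error(read_epoch_matrix(path), "ragged")

  # undeclared fs
  write_epoch_matrix(x, path)
  lines <- readLines(path)
  writeLines(lines[!grepl("^# fs=", lines)], path)
  expect_error(read_epoch_matrix(path), "fs")
})

test_that("EDF and matrix readers agree on the same underlying signal", {
  x <- make_set(ne = 4, nc = 19, ns = 100, fs = 50, seed = 6,
                labels = montage_1020())
  p1 <- withr::local_tempfile(fileext = ".edf")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_edf(x, p1)
  write_epoch_matrix(x, p2)
  a <- read_edf(p1, epoch_seconds = 2)
  b <- read_epoch_matrix(p2)
  expect_identical(a$channel_labels, b$channel_labels)
  qstep <- max(apply(x$data, 2, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(a$data - b$data)), 2 * qstep)
})

test_that("result tables have the right shape and rewrite byte-identically", {
  fm <- fake_metrics()
  cfg <- default_config(); cfg$n_perm <- 200
  res <- compare_groups(fm$metrics, fm$covariates, cfg)
  expect_equal(nrow(res), 60)
  dir <- withr::local_tempdir()
  paths <- write_results(res, fm$metrics, dir)
  r2 <- read.csv(paths["comparisons"])
  expect_equal(nrow(r2), 60)
  expect_equal(r2$observed_diff, res$observed_diff)
  # write -> read -> write is idempotent at the byte level
  dir2 <- withr::local_tempdir()
  write_results(r2, read.csv(paths["metrics"]), dir2)
  expect_identical(readLines(file.path(dir2, "group_comparisons.csv")),
                   readLines(paths["comparisons"]))
  expect_error(write_results(res[0, ], fm$metrics, dir), "empty")
  expect_error(write_results(res, fm$metrics[0, ], dir), "empty")
})

test_that("configuration survives a YAML round trip and is validated", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$bands, cfg$bands)
  expect_equal(cfg2$n_perm, cfg$n_perm)
  expect_equal(cfg2$train_frac, cfg$train_frac)
  bad <- cfg; bad$train_frac <- 1.2
  expect_error(write_config(bad, path), "train fraction")
  bad2 <- cfg; bad2$bands$f_low[1] <- 99
  expect_error(write_config(bad2, path), "f_low")
})

test_that("adjacency tables round-trip the per-band graphs", {
  cfg <- tiny_config(n_per_group = 2, n_epochs = 4, seed = 21)
  set.seed(21)
  s <- generate_subject(cfg, "A", "adj")
  gs <- subject_connectivity(s, bands = cfg$bands)
  path <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(gs, path)
  back <- read_adjacency(path)
  expect_named(back, names(gs))
  for (b in names(gs)) {
    expect_identical(back[[b]]$W, gs[[b]]$W)
    expect_identical(back[[b]]$channel_labels, gs[[b]]$channel_labels)
  }
  expect_error(write_adjacency(list(), path), "empty")
})
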