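test_that("cell tables parse, report bad rows, and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,class,x_um,y_um,dist_um",
               "A,cancer,100,200,",
               "A,cancer,150,250,",
               "A,cd8,120,210,12.5"), f)
  tab <- read_cell_table(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(table(tab$class)[["cancer"]], 2L)
  expect_equal(tab$dist_um, c(NA, NA, 12.5))

  # header only -> empty with a warning
  writeLines("subject_id,class,x_um,y_um,dist_um", f)
  expect_warning(empty <- read_cell_table(f), "no rows")
  expect_equal(nrow(empty), 0L)

  # missing required column is a hard error naming it
  writeLines(c("subject_id,class,x_um", "A,cancer,1"), f)
  expect_error(read_cell_table(f), "y_um")

  # a non-numeric coordinate is reported with its line number
  writeLines(c("subject_id,class,x_um,y_um",
               "A,cancer,1,2", "A,cancer,oops,4"), f)
  expect_warning(ok <- read_cell_table(f), "line.*3")
  expect_equal(nrow(ok), 1L)

  # 100 generated rows survive write -> read far beyond 6 decimals
  set.seed(11)
  gen <- data.frame(subject_id = "S1",
                    class = sample(c("cancer", "cd8"), 100, TRUE),
                    x_um = runif(100, 0, 1e4), y_um = runif(100, 0, 1e4),
                    dist_um = runif(100, 0, 100))
  write_cell_table(gen, f)
  back <- read_cell_table(f)
  expect_equal(back$x_um, gen$x_um, tolerance = 1e-9)
  expect_equal(back$y_um, gen$y_um, tolerance = 1e-9)
  expect_equal(back$class, gen$class)
})

test_that("tab-delimited input and custom dialects are accepted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pid\ttype\tX\tY", "A\tcancer\t10\t20", "A\tcd8\t12\t22"), f)
  tab <- read_cell_table(f, dialect = cell_table_dialect(
    subject_id = "pid", class = "type", x = "X", y = "Y"))
  expect_equal(tab$x_um, c(10, 12))
})

test_that("subject patterns rescale 1:1000 with bounding-box windows", {
  rec <- data.frame(subject_id = "A", class = c("cancer", "cd8"),
                    x_um = c(1500, 300), y_um = c(500, 700),
                    dist_um = c(NA, 10))
  p <- build_subject_pattern(rec, "A")
  expect_equal(p$cancer$x, 1.5)
  expect_equal(p$cancer$y, 0.5)
  expect_equal(p$window, c(0.3, 1.5, 0.5, 0.7))
  # rescale is exactly x 1e-3, hence invertible
  expect_identical(p$cd8$x * 1000, 300)
  expect_error(build_subject_pattern(rec, "ZZ"), "no records")

  # brute-force window check on 500 random points
  set.seed(21)
  rnd <- data.frame(subject_id = "B", class = "cancer",
                    x_um = runif(500, 0, 10000), y_um = runif(500, 0, 8000),
                    dist_um = NA_real_)
  pb <- build_subject_pattern(rnd, "B")
  area <- (max(rnd$x_um) - min(rnd$x_um)) * (max(rnd$y_um) - min(rnd$y_um))
  expect_equal((pb$window[2] - pb$window[1]) * (pb$window[4] - pb$window[3]),
               area / 1e6, tolerance = 1e-12)
})

test_that("the minimum-count inclusion rule keeps >=10/>=10 and partitions", {
  mk <- function(nc, nd, id) make_pattern(
    cbind(runif(nc), runif(nc)), cbind(runif(nd), runif(nd)),
    subject_id = id)
  set.seed(31)
  pats <- list(mk(9, 50, "low_cancer"), mk(10, 10, "boundary"),
               mk(50, 9, "low_cd8"), mk(40, 40, "fine"))
  inc <- apply_subject_inclusion(pats)
  kept_ids <- vapply(inc$kept, `[[`, "", "subject_id")
  expect_setequal(kept_ids, c("boundary", "fine"))
  expect_equal(inc$excluded$reason[inc$excluded$subject_id == "low_cancer"],
               "cancer<10")
  expect_equal(inc$excluded$reason[inc$excluded$subject_id == "low_cd8"],
               "cd8<10")
  # no subject lost or duplicated
  expect_setequal(c(kept_ids, inc$excluded$subject_id),
                  vapply(pats, `[[`, "", "subject_id"))
})

test_that("a 66-subject cohort with 5 seeded violators keeps 61", {
  p <- synthetic_defaults()
  p$window <- c(0, 3, 0, 2)        # small slides; the rule is about counts
  coh <- simulate_cohort(seed = 41, params = p, n_inadequate = 5)
  filtered <- lapply(coh$patterns, filter_tils)
  inc <- apply_subject_inclusion(filtered)
  expect_length(inc$kept, 61L)
  expect_equal(nrow(inc$excluded), 5L)
  expect_setequal(inc$excluded$subject_id, coh$truth$inadequate)
})
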