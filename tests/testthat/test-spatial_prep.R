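test_that("nearest cancer distances are exact", {
  expect_equal(nearest_cancer_distance(cbind(0, 0), cbind(0, 0)), 0)
  # 3-4-5 triangle: (0.03, 0.04) mm away -> 50 um
  expect_equal(nearest_cancer_distance(cbind(0, 0), cbind(0.03, 0.04)), 50)
  expect_error(nearest_cancer_distance(cbind(0, 0), cbind(numeric(0),
                                                          numeric(0))),
               "empty")
  set.seed(52)
  cd8 <- cbind(runif(200, 0, 8), runif(200, 0, 6))
  cancer <- cbind(runif(500, 0, 8), runif(500, 0, 6))
  expect_equal(nearest_cancer_distance(cd8, cancer),
               brute_nearest_um(cd8, cancer), tolerance = 1e-9)
})

test_that("the TIL filter keeps <=50 um, is idempotent and monotone", {
  set.seed(53)
  # 100 cd8 at controlled platform distances, 37 of them within 50 um
  d <- c(runif(37, 0, 50), runif(63, 50.001, 400))
  pat <- make_pattern(cbind(runif(20, 0, 1), runif(20, 0, 1)),
                      cbind(runif(100, 0, 1), runif(100, 0, 1), d))
  f <- filter_tils(pat)
  expect_equal(nrow(f$cd8), 37L)
  expect_equal(f$dist_source, "platform")
  # boundary: exactly 50 kept, 50.1 removed
  pb <- make_pattern(cbind(0, 0), rbind(c(0.03, 0.04, NA), c(0.0502, 0, NA)),
                     window = c(0, 1, 0, 1))
  fb <- filter_tils(pb)
  expect_equal(fb$dist_source, "centroid")
  expect_equal(nrow(fb$cd8), 1L)
  expect_equal(fb$cd8$x, 0.03)
  # idempotent
  expect_equal(filter_tils(f)$cd8, f$cd8)
  # monotone in the threshold: smaller threshold is a subset
  f25 <- filter_tils(pat, 25)
  expect_true(all(f25$cd8$dist_um %in% f$cd8$dist_um))
  # cancer set untouched
  expect_equal(f$cancer, pat$cancer)
})

test_that("quadrat grids conserve counts and follow the half-open rule", {
  pat <- make_pattern(cbind(0.2, 0.3), cbind(0.9, 0.9),
                      window = c(0, 1, 0, 1))
  g <- make_quadrat_grid(pat, 0.5)
  expect_equal(dim(g$cancer_counts), c(2L, 2L))
  expect_equal(sum(g$cancer_counts), 1L)
  expect_equal(sum(g$cd8_counts), 1L)
  # a point on an interior boundary goes to the right-hand quadrat
  pb <- make_pattern(cbind(0.5, 0.1), cbind(0.1, 0.1),
                     window = c(0, 1, 0, 1))
  gb <- make_quadrat_grid(pb, 0.5)
  expect_equal(gb$cancer_counts[1, 2], 1L)
  expect_equal(gb$cancer_counts[1, 1], 0L)
  # points on the closed max edge are not lost
  pe <- make_pattern(cbind(1, 1), cbind(0, 0), window = c(0, 1, 0, 1))
  ge <- make_quadrat_grid(pe, 0.5)
  expect_equal(sum(ge$cancer_counts), 1L)
  expect_equal(ge$cancer_counts[2, 2], 1L)
})

test_that("quadrat counts match a brute-force binning oracle", {
  set.seed(54)
  win <- c(0, 4.3, 0, 3.1)           # non-multiple extent: edge quadrats
  ca <- cbind(runif(1000, win[1], win[2]), runif(1000, win[3], win[4]))
  cd <- cbind(runif(300, win[1], win[2]), runif(300, win[3], win[4]))
  pat <- make_pattern(ca, cd, window = win)
  g <- make_quadrat_grid(pat, 0.5)
  expect_identical(g$cancer_counts, brute_bin(ca[, 1], ca[, 2], win, 0.5))
  expect_identical(g$cd8_counts, brute_bin(cd[, 1], cd[, 2], win, 0.5))
  expect_equal(sum(g$cancer_counts), 1000L)
  # active mask is exactly the union support
  expect_identical(g$active, g$cancer_counts + g$cd8_counts > 0L)
  # translation equivariance
  sh <- make_pattern(ca + 2.5, cd + 2.5, window = win + 2.5)
  gs <- make_quadrat_grid(sh, 0.5)
  expect_identical(gs$cancer_counts, g$cancer_counts)
  expect_identical(gs$cd8_counts, g$cd8_counts)
})

test_that("quadrat summaries use active quadrats and sample SD", {
  g <- structure(list(subject_id = "H", origin = c(0, 0), cell_size = 0.5,
                      n_rows = 2L, n_cols = 2L,
                      cancer_counts = matrix(c(0L, 4L, 0L, 0L), 2),
                      cd8_counts = matrix(c(1L, 0L, 0L, 0L), 2),
                      active = matrix(c(TRUE, TRUE, FALSE, FALSE), 2)),
                 class = "quadrat_grid")
  s <- quadrat_summaries(g)
  expect_equal(s$quadrat_mean_cancer, 2)
  expect_equal(s$quadrat_sd_cancer, sqrt(8))
  expect_equal(s$quadrat_mean_cd8, 0.5)
  # constant counts -> sd 0
  g$cancer_counts <- matrix(2L, 2, 2); g$cd8_counts <- matrix(1L, 2, 2)
  g$active <- matrix(TRUE, 2, 2)
  expect_equal(quadrat_summaries(g)$quadrat_sd_cancer, 0)
  # single active quadrat -> warning (once per class), sd 0
  g$active <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  expect_warning(expect_warning(s1 <- quadrat_summaries(g), "single"),
                 "single")
  expect_equal(s1$quadrat_sd_cancer, 0)
})

test_that("quartic-kernel density conserves mass and is linear", {
  d1 <- density_map(cbind(0.5, 0.5), c(0, 1, 0, 1), bandwidth = 0.25,
                    resolution = 0.02)
  expect_true(all(d1$values >= 0))
  expect_equal(sum(d1$values) * 0.02^2, 1, tolerance = 0.02)
  # two coincident points: exactly twice the single-point surface
  d2 <- density_map(rbind(c(0.5, 0.5), c(0.5, 0.5)), c(0, 1, 0, 1),
                    bandwidth = 0.25, resolution = 0.02)
  expect_equal(d2$values, 2 * d1$values)
  expect_error(density_map(cbind(0.5, 0.5), c(0, 1, 0, 1), bandwidth = 0),
               "bandwidth")
})

test_that("density of a uniform pattern approaches its intensity", {
  set.seed(55)
  pts <- cbind(runif(1e4), runif(1e4))
  dm <- density_map(pts, c(0, 1, 0, 1), bandwidth = 0.1, resolution = 0.02)
  interior <- dm$x >= 0.1 & dm$x <= 0.9
  mean_int <- mean(dm$values[dm$y >= 0.1 & dm$y <= 0.9, interior])
  expect_equal(mean_int, 1e4, tolerance = 0.05)
})
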