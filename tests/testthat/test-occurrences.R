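grid10 <- grid2d(matrix(0, 10, 10), cell_size = 1000)

test_that("thinning keeps one record per cell with a stable tie-break", {
  ctr <- cell_centers(grid10, 1:5, 1:5)
  occ <- data.frame(x = ctr$x, y = ctr$y, year = 2000)
  r <- thin_occurrences(occ, grid10)
  expect_equal(nrow(r$kept), 5)
  expect_equal(nrow(r$rejected), 0)
  # four points piled in one cell: newest year wins
  pile <- data.frame(x = rep(ctr$x[1], 4) + c(0, 100, 200, 300),
                     y = rep(ctr$y[1], 4), year = c(2001, 2010, 2005, 2010))
  rp <- thin_occurrences(pile, grid10)
  expect_equal(nrow(rp$kept), 1)
  expect_equal(rp$kept$x, ctr$x[1] + 100)   # first of the 2010 ties
  expect_true(all(rp$rejected$reason == "duplicate_cell"))
  # kept count equals the number of distinct occupied cells
  cells <- c(1, 1, 2, 3, 3)
  occ2 <- data.frame(x = ctr$x[cells], y = ctr$y[cells])
  expect_equal(nrow(thin_occurrences(occ2, grid10)$kept),
               length(unique(cells)))
  expect_equal(nrow(thin_occurrences(occ2[0, ], grid10)$kept), 0)
})

test_that("the three exclusion rules fire in order with inclusive bounds", {
  elev <- grid2d(matrix(seq(100, 4000, length.out = 100), 10, 10),
                 cell_size = 1000)
  lc <- grid2d(matrix(rep(c(1, 2), 50), 10, 10), cell_size = 1000)
  poly <- cbind(c(0, 10000, 10000, 0), c(0, 0, 10000, 10000))
  occ <- data.frame(
    x = c(-500, 500, 1500, 2500, 3500),
    y = c(5500, 5500, 5500, 5500, 5500),
    elevation = c(1000, 1000, 2100, 1000, 1000))
  # row 3: elevation exactly elev_max + buffer is kept (inclusive)
  r <- filter_occurrences(occ, poly, elev, elev_min = 500, elev_max = 2000,
                          elev_buffer = 100, landcover = lc,
                          allowed_classes = c(1))
  expect_equal(nrow(r$kept) + nrow(r$rejected), nrow(occ))
  expect_equal(r$rejected$reason[r$rejected$x == -500], "outside_polygon")
  expect_true(1500 %in% r$kept$x)   # boundary elevation kept
  # landcover mismatch: lc alternates 1/2 down columns; odd rows are class 1
  occ_lc <- data.frame(x = 500, y = 10000 - 1500, elevation = 1000) # row 2
  r2 <- filter_occurrences(occ_lc, poly, elev, 500, 2000, 100, lc, c(1))
  expect_equal(r2$rejected$reason, "landcover_mismatch")
  # elevation falls back to the layer when the record lacks it
  occ_na <- data.frame(x = 500, y = 9500)  # row 1 -> elev value 100
  r3 <- filter_occurrences(occ_na, poly, elev, 500, 2000, 100)
  expect_equal(r3$rejected$reason, "elevation_out_of_range")
})

test_that("filtering is idempotent and order-independent", {
  elev <- grid2d(matrix(1500, 10, 10), cell_size = 1000)
  poly <- cbind(c(0, 6000, 6000, 0), c(0, 0, 10000, 10000))
  set.seed(31)
  occ <- data.frame(x = runif(40, 0, 10000), y = runif(40, 0, 10000),
                    elevation = runif(40, 0, 3000))
  r1 <- filter_occurrences(occ, poly, elev, 1000, 2000)
  r2 <- filter_occurrences(r1$kept, poly, elev, 1000, 2000)
  expect_equal(r1$kept, r2$kept, ignore_attr = TRUE)
  expect_equal(nrow(r2$rejected), 0)
  perm <- sample(nrow(occ))
  r3 <- filter_occurrences(occ[perm, ], poly, elev, 1000, 2000)
  expect_setequal(paste(r3$kept$x, r3$kept$y), paste(r1$kept$x, r1$kept$y))
})

test_that("pseudo-absence draws exclude presences and honour seeds", {
  mask <- grid2d(matrix(0, 10, 10), cell_size = 1000)
  pres <- c(5L, 17L, 60L)
  # exhaustive draw uses every valid non-presence cell once
  full <- sample_pseudo_absences(mask, 97, pres, n_sets = 1, seed = 2)
  expect_equal(sort(full[[1]]$cells), setdiff(1:100, pres))
  # presences never sampled, over many seeds
  for (s in 1:100) {
    pa <- sample_pseudo_absences(mask, 50, pres, n_sets = 1, seed = s)
    expect_length(intersect(pa[[1]]$cells, pres), 0)
  }
  # reproducible by seed; distinct sets differ
  a <- sample_pseudo_absences(mask, 30, pres, n_sets = 3, seed = 11)
  b <- sample_pseudo_absences(mask, 30, pres, n_sets = 3, seed = 11)
  expect_identical(a[[1]]$cells, b[[1]]$cells)
  expect_false(identical(sort(a[[1]]$cells), sort(a[[2]]$cells)))
  expect_error(sample_pseudo_absences(mask, 200, pres, 1, 1), "available")
})

test_that("occurrence and polygon files round-trip", {
  occ <- data.frame(x = c(1.5, 2.5), y = c(3, 4), elevation = c(100, 200),
                    year = c(2001L, 2002L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, p)
  expect_equal(read_occurrences(p), occ)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_occurrences_geojson(occ, gj)
  j <- jsonlite::read_json(gj)
  expect_length(j$features, 2)
  poly <- cbind(c(0, 2, 1), c(0, 0, 2))
  pg <- withr::local_tempfile(fileext = ".geojson")
  write_polygon_geojson(poly, pg)
  back <- read_polygon_geojson(pg)
  expect_equal(back[1:3, ], poly, ignore_attr = TRUE)
})
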