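test_that("Clarke zones match the canonical rule set on known points", {
  expect_equal(as.character(clarke_zone(120, 123)), "A")
  expect_equal(as.character(clarke_zone(50, 200)), "E")
  expect_equal(as.character(clarke_zone(200, 45)), "E")
  expect_equal(as.character(clarke_zone(100, 215)), "C")   # pred >= ref + 110
  expect_equal(as.character(clarke_zone(150, 25)), "C")    # pred <= 1.4 ref - 182
  expect_equal(as.character(clarke_zone(300, 120)), "D")
  expect_equal(as.character(clarke_zone(50, 120)), "D")
  expect_equal(as.character(clarke_zone(150, 190)), "B")
  # 20% band edge belongs to A
  expect_equal(as.character(clarke_zone(100, 120)), "A")
  expect_equal(as.character(clarke_zone(100, 120.5)), "B")
})

test_that("Clarke assignment partitions the plane and keeps the diagonal in A", {
  grid <- expand.grid(ref = seq(1, 400, by = 7), pred = seq(0, 400, by = 7))
  z <- clarke_zone(grid$ref, grid$pred)
  expect_false(anyNA(z))
  diag_z <- clarke_zone(1:400, 1:400)
  expect_true(all(diag_z == "A"))
})

test_that("Clarke E corners are symmetric under axis swap", {
  set.seed(5)
  a <- runif(500, 1, 400); b <- runif(500, 1, 400)
  expect_equal(clarke_zone(a, b) == "E", clarke_zone(b, a) == "E")
})

test_that("Parkes zones keep the diagonal in A and honour the type-2 contract", {
  for (type in c("type1", "type2")) {
    expect_true(all(parkes_zone(c(50, 150, 350), c(50, 150, 350), type) == "A"))
    expect_true(all(parkes_zone(1:550, 1:550, type) == "A"))
  }
  grid <- expand.grid(ref = seq(0, 550, by = 10), pred = seq(0, 550, by = 10))
  z2 <- parkes_zone(grid$ref, grid$pred, "type2")
  expect_false(anyNA(z2))
  expect_false(any(z2 == "E"))
  z1 <- parkes_zone(grid$ref, grid$pred, "type1")
  expect_true(any(z1 == "E"))  # type 1 retains the extreme upper zone
})

test_that("Parkes assignment matches an independent point-in-polygon oracle", {
  set.seed(12)
  n <- 1000
  ref <- runif(n, 0, 550); pred <- runif(n, 0, 550)
  for (type in c("type1", "type2")) {
    got <- as.character(parkes_zone(ref, pred, type))
    want <- vapply(seq_len(n),
                   function(i) oracle_parkes_zone(ref[i], pred[i], type),
                   character(1))
    expect_equal(got, want, label = paste("parkes", type))
  }
})

test_that("Parkes risk rank is monotone along vertical lines", {
  rank_of <- c(A = 1, B = 2, C = 3, D = 4, E = 5)
  for (type in c("type1", "type2")) {
    for (ref in c(5, 60, 120, 200, 340, 500)) {
      up <- as.character(parkes_zone(rep(ref, 111),
                                     seq(ref, 550, length.out = 111), type))
      expect_true(all(diff(rank_of[up]) >= 0),
                  label = sprintf("%s up at ref=%g", type, ref))
      down <- as.character(parkes_zone(rep(ref, 111),
                                       seq(ref, 0, length.out = 111), type))
      expect_true(all(diff(rank_of[down]) >= 0),
                  label = sprintf("%s down at ref=%g", type, ref))
    }
  }
})

test_that("out-of-domain Parkes readings are clipped with a warning", {
  expect_warning(z <- parkes_zone(600, 600), "clipped")
  expect_equal(as.character(z), "A")
})

test_that("surrogate SEG surface is zero on the diagonal and capped at 4", {
  g <- seg_surrogate_grid()
  expect_identical(g$provenance, "surrogate")
  expect_equal(seg_risk(c(40, 120, 300, 600), c(40, 120, 300, 600), g),
               rep(0, 4))
  expect_true(all(g$risk >= 0 & g$risk <= 4))
})

test_that("SEG interpolation is exact on nodes and bilinear between them", {
  g <- seg_surrogate_grid(step = 5)
  # lattice nodes reproduce stored values exactly
  set.seed(3)
  i <- sample(seq_along(g$ref), 50, replace = TRUE)
  j <- sample(seq_along(g$pred), 50, replace = TRUE)
  expect_equal(seg_risk(g$ref[i], g$pred[j], g), g$risk[cbind(i, j)])
  # cell-centre value is the mean of the 4 surrounding nodes
  i <- sample(seq_along(g$ref)[-length(g$ref)], 20)
  j <- sample(seq_along(g$pred)[-length(g$pred)], 20)
  mid <- seg_risk(g$ref[i] + 2.5, g$pred[j] + 2.5, g)
  corners <- (g$risk[cbind(i, j)] + g$risk[cbind(i + 1L, j)] +
                g$risk[cbind(i, j + 1L)] + g$risk[cbind(i + 1L, j + 1L)]) / 4
  expect_equal(mid, corners, tolerance = 1e-12)
  expect_warning(seg_risk(650, 100, g), "clamped")
})

test_that("SEG grids survive a CSV round trip", {
  g <- seg_surrogate_grid(step = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_seg_grid(g, path)
  back <- read_seg_grid(path, provenance = "surrogate")
  expect_equal(back$ref, g$ref)
  expect_equal(back$pred, g$pred)
  expect_equal(back$risk, g$risk, tolerance = 1e-12)
})

test_that("SEG risk categories follow the published bins", {
  expect_equal(as.character(seg_category(0)), "none")
  expect_equal(as.character(seg_category(0.3)), "none")
  expect_equal(as.character(seg_category(0.5)), "none")       # closed at 0.5
  expect_equal(as.character(seg_category(0.500001)), "slight_lower")
  expect_equal(as.character(seg_category(0.8)), "slight_lower")
  expect_equal(as.character(seg_category(1.2)), "slight_higher")
  expect_equal(as.character(seg_category(3.4)), "great_higher")
  expect_equal(as.character(seg_category(3.7)), "extreme")
  expect_error(seg_category(-0.1), "non-negative")
})

test_that("zone summaries count, percentage and partition correctly", {
  s <- summarize_zones(rep(100, 125), rep(100, 125), "clarke")
  expect_equal(s$n[s$zone == "A"], 125L)
  expect_equal(s$pct[s$zone == "A"], 100)
  # a constructed 121 / 4 split of no-risk and slight-risk readings
  ref <- rep(200, 125)
  pred <- c(rep(200, 121), rep(200 * 1.2, 4))  # |d|/ref = 0.2 -> risk 0.8
  s2 <- summarize_zones(ref, pred, "seg")
  expect_equal(s2$n[s2$zone == "none"], 121L)
  expect_equal(s2$n[s2$zone == "slight_lower"], 4L)
  expect_equal(s2$pct[s2$zone == "none"], 96.8)
  expect_equal(s2$pct[s2$zone == "slight_lower"], 3.2)
  # partition property on random inputs
  set.seed(8)
  ref <- runif(200, 1, 400); pred <- runif(200, 0, 400)
  for (grid in c("clarke", "parkes_t1", "parkes_t2", "seg")) {
    s3 <- summarize_zones(ref, pred, grid)
    expect_equal(sum(s3$n), 200L)
    expect_equal(sum(s3$pct), 100, tolerance = 1e-9)
  }
  expect_error(summarize_zones(numeric(0), numeric(0), "clarke"), "at least one")
})
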