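seg_len <- function(s) sqrt((s$x2 - s$x1)^2 + (s$y2 - s$y1)^2)

test_that("vernier geometry matches the printed dimensions", {
  v <- make_vernier(0)
  expect_equal(nrow(v), 2)
  expect_true(all(v$orientation_class == "vertical"))
  expect_equal(seg_len(v), c(40, 40))
  # 4' gap between the lines, total extent 84'
  ys <- sort(c(v$y1, v$y2))
  expect_equal(ys[3] - ys[2], 4)
  expect_equal(max(ys) - min(ys), 84)
  # zero offset: collinear
  expect_equal(unique(c(v$x1, v$x2)), 0)
})

test_that("vernier offset is applied wholly to the bottom line", {
  v <- make_vernier(800)
  top <- v[v$y1 > 0, ]; bot <- v[v$y1 < 0, ]
  expect_equal(top$x1, 0)
  expect_equal(bot$x1, 800 / 60, tolerance = 1e-12)  # 13.333... arcmin
  expect_equal(seg_len(v), c(40, 40))
  # sign convention: positive = rightward
  expect_lt(make_vernier(-300)[2, "x1"], 0)
})

test_that("offsets beyond the 1600-arcsec bound are rejected", {
  expect_error(make_vernier(1601), "1600")
  expect_error(make_vernier(-2000), "1600")
  expect_silent(make_vernier(1600))
})

test_that("flanker configurations reproduce every printed dimension", {
  ln <- make_flankers("Lines")
  expect_equal(seg_len(ln), c(84, 84))
  expect_equal(sort(ln$x1), c(-23, 23))          # spaced 46' apart

  rc <- make_flankers("Rectangles")
  for (xc in c(-81.5, 81.5)) {
    side <- rc[abs((rc$x1 + rc$x2) / 2 - xc) < 60, ]
    expect_equal(max(side$x2) - min(side$x1), 117)   # width
    expect_equal(max(side$y2) - min(side$y1), 84)    # same height as lines
  }

  cb <- make_flankers("Cubes")
  obl <- cb[cb$orientation_class %in% c("diag45", "diag135"), ]
  expect_equal(nrow(obl), 6)                      # three obliques per side
  expect_equal(seg_len(obl), rep(53, 6), tolerance = 1e-9)
  ang <- abs(atan2(obl$y2 - obl$y1, obl$x2 - obl$x1)) * 180 / pi
  expect_true(all(abs(ang %% 90 - 45) < 1e-9))    # 45 degrees

  tr <- make_flankers("Triangles")
  inner <- tr[tr$orientation_class == "vertical", ]
  expect_equal(seg_len(inner), c(84, 84))
  expect_equal(sort(inner$x1), c(-23, 23))
  expect_equal(seg_len(tr[tr$orientation_class != "vertical", ]),
               rep(124.3, 4), tolerance = 1e-9)

  cr <- make_flankers("CentralRectangle")
  expect_equal(max(cr$x2) - min(cr$x1), 46)
  expect_equal(max(cr$y2) - min(cr$y1), 84)
  expect_equal(mean(range(c(cr$x1, cr$x2))), 0)   # centred on the vernier
})

test_that("configuration nesting holds: Lines in Rectangles in Cubes", {
  key <- function(s) apply(round(s[, c("x1", "y1", "x2", "y2")] / 0.01), 1,
                           paste, collapse = ",")
  ln <- key(make_flankers("Lines"))
  rc <- key(make_flankers("Rectangles"))
  cb <- key(make_flankers("Cubes"))
  expect_true(all(ln %in% rc))
  expect_true(all(rc %in% cb))
})

test_that("flanker sets are mirror symmetric about x = 0", {
  # canonical key: endpoint order within a segment is irrelevant
  key <- function(d) {
    k <- apply(round(d[, c("x1", "y1", "x2", "y2")] / 0.001), 1, function(s) {
      a <- s[1:2]; b <- s[3:4]
      if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) { t <- a; a <- b; b <- t }
      paste(c(a, b), collapse = ",")
    })
    sort(k)
  }
  for (cfg in c("Lines", "Rectangles", "Cubes", "Triangles",
                "CentralRectangle")) {
    s <- make_flankers(cfg)
    mirrored <- data.frame(x1 = -s$x1, y1 = s$y1, x2 = -s$x2, y2 = s$y2)
    expect_equal(key(mirrored), key(s), info = cfg)
  }
  # and a mirrored frame maps +offset to -offset
  f <- make_frame("Lines", 600)
  m <- f$segments
  m[, c("x1", "x2")] <- -m[, c("x1", "x2")]
  expect_equal(key(m), key(make_frame("Lines", -600)$segments))
})

test_that("ScrambledCubes preserves segment lengths and orientations", {
  sc <- make_flankers("ScrambledCubes", seed = 42)
  cb <- make_flankers("Cubes")
  expect_equal(sort(round(seg_len(sc), 6)), sort(round(seg_len(cb), 6)))
  expect_equal(sort(sc$orientation_class), sort(cb$orientation_class))
  # reproducible given the seed; different across seeds
  expect_identical(sc, make_flankers("ScrambledCubes", seed = 42))
  expect_false(identical(sc, make_flankers("ScrambledCubes", seed = 43)))
  expect_error(make_flankers("ScrambledCubes"), "seed")
  # the shuffle never occludes the vernier zone |x| < 15'
  for (seed in 1:20) {
    s <- make_flankers("ScrambledCubes", seed = seed)
    expect_true(all(pmax(s$x1, s$x2) <= -15 | pmin(s$x1, s$x2) >= 15))
  }
})

test_that("unknown configurations are rejected", {
  expect_error(make_flankers("Hexagons"), "unknown")
  expect_error(stimulus_frame(make_vernier(0), vernier_offset = 100,
                              contains_vernier = FALSE), "vernier_offset")
})

test_that("rasterization is deterministic, channel-exclusive and counted", {
  rg <- raster_geometry()
  # empty frame -> all-zero raster
  expect_equal(sum(rasterize(blank_frame(), rg)$arr), 0)
  # single vertical 40' segment at 0.5 px/arcmin -> 20 vertical-channel px
  f <- stimulus_frame(data.frame(x1 = 0, y1 = 2, x2 = 0, y2 = 42,
                                 orientation_class = "vertical"))
  r <- rasterize(f, rg)
  expect_equal(sum(r$arr[1, , ]), 20)
  expect_equal(sum(r$arr[2:4, , ]), 0)
  # 45-degree oblique marks only the diag45 channel
  o <- stimulus_frame(data.frame(x1 = 0, y1 = 0, x2 = 30, y2 = 30,
                                 orientation_class = "diag45"))
  ro <- rasterize(o, rg)
  expect_gt(sum(ro$arr[3, , ]), 0)
  expect_equal(sum(ro$arr[c(1, 2, 4), , ]), 0)
  # determinism / idempotence
  expect_identical(rasterize(f, rg)$arr, r$arr)
})

test_that("doubling resolution doubles axis-aligned pixel counts", {
  f <- stimulus_frame(data.frame(x1 = c(0, 3), y1 = c(2, 7),
                                 x2 = c(0, 63), y2 = c(42, 7),
                                 orientation_class = c("vertical", "horizontal")))
  n1 <- sum(rasterize(f, raster_geometry(0.5))$arr)
  n2 <- sum(rasterize(f, raster_geometry(1, c(-201, 201), c(-101, 101)))$arr)
  expect_lte(abs(n2 - 2 * n1), 2)   # +/- 1 px end effect per segment
})

test_that("segments exceeding the canvas are rejected by name", {
  f <- stimulus_frame(data.frame(x1 = 0, y1 = 0, x2 = 500, y2 = 0,
                                 orientation_class = "horizontal"))
  expect_error(rasterize(f, raster_geometry()), "segment 1")
})

test_that("frame sequences encode the experimental timelines", {
  s <- build_sequence(2, list(flanker = "Cubes", design = "preview"))
  expect_equal(s$durations_ms, c(20, 120, 20))
  expect_equal(s$vernier_onset_ms, 140)
  expect_false(s$frames[[1]]$contains_vernier)
  expect_true(s$frames[[3]]$contains_vernier)

  s1 <- build_sequence(1, list(flanker = "Lines", duration_ms = 160))
  expect_equal(s1$durations_ms, 160)
  expect_equal(s1$vernier_onset_ms, 0)

  s4 <- build_sequence(4, list(intermediate = "Triangles"))
  expect_equal(sum(s4$durations_ms), 300)   # 20+120+20+120+20
  expect_equal(s4$vernier_onset_ms, 280)

  # exactly one vernier-bearing frame in every experimental condition
  for (e in 1:4) for (cd in experiment_conditions(e)) {
    sq <- build_sequence(e, cd, seed = 3)
    expect_equal(sum(vapply(sq$frames, function(f) f$contains_vernier,
                            logical(1))), 1)
    expect_true(all(sq$durations_ms %% 20 == 0))
  }
})

test_that("invalid experiment/condition pairings are rejected", {
  expect_error(build_sequence(1, list(flanker = "Cubes", duration_ms = 80)),
               "invalid condition")
  expect_error(build_sequence(2, list(flanker = "Rectangles",
                                      design = "preview")), "invalid")
  expect_error(build_sequence(3, list(isi_ms = 50)), "invalid")
  expect_error(build_sequence(4, list(intermediate = "Hexagons")), "invalid")
})

test_that("geometry invariants are enforced", {
  expect_error(geometry_spec(vernier_line_len = -1), "positive")
  expect_error(geometry_spec(vernier_gap = 10), "flanker_line_len")
  expect_error(geometry_spec(nonsense = 1), "unknown")
  # self-consistency: 2*40 + 4 == 84
  g <- geometry_spec()
  expect_equal(2 * g$vernier_line_len + g$vernier_gap, g$flanker_line_len)
})

test_that("segment CSV export round-trips coordinates", {
  path <- tempfile(fileext = ".csv")
  f <- make_frame("Lines", 240)
  write_segment_csv(list(f), path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), nrow(f$segments))
  expect_equal(tab$x1, f$segments$x1)
  unlink(path)
})
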