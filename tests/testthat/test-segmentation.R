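test_that("spreading on a toy cross equals the BFS ball", {
  H <- 7; W <- 7
  cross <- matrix(FALSE, H, W)
  cross[4, ] <- TRUE; cross[, 4] <- TRUE
  p <- model_params(spread_px_per_step = 1, spread_activity_exponent = 0,
                    tau_contour_ms = 1e9, seed_jitter_arcmin = 0)
  st <- toy_state(cross, seed_px = cbind(4, 4), params = p)
  for (k in 1:3) {
    st <- seed_and_spread(st, p)
    oracle <- bfs_select_oracle(cross, cbind(4, 4), rings = k)
    expect_identical(st$s > 0, oracle, info = paste("step", k))
  }
})

test_that("selection spreading matches the budgeted BFS oracle on random maps", {
  set.seed(202)
  for (rep in 1:12) {
    H <- sample(16:32, 1); W <- sample(16:32, 1)
    m <- random_contour_map(H, W)
    seed_px <- which(m, arr.ind = TRUE)[1, , drop = FALSE]
    v <- sample(1:3, 1)
    p <- model_params(spread_px_per_step = v, spread_activity_exponent = 0,
                      tau_contour_ms = 1e9)
    st <- toy_state(m, seed_px, params = p)
    steps <- sample(2:4, 1)
    for (k in seq_len(steps)) st <- seed_and_spread(st, p)
    oracle <- bfs_select_oracle(m, seed_px, rings = v * steps)
    expect_identical(st$s > 0, oracle)
  }
})

test_that("a seed with no contour neighbours never grows", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE          # isolated pixel
  m[1, 1] <- TRUE          # distant pixel, beyond gap tolerance
  p <- model_params(spread_px_per_step = 2, spread_activity_exponent = 0,
                    tau_contour_ms = 1e9)
  st <- toy_state(m, cbind(5, 5), params = p)
  for (k in 1:5) st <- seed_and_spread(st, p)
  expect_identical(which(st$s > 0), which(m & row(m) == 5 & col(m) == 5))
})

test_that("disconnected components are never co-selected", {
  m <- matrix(FALSE, 12, 12)
  m[3, 2:5] <- TRUE                 # component A
  m[9:11, 8] <- TRUE                # component B, > 2 px away
  p <- model_params(spread_px_per_step = 3, spread_activity_exponent = 0,
                    tau_contour_ms = 1e9)
  st <- toy_state(m, cbind(3, 2), params = p)
  for (k in 1:10) st <- seed_and_spread(st, p)
  expect_true(all(st$s[9:11, 8] == 0))
  expect_true(all(st$s[3, 2:5] > 0))
})

test_that("the miss property holds: no seeded contour, no Layer-1 activity", {
  rg <- test_rg()
  p <- zero_jitter_params()
  sig <- data.frame(side = "right", center_x = 190, center_y = -95,
                    radius = 5, onset_ms = 0)   # empty corner of the canvas
  st <- init_segmentation(rg, sig)
  r <- rasterize(make_frame("Cubes", 240), rg)
  for (k in 1:10) st <- step_segmentation(st, r, p)
  expect_equal(total_activity(st$field, 1), 0)
  expect_gt(total_activity(st$field, 0), 0)
})

test_that("transfer conserves per-pixel two-layer activity", {
  rg <- raster_geometry(1, c(0, 20), c(0, 15))
  p <- model_params(transfer_rate = 0.7)
  st <- init_segmentation(rg, NULL)
  set.seed(11)
  st$field$a[1, , , ] <- array(runif(4 * 15 * 20, 0, 0.6), c(4, 15, 20))
  st$field$a[2, , , ] <- array(runif(4 * 15 * 20, 0, 0.3), c(4, 15, 20))
  st$s <- matrix(runif(15 * 20), 15, 20)
  st$seeded <- TRUE
  pre <- st$field$a[1, , , ] + st$field$a[2, , , ]
  st2 <- transfer_contours(st, p)
  post <- st2$field$a[1, , , ] + st2$field$a[2, , , ]
  expect_equal(post, pre, tolerance = 1e-12)
  expect_true(all(st2$field$a >= 0 & st2$field$a <= 1))
})

test_that("transfer_rate 1 with full mask shifts everything at once", {
  rg <- raster_geometry(1, c(0, 10), c(0, 10))
  p <- model_params(transfer_rate = 1)
  st <- init_segmentation(rg, NULL)
  st$field$a[1, 1, 3, 4] <- 0.8
  st$s <- matrix(1, 10, 10)
  st$seeded <- TRUE
  st <- transfer_contours(st, p)
  expect_equal(st$field$a[1, 1, 3, 4], 0)
  expect_equal(st$field$a[2, 1, 3, 4], 0.8)
})

test_that("step_segmentation equals the manual sub-step composition", {
  rg <- test_rg()
  p <- zero_jitter_params()
  sq <- build_sequence(2, list(flanker = "Cubes", design = "preview"))
  rasters <- lapply(sq$frames, function(f)
    if (nrow(f$segments) == 0) NULL else rasterize(f, rg))
  steps <- rep(seq_along(sq$frames), sq$durations_ms / 20)
  sig <- place_selection_signals("Cubes", p, onset_ms = 0)
  a <- init_segmentation(rg, sig)
  b <- init_segmentation(rg, sig)
  for (k in seq_along(steps)) {
    input <- rasters[[steps[k]]]
    a <- step_segmentation(a, input, p)
    route <- if (b$seeded) pmax(b$disc, b$s) else NULL
    b$field <- step_field(b$field, input, p, route_mask = route)
    if (!b$seeded) b <- seed_selection(b, p)
    b <- seed_and_spread(b, p)
    b <- transfer_contours(b, p)
    expect_equal(a$field$a, b$field$a, tolerance = 1e-12)
    expect_equal(a$s, b$s, tolerance = 1e-12)
  }
})

test_that("mirrored stimulus and seeds give the mirrored state", {
  rg <- test_rg()
  p <- zero_jitter_params()
  # geometry with flanking lines off pixel boundaries so the raster
  # mirrors exactly
  geom <- geometry_spec(line_separation = 45)
  mk <- function(off) {
    f <- make_frame("Lines", off, geom = geom)
    rasterize(f, rg)
  }
  sigR <- data.frame(side = c("left", "right"), center_x = c(-22.5, 22.5),
                     center_y = 0, radius = 50, onset_ms = 0)
  stP <- init_segmentation(rg, sigR)
  stM <- init_segmentation(rg, sigR)   # symmetric seeds mirror onto themselves
  rp <- mk(240); rm <- mk(-240)
  for (k in 1:6) {
    stP <- step_segmentation(stP, rp, p)
    stM <- step_segmentation(stM, rm, p)
    flip <- function(m) m[, rev(seq_len(ncol(m)))]
    expect_equal(flip(stP$field$a[1, 1, , ]), stM$field$a[1, 1, , ],
                 tolerance = 1e-12)
    expect_equal(flip(stP$s), stM$s, tolerance = 1e-12)
  }
})

test_that("selection placement is reproducible and symmetric", {
  p <- model_params()
  set.seed(5); a <- place_selection_signals("Cubes", p)
  set.seed(5); b <- place_selection_signals("Cubes", p)
  expect_identical(a, b)
  z <- place_selection_signals("Cubes", zero_jitter_params())
  expect_equal(z$center_x[1], -z$center_x[2])
  expect_equal(z$center_y[1], z$center_y[2])
  expect_equal(nrow(place_selection_signals("unflanked", p)), 0)
})

test_that("Lines seeds cover the vernier zone, Cubes seeds do not", {
  p <- zero_jitter_params()
  ln <- place_selection_signals("Lines", p)
  cb <- place_selection_signals("Cubes", p)
  # distance from each seed centre to the vernier centre (0, 0)
  d_ln <- sqrt(ln$center_x^2 + ln$center_y^2)
  d_cb <- sqrt(cb$center_x^2 + cb$center_y^2)
  expect_true(all(d_ln < ln$radius))    # target zone inside the Lines seed
  expect_true(all(d_cb > cb$radius))    # Cubes seeds exclude the vernier
})

test_that("flanker contours segregate to Layer 1 while the vernier stays", {
  rg <- test_rg()
  p <- zero_jitter_params()
  sq <- build_sequence(1, list(flanker = "Cubes", duration_ms = 160))
  r_flank <- rasterize(make_frame("Cubes", 0, with_vernier = FALSE), rg)
  r_vern <- rasterize(make_frame("unflanked", 240), rg)
  r_all <- rasterize(sq$frames[[1]], rg)
  sig <- place_selection_signals("Cubes", p, onset_ms = 0)
  st <- init_segmentation(rg, sig)
  for (k in 1:8) st <- step_segmentation(st, r_all, p)   # 160 ms
  fl <- r_flank$arr > 0; vn <- r_vern$arr > 0
  flank_l0 <- sum(st$field$a[1, , , ][fl]); flank_l1 <- sum(st$field$a[2, , , ][fl])
  vern_l0 <- sum(st$field$a[1, , , ][vn]); vern_l1 <- sum(st$field$a[2, , , ][vn])
  expect_gte(flank_l1 / (flank_l0 + flank_l1), 0.8)
  expect_gte(vern_l0 / (vern_l0 + vern_l1), 0.8)
})
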