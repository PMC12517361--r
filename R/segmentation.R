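#' Fixed selection-signal anchor for a flanker configuration
#'
#' The top-down selection signal is planted at a fixed, configuration-
#' specific location that yields good segmentation when segmentation is
#' feasible. For the large flankers (Rectangles, Cubes, ScrambledCubes,
#' Triangles) the anchor sits at the outer-top corner of the flanker's
#' front face, far from the vernier, so the signal never covers the target
#' and must spread inward along the flanker contours before the inner
#' edges are released from the readout layer. For the small Lines (and the
#' Central-Rectangle, whose vertical edges sit at the Lines positions) the
#' only available structure is at +/-23', so the signal unavoidably covers
#' both the line and the region where the vernier appears.
#'
#' @param config flanker configuration name.
#' @param geom geometry spec.
#' @return data.frame with columns side, x, y (arcmin).
#' @keywords internal
flanker_anchor <- function(config, geom = geometry_spec()) {
  xin <- geom$line_separation / 2
  xout <- xin + geom$rect_width
  h2 <- geom$flanker_line_len / 2
  a <- switch(config,
    Lines            = c(xin, 0),
    CentralRectangle = c(geom$central_rect_w / 2, 0),
    Rectangles       = c(xout, h2),
    Cubes            = c(xout, h2),
    ScrambledCubes   = c(xout, h2),
    Triangles        = c(xin + sqrt(geom$triangle_oblique^2 -
                                    (geom$triangle_inner / 2)^2), 0),
    stop("no selection anchor for configuration: ", config)
  )
  data.frame(side = c("left", "right"), x = c(-a[1], a[1]),
             y = c(a[2], a[2]), stringsAsFactors = FALSE)
}

#' Place top-down selection signals for a condition
#'
#' One signal per flanker side, centred on the configuration's fixed anchor
#' plus isotropic Gaussian jitter (the only stochastic element of a model
#' trial besides the ScrambledCubes shuffle). Signals are planted at the
#' onset of the first flanker-bearing frame.
#'
#' @param config flanker configuration of the first flanker frame, or
#'   `"unflanked"`.
#' @param params [model_params()].
#' @param geom geometry spec.
#' @param onset_ms onset time of the first flanker frame.
#' @return data.frame with columns side, center_x, center_y, radius,
#'   onset_ms (empty for unflanked conditions).
#' @export
place_selection_signals <- function(config, params = model_params(),
                                    geom = geometry_spec(), onset_ms = 0) {
  if (identical(config, "unflanked"))
    return(data.frame(side = character(0), center_x = numeric(0),
                      center_y = numeric(0), radius = numeric(0),
                      onset_ms = numeric(0)))
  anc <- flanker_anchor(config, geom)
  n <- nrow(anc)
  data.frame(side = anc$side,
             center_x = anc$x + stats::rnorm(n, 0, params$seed_jitter_arcmin),
             center_y = anc$y + stats::rnorm(n, 0, params$seed_jitter_arcmin),
             radius = params$seed_radius_arcmin,
             onset_ms = onset_ms,
             stringsAsFactors = FALSE)
}

#' Initialise a segmentation state
#'
#' @param rg raster geometry.
#' @param signals selection signals (from [place_selection_signals()]).
#' @return `segmentation_state`: field, seed-disc mask `disc`, spread mask
#'   `s`, signals, fractional ring budget `carry`, `seeded` flag.
#' @export
init_segmentation <- function(rg = raster_geometry(), signals = NULL) {
  structure(list(field = init_field(rg),
                 disc = matrix(0, rg$H, rg$W),
                 s = matrix(0, rg$H, rg$W),
                 signals = signals,
                 carry = 0,
                 seeded = FALSE),
            class = "segmentation_state")
}

# per-pixel contour support: max activity over layers and channels
contour_support <- function(field) {
  a <- field$a
  m <- a[1, 1, , ]
  for (l in 1:2) for (ch in 1:4) m <- pmax(m, a[l, ch, , ])
  m
}

# Chebyshev-radius-1 binary dilation via shifts (separable 3x3 max).
# One spreading ring is two of these (Chebyshev radius 2), which gives
# 8-connected growth with a one-pixel gap tolerance.
dilate1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  r <- m
  r[-H, ] <- r[-H, ] | m[-1, ]
  r[-1, ] <- r[-1, ] | m[-H, ]
  out <- r
  out[, -W] <- out[, -W] | r[, -1]
  out[, -1] <- out[, -1] | r[, -W]
  out
}

#' Plant selection signals into the state (seeding)
#'
#' Marks the seed discs: every pixel within a signal's radius becomes part
#' of the persistent top-down selected region; contour-bearing pixels
#' inside a disc additionally start the spreading mask.
#'
#' @param state segmentation_state.
#' @param params model params.
#' @return updated state.
#' @export
seed_selection <- function(state, params = model_params()) {
  rg <- state$field$rg
  sig <- state$signals
  if (is.null(sig) || nrow(sig) == 0) { state$seeded <- TRUE; return(state) }
  xc <- rg$xlim[1] + (seq_len(rg$W) - 0.5) / rg$ppa
  yc <- rg$ylim[1] + (seq_len(rg$H) - 0.5) / rg$ppa
  disc <- state$disc
  for (i in seq_len(nrow(sig))) {
    dx2 <- outer(rep(1, rg$H), (xc - sig$center_x[i])^2)
    dy2 <- outer((yc - sig$center_y[i])^2, rep(1, rg$W))
    disc[dx2 + dy2 <= sig$radius[i]^2] <- 1
  }
  state$disc <- disc
  supp <- contour_support(state$field)
  state$s <- pmax(state$s, disc * (supp >= params$act_threshold))
  state$seeded <- TRUE
  state
}

#' Spread the selection mask along connected contours (one step)
#'
#' The mask grows by breadth-first rings over contour-bearing pixels
#' (8-connected with a one-pixel gap tolerance, i.e. Chebyshev radius 2 per
#' ring). The per-step ring budget is `spread_px_per_step * mean(a)^p` over
#' the contour pixels just ahead of the front, so spreading is fast along
#' driven contours and slows as contours fade; fractional budget carries
#' over. Where the supporting contour activity has fallen below
#' `act_threshold` the spread mask decays with `tau_selection_ms`.
#'
#' @param state segmentation_state (seeded).
#' @param params model params.
#' @return updated state.
#' @export
seed_and_spread <- function(state, params = model_params()) {
  if (!state$seeded) state <- seed_selection(state, params)
  supp <- contour_support(state$field)
  contour <- supp >= params$act_threshold
  sel <- (state$disc > 0 & contour) | (state$s > 0)
  # contour pixels adjacent to the current front set the speed
  if (any(sel)) {
    halo <- dilate1(dilate1(sel)) & contour & !sel
    a_ahead <- if (any(halo)) mean(supp[halo]) else 0
    budget <- state$carry +
      params$spread_px_per_step * a_ahead^params$spread_activity_exponent
    rings <- floor(budget)
    state$carry <- budget - rings
    if (rings > 0 && any(halo)) {
      s <- state$s
      grown <- sel
      for (k in seq_len(rings)) {
        new <- dilate1(dilate1(grown)) & contour & !grown
        if (!any(new)) break
        grown <- grown | new
      }
      s[grown & contour] <- pmax(s[grown & contour], 1)
      state$s <- s
    } else {
      state$s[sel & contour] <- pmax(state$s[sel & contour], 1)
    }
  }
  # decay where the supporting contour is gone; hold where it persists
  dead <- !contour & state$s > 0
  if (any(dead))
    state$s[dead] <- state$s[dead] * exp(-params$dt_ms / params$tau_selection_ms)
  state$s[state$s < 1e-3] <- 0
  state
}

#' Transfer selected contours from Layer 0 to Layer 1 (one step)
#'
#' At each selected pixel a fraction `transfer_rate * m` of the Layer-0
#' activity moves to Layer 1 at the same pixel, in every channel, where
#' `m` is the combined selection mask (seed disc or spread mask). The
#' transfer conserves per-pixel Layer0+Layer1 activity exactly wherever
#' Layer 1 has headroom; at a Layer-1 pixel already driven to saturation
#' the incoming activity saturates at 1, exactly as bottom-up drive does
#' in Layer 0.
#'
#' @param state segmentation_state.
#' @param params model params.
#' @return updated state.
#' @export
transfer_contours <- function(state, params = model_params()) {
  m <- pmax(state$disc, state$s)
  if (!any(m > 0)) return(state)
  f <- params$transfer_rate * m
  a <- state$field$a
  for (ch in 1:4) {
    # cap at the Layer-1 headroom: the shift conserves per-pixel
    # Layer0+Layer1 activity exactly while both layers stay in [0, 1];
    # the residue (rare: Layer 1 already saturated) stays in Layer 0 and
    # drains on later steps as Layer 1 decays
    mv <- pmin(f * a[1, ch, , ], 1 - a[2, ch, , ])
    a[1, ch, , ] <- a[1, ch, , ] - mv
    a[2, ch, , ] <- a[2, ch, , ] + mv
  }
  state$field$a <- a
  state
}

#' Advance the full segmentation model by one time step
#'
#' Composition of the three sub-steps in order: contour-field update
#' (decay + bottom-up drive), selection seeding/spreading, and contour
#' transfer. Selection signals whose onset time has been reached are
#' planted before spreading.
#'
#' @param state segmentation_state.
#' @param input orientation raster for this step, or NULL (blank/ISI).
#' @param params model params.
#' @return updated state.
#' @export
step_segmentation <- function(state, input, params = model_params()) {
  route <- if (state$seeded) pmax(state$disc, state$s) else NULL
  state$field <- step_field(state$field, input, params, route_mask = route)
  if (!state$seeded && !is.null(state$signals) &&
      (nrow(state$signals) == 0 ||
       state$field$time_ms > state$signals$onset_ms[1]))
    state <- seed_selection(state, params)
  if (state$seeded) {
    state <- seed_and_spread(state, params)
    state <- transfer_contours(state, params)
  }
  state
}
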