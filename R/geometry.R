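#' Default stimulus geometry
#'
#' All lengths are in arcmin in a stimulus-centred frame: origin at the
#' vernier centre, x rightward, y upward. Vernier offsets are given in
#' arcsec. Eccentricity is carried as metadata only; the model operates on
#' a stimulus-centred canvas.
#'
#' @param ... named overrides of the default fields (values in arcmin,
#'   except `eccentricity_deg`).
#' @return A `geometry_spec` list with fields:
#'   `vernier_line_len` (40), `vernier_gap` (4), `flanker_line_len` (84),
#'   `line_separation` (46), `rect_width` (117), `cube_oblique_len` (53),
#'   `cube_oblique_angle` (45, degrees), `triangle_inner` (84),
#'   `triangle_oblique` (124.3), `central_rect_w` (46), `central_rect_h`
#'   (84), `eccentricity_deg` (9).
#' @export
#' @examples
#' g <- geometry_spec()
#' g$rect_width
geometry_spec <- function(...) {
  g <- list(
    vernier_line_len   = 40,
    vernier_gap        = 4,
    flanker_line_len   = 84,
    line_separation    = 46,
    rect_width         = 117,
    cube_oblique_len   = 53,
    cube_oblique_angle = 45,
    triangle_inner     = 84,
    triangle_oblique   = 124.3,
    central_rect_w     = 46,
    central_rect_h     = 84,
    eccentricity_deg   = 9
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(g))
    if (length(bad)) stop("unknown geometry field(s): ", paste(bad, collapse = ", "))
    g[names(dots)] <- dots
  }
  num <- g[setdiff(names(g), "eccentricity_deg")]
  if (any(vapply(num, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all geometry lengths must be strictly positive numbers")
  tot <- 2 * g$vernier_line_len + g$vernier_gap
  if (abs(tot - g$flanker_line_len) > 1e-9)
    stop("vernier total height (", tot, "') must equal flanker_line_len (",
         g$flanker_line_len, "')")
  class(g) <- "geometry_spec"
  g
}

orientation_classes <- c("vertical", "horizontal", "diag45", "diag135")

# Classify a segment's angle into one of the four orientation channels.
# Diagonals must be within 1 degree of +/-45.
classify_orientation <- function(x1, y1, x2, y2, tol_deg = 1) {
  dx <- x2 - x1; dy <- y2 - y1
  if (dx == 0 && dy == 0) stop("zero-length segment")
  if (dx == 0) return("vertical")
  if (dy == 0) return("horizontal")
  ang <- atan2(dy, dx) * 180 / pi          # (-180, 180]
  ang <- ang %% 180                         # orientation, [0, 180)
  if (abs(ang - 45) <= tol_deg) return("diag45")
  if (abs(ang - 135) <= tol_deg) return("diag135")
  stop(sprintf("segment angle %.2f deg is not vertical/horizontal/45/135", ang))
}

#' Build a line-segment table
#'
#' @param x1,y1,x2,y2 numeric vectors of endpoints (arcmin).
#' @return data.frame with columns x1, y1, x2, y2, orientation_class.
#' @keywords internal
segments_df <- function(x1, y1, x2, y2) {
  stopifnot(length(x1) == length(y1), length(x1) == length(x2),
            length(x1) == length(y2))
  oc <- character(length(x1))
  for (i in seq_along(x1)) oc[i] <- classify_orientation(x1[i], y1[i], x2[i], y2[i])
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             orientation_class = oc, stringsAsFactors = FALSE)
}

#' Construct the vernier target
#'
#' Two vertical 40-arcmin lines separated by a 4-arcmin vertical gap. The
#' top line is fixed at x = 0; the whole horizontal offset is applied to
#' the bottom line (positive = rightward). Observers judge the offset of
#' the bottom line, so the offset is carried entirely by it.
#'
#' @param offset_arcsec signed vernier offset in arcsec; |offset| <= 1600.
#' @param geom a [geometry_spec()].
#' @return segment data.frame (two rows, both `vertical`).
#' @export
#' @examples
#' make_vernier(800)   # bottom line at +13.33 arcmin
make_vernier <- function(offset_arcsec, geom = geometry_spec()) {
  if (!is.numeric(offset_arcsec) || length(offset_arcsec) != 1 || is.na(offset_arcsec))
    stop("offset_arcsec must be a single number")
  if (abs(offset_arcsec) > 1600)
    stop("vernier offset ", offset_arcsec, "'' exceeds the 1600'' bound")
  L <- geom$vernier_line_len
  hg <- geom$vernier_gap / 2
  dx <- offset_arcsec / 60
  segments_df(
    x1 = c(0, dx), y1 = c(hg, -hg),
    x2 = c(0, dx), y2 = c(hg + L, -hg - L)
  )
}

# One perspective cube wireframe, centred on (xc, 0). Front face is the
# flanker rectangle; three obliques (45 deg, len 53') leave the inner-top,
# outer-top and outer-bottom front corners toward the upper-outer side
# (away from the vernier, so the display stays symmetric about x = 0);
# back-face edges join the oblique endpoints.
cube_segments <- function(xc, geom) {
  rect <- rect_segments(xc, geom$rect_width, geom$flanker_line_len)
  w2 <- geom$rect_width / 2
  h2 <- geom$flanker_line_len / 2
  d <- geom$cube_oblique_len * cos(geom$cube_oblique_angle * pi / 180)
  s <- if (xc >= 0) 1 else -1            # outward direction
  xin <- xc - s * w2; xout <- xc + s * w2
  # obliques from three front corners toward the upper-outer direction
  obl <- segments_df(
    x1 = c(xin, xout, xout), y1 = c(h2, h2, -h2),
    x2 = c(xin + s * d, xout + s * d, xout + s * d),
    y2 = c(h2 + d, h2 + d, -h2 + d)
  )
  # back-face edges: top edge joining the two upper oblique tips, outer
  # edge joining the two outer tips
  back <- segments_df(
    x1 = c(xin + s * d, xout + s * d), y1 = c(h2 + d, h2 + d),
    x2 = c(xout + s * d, xout + s * d), y2 = c(h2 + d, -h2 + d)
  )
  rbind(rect, obl, back)
}

rect_segments <- function(xc, w, h) {
  w2 <- w / 2; h2 <- h / 2
  segments_df(
    x1 = c(xc - w2, xc + w2, xc - w2, xc - w2),
    y1 = c(-h2, -h2, h2, -h2),
    x2 = c(xc - w2, xc + w2, xc + w2, xc + w2),
    y2 = c(h2, h2, h2, -h2)
  )
}

triangle_segments <- function(side, geom) {
  # inner vertical side at +/-23', apex pointing away from the vernier.
  s <- if (side == "right") 1 else -1
  xin <- s * geom$line_separation / 2
  h2 <- geom$triangle_inner / 2
  apex_dx <- sqrt(geom$triangle_oblique^2 - h2^2)
  xap <- xin + s * apex_dx
  df <- data.frame(
    x1 = c(xin, xin, xin),
    y1 = c(-h2, h2, -h2),
    x2 = c(xin, xap, xap),
    y2 = c(h2, 0, 0),
    stringsAsFactors = FALSE
  )
  # obliques of a triangle are not at 45 deg; classify by nearest diagonal
  # channel is wrong here, so store the true class: inner side vertical, the
  # two long sides map to the diagonal channels.
  ang <- function(i) (atan2(df$y2[i] - df$y1[i], df$x2[i] - df$x1[i]) * 180 / pi) %% 180
  oc <- c("vertical",
          if (ang(2) < 90) "diag45" else "diag135",
          if (ang(3) < 90) "diag45" else "diag135")
  df$orientation_class <- oc
  df
}

# Scrambled cubes: same multiset of (length, orientation) as one cube per
# side, repositioned uniformly inside that side's cube bounding box; reject
# positions whose segment intrudes into the vernier zone |x| < 15'.
scrambled_cube_segments <- function(xc, geom, rng) {
  base <- cube_segments(xc, geom)
  w2 <- geom$rect_width / 2
  d <- geom$cube_oblique_len * cos(geom$cube_oblique_angle * pi / 180)
  h2 <- geom$flanker_line_len / 2
  s <- if (xc >= 0) 1 else -1
  xlim <- sort(c(xc - s * w2, xc + s * (w2 + d)))
  ylim <- c(-h2, h2 + d)
  out <- base
  for (i in seq_len(nrow(base))) {
    dx <- base$x2[i] - base$x1[i]; dy <- base$y2[i] - base$y1[i]
    # valid ranges keep both endpoints inside the bounding box
    xr <- c(xlim[1] - min(dx, 0), xlim[2] - max(dx, 0))
    yr <- c(ylim[1] - min(dy, 0), ylim[2] - max(dy, 0))
    repeat {
      x0 <- stats::runif(1, xr[1], xr[2])
      y0 <- stats::runif(1, yr[1], yr[2])
      # redraw if the segment intrudes into the vernier zone |x| < 15'
      if (max(x0, x0 + dx) <= -15 || min(x0, x0 + dx) >= 15) break
    }
    out$x1[i] <- x0; out$x2[i] <- x0 + dx
    out$y1[i] <- y0; out$y2[i] <- y0 + dy
  }
  out
}

#' Construct a flanker configuration
#'
#' Builds the segment set for one of the six flanker configurations, always
#' symmetric about x = 0 (ScrambledCubes only in its bounding boxes). The
#' configurations nest: the Lines are contained in the Rectangles, which are
#' contained in the Cubes.
#'
#' @param config one of `"Lines"`, `"Rectangles"`, `"Cubes"`, `"Triangles"`,
#'   `"CentralRectangle"`, `"ScrambledCubes"`.
#' @param seed integer seed; required by (and only used for)
#'   `"ScrambledCubes"` so the shuffle is reproducible.
#' @param geom a [geometry_spec()].
#' @return segment data.frame.
#' @export
#' @examples
#' f <- make_flankers("Cubes")
#' range(f$x1)
make_flankers <- function(config, seed = NULL, geom = geometry_spec()) {
  configs <- c("Lines", "Rectangles", "Cubes", "Triangles",
               "CentralRectangle", "ScrambledCubes")
  if (!is.character(config) || length(config) != 1 || !(config %in% configs))
    stop("unknown flanker configuration: ", paste(config, collapse = "/"),
         " (expected one of ", paste(configs, collapse = ", "), ")")
  xc <- (geom$line_separation + geom$rect_width) / 2   # rectangle centre
  xin <- geom$line_separation / 2                      # inner line x = 23'
  h2 <- geom$flanker_line_len / 2
  switch(config,
    Lines = segments_df(
      x1 = c(-xin, xin), y1 = c(-h2, -h2),
      x2 = c(-xin, xin), y2 = c(h2, h2)),
    Rectangles = rbind(rect_segments(-xc, geom$rect_width, geom$flanker_line_len),
                       rect_segments(xc, geom$rect_width, geom$flanker_line_len)),
    Cubes = rbind(cube_segments(-xc, geom), cube_segments(xc, geom)),
    Triangles = rbind(triangle_segments("left", geom),
                      triangle_segments("right", geom)),
    CentralRectangle = rect_segments(0, geom$central_rect_w, geom$central_rect_h),
    ScrambledCubes = {
      if (is.null(seed)) stop("ScrambledCubes requires a seed for reproducibility")
      withr_seed <- function(expr) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
                else suppressWarnings(rm(".Random.seed", envir = globalenv())))
        set.seed(seed)
        expr
      }
      withr_seed(rbind(scrambled_cube_segments(-xc, geom, NULL),
                       scrambled_cube_segments(xc, geom, NULL)))
    }
  )
}

#' Assemble a stimulus frame
#'
#' @param segments segment data.frame (possibly empty).
#' @param label condition tag.
#' @param vernier_offset signed offset in arcsec (0 if no vernier).
#' @param contains_vernier logical.
#' @return A `stimulus_frame` object.
#' @export
stimulus_frame <- function(segments, label = "",
                           vernier_offset = 0, contains_vernier = FALSE) {
  if (!contains_vernier && vernier_offset != 0)
    stop("vernier_offset must be 0 when the frame contains no vernier")
  structure(list(segments = segments, label = label,
                 vernier_offset = vernier_offset,
                 contains_vernier = contains_vernier),
            class = "stimulus_frame")
}

#' Blank frame (ISI)
#' @return stimulus_frame with no segments.
#' @export
blank_frame <- function() {
  stimulus_frame(segments_df(numeric(0), numeric(0), numeric(0), numeric(0)),
                 label = "blank")
}

#' Flanked (or unflanked) vernier frame
#'
#' @param config flanker configuration name or `"unflanked"`.
#' @param offset_arcsec vernier offset (arcsec).
#' @param seed seed for ScrambledCubes.
#' @param geom geometry.
#' @param with_vernier include the vernier target?
#' @return stimulus_frame.
#' @export
make_frame <- function(config, offset_arcsec = 0, seed = NULL,
                       geom = geometry_spec(), with_vernier = TRUE) {
  segs <- if (identical(config, "unflanked")) {
    segments_df(numeric(0), numeric(0), numeric(0), numeric(0))
  } else make_flankers(config, seed = seed, geom = geom)
  if (with_vernier) segs <- rbind(make_vernier(offset_arcsec, geom), segs)
  stimulus_frame(segs, label = config,
                 vernier_offset = if (with_vernier) offset_arcsec else 0,
                 contains_vernier = with_vernier)
}
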