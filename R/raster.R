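#' Raster geometry descriptor
#'
#' The canvas is a grid of square pixels of side `1/px_per_arcmin` arcmin.
#' Pixel (row r, col c) covers the half-open cell
#' x in [xlim1 + (c-1)/ppa, xlim1 + c/ppa), y likewise from `ylim[1]`;
#' rows index y upward. Default: 0.5 px/arcmin on x in [-201, 201],
#' y in [-101, 101] (201 x 101 px, odd so that x = 0 falls on the centre
#' pixel and left/right mirror stimuli rasterize symmetrically).
#'
#' @param px_per_arcmin pixels per arcmin (> 0).
#' @param xlim,ylim canvas extent in arcmin.
#' @return a `raster_geometry` list with `ppa`, `xlim`, `ylim`, `W`, `H`.
#' @export
raster_geometry <- function(px_per_arcmin = 0.5,
                            xlim = c(-201, 201), ylim = c(-101, 101)) {
  stopifnot(px_per_arcmin > 0, xlim[2] > xlim[1], ylim[2] > ylim[1])
  W <- round(diff(xlim) * px_per_arcmin)
  H <- round(diff(ylim) * px_per_arcmin)
  structure(list(ppa = px_per_arcmin, xlim = xlim, ylim = ylim, W = W, H = H),
            class = "raster_geometry")
}

# Deterministic line-drawing rule (integer midpoint sampling): along the
# dominant axis, a segment occupies every pixel whose cell-centre coordinate
# lies within the half-open span [lo, hi); the cross-axis pixel is the cell
# containing the line's position at that centre. Exact for the four
# orientation classes used here: an axis-aligned segment of length L
# occupies round(L*ppa) pixels, and doubling ppa doubles that count.
trace_segment_px <- function(x1, y1, x2, y2, rg) {
  ppa <- rg$ppa
  cell <- function(v, lim) floor((v - lim[1]) * ppa) + 1L
  # cell centres with index in [c1, c2] lie in [lo, hi)
  span <- function(lo, hi, lim) {
    c1 <- ceiling((lo - lim[1]) * ppa + 0.5)
    c2 <- ceiling((hi - lim[1]) * ppa + 0.5) - 1
    if (c2 < c1) integer(0) else c1:c2
  }
  dx <- x2 - x1; dy <- y2 - y1
  if (abs(dx) >= abs(dy)) {            # x dominant (ties -> x)
    cols <- span(min(x1, x2), max(x1, x2), rg$xlim)
    if (!length(cols)) return(cbind(row = integer(0), col = integer(0)))
    xc <- rg$xlim[1] + (cols - 0.5) / ppa
    rows <- cell(y1 + dy * (xc - x1) / dx, rg$ylim)
  } else {                             # y dominant
    rows <- span(min(y1, y2), max(y1, y2), rg$ylim)
    if (!length(rows)) return(cbind(row = integer(0), col = integer(0)))
    yc <- rg$ylim[1] + (rows - 0.5) / ppa
    cols <- if (dx == 0) rep.int(cell(x1, rg$xlim), length(rows))
            else cell(x1 + dx * (yc - y1) / dy, rg$xlim)
  }
  cbind(row = rows, col = cols)
}

#' Rasterize a stimulus frame into orientation channels
#'
#' Each line segment marks binary occupancy in its own orientation channel
#' (vertical, horizontal, diag45, diag135). Rasterization is deterministic.
#'
#' @param frame a [stimulus_frame()].
#' @param rg a [raster_geometry()].
#' @return an `orientation_raster`: list with `arr` (array 4 x H x W of 0/1,
#'   channels in [orientation_classes] order) and the geometry `rg`.
#' @export
#' @examples
#' r <- rasterize(make_frame("unflanked", 0), raster_geometry())
#' sum(r$arr)
rasterize <- function(frame, rg = raster_geometry()) {
  stopifnot(inherits(frame, "stimulus_frame"), inherits(rg, "raster_geometry"))
  arr <- array(0, dim = c(4L, rg$H, rg$W),
               dimnames = list(orientation_classes, NULL, NULL))
  segs <- frame$segments
  for (i in seq_len(nrow(segs))) {
    if (min(segs$x1[i], segs$x2[i]) < rg$xlim[1] ||
        max(segs$x1[i], segs$x2[i]) > rg$xlim[2] ||
        min(segs$y1[i], segs$y2[i]) < rg$ylim[1] ||
        max(segs$y1[i], segs$y2[i]) > rg$ylim[2])
      stop(sprintf("segment %d [(%.1f,%.1f)-(%.1f,%.1f)] exceeds the canvas",
                   i, segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i]))
    ch <- match(segs$orientation_class[i], orientation_classes)
    px <- trace_segment_px(segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i], rg)
    keep <- px[, "row"] >= 1 & px[, "row"] <= rg$H &
            px[, "col"] >= 1 & px[, "col"] <= rg$W
    px <- px[keep, , drop = FALSE]
    arr[cbind(ch, px[, "row"], px[, "col"])] <- 1
  }
  structure(list(arr = arr, rg = rg, frame = frame), class = "orientation_raster")
}

#' Build the frame sequence for an experimental condition
#'
#' Encodes the timeline of one trial of Experiments 1-4: which frames are
#' shown, for how long (multiples of the 20-ms step), with blank frames for
#' interstimulus intervals, plus the derived onset time of the
#' vernier-bearing frame.
#'
#' Valid pairings:
#' \itemize{
#' \item Exp 1: `flanker` in Lines/Rectangles/Cubes/unflanked,
#'   `duration_ms` 20 or 160. Single frame.
#' \item Exp 2: `flanker` in Lines/Cubes, `design` in
#'   preview/postview/baseline. Preview: flankers 20 ms, blank 120 ms,
#'   flanked vernier 20 ms; postview is the reverse; baseline is the flanked
#'   vernier alone for 20 ms.
#' \item Exp 3: Cubes preview with `isi_ms` in
#'   \{20, 120, 260, 600, 1000, 1500, 2000\}, or `design = "baseline"`.
#' \item Exp 4: Cubes 20 ms, blank 120 ms, `intermediate` flanker 20 ms
#'   (Cubes/Rectangles/Triangles/CentralRectangle/ScrambledCubes/Lines),
#'   blank 120 ms, Cubes+vernier 20 ms; or `design = "baseline"`.
#' }
#'
#' @param experiment integer 1-4.
#' @param condition named list describing the condition (see Details).
#' @param offset_arcsec vernier offset for the vernier-bearing frame.
#' @param seed seed forwarded to ScrambledCubes.
#' @param geom geometry spec.
#' @return a `frame_sequence`: list of `frames`, `durations_ms`,
#'   `vernier_onset_ms`, `label`.
#' @export
#' @examples
#' s <- build_sequence(2, list(flanker = "Cubes", design = "preview"))
#' s$durations_ms
build_sequence <- function(experiment, condition, offset_arcsec = 240,
                           seed = NULL, geom = geometry_spec()) {
  fr <- function(cfg, vern, off = 0)
    make_frame(cfg, offset_arcsec = off, seed = seed, geom = geom,
               with_vernier = vern)
  bad <- function() stop("invalid condition for experiment ", experiment, ": ",
                         paste(names(condition), unlist(condition),
                               sep = "=", collapse = ", "))
  frames <- NULL; dur <- NULL; label <- NULL
  if (experiment == 1) {
    f <- condition$flanker; d <- condition$duration_ms
    if (is.null(f) || is.null(d) ||
        !(f %in% c("Lines", "Rectangles", "Cubes", "unflanked")) ||
        !(d %in% c(20, 160))) bad()
    frames <- list(fr(f, TRUE, offset_arcsec)); dur <- d
    label <- paste0(f, "-", d)
  } else if (experiment == 2) {
    f <- condition$flanker; des <- condition$design
    if (is.null(f) || is.null(des) || !(f %in% c("Lines", "Cubes")) ||
        !(des %in% c("preview", "postview", "baseline"))) bad()
    v <- fr(f, TRUE, offset_arcsec)
    if (des == "preview") {
      frames <- list(fr(f, FALSE), blank_frame(), v); dur <- c(20, 120, 20)
    } else if (des == "postview") {
      frames <- list(v, blank_frame(), fr(f, FALSE)); dur <- c(20, 120, 20)
    } else { frames <- list(v); dur <- 20 }
    label <- paste0(f, "-", des)
  } else if (experiment == 3) {
    if (identical(condition$design, "baseline")) {
      frames <- list(fr("Cubes", TRUE, offset_arcsec)); dur <- 20
      label <- "Cubes-baseline"
    } else {
      isi <- condition$isi_ms
      if (is.null(isi) || !(isi %in% c(20, 120, 260, 600, 1000, 1500, 2000))) bad()
      frames <- list(fr("Cubes", FALSE), blank_frame(),
                     fr("Cubes", TRUE, offset_arcsec))
      dur <- c(20, isi, 20)
      label <- paste0("Cubes-isi", isi)
    }
  } else if (experiment == 4) {
    if (identical(condition$design, "baseline")) {
      frames <- list(fr("Cubes", TRUE, offset_arcsec)); dur <- 20
      label <- "Cubes-baseline"
    } else {
      im <- condition$intermediate
      if (is.null(im) || !(im %in% c("Cubes", "Rectangles", "Triangles",
                                     "CentralRectangle", "ScrambledCubes",
                                     "Lines"))) bad()
      frames <- list(fr("Cubes", FALSE), blank_frame(), fr(im, FALSE),
                     blank_frame(), fr("Cubes", TRUE, offset_arcsec))
      dur <- c(20, 120, 20, 120, 20)
      label <- paste0("intermediate-", im)
    }
  } else bad()
  if (any(dur %% 20 != 0)) stop("durations must be multiples of 20 ms")
  has_v <- vapply(frames, function(f) isTRUE(f$contains_vernier), logical(1))
  onset <- if (any(has_v)) sum(dur[seq_len(which(has_v)[1] - 1)]) else NA_real_
  structure(list(frames = frames, durations_ms = dur,
                 vernier_onset_ms = onset, label = label),
            class = "frame_sequence")
}

#' Export a frame's segments as a CSV table
#' @param frames list of stimulus_frame.
#' @param path output CSV path.
#' @return invisibly, the written data.frame.
#' @export
write_segment_csv <- function(frames, path) {
  tabs <- lapply(seq_along(frames), function(i) {
    s <- frames[[i]]$segments
    if (nrow(s) == 0) return(NULL)
    cbind(frame_idx = i, s)
  })
  out <- do.call(rbind, tabs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Export an orientation raster as PNG
#'
#' Red = vertical, green = horizontal, blue = either diagonal.
#' @param raster an `orientation_raster` or a layer slice (4 x H x W array).
#' @param path PNG path.
#' @return invisibly, path.
#' @export
write_raster_png <- function(raster, path) {
  arr <- if (inherits(raster, "orientation_raster")) raster$arr else raster
  H <- dim(arr)[2]; W <- dim(arr)[3]
  img <- array(0, c(H, W, 3))
  img[, , 1] <- arr[1, , ]
  img[, , 2] <- arr[2, , ]
  img[, , 3] <- pmin(1, arr[3, , ] + arr[4, , ])
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img[H:1, , , drop = FALSE], path)  # flip: row 1 is bottom
  invisible(path)
}
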