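#' Build the left/right vernier template pair
#'
#' The templates are binary spatial masks on the vertical orientation
#' channel. Each is the rasterized vernier at the reference offset
#' (-delta_ref for the left template, +delta_ref for the right), dilated by
#' `template_dilation_px` (Chebyshev) so that it also covers nearby
#' flanking elements; the pixels that are diagnostic for the *opposite*
#' offset (the other core minus the own core) are excluded, so the two
#' masks share the flanker-catching surround but differ in the
#' bottom-line region that discriminates the offset direction.
#'
#' @param params model params (`ref_offset_arcmin`, `template_dilation_px`).
#' @param rg raster geometry.
#' @param geom geometry spec.
#' @return `template_pair`: list with logical H x W matrices `mask_L`,
#'   `mask_R` and the geometry `rg`.
#' @export
build_templates <- function(params = model_params(), rg = raster_geometry(),
                            geom = geometry_spec()) {
  off <- params$ref_offset_arcmin * 60
  if (params$ref_offset_arcmin * rg$ppa < 1)
    stop("reference offset ", params$ref_offset_arcmin,
         "' is sub-pixel at ", rg$ppa, " px/arcmin")
  core <- function(sign) {
    r <- rasterize(stimulus_frame(make_vernier(sign * off, geom),
                                  label = "template", vernier_offset = sign * off,
                                  contains_vernier = TRUE), rg)
    r$arr[1, , ] > 0                     # vertical channel
  }
  core_L <- core(-1); core_R <- core(1)
  dil <- function(m, d) { for (i in seq_len(d)) m <- dilate1(m); m }
  d <- params$template_dilation_px
  mask_L <- dil(core_L, d) & !(core_R & !core_L)
  mask_R <- dil(core_R, d) & !(core_L & !core_R)
  structure(list(mask_L = mask_L, mask_R = mask_R, rg = rg),
            class = "template_pair")
}

#' Template scores from the readout layer
#'
#' Sums vertical-channel Layer-0 activity under each template mask.
#'
#' @param field orientation_field.
#' @param templates template_pair.
#' @return named numeric vector c(S_L, S_R).
#' @export
template_scores <- function(field, templates) {
  v <- field$a[1, 1, , ]                 # Layer 0, vertical channel
  if (!all(dim(v) == dim(templates$mask_L)))
    stop("field geometry does not match template geometry")
  c(S_L = sum(v[templates$mask_L]), S_R = sum(v[templates$mask_R]))
}

#' Template contrast score
#'
#' `C = (S_R - S_L) / (100 + S_R + S_L)`. The additive constant 100 keeps
#' the score bounded and makes |C| shrink when overall activity fades or
#' when symmetric flanker activity inflates both template sums (the
#' crowding mechanism).
#'
#' @param S_L,S_R nonnegative template scores.
#' @return contrast in (-1, 1).
#' @export
#' @examples
#' contrast_score(0, 100)   # 0.5
contrast_score <- function(S_L, S_R) {
  if (S_L < 0 || S_R < 0) stop("template scores must be nonnegative")
  (S_R - S_L) / (100 + S_R + S_L)
}

#' Sum a contrast trace over the readout window
#'
#' @param trace data.frame with columns t_ms and C (one row per step;
#'   t_ms is the time at the *end* of the step, when the readout happens).
#' @param vernier_onset_ms onset of the vernier-bearing frame.
#' @param window_ms inclusive window (ms after vernier onset).
#' @return model evidence (sum of C over the window).
#' @export
model_evidence <- function(trace, vernier_onset_ms,
                           window_ms = c(20, 100)) {
  lo <- vernier_onset_ms + window_ms[1]
  hi <- vernier_onset_ms + window_ms[2]
  if (max(trace$t_ms) < hi)
    stop("trace ends at ", max(trace$t_ms), " ms, before window end ", hi, " ms")
  sum(trace$C[trace$t_ms >= lo & trace$t_ms <= hi])
}

#' Run one model trial on a frame sequence
#'
#' Simulates the two-layer segmentation model over the sequence (and past
#' its end up to the evidence-window close), recording per-step template
#' scores and contrast, and returns the evidence trace.
#'
#' @param seq a [build_sequence()] result (or any frame_sequence).
#' @param params model params.
#' @param rg raster geometry.
#' @param geom geometry spec.
#' @param templates optional precomputed [build_templates()] (rebuilt if
#'   NULL).
#' @param signals optional precomputed selection signals; if NULL they are
#'   placed from the first flanker-bearing frame's configuration using the
#'   current RNG state.
#' @return `evidence_trace`: data.frame (t_ms, S_L, S_R, C) with attributes
#'   `evidence`, `vernier_onset_ms`, `label`.
#' @export
run_trial <- function(seq, params = model_params(), rg = raster_geometry(),
                      geom = geometry_spec(), templates = NULL,
                      signals = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (any(seq$durations_ms %% params$dt_ms != 0))
    stop("frame durations must be multiples of dt_ms")
  if (is.null(templates)) templates <- build_templates(params, rg, geom)
  # first flanker-bearing frame defines seed placement and onset
  is_flanked <- vapply(seq$frames, function(f)
    nrow(f$segments) > 0 && !identical(f$label, "blank") &&
      !identical(f$label, "unflanked"), logical(1))
  has_v <- vapply(seq$frames, function(f) isTRUE(f$contains_vernier), logical(1))
  # a frame whose only segments are the vernier is not a flanker frame
  only_vernier <- has_v & vapply(seq$frames, function(f)
    nrow(f$segments) <= 2, logical(1))
  first_flank <- which(is_flanked & !only_vernier)
  if (is.null(signals)) {
    signals <- if (length(first_flank)) {
      onset <- if (first_flank[1] == 1) 0 else
        sum(seq$durations_ms[seq_len(first_flank[1] - 1)])
      place_selection_signals(seq$frames[[first_flank[1]]]$label, params,
                              geom, onset_ms = onset)
    } else place_selection_signals("unflanked", params, geom)
  }
  state <- init_segmentation(rg, signals)
  rasters <- lapply(seq$frames, function(f)
    if (nrow(f$segments) == 0) NULL else rasterize(f, rg))
  onset <- seq$vernier_onset_ms
  t_end <- onset + params$evidence_window_ms[2]
  step_inputs <- unlist(lapply(seq_along(seq$frames), function(i)
    rep(i, seq$durations_ms[i] / params$dt_ms)))
  n_steps <- max(length(step_inputs), t_end / params$dt_ms)
  t_ms <- S_L <- S_R <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    input <- if (k <= length(step_inputs)) rasters[[step_inputs[k]]] else NULL
    state <- step_segmentation(state, input, params)
    sc <- template_scores(state$field, templates)
    t_ms[k] <- state$field$time_ms
    S_L[k] <- sc["S_L"]; S_R[k] <- sc["S_R"]
  }
  trace <- data.frame(t_ms = t_ms, S_L = S_L, S_R = S_R,
                      C = (S_R - S_L) / (100 + S_R + S_L))
  attr(trace, "evidence") <- model_evidence(trace, onset,
                                            params$evidence_window_ms)
  attr(trace, "vernier_onset_ms") <- onset
  attr(trace, "label") <- seq$label
  class(trace) <- c("evidence_trace", "data.frame")
  trace
}
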