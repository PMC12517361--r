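#' Model parameters
#'
#' Tunable parameters of the simplified two-layer segmentation model. The
#' contour substrate is a per-pixel leaky rate unit per orientation channel:
#' activity decays exponentially with time constant `tau_contour_ms` and is
#' driven to saturation (1) by stimulus input. Defaults are calibrated so
#' that contours persist at >= 50% through a 120-ms blank but fade to < 4%
#' by 600 ms, and so that the selection signal fully covers a Cube within
#' about 160 ms of spreading.
#'
#' @param dt_ms simulation step (ms); all frame durations must be multiples.
#' @param tau_contour_ms contour decay constant (ms).
#' @param tau_selection_ms selection-mask decay constant (ms) where the mask
#'   is not refreshed by contour activity.
#' @param spread_px_per_step selection spreading speed (pixels per step).
#' @param transfer_rate fraction of selected Layer-0 activity moved to
#'   Layer 1 per step, in (0, 1].
#' @param seed_radius_arcmin radius of a top-down selection signal.
#' @param seed_jitter_arcmin SD of Gaussian jitter on seed centres.
#' @param evidence_window_ms readout window (ms after vernier onset),
#'   endpoints inclusive.
#' @param ref_offset_arcmin reference vernier offset used by model trials.
#' @param template_dilation_px dilation radius of the template masks (px).
#' @param act_threshold minimum contour activity (either layer) for a pixel
#'   to count as contour-bearing during spreading and to keep supporting the
#'   selection mask.
#' @param spread_activity_exponent exponent p of the activity-dependent
#'   spreading speed: the per-step ring budget is
#'   `spread_px_per_step * mean(a)^p` over the contour pixels ahead of the
#'   spreading front, so selection spreads at full speed along driven
#'   contours and progressively slower along fading ones.
#' @return a `model_params` list.
#' @export
model_params <- function(dt_ms = 20,
                         tau_contour_ms = 180,
                         tau_selection_ms = 8,
                         spread_px_per_step = 6,
                         transfer_rate = 1,
                         seed_radius_arcmin = 50,
                         seed_jitter_arcmin = 4,
                         evidence_window_ms = c(20, 100),
                         ref_offset_arcmin = 4,
                         template_dilation_px = 15,
                         act_threshold = 0.3,
                         spread_activity_exponent = 6.5) {
  stopifnot(dt_ms > 0, tau_contour_ms > 0, tau_selection_ms > 0,
            spread_px_per_step >= 0,
            transfer_rate > 0, transfer_rate <= 1,
            seed_radius_arcmin > 0, seed_jitter_arcmin >= 0,
            length(evidence_window_ms) == 2,
            evidence_window_ms[1] <= evidence_window_ms[2],
            all(evidence_window_ms %% dt_ms == 0),
            ref_offset_arcmin > 0, template_dilation_px >= 0)
  structure(list(dt_ms = dt_ms,
                 tau_contour_ms = tau_contour_ms,
                 tau_selection_ms = tau_selection_ms,
                 spread_px_per_step = spread_px_per_step,
                 transfer_rate = transfer_rate,
                 seed_radius_arcmin = seed_radius_arcmin,
                 seed_jitter_arcmin = seed_jitter_arcmin,
                 evidence_window_ms = evidence_window_ms,
                 evidence_offset_const = 100,   # printed constant, not tunable
                 ref_offset_arcmin = ref_offset_arcmin,
                 template_dilation_px = template_dilation_px,
                 act_threshold = act_threshold,
                 spread_activity_exponent = spread_activity_exponent),
            class = "model_params")
}

#' Initialise an orientation activity field
#'
#' Two segmentation layers (0 and 1), four orientation channels each, all
#' activity zero at time 0. Layer 1 receives no bottom-up drive; it is fed
#' only by contour transfer.
#'
#' @param rg a [raster_geometry()].
#' @return an `orientation_field`: list with `a` (array 2 x 4 x H x W),
#'   `time_ms`, `rg`.
#' @export
init_field <- function(rg = raster_geometry()) {
  stopifnot(rg$H > 0, rg$W > 0)
  structure(list(a = array(0, dim = c(2L, 4L, rg$H, rg$W)),
                 time_ms = 0, rg = rg),
            class = "orientation_field")
}

#' Advance the contour field by one time step
#'
#' Both layers decay by `exp(-dt/tau_contour)`; unit-gain stimulus drive is
#' deposited at input pixels, hard-saturated at 1. Without a routing mask,
#' all drive enters Layer 0 and Layer 1 is fed only by contour transfer.
#' When the segmentation engine supplies its selection mask as
#' `route_mask`, the drive at a selected pixel is routed into Layer 1 in
#' proportion to the mask value: once a location has been segmented, new
#' contour input there belongs to the segmented object's layer.
#' A blank input (NULL) models an interstimulus interval.
#'
#' @param field an [init_field()] result.
#' @param input an `orientation_raster` matching the field geometry, or
#'   NULL for a blank step.
#' @param params [model_params()].
#' @param route_mask optional H x W matrix in [0,1]: fraction of drive per
#'   pixel diverted to Layer 1.
#' @return updated `orientation_field`.
#' @export
step_field <- function(field, input, params = model_params(),
                       route_mask = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  decay <- exp(-params$dt_ms / params$tau_contour_ms)
  a <- field$a * decay
  if (!is.null(input)) {
    arr <- if (inherits(input, "orientation_raster")) input$arr else input
    if (!all(dim(arr) == dim(field$a)[2:4]))
      stop("input raster shape ", paste(dim(arr), collapse = "x"),
           " does not match field ", paste(dim(field$a)[2:4], collapse = "x"))
    if (is.null(route_mask)) {
      a[1, , , ] <- pmin(1, a[1, , , ] + arr)
    } else {
      for (ch in 1:4) {
        a[1, ch, , ] <- pmin(1, a[1, ch, , ] + (1 - route_mask) * arr[ch, , ])
        a[2, ch, , ] <- pmin(1, a[2, ch, , ] + route_mask * arr[ch, , ])
      }
    }
  }
  field$a <- a
  field$time_ms <- field$time_ms + params$dt_ms
  field
}

#' Total activity in one layer
#' @param field orientation_field.
#' @param layer 0 or 1.
#' @return sum of activity over channels and pixels.
#' @export
total_activity <- function(field, layer) {
  stopifnot(layer %in% c(0, 1))
  sum(field$a[layer + 1L, , , ])
}
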