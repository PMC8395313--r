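# Binding-mode classification from trajectory traces, plus the flow
# linear-dichroism band-sign logic that links helix orientation to the
# measurable LD spectrum.

#' Predict flow-LD band signs from helix tilt
#'
#' For a shear-aligned membrane, the sign of each peptide absorption band
#' reports the orientation of its transition moment relative to the
#' membrane. The low-energy pi->pi* component (~210 nm) is polarized along
#' the helix axis; the n->pi* transition (~222 nm) is perpendicular to it
#' (azimuthally averaged about the axis). With gamma the angle between a
#' moment and the membrane normal, the band sign follows the orientation
#' factor \eqn{1 - 3\cos^2\gamma}: positive for in-plane moments, negative
#' for moments along the normal, zero at the magic angle (54.7 deg). A
#' surface-parallel helix (tilt 90 deg) therefore shows + at ~210 nm and -
#' at ~222 nm; an upright helix (tilt 0) shows the reverse; within 1 deg of
#' the magic angle both bands vanish. The two factors satisfy
#' `f222 = -f210 / 2`, so the signs are always opposite or both zero.
#'
#' @param tilt Helix tilt from the membrane normal, degrees in [0, 90].
#' @param magic_tol Half-width (degrees) of the null band around the magic
#'   angle within which signs are reported as `"0"`.
#' @return A tibble with one row per band: `band` (`"210"`, `"222"`),
#'   `moment` (axis-parallel / axis-perpendicular), `orientation_factor`,
#'   `sign` (`"+"`, `"-"`, `"0"`).
#' @examples
#' predict_ld_signs(90) # carpet-like: + at 210 nm, - at 222 nm
#' @export
predict_ld_signs <- function(tilt, magic_tol = 1) {
  if (!is.numeric(tilt) || length(tilt) != 1L || is.na(tilt) ||
      tilt < 0 || tilt > 90) {
    abort("`tilt` must be a single value in [0, 90] degrees.")
  }
  magic <- acos(1 / sqrt(3)) * 180 / pi # 54.7356...
  ct2 <- cos(tilt * pi / 180)^2
  f210 <- 1 - 3 * ct2                    # moment along the helix axis
  f222 <- 1 - 3 * (1 - ct2) / 2          # azimuthal average perpendicular
  null_band <- abs(tilt - magic) <= magic_tol
  sgn <- function(f) {
    if (null_band) "0" else if (f > 0) "+" else if (f < 0) "-" else "0"
  }
  tibble(
    band = c("210", "222"),
    moment = c("axis-parallel", "axis-perpendicular"),
    orientation_factor = c(f210, f222),
    sign = c(sgn(f210), sgn(f222))
  )
}

#' Projected surface footprint of a frame
#'
#' Area of the convex hull of the peptide atoms projected onto the membrane
#' (xy) plane -- a proxy for how much bilayer surface the peptide covers.
#' Degenerate projections (fewer than 3 atoms, or collinear) return 0.
#'
#' @param frame A frame tibble containing peptide atoms.
#' @return Area in nm^2.
#' @export
surface_footprint <- function(frame) {
  pep <- .peptide_part(frame)
  if (nrow(pep) < 3) return(0)
  xy <- unique(as.matrix(pep[, c("x", "y")]))
  if (nrow(xy) < 3) return(0)
  hull <- chull(xy)
  if (length(hull) < 3) return(0)
  h <- xy[hull, , drop = FALSE]
  n <- nrow(h)
  j <- c(2:n, 1)
  abs(sum(h[, 1] * h[j, 2] - h[j, 1] * h[, 2])) / 2
}

#' @rdname distance_trace
#' @export
footprint_trace <- function(traj) {
  frames <- traj_frames(traj)
  values <- vapply(frames, surface_footprint, numeric(1))
  .new_trace(frames, values, metric = "footprint", units = "nm^2")
}

#' Classifier thresholds
#'
#' The decision thresholds of [classify_binding_mode()], gathered in one
#' place. The source observations are qualitative ("highly helical",
#' "partially helical", "perpendicular to the surface"), so the cuts are
#' package defaults chosen to separate the three regimes cleanly on
#' synthetic reconstructions: a peptide is bound when its surface distance
#' is below `d_bind`; helicity above `helicity_high` is "highly helical"
#' and between `helicity_low` and `helicity_high` "partially helical";
#' tilt at or above `tilt_parallel` lies on the surface while below
#' `tilt_upright` stands; a residue anchors when its mean side-chain depth
#' is below `anchor_depth` (nm, negative = below the phosphate plane).
#' Classification uses the final `window_fraction` of the trajectory and
#' requires `min_window_frames` frames there.
#'
#' @param d_bind,helicity_high,helicity_low,tilt_parallel,tilt_upright,anchor_depth,window_fraction,min_window_frames
#'   See description.
#' @return Named list of thresholds.
#' @export
mode_thresholds <- function(d_bind = 1.2, helicity_high = 0.6,
                            helicity_low = 0.2, tilt_parallel = 60,
                            tilt_upright = 45, anchor_depth = -0.1,
                            window_fraction = 1 / 3,
                            min_window_frames = 20L) {
  list(
    d_bind = d_bind, helicity_high = helicity_high,
    helicity_low = helicity_low, tilt_parallel = tilt_parallel,
    tilt_upright = tilt_upright, anchor_depth = anchor_depth,
    window_fraction = window_fraction,
    min_window_frames = as.integer(min_window_frames)
  )
}

#' Classify the membrane binding mode
#'
#' Turns time-aligned traces into one of the three binding modes or
#' `"unbound"`, evaluated over the final `window_fraction` of the
#' trajectory:
#'
#' * **unbound** -- fewer than half of the window frames have surface
#'   distance below `d_bind`;
#' * **Mode I** (carpet-like) -- mean helicity >= `helicity_high` and
#'   median tilt >= `tilt_parallel` (lying on the surface);
#' * **Mode II** (anchored, partially helical) -- mean helicity in
#'   [`helicity_low`, `helicity_high`) and at least one residue's mean
#'   depth below `anchor_depth`;
#' * **Mode III** (antenna) -- mean helicity >= `helicity_high`, median
#'   tilt < `tilt_upright`, centre of mass above the phosphate plane, and
#'   at least one of the first three residues anchored below it.
#'
#' When no rule fires exactly, the nearest rule by normalized slack margin
#' is reported with `low_confidence = TRUE`; classification is total on
#' valid input. The azimuth circular variance of the helix axis is reported
#' as evidence for the antenna mode's swinging motion but is not a gate.
#'
#' @param helicity,distance,tilt Trace tibbles from [helicity_trace()],
#'   [distance_trace()], [tilt_trace()] (time-aligned, equal length).
#' @param depths Long per-residue depth table from [depth_trace()].
#' @param com_height Optional signed centre-of-mass height trace
#'   ([com_height_trace()]); when absent, the mean over residues of the
#'   depth table is used as a proxy.
#' @param footprint Optional footprint trace, reported as evidence.
#' @param thresholds A [mode_thresholds()] list.
#' @return An object of class `"binding_mode_call"`: list with `mode`,
#'   `evidence` (named numerics), `low_confidence`, `window_used`,
#'   `thresholds`.
#' @export
classify_binding_mode <- function(helicity, distance, tilt, depths,
                                  com_height = NULL, footprint = NULL,
                                  thresholds = mode_thresholds()) {
  th <- thresholds
  n <- nrow(helicity)
  if (nrow(distance) != n || nrow(tilt) != n ||
      !isTRUE(all.equal(helicity$time, distance$time)) ||
      !isTRUE(all.equal(helicity$time, tilt$time))) {
    abort("Traces are not time-aligned (unequal lengths or times).")
  }
  w0 <- n - ceiling(n * th$window_fraction) + 1L
  win <- w0:n
  if (length(win) < th$min_window_frames) {
    abort(sprintf(
      "Analysis window has %d frames; need at least %d.",
      length(win), th$min_window_frames
    ))
  }
  dw <- depths[depths$frame %in% win, , drop = FALSE]
  mean_depth <- dw |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(depth = mean(.data$depth), .groups = "drop")
  az <- tilt$azimuth[win] * pi / 180
  evidence <- c(
    bound_fraction = mean(distance$value[win] < th$d_bind),
    mean_helicity = mean(helicity$value[win]),
    median_tilt = stats::median(tilt$value[win]),
    azimuth_circular_variance =
      1 - .vnorm(c(mean(cos(az)), mean(sin(az)))),
    anchor_depth_min = min(mean_depth$depth),
    nterm_depth_min = min(mean_depth$depth[mean_depth$residue <= 3]),
    com_height_mean = if (!is.null(com_height)) {
      mean(com_height$value[win])
    } else {
      mean(dw$depth)
    },
    footprint_area = if (!is.null(footprint)) {
      mean(footprint$value[win])
    } else NA_real_
  )
  e <- as.list(evidence)

  gates <- list(
    unbound = c(bound = (0.5 - e$bound_fraction) / 0.5),
    I = c(
      bound = (e$bound_fraction - 0.5) / 0.5,
      helicity = (e$mean_helicity - th$helicity_high) / th$helicity_high,
      tilt = (e$median_tilt - th$tilt_parallel) / th$tilt_parallel
    ),
    II = c(
      bound = (e$bound_fraction - 0.5) / 0.5,
      hel_low = (e$mean_helicity - th$helicity_low) / th$helicity_high,
      hel_high = (th$helicity_high - e$mean_helicity) / th$helicity_high,
      anchor = (th$anchor_depth - e$anchor_depth_min) / abs(th$anchor_depth)
    ),
    III = c(
      bound = (e$bound_fraction - 0.5) / 0.5,
      helicity = (e$mean_helicity - th$helicity_high) / th$helicity_high,
      tilt = (th$tilt_upright - e$median_tilt) / th$tilt_upright,
      com_above = e$com_height_mean / 0.1,
      nterm_anchor = (th$anchor_depth - e$nterm_depth_min) / abs(th$anchor_depth)
    )
  )
  margins <- vapply(gates, min, numeric(1))

  if (e$bound_fraction < 0.5) {
    mode <- "unbound"; low <- FALSE
  } else if (e$mean_helicity >= th$helicity_high &&
             e$median_tilt >= th$tilt_parallel) {
    mode <- "I"; low <- FALSE
  } else if (e$mean_helicity >= th$helicity_low &&
             e$mean_helicity < th$helicity_high &&
             e$anchor_depth_min < th$anchor_depth) {
    mode <- "II"; low <- FALSE
  } else if (e$mean_helicity >= th$helicity_high &&
             e$median_tilt < th$tilt_upright &&
             e$com_height_mean > 0 &&
             e$nterm_depth_min < th$anchor_depth) {
    mode <- "III"; low <- FALSE
  } else {
    mode <- names(margins)[which.max(margins)]
    low <- TRUE
  }
  structure(
    list(
      mode = mode, evidence = evidence, low_confidence = low,
      margins = margins,
      window_used = c(first_frame = w0, last_frame = n),
      thresholds = th
    ),
    class = "binding_mode_call"
  )
}

#' @export
print.binding_mode_call <- function(x, ...) {
  cat(sprintf(
    "<binding_mode_call> mode %s%s (frames %d-%d)\n",
    x$mode, if (x$low_confidence) " [low confidence]" else "",
    x$window_used[["first_frame"]], x$window_used[["last_frame"]]
  ))
  ev <- x$evidence[!is.na(x$evidence)]
  cat(paste(sprintf("  %s = %.3f", names(ev), ev), collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy a binding-mode call
#'
#' `tidy()` returns one row per evidence criterion; `glance()` a one-row
#' summary with the called mode.
#'
#' @param x A `binding_mode_call`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.binding_mode_call <- function(x, ...) {
  tibble(
    criterion = names(x$evidence),
    value = unname(x$evidence)
  )
}

#' @rdname tidy.binding_mode_call
#' @export
glance.binding_mode_call <- function(x, ...) {
  tibble(
    mode = x$mode,
    low_confidence = x$low_confidence,
    bound_fraction = x$evidence[["bound_fraction"]],
    mean_helicity = x$evidence[["mean_helicity"]],
    median_tilt = x$evidence[["median_tilt"]],
    anchor_depth_min = x$evidence[["anchor_depth_min"]],
    first_frame = x$window_used[["first_frame"]],
    last_frame = x$window_used[["last_frame"]]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
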