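# Calcium-imaging activity analysis: delta-F/F transformation, responder
# classification per stimulus window, activation kinetics, trace alignment
# and marker-rule subpopulation calls.

#' Default imaging frame interval (seconds per frame)
#' @export
FRAME_INTERVAL_S <- 1.72

#' Delta-F/F transformation of a fluorescence trace
#'
#' Baseline fluorescence F is the mean over the 10-frame window starting 20
#' frames before stimulus onset (frames onset-20 to onset-11; half-open
#' \[-20, -10) relative to onset, 17.2 s at 1.72 s/frame). The trace is
#' returned as `(value - F) / F` per frame. Invariant to positive rescaling
#' of the raw trace.
#'
#' @param trace Numeric fluorescence vector (one cell).
#' @param onset Stimulus onset frame (1-based index into `trace`); must be
#'   at least 21 so that the full baseline window exists.
#' @return Numeric delta-F/F vector of the same length, with attribute
#'   `baseline` holding F.
#' @export
delta_f_over_f <- function(trace, onset) {
  stop_if(onset < 21, "onset must be >= 21 so baseline frames exist")
  stop_if(onset > length(trace), "onset beyond trace extent")
  base <- trace[(onset - 20):(onset - 11)]
  f <- mean(base)
  stop_if(f <= 0, "nonpositive baseline fluorescence")
  out <- (trace - f) / f
  attr(out, "baseline") <- f
  out
}

#' Frame window for a stimulus
#'
#' Standard window conventions: for stretch stimuli with a recorded offset,
#' the window spans onset to offset; for intestine stretch, 40 frames
#' (68.8 s) after onset; for intestine infusion, 90 frames (154.8 s) after
#' onset.
#'
#' @param onset Onset frame.
#' @param offset Offset frame (used when `type = "stretch"`).
#' @param type One of "stretch", "intestine_stretch", "infusion", or
#'   "frames" (explicit `n_frames` after onset).
#' @param n_frames Window length for `type = "frames"`.
#' @return Integer vector of frame indices.
#' @export
stimulus_window <- function(onset, offset = NULL,
                            type = c("stretch", "intestine_stretch",
                                     "infusion", "frames"),
                            n_frames = NULL) {
  type <- match.arg(type)
  end <- switch(type,
    stretch = { stop_if(is.null(offset), "stretch window needs offset"); offset },
    intestine_stretch = onset + 40,
    infusion = onset + 90,
    frames = { stop_if(is.null(n_frames), "type 'frames' needs n_frames"); onset + n_frames })
  stop_if(end < onset, "window ends before onset")
  seq.int(onset, end)
}

#' Responder call for one stimulus
#'
#' A cell is responsive when its peak delta-F/F within the stimulus window
#' is strictly greater than the threshold — by default 1.0, i.e. more than
#' 100% above baseline.
#'
#' @param dff Delta-F/F vector (see [delta_f_over_f()]).
#' @param window Frame indices of the stimulus period.
#' @param threshold Strict responsiveness cutoff on delta-F/F, default 1.0.
#' @return Logical flag.
#' @export
is_responsive <- function(dff, window, threshold = 1.0) {
  stop_if(length(window) == 0, "empty stimulus window")
  window <- window[window >= 1 & window <= length(dff)]
  stop_if(length(window) == 0, "window outside trace extent")
  max(dff[window]) > threshold
}

#' Activation kinetics of a responsive cell
#'
#' The peak is the maximum delta-F/F in the stimulus window. Activity is
#' deemed "on" while delta-F/F is at or above 10% of the peak. The
#' activation frame is the first frame of the contiguous on-run containing
#' the peak (equivalently: one frame after the last pre-peak frame below
#' the 10% level). The activation duration is the number of frames in that
#' run, between its pre-peak and post-peak 10% boundaries. When activity
#' never falls back below 10% of peak before the trace ends, the duration
#' is censored at the trace end (`censored = TRUE`).
#'
#' No interpolation between frames is performed; crossings are resolved at
#' whole frames, matching integer frame-count reporting.
#'
#' @param dff Delta-F/F vector.
#' @param window Frame indices of the stimulus period.
#' @param level Fraction of peak defining the on-state boundary, default 0.1.
#' @return List: `peak`, `peak_frame`, `activation_frame`,
#'   `activation_duration` (frames), `censored`.
#' @export
activation_metrics <- function(dff, window, level = 0.1) {
  window <- window[window >= 1 & window <= length(dff)]
  stop_if(length(window) == 0, "window outside trace extent")
  peak_frame <- window[which.max(dff[window])]
  peak <- dff[peak_frame]
  stop_if(peak <= 0, "nonpositive peak; cell is not responsive")
  thr <- level * peak
  on <- dff >= thr
  # walk out from the peak along the contiguous on-run
  start <- peak_frame
  while (start > 1 && on[start - 1]) start <- start - 1
  end <- peak_frame
  while (end < length(dff) && on[end + 1]) end <- end + 1
  censored <- end == length(dff) && on[end]
  list(peak = peak, peak_frame = peak_frame, activation_frame = start,
       activation_duration = end - start + 1, censored = censored)
}

#' Align delta-F/F traces at their activation frames
#'
#' Shifts each trace so that its activation frame maps to a common column,
#' enabling comparison of adaptation time courses across cells. Columns are
#' labelled by frame offset relative to activation; positions outside a
#' trace's extent are `NA`.
#'
#' @param dff_list List of delta-F/F vectors (all responsive cells).
#' @param window Frame indices of the stimulus period (shared).
#' @return Numeric matrix, one row per cell; column `"0"` holds each cell's
#'   activation-frame value.
#' @export
align_at_activation <- function(dff_list, window) {
  stop_if(length(dff_list) == 0, "no traces to align")
  act <- vapply(dff_list, function(d)
    activation_metrics(d, window)$activation_frame, numeric(1))
  lens <- vapply(dff_list, length, numeric(1))
  lo <- min(1 - act)          # most negative relative index
  hi <- max(lens - act)       # largest positive relative index
  offsets <- seq.int(lo, hi)
  m <- matrix(NA_real_, nrow = length(dff_list), ncol = length(offsets),
              dimnames = list(names(dff_list), as.character(offsets)))
  for (i in seq_along(dff_list)) {
    idx <- offsets + act[i]
    ok <- idx >= 1 & idx <= lens[i]
    m[i, ok] <- dff_list[[i]][idx[ok]]
  }
  m
}

# marker-rule subpopulation calls --------------------------------------------

# helper: at least k of the named markers positive
multi_hit <- function(pos, genes, k = 2) sum(pos[genes]) >= k

#' Default marker rule set for VSN subpopulations
#'
#' Ordered positivity rules over the in situ hybridisation marker panel used
#' to call vagal sensory neuron subpopulations A-L; evaluation proceeds in
#' listing order and the first match wins ([classify_subpopulation()]).
#' "Multiple hits" means at least two of the listed positive markers.
#' Cells matching no rule are labelled "X" (unlabelled). Damaged cells (the
#' E subpopulation) are identified transcriptomically, not by this panel,
#' so no E rule appears here.
#'
#' @return Named list of predicate functions over a named logical
#'   marker-positivity vector.
#' @export
default_marker_rules <- function() {
  list(
    A = function(p) (p["Runx3"] || (p["Piezo2"] && p["P2ry1"])) && !p["Tmc3"],
    B = function(p) p["Gabra1"],
    C = function(p) multi_hit(p, c("Slit2", "Piezo2", "Ddc", "Tmc3")) &&
      !p["Trpv1"] && !p["P2ry1"],
    D = function(p) p["Tmc3"] && !p["Trpv1"],
    F = function(p) p["Gpr65"],
    G = function(p) p["Trpv1"] &&
      multi_hit(p, c("Uts2b", "Vip", "Glp1r", "Cckar")),
    H = function(p) p["Trpv1"] && !p["Tmc3"] && p["Trpa1"],
    I = function(p) multi_hit(p, c("Tmc3", "Car8", "Cckar")) && !p["Piezo2"],
    J = function(p) p["Trpv1"] && p["Calca"] && !p["Piezo2"],
    K = function(p) p["Trpa1"] && p["Kcng1"] && p["Trpv1"] && p["Calca"],
    L = function(p) p["P2ry1"] && !p["Trpv1"]
  )
}

#' Genes referenced by a rule set's default panel
#' @return Character vector of marker genes used by [default_marker_rules()].
#' @export
default_marker_panel <- function() {
  c("Trpa1", "Runx3", "Uts2b", "Gabra1", "Slit2", "Kcng1", "Piezo2", "Ddc",
    "Vip", "Trpv1", "Gpr65", "Glp1r", "Tmc3", "Car8", "Cckar", "Calca",
    "P2ry1")
}

#' Call a subpopulation from marker positivity
#'
#' Evaluates an ordered rule set against a cell's marker-positivity profile;
#' the first matching rule gives the label, and a cell matching no rule is
#' "X" (unlabelled).
#'
#' @param marker_positivity Named logical vector over the marker panel.
#' @param rules Named list of predicates; default [default_marker_rules()].
#' @param panel Genes the rules may reference; default
#'   [default_marker_panel()]. All must be present in
#'   `marker_positivity`.
#' @return Subpopulation label (single character string).
#' @export
#' @examples
#' p <- setNames(rep(FALSE, length(default_marker_panel())),
#'               default_marker_panel())
#' p["Gpr65"] <- TRUE
#' classify_subpopulation(p)  # "F"
classify_subpopulation <- function(marker_positivity,
                                   rules = default_marker_rules(),
                                   panel = default_marker_panel()) {
  missing <- setdiff(panel, names(marker_positivity))
  stop_if(length(missing) > 0,
          paste("unmeasured marker(s):", paste(missing, collapse = ", ")))
  for (lab in names(rules)) {
    if (isTRUE(rules[[lab]](marker_positivity))) return(lab)
  }
  "X"
}
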