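#' Cross-section specification
#'
#' An outer bone outline plus a cortical-wall fraction, from which a hollow
#' beam section is constructed. The cortical fraction expresses mean wall
#' thickness as a fraction of the mean external radius (1 gives a solid
#' section).
#'
#' @param outline two-column matrix of outer boundary vertices (m), closed
#'   implicitly.
#' @param corticalFraction wall thickness / mean external radius, in (0, 1].
#' @return object of class `crossSectionSpec`.
#' @export
crossSectionSpec <- function(outline, corticalFraction = 1) {
  outline <- as.matrix(outline)
  if (!is.numeric(corticalFraction) || length(corticalFraction) != 1 ||
      corticalFraction <= 0 || corticalFraction > 1)
    stop("corticalFraction must be a single value in (0, 1]")
  if (!polygonIsSimple(outline)) stop("section outline is self-intersecting")
  structure(list(outline = outline, corticalFraction = corticalFraction),
            class = "crossSectionSpec")
}

#' Section properties of a (possibly hollow) bone cross-section
#'
#' The mean external radius is the mean distance of the outer boundary
#' vertices from their centroid; the wall thickness is
#' `corticalFraction * meanRadius`, and the inner boundary is the outer
#' boundary offset uniformly inward by that thickness (collapsed vertices are
#' dropped). Properties are those of the outer polygon minus the inner one,
#' reported about the centroidal axes of the net section, with both
#' boundaries stored centroid-relative.
#'
#' @param spec a [crossSectionSpec()].
#' @return object of class `sectionProperties` with fields `A`, `Ix`, `Iy`,
#'   `Ixy`, `centroid`, `outerBoundary`, `innerBoundary` (NULL if solid).
#' @export
hollowSectionFromOutline <- function(spec) {
  stopifnot(inherits(spec, "crossSectionSpec"))
  outer <- spec$outline
  if (polygonSignedArea(outer) < 0) outer <- outer[rev(seq_len(nrow(outer))), ]
  po <- polygonRawMoments(outer)
  co <- c(po$Sy / po$A, po$Sx / po$A)
  inner <- NULL
  if (spec$corticalFraction < 1) {
    rbar <- mean(sqrt(rowSums(sweep(outer, 2, co)^2)))
    t <- spec$corticalFraction * rbar
    inner <- polygonInwardOffset(outer, t)
  }
  if (is.null(inner)) {
    A <- po$A
    cx <- co[1]; cy <- co[2]
    Ix <- po$Ix0 - A * cy^2
    Iy <- po$Iy0 - A * cx^2
    Ixy <- po$Ixy0 - A * cx * cy
  } else {
    pi_ <- polygonRawMoments(inner)
    A <- po$A - pi_$A
    if (A <= 1e-12 * po$A) stop("inward offset annihilates the section")
    cx <- (po$Sy - pi_$Sy) / A
    cy <- (po$Sx - pi_$Sx) / A
    Ix <- (po$Ix0 - pi_$Ix0) - A * cy^2
    Iy <- (po$Iy0 - pi_$Iy0) - A * cx^2
    Ixy <- (po$Ixy0 - pi_$Ixy0) - A * cx * cy
  }
  sectionProperties(
    A = A, Ix = Ix, Iy = Iy, Ixy = Ixy, centroid = c(cx, cy),
    outerBoundary = sweep(outer, 2, c(cx, cy)),
    innerBoundary = if (is.null(inner)) NULL else sweep(inner, 2, c(cx, cy)))
}

#' Construct a sectionProperties object
#'
#' @param A area m^2; `Ix`, `Iy`, `Ixy` centroidal moments m^4; `centroid`
#'   location of the centroid in the original outline frame; boundaries are
#'   centroid-relative two-column matrices.
#' @return object of class `sectionProperties`.
#' @export
sectionProperties <- function(A, Ix, Iy, Ixy, centroid = c(0, 0),
                              outerBoundary = NULL, innerBoundary = NULL) {
  if (A <= 0) stop("section area must be positive")
  if (Ix <= 0 || Iy <= 0) stop("second moments must be positive")
  if (Ix * Iy - Ixy^2 <= 0) stop("section moment tensor is singular")
  structure(list(A = A, Ix = Ix, Iy = Iy, Ixy = Ixy, centroid = centroid,
                 outerBoundary = outerBoundary,
                 innerBoundary = innerBoundary),
            class = "sectionProperties")
}

#' @export
print.sectionProperties <- function(x, ...) {
  cat(sprintf(
    "Beam cross-section: A = %.6g m^2, Ix = %.6g m^4, Iy = %.6g m^4, Ixy = %.6g m^4\n",
    x$A, x$Ix, x$Iy, x$Ixy))
  if (!is.null(x$outerBoundary))
    cat(sprintf("  outer boundary: %d vertices%s\n", nrow(x$outerBoundary),
                if (is.null(x$innerBoundary)) " (solid)" else
                  sprintf("; inner boundary: %d vertices",
                          nrow(x$innerBoundary))))
  invisible(x)
}

#' Mid-shaft load state
#'
#' Longitudinal force plus bending moments about the centroidal section axes.
#' Tension is positive. In the planar simulator only the mediolateral
#' bending component (`Mx`) is generated dynamically; `My` is zero by
#' construction.
#'
#' @param F longitudinal force (N, tension positive).
#' @param Mx,My bending moments (N m).
#' @return object of class `loadState`.
#' @export
loadState <- function(F = 0, Mx = 0, My = 0) {
  v <- c(F, Mx, My)
  if (!all(is.finite(v))) stop("load components must be finite")
  structure(list(F = F, Mx = Mx, My = My), class = "loadState")
}

#' Uniform compressive/tensile stress, sigma = F / A
#'
#' @param load a [loadState()].
#' @param section a [sectionProperties()].
#' @return stress (Pa, tension positive).
#' @export
compressiveStress <- function(load, section) {
  load$F / section$A
}

#' Bending stress at a point of an arbitrary (asymmetric) cross-section
#'
#' Unsymmetric-beam formula:
#' sigma = ((Mx Iy + My Ixy) y - (My Ix + Mx Ixy) x) / (Ix Iy - Ixy^2)
#' with x, y measured from the section centroid.
#'
#' @param load a [loadState()].
#' @param section a [sectionProperties()].
#' @param x,y centroid-relative coordinates (m); vectorised.
#' @return stress (Pa, tension positive).
#' @export
bendingStress <- function(load, section, x, y) {
  D <- section$Ix * section$Iy - section$Ixy^2
  if (D <= 0) stop("singular section: Ix*Iy - Ixy^2 must be positive")
  (load$Mx * section$Iy + load$My * section$Ixy) / D * y -
    (load$My * section$Ix + load$Mx * section$Ixy) / D * x
}

#' Extreme combined stress on the outer boundary
#'
#' Evaluates axial-plus-bending stress at every outer boundary vertex and
#' returns the extremes (the extreme fibre of a combined axial + bending
#' field lies on the outer boundary).
#'
#' @param load a [loadState()].
#' @param section a [sectionProperties()] carrying an `outerBoundary`.
#' @return list with `max`, `min` (Pa), `maxLocation`, `minLocation`
#'   (centroid-relative coordinates).
#' @export
peakBoundaryStress <- function(load, section) {
  b <- section$outerBoundary
  if (is.null(b)) stop("section carries no boundary points")
  s <- compressiveStress(load, section) +
    bendingStress(load, section, b[, 1], b[, 2])
  imax <- which.max(s); imin <- which.min(s)
  list(max = s[imax], min = s[imin],
       maxLocation = b[imax, ], minLocation = b[imin, ])
}

#' Butterworth biquad coefficients for the in-loop filter
#' @keywords internal
butterworthCoefficients <- function(sampleRate, cutoff = 5, order = 2) {
  if (cutoff >= sampleRate / 2)
    stop("cutoff must be below the Nyquist frequency")
  bt <- signal::butter(order, 2 * cutoff / sampleRate, type = "low")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

#' Causal low-pass Butterworth filter
#'
#' Second-order (by default) Butterworth low-pass at 5 Hz, applied causally
#' with the filter state initialised to the first sample so a constant
#' series passes unchanged. `mode = "zero-phase"` applies the same filter
#' forward and backward for post-hoc, phase-free smoothing.
#'
#' @param series numeric vector.
#' @param sampleRate sampling rate (Hz); must exceed twice the cutoff.
#' @param cutoff cutoff frequency (Hz), default 5.
#' @param order filter order, default 2.
#' @param mode "causal" (default, as used by the in-loop fail monitor) or
#'   "zero-phase".
#' @return filtered series.
#' @export
butterworthLowpass <- function(series, sampleRate, cutoff = 5, order = 2,
                               mode = c("causal", "zero-phase")) {
  mode <- match.arg(mode)
  co <- butterworthCoefficients(sampleRate, cutoff, order)
  if (mode == "causal") {
    # steady-state start: filter the deviation from the first sample
    # (DC gain is 1, so this equals priming the state at series[1])
    s0 <- series[1]
    as.numeric(signal::filter(co$b, co$a, series - s0)) + s0
  } else {
    s0 <- series[1]; s1 <- series[length(series)]
    fwd <- as.numeric(signal::filter(co$b, co$a, series - s0)) + s0
    rev(as.numeric(signal::filter(co$b, co$a, rev(fwd) - s1)) + s1)
  }
}

#' Peak-stress trace container
#'
#' @param time time grid (s).
#' @param raw,filtered matrices (time x bone) of peak stress magnitude (Pa).
#' @param limit stress limit (Pa).
#' @return object of class `stressTrace`.
#' @export
stressTrace <- function(time, raw, filtered, limit) {
  raw <- as.matrix(raw); filtered <- as.matrix(filtered)
  if (!all(dim(raw) == dim(filtered)))
    stop("raw and filtered traces must have equal dimensions")
  if (limit <= 0) stop("stress limit must be positive")
  structure(list(time = time, raw = raw, filtered = filtered, limit = limit),
            class = "stressTrace")
}

#' Hard peak-stress fail monitor
#'
#' Scans filtered peak-stress traces (one column per monitored bone) and
#' reports the first instant at which any bone exceeds the limit.
#'
#' @param traces a [stressTrace()], or a matrix of filtered peak stress with
#'   one column per bone.
#' @param limit stress limit (Pa); ignored if `traces` is a `stressTrace`
#'   and `limit` is missing.
#' @param time optional time grid when `traces` is a bare matrix.
#' @return list with `passed` (logical) and, on failure, `time` and `bone`.
#' @export
stressFailMonitor <- function(traces, limit = NULL, time = NULL) {
  if (inherits(traces, "stressTrace")) {
    if (is.null(limit)) limit <- traces$limit
    time <- traces$time
    mat <- traces$filtered
  } else {
    mat <- as.matrix(traces)
    if (is.null(time)) time <- seq_len(nrow(mat))
  }
  exceed <- abs(mat) > limit
  if (!any(exceed)) return(list(passed = TRUE, time = NA_real_, bone = NA))
  idx <- which(rowSums(exceed) > 0)[1]
  bone <- which(exceed[idx, ])[1]
  nm <- colnames(mat)
  list(passed = FALSE, time = time[idx],
       bone = if (!is.null(nm)) nm[bone] else bone)
}
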