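#' Per-limb ground contact from a trajectory
#'
#' A limb is in contact when any of its spheres transmits a normal force
#' above the detection threshold (default 0.1% of body weight, suppressing
#' numerical chatter). Limbs are identified by `_l` / `_r` suffixes of the
#' contact segment names.
#'
#' @param traj a `trajectory`.
#' @param threshold normal-force threshold (N); default 0.1% of body
#'   weight.
#' @return logical matrix (samples x limbs) with columns `left`, `right`
#'   (or a single `all` column when sides cannot be identified).
#' @export
limbContact <- function(traj, threshold = NULL) {
  nc <- ncol(traj$contactForce) / 2
  if (nc == 0) stop("trajectory has no contacts")
  if (is.null(threshold)) threshold <- 0.001 * traj$totalMass * 9.81
  normal <- traj$contactForce[, 2 * seq_len(nc), drop = FALSE]
  segs <- traj$contactSegments
  if (!is.null(segs) && any(grepl("_l", segs)) && any(grepl("_r", segs))) {
    left <- normal[, grepl("_l", segs), drop = FALSE]
    right <- normal[, grepl("_r", segs), drop = FALSE]
    out <- cbind(left = rowSums(left > threshold) > 0,
                 right = rowSums(right > threshold) > 0)
  } else {
    out <- cbind(all = rowSums(normal > threshold) > 0)
  }
  out
}

#' Touchdown times of a limb
#' @keywords internal
touchdowns <- function(contact, time) {
  rising <- which(diff(c(FALSE, contact)) == 1)
  time[rising]
}

#' Duty factor
#'
#' Fraction of the gait cycle a limb spends in ground contact, averaged
#' over complete cycles. Values above 0.5 indicate walking (a dual-support
#' phase exists); below 0.5 the limb is airborne more than half the time.
#'
#' @param contact logical matrix (samples x limbs) or vector.
#' @param time sample times (s).
#' @param cycleBounds times delimiting complete cycles (length >= 2, e.g.
#'   successive touchdowns of the same foot).
#' @return per-limb duty factor in [0, 1].
#' @export
dutyFactor <- function(contact, time, cycleBounds) {
  contact <- as.matrix(contact)
  if (length(cycleBounds) < 2)
    stop("need at least one complete cycle")
  inCycle <- time >= cycleBounds[1] & time < cycleBounds[length(cycleBounds)]
  if (!any(inCycle)) stop("no samples inside the cycles")
  apply(contact[inCycle, , drop = FALSE], 2, mean)
}

#' Froude number
#'
#' Dimensionless speed Fr = v^2 / (g h) with h the standing hip height.
#' Fr = 1 marks the inverted-pendulum upper limit for walking gaits.
#'
#' @param velocity horizontal velocity (m/s).
#' @param hipHeight standing hip height (m), > 0.
#' @param g gravitational acceleration (m/s^2).
#' @return Froude number.
#' @export
froudeNumber <- function(velocity, hipHeight, g = 9.81) {
  if (any(hipHeight <= 0)) stop("hip height must be positive")
  velocity^2 / (g * hipHeight)
}

#' Stride length and gait cycle duration
#'
#' Cycle duration is the mean interval between successive touchdowns of
#' the same foot; stride length is the mean forward COM displacement per
#' cycle.
#'
#' @param traj a `trajectory`.
#' @param limb which limb's touchdowns define the cycle.
#' @return list with `strideLength` (m), `cycleDuration` (s),
#'   `touchdownTimes`.
#' @export
strideMetrics <- function(traj, limb = "left") {
  ct <- limbContact(traj)
  col <- if (limb %in% colnames(ct)) limb else colnames(ct)[1]
  td <- touchdowns(ct[, col], traj$time)
  if (length(td) < 2)
    stop("need at least two touchdowns of the same foot")
  comx <- stats::approx(traj$time, traj$com[, 1], xout = td)$y
  list(strideLength = mean(diff(comx)),
       cycleDuration = mean(diff(td)),
       touchdownTimes = td)
}

#' Phase difference between two cyclic energy series
#'
#' Cross-correlates the mean-removed series over lags spanning one cycle
#' and reports the correlation-maximising lag as a percentage of the cycle,
#' folded into [0, 50]. 0% means in-phase (running-like energy
#' fluctuation), 50% antiphase (pendular walking-like exchange).
#'
#' @param a,b numeric series on a uniform time grid.
#' @param dt sample interval (s).
#' @param cycleDuration gait cycle period (s).
#' @return phase difference in percent of a cycle, in [0, 50].
#' @export
energyPhaseDifference <- function(a, b, dt, cycleDuration) {
  a <- a - mean(a); b <- b - mean(b)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    stop("phase difference undefined for a constant series")
  L <- round(cycleDuration / dt)
  if (L < 4) stop("cycle too short for the sampling interval")
  maxLag <- ceiling(L / 2)
  lags <- seq(-maxLag, maxLag)
  n <- length(a)
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      ia <- seq_len(n - l); ib <- ia + l
    } else {
      ib <- seq_len(n + l); ia <- ib - l
    }
    sum(a[ia] * b[ib]) / sqrt(sum(a^2) * sum(b^2))
  }, 0)
  best <- lags[which.max(cc)]
  ph <- abs(best) / L * 100
  min(ph, 100 - ph)
}

#' Kinetic/potential energy transformations of a gait
#'
#' Horizontal kinetic energy (1/2 M v_x^2 of the COM), gravitational
#' potential energy (M g y_COM) and their sum, plus the KE/PE phase
#' difference over the gait cycle.
#'
#' @param traj a `trajectory`.
#' @param cycleDuration gait cycle period (s); estimated from touchdowns
#'   when `NULL`.
#' @return object of class `energyTrace`: `time`, `kineticHorizontal`,
#'   `potential`, `total` (J), `phaseDifference` (% of cycle).
#' @export
energyTransformations <- function(traj, cycleDuration = NULL) {
  M <- traj$totalMass
  ke <- 0.5 * M * traj$comVel[, 1]^2
  pe <- M * 9.81 * traj$com[, 2]
  if (is.null(cycleDuration))
    cycleDuration <- strideMetrics(traj)$cycleDuration
  dt <- traj$time[2] - traj$time[1]
  if (max(traj$time) < 2 * cycleDuration)
    stop("need at least two complete cycles")
  ph <- energyPhaseDifference(ke, pe, dt, cycleDuration)
  structure(list(time = traj$time, kineticHorizontal = ke, potential = pe,
                 total = ke + pe, phaseDifference = ph,
                 cycleDuration = cycleDuration),
            class = "energyTrace")
}

#' Classify a gait as walk, grounded run or aerial run
#'
#' An aerial phase (both feet simultaneously off the ground) defines an
#' aerial run. Without one, a large KE/PE phase difference (pendular
#' exchange) defines a walk; a small one defines a grounded run -
#' running-like COM mechanics without an aerial phase.
#'
#' @param dutyFactors per-limb duty factors.
#' @param aerialPhase logical: any instant with no ground contact.
#' @param phaseDifference KE/PE phase difference (% of cycle, [0, 50]).
#' @param walkThreshold phase difference at or above which the gait is a
#'   walk (default 25%).
#' @return one of "walk", "grounded run", "aerial run".
#' @export
classifyGait <- function(dutyFactors, aerialPhase, phaseDifference,
                         walkThreshold = 25) {
  if (aerialPhase) return("aerial run")
  if (phaseDifference >= walkThreshold) return("walk")
  "grounded run"
}

#' Summary gait analytics for a trajectory
#'
#' @param traj a `trajectory`.
#' @param hipHeight standing hip height (m); defaults to the hip height at
#'   the first sample.
#' @return object of class `gaitSummary`: mean velocity, Froude number,
#'   stride length, cycle duration, per-limb duty factor, aerial-phase
#'   flag, KE/PE phase difference, gait class.
#' @export
gaitSummary <- function(traj, hipHeight = traj$hipHeight[1]) {
  elapsed <- traj$termination$time
  distance <- traj$com[nrow(traj$com), 1] - traj$com[1, 1]
  v <- if (elapsed > 0) distance / elapsed else 0
  sm <- strideMetrics(traj)
  ct <- limbContact(traj)
  td <- sm$touchdownTimes
  df <- dutyFactor(ct, traj$time, td)
  inCycle <- traj$time >= td[1] & traj$time < td[length(td)]
  aerial <- any(rowSums(ct[inCycle, , drop = FALSE]) == 0)
  en <- energyTransformations(traj, sm$cycleDuration)
  structure(list(meanVelocity = v,
                 froude = froudeNumber(v, hipHeight),
                 strideLength = sm$strideLength,
                 cycleDuration = sm$cycleDuration,
                 dutyFactor = df,
                 aerialPhase = aerial,
                 phaseDifference = en$phaseDifference,
                 gaitClass = classifyGait(df, aerial, en$phaseDifference),
                 hipHeight = hipHeight),
            class = "gaitSummary")
}

#' @export
print.gaitSummary <- function(x, ...) {
  cat(sprintf(
    "Gait: %s | v = %.3f m/s, Fr = %.3f, stride %.3f m, cycle %.3f s\n",
    x$gaitClass, x$meanVelocity, x$froude, x$strideLength,
    x$cycleDuration))
  cat(sprintf("  duty factor %s; aerial phase: %s; KE/PE phase %.1f%%\n",
              paste(sprintf("%s %.2f", names(x$dutyFactor), x$dutyFactor),
                    collapse = ", "),
              x$aerialPhase, x$phaseDifference))
  invisible(x)
}
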