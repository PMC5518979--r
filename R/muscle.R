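#' Active force-length curve
#'
#' Unimodal (Gaussian) curve peaking at 1 at the optimal fibre length.
#' @param lnorm fibre length / optimal fibre length.
#' @return dimensionless factor in [0, 1].
#' @export
forceLengthCurve <- function(lnorm) {
  exp(-((lnorm - 1) / 0.45)^2)
}

#' Force-velocity curve
#'
#' Hyperbolic shortening branch reaching zero at the maximum contraction
#' velocity and a saturating lengthening branch; `forceVelocityCurve(0) = 1`.
#' @param vnorm fibre velocity / maximum shortening velocity (shortening
#'   negative).
#' @return dimensionless factor in [0, 1.8].
#' @export
forceVelocityCurve <- function(vnorm) {
  ifelse(vnorm <= -1, 0,
         ifelse(vnorm <= 0, (1 + vnorm) / (1 - vnorm / 0.25),
                (0.135 + 1.8 * vnorm) / (0.135 + vnorm)))
}

#' Passive fibre force-length curve
#'
#' Exponential toe region engaging above the optimal length, capped at twice
#' the maximum isometric force.
#' @param lnorm fibre length / optimal fibre length.
#' @return dimensionless factor >= 0.
#' @export
passiveForceCurve <- function(lnorm) {
  f <- ifelse(lnorm <= 1, 0,
              (exp(4 * (lnorm - 1) / 0.6) - 1) / (exp(4) - 1))
  pmin(f, 2)
}

#' Muscle-tendon unit length in a pose
#'
#' Sum of straight-line distances between consecutive world-frame
#' way-points of the muscle path.
#'
#' @param model a [bipedModel()].
#' @param muscle a [muscleTendonUnit()] or its name in the model.
#' @param pose a pose (see [referencePose()]).
#' @return length (m).
#' @export
mtuLength <- function(model, muscle, pose = referencePose(model)) {
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  fk <- forwardKinematics(model, pose)
  pts <- t(vapply(seq_len(nrow(muscle$path)), function(i)
    worldPoint(fk, muscle$path$segment[i],
               c(muscle$path$x[i], muscle$path$y[i])),
    numeric(2)))
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Muscle moment arm about a joint
#'
#' Central finite difference `-dL/dtheta` of the muscle-tendon length with
#' respect to the joint angle (step 1e-5 rad). Positive values produce an
#' extension (counterclockwise child-segment) moment.
#'
#' @param model a [bipedModel()].
#' @param muscle a [muscleTendonUnit()] or its name.
#' @param joint a [hingeJoint()] or the name of its child segment.
#' @param pose evaluation pose.
#' @param h finite-difference step (rad).
#' @return moment arm (m).
#' @export
momentArm <- function(model, muscle, joint, pose = referencePose(model),
                      h = 1e-5) {
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  if (is.character(joint)) {
    jn <- joint
    joint <- Find(function(j) j$child == jn, model$joints)
    if (is.null(joint)) stop(sprintf("no joint with child '%s'", jn))
  }
  crossed <- vapply(musclesCrossedJoints(model, muscle),
                    function(j) j$child, "")
  if (!(joint$child %in% crossed))
    stop(sprintf("muscle '%s' does not cross the %s joint",
                 muscle$name, joint$child))
  pp <- pose; pm <- pose
  a0 <- pose$angles[[joint$child]]
  if (is.null(a0) || is.na(a0)) a0 <- 0
  pp$angles[[joint$child]] <- a0 + h
  pm$angles[[joint$child]] <- a0 - h
  -(mtuLength(model, muscle, pp) - mtuLength(model, muscle, pm)) / (2 * h)
}

#' Muscle-tendon unit force (series-elastic, quasi-static)
#'
#' Hill-type force with contractile fibres (active force-length and
#' force-velocity plus passive elasticity) in series with a linear-stiffness
#' tendon that is slack below its slack length. The fibre length is solved
#' from force equilibrium across the tendon at the given MTU length; the
#' fibre carries the MTU velocity (normalised by the maximum shortening
#' velocity, `vmaxFactor * fibreLength` per second).
#'
#' @param muscle a [muscleTendonUnit()].
#' @param activation in [0, 1].
#' @param mtuLengthValue current MTU length (m).
#' @param mtuVelocity current MTU lengthening velocity (m/s).
#' @param tendonStiffness dimensionless tendon stiffness: tendon force is
#'   `fmax * tendonStiffness * strain`; default 30 (about 3.3% strain at
#'   the maximum isometric force).
#' @param vmaxFactor maximum shortening velocity in optimal fibre lengths
#'   per second, default 10.
#' @return force (N), never negative.
#' @export
mtuForce <- function(muscle, activation, mtuLengthValue, mtuVelocity = 0,
                     tendonStiffness = 30, vmaxFactor = 10) {
  if (!all(is.finite(c(activation, mtuLengthValue, mtuVelocity))))
    stop("inputs must be finite")
  if (activation < 0 || activation > 1)
    stop("activation must lie in [0, 1]")
  lopt <- muscle$fibreLength
  lsl <- muscle$tendonSlackLength
  fmax <- muscle$fmax
  vmax <- vmaxFactor * lopt
  vn <- if (vmax > 0) mtuVelocity / vmax else 0
  tendonForce <- function(lt) {
    if (lsl <= 0) return(NA_real_)   # rigid tendon handled below
    fmax * tendonStiffness * max(0, (lt - lsl) / lsl)
  }
  fibreForce <- function(lf) {
    ln <- lf / lopt
    fmax * max(0, activation * forceLengthCurve(ln) *
                 forceVelocityCurve(vn) + passiveForceCurve(ln))
  }
  if (lsl <= 0) {
    lf <- mtuLengthValue
    if (lf <= 0) return(0)
    return(fibreForce(lf))
  }
  # equilibrium: tendonForce(Lmtu - lf) = fibreForce(lf)
  g <- function(lf) tendonForce(mtuLengthValue - lf) - fibreForce(lf)
  lo <- 1e-6 * lopt
  hi <- max(mtuLengthValue, lo * 2)
  if (g(lo) <= 0) return(max(0, tendonForce(mtuLengthValue - lo)))
  if (g(hi) >= 0) return(fibreForce(hi))
  lf <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  max(0, fibreForce(lf))
}

#' First-order activation dynamics
#'
#' Exact exponential relaxation of activation toward the neural excitation
#' over one timestep; output stays in [0, 1].
#'
#' @param excitation target excitation in [0, 1].
#' @param activation current activation in [0, 1].
#' @param dt timestep (s).
#' @param timeConstant activation time constant (s), default 0.05.
#' @return updated activation.
#' @export
activationUpdate <- function(excitation, activation, dt,
                             timeConstant = 0.05) {
  if (any(excitation < 0 | excitation > 1))
    stop("excitation must lie in [0, 1]")
  a <- excitation + (activation - excitation) * exp(-dt / timeConstant)
  pmin(pmax(a, 0), 1)
}
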