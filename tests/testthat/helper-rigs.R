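# Small test rigs shared across files; everything is generated in code.

rectOutline <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# fixed base with a single hinged arm; the muscle runs from a base point to
# an arm point, so the closed-form (law-of-cosines) MTU length is available
makeArmRig <- function(basePoint = c(0.1, 0), armPoint = c(0, -0.2),
                       rangeMin = -1, rangeMax = 1) {
  base <- segment("base", rectOutline(-0.2, 0.2, -0.05, 0.05),
                  mass = 1, length = 0.1,
                  proximalAnchor = c(0, 0), distalAnchor = c(0.2, 0))
  arm <- segment("arm", rectOutline(-0.02, 0.02, -0.4, 0),
                 mass = 1, length = 0.4,
                 proximalAnchor = c(0, 0), distalAnchor = c(0, -0.4))
  mus <- muscleTendonUnit(
    "mus",
    data.frame(segment = c("base", "arm"),
               x = c(basePoint[1], armPoint[1]),
               y = c(basePoint[2], armPoint[2])),
    fmax = 1000, fibreLength = 0.05, tendonSlackLength = 0.1)
  m <- bipedModel(list(base, arm),
                  list(hingeJoint("base", "arm", c(0, 0), c(0, 0),
                                  rangeMin = rangeMin, rangeMax = rangeMax)),
                  muscles = list(mus), name = "arm-rig")
  attr(m, "fixedRoot") <- TRUE
  attr(m, "jointDamping") <- 0
  m
}

# closed-form MTU length of the arm rig at joint angle theta
armRigLength <- function(theta, basePoint = c(0.1, 0),
                         armPoint = c(0, -0.2)) {
  a <- sqrt(sum(basePoint^2))
  b <- sqrt(sum(armPoint^2))
  g0 <- atan2(basePoint[2], basePoint[1]) -
    atan2(armPoint[2], armPoint[1])
  sqrt(a^2 + b^2 - 2 * a * b * cos(g0 - theta))
}

# minimal trajectory-shaped object for the gait-metric unit tests
makeFakeTrajectory <- function(time, comx, comy, contactLeft, contactRight,
                               totalMass = 80, bodyWeightN = totalMass * 9.81) {
  n <- length(time)
  cf <- cbind(0, ifelse(contactLeft, 0.5 * bodyWeightN, 0),
              0, ifelse(contactRight, 0.5 * bodyWeightN, 0))
  structure(list(
    time = time,
    com = cbind(comx, comy),
    comVel = cbind(c(diff(comx) / diff(time), NA), 0),
    hipHeight = comy,
    contactForce = cf,
    contactFlag = cbind(as.integer(contactLeft), as.integer(contactRight)),
    contactSegments = c("pes_l", "pes_r"),
    totalMass = totalMass,
    termination = list(cause = "completed", time = max(time), bone = NA),
    muscleNames = character(0), boneNames = character(0)),
    class = "trajectory")
}

# an asymmetric (no mirror symmetry) simple polygon for rotation tests
asymmetricSection <- function(n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 0.05 * (1 + 0.25 * cos(th + 0.7) + 0.12 * sin(2 * th))
  cbind(r * cos(th), r * sin(th))
}
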