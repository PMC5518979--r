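#' Rectangle outline helper
#' @keywords internal
rectOutline <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Single (or double) pendulum validation rig
#'
#' A fixed base with one or two uniform bars on frictionless hinges; no
#' muscles, no contacts, no joint damping. Used as a closed-form dynamics
#' oracle (period, energy conservation, split/unsplit equivalence).
#'
#' @param length bar length (m).
#' @param mass bar mass (kg).
#' @param double add a second, distally hinged bar.
#' @param width bar width (m) for the hull.
#' @return a [bipedModel()] with a fixed root.
#' @export
makePendulum <- function(length = 1, mass = 1, double = FALSE,
                         width = 0.02) {
  base <- segment("base", rectOutline(-0.05, 0.05, -0.05, 0.05),
                  mass = 1, length = 0.1,
                  proximalAnchor = c(0, 0), distalAnchor = c(0, -0.05))
  bar <- segment("bar", rectOutline(-width / 2, width / 2, -length, 0),
                 mass = mass, length = length,
                 proximalAnchor = c(0, 0), distalAnchor = c(0, -length))
  joints <- list(hingeJoint("base", "bar", c(0, 0), c(0, 0),
                            rangeMin = -50, rangeMax = 50))
  segs <- list(base, bar)
  if (double) {
    bar2 <- segment("bar2", rectOutline(-width / 2, width / 2, -length, 0),
                    mass = mass, length = length,
                    proximalAnchor = c(0, 0), distalAnchor = c(0, -length))
    segs <- c(segs, list(bar2))
    joints <- c(joints, list(hingeJoint("bar", "bar2", c(0, -length),
                                        c(0, 0), rangeMin = -50,
                                        rangeMax = 50)))
  }
  m <- bipedModel(segs, joints, name = if (double) "double-pendulum"
                  else "pendulum")
  attr(m, "fixedRoot") <- TRUE
  attr(m, "jointDamping") <- 0
  m
}

#' Ball-on-plane contact validation rig
#'
#' A single free body with one contact sphere; settles to the static
#' penetration m g / k.
#'
#' @param mass kg.
#' @param radius sphere radius (m).
#' @param stiffness contact stiffness (N/m).
#' @param damping contact damping (N s/m); default slightly under critical.
#' @return a [bipedModel()].
#' @export
makeDropTest <- function(mass = 1, radius = 0.1, stiffness = 1e4,
                         damping = 1.4 * sqrt(stiffness * mass)) {
  ball <- segment("ball", circleOutline(radius, 32L), mass = mass,
                  length = radius,
                  proximalAnchor = c(0, 0), distalAnchor = c(0, -radius))
  m <- bipedModel(list(ball), list(),
                  contacts = list(contactSphere("ball", c(0, 0), radius,
                                                stiffness, damping,
                                                frictionMu = 1)),
                  name = "drop-test")
  pose <- referencePose(m)
  pose$root <- c(0, radius, 0)         # resting exactly on the plane
  attr(m, "initialPose") <- pose
  m
}

# muscle archetypes of one limb: name, origin segment/point, insertion
# segment/point (local coordinates in units of leg length)
limbMuscleArchetypes <- function() {
  list(
    hip_ext = list(o = c("trunk", -0.10, 0.08), i = c("thigh", -0.045, -0.20),
                   group = "proximal extensor"),
    hip_flex = list(o = c("trunk", 0.10, 0.08), i = c("thigh", 0.045, -0.20),
                    group = "proximal flexor"),
    knee_ext = list(o = c("thigh", 0.055, -0.32), i = c("shank", 0.042, -0.10),
                    group = "intermediate extensor"),
    knee_flex = list(o = c("thigh", -0.055, -0.32),
                     i = c("shank", -0.040, -0.10),
                     group = "intermediate flexor"),
    ankle_ext = list(o = c("shank", -0.042, -0.15),
                     i = c("metatarsal", -0.028, -0.06),
                     group = "distal extensor"),
    ankle_flex = list(o = c("shank", 0.042, -0.15),
                      i = c("metatarsal", 0.028, -0.06),
                      group = "distal flexor"))
}

#' Parameterised planar biped builder
#'
#' Shared geometry generator behind [makeToyBiped()] and [makeTrexLike()]:
#' trunk plus per-side thigh, shank, metatarsal and pes chains, hinge
#' joints with ranges, paired flexor/extensor muscles at hip, knee and
#' ankle, contact spheres under heel and toe, and hollow-circular bone
#' cross-sections at the segment mid-shafts. Fibre and tendon-slack
#' lengths are tuned from the joint-range length sweep; maximum isometric
#' forces derive from the allocated muscle masses. Deterministic: the same
#' arguments always produce an identical model.
#'
#' @param name model name.
#' @param legLength standing hip height scale (m).
#' @param totalMass total body mass (kg); segment masses follow the limb
#'   mass-fraction table, remainder to the trunk (forelimbs, where
#'   present, are merged into the trunk for the planar model).
#' @param musclesPerLimb >= 6; muscles beyond 6 cycle through the
#'   archetypes (hip/knee/ankle x flexor/extensor) sharing group mass.
#' @param muscleFraction total muscle mass as a fraction of body mass.
#' @param limbFractions per-side limb mass fractions.
#' @param sectionRadii named outer radii (m) for femur, tibia, fibula,
#'   metatarsus mid-shaft sections.
#' @param corticalFractions named cortical-thickness fractions.
#' @param fibreFraction fibre share of the muscle-tendon length sweep.
#' @param staticPenetration target standing contact penetration as a
#'   fraction of leg length (sets contact stiffness from body weight).
#' @return a validated [bipedModel()] with a standing `initialPose`
#'   attribute.
#' @export
buildBiped <- function(name, legLength, totalMass, musclesPerLimb = 6L,
                       muscleFraction = 0.5,
                       limbFractions = limbMassFractionDefaults(),
                       sectionRadii = c(femur = 0.030, tibia = 0.025,
                                        fibula = 0.009,
                                        metatarsus = 0.018) * legLength,
                       corticalFractions = c(femur = 0.38, tibia = 0.35,
                                             fibula = 0.96,
                                             metatarsus = 0.60),
                       fibreFraction = 0.5,
                       staticPenetration = 0.01) {
  if (musclesPerLimb < 6)
    stop("need at least 6 muscles per limb (flexor/extensor at hip, knee, ankle)")
  L <- legLength
  Lt <- 0.45 * L; Ls <- 0.45 * L; Lm <- 0.10 * L
  masses <- assignLimbMassFractions(
    totalMass,
    stats::setNames(rep(limbFractions[c("thigh", "shank", "metatarsal",
                                        "pes")], 2),
                    c(paste0(c("thigh", "shank", "metatarsal", "pes"), "_l"),
                      paste0(c("thigh", "shank", "metatarsal", "pes"), "_r"))))

  nv <- 128L
  sections <- list(
    thigh = crossSectionSpec(circleOutline(sectionRadii[["femur"]], nv),
                             corticalFractions[["femur"]]),
    shank = list(
      tibia = crossSectionSpec(circleOutline(sectionRadii[["tibia"]], nv),
                               corticalFractions[["tibia"]]),
      fibula = crossSectionSpec(circleOutline(sectionRadii[["fibula"]], nv),
                                corticalFractions[["fibula"]])),
    metatarsal = crossSectionSpec(
      circleOutline(sectionRadii[["metatarsus"]], nv),
      corticalFractions[["metatarsus"]]))

  trunk <- segment("trunk", rectOutline(-0.30 * L, 0.30 * L,
                                        -0.05 * L, 0.55 * L),
                   mass = masses[["trunk"]], length = 0.6 * L,
                   proximalAnchor = c(0, 0), distalAnchor = c(0, 0.55 * L))
  mkLeg <- function(side) {
    sfx <- paste0("_", side)
    list(
      segment(paste0("thigh", sfx),
              rectOutline(-0.06 * L, 0.06 * L, -Lt, 0),
              mass = masses[[paste0("thigh", sfx)]], length = Lt,
              proximalAnchor = c(0, 0), distalAnchor = c(0, -Lt),
              section = sections$thigh),
      segment(paste0("shank", sfx),
              rectOutline(-0.045 * L, 0.045 * L, -Ls, 0),
              mass = masses[[paste0("shank", sfx)]], length = Ls,
              proximalAnchor = c(0, 0), distalAnchor = c(0, -Ls),
              section = sections$shank),
      segment(paste0("metatarsal", sfx),
              rectOutline(-0.03 * L, 0.03 * L, -Lm, 0),
              mass = masses[[paste0("metatarsal", sfx)]], length = Lm,
              proximalAnchor = c(0, 0), distalAnchor = c(0, -Lm),
              section = sections$metatarsal),
      segment(paste0("pes", sfx),
              rectOutline(-0.11 * L, 0.11 * L, -0.035 * L, 0.015 * L),
              mass = masses[[paste0("pes", sfx)]], length = 0.11 * L,
              proximalAnchor = c(0, 0), distalAnchor = c(0.11 * L, 0)))
  }
  mkJoints <- function(side) {
    sfx <- paste0("_", side)
    list(
      hingeJoint("trunk", paste0("thigh", sfx), c(0, 0), c(0, 0),
                 rangeMin = -0.6, rangeMax = 1.0),
      hingeJoint(paste0("thigh", sfx), paste0("shank", sfx),
                 c(0, -Lt), c(0, 0), rangeMin = -2.0, rangeMax = 0.05),
      hingeJoint(paste0("shank", sfx), paste0("metatarsal", sfx),
                 c(0, -Ls), c(0, 0), rangeMin = -0.6, rangeMax = 0.6),
      hingeJoint(paste0("metatarsal", sfx), paste0("pes", sfx),
                 c(0, -Lm), c(0, 0), rangeMin = -0.4, rangeMax = 0.4))
  }

  W <- totalMass * 9.81
  k <- W / (4 * staticPenetration * L)
  cdamp <- 2 * sqrt(k * masses[["pes_l"]])
  mkContacts <- function(side) {
    # heel and toe spheres symmetric about the metatarsophalangeal joint
    # so the standing pose starts at static equilibrium
    sfx <- paste0("_", side)
    list(contactSphere(paste0("pes", sfx), c(-0.09 * L, -0.010 * L),
                       0.025 * L, k, cdamp, frictionMu = 1),
         contactSphere(paste0("pes", sfx), c(0.09 * L, -0.010 * L),
                       0.025 * L, k, cdamp, frictionMu = 1))
  }

  arch <- limbMuscleArchetypes()
  groups <- stats::setNames(vector("list", 6), names(muscleMassAllocationDefaults()))
  muscles <- list()
  for (side in c("l", "r")) {
    sfx <- paste0("_", side)
    for (j in seq_len(musclesPerLimb)) {
      a <- arch[[(j - 1) %% 6 + 1]]
      nm <- names(arch)[(j - 1) %% 6 + 1]
      mname <- if (j <= 6) paste0(nm, sfx)
      else paste0(nm, (j - 1) %/% 6 + 1, sfx)
      segO <- if (a$o[1] == "trunk") "trunk" else paste0(a$o[1], sfx)
      segI <- paste0(a$i[1], sfx)
      path <- data.frame(
        segment = c(segO, segI),
        x = as.numeric(c(a$o[2], a$i[2])) * L,
        y = as.numeric(c(a$o[3], a$i[3])) * L)
      muscles[[mname]] <- muscleTendonUnit(
        mname, path, fmax = 1, fibreLength = 1, tendonSlackLength = 0,
        group = a$group)
      groups[[a$group]] <- c(groups[[a$group]], mname)
    }
  }

  model <- bipedModel(
    c(list(trunk), mkLeg("l"), mkLeg("r")),
    c(mkJoints("l"), mkJoints("r")),
    muscles = muscles,
    contacts = c(mkContacts("l"), mkContacts("r")),
    name = name)

  # allocate muscle masses, then tune fibre/tendon lengths and set forces
  mm <- assignMuscleMasses(totalMass, muscleFraction,
                           muscleMassAllocationDefaults(), groups)
  for (nm in names(model$muscles)) {
    tuned <- tuneFibreTendonLengths(model, model$muscles[[nm]],
                                    fibreFraction = fibreFraction)
    model$muscles[[nm]]$fibreLength <- tuned$fibreLength
    model$muscles[[nm]]$tendonSlackLength <- tuned$tendonSlackLength
    model$muscles[[nm]]$mass <- mm[[nm]]
    model$muscles[[nm]]$fmax <- muscleFmaxFromMass(mm[[nm]],
                                                   tuned$fibreLength)
  }

  pose <- referencePose(model)
  pose$root <- c(0, (0.45 + 0.45 + 0.10) * L + 0.035 * L -
                   staticPenetration * L, 0)
  attr(model, "initialPose") <- pose
  attr(model, "muscleMasses") <- mm
  model
}

#' Small optimisable toy biped
#'
#' Scaled-down planar biped (default 1 m leg, 80 kg) carrying the same
#' structure as the full-scale model: hollow-circular bone sections with
#' the tyrannosaur cortical-thickness fractions (femur 0.38, tibia 0.35,
#' fibula 0.96, metatarsus 0.60), paired muscles at hip, knee and ankle,
#' and heel/toe contact spheres.
#'
#' @param legLength m.
#' @param totalMass kg.
#' @param musclesPerLimb >= 6.
#' @return a [bipedModel()].
#' @export
makeToyBiped <- function(legLength = 1, totalMass = 80,
                         musclesPerLimb = 6L) {
  buildBiped("toy-biped", legLength, totalMass, musclesPerLimb)
}

#' Tyrannosaurus-scale planar stand-in model
#'
#' A geometric stand-in at full T. rex scale: total body mass 7206.7 kg,
#' total muscle mass 50% of body mass, hind-limb chain of thigh, shank,
#' metatarsal and pes per side with the forelimbs merged into the trunk,
#' and hollow-circular bone sections using the published cortical
#' fractions. Hulls are simplified boxes sized to plausible segment
#' proportions - this fixture is NOT the laser-scan reconstruction; it
#' guarantees self-contained testability at the right scale. Per-segment
#' convex-hull volumes consistent with the shipped stand-in mass
#' regression (see attributes `hullVolumes`, `massRegression`) are
#' attached so the hull-to-mass pipeline can be exercised end to end.
#'
#' @param musclesPerLimb >= 6 (the anatomical model's 29 muscles per limb
#'   collapse onto functional flexor/extensor groups here).
#' @return a [bipedModel()].
#' @export
makeTrexLike <- function(musclesPerLimb = 6L) {
  totalMass <- 7206.7
  m <- buildBiped("trex-like", legLength = 2.95, totalMass = totalMass,
                  musclesPerLimb = musclesPerLimb,
                  muscleFraction = 0.5,
                  sectionRadii = c(femur = 0.085, tibia = 0.072,
                                   fibula = 0.024, metatarsus = 0.050))
  reg <- c(a = 1214, b = 1)   # stand-in hull-density regression (kg per m^3)
  segMasses <- vapply(m$segments, function(s) s$mass, 0)
  attr(m, "massRegression") <- reg
  attr(m, "hullVolumes") <- (segMasses / reg[["a"]])^(1 / reg[["b"]])
  m
}
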