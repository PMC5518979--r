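#' Simulation configuration
#'
#' @param timestep integration timestep (s), default 1e-4 (stiff
#'   spring-damper contacts need small fixed steps).
#' @param duration simulated time (s).
#' @param integrator only "semi_implicit_euler" (fixed-step symplectic
#'   Euler) is provided.
#' @param recordInterval trajectory sampling interval (s).
#' @param stressLimit hard peak-stress limit (Pa); `Inf` disables failing
#'   (traces are still recorded).
#' @param filterCutoff low-pass cutoff for the in-loop peak-stress filter
#'   (Hz), default 5.
#' @param filterOrder Butterworth order, default 2.
#' @param frictionVreg regularisation velocity for Coulomb friction (m/s).
#' @param fallHeightFraction terminate when the hip drops below this
#'   fraction of its starting height; `NA` disables the check.
#' @param maxComSpeed divergence guard: terminate when the COM speed
#'   exceeds this bound (m/s). `NULL` (default) picks
#'   `15 * sqrt(g * h0)` from the starting hip height `h0` - far above any
#'   physical gait, so only numerical blow-ups trigger it.
#' @param constraintTol accepted hinge anchor residual (m); reduced
#'   coordinates keep residuals at round-off, the value is retained for
#'   diagnostics.
#' @param rngSeed seed recorded with every run for provenance (the forward
#'   dynamics itself is deterministic).
#' @return object of class `simConfig`.
#' @export
simConfig <- function(timestep = 1e-4, duration = 10,
                      integrator = "semi_implicit_euler",
                      recordInterval = 0.005, stressLimit = Inf,
                      filterCutoff = 5, filterOrder = 2,
                      frictionVreg = 0.02, fallHeightFraction = 0.5,
                      maxComSpeed = NULL,
                      constraintTol = 1e-8, rngSeed = 1L) {
  if (timestep <= 0) stop("timestep must be positive")
  if (duration <= 0) stop("duration must be positive")
  integrator <- match.arg(integrator, "semi_implicit_euler")
  structure(list(timestep = timestep, duration = duration,
                 integrator = integrator, recordInterval = recordInterval,
                 stressLimit = stressLimit, filterCutoff = filterCutoff,
                 filterOrder = filterOrder, frictionVreg = frictionVreg,
                 fallHeightFraction = fallHeightFraction,
                 maxComSpeed = maxComSpeed,
                 constraintTol = constraintTol, rngSeed = rngSeed),
            class = "simConfig")
}

#' Ground reaction force of a single contact sphere
#'
#' Spring-damper normal force under compression only (never tensile) with
#' regularised Coulomb friction. Ground is the horizontal plane at
#' `groundHeight`.
#'
#' @param sphere a [contactSphere()].
#' @param center world position of the sphere centre (m).
#' @param centerVel world velocity of the sphere centre (m/s).
#' @param groundHeight ground plane height (m), default 0.
#' @param vreg friction regularisation velocity (m/s).
#' @return length-2 force vector (N) applied at the contact point.
#' @export
contactForce <- function(sphere, center, centerVel = c(0, 0),
                         groundHeight = 0, vreg = 0.02) {
  pen <- groundHeight - (center[2] - sphere$radius)
  if (pen <= 0) return(c(0, 0))
  N <- sphere$stiffness * pen - sphere$damping * centerVel[2]
  if (N <= 0) return(c(0, 0))
  s <- max(-1, min(1, centerVel[1] / vreg))
  c(-sphere$frictionMu * N * s, N)
}

#' Split a segment into two bodies joined by a fixed joint
#'
#' Replaces `segmentName` by a proximal and a distal half (local frames
#' unchanged) welded at the cut point on the segment's functional axis.
#' The hull is clipped at the cut plane, so the halves' masses, centres of
#' mass and inertias recombine exactly to the original (parallel-axis
#' theorem). Joints, muscle way-points and contact spheres attached to the
#' segment are re-homed to the correct half by their position along the
#' axis. The weld carries the segment's cross-section as a load monitor.
#'
#' @param model a [bipedModel()].
#' @param segmentName segment to split.
#' @param cutFraction position of the cut along the proximal-to-distal
#'   axis, in (0, 1); default 0.5 (functional mid-point).
#' @return modified model.
#' @export
splitSegmentForLoad <- function(model, segmentName, cutFraction = 0.5) {
  if (!(segmentName %in% names(model$segments)))
    stop(sprintf("unknown segment '%s'", segmentName))
  if (cutFraction <= 0 || cutFraction >= 1)
    stop("cutFraction must lie strictly between 0 and 1")
  seg <- model$segments[[segmentName]]
  u <- seg$distalAnchor - seg$proximalAnchor
  L <- sqrt(sum(u^2))
  if (L <= 0) stop("segment has no functional axis")
  u <- u / L
  cutPoint <- seg$proximalAnchor + cutFraction * L * u
  sCut <- cutFraction * L
  along <- function(p) sum((p - seg$proximalAnchor) * u)

  hullProx <- polygonClipHalfplane(seg$hull, u, sum(u * cutPoint))
  hullDist <- polygonClipHalfplane(seg$hull, -u, -sum(u * cutPoint))
  if (is.null(hullProx) || is.null(hullDist))
    stop("cut plane does not intersect the segment hull")

  hp <- polygonSectionProperties(hullProx, check = FALSE)
  hd <- polygonSectionProperties(hullDist, check = FALSE)
  Atot <- hp$A + hd$A
  m1 <- seg$mass * hp$A / Atot
  m2 <- seg$mass * hd$A / Atot
  rho <- seg$mass / Atot
  I1 <- rho * (hp$Ix + hp$Iy)
  I2 <- rho * (hd$Ix + hd$Iy)
  com0 <- (m1 * hp$centroid + m2 * hd$centroid) / seg$mass
  recombined <- I1 + m1 * sum((hp$centroid - com0)^2) +
    I2 + m2 * sum((hd$centroid - com0)^2)
  corr <- seg$inertiaZz - recombined
  I1 <- max(0, I1 + corr * m1 / seg$mass)
  I2 <- max(0, I2 + corr * m2 / seg$mass)

  nProx <- paste0(segmentName, "_prox")
  nDist <- paste0(segmentName, "_dist")
  segProx <- structure(list(
    name = nProx, mass = m1, comLocal = hp$centroid, inertiaZz = I1,
    length = sCut, proximalAnchor = seg$proximalAnchor,
    distalAnchor = cutPoint, hull = hullProx, section = NULL),
    class = "segment")
  segDist <- structure(list(
    name = nDist, mass = m2, comLocal = hd$centroid, inertiaZz = I2,
    length = L - sCut, proximalAnchor = cutPoint,
    distalAnchor = seg$distalAnchor, hull = hullDist,
    section = seg$section), class = "segment")

  weld <- weldJoint(nProx, nDist, anchorParent = cutPoint,
                    anchorChild = cutPoint)
  weld$monitor <- list(segment = segmentName, section = seg$section,
                       axisLocal = u, cutLocal = cutPoint)

  segs <- model$segments
  idx <- match(segmentName, names(segs))
  segs <- append(segs[-idx], list(segProx, segDist), after = idx - 1)
  names(segs) <- vapply(segs, function(s) s$name, "")

  joints <- lapply(model$joints, function(j) {
    if (j$parent == segmentName)
      j$parent <- if (along(j$anchorParent) > sCut) nDist else nProx
    if (j$child == segmentName) j$child <- nProx
    j
  })
  joints <- c(joints, list(weld))

  muscles <- lapply(model$muscles, function(mu) {
    on <- mu$path$segment == segmentName
    if (any(on)) {
      s <- vapply(which(on), function(i)
        along(c(mu$path$x[i], mu$path$y[i])), 0)
      mu$path$segment[on] <- ifelse(s > sCut, nDist, nProx)
    }
    mu
  })

  contacts <- lapply(model$contacts, function(ct) {
    if (ct$segment == segmentName)
      ct$segment <- if (along(ct$centerLocal) > sCut) nDist else nProx
    ct
  })

  model$segments <- segs
  model$joints <- joints
  model$muscles <- muscles
  model$contacts <- contacts
  pose <- attr(model, "initialPose")
  if (!is.null(pose) && segmentName %in% names(pose$angles)) {
    names(pose$angles)[names(pose$angles) == segmentName] <- nProx
    attr(model, "initialPose") <- pose
  }
  model
}

#' Split every sectioned segment for mid-shaft stress monitoring
#'
#' @param model a [bipedModel()].
#' @param segments segment names to split; defaults to every segment
#'   carrying a cross-section.
#' @param cutFraction cut position, default 0.5.
#' @return model with weld-joint load monitors attached.
#' @export
attachStressMonitors <- function(model, segments = NULL,
                                 cutFraction = 0.5) {
  if (is.null(segments))
    segments <- names(Filter(function(s) !is.null(s$section),
                             model$segments))
  for (s in segments) model <- splitSegmentForLoad(model, s, cutFraction)
  model
}

#' Weld-joint load monitors present in a model
#' @keywords internal
monitoredCuts <- function(model) {
  Filter(function(j) j$type == "weld" && !is.null(j$monitor), model$joints)
}

# ---- model compilation ----------------------------------------------------

#' Lower a model to the flat arrays consumed by the compiled engine
#' @keywords internal
compileModel <- function(model, config, pose = NULL) {
  viol <- validateModel(model)
  if (length(viol))
    stop("model is invalid: ", paste(viol, collapse = "; "))
  if (is.null(pose)) pose <- attr(model, "initialPose")
  if (is.null(pose)) pose <- referencePose(model)

  root <- rootSegment(model)
  jointsByChild <- stats::setNames(
    model$joints, vapply(model$joints, function(j) j$child, ""))
  # topological order from root
  order <- root
  repeat {
    nxt <- vapply(model$joints, function(j)
      j$parent %in% order && !(j$child %in% order), TRUE)
    if (!any(nxt)) break
    order <- c(order, vapply(model$joints[nxt], function(j) j$child, ""))
  }
  nb <- length(order)
  idx <- stats::setNames(seq_len(nb) - 1L, order)   # 0-based

  fixedRoot <- isTRUE(attr(model, "fixedRoot"))
  parent <- integer(nb); jtype <- integer(nb); dof <- integer(nb)
  ap <- matrix(0, 2, nb); ac <- matrix(0, 2, nb); refAng <- numeric(nb)
  mass <- numeric(nb); inert <- numeric(nb); comL <- matrix(0, 2, nb)
  nq <- if (fixedRoot) 0L else 3L
  q0 <- numeric(64); qd0 <- numeric(64)
  limDof <- integer(0); limMin <- numeric(0); limMax <- numeric(0)

  for (i in seq_len(nb)) {
    s <- model$segments[[order[i]]]
    mass[i] <- s$mass; inert[i] <- s$inertiaZz; comL[, i] <- s$comLocal
    if (order[i] == root) {
      parent[i] <- -1L
      dof[i] <- -1L
      if (fixedRoot) {
        jtype[i] <- 3L
        ap[, i] <- pose$root[1:2]
        refAng[i] <- pose$root[3]
      } else {
        jtype[i] <- 0L
      }
    } else {
      j <- jointsByChild[[order[i]]]
      parent[i] <- idx[[j$parent]]
      refAng[i] <- j$refAngle
      ap[, i] <- j$anchorParent; ac[, i] <- j$anchorChild
      if (j$type == "hinge") {
        jtype[i] <- 1L
        dof[i] <- nq
        limDof <- c(limDof, nq)
        limMin <- c(limMin, j$rangeMin); limMax <- c(limMax, j$rangeMax)
        a0 <- if (j$child %in% names(pose$angles))
          pose$angles[[j$child]] else 0
        q0[nq + 1] <- if (is.na(a0)) 0 else a0
        nq <- nq + 1L
      } else {
        jtype[i] <- 2L; dof[i] <- -1L
      }
    }
  }
  if (nq == 0L) stop("a fixed-root model needs at least one hinge joint")
  q0 <- q0[seq_len(nq)]
  if (!fixedRoot) q0[1:3] <- pose$root
  qd0 <- numeric(nq)
  if (!fixedRoot && !is.null(pose$rootVelocity))
    qd0[1:3] <- pose$rootVelocity
  if (!is.null(pose$angularVelocities)) {
    for (nm in names(pose$angularVelocities)) {
      b <- idx[[nm]] + 1L
      if (dof[b] >= 0) qd0[dof[b] + 1L] <- pose$angularVelocities[[nm]]
    }
  }

  # joint limit spring scale: a weight * leg-length scale torque per radian
  wScale <- sum(mass) * 9.81 * max(vapply(model$segments,
                                          function(s) s$length, 0))
  limK <- rep(2 * wScale, length(limDof))
  limC <- rep(0.05 * wScale, length(limDof))
  jdamp <- rep(attr(model, "jointDamping") %||% (0.002 * wScale),
               length(limDof))

  bodyL <- list(parent = parent, jtype = jtype, dof = dof,
                anchorParent = ap, anchorChild = ac, refAngle = refAng,
                mass = mass, inertia = inert, comLocal = comL,
                nq = nq, q0 = q0, qd0 = qd0,
                limDof = limDof, limMin = limMin, limMax = limMax,
                limK = limK, limC = limC, jointDamping = jdamp)

  nm_ <- length(model$muscles)
  if (nm_ > 0) {
    npts <- vapply(model$muscles, function(m) nrow(m$path), 0L)
    mbody <- integer(0); mpts <- NULL
    for (m in model$muscles) {
      mbody <- c(mbody, idx[m$path$segment])
      mpts <- cbind(mpts, rbind(m$path$x, m$path$y))
    }
    lopt <- vapply(model$muscles, function(m) m$fibreLength, 0)
    musL <- list(nm = nm_, npts = unname(npts), body = mbody, pts = mpts,
                 fmax = unname(vapply(model$muscles, function(m) m$fmax, 0)),
                 lopt = unname(lopt),
                 lslack = unname(vapply(model$muscles,
                                        function(m) m$tendonSlackLength, 0)),
                 tauAct = rep(0.05, nm_), act0 = rep(0, nm_),
                 vmax = unname(10 * lopt), damping = 0.01)
  } else {
    musL <- list(nm = 0L)
  }

  ncon <- length(model$contacts)
  if (ncon > 0) {
    conL <- list(ncon = ncon,
                 body = vapply(model$contacts, function(ct) idx[[ct$segment]], 0L),
                 pos = vapply(model$contacts, function(ct) ct$centerLocal,
                              numeric(2)),
                 radius = vapply(model$contacts, function(ct) ct$radius, 0),
                 k = vapply(model$contacts, function(ct) ct$stiffness, 0),
                 c = vapply(model$contacts, function(ct) ct$damping, 0),
                 mu = vapply(model$contacts, function(ct) ct$frictionMu, 0))
  } else {
    conL <- list(ncon = 0L)
  }

  # monitored bones at weld cuts
  cuts <- monitoredCuts(model)
  boneEntries <- list()
  children <- vapply(model$joints, function(j) j$child, "")
  descendants <- function(seg) {
    out <- seg
    repeat {
      more <- children[vapply(model$joints, function(j)
        j$parent %in% out && !(j$child %in% out), TRUE)]
      if (!length(more)) break
      out <- c(out, more)
    }
    out
  }
  for (j in cuts) {
    if (is.null(j$monitor$section)) next
    secs <- j$monitor$section
    if (inherits(secs, "crossSectionSpec")) secs <- list(bone = secs)
    props <- lapply(secs, hollowSectionFromOutline)
    wA <- vapply(props, function(p) p$A, 0); wA <- wA / sum(wA)
    wI <- vapply(props, function(p) p$Ix, 0); wI <- wI / sum(wI)
    sub <- idx[descendants(j$child)]
    for (k in seq_along(props)) {
      p <- props[[k]]
      D <- p$Ix * p$Iy - p$Ixy^2
      g <- (p$Iy * p$outerBoundary[, 2] - p$Ixy * p$outerBoundary[, 1]) / D
      boneEntries[[length(boneEntries) + 1]] <- list(
        name = if (length(props) > 1)
          paste(j$monitor$segment, names(props)[k]) else j$monitor$segment,
        cutBody = idx[[j$child]],
        cutLocal = j$anchorChild,
        axisLocal = j$monitor$axisLocal,
        A = p$A / wA[k],
        gmax = max(g) * wI[k], gmin = min(g) * wI[k],
        subtree = unname(sub))
    }
  }
  nbone <- length(boneEntries)
  if (nbone > 0) {
    co <- butterworthCoefficients(1 / config$timestep, config$filterCutoff,
                                  config$filterOrder)
    boneL <- list(
      nbone = nbone,
      cutBody = vapply(boneEntries, function(b) b$cutBody, 0L),
      cutLocal = vapply(boneEntries, function(b) b$cutLocal, numeric(2)),
      axisLocal = vapply(boneEntries, function(b) b$axisLocal, numeric(2)),
      A = vapply(boneEntries, function(b) b$A, 0),
      gmax = vapply(boneEntries, function(b) b$gmax, 0),
      gmin = vapply(boneEntries, function(b) b$gmin, 0),
      subtree = lapply(boneEntries, function(b) as.integer(b$subtree)),
      filter = c(co$b[1:3], co$a[2:3]),
      names = vapply(boneEntries, function(b) b$name, ""))
  } else {
    boneL <- list(nbone = 0L)
  }

  # hip marker: parent-side anchor of the first hinge off the root chain
  hipBody <- 0L; hipLocal <- c(0, 0)
  for (j in model$joints) {
    if (j$type == "hinge" &&
        j$parent %in% c(root, paste0(sub("_prox$|_dist$", "", root)))) {
      hipBody <- idx[[j$parent]]; hipLocal <- j$anchorParent
      break
    }
  }

  list(body = bodyL, muscles = musL, contacts = conL, bones = boneL,
       idx = idx, order = order, hipBody = hipBody, hipLocal = hipLocal,
       muscleNames = names(model$muscles),
       boneNames = if (nbone > 0) boneL$names else character(0),
       totalMass = sum(mass),
       contactSegments = vapply(model$contacts,
                                function(ct) ct$segment, ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a forward-dynamics simulation
#'
#' Integrates the model under gravity, contact, muscle and joint-limit
#' forces until the configured duration, a fall (hip below the configured
#' fraction of its starting height), or a filtered peak-bone-stress
#' exceedance of `config$stressLimit`. Deterministic: identical inputs give
#' bit-identical trajectories.
#'
#' @param model a validated [bipedModel()] (split segments monitor bone
#'   load, see [attachStressMonitors()]).
#' @param controller a [cyclicController()] or `NULL` for zero activation.
#' @param config a [simConfig()].
#' @param pose initial pose; defaults to the model's stored initial pose or
#'   the reference pose.
#' @return object of class `trajectory`.
#' @export
runSimulation <- function(model, controller = NULL, config = simConfig(),
                          pose = NULL) {
  comp <- compileModel(model, config, pose)
  nm_ <- comp$muscles$nm
  if (nm_ > 0) {
    if (is.null(controller)) {
      ctrlL <- list(levels = matrix(0, nm_, 1), cycleDuration = 1)
    } else {
      U <- controllerLevels(controller, comp$muscleNames)
      ctrlL <- list(levels = U, cycleDuration = controller$cycleDuration)
    }
  } else {
    ctrlL <- list(levels = matrix(0, 1, 1), cycleDuration = 1)
  }

  # initial hip height for the fall criterion
  fk0 <- forwardKinematics(model, pose %||% attr(model, "initialPose") %||%
                             referencePose(model))
  hipSeg <- comp$order[comp$hipBody + 1L]
  hipY0 <- worldPoint(fk0, hipSeg, comp$hipLocal)[2]
  fallY <- if (is.na(config$fallHeightFraction)) NA_real_ else
    config$fallHeightFraction * hipY0

  cfgL <- list(dt = config$timestep, duration = config$duration,
               recordEvery = max(1L, as.integer(round(
                 config$recordInterval / config$timestep))),
               stressLimit = config$stressLimit,
               gravity = model$gravity,
               frictionVreg = config$frictionVreg,
               fallHeight = fallY,
               maxComSpeed = config$maxComSpeed %||%
                 (15 * sqrt(9.81 * max(hipY0, 0.5))),
               hipBody = comp$hipBody, hipLocal = comp$hipLocal)

  raw <- .engineSimulate(comp$body, comp$muscles, comp$contacts,
                         comp$bones, ctrlL, cfgL)

  nbone <- comp$bones$nbone
  if (nbone > 0) {
    colnames(raw$stressRaw) <- comp$boneNames
    colnames(raw$stressFiltered) <- comp$boneNames
    colnames(raw$boneAxial) <- comp$boneNames
    colnames(raw$boneShear) <- comp$boneNames
    colnames(raw$boneMoment) <- comp$boneNames
  }
  term <- list(
    cause = c("completed", "fell", "stress_fail",
              "diverged")[raw$termCode + 1L],
    time = raw$termTime,
    bone = if (raw$termCode == 2L) comp$boneNames[raw$termBone] else NA)

  structure(c(raw[setdiff(names(raw), c("termCode", "termTime", "termBone"))],
              list(termination = term,
                   muscleNames = comp$muscleNames,
                   boneNames = comp$boneNames,
                   bodyOrder = comp$order,
                   totalMass = comp$totalMass,
                   contactSegments = comp$contactSegments,
                   stressLimit = config$stressLimit,
                   config = config)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d samples over %.3f s; termination: %s at t = %.3f s\n",
    length(x$time), max(x$time), x$termination$cause, x$termination$time))
  cat(sprintf("  COM travel: %.3f m; %d muscles, %d monitored bones\n",
              x$com[nrow(x$com), 1] - x$com[1, 1],
              length(x$muscleNames), length(x$boneNames)))
  invisible(x)
}

#' Internal load transmitted at a mid-shaft cut in a static pose
#'
#' Resolves the force and moment carried across a weld-joint cut with all
#' accelerations zero: the load balances gravity and any supplied external
#' forces acting on the distal subtree. Axial force is positive in tension;
#' shear is the in-plane transverse component; the bending moment is the
#' out-of-plane component at the cut.
#'
#' @param model a model containing the weld (see [splitSegmentForLoad()]).
#' @param cut name of the split segment (or of the weld's distal half).
#' @param pose evaluation pose.
#' @param externalForces optional list of `list(segment =, point =, force =)`
#'   world-frame forces applied at local points of segments.
#' @return list with `axial` (N, tension positive), `shear` (N),
#'   `moment` (N m), and the world-frame `force` vector.
#' @export
measureInternalLoad <- function(model, cut, pose = referencePose(model),
                                externalForces = list()) {
  cuts <- monitoredCuts(model)
  j <- Find(function(j) j$monitor$segment == cut || j$child == cut, cuts)
  if (is.null(j))
    stop(sprintf("'%s' is not a monitored fixed-joint cut", cut))
  fk <- forwardKinematics(model, pose)
  children <- vapply(model$joints, function(jj) jj$child, "")
  sub <- j$child
  repeat {
    more <- children[vapply(model$joints, function(jj)
      jj$parent %in% sub && !(jj$child %in% sub), TRUE)]
    if (!length(more)) break
    sub <- c(sub, more)
  }
  g <- model$gravity
  pcut <- worldPoint(fk, j$child, j$anchorChild)
  Fc <- c(0, 0); Mc <- 0
  for (s in sub) {
    seg <- model$segments[[s]]
    cworld <- worldPoint(fk, s, seg$comLocal)
    Fg <- -seg$mass * g                      # m (a - g) with a = 0
    Fc <- Fc + Fg
    Mc <- Mc + (cworld[1] - pcut[1]) * Fg[2] - (cworld[2] - pcut[2]) * Fg[1]
  }
  for (ef in externalForces) {
    if (!(ef$segment %in% sub)) next
    pw <- worldPoint(fk, ef$segment, ef$point)
    Fc <- Fc - ef$force
    Mc <- Mc - ((pw[1] - pcut[1]) * ef$force[2] -
                  (pw[2] - pcut[2]) * ef$force[1])
  }
  phi <- fk[[j$child]]$angle
  axis <- as.numeric(rot2(phi) %*% j$monitor$axisLocal)
  list(axial = -sum(Fc * axis),
       shear = -(axis[1] * Fc[2] - axis[2] * Fc[1]),
       moment = Mc,
       force = Fc)
}
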