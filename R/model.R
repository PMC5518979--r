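#' Rigid body segment
#'
#' Coordinate convention throughout: x forward, y up, angles
#' counterclockwise-positive, SI units. Segment frames sit at the proximal
#' joint; the segment long axis runs from `proximalAnchor` to `distalAnchor`
#' in the local frame.
#'
#' @param name identifier.
#' @param hull closed 2D polygon (two-column matrix, local frame, m) used
#'   for inertia and for mid-shaft splitting.
#' @param mass kg (> 0).
#' @param length functional segment length (m).
#' @param proximalAnchor,distalAnchor 2D positions in the local frame (m).
#' @param comLocal optional COM override; default is the hull centroid.
#' @param inertiaZz optional planar inertia override (kg m^2 about COM);
#'   default from the hull scaled to `mass`.
#' @param section optional [crossSectionSpec()] for the bone cross-section
#'   at the functional mid-point.
#' @return object of class `segment`.
#' @export
segment <- function(name, hull, mass, length,
                    proximalAnchor = c(0, 0), distalAnchor = c(0, -length),
                    comLocal = NULL, inertiaZz = NULL, section = NULL) {
  hull <- as.matrix(hull)
  pin <- computePlanarInertia(hull, mass)
  if (is.null(comLocal)) comLocal <- pin$com
  if (is.null(inertiaZz)) inertiaZz <- pin$inertiaZz
  structure(list(name = name, mass = mass, comLocal = comLocal,
                 inertiaZz = inertiaZz, length = length,
                 proximalAnchor = proximalAnchor,
                 distalAnchor = distalAnchor,
                 hull = hull, section = section),
            class = "segment")
}

#' Hinge joint (pure flexion-extension)
#'
#' @param parent,child segment names.
#' @param anchorParent,anchorChild joint centre in the respective local
#'   frames (m).
#' @param rangeMin,rangeMax permitted joint angle range (rad),
#'   `rangeMin < rangeMax`; angle zero is the reference pose.
#' @param refAngle orientation of the child frame relative to the parent
#'   frame at joint angle zero (rad).
#' @return object of class `hingeJoint`.
#' @export
hingeJoint <- function(parent, child, anchorParent, anchorChild,
                       rangeMin = -pi, rangeMax = pi, refAngle = 0) {
  if (!(rangeMin < rangeMax)) stop("rangeMin must be below rangeMax")
  if (identical(parent, child)) stop("a joint cannot connect a segment to itself")
  structure(list(parent = parent, child = child,
                 anchorParent = anchorParent, anchorChild = anchorChild,
                 rangeMin = rangeMin, rangeMax = rangeMax,
                 refAngle = refAngle, type = "hinge"),
            class = "hingeJoint")
}

#' Fixed (weld) joint used for mid-shaft load recovery
#' @inheritParams hingeJoint
#' @return object of class `hingeJoint` with `type = "weld"`.
#' @export
weldJoint <- function(parent, child, anchorParent, anchorChild,
                      refAngle = 0) {
  structure(list(parent = parent, child = child,
                 anchorParent = anchorParent, anchorChild = anchorChild,
                 rangeMin = 0, rangeMax = 0, refAngle = refAngle,
                 type = "weld"),
            class = "hingeJoint")
}

#' Ground contact sphere
#'
#' Acts as a stiff damped spring under compression only; the foot lifts off
#' with no resistance.
#'
#' @param segment segment name.
#' @param centerLocal sphere centre in the segment frame (m).
#' @param radius m (> 0).
#' @param stiffness N/m (> 0).
#' @param damping N s/m (>= 0).
#' @param frictionMu Coulomb friction coefficient (>= 0).
#' @return object of class `contactSphere`.
#' @export
contactSphere <- function(segment, centerLocal, radius, stiffness,
                          damping = 0, frictionMu = 1) {
  if (radius <= 0) stop("radius must be positive")
  if (stiffness <= 0) stop("stiffness must be positive")
  if (damping < 0 || frictionMu < 0)
    stop("damping and friction must be non-negative")
  structure(list(segment = segment, centerLocal = centerLocal,
                 radius = radius, stiffness = stiffness, damping = damping,
                 frictionMu = frictionMu),
            class = "contactSphere")
}

#' Muscle-tendon unit
#'
#' A polyline path of way-points fixed in segment frames; contractile
#' fibres in series with an elastic tendon.
#'
#' @param name identifier.
#' @param path data.frame/list with `segment` (names) and `x`, `y` local
#'   coordinates, at least two points spanning at least two segments.
#' @param fmax maximum isometric force (N); if `NULL`, derived from `mass`
#'   via specific tension and density (see [muscleFmaxFromMass()]).
#' @param fibreLength optimal fibre length (m).
#' @param tendonSlackLength tendon slack length (m).
#' @param mass muscle mass (kg).
#' @param group optional label such as "proximal extensor".
#' @return object of class `muscleTendonUnit`.
#' @export
muscleTendonUnit <- function(name, path, fmax = NULL, fibreLength,
                             tendonSlackLength, mass = NA_real_,
                             group = NA_character_) {
  path <- as.data.frame(path)
  if (nrow(path) < 2) stop("muscle path needs at least two way-points")
  if (length(unique(path$segment)) < 2)
    stop("muscle path must span at least two segments")
  if (is.null(fmax)) {
    if (!is.finite(mass)) stop("either fmax or mass must be given")
    fmax <- muscleFmaxFromMass(mass, fibreLength)
  }
  if (fmax <= 0) stop("fmax must be positive")
  if (fibreLength < 0 || tendonSlackLength < 0)
    stop("lengths must be non-negative")
  structure(list(name = name, path = path, fmax = fmax,
                 fibreLength = fibreLength,
                 tendonSlackLength = tendonSlackLength,
                 mass = mass, group = group),
            class = "muscleTendonUnit")
}

#' Articulated planar biped model
#'
#' @param segments list of [segment()]s; exactly one (the trunk) must be
#'   the root, i.e. appear as a child of no joint.
#' @param joints list of [hingeJoint()]s forming a tree rooted at the trunk.
#' @param muscles list of [muscleTendonUnit()]s.
#' @param contacts list of [contactSphere()]s.
#' @param gravity acceleration vector, default `c(0, -9.81)` m/s^2.
#' @param name model name.
#' @return object of class `bipedModel`.
#' @export
bipedModel <- function(segments, joints, muscles = list(),
                       contacts = list(), gravity = c(0, -9.81),
                       name = "model") {
  names(segments) <- vapply(segments, function(s) s$name, "")
  names(muscles) <- vapply(muscles, function(m) m$name, character(1))
  m <- structure(list(name = name, segments = segments, joints = joints,
                      muscles = muscles, contacts = contacts,
                      gravity = gravity),
                 class = "bipedModel")
  m
}

#' @export
print.bipedModel <- function(x, ...) {
  cat(sprintf("Planar biped model '%s': %d segments, %d joints, %d muscles, %d contact spheres\n",
              x$name, length(x$segments), length(x$joints),
              length(x$muscles), length(x$contacts)))
  v <- validateModel(x)
  if (length(v)) cat("  INVALID:", paste(v, collapse = "; "), "\n")
  invisible(x)
}

#' Root (trunk) segment name of a model
#' @param model a [bipedModel()].
#' @return character name of the root segment.
#' @export
rootSegment <- function(model) {
  children <- vapply(model$joints, function(j) j$child, "")
  segs <- names(model$segments)
  roots <- setdiff(segs, children)
  if (length(roots) != 1) stop("model must have exactly one root segment")
  roots
}

#' Power-law mass from convex-hull volume
#'
#' mass = a * volume^b, the regression form used to predict segment mass
#' from minimum convex hull volume.
#'
#' @param hullVolume m^3 (>= 0).
#' @param a,b power-law coefficients (`a` > 0).
#' @return mass (kg).
#' @export
estimateMassFromHull <- function(hullVolume, a, b) {
  if (any(hullVolume < 0)) stop("hull volume cannot be negative")
  if (a <= 0) stop("regression coefficient a must be positive")
  a * hullVolume^b
}

#' Planar inertia and centroid of a uniform-density polygon, scaled to mass
#'
#' The polygon's second polar moment about its centroid is computed exactly
#' and scaled so the polygon carries the requested mass.
#'
#' @param hull two-column vertex matrix (m).
#' @param mass kg (> 0).
#' @return list with `inertiaZz` (kg m^2 about the centroid) and `com`.
#' @export
computePlanarInertia <- function(hull, mass) {
  if (mass <= 0) stop("mass must be positive")
  p <- polygonSectionProperties(hull)
  # polar second moment per unit area, times areal density mass/A
  list(inertiaZz = mass * (p$Ix + p$Iy) / p$A, com = p$centroid)
}

#' Allocate limb segment masses as fractions of total body mass
#'
#' Fractions are per named segment; whatever is not allocated goes to the
#' trunk. The shipped defaults (see [limbMassFractionDefaults()]) are
#' documented stand-ins in the style of running-bird limb data and are fully
#' overridable.
#'
#' @param totalMass kg.
#' @param fractions named numeric vector of per-segment fractions (>= 0,
#'   summing to at most 1).
#' @param trunkName name for the remainder entry, default "trunk".
#' @return named numeric vector of masses including the trunk; sums to
#'   `totalMass`.
#' @export
assignLimbMassFractions <- function(totalMass, fractions,
                                    trunkName = "trunk") {
  if (any(fractions < 0)) stop("mass fractions cannot be negative")
  if (sum(fractions) > 1 + 1e-12)
    stop("limb mass fractions sum above 1")
  masses <- fractions * totalMass
  out <- c(masses, stats::setNames(totalMass - sum(masses), trunkName))
  out
}

#' Default limb mass fractions (per side)
#'
#' Stand-in values in the style of cursorial-bird limb mass data (the
#' calibration sources report these only in supplements); override freely.
#' @return named numeric vector of per-side fractions of total body mass.
#' @export
limbMassFractionDefaults <- function() {
  c(thigh = 0.105, shank = 0.048, metatarsal = 0.016, pes = 0.006)
}

#' Default muscle-mass allocation over action x joint-level groups
#'
#' Fractions of total muscle mass per functional group (both sides pooled),
#' summing to 1. Documented stand-ins; override freely.
#' @return named numeric vector over
#'   {proximal, intermediate, distal} x {extensor, flexor}.
#' @export
muscleMassAllocationDefaults <- function() {
  c("proximal extensor" = 0.34, "proximal flexor" = 0.16,
    "intermediate extensor" = 0.22, "intermediate flexor" = 0.12,
    "distal extensor" = 0.12, "distal flexor" = 0.04)
}

#' Allocate per-muscle masses from a group allocation table
#'
#' Total muscle mass is `muscleFraction * totalMass`; each functional group
#' (muscle action x joint level) receives its table fraction of that, split
#' equally among the muscles assigned to the group.
#'
#' @param totalMass total body mass (kg).
#' @param muscleFraction total muscle mass as a fraction of body mass,
#'   in (0, 1].
#' @param allocation named numeric vector of group fractions summing to 1.
#' @param groups named list mapping group name -> character vector of
#'   muscle names.
#' @return named numeric vector of per-muscle masses (kg).
#' @export
assignMuscleMasses <- function(totalMass, muscleFraction,
                               allocation = muscleMassAllocationDefaults(),
                               groups) {
  if (muscleFraction < 0 || muscleFraction > 1)
    stop("muscleFraction must lie in [0, 1]")
  if (any(allocation < 0)) stop("allocation fractions cannot be negative")
  if (abs(sum(allocation) - 1) > 1e-9)
    stop("allocation fractions must sum to 1")
  out <- numeric(0)
  for (g in names(allocation)) {
    members <- groups[[g]]
    if (allocation[[g]] > 0 && (is.null(members) || length(members) == 0))
      stop(sprintf("group '%s' has a nonzero fraction but no muscles", g))
    if (length(members) == 0) next
    gm <- muscleFraction * totalMass * allocation[[g]] / length(members)
    out <- c(out, stats::setNames(rep(gm, length(members)), members))
  }
  out
}

#' Maximum isometric force from muscle mass
#'
#' fmax = specificTension * mass / (density * fibreLength), i.e. specific
#' tension times physiological cross-sectional area.
#'
#' @param mass muscle mass (kg).
#' @param fibreLength optimal fibre length (m).
#' @param specificTension Pa, default 3e5.
#' @param density kg/m^3, default 1056.
#' @return force (N).
#' @export
muscleFmaxFromMass <- function(mass, fibreLength, specificTension = 3e5,
                               density = 1056) {
  if (fibreLength <= 0) stop("fibreLength must be positive")
  specificTension * mass / (density * fibreLength)
}

# ---- forward kinematics (R side) -----------------------------------------

rot2 <- function(phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  matrix(c(c_, s_, -s_, c_), 2, 2)
}

#' Reference pose of a model
#'
#' All joint angles zero, root at the origin with zero orientation.
#' @param model a [bipedModel()].
#' @param rootPosition,rootAngle root placement overrides.
#' @return named list: `root = c(x, y, phi)` and `angles` named by joint
#'   child segment.
#' @export
referencePose <- function(model, rootPosition = c(0, 0), rootAngle = 0) {
  hinges <- Filter(function(j) j$type == "hinge", model$joints)
  ang <- stats::setNames(rep(0, length(hinges)),
                         vapply(hinges, function(j) j$child, ""))
  list(root = c(rootPosition, rootAngle), angles = ang)
}

#' Forward kinematics: world transform of every segment
#'
#' @param model a [bipedModel()].
#' @param pose a pose as returned by [referencePose()]; hinge angles are
#'   looked up by child-segment name (missing entries are zero).
#' @return named list per segment with `origin` (world position of the
#'   local frame origin) and `angle` (world orientation, rad).
#' @export
forwardKinematics <- function(model, pose = referencePose(model)) {
  root <- rootSegment(model)
  out <- list()
  out[[root]] <- list(origin = pose$root[1:2], angle = pose$root[3])
  jointsByChild <- stats::setNames(model$joints,
                                   vapply(model$joints, function(j) j$child, ""))
  placed <- root
  remaining <- setdiff(names(model$segments), root)
  while (length(remaining)) {
    progressed <- FALSE
    for (s in remaining) {
      j <- jointsByChild[[s]]
      if (is.null(j) || !(j$parent %in% placed)) next
      th <- if (j$type == "hinge" && j$child %in% names(pose$angles)) {
        a <- pose$angles[[j$child]]
        if (is.na(a)) 0 else a
      } else 0
      pp <- out[[j$parent]]
      phi <- pp$angle + j$refAngle + th
      anchorW <- pp$origin + rot2(pp$angle) %*% j$anchorParent
      origin <- as.numeric(anchorW - rot2(phi) %*% j$anchorChild)
      out[[s]] <- list(origin = origin, angle = phi)
      placed <- c(placed, s)
      progressed <- TRUE
    }
    remaining <- setdiff(remaining, placed)
    if (!progressed) stop("joint graph is not a tree reachable from the root")
  }
  out
}

#' World position of a point fixed in a segment frame
#' @keywords internal
worldPoint <- function(fk, segmentName, local) {
  f <- fk[[segmentName]]
  as.numeric(f$origin + rot2(f$angle) %*% local)
}

#' Tune fibre and tendon-slack lengths from the joint-range length sweep
#'
#' Sweeps every joint the muscle crosses over its permitted range on an even
#' grid (64 samples for a single joint; the per-joint resolution is reduced
#' for multi-joint muscles so the full grid stays below ~4096 poses),
#' records the muscle-tendon length extrema, and sets
#' `fibreLength = fibreFraction * (maxL - minL)` and
#' `tendonSlack = L(mid-range) - fibreLength` floored at zero.
#'
#' @param model a [bipedModel()].
#' @param muscle a [muscleTendonUnit()] or muscle name in the model.
#' @param fibreFraction fraction of the length sweep assigned to the
#'   fibres, default 0.5.
#' @param gridPoints samples per joint for single-joint muscles, default 64.
#' @return list with `fibreLength`, `tendonSlackLength`, `deltaL`,
#'   `midLength` (m).
#' @export
tuneFibreTendonLengths <- function(model, muscle, fibreFraction = 0.5,
                                   gridPoints = 64L) {
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  crossed <- musclesCrossedJoints(model, muscle)
  if (length(crossed) == 0)
    stop("muscle crosses no joint; the length sweep is degenerate")
  k <- length(crossed)
  npts <- if (k == 1) gridPoints else max(4L, as.integer(4096^(1 / k)))
  grids <- lapply(crossed, function(j)
    seq(j$rangeMin, j$rangeMax, length.out = npts))
  names(grids) <- vapply(crossed, function(j) j$child, "")
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  pose <- referencePose(model)
  lengths <- apply(combos, 1, function(row) {
    pose$angles[names(grids)] <- as.numeric(row)
    mtuLength(model, muscle, pose)
  })
  dL <- max(lengths) - min(lengths)
  if (dL <= 1e-12)
    stop("muscle-tendon length does not change over the joint ranges")
  pose <- referencePose(model)
  pose$angles[names(grids)] <- vapply(crossed, function(j)
    (j$rangeMin + j$rangeMax) / 2, 0)
  midL <- mtuLength(model, muscle, pose)
  fl <- fibreFraction * dL
  list(fibreLength = fl,
       tendonSlackLength = max(0, midL - fl),
       deltaL = dL, midLength = midL)
}

#' Joints crossed by a muscle path
#' @keywords internal
musclesCrossedJoints <- function(model, muscle) {
  segs <- unique(muscle$path$segment)
  # a joint is crossed when parent and child both carry path points or lie
  # between path segments on the chain; use the tree path between waypoint
  # segments
  parentOf <- stats::setNames(
    vapply(model$joints, function(j) j$parent, ""),
    vapply(model$joints, function(j) j$child, ""))
  chainToRoot <- function(s) {
    out <- s
    while (s %in% names(parentOf)) {
      s <- parentOf[[s]]
      out <- c(out, s)
    }
    out
  }
  crossed <- character(0)
  for (i in seq_len(length(segs) - 1)) {
    a <- chainToRoot(segs[i]); b <- chainToRoot(segs[i + 1])
    common <- intersect(a, b)[1]
    onpath <- c(setdiff(a, a[seq(match(common, a), length(a))]),
                setdiff(b, b[seq(match(common, b), length(b))]))
    crossed <- union(crossed, onpath)
  }
  Filter(Negate(is.null),
         lapply(crossed, function(s) {
           j <- Find(function(j) j$child == s && j$type == "hinge",
                     model$joints)
           j
         }))
}

#' Validate a model against its structural invariants
#'
#' Checks masses, inertias, hull simplicity, anchor placement, joint
#' ranges, tree structure, reference resolution, contact and section
#' parameters. Violations are returned as data, never thrown.
#'
#' @param model a [bipedModel()].
#' @return character vector of violations; empty when the model is valid.
#' @export
validateModel <- function(model) {
  v <- character(0)
  segs <- names(model$segments)
  for (s in model$segments) {
    if (!is.finite(s$mass) || s$mass <= 0)
      v <- c(v, sprintf("segment '%s': mass must be positive", s$name))
    if (!is.finite(s$inertiaZz) || s$inertiaZz < 0)
      v <- c(v, sprintf("segment '%s': inertia must be non-negative", s$name))
    if (!polygonIsSimple(s$hull))
      v <- c(v, sprintf("segment '%s': hull is self-intersecting", s$name))
    bb <- apply(s$hull, 2, range)
    tol <- 1e-9 + 1e-6 * max(abs(bb))
    for (a in list(s$proximalAnchor, s$distalAnchor)) {
      if (a[1] < bb[1, 1] - tol || a[1] > bb[2, 1] + tol ||
          a[2] < bb[1, 2] - tol || a[2] > bb[2, 2] + tol) {
        v <- c(v, sprintf("segment '%s': anchor outside hull bounding box",
                          s$name))
        break
      }
    }
  }
  for (j in model$joints) {
    if (!(j$parent %in% segs))
      v <- c(v, sprintf("joint %s->%s: unknown parent", j$parent, j$child))
    if (!(j$child %in% segs))
      v <- c(v, sprintf("joint %s->%s: unknown child", j$parent, j$child))
    if (j$type == "hinge" && !(j$rangeMin < j$rangeMax))
      v <- c(v, sprintf("joint %s->%s: empty angle range", j$parent, j$child))
  }
  children <- vapply(model$joints, function(j) j$child, "")
  if (anyDuplicated(children))
    v <- c(v, sprintf("segment '%s' is the child of more than one joint",
                      children[duplicated(children)][1]))
  roots <- setdiff(segs, children)
  if (length(roots) != 1) {
    v <- c(v, sprintf("model must have exactly one root segment (found %d)",
                      length(roots)))
  } else {
    # reachability: a cycle leaves segments unreachable from the root
    parentOf <- stats::setNames(
      vapply(model$joints, function(j) j$parent, ""), children)
    for (s in segs) {
      seen <- character(0)
      cur <- s
      ok <- FALSE
      while (TRUE) {
        if (cur == roots) { ok <- TRUE; break }
        if (cur %in% seen || !(cur %in% names(parentOf))) break
        seen <- c(seen, cur)
        cur <- parentOf[[cur]]
      }
      if (!ok) {
        v <- c(v, sprintf(
          "segment '%s' is not connected to the root (joint cycle or orphan)", s))
      }
    }
  }
  for (m in model$muscles) {
    bad <- setdiff(unique(m$path$segment), segs)
    if (length(bad))
      v <- c(v, sprintf("muscle '%s': unknown segment '%s'", m$name, bad[1]))
  }
  for (ct in model$contacts) {
    if (!(ct$segment %in% segs))
      v <- c(v, sprintf("contact on unknown segment '%s'", ct$segment))
  }
  v
}
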