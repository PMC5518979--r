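fmtNum <- function(x) sprintf("%.17g", as.numeric(x))

pointsToText <- function(m) {
  paste(paste(fmtNum(m[, 1]), fmtNum(m[, 2]), sep = ","), collapse = " ")
}
textToPoints <- function(s) {
  pairs <- strsplit(strsplit(trimws(s), "\\s+")[[1]], ",")
  do.call(rbind, lapply(pairs, function(p) as.numeric(p)))
}

#' Write a model to the package's XML dialect
#'
#' Versioned, human-readable XML in SI units. Writing is normalising:
#' write -> read -> write reproduces the file byte for byte.
#'
#' @param model a [bipedModel()].
#' @param path output file.
#' @param provenance named character vector stored verbatim on the
#'   `provenance` element.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path,
                       provenance = attr(model, "provenance") %||%
                         c(source = "bipedsim")) {
  L <- character(0)
  add <- function(...) L[[length(L) + 1]] <<- paste0(...)
  att <- function(...) {
    v <- c(...)
    paste(sprintf('%s="%s"', names(v), v), collapse = " ")
  }
  add('<?xml version="1.0" encoding="UTF-8"?>')
  fixedRoot <- isTRUE(attr(model, "fixedRoot"))
  jd <- attr(model, "jointDamping")
  add('<bipedModel ', att(version = "1.0", name = model$name,
                          gravityX = fmtNum(model$gravity[1]),
                          gravityY = fmtNum(model$gravity[2]),
                          fixedRoot = tolower(fixedRoot)),
      if (!is.null(jd)) paste0(' jointDamping="', fmtNum(jd), '"') else "",
      '>')
  add('  <provenance ', att(provenance), '/>')
  for (s in model$segments) {
    add('  <segment ', att(name = s$name, mass = fmtNum(s$mass),
                           inertiaZz = fmtNum(s$inertiaZz),
                           length = fmtNum(s$length),
                           comX = fmtNum(s$comLocal[1]),
                           comY = fmtNum(s$comLocal[2]),
                           proximalX = fmtNum(s$proximalAnchor[1]),
                           proximalY = fmtNum(s$proximalAnchor[2]),
                           distalX = fmtNum(s$distalAnchor[1]),
                           distalY = fmtNum(s$distalAnchor[2])), '>')
    add('    <hull units="m">', pointsToText(s$hull), '</hull>')
    secs <- s$section
    if (!is.null(secs)) {
      if (inherits(secs, "crossSectionSpec")) secs <- list(bone = secs)
      for (nm in names(secs)) {
        add('    <section ', att(name = nm, corticalFraction =
                                   fmtNum(secs[[nm]]$corticalFraction)), '>')
        add('      <outline units="m">', pointsToText(secs[[nm]]$outline),
            '</outline>')
        add('    </section>')
      }
    }
    add('  </segment>')
  }
  for (j in model$joints) {
    add('  <joint ', att(type = j$type, parent = j$parent, child = j$child,
                         anchorParentX = fmtNum(j$anchorParent[1]),
                         anchorParentY = fmtNum(j$anchorParent[2]),
                         anchorChildX = fmtNum(j$anchorChild[1]),
                         anchorChildY = fmtNum(j$anchorChild[2]),
                         rangeMin = fmtNum(j$rangeMin),
                         rangeMax = fmtNum(j$rangeMax),
                         refAngle = fmtNum(j$refAngle)), '/>')
  }
  for (m in model$muscles) {
    add('  <muscle ', att(name = m$name, fmax = fmtNum(m$fmax),
                          fibreLength = fmtNum(m$fibreLength),
                          tendonSlackLength = fmtNum(m$tendonSlackLength),
                          mass = fmtNum(m$mass), group = m$group), '>')
    for (i in seq_len(nrow(m$path))) {
      add('    <point ', att(segment = m$path$segment[i],
                             x = fmtNum(m$path$x[i]),
                             y = fmtNum(m$path$y[i])), '/>')
    }
    add('  </muscle>')
  }
  for (ct in model$contacts) {
    add('  <contact ', att(segment = ct$segment,
                           x = fmtNum(ct$centerLocal[1]),
                           y = fmtNum(ct$centerLocal[2]),
                           radius = fmtNum(ct$radius),
                           stiffness = fmtNum(ct$stiffness),
                           damping = fmtNum(ct$damping),
                           frictionMu = fmtNum(ct$frictionMu)), '/>')
  }
  pose <- attr(model, "initialPose")
  if (!is.null(pose)) {
    add('  <initialPose ', att(rootX = fmtNum(pose$root[1]),
                               rootY = fmtNum(pose$root[2]),
                               rootAngle = fmtNum(pose$root[3])), '>')
    for (nm in names(pose$angles)) {
      add('    <angle ', att(segment = nm,
                             value = fmtNum(pose$angles[[nm]])), '/>')
    }
    add('  </initialPose>')
  }
  add('</bipedModel>')
  writeLines(L, path)
  invisible(path)
}

num <- function(node, attrName) {
  v <- xml2::xml_attr(node, attrName)
  if (is.na(v)) stop(sprintf("missing attribute '%s' on <%s> (%s)",
                             attrName, xml2::xml_name(node),
                             xml2::xml_path(node)))
  as.numeric(v)
}

#' Read a model from the package's XML dialect
#'
#' Unknown elements are rejected with their name and document location.
#'
#' @param path model file written by [writeModel()].
#' @return a [bipedModel()] with initial pose and provenance attributes.
#' @export
readModel <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "bipedModel")
    stop(sprintf("not a bipedModel file (root element <%s>)",
                 xml2::xml_name(doc)))
  known <- c("provenance", "segment", "joint", "muscle", "contact",
             "initialPose")
  for (ch in xml2::xml_children(doc)) {
    if (!(xml2::xml_name(ch) %in% known))
      stop(sprintf("unknown element <%s> at %s", xml2::xml_name(ch),
                   xml2::xml_path(ch)))
  }
  segs <- lapply(xml2::xml_find_all(doc, "./segment"), function(nd) {
    hull <- textToPoints(xml2::xml_text(xml2::xml_find_first(nd, "./hull")))
    secNodes <- xml2::xml_find_all(nd, "./section")
    secs <- NULL
    if (length(secNodes)) {
      secs <- lapply(secNodes, function(sn)
        crossSectionSpec(
          textToPoints(xml2::xml_text(xml2::xml_find_first(sn, "./outline"))),
          num(sn, "corticalFraction")))
      names(secs) <- xml2::xml_attr(secNodes, "name")
      if (length(secs) == 1 && names(secs) == "bone") secs <- secs[[1]]
    }
    structure(list(name = xml2::xml_attr(nd, "name"),
                   mass = num(nd, "mass"),
                   comLocal = c(num(nd, "comX"), num(nd, "comY")),
                   inertiaZz = num(nd, "inertiaZz"),
                   length = num(nd, "length"),
                   proximalAnchor = c(num(nd, "proximalX"),
                                      num(nd, "proximalY")),
                   distalAnchor = c(num(nd, "distalX"), num(nd, "distalY")),
                   hull = hull, section = secs),
              class = "segment")
  })
  joints <- lapply(xml2::xml_find_all(doc, "./joint"), function(nd) {
    j <- structure(list(parent = xml2::xml_attr(nd, "parent"),
                        child = xml2::xml_attr(nd, "child"),
                        anchorParent = c(num(nd, "anchorParentX"),
                                         num(nd, "anchorParentY")),
                        anchorChild = c(num(nd, "anchorChildX"),
                                        num(nd, "anchorChildY")),
                        rangeMin = num(nd, "rangeMin"),
                        rangeMax = num(nd, "rangeMax"),
                        refAngle = num(nd, "refAngle"),
                        type = xml2::xml_attr(nd, "type")),
                   class = "hingeJoint")
    j
  })
  muscles <- lapply(xml2::xml_find_all(doc, "./muscle"), function(nd) {
    pts <- xml2::xml_find_all(nd, "./point")
    path <- data.frame(segment = xml2::xml_attr(pts, "segment"),
                       x = as.numeric(xml2::xml_attr(pts, "x")),
                       y = as.numeric(xml2::xml_attr(pts, "y")))
    muscleTendonUnit(xml2::xml_attr(nd, "name"), path,
                     fmax = num(nd, "fmax"),
                     fibreLength = num(nd, "fibreLength"),
                     tendonSlackLength = num(nd, "tendonSlackLength"),
                     mass = num(nd, "mass"),
                     group = xml2::xml_attr(nd, "group"))
  })
  contacts <- lapply(xml2::xml_find_all(doc, "./contact"), function(nd) {
    contactSphere(xml2::xml_attr(nd, "segment"),
                  c(num(nd, "x"), num(nd, "y")), num(nd, "radius"),
                  num(nd, "stiffness"), num(nd, "damping"),
                  num(nd, "frictionMu"))
  })
  model <- bipedModel(segs, joints, muscles, contacts,
                      gravity = c(num(doc, "gravityX"),
                                  num(doc, "gravityY")),
                      name = xml2::xml_attr(doc, "name"))
  if (identical(xml2::xml_attr(doc, "fixedRoot"), "true"))
    attr(model, "fixedRoot") <- TRUE
  jd <- xml2::xml_attr(doc, "jointDamping")
  if (!is.na(jd)) attr(model, "jointDamping") <- as.numeric(jd)
  poseNode <- xml2::xml_find_first(doc, "./initialPose")
  if (!inherits(poseNode, "xml_missing")) {
    pose <- referencePose(model)
    pose$root <- c(num(poseNode, "rootX"), num(poseNode, "rootY"),
                   num(poseNode, "rootAngle"))
    for (an in xml2::xml_find_all(poseNode, "./angle"))
      pose$angles[[xml2::xml_attr(an, "segment")]] <- num(an, "value")
    attr(model, "initialPose") <- pose
  }
  provNode <- xml2::xml_find_first(doc, "./provenance")
  if (!inherits(provNode, "xml_missing")) {
    pa <- xml2::xml_attrs(provNode)
    attr(model, "provenance") <- pa
  }
  model
}

#' Import a legacy GaitSym-style model file
#'
#' Best-effort planar mapping of the legacy whole-body simulator dialect
#' (root element `GAITSYM`-family with `BODY`, `JOINT`, `MUSCLE` and
#' `GEOM` children): 3D positions are projected onto the sagittal (x, z)
#' plane. Nothing is dropped silently - the returned report counts every
#' element class, including unmapped ones.
#'
#' @param path legacy model XML.
#' @return list with `model` (best-effort [bipedModel()], possibly failing
#'   strict validation) and `report` (`nSegments`, `nJoints`, `nMuscles`,
#'   `nContacts`, `segmentNames`, `muscleNames`, `unmapped`).
#' @export
importPublishedModel <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (!grepl("GAITSYM", toupper(root)))
    stop(sprintf("unrecognised dialect: root element <%s>", root))
  kids <- xml2::xml_children(doc)
  nms <- xml2::xml_name(kids)
  mapped <- c("BODY", "JOINT", "MUSCLE", "GEOM")
  unmapped <- table(nms[!(toupper(nms) %in% mapped)])

  planar <- function(s) {
    v <- as.numeric(strsplit(trimws(s), "\\s+")[[1]])
    if (length(v) >= 3) c(v[1], v[3]) else c(v[1], v[length(v)])
  }
  numAttr <- function(nd, name, default) {
    v <- suppressWarnings(as.numeric(xml2::xml_attr(nd, name)))
    if (length(v) == 0 || is.na(v)) default else v
  }
  strAttr <- function(nd, names) {
    for (n in names) {
      v <- xml2::xml_attr(nd, n)
      if (!is.na(v)) return(v)
    }
    NA_character_
  }
  bodies <- kids[toupper(nms) == "BODY"]
  if (length(bodies) == 0)
    stop("unrecognised dialect: no BODY elements found")
  segs <- lapply(bodies, function(nd) {
    mass <- as.numeric(xml2::xml_attr(nd, "Mass"))
    if (is.na(mass)) mass <- 1
    moi <- xml2::xml_attr(nd, "MOI")
    izz <- if (!is.na(moi)) {
      v <- as.numeric(strsplit(trimws(moi), "\\s+")[[1]])
      if (length(v) >= 5) v[5] else v[1]
    } else NA_real_
    pos <- xml2::xml_attr(nd, "Position")
    side <- (mass / 1000)^(1 / 3) + 0.05
    s <- segment(strAttr(nd, c("Name", "ID")),
                 rectOutline(-side / 2, side / 2, -side / 2, side / 2),
                 mass = mass, length = side,
                 proximalAnchor = c(0, 0), distalAnchor = c(0, -side / 2))
    if (!is.na(izz)) s$inertiaZz <- izz
    if (!is.na(pos)) s$position <- planar(pos)
    s
  })
  jointsNodes <- kids[toupper(nms) == "JOINT"]
  joints <- lapply(jointsNodes, function(nd) {
    hingeJoint(xml2::xml_attr(nd, "Body1"), xml2::xml_attr(nd, "Body2"),
               anchorParent = if (!is.na(xml2::xml_attr(nd, "Body1AnchorPoint")))
                 planar(xml2::xml_attr(nd, "Body1AnchorPoint")) else c(0, 0),
               anchorChild = if (!is.na(xml2::xml_attr(nd, "Body2AnchorPoint")))
                 planar(xml2::xml_attr(nd, "Body2AnchorPoint")) else c(0, 0),
               rangeMin = -pi, rangeMax = pi)
  })
  muscleNodes <- kids[toupper(nms) == "MUSCLE"]
  muscles <- lapply(muscleNodes, function(nd) {
    ob <- xml2::xml_attr(nd, "OriginBody")
    ib <- xml2::xml_attr(nd, "InsertionBody")
    op <- xml2::xml_attr(nd, "Origin")
    ip <- xml2::xml_attr(nd, "Insertion")
    o <- if (!is.na(op)) planar(op) else c(0, 0)
    i <- if (!is.na(ip)) planar(ip) else c(0, 0)
    muscleTendonUnit(strAttr(nd, c("Name", "ID")),
                     data.frame(segment = c(ob, ib),
                                x = c(o[1], i[1]), y = c(o[2], i[2])),
                     fmax = numAttr(nd, "PCA", 1 / 3e5) * 3e5,
                     fibreLength = numAttr(nd, "FibreLength", 0.1),
                     tendonSlackLength = numAttr(nd, "TendonLength", 0.1))
  })
  geomNodes <- kids[toupper(nms) == "GEOM"]
  contacts <- lapply(geomNodes, function(nd) {
    contactSphere(strAttr(nd, c("Body", "BodyID")),
                  if (!is.na(xml2::xml_attr(nd, "Position")))
                    planar(xml2::xml_attr(nd, "Position")) else c(0, 0),
                  radius = numAttr(nd, "Radius", 0.05),
                  stiffness = 1e5, damping = 1e3)
  })
  model <- bipedModel(segs, joints, muscles, contacts,
                      name = paste0("imported:", basename(path)))
  report <- list(nSegments = length(segs), nJoints = length(joints),
                 nMuscles = length(muscles), nContacts = length(contacts),
                 segmentNames = vapply(segs, function(s) s$name, ""),
                 muscleNames = vapply(muscles, function(m) m$name, ""),
                 unmapped = unmapped)
  list(model = model, report = report)
}

#' Write a synthetic legacy-dialect model file
#'
#' Generates a SYNTHETIC stand-in file in the legacy GaitSym-style dialect
#' with the full-model structure (a trunk, left/right thigh, shank,
#' metatarsal and pes, left/right arm, forearm and manus segments - 15
#' bodies - and a configurable hind-limb muscle count per limb). It
#' exercises the importer without any external download; it is not the
#' published reconstruction.
#'
#' @param path output file.
#' @param musclesPerLimb hind-limb muscles per limb (default 29).
#' @return `path`, invisibly.
#' @export
writeSyntheticLegacyModel <- function(path, musclesPerLimb = 29L) {
  L <- character(0)
  add <- function(...) L[[length(L) + 1]] <<- paste0(...)
  add('<?xml version="1.0"?>')
  add('<GAITSYM synthetic="true">')
  add('  <GLOBAL IntegrationStepSize="1e-4" GravityVector="0.0 0.0 -9.81"/>')
  hind <- c("Thigh", "Shank", "Metatarsal", "Pes")
  fore <- c("Arm", "Forearm", "Manus")
  bodies <- c("Trunk",
              paste0("Left", c(hind, fore)), paste0("Right", c(hind, fore)))
  massOf <- c(4700, rep(c(760, 345, 115, 45, 60, 25, 10), 2))
  for (i in seq_along(bodies)) {
    add(sprintf(
      '  <BODY Name="%s" Mass="%g" MOI="%g 0 0 0 %g 0 0 0 %g" Position="%g 0.0 %g"/>',
      bodies[i], massOf[i], massOf[i] * 0.4, massOf[i] * 0.5,
      massOf[i] * 0.4, 0.1 * i, 3.0 - 0.2 * i))
  }
  for (side in c("Left", "Right")) {
    chain <- c("Trunk", paste0(side, hind))
    for (k in seq_len(length(chain) - 1)) {
      add(sprintf(
        '  <JOINT Name="%s" Type="Hinge" Body1="%s" Body2="%s" Body1AnchorPoint="0 0 0" Body2AnchorPoint="0 0 0"/>',
        paste0(side, c("Hip", "Knee", "Ankle", "MTP")[k]),
        chain[k], chain[k + 1]))
    }
    add(sprintf(
      '  <JOINT Name="%s" Type="Hinge" Body1="Trunk" Body2="%sArm" Body1AnchorPoint="0 0 0" Body2AnchorPoint="0 0 0"/>',
      paste0(side, "Shoulder"), side))
    add(sprintf(
      '  <JOINT Name="%s" Type="Hinge" Body1="%sArm" Body2="%sForearm" Body1AnchorPoint="0 0 0" Body2AnchorPoint="0 0 0"/>',
      paste0(side, "Elbow"), side, side))
    add(sprintf(
      '  <JOINT Name="%s" Type="Hinge" Body1="%sForearm" Body2="%sManus" Body1AnchorPoint="0 0 0" Body2AnchorPoint="0 0 0"/>',
      paste0(side, "Wrist"), side, side))
    for (j in seq_len(musclesPerLimb)) {
      org <- chain[(j - 1) %% 4 + 1]
      ins <- chain[(j - 1) %% 4 + 2]
      add(sprintf(
        '  <MUSCLE Name="%sHindMuscle%d" Type="MinettiAlexander" OriginBody="%s" Origin="0.1 0 0.2" InsertionBody="%s" Insertion="0.05 0 -0.1" PCA="0.01" FibreLength="0.4" TendonLength="0.6"/>',
        side, j, org, ins))
    }
    add(sprintf(
      '  <GEOM Name="%sToe" Type="Sphere" Body="%sPes" Position="0.2 0 0.05" Radius="0.08"/>',
      side, side))
  }
  add('  <DRIVER Name="Cycler" Type="Cyclic" Target="LeftHindMuscle1" DurationValuePairs="0.2 0.5"/>')
  add('</GAITSYM>')
  writeLines(L, path)
  invisible(path)
}

#' Write a trajectory to tab-separated values
#'
#' Column names carry SI units; run metadata (total mass, termination) is
#' stored in leading `#` comment lines.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  df <- data.frame(time_s = traj$time,
                   com_x_m = traj$com[, 1], com_y_m = traj$com[, 2],
                   comvel_x_m_per_s = traj$comVel[, 1],
                   comvel_y_m_per_s = traj$comVel[, 2],
                   hip_height_m = traj$hipHeight,
                   kinetic_energy_J = traj$kineticEnergy,
                   potential_energy_J = traj$potentialEnergy,
                   check.names = FALSE)
  for (i in seq_along(traj$muscleNames)) {
    df[[paste0("activation_", traj$muscleNames[i])]] <- traj$activation[, i]
    df[[paste0("muscle_force_", traj$muscleNames[i], "_N")]] <-
      traj$muscleForce[, i]
  }
  nc <- length(traj$contactSegments)
  for (i in seq_len(nc)) {
    tag <- paste0(i, "_", traj$contactSegments[i])
    df[[paste0("contact_fx_", tag, "_N")]] <- traj$contactForce[, 2 * i - 1]
    df[[paste0("contact_fy_", tag, "_N")]] <- traj$contactForce[, 2 * i]
    df[[paste0("contact_flag_", tag)]] <- traj$contactFlag[, i]
  }
  for (i in seq_along(traj$boneNames)) {
    nm <- gsub("[^A-Za-z0-9]", "_", traj$boneNames[i])
    df[[paste0("bone_axial_", nm, "_N")]] <- traj$boneAxial[, i]
    df[[paste0("bone_moment_", nm, "_Nm")]] <- traj$boneMoment[, i]
    df[[paste0("stress_raw_", nm, "_Pa")]] <- traj$stressRaw[, i]
    df[[paste0("stress_filtered_", nm, "_Pa")]] <- traj$stressFiltered[, i]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bipedsim trajectory"),
               sprintf("# totalMass_kg\t%s", fmtNum(traj$totalMass)),
               sprintf("# termination\t%s\t%s", traj$termination$cause,
                       fmtNum(traj$termination$time)),
               sprintf("# contactSegments\t%s",
                       paste(traj$contactSegments, collapse = "\t"))),
             con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory TSV back into a minimal trajectory object
#'
#' Restores the fields needed by the gait analytics ([gaitSummary()] and
#' friends); integrator state (q, qd) is not stored in the TSV.
#'
#' @param path file written by [writeTrajectory()].
#' @return a `trajectory`-classed list.
#' @export
readTrajectory <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  getMeta <- function(key) {
    ln <- meta[grepl(paste0("^# ", key), meta)]
    if (!length(ln)) return(NULL)
    strsplit(ln, "\t")[[1]][-1]
  }
  contactSegments <- getMeta("contactSegments") %||% character(0)
  term <- getMeta("termination")
  nc <- length(contactSegments)
  cf <- matrix(0, nrow(df), 2 * max(nc, 1))
  fl <- matrix(0L, nrow(df), max(nc, 1))
  for (i in seq_len(nc)) {
    tag <- paste0(i, "_", contactSegments[i])
    cf[, 2 * i - 1] <- df[[paste0("contact_fx_", tag, "_N")]]
    cf[, 2 * i] <- df[[paste0("contact_fy_", tag, "_N")]]
    fl[, i] <- df[[paste0("contact_flag_", tag)]]
  }
  structure(list(
    time = df$time_s,
    com = cbind(df$com_x_m, df$com_y_m),
    comVel = cbind(df$comvel_x_m_per_s, df$comvel_y_m_per_s),
    hipHeight = df$hip_height_m,
    kineticEnergy = df$kinetic_energy_J,
    potentialEnergy = df$potential_energy_J,
    contactForce = cf, contactFlag = fl,
    contactSegments = contactSegments,
    totalMass = as.numeric(getMeta("totalMass_kg")),
    termination = list(cause = term[1], time = as.numeric(term[2]),
                       bone = NA),
    muscleNames = character(0), boneNames = character(0)),
    class = "trajectory")
}

#' Write a controller to XML
#' @param controller a [cyclicController()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeController <- function(controller, path) {
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         sprintf('<cyclicController cycleDuration="%s" symmetric="%s">',
                 fmtNum(controller$cycleDuration),
                 tolower(isTRUE(controller$symmetric))))
  for (nm in rownames(controller$levels)) {
    L <- c(L, sprintf('  <muscle name="%s" levels="%s"/>', nm,
                      paste(fmtNum(controller$levels[nm, ]),
                            collapse = " ")))
  }
  L <- c(L, '</cyclicController>')
  writeLines(L, path)
  invisible(path)
}

#' Read a controller written by [writeController()]
#' @param path controller XML file.
#' @return a [cyclicController()].
#' @export
readController <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "cyclicController")
    stop("not a cyclicController file")
  ms <- xml2::xml_find_all(doc, "./muscle")
  lv <- do.call(rbind, lapply(ms, function(nd)
    as.numeric(strsplit(trimws(xml2::xml_attr(nd, "levels")), "\\s+")[[1]])))
  rownames(lv) <- xml2::xml_attr(ms, "name")
  cyclicController(num(doc, "cycleDuration"), lv,
                   symmetric = identical(xml2::xml_attr(doc, "symmetric"),
                                         "true"))
}
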