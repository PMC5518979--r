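#' Cyclic muscle-activation controller
#'
#' Piecewise-constant excitation levels over N equal phases of a gait
#' cycle, per muscle. With `symmetric = TRUE` the right-limb pattern is the
#' left-limb pattern delayed by half a cycle (muscles are paired by their
#' `_l` / `_r` name suffixes when the controller is built from a
#' left-side level matrix, see [symmetricController()]).
#'
#' @param cycleDuration gait cycle period (s), > 0.
#' @param levels matrix of excitation levels in [0, 1], one row per muscle
#'   (rownames are muscle names), one column per phase (N >= 2 for a
#'   time-varying pattern; a single column gives constant excitation).
#' @param symmetric logical flag recording left-right symmetry.
#' @return object of class `cyclicController`.
#' @export
cyclicController <- function(cycleDuration, levels, symmetric = FALSE) {
  levels <- as.matrix(levels)
  if (cycleDuration <= 0) stop("cycleDuration must be positive")
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  if (is.null(rownames(levels))) stop("levels must have muscle rownames")
  structure(list(cycleDuration = cycleDuration, levels = levels,
                 symmetric = symmetric),
            class = "cyclicController")
}

#' Build a left-right symmetric controller from left-limb levels
#'
#' Right-limb muscles (`_r` suffix) receive the left pattern (`_l` suffix)
#' circularly shifted by half a cycle. The number of phases must be even so
#' the half-cycle shift is exact.
#'
#' @param cycleDuration cycle period (s).
#' @param leftLevels matrix with rownames ending in `_l`.
#' @return a [cyclicController()].
#' @export
symmetricController <- function(cycleDuration, leftLevels) {
  leftLevels <- as.matrix(leftLevels)
  N <- ncol(leftLevels)
  if (N %% 2 != 0) stop("phase count must be even for a half-cycle shift")
  shift <- c((N / 2 + 1):N, 1:(N / 2))
  right <- leftLevels[, shift, drop = FALSE]
  rownames(right) <- sub("_l$", "_r", rownames(leftLevels))
  cyclicController(cycleDuration, rbind(leftLevels, right),
                   symmetric = TRUE)
}

#' Excitation vector at a time
#'
#' @param controller a [cyclicController()].
#' @param time s (>= 0).
#' @return named vector of per-muscle excitation in [0, 1].
#' @export
activationsAt <- function(controller, time) {
  if (any(time < 0)) stop("time must be non-negative")
  N <- ncol(controller$levels)
  ph <- floor(N * (time %% controller$cycleDuration) /
                controller$cycleDuration) + 1L
  ph <- pmin(ph, N)
  stats::setNames(controller$levels[, ph], rownames(controller$levels))
}

#' Reorder controller levels to an engine muscle ordering
#' @keywords internal
controllerLevels <- function(controller, muscleNames) {
  miss <- setdiff(muscleNames, rownames(controller$levels))
  if (length(miss))
    stop("controller lacks levels for muscle(s): ",
         paste(miss, collapse = ", "))
  controller$levels[muscleNames, , drop = FALSE]
}

#' Evaluate a controller's locomotor fitness
#'
#' Runs the stress-monitored simulation and scores the controller by the
#' horizontal centre-of-mass distance achieved before termination (full
#' duration, fall, or hard stress fail). Early termination is its own
#' penalty; no extra cost is added.
#'
#' @param model a monitored [bipedModel()].
#' @param controller a [cyclicController()].
#' @param config a [simConfig()].
#' @param stressLimit hard peak-stress limit (Pa); overrides the config.
#' @return object of class `fitnessResult`: `distance` (m),
#'   `meanVelocity` (m/s, distance over elapsed time), `terminationCause`,
#'   `peakStress` (named, Pa, filtered), `trajectory`.
#' @export
evaluateFitness <- function(model, controller, config = simConfig(),
                            stressLimit = config$stressLimit) {
  config$stressLimit <- stressLimit
  traj <- runSimulation(model, controller, config)
  distance <- traj$com[nrow(traj$com), 1] - traj$com[1, 1]
  elapsed <- traj$termination$time
  peak <- if (length(traj$boneNames))
    apply(traj$stressFiltered, 2, max) else numeric(0)
  structure(list(distance = distance,
                 meanVelocity = if (elapsed > 0) distance / elapsed else 0,
                 terminationCause = traj$termination$cause,
                 elapsed = elapsed,
                 peakStress = peak,
                 trajectory = traj),
            class = "fitnessResult")
}

#' @export
print.fitnessResult <- function(x, ...) {
  cat(sprintf("Fitness: %.3f m in %.2f s (%.3f m/s), termination: %s\n",
              x$distance, x$elapsed, x$meanVelocity, x$terminationCause))
  invisible(x)
}

#' Optimiser configuration
#'
#' Generational genetic algorithm with tournament selection and elitism.
#'
#' @param populationSize >= 2.
#' @param generations number of generations.
#' @param mutationRate per-gene mutation probability.
#' @param mutationSd Gaussian mutation standard deviation (genes live in
#'   [0, 1] and are clipped).
#' @param crossoverRate probability of uniform crossover per offspring.
#' @param tournamentSize selection tournament size.
#' @param elitism number of best individuals copied unchanged.
#' @param seed RNG seed.
#' @param nPhases activation phases per cycle (genome resolution).
#' @param cycleRange min/max cycle duration (s) spanned by the cycle gene.
#' @param morphScale perturbation scale for warm-start (gait-morphing)
#'   populations.
#' @param symmetric left-right symmetric genomes (halves the search space).
#' @return object of class `optimConfig`.
#' @export
optimConfig <- function(populationSize = 32L, generations = 40L,
                        mutationRate = 0.15, mutationSd = 0.2,
                        crossoverRate = 0.7, tournamentSize = 2L,
                        elitism = 1L, seed = 1L, nPhases = 8L,
                        cycleRange = c(0.3, 1.2), morphScale = 0.1,
                        symmetric = TRUE) {
  if (populationSize < 2) stop("populationSize must be at least 2")
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 mutationRate = mutationRate, mutationSd = mutationSd,
                 crossoverRate = crossoverRate,
                 tournamentSize = as.integer(tournamentSize),
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 nPhases = as.integer(nPhases), cycleRange = cycleRange,
                 morphScale = morphScale, symmetric = symmetric),
            class = "optimConfig")
}

#' Generic GA core over [0, 1]^n genomes (maximising)
#'
#' @param objective function(genome) -> numeric fitness.
#' @param nGenes genome length.
#' @param config an [optimConfig()].
#' @param initial optional matrix (individuals x genes) seeding the
#'   population.
#' @return list with `bestGenome`, `bestFitness`, `log` (data.frame with
#'   generation, best, mean), `evaluations`.
#' @export
gaOptimize <- function(objective, nGenes, config = optimConfig(),
                       initial = NULL) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(config$seed)
  np <- config$populationSize
  pop <- matrix(stats::runif(np * nGenes), np, nGenes)
  if (!is.null(initial)) {
    initial <- as.matrix(initial)
    k <- min(nrow(initial), np)
    pop[seq_len(k), ] <- pmin(pmax(initial[seq_len(k), , drop = FALSE],
                                   0), 1)
  }
  fit <- apply(pop, 1, objective)
  nEval <- np
  bestGenome <- pop[which.max(fit), ]
  bestFitness <- max(fit)
  log <- data.frame(generation = 0L, best = bestFitness, mean = mean(fit))
  for (gen in seq_len(config$generations)) {
    newPop <- matrix(0, np, nGenes)
    ord <- order(fit, decreasing = TRUE)
    ne <- min(config$elitism, np)
    if (ne > 0) newPop[seq_len(ne), ] <- pop[ord[seq_len(ne)], , drop = FALSE]
    for (i in seq(ne + 1, np)) {
      pick <- function() {
        cand <- sample.int(np, config$tournamentSize, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      p1 <- pop[pick(), ]
      if (stats::runif(1) < config$crossoverRate) {
        p2 <- pop[pick(), ]
        mask <- stats::runif(nGenes) < 0.5
        p1[mask] <- p2[mask]
      }
      mut <- stats::runif(nGenes) < config$mutationRate
      p1[mut] <- p1[mut] + stats::rnorm(sum(mut), 0, config$mutationSd)
      newPop[i, ] <- pmin(pmax(p1, 0), 1)
    }
    pop <- newPop
    fit <- apply(pop, 1, objective)
    nEval <- nEval + np
    if (max(fit) > bestFitness) {
      bestFitness <- max(fit)
      bestGenome <- pop[which.max(fit), ]
    }
    log <- rbind(log, data.frame(generation = gen, best = bestFitness,
                                 mean = mean(fit)))
  }
  list(bestGenome = bestGenome, bestFitness = bestFitness, log = log,
       evaluations = nEval)
}

#' Genome length for a model under an optimiser configuration
#' @keywords internal
genomeLength <- function(model, config) {
  nm <- controlledMuscles(model, config)
  length(nm) * config$nPhases + 1L
}

#' Muscles carrying genes (left side only when symmetric)
#' @keywords internal
controlledMuscles <- function(model, config) {
  nms <- names(model$muscles)
  if (config$symmetric) {
    left <- grep("_l$", nms, value = TRUE)
    if (length(left) && all(sub("_l$", "_r", left) %in% nms)) return(left)
  }
  nms
}

#' Decode a genome into a controller
#'
#' Genes are excitation levels in [0, 1] plus a final gene mapped linearly
#' onto the configured cycle-duration range.
#'
#' @param genome numeric vector in [0, 1].
#' @param model the model the genome controls.
#' @param config an [optimConfig()].
#' @return a [cyclicController()].
#' @export
decodeGenome <- function(genome, model, config) {
  ctrl <- controlledMuscles(model, config)
  N <- config$nPhases
  lv <- matrix(genome[seq_len(length(ctrl) * N)], length(ctrl), N,
               byrow = TRUE, dimnames = list(ctrl, NULL))
  cyc <- config$cycleRange[1] +
    genome[length(genome)] * diff(config$cycleRange)
  if (config$symmetric && all(grepl("_l$", ctrl)))
    symmetricController(cyc, lv)
  else cyclicController(cyc, lv)
}

#' Evolve a muscle-activation controller
#'
#' Genetic-algorithm search over cyclic controller parameters maximising
#' the distance travelled in the configured simulation time under the hard
#' peak-stress limit. Reproducible for a fixed seed.
#'
#' @param model a monitored [bipedModel()].
#' @param config an [optimConfig()].
#' @param simConfiguration a [simConfig()].
#' @param stressLimit Pa.
#' @param warmStart optional [cyclicController()] or genome (vector /
#'   population matrix) seeding the search ("gait morphing").
#' @return list with `controller`, `fitness` (a `fitnessResult`),
#'   `bestGenome`, `log`.
#' @export
optimizeController <- function(model, config = optimConfig(),
                               simConfiguration = simConfig(),
                               stressLimit = Inf, warmStart = NULL) {
  ng <- genomeLength(model, config)
  init <- NULL
  if (!is.null(warmStart)) {
    ws <- if (inherits(warmStart, "cyclicController"))
      encodeController(warmStart, model, config) else warmStart
    if (is.null(dim(ws))) {
      init <- morphSeed(ws, config$populationSize, config$morphScale,
                        seed = config$seed)
    } else init <- ws
  }
  objective <- function(genome) {
    ctr <- decodeGenome(genome, model, config)
    fr <- evaluateFitness(model, ctr, simConfiguration, stressLimit)
    fr$distance
  }
  res <- gaOptimize(objective, ng, config, initial = init)
  best <- decodeGenome(res$bestGenome, model, config)
  fit <- evaluateFitness(model, best, simConfiguration, stressLimit)
  list(controller = best, fitness = fit, bestGenome = res$bestGenome,
       log = res$log, evaluations = res$evaluations)
}

#' Encode a controller back into a genome
#' @keywords internal
encodeController <- function(controller, model, config) {
  ctrl <- controlledMuscles(model, config)
  lv <- controller$levels[ctrl, , drop = FALSE]
  if (ncol(lv) != config$nPhases)
    stop("controller phase count does not match the optimiser config")
  cyc <- (controller$cycleDuration - config$cycleRange[1]) /
    diff(config$cycleRange)
  c(as.numeric(t(lv)), min(max(cyc, 0), 1))
}

#' Seed a morphing population from a previous best genome
#'
#' The previous best is kept verbatim; the remainder of the population is
#' the best plus bounded Gaussian perturbations, clipped to [0, 1]. This is
#' the staged re-optimisation ("gait morphing") used when the stress limit
#' changes.
#'
#' @param genome numeric genome in [0, 1].
#' @param populationSize rows to produce.
#' @param scale perturbation standard deviation (0 duplicates the genome).
#' @param seed RNG seed.
#' @return matrix (populationSize x genes) in [0, 1].
#' @export
morphSeed <- function(genome, populationSize, scale = 0.1, seed = 1L) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(seed)
  ng <- length(genome)
  pop <- matrix(rep(genome, each = populationSize), populationSize, ng)
  if (populationSize > 1 && scale > 0) {
    idx <- 2:populationSize
    pop[idx, ] <- pop[idx, ] +
      matrix(stats::rnorm(length(idx) * ng, 0, scale), length(idx), ng)
  }
  pmin(pmax(pop, 0), 1)
}

#' Optimise across a range of stress limits (gait-morphing sweep)
#'
#' Runs the evolutionary search at each stress limit, warm-starting each
#' search from the best controller of the previous (higher) limit, and
#' collects the gait metrics at each limit.
#'
#' @param model a monitored [bipedModel()].
#' @param limits numeric vector of >= 2 stress limits (Pa).
#' @param config an [optimConfig()].
#' @param simConfiguration a [simConfig()].
#' @return object of class `sweepResult`: a data.frame with one row per
#'   limit (`limit`, `bestVelocity`, `froude`, `strideLength`,
#'   `cycleDuration`, `distance`, `terminationCause`) with the winning
#'   controllers attached as an attribute.
#' @export
sweepStressLimits <- function(model, limits, config = optimConfig(),
                              simConfiguration = simConfig()) {
  if (length(limits) < 2) stop("provide at least two stress limits")
  ord <- order(limits, decreasing = TRUE)
  rows <- vector("list", length(limits))
  controllers <- vector("list", length(limits))
  prevGenome <- NULL
  for (k in seq_along(ord)) {
    i <- ord[k]
    res <- optimizeController(model, config, simConfiguration,
                              stressLimit = limits[i],
                              warmStart = prevGenome)
    prevGenome <- res$bestGenome
    controllers[[i]] <- res$controller
    traj <- res$fitness$trajectory
    gm <- tryCatch(gaitSummary(traj), error = function(e) NULL)
    rows[[i]] <- data.frame(
      limit = limits[i],
      bestVelocity = res$fitness$meanVelocity,
      froude = if (!is.null(gm)) gm$froude else NA_real_,
      strideLength = if (!is.null(gm)) gm$strideLength else NA_real_,
      cycleDuration = if (!is.null(gm)) gm$cycleDuration else NA_real_,
      distance = res$fitness$distance,
      terminationCause = res$fitness$terminationCause)
  }
  out <- do.call(rbind, rows)
  attr(out, "controllers") <- controllers
  class(out) <- c("sweepResult", class(out))
  out
}
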