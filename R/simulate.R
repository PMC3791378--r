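#' Run one event-driven simulation replicate
#'
#' Simulates all molecules of all species on the genome until
#' \code{duration} seconds (or until the first cognate arrival at the
#' target site when \code{stopAtFirstPassage = TRUE}).  Free mobile
#' molecules attempt to bind at exponentially distributed times (rate
#' \code{assocRate} each); an attempt draws a uniform candidate position and
#' succeeds only if the footprint interval is completely vacant, otherwise
#' the molecule stays free and redraws its clock.  A bound molecule resides
#' for an exponential time with position-dependent mean given by its energy
#' landscape, then slides one base pair, hops, or unbinds according to its
#' move probabilities.  Blocked slides (steric or at a linear end) leave the
#' molecule in place; hops that would clash sterically (or overshoot a
#' linear end) unbind the molecule.  Steric hindrance never lets two
#' footprints share a base pair.  Immobile species are placed uniformly at
#' random without overlap at time zero — possibly on top of the target
#' site — and never move.
#'
#' @param genome an \linkS4class{FDGenome}.
#' @param species a \linkS4class{TFSpecies} or list of them.
#' @param duration simulated time, seconds (>= 0).
#' @param seed integer seed; a replicate is fully reproducible from it.
#' @param stopAtFirstPassage halt as soon as a cognate molecule reaches the
#'   target site (first-passage experiments).
#' @param burnin time (seconds) excluded from coverage and bound-fraction
#'   averages, so they describe the stationary phase.  Target occupancy is
#'   always measured over the whole duration (it is a fraction of the cell
#'   cycle).
#' @param audit after every event, recompute the occupancy index from
#'   scratch and verify the steric invariant (slow; for testing).
#' @param maxIntervals cap on the number of recorded target-site occupancy
#'   intervals (the total occupied time is always exact).
#' @param trackPositions record the time-at-position profile of the first
#'   molecule (used for stationarity diagnostics).
#' @param maxPlacementTries rejection-sampling budget per immobile molecule
#'   before an over-packed genome is reported as an error.
#' @return an \linkS4class{FDTrajectory}.
#' @examples
#' g <- generateGenome(2000, seed = 1)
#' nc <- TFSpecies("nc", copyNumber = 5, assocRate = 1800)
#' runSimulation(g, nc, duration = 1, seed = 1)
#' @export
runSimulation <- function(genome, species, duration, seed,
                          stopAtFirstPassage = FALSE, burnin = 0,
                          audit = FALSE, maxIntervals = 100000L,
                          trackPositions = FALSE,
                          maxPlacementTries = 10000L) {
    if (is(species, "TFSpecies")) species <- list(species)
    stopifnot(length(species) >= 1L, duration >= 0, burnin >= 0)
    L <- genomeLength(genome)
    circular <- topology(genome) == "circular"
    spNames <- vapply(species, function(s) s@name, "")

    speciesList <- lapply(species, function(sp) {
        validObject(sp)
        nPos <- if (circular) L else L - sp@footprint + 1L
        if (nPos < 1L)
            stop("footprint of species '", sp@name,
                 "' exceeds the genome length")
        if (is.null(sp@landscape)) {
            res <- sp@tau0
        } else {
            res <- meanResidence(sp@landscape)
            if (length(res) != nPos)
                stop(sprintf(
                    paste0("landscape of species '%s' has %d positions but ",
                           "the genome offers %d (footprint %d, %s); build ",
                           "the landscape from the same genome and a motif ",
                           "as wide as the footprint"),
                    sp@name, length(res), nPos, sp@footprint,
                    topology(genome)))
        }
        ip <- sp@initialPositions
        if (length(ip) && any(ip < 1L | ip > nPos))
            stop("initialPositions out of range for species '", sp@name, "'")
        list(footprint = sp@footprint, k_assoc = sp@assocRate,
             move_probs = sp@moveProbs, hop_range = sp@hopRange,
             mobile = sp@mobile, cognate = sp@cognate,
             residence = res, n_pos = nPos,
             copy_number = sp@copyNumber,
             initial_positions = ip - 1L)
    })

    raw <- .cppRunSimulation(
        L, circular, targetStart(genome) - 1L, speciesList,
        as.numeric(duration), as.numeric(seed), stopAtFirstPassage,
        as.numeric(burnin), audit, as.integer(maxIntervals),
        trackPositions, as.integer(maxPlacementTries))

    toNamed <- function(x, nm) { names(x) <- nm; x }
    plus1 <- function(lst) lapply(lst, function(v) v + 1L)
    iv <- raw$intervals
    colnames(iv) <- c("tOn", "tOff")
    new("FDTrajectory",
        duration = as.numeric(duration),
        firstPassage = raw$first_passage,
        censored = raw$censored,
        occupancyFraction = raw$occupancy_fraction,
        meanCoverage = raw$mean_coverage,
        intervals = iv,
        boundFraction = toNamed(raw$bound_fraction, spNames),
        bindCount = toNamed(raw$n_bind, spNames),
        unbindCount = toNamed(raw$n_unbind, spNames),
        immobilePositions = toNamed(plus1(raw$immobile_positions), spNames),
        finalPositions = toNamed(plus1(raw$final_positions), spNames),
        freeCount = toNamed(as.integer(unlist(raw$n_free)), spNames),
        positionTime = if (trackPositions) raw$position_time else numeric(),
        seed = as.numeric(seed),
        timeSimulated = raw$time_simulated)
}

#' Write a trajectory to CSV and JSON
#'
#' The CSV holds one row per target-site occupancy interval; the JSON
#' summary records the headline observables.
#'
#' @param traj an \linkS4class{FDTrajectory}.
#' @param csvPath path for the interval table (\code{NULL} to skip).
#' @param jsonPath path for the JSON summary (\code{NULL} to skip).
#' @return invisibly, the JSON summary as a list.
#' @export
writeTrajectory <- function(traj, csvPath = NULL, jsonPath = NULL) {
    if (!is.null(csvPath)) {
        df <- as.data.frame(traj@intervals)
        utils::write.csv(df, csvPath, row.names = FALSE)
    }
    summary <- list(
        first_passage = if (traj@censored) NULL else traj@firstPassage,
        censored = traj@censored,
        occupancy_fraction = traj@occupancyFraction,
        mean_coverage = traj@meanCoverage)
    if (!is.null(jsonPath))
        jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE,
                             digits = NA, null = "null")
    invisible(summary)
}
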