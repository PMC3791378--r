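#' @import methods
NULL

#' Genome segment with a designated target site
#'
#' An \code{FDGenome} holds the DNA sequence a simulation runs on, the
#' coordinates of the target site (for the lac repressor this is the 21-bp
#' \emph{O1} operator) and the topology of the segment.  Coordinates are
#' 1-based and left-aligned: a binding position \code{i} covers base pairs
#' \code{i} to \code{i + footprint - 1}.
#'
#' @slot seq a \link[Biostrings]{DNAString} restricted to the alphabet
#'   \code{A, C, G, T}.
#' @slot targetStart 1-based position of the left edge of the target site.
#' @slot targetWidth width of the target site in base pairs.
#' @slot topology \code{"circular"} (the default for synthetic segments,
#'   which avoids end artifacts) or \code{"linear"}.
#'
#' @seealso \code{\link{FDGenome}}, \code{\link{generateGenome}},
#'   \code{\link{readGenomeFasta}}
#' @exportClass FDGenome
setClass("FDGenome",
    slots = c(
        seq = "DNAString",
        targetStart = "integer",
        targetWidth = "integer",
        topology = "character"
    )
)

setValidity("FDGenome", function(object) {
    msg <- character()
    L <- length(object@seq)
    freq <- Biostrings::alphabetFrequency(object@seq)
    extra <- sum(freq) - sum(freq[c("A", "C", "G", "T")])
    if (extra > 0)
        msg <- c(msg, "sequence contains characters outside {A,C,G,T}")
    if (length(object@topology) != 1L ||
        !object@topology %in% c("circular", "linear"))
        msg <- c(msg, "topology must be 'circular' or 'linear'")
    if (length(object@targetStart) != 1L || length(object@targetWidth) != 1L)
        msg <- c(msg, "targetStart and targetWidth must be scalars")
    else {
        if (object@targetWidth < 1L)
            msg <- c(msg, "targetWidth must be >= 1")
        if (object@targetStart < 1L ||
            object@targetStart > L - object@targetWidth + 1L)
            msg <- c(msg, sprintf(
                "targetStart must lie in [1, %d]", L - object@targetWidth + 1L))
    }
    if (length(msg)) msg else TRUE
})

#' Per-position binding-energy landscape
#'
#' Stores, for every left-aligned binding position of a species on a genome,
#' the motif score and the mean residence time (seconds) derived from it via
#' \code{meanResidence = tau0 * exp(beta * score)}.  For circular genomes the
#' landscape wraps around the origin and has one entry per base pair; for
#' linear genomes it has \code{L - W + 1} entries.
#'
#' @slot scores numeric vector of position weight matrix scores.
#' @slot meanResidence strictly positive numeric vector of mean waiting
#'   times, seconds, same length as \code{scores}.
#' @slot width motif width (bp) the scores were computed with.
#'
#' @seealso \code{\link{buildLandscape}}
#' @exportClass EnergyLandscape
setClass("EnergyLandscape",
    slots = c(
        scores = "numeric",
        meanResidence = "numeric",
        width = "integer"
    )
)

setValidity("EnergyLandscape", function(object) {
    msg <- character()
    if (length(object@scores) != length(object@meanResidence))
        msg <- c(msg, "scores and meanResidence must have equal length")
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (any(!is.finite(object@meanResidence)) || any(object@meanResidence <= 0))
        msg <- c(msg, "meanResidence must be strictly positive and finite")
    if (length(msg)) msg else TRUE
})

setClassUnion("EnergyLandscapeOrNULL", c("EnergyLandscape", "NULL"))

#' Kinetic and geometric parameters of one molecule species
#'
#' A \code{TFSpecies} bundles everything the simulator needs to know about
#' one type of DNA-binding molecule: how many copies exist, how many base
#' pairs a bound copy occludes, how fast free copies attempt to bind
#' (\code{assocRate}, per free molecule, s^-1), what a copy does when its
#' residence time expires (slide left/right by one base pair, hop, or
#' unbind), and which energy landscape controls its residence times
#' (\code{NULL} means a flat, sequence-nonspecific landscape).
#'
#' Immobile species (\code{mobile = FALSE}) are placed at uniform random
#' non-overlapping positions when a simulation starts and never move;
#' their \code{moveProbs} and \code{assocRate} are ignored.
#'
#' @slot name species label, e.g. \code{"lacI"} or \code{"nc"}.
#' @slot copyNumber number of molecules.
#' @slot footprint occluded base pairs per bound molecule (21 for the lac
#'   repressor, 46 for the generic non-cognate species).
#' @slot assocRate per-free-molecule binding attempt rate, s^-1.
#' @slot moveProbs named numeric of length 4, \code{(left, right, hop,
#'   unbind)}, summing to one.
#' @slot hopRange maximum hop displacement, bp; hops are uniform on
#'   \code{-hopRange..hopRange} excluding zero.
#' @slot mobile logical; \code{FALSE} marks a fixed obstacle species.
#' @slot cognate logical; cognate molecules are the ones whose arrival at
#'   the target site defines first passage and occupancy.
#' @slot landscape an \linkS4class{EnergyLandscape} or \code{NULL} (flat).
#' @slot tau0 baseline mean residence time, seconds, used when
#'   \code{landscape} is \code{NULL}.
#' @slot initialPositions integer vector of 1-based start positions for the
#'   first molecules of the species (a test/experiment hook; remaining
#'   copies start free, or randomly placed if immobile).  Zero length means
#'   no pre-placement.
#'
#' @seealso \code{\link{TFSpecies}}, \code{\link{defaultMoveProbs}},
#'   \code{\link{calibrateAssociationRate}}
#' @exportClass TFSpecies
setClass("TFSpecies",
    slots = c(
        name = "character",
        copyNumber = "integer",
        footprint = "integer",
        assocRate = "numeric",
        moveProbs = "numeric",
        hopRange = "integer",
        mobile = "logical",
        cognate = "logical",
        landscape = "EnergyLandscapeOrNULL",
        tau0 = "numeric",
        initialPositions = "integer"
    )
)

setValidity("TFSpecies", function(object) {
    msg <- character()
    if (object@copyNumber < 0L) msg <- c(msg, "copyNumber must be >= 0")
    if (object@footprint < 1L) msg <- c(msg, "footprint must be >= 1")
    if (length(object@moveProbs) != 4L)
        msg <- c(msg, "moveProbs must have length 4 (left, right, hop, unbind)")
    else if (object@mobile) {
        if (any(object@moveProbs < 0))
            msg <- c(msg, "moveProbs must be non-negative")
        if (abs(sum(object@moveProbs) - 1) > 1e-12)
            msg <- c(msg, "moveProbs must sum to 1 (within 1e-12)")
    }
    if (object@mobile && (!is.finite(object@assocRate) || object@assocRate <= 0))
        msg <- c(msg, "assocRate must be positive for mobile species")
    if (object@hopRange < 1L) msg <- c(msg, "hopRange must be >= 1")
    if (!is.finite(object@tau0) || object@tau0 <= 0)
        msg <- c(msg, "tau0 must be positive")
    if (length(object@initialPositions) > object@copyNumber)
        msg <- c(msg, "more initialPositions than copies")
    if (length(msg)) msg else TRUE
})

#' Result of one simulation replicate
#'
#' An \code{FDTrajectory} records the observables of a single replicate:
#' the first-passage time of a cognate molecule to the target site (or a
#' censoring flag when the site was never reached within the simulated
#' duration), the disjoint ordered intervals during which the site was
#' occupied, the occupancy fraction relative to the duration, the
#' time-averaged DNA coverage, and per-species bound-state statistics.
#'
#' @slot duration simulated duration, seconds.
#' @slot firstPassage seconds, or \code{NA} when censored.
#' @slot censored logical.
#' @slot occupancyFraction fraction of \code{duration} during which a
#'   cognate molecule was bound at the target site.
#' @slot meanCoverage time-averaged fraction of base pairs under any bound
#'   footprint (after the burn-in, if one was requested).
#' @slot intervals two-column matrix of target-site occupancy intervals
#'   \code{(tOn, tOff)}.
#' @slot boundFraction named per-species fraction of (time x molecules)
#'   spent bound.
#' @slot bindCount,unbindCount named per-species transition counts.
#' @slot immobilePositions named list of initial positions of immobile
#'   molecules (1-based).
#' @slot finalPositions named list of bound positions at the end.
#' @slot freeCount named integer, free molecules per species at the end.
#' @slot positionTime optional time-at-position profile for the first
#'   molecule (only when \code{trackPositions = TRUE}).
#' @slot seed integer seed of the replicate.
#' @slot timeSimulated last event time processed (equals \code{duration}
#'   unless the run stopped at first passage).
#'
#' @seealso \code{\link{runSimulation}}
#' @exportClass FDTrajectory
setClass("FDTrajectory",
    slots = c(
        duration = "numeric",
        firstPassage = "numeric",
        censored = "logical",
        occupancyFraction = "numeric",
        meanCoverage = "numeric",
        intervals = "matrix",
        boundFraction = "numeric",
        bindCount = "numeric",
        unbindCount = "numeric",
        immobilePositions = "list",
        finalPositions = "list",
        freeCount = "integer",
        positionTime = "numeric",
        seed = "numeric",
        timeSimulated = "numeric"
    )
)

setValidity("FDTrajectory", function(object) {
    msg <- character()
    iv <- object@intervals
    if (ncol(iv) != 2L) msg <- c(msg, "intervals must have two columns")
    else if (nrow(iv) > 0L) {
        if (any(iv[, 2] < iv[, 1]))
            msg <- c(msg, "intervals must have tOff >= tOn")
        if (nrow(iv) > 1L && any(diff(iv[, 1]) < 0))
            msg <- c(msg, "intervals must be ordered")
        if (any(iv < -1e-9) || any(iv > object@duration + 1e-9))
            msg <- c(msg, "intervals must lie within [0, duration]")
        if (!object@censored &&
            abs(iv[1, 1] - object@firstPassage) > 1e-9)
            msg <- c(msg, "firstPassage must equal the first interval start")
    }
    if (object@occupancyFraction < 0 || object@occupancyFraction > 1)
        msg <- c(msg, "occupancyFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
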