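#' @include AllClasses.R
NULL

#' Accessors for fdSim objects
#'
#' Small accessor generics for the S4 containers: genome geometry
#' (\code{genomeSeq}, \code{genomeLength}, \code{targetStart},
#' \code{targetWidth}, \code{topology}), landscape content (\code{scores},
#' \code{meanResidence}), species parameters (\code{copyNumber},
#' \code{footprint}, \code{assocRate}, \code{moveProbs}, \code{isMobile},
#' \code{isCognate}) and trajectory observables (\code{firstPassage},
#' \code{isCensored}, \code{occupancyFraction}, \code{meanCoverage},
#' \code{boundFraction}, \code{targetIntervals}).
#'
#' @param x an fdSim S4 object.
#' @return the corresponding slot value.
#' @name accessors
#' @rdname accessors
#' @examples
#' g <- generateGenome(1000, seed = 1)
#' genomeLength(g)
#' targetStart(g)
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("targetStart", function(x) standardGeneric("targetStart"))
#' @rdname accessors
#' @export
setGeneric("targetWidth", function(x) standardGeneric("targetWidth"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("meanResidence", function(x) standardGeneric("meanResidence"))
#' @rdname accessors
#' @export
setGeneric("copyNumber", function(x) standardGeneric("copyNumber"))
#' @rdname accessors
#' @export
setGeneric("footprint", function(x) standardGeneric("footprint"))
#' @rdname accessors
#' @export
setGeneric("assocRate", function(x) standardGeneric("assocRate"))
#' @rdname accessors
#' @export
setGeneric("moveProbs", function(x) standardGeneric("moveProbs"))
#' @rdname accessors
#' @export
setGeneric("isMobile", function(x) standardGeneric("isMobile"))
#' @rdname accessors
#' @export
setGeneric("isCognate", function(x) standardGeneric("isCognate"))
#' @rdname accessors
#' @export
setGeneric("firstPassage", function(x) standardGeneric("firstPassage"))
#' @rdname accessors
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))
#' @rdname accessors
#' @export
setGeneric("occupancyFraction", function(x) standardGeneric("occupancyFraction"))
#' @rdname accessors
#' @export
setGeneric("meanCoverage", function(x) standardGeneric("meanCoverage"))
#' @rdname accessors
#' @export
setGeneric("boundFraction", function(x) standardGeneric("boundFraction"))
#' @rdname accessors
#' @export
setGeneric("targetIntervals", function(x) standardGeneric("targetIntervals"))

#' @rdname accessors
#' @export
setMethod("genomeSeq", "FDGenome", function(x) x@seq)
#' @rdname accessors
#' @export
setMethod("genomeLength", "FDGenome", function(x) length(x@seq))
#' @rdname accessors
#' @export
setMethod("targetStart", "FDGenome", function(x) x@targetStart)
#' @rdname accessors
#' @export
setMethod("targetWidth", "FDGenome", function(x) x@targetWidth)
#' @rdname accessors
#' @export
setMethod("topology", "FDGenome", function(x) x@topology)

#' @rdname accessors
#' @export
setMethod("scores", "EnergyLandscape", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("meanResidence", "EnergyLandscape", function(x) x@meanResidence)

#' @rdname accessors
#' @export
setMethod("copyNumber", "TFSpecies", function(x) x@copyNumber)
#' @rdname accessors
#' @export
setMethod("footprint", "TFSpecies", function(x) x@footprint)
#' @rdname accessors
#' @export
setMethod("assocRate", "TFSpecies", function(x) x@assocRate)
#' @rdname accessors
#' @export
setMethod("moveProbs", "TFSpecies", function(x) x@moveProbs)
#' @rdname accessors
#' @export
setMethod("isMobile", "TFSpecies", function(x) x@mobile)
#' @rdname accessors
#' @export
setMethod("isCognate", "TFSpecies", function(x) x@cognate)

#' @rdname accessors
#' @export
setMethod("firstPassage", "FDTrajectory", function(x) x@firstPassage)
#' @rdname accessors
#' @export
setMethod("isCensored", "FDTrajectory", function(x) x@censored)
#' @rdname accessors
#' @export
setMethod("occupancyFraction", "FDTrajectory", function(x) x@occupancyFraction)
#' @rdname accessors
#' @export
setMethod("meanCoverage", "FDTrajectory", function(x) x@meanCoverage)
#' @rdname accessors
#' @export
setMethod("boundFraction", "FDTrajectory", function(x) x@boundFraction)
#' @rdname accessors
#' @export
setMethod("targetIntervals", "FDTrajectory", function(x) x@intervals)

setMethod("show", "FDGenome", function(object) {
    cat(sprintf(
        "FDGenome: %d bp (%s), target site %d-%d (%d bp)\n",
        length(object@seq), object@topology, object@targetStart,
        object@targetStart + object@targetWidth - 1L, object@targetWidth))
})

setMethod("show", "EnergyLandscape", function(object) {
    cat(sprintf(
        "EnergyLandscape: %d positions, motif width %d\n  score range [%.3g, %.3g], mean residence range [%.3g, %.3g] s\n",
        length(object@scores), object@width,
        min(object@scores), max(object@scores),
        min(object@meanResidence), max(object@meanResidence)))
})

setMethod("show", "TFSpecies", function(object) {
    cat(sprintf(
        "TFSpecies '%s': %d copies, footprint %d bp, %s%s\n",
        object@name, object@copyNumber, object@footprint,
        if (object@mobile) sprintf("k_assoc %.3g /s", object@assocRate)
        else "immobile",
        if (object@cognate) ", cognate" else ""))
    if (object@mobile)
        cat(sprintf(
            "  move probs (L/R/hop/unbind): %.4g/%.4g/%.4g/%.4g, hop range %d bp\n",
            object@moveProbs[1], object@moveProbs[2], object@moveProbs[3],
            object@moveProbs[4], object@hopRange))
})

setMethod("show", "FDTrajectory", function(object) {
    fp <- if (object@censored) "censored"
          else sprintf("%.4g s", object@firstPassage)
    cat(sprintf(
        "FDTrajectory: %.4g s simulated (seed %d)\n  first passage: %s\n  target occupancy: %.4g, mean coverage: %.4g\n",
        object@duration, as.integer(object@seed), fp,
        object@occupancyFraction, object@meanCoverage))
})
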