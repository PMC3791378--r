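#' E. coli K-12 genome length used by the copy-number model
#'
#' The whole-genome length (bp) against which subsystem abundances are
#' scaled.  This is the unique value for which ceiling scaling reproduces
#' every printed subsystem copy number of the parameter presets (see the
#' package tests for the exhaustive consistency check).
#' @export
ECOLI_GENOME_LENGTH <- 4639675L

#' Scale a whole-genome abundance to a subsystem
#'
#' The copy-number model keeps the molecule density constant when a
#' simulation is reduced from the full genome to a subsegment:
#' \deqn{N_{sub} = \lceil N_{full} \cdot L_{sub} / L_{full} \rceil.}
#' Ceiling (rather than rounding or flooring) is the rule consistent with
#' all published subsystem abundances; the package tests verify this.
#'
#' @param nFull whole-genome copy number (>= 0).
#' @param lFull whole-genome length, bp.
#' @param lSub subsystem length, bp (must not exceed \code{lFull}).
#' @return integer subsystem copy number; vectorised over \code{nFull}.
#' @examples
#' copyNumberScale(10000, ECOLI_GENOME_LENGTH, 1e5)  # 216
#' copyNumberScale(40000, ECOLI_GENOME_LENGTH, 1e5)  # 863
#' @export
copyNumberScale <- function(nFull, lFull = ECOLI_GENOME_LENGTH, lSub) {
    if (any(nFull < 0)) stop("nFull must be >= 0")
    if (lFull <= 0 || lSub <= 0) stop("lengths must be positive")
    if (lSub > lFull) stop("subsystem cannot be larger than the full genome")
    as.integer(ceiling(as.numeric(nFull) * as.numeric(lSub) /
                       as.numeric(lFull)))
}

#' Load the subsystem parameter presets
#'
#' Returns the 100-Kbp subsystem presets for the non-cognate abundance
#' series: full-genome abundance, non-cognate association rate, reference
#' covered-DNA percentage, subsystem abundance, and the cognate (lacI)
#' association rates for 1, 10, 100 and 1000 lacI molecules.  Five rows
#' describe the mobile-obstacle series; a sixth row carries the
#' 40,000-copy immobile-obstacle preset (subsystem abundance 863, a single
#' lacI association rate of 7.37 s^-1 for all abundances).  The
#' lacI association rates come from an association-rate scaling model
#' published separately; they are shipped as fixed presets, not re-derived.
#'
#' @return a data.frame with columns \code{tfNcFull}, \code{kAssocNc},
#'   \code{coveredPct}, \code{tfNcSub}, \code{kLacI1}, \code{kLacI10},
#'   \code{kLacI100}, \code{kLacI1000}, \code{obstacles}.
#' @examples
#' loadSubsystemPresets()
#' @export
loadSubsystemPresets <- function() {
    path <- system.file("extdata", "subsystem_presets.tsv", package = "fdSim",
                        mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$tfNcFull <- as.integer(df$tfNcFull)
    df$tfNcSub <- as.integer(df$tfNcSub)
    df
}

#' Expand the presets into an experiment grid
#'
#' Crosses the non-cognate abundance presets with the cognate abundances
#' and rescales copy numbers to a segment of \code{scale} times 100 Kbp
#' with the copy-number model.  Cognate abundances of 100 and 1000 (which
#' are themselves 100-Kbp subsystem abundances) are rescaled the same way;
#' 1 and 10 are kept as-is so the low-abundance regimes survive reduction.
#'
#' @param scale fraction of the 100 Kbp reference segment, in (0, 1].
#' @param lacIAbundances cognate abundances to cross with the non-cognate
#'   presets.
#' @param obstacles which obstacle protocols to include,
#'   \code{"mobile"}, \code{"immobile"} or both.
#' @return a data.frame with one row per experimental condition: columns
#'   \code{condition}, \code{obstacles}, \code{tfNcFull}, \code{tfNc},
#'   \code{kAssocNc}, \code{lacIRef}, \code{lacI}, \code{kAssocLacI},
#'   \code{crowdingRef} (reference covered-DNA fraction used as the
#'   crowding axis) and \code{lSub}.
#' @examples
#' grid <- makeExperimentGrid(scale = 0.1, lacIAbundances = 10)
#' grid[, c("condition", "tfNc", "kAssocNc")]
#' @export
makeExperimentGrid <- function(scale = 1,
                               lacIAbundances = c(1L, 10L, 100L, 1000L),
                               obstacles = c("mobile", "immobile")) {
    if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
    obstacles <- match.arg(obstacles, several.ok = TRUE)
    presets <- loadSubsystemPresets()
    lSub <- as.integer(round(1e5 * scale))
    rows <- list()
    for (i in seq_len(nrow(presets))) {
        p <- presets[i, ]
        if (!p$obstacles %in% obstacles) next
        tfNc <- if (p$tfNcFull > 0)
            copyNumberScale(p$tfNcFull, ECOLI_GENOME_LENGTH, lSub) else 0L
        if (p$tfNcFull > 0 && tfNc < 1L) {
            warning("scale yields 0 molecules for a nonzero preset; ",
                    "clamping to 1")
            tfNc <- 1L
        }
        for (nl in lacIAbundances) {
            lacI <- if (nl > 10) {
                # subsystem abundances rescale with the segment
                max(1L, as.integer(ceiling(nl * lSub / 1e5)))
            } else as.integer(nl)
            kCol <- paste0("kLacI", nl)
            if (!kCol %in% names(presets))
                stop("no association-rate preset for ", nl, " lacI molecules")
            rows[[length(rows) + 1L]] <- data.frame(
                condition = sprintf("%s_nc%d_lacI%d", substr(p$obstacles, 1, 3),
                                    p$tfNcFull, nl),
                obstacles = p$obstacles,
                tfNcFull = p$tfNcFull,
                tfNc = tfNc,
                kAssocNc = p$kAssocNc,
                lacIRef = as.integer(nl),
                lacI = lacI,
                kAssocLacI = p[[kCol]],
                crowdingRef = if (p$obstacles == "immobile")
                    tfNc * 46 / lSub else p$coveredPct / 100,
                lSub = lSub,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Serialise an experiment grid to a config file
#'
#' @param grid a data.frame from \code{\link{makeExperimentGrid}}.
#' @param path output path (JSON).
#' @return \code{path}, invisibly.
#' @export
writeExperimentGrid <- function(grid, path) {
    jsonlite::write_json(grid, path, digits = NA, dataframe = "rows")
    invisible(path)
}

#' Read an experiment grid config file
#'
#' @param path path written by \code{\link{writeExperimentGrid}}.
#' @return the grid data.frame.
#' @export
readExperimentGrid <- function(path) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
    df$tfNcFull <- as.integer(df$tfNcFull)
    df$tfNc <- as.integer(df$tfNc)
    df$lacIRef <- as.integer(df$lacIRef)
    df$lacI <- as.integer(df$lacI)
    df$lSub <- as.integer(df$lSub)
    df
}
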