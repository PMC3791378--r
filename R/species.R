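#' Default baseline residence time (seconds per position)
#'
#' Baseline mean residence of a bound molecule at one position.  One
#' millisecond keeps nonspecific visits short relative to the 3000 s cell
#' cycle while remaining desk-simulable; see the package vignette for the
#' calibration argument.
#' @export
DEFAULT_TAU0 <- 1e-3

#' Default move probabilities for a species role
#'
#' Returns the probabilities \code{(left, right, hop, unbind)} applied when
#' a bound molecule's residence time expires.
#'
#' The non-cognate defaults (\code{unbind = 0.2}, \code{hop = 0.04},
#' symmetric slides) give a mean bound period of \code{tau0 / 0.2 = 5} ms,
#' which together with the calibrated association rate puts a molecule on
#' the DNA 90\% of the time.  The cognate (lac repressor-like) defaults
#' (\code{unbind = 5e-4}, \code{hop = 1e-4}) give second-scale nonspecific
#' bound periods and a sliding length of roughly 40 bp per visit.
#'
#' @param role \code{"noncognate"} or \code{"cognate"}.
#' @return named numeric of length 4 summing to one.
#' @seealso \code{\link{calibrateAssociationRate}}
#' @export
defaultMoveProbs <- function(role = c("noncognate", "cognate")) {
    role <- match.arg(role)
    if (role == "noncognate") {
        c(left = 0.38, right = 0.38, hop = 0.04, unbind = 0.2)
    } else {
        pu <- 5e-4
        ph <- 1e-4
        c(left = (1 - pu - ph) / 2, right = (1 - pu - ph) / 2,
          hop = ph, unbind = pu)
    }
}

#' Calibrate the association rate for a target bound-state fraction
#'
#' On empty DNA a mobile molecule alternates free periods of mean
#' \code{1/k} with bound periods of mean \code{tau0 / p_unbind} (each
#' residence lasts \code{tau0} on average and the molecule detaches with
#' probability \code{p_unbind} per residence expiry; hops never clash on
#' empty DNA).  Requiring a stationary bound fraction \eqn{\phi} gives
#' \deqn{k = \frac{\phi}{1 - \phi} \cdot \frac{p_{unbind}}{\tau_0}.}
#' With the default non-cognate parameters and \eqn{\phi = 0.9} this yields
#' 1800 s^-1, matching the obstacle-free subsystem preset.
#'
#' @param boundFraction target stationary fraction of time spent bound
#'   (default 0.9, the experimentally motivated value).
#' @param moveProbs move probabilities of the species (the unbinding entry
#'   is used).
#' @param tau0 baseline mean residence time, seconds.
#' @return association rate, s^-1 per free molecule.
#' @examples
#' calibrateAssociationRate()  # 1800
#' @export
calibrateAssociationRate <- function(boundFraction = 0.9,
                                     moveProbs = defaultMoveProbs("noncognate"),
                                     tau0 = DEFAULT_TAU0) {
    if (boundFraction <= 0 || boundFraction >= 1)
        stop("boundFraction must lie in (0, 1)")
    unname(boundFraction / (1 - boundFraction) * moveProbs[4] / tau0)
}

#' Construct a molecule species
#'
#' @param name species label.
#' @param copyNumber number of molecules (>= 0).
#' @param footprint occluded base pairs per bound molecule.
#' @param assocRate binding attempt rate per free molecule, s^-1.
#' @param moveProbs probabilities \code{(left, right, hop, unbind)} on
#'   residence expiry; must sum to one.  Ignored for immobile species.
#' @param hopRange maximum hop displacement in bp.
#' @param mobile \code{FALSE} turns the species into fixed obstacles placed
#'   uniformly at random (non-overlapping) at time zero.
#' @param cognate whether arrivals of this species at the target site define
#'   first passage and occupancy.
#' @param landscape an \linkS4class{EnergyLandscape}, or \code{NULL} for a
#'   flat (sequence-nonspecific) landscape with mean residence \code{tau0} —
#'   the treatment used for non-cognate species.
#' @param tau0 mean residence time used when \code{landscape} is
#'   \code{NULL}, seconds.
#' @param initialPositions optional 1-based start positions for the first
#'   molecules of the species (test/experiment hook).
#' @return a \linkS4class{TFSpecies}.
#' @examples
#' TFSpecies("nc", copyNumber = 65, footprint = 46, assocRate = 2571)
#' @export
TFSpecies <- function(name, copyNumber, footprint = 46L,
                      assocRate = calibrateAssociationRate(),
                      moveProbs = defaultMoveProbs("noncognate"),
                      hopRange = 100L, mobile = TRUE, cognate = FALSE,
                      landscape = NULL, tau0 = DEFAULT_TAU0,
                      initialPositions = integer()) {
    new("TFSpecies", name = name, copyNumber = as.integer(copyNumber),
        footprint = as.integer(footprint), assocRate = as.numeric(assocRate),
        moveProbs = as.numeric(moveProbs), hopRange = as.integer(hopRange),
        mobile = mobile, cognate = cognate, landscape = landscape,
        tau0 = as.numeric(tau0),
        initialPositions = as.integer(initialPositions))
}

#' Cognate (lac repressor-like) species constructor
#'
#' Convenience wrapper with the cognate defaults: 21-bp footprint, slow
#' unbinding (long slides), and a PWM-derived landscape.
#'
#' @param copyNumber number of cognate molecules.
#' @param assocRate association rate, s^-1 per free molecule (the subsystem
#'   presets of \code{\link{loadSubsystemPresets}} are the usual source).
#' @param landscape an \linkS4class{EnergyLandscape} built from the cognate
#'   PWM (see \code{\link{buildLandscape}}).
#' @param ... further arguments passed to \code{\link{TFSpecies}}.
#' @return a \linkS4class{TFSpecies}.
#' @export
cognateSpecies <- function(copyNumber, assocRate, landscape, ...) {
    TFSpecies("lacI", copyNumber = copyNumber, footprint = 21L,
              assocRate = assocRate,
              moveProbs = defaultMoveProbs("cognate"),
              cognate = TRUE, landscape = landscape, ...)
}

#' Steric exclusion window around the target site
#'
#' A molecule with footprint \code{fObstacle} whose left edge lies anywhere
#' within \code{fCognate + fObstacle - 1} base pairs around the target
#' position overlaps every possible cognate placement on the site, so its
#' presence excludes the cognate from the target.  With the lac repressor
#' (21 bp) and the generic non-cognate species (46 bp) the window spans
#' 66 bp.
#'
#' @param fCognate cognate footprint, bp.
#' @param fObstacle obstacle footprint, bp.
#' @return window width in bp.
#' @examples
#' exclusionWindow(21, 46)  # 66
#' @export
exclusionWindow <- function(fCognate = 21L, fObstacle = 46L) {
    as.integer(fCognate + fObstacle - 1L)
}
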