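#' Stand-in lac operator consensus (synthetic fixture)
#'
#' A 21-bp palindromic operator-like sequence used as the default embedded
#' target site.  It is a documented stand-in consistent with the 21-bp
#' cognate footprint (so the steric exclusion window is
#' \code{21 + 46 - 1 = 66} bp), not a measured motif.
#' @export
LAC_O1_CONSENSUS <- "AATTGTGAGCGGATAACAATT"

# run `expr` under a seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Generate a random genome segment with an embedded target site
#'
#' Draws i.i.d. bases at the requested GC content and splices the target
#' sequence in at the requested position, emulating a bacterial genome
#' subsegment that contains a single strong operator.  Fully reproducible
#' from \code{(parameters, seed)}.
#'
#' @param L segment length, bp.
#' @param gc GC content in (0, 1).
#' @param siteSequence target sequence to embed (default the stand-in
#'   21-bp operator consensus).
#' @param sitePosition 1-based position of the site's left edge (default:
#'   the middle of the segment).
#' @param seed integer seed.
#' @param topology passed to \code{\link{FDGenome}}.
#' @return an \linkS4class{FDGenome} whose target coordinates point at the
#'   embedded site.
#' @examples
#' g <- generateGenome(10000, seed = 1)
#' targetSequence(g) == LAC_O1_CONSENSUS
#' @export
generateGenome <- function(L, gc = 0.5, siteSequence = LAC_O1_CONSENSUS,
                           sitePosition = NULL, seed,
                           topology = c("circular", "linear")) {
    L <- as.integer(L)
    W <- nchar(siteSequence)
    if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
    if (is.null(sitePosition)) sitePosition <- max(1L, L %/% 2L)
    sitePosition <- as.integer(sitePosition)
    if (sitePosition < 1L || sitePosition + W - 1L > L)
        stop("site overhangs the genome")
    bases <- withSeed(seed, sample(
        c("A", "C", "G", "T"), L, replace = TRUE,
        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
    bases[sitePosition:(sitePosition + W - 1L)] <-
        strsplit(toupper(siteSequence), "")[[1]]
    FDGenome(paste(bases, collapse = ""), targetStart = sitePosition,
             targetWidth = W, topology = match.arg(topology))
}

#' Generate a stand-in position weight matrix
#'
#' Builds a PWM whose unique maximum-scoring window is the consensus: each
#' column rewards the consensus base with \code{+specificity}, penalises the
#' three others with a random draw from \code{-specificity * U(0.5, 1.5)},
#' and is then centred so the four entries of every column average to zero
#' (the log-odds-like convention under a uniform background).  A single
#' mismatch costs strictly more than the consensus reward, so no window
#' with any mismatch can tie the consensus; centring shifts whole columns
#' and therefore preserves the ranking of windows.  \code{specificity = 0}
#' yields the all-zero matrix (a flat landscape).
#'
#' Because columns are centred, a random background window scores around
#' zero, so with the default residence mapping (\code{tau0 = 1e-3} s,
#' \code{beta = 1}) the genome-average residence stays in the millisecond
#' range while the consensus site (score about \code{1.5 * 21 *
#' specificity}) resides for seconds — a deliberately scaled-down affinity
#' that keeps desk-scale runs feasible while preserving a strongly
#' preferred site.
#'
#' @param width motif width, bp.
#' @param specificity score scale per column (>= 0); the default 0.25
#'   gives a mean target residence of roughly 2.6 s under the default
#'   mapping.
#' @param seed integer seed for the mismatch penalties.
#' @param consensus consensus sequence (its width overrides \code{width}).
#' @return a 4 x width numeric matrix with rownames \code{A, C, G, T}.
#' @examples
#' pwm <- generatePWM(seed = 1)
#' colSums(pwm)  # ~0: columns are centred
#' @export
generatePWM <- function(width = 21L, specificity = 0.25, seed,
                        consensus = LAC_O1_CONSENSUS) {
    if (specificity < 0) stop("specificity must be >= 0")
    cons <- strsplit(toupper(consensus), "")[[1]]
    width <- length(cons)
    m <- matrix(0, nrow = 4, ncol = width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    if (specificity > 0) {
        pen <- withSeed(seed,
            matrix(-specificity * stats::runif(4 * width, 0.5, 1.5),
                   nrow = 4))
        m[] <- pen
        for (j in seq_len(width)) m[cons[j], j] <- specificity
        m <- sweep(m, 2, colMeans(m))
    }
    m
}
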