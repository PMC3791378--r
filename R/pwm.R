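#' Read a position weight matrix from a text file
#'
#' The expected format is a one-line header naming the row order (a
#' permutation of \code{A C G T}) followed by four whitespace-delimited rows
#' of \code{W} numbers each.  Rows are reordered to \code{A, C, G, T} on
#' read.
#'
#' @param path path to the PWM file.
#' @return a 4 x W numeric matrix with rownames \code{A, C, G, T}.
#' @seealso \code{\link{writePWM}}, \code{\link{generatePWM}}
#' @export
readPWM <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) != 5L)
        stop("expected a header line plus 4 rows, found ", length(lines),
             " non-empty lines")
    order <- toupper(strsplit(trimws(lines[1]), "\\s+")[[1]])
    if (!identical(sort(order), c("A", "C", "G", "T")))
        stop("header must name the row order as a permutation of A C G T")
    rows <- lapply(lines[2:5], function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    W <- length(rows[[1]])
    if (any(vapply(rows, length, 1L) != W))
        stop("all PWM rows must have the same number of columns")
    m <- do.call(rbind, rows)
    rownames(m) <- order
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(!is.finite(m))) stop("PWM entries must be finite numbers")
    m
}

#' Write a position weight matrix to a text file
#'
#' @param pwm a 4 x W numeric matrix with rownames \code{A, C, G, T}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePWM <- function(pwm, path) {
    pwm <- checkPWM(pwm)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("A C G T", con)
    for (i in seq_len(4))
        writeLines(paste(format(pwm[i, ], digits = 17), collapse = " "), con)
    invisible(path)
}

checkPWM <- function(pwm) {
    if (!is.matrix(pwm) || !is.numeric(pwm) || nrow(pwm) != 4L)
        stop("pwm must be a 4 x W numeric matrix")
    if (ncol(pwm) < 1L) stop("pwm must have width >= 1")
    if (any(!is.finite(pwm))) stop("pwm entries must be finite")
    if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
    if (!identical(sort(rownames(pwm)), c("A", "C", "G", "T")))
        stop("pwm rownames must be A, C, G, T")
    pwm[c("A", "C", "G", "T"), , drop = FALSE]
}

#' Score binding positions with a position weight matrix
#'
#' The score of a window is the sum over motif columns of the weight of the
#' observed base (additive PWM scoring).  Only the forward strand is scored,
#' so the landscape stays single-valued per position.
#'
#' @param pwm a 4 x W numeric matrix with rownames \code{A, C, G, T}.
#' @param genome an \linkS4class{FDGenome}.
#' @param position 1-based left-aligned window position(s), each in
#'   \code{[1, L - W + 1]}.
#' @return numeric vector of scores, one per position.
#' @examples
#' g <- generateGenome(200, seed = 1)
#' pwm <- generatePWM(seed = 1)
#' pwmScore(pwm, g, targetStart(g))
#' @export
pwmScore <- function(pwm, genome, position) {
    pwm <- checkPWM(pwm)
    W <- ncol(pwm)
    L <- genomeLength(genome)
    position <- as.integer(position)
    if (any(position < 1L | position > L - W + 1L))
        stop(sprintf("position out of range [1, %d]", L - W + 1L))
    Biostrings::PWMscoreStartingAt(pwm, genome@seq, starting.at = position)
}

#' Build the per-position energy landscape of a species
#'
#' Scores every left-aligned binding position of the genome with the PWM and
#' converts scores to mean residence times via
#' \deqn{\tau(i) = \tau_0 \exp(\beta \cdot s_i),}
#' so a higher (stronger) score yields a longer mean residence.  On circular
#' genomes windows wrap across the origin and the landscape has \code{L}
#' entries; on linear genomes it has \code{L - W + 1}.
#'
#' @inheritParams pwmScore
#' @param tau0 baseline mean residence time at score zero, seconds
#'   (must be positive).
#' @param beta inverse energy scale converting score units to log-residence
#'   units; \code{beta = 0} gives a flat landscape.
#' @return an \linkS4class{EnergyLandscape}.
#' @examples
#' g <- generateGenome(500, seed = 7)
#' land <- buildLandscape(generatePWM(seed = 7), g, tau0 = 1e-3)
#' which.max(scores(land)) == targetStart(g)
#' @export
buildLandscape <- function(pwm, genome, tau0 = 1e-3, beta = 1) {
    pwm <- checkPWM(pwm)
    if (!is.finite(tau0) || tau0 <= 0) stop("tau0 must be positive")
    W <- ncol(pwm)
    L <- genomeLength(genome)
    if (W > L) stop("motif wider than the genome")
    if (genome@topology == "circular") {
        subject <- Biostrings::xscat(
            genome@seq, Biostrings::subseq(genome@seq, 1L, W - 1L))
        sc <- Biostrings::PWMscoreStartingAt(pwm, subject, starting.at = 1:L)
    } else {
        sc <- Biostrings::PWMscoreStartingAt(pwm, genome@seq,
                                             starting.at = 1:(L - W + 1L))
    }
    sc <- as.numeric(sc)
    new("EnergyLandscape", scores = sc,
        meanResidence = tau0 * exp(beta * sc), width = as.integer(W))
}
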