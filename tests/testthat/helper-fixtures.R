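# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately naive re-implementations (loops, linear solves, explicit
# formulas) kept independent of the package code paths they check.

randomGenome <- function(L, seed, targetStart = max(1L, L %/% 2L),
                         targetWidth = 5L, topology = "circular") {
    bases <- withr::with_seed(seed,
        sample(c("A", "C", "G", "T"), L, replace = TRUE))
    FDGenome(paste(bases, collapse = ""), targetStart = targetStart,
             targetWidth = targetWidth, topology = topology)
}

# a single-molecule flat-landscape species used in many simulator tests
flatSpecies <- function(copyNumber = 1, footprint = 5L, assocRate = 20,
                        moveProbs = c(0.38, 0.38, 0.04, 0.2),
                        hopRange = 8L, tau0 = 0.01, cognate = TRUE, ...) {
    TFSpecies("tf", copyNumber = copyNumber, footprint = footprint,
              assocRate = assocRate, moveProbs = moveProbs,
              hopRange = hopRange, cognate = cognate, tau0 = tau0, ...)
}

# brute-force PWM window score: explicit per-column loop
naivePwmScore <- function(pwm, seqChar, position) {
    total <- 0
    for (j in seq_len(ncol(pwm))) {
        base <- substr(seqChar, position + j - 1L, position + j - 1L)
        total <- total + pwm[base, j]
    }
    total
}

# mean first-passage time of the continuous-time Markov chain equivalent to
# a single molecule on an empty circular genome with a flat landscape:
# states are {free} and the bound positions except the absorbing target.
ctmcMeanFPT <- function(L, targetStart1, k, tau0, moveProbs, hopRange) {
    target <- targetStart1 - 1L
    pos <- setdiff(0:(L - 1L), target)
    idx <- integer(L)
    idx[pos + 1L] <- seq_along(pos) + 1L
    n <- length(pos) + 1L
    P <- matrix(0, n, n)
    h <- numeric(n)
    h[1] <- 1 / k
    for (p in pos) P[1, idx[p + 1L]] <- 1 / L
    for (p in pos) {
        i <- idx[p + 1L]
        h[i] <- tau0
        add <- function(q, pr) {
            q <- q %% L
            if (q != target) P[i, idx[q + 1L]] <<- P[i, idx[q + 1L]] + pr
        }
        add(p - 1L, moveProbs[1])
        add(p + 1L, moveProbs[2])
        for (d in c(-hopRange:-1, 1:hopRange))
            add(p + d, moveProbs[3] / (2 * hopRange))
        P[i, 1] <- P[i, 1] + moveProbs[4]
    }
    solve(diag(n) - P, h)[1]
}

# exhaustive count of vacant left-aligned placements for a footprint on an
# occupancy vector (1 = covered)
countVacantPlacements <- function(occupied, footprint, circular) {
    L <- length(occupied)
    nPos <- if (circular) L else L - footprint + 1L
    count <- 0L
    for (p in seq_len(nPos) - 1L) {
        cells <- if (circular) (p + 0:(footprint - 1L)) %% L
                 else p + 0:(footprint - 1L)
        if (all(occupied[cells + 1L] == 0L)) count <- count + 1L
    }
    count
}

# do any two footprints in a set of positions overlap? (circular-aware)
anyOverlap <- function(positions, footprint, L, circular) {
    cells <- integer(0)
    for (p in positions) {
        cc <- if (circular) ((p - 1L) + 0:(footprint - 1L)) %% L
              else (p - 1L) + 0:(footprint - 1L)
        if (any(cc %in% cells)) return(TRUE)
        cells <- c(cells, cc)
    }
    FALSE
}

# rule-following boxplot oracle: recomputes the caption's six-part summary
# directly from the sorted sample with hand-written interpolation quartiles
ruleBoxplot <- function(x) {
    s <- sort(x)
    n <- length(s)
    interp <- function(p) {
        hh <- (n - 1) * p + 1
        lo <- floor(hh)
        hi <- ceiling(hh)
        s[lo] + (hh - lo) * (s[hi] - s[lo])
    }
    q1 <- interp(0.25); md <- interp(0.5); q3 <- interp(0.75)
    iqr <- q3 - q1
    lw <- max(q1 - 1.5 * iqr, s[1])
    uw <- min(q3 + 1.5 * iqr, s[n])
    list(median = md, q1 = q1, q3 = q3, iqr = iqr,
         lowerWhisker = lw, upperWhisker = uw,
         outliers = s[s < lw | s > uw],
         notchLow = md - 1.57 * iqr / sqrt(n),
         notchHigh = md + 1.57 * iqr / sqrt(n))
}
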