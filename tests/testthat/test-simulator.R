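test_that("initial placement of immobile obstacles never overlaps", {
    g <- randomGenome(2000, seed = 1)
    imm <- TFSpecies("roadblock", copyNumber = 25, footprint = 46,
                     assocRate = 1, mobile = FALSE)
    for (s in 1:200) {
        tr <- runSimulation(g, imm, duration = 0, seed = s)
        pos <- tr@immobilePositions$roadblock
        expect_length(pos, 25)
        expect_false(anyOverlap(pos, 46L, 2000L, circular = TRUE))
    }
})

test_that("an over-packed genome is reported, not silently mis-placed", {
    g <- randomGenome(200, seed = 2)
    imm <- TFSpecies("roadblock", copyNumber = 10, footprint = 46,
                     assocRate = 1, mobile = FALSE)
    expect_error(runSimulation(g, imm, duration = 0, seed = 1,
                               maxPlacementTries = 50),
                 "coverage")
})

test_that("simulations are bit-reproducible from their seed", {
    g <- randomGenome(1000, seed = 3)
    spl <- list(flatSpecies(copyNumber = 3),
                TFSpecies("nc", copyNumber = 8, footprint = 46,
                          assocRate = 1800))
    a <- runSimulation(g, spl, duration = 5, seed = 99)
    b <- runSimulation(g, spl, duration = 5, seed = 99)
    expect_identical(firstPassage(a), firstPassage(b))
    expect_identical(targetIntervals(a), targetIntervals(b))
    expect_identical(meanCoverage(a), meanCoverage(b))
    expect_identical(a@finalPositions, b@finalPositions)
    c <- runSimulation(g, spl, duration = 5, seed = 100)
    expect_false(identical(a@finalPositions, c@finalPositions))
})

test_that("binding acceptance frequency matches the exhaustive vacancy count", {
    L <- 500L
    f <- 46L
    set.seed(7)
    for (circular in c(TRUE, FALSE)) {
        occ <- integer(L)
        # park some footprints to create a fragmented occupancy pattern
        for (p in c(10, 80, 200, 390)) occ[p:(p + f - 1L)] <- 1L
        trials <- 1e5L
        acc <- fdSim:::.cppBindAcceptance(occ, circular, f, trials, 123)
        nPos <- if (circular) L else L - f + 1L
        pExp <- countVacantPlacements(occ, f, circular) / nPos
        se <- sqrt(pExp * (1 - pExp) / trials)
        expect_lt(abs(acc / trials - pExp), 3 * se + 1e-9)
    }
})

test_that("empty DNA always accepts and full DNA always rejects binding", {
    L <- 200L
    expect_equal(fdSim:::.cppBindAcceptance(integer(L), TRUE, 46L, 1000L, 1),
                 1000L)
    expect_equal(fdSim:::.cppBindAcceptance(rep(1L, L), TRUE, 46L, 1000L, 1),
                 0L)
})

test_that("move outcome frequencies follow the move probabilities", {
    probs <- c(0.38, 0.38, 0.04, 0.2)
    n <- 1e5L
    counts <- fdSim:::.cppMoveOutcomes(probs, n, 17)
    expect_equal(sum(counts), n)
    for (i in 1:4) {
        se <- sqrt(probs[i] * (1 - probs[i]) / n)
        expect_lt(abs(counts[i] / n - probs[i]), 3 * se)
    }
    # degenerate distribution: always unbind
    expect_equal(fdSim:::.cppMoveOutcomes(c(0, 0, 0, 1), 1000L, 5),
                 c(0L, 0L, 0L, 1000L))
})

test_that("a pure-unbind species alternates binds and unbinds", {
    g <- randomGenome(500, seed = 4)
    sp <- flatSpecies(moveProbs = c(0, 0, 0, 1), assocRate = 50)
    tr <- runSimulation(g, sp, duration = 50, seed = 8)
    expect_gt(tr@bindCount[["tf"]], 500)
    expect_lte(abs(tr@bindCount[["tf"]] - tr@unbindCount[["tf"]]), 1)
})

test_that("the steric invariant survives a crowded run (full audit)", {
    g <- randomGenome(600, seed = 5)
    spl <- list(flatSpecies(copyNumber = 4, footprint = 21, assocRate = 500,
                            tau0 = 1e-3),
                TFSpecies("nc", copyNumber = 8, footprint = 46,
                          assocRate = 2000))
    # audit recomputes the occupancy index after every event and stops on
    # any overlap or index drift
    expect_no_error(runSimulation(g, spl, duration = 2, seed = 21,
                                  audit = TRUE))
})

test_that("molecule counts are conserved through a run", {
    g <- randomGenome(800, seed = 6)
    spl <- list(flatSpecies(copyNumber = 5),
                TFSpecies("nc", copyNumber = 7, footprint = 46,
                          assocRate = 1800),
                TFSpecies("roadblock", copyNumber = 3, footprint = 46,
                          assocRate = 1, mobile = FALSE))
    tr <- runSimulation(g, spl, duration = 3, seed = 31)
    nm <- c(tf = 5L, nc = 7L, roadblock = 3L)
    for (s in names(nm))
        expect_equal(length(tr@finalPositions[[s]]) + tr@freeCount[[s]],
                     nm[[s]])
    # immobile molecules sit exactly where they started
    expect_setequal(tr@finalPositions$roadblock,
                    tr@immobilePositions$roadblock)
})

test_that("a cognate pre-placed on the target registers first passage zero", {
    g <- randomGenome(300, seed = 7, targetStart = 120, targetWidth = 5)
    sp <- flatSpecies(initialPositions = 120L)
    tr <- runSimulation(g, sp, duration = 1, seed = 1)
    expect_false(isCensored(tr))
    expect_equal(firstPassage(tr), 0)
    expect_equal(targetIntervals(tr)[1, "tOn"], c(tOn = 0))
})

test_that("zero-duration runs return an empty censored trajectory", {
    g <- randomGenome(300, seed = 8)
    tr <- runSimulation(g, flatSpecies(), duration = 0, seed = 1)
    expect_true(isCensored(tr))
    expect_true(is.na(firstPassage(tr)))
    expect_equal(nrow(targetIntervals(tr)), 0)
    expect_equal(occupancyFraction(tr), 0)
})

test_that("instantaneous coverage counts occluded base pairs", {
    g <- randomGenome(100, seed = 9, targetStart = 10, targetWidth = 5)
    sp <- TFSpecies("nc", copyNumber = 1, footprint = 46, assocRate = 1,
                    initialPositions = 20L)
    tr <- runSimulation(g, sp, duration = 0, seed = 1)
    expect_equal(meanCoverage(tr), 0.46)
    empty <- runSimulation(g, TFSpecies("nc", copyNumber = 0, footprint = 46,
                                        assocRate = 1), duration = 0, seed = 1)
    expect_equal(meanCoverage(empty), 0)
})

test_that("an immobile molecule inside the 66-bp window blocks the target, one outside does not", {
    ts <- 200L
    g <- randomGenome(500, seed = 10, targetStart = ts, targetWidth = 21L)
    lac <- flatSpecies(footprint = 21L, assocRate = 100, tau0 = 1e-3)
    blockAt <- function(p) {
        imm <- TFSpecies("roadblock", copyNumber = 1, footprint = 46,
                         assocRate = 1, mobile = FALSE,
                         initialPositions = as.integer(p))
        runSimulation(g, list(lac, imm), duration = 30, seed = 44,
                      stopAtFirstPassage = TRUE)
    }
    # left edges ts-45 .. ts+20 overlap every cognate placement on the site
    expect_true(isCensored(blockAt(ts - 45L)))
    expect_true(isCensored(blockAt(ts)))
    expect_true(isCensored(blockAt(ts + 20L)))
    # one base pair further out the site is reachable again
    expect_false(isCensored(blockAt(ts - 46L)))
    expect_false(isCensored(blockAt(ts + 21L)))
    expect_equal(exclusionWindow(21, 46), 66L)
})

test_that("a single slider on a flat circular landscape visits positions uniformly", {
    L <- 400L
    g <- randomGenome(L, seed = 13)
    sp <- flatSpecies(footprint = 5L, assocRate = 500, tau0 = 1e-3)
    tr <- runSimulation(g, sp, duration = 400, seed = 5,
                        trackPositions = TRUE)
    # coarse bins blunt the short-range correlation of the 1D walk; the
    # effective sample size is the number of independent binding events
    bins <- 20L
    tm <- tapply(tr@positionTime, rep(seq_len(bins), each = L / bins), sum)
    nEff <- tr@bindCount[["tf"]]
    counts <- tm / sum(tm) * nEff
    p <- chisq.test(counts, p = rep(1 / bins, bins))$p.value
    expect_gt(p, 1e-3)
})

test_that("the stationary occupancy intervals are disjoint, ordered and in range", {
    g <- randomGenome(300, seed = 14, targetWidth = 5L)
    sp <- flatSpecies(footprint = 5L, assocRate = 200, tau0 = 5e-3)
    tr <- runSimulation(g, sp, duration = 50, seed = 3)
    iv <- targetIntervals(tr)
    expect_gt(nrow(iv), 2)
    expect_true(all(iv[, "tOff"] >= iv[, "tOn"]))
    expect_true(all(diff(iv[, "tOn"]) > 0))
    # intervals never overlap: each opens after the previous closed
    expect_true(all(iv[-1, "tOn"] >= iv[-nrow(iv), "tOff"]))
    expect_equal(firstPassage(tr), iv[1, "tOn"], ignore_attr = TRUE)
    expect_equal(occupancyFraction(tr),
                 sum(iv[, "tOff"] - iv[, "tOn"]) / 50)
})
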