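mkEnsemble <- function(fp, censored = rep(FALSE, length(fp)),
                       occ = rep(0.5, length(fp)),
                       condition = "c1", crowding = 0.1) {
    data.frame(replicate = seq_along(fp), seed = seq_along(fp),
               condition = condition, crowding = crowding,
               first_passage = ifelse(censored, NA_real_, fp),
               censored = censored, occupancy_fraction = occ,
               mean_coverage = 0.1, stringsAsFactors = FALSE)
}

test_that("first-passage statistics average the uncensored replicates only", {
    e <- mkEnsemble(c(10, 20, 30))
    st <- firstPassageStats(e)
    expect_equal(st$mean, 20)
    expect_equal(st$variance, 100)
    expect_equal(st$n, 3L)
    expect_equal(st$nCensored, 0L)

    e2 <- mkEnsemble(c(10, 20, 30, 999), censored = c(FALSE, FALSE, FALSE, TRUE))
    st2 <- firstPassageStats(e2)
    expect_equal(st2$mean, 20)
    expect_equal(st2$nCensored, 1L)

    allc <- mkEnsemble(c(1, 2), censored = c(TRUE, TRUE))
    expect_error(firstPassageStats(allc), "censored")
})

test_that("first-passage mean recovers the rate of simulated exponential searches", {
    x <- withr::with_seed(42, rexp(4000, rate = 1 / 50))
    e <- mkEnsemble(x)
    st <- firstPassageStats(e)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(st$mean - 50), 3 * se)
})

test_that("occupancy statistics honour the two censoring protocols", {
    e <- mkEnsemble(c(1, 2), occ = c(0.2, 0.4))
    expect_equal(occupancyStats(e)$mean, 0.3)

    e2 <- mkEnsemble(c(1, 2, 3), censored = c(FALSE, FALSE, TRUE),
                     occ = c(0.2, 0.4, 0))
    # mobile protocol: censored replicates count as zero occupancy
    keep <- occupancyStats(e2, discardCensored = FALSE)
    expect_equal(keep$mean, 0.2)
    expect_equal(keep$n, 3L)
    # immobile protocol: censored replicates are discarded
    drop <- occupancyStats(e2, discardCensored = TRUE)
    expect_equal(drop$mean, 0.3)
    expect_equal(drop$n, 2L)

    allc <- mkEnsemble(1, censored = TRUE)
    expect_error(occupancyStats(allc, discardCensored = TRUE), "discard")
})

test_that("occupancy variance matches an independent two-pass computation", {
    occ <- withr::with_seed(9, runif(1000))
    e <- mkEnsemble(seq_along(occ), occ = occ)
    v <- occupancyStats(e)$variance
    m <- sum(occ) / length(occ)
    twoPass <- sum((occ - m)^2) / (length(occ) - 1)
    expect_equal(v, twoPass)
})

test_that("reach probability is the uncensored fraction", {
    expect_equal(reachProbability(mkEnsemble(1:10)), 1)
    expect_equal(reachProbability(mkEnsemble(1:10, censored = rep(TRUE, 10))), 0)
    e <- mkEnsemble(1:100, censored = c(rep(FALSE, 10), rep(TRUE, 90)))
    expect_equal(reachProbability(e), 0.1)
    # n * reach is an integer by construction
    expect_equal(reachProbability(e) * nrow(e), round(reachProbability(e) * nrow(e)))
})

test_that("crowding correlation matches the closed-form product-moment formula", {
    expect_equal(crowdingCorrelation(c(0, 1, 2), c(5, 7, 9)), 1)
    expect_equal(crowdingCorrelation(c(0, 1, 2), c(9, 7, 5)), -1)
    x <- c(0, 1, 2)
    y <- c(1, 3, 4)
    # explicit hand computation of r
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(crowdingCorrelation(x, y), r)
    expect_error(crowdingCorrelation(c(1, 1, 1), y), "constant")
    expect_error(crowdingCorrelation(c(0, 1), c(1, 2)), "3 conditions")
})

test_that("ANOVA F matches an explicit sum-of-squares oracle and Tukey flags extremes", {
    groups <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8),
                   c = c(13, 9, 11, 8, 7, 12))
    res <- anovaTukey(groups)
    # explicit between/within sum-of-squares computation
    all <- unlist(groups)
    gm <- mean(all)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    Fexp <- (ssb / 2) / (ssw / (length(all) - 3))
    expect_equal(res$F, Fexp)
    expect_true(res$p < 0.05)

    same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
    expect_false(any(anovaTukey(same)$tukey$significant))

    far <- list(a = rnorm(10, 0, 1), b = rnorm(10, 30, 1))
    expect_true(all(anovaTukey(far)$tukey$significant))

    expect_error(anovaTukey(list(a = 1:3)), "two groups")
    expect_error(anovaTukey(list(a = 1:3, b = 2)), "at least two")
})

test_that("boxplot summaries follow the whisker/notch rules on random samples", {
    b <- boxplotSummary(1:7)
    expect_equal(b$median, 4)
    expect_equal(b$q1, 2.5)
    expect_equal(b$q3, 5.5)

    one <- boxplotSummary(3)
    expect_equal(one$median, 3)
    expect_equal(one$q1, 3)
    expect_equal(one$q3, 3)
    expect_length(one$outliers, 0)

    set.seed(31)
    for (i in 1:500) {
        n <- sample(2:60, 1)
        x <- switch(sample(3, 1), rnorm(n), rexp(n), rcauchy(n))
        got <- boxplotSummary(x)
        exp <- ruleBoxplot(x)
        got$outliers <- sort(got$outliers)
        for (f in names(exp))
            expect_equal(got[[f]], exp[[f]], tolerance = 1e-12)
        expect_true(got$q1 <= got$median && got$median <= got$q3)
        expect_true(all(got$outliers < got$lowerWhisker |
                        got$outliers > got$upperWhisker))
    }
})

test_that("summary statistics are invariant under replicate permutation", {
    e <- mkEnsemble(c(5, 1, 9, 3), occ = c(0.1, 0.9, 0.4, 0.2))
    perm <- e[sample(nrow(e)), ]
    expect_equal(firstPassageStats(e)$mean, firstPassageStats(perm)$mean)
    expect_equal(occupancyStats(e)$variance, occupancyStats(perm)$variance)
    expect_equal(reachProbability(e), reachProbability(perm))
    expect_equal(boxplotSummary(e$occupancy_fraction)$median,
                 boxplotSummary(perm$occupancy_fraction)$median)
})
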