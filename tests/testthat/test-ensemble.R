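tinyGrid <- function(obstacles = "mobile", n = 1L) {
    g <- makeExperimentGrid(scale = 0.02, lacIAbundances = 1,
                            obstacles = obstacles)
    head(g, n)
}

test_that("a one-replicate grid yields one schema-complete record", {
    ens <- runGrid(tinyGrid(), replicates = 1, baseSeed = 5, duration = 2)
    expect_equal(nrow(ens), 1L)
    expect_named(ens, c("replicate", "seed", "condition", "crowding",
                        "first_passage", "censored", "occupancy_fraction",
                        "mean_coverage"))
    expect_equal(ens$seed, 6)
})

test_that("grid reruns are bit-identical and CSVs round-trip", {
    dir1 <- withr::local_tempdir()
    dir2 <- withr::local_tempdir()
    grid <- tinyGrid(n = 2L)
    e1 <- runGrid(grid, replicates = 3, baseSeed = 11, duration = 2,
                  outDir = dir1)
    e2 <- runGrid(grid, replicates = 3, baseSeed = 11, duration = 2,
                  outDir = dir2)
    expect_identical(e1, e2)
    f1 <- list.files(dir1, pattern = "^ensemble_.*csv$", full.names = TRUE)
    f2 <- list.files(dir2, pattern = "^ensemble_.*csv$", full.names = TRUE)
    expect_length(f1, 2L)
    for (i in seq_along(f1))
        expect_identical(readLines(f1[i]), readLines(f2[i]))
    back <- readEnsemble(f1[1])
    cond <- e1[e1$condition == back$condition[1], ]
    expect_equal(back$first_passage, cond$first_passage, tolerance = 1e-12)
    expect_equal(back$censored, cond$censored)

    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines("replicate,seed\n1,2", bad)
    expect_error(readEnsemble(bad), "schema|missing")
})

test_that("the manifest traces every condition to its config and seeds", {
    dir <- withr::local_tempdir()
    grid <- tinyGrid(n = 2L)
    runGrid(grid, replicates = 2, baseSeed = 7, duration = 1, outDir = dir)
    man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                               simplifyVector = FALSE)
    expect_equal(man$baseSeed, 7)
    expect_length(man$conditions, 2L)
    for (cc in man$conditions) {
        expect_true(nzchar(cc$configHash))
        expect_equal(unlist(cc$seeds), c(8, 9))
        expect_true(cc$complete)
        expect_true(file.exists(file.path(dir, cc$file)))
    }
})

test_that("reports reproduce hand-computed statistics from a planted ensemble", {
    planted <- do.call(rbind, lapply(1:3, function(i) data.frame(
        replicate = 1:5, seed = 1:5,
        condition = paste0("c", i), crowding = c(0, 0.2, 0.5)[i],
        first_passage = c(1, 2, 3, 4, 100) * i,
        censored = FALSE,
        occupancy_fraction = c(0.5, 0.4, 0.3, 0.2, 0.1) / i,
        mean_coverage = 0.1 * i, stringsAsFactors = FALSE)))
    s <- summarizeEnsembles(planted)
    expect_equal(s$conditions$c1$firstPassageBox$median, 3)
    expect_equal(s$conditions$c2$firstPassageBox$median, 6)
    expect_equal(s$conditions$c1$occupancyBox$median, 0.3)
    expect_equal(s$conditions$c3$firstPassage$mean, 110 * 3 / 5)
    expect_equal(s$searchTimeCorrelation$r,
                 crowdingCorrelation(c(0, 0.2, 0.5), c(22, 44, 66)))
    expect_true(s$occupancyCorrelation$r < 0)

    dir <- withr::local_tempdir()
    writeReport(s, dir)
    expect_true(file.exists(file.path(dir, "summary.csv")))
    expect_true(file.exists(file.path(dir, "summary.json")))
    expect_true(file.exists(file.path(dir, "first_passage_boxplot.pdf")))
    tab <- read.csv(file.path(dir, "summary.csv"))
    expect_equal(tab$mean_first_passage[tab$condition == "c1"], 22)
    # idempotent: a rerun writes the identical summary table
    first <- readLines(file.path(dir, "summary.csv"))
    writeReport(s, dir)
    expect_identical(readLines(file.path(dir, "summary.csv")), first)
})

test_that("single-condition ensembles refuse the crowding correlation", {
    one <- data.frame(replicate = 1:3, seed = 1:3, condition = "only",
                      crowding = 0, first_passage = c(1, 2, 3),
                      censored = FALSE, occupancy_fraction = 0.5,
                      mean_coverage = 0, stringsAsFactors = FALSE)
    s <- summarizeEnsembles(one)
    expect_true(is.na(s$searchTimeCorrelation$r))
    expect_match(s$searchTimeCorrelation$note, "fewer than 3")
})

test_that("trajectory exports write the interval table, summary and BED line", {
    g <- randomGenome(300, seed = 15, targetWidth = 5L)
    tr <- runSimulation(g, flatSpecies(assocRate = 100), duration = 20,
                        seed = 2)
    csv <- withr::local_tempfile(fileext = ".csv")
    js <- withr::local_tempfile(fileext = ".json")
    writeTrajectory(tr, csv, js)
    iv <- read.csv(csv)
    expect_equal(nrow(iv), nrow(targetIntervals(tr)))
    summ <- jsonlite::read_json(js)
    expect_equal(summ$occupancy_fraction, occupancyFraction(tr))

    bed <- withr::local_tempfile(fileext = ".bed")
    writeTargetBed(g, bed)
    fields <- strsplit(readLines(bed), "\t")[[1]]
    expect_equal(as.integer(fields[2]) + 1L, targetStart(g))
    expect_equal(as.integer(fields[3]) - as.integer(fields[2]),
                 targetWidth(g))
})

test_that("mean coverage rises monotonically across the crowding presets", {
    grid <- makeExperimentGrid(scale = 0.02, lacIAbundances = 1,
                               obstacles = "mobile")
    ens <- runGrid(grid, replicates = 2, baseSeed = 77, duration = 2,
                   burnin = 0.5)
    cov <- tapply(ens$mean_coverage, ens$condition, mean)
    cov <- cov[match(grid$condition, names(cov))]
    expect_true(all(diff(cov) > 0))
})
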