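ENSEMBLE_COLUMNS <- c("replicate", "seed", "condition", "crowding",
                      "first_passage", "censored", "occupancy_fraction",
                      "mean_coverage")

#' Run an experiment grid
#'
#' Runs \code{replicates} independent simulations for every condition of an
#' experiment grid (see \code{\link{makeExperimentGrid}}).  Replicate
#' \code{r} of every condition uses seed \code{baseSeed + r}, so a grid is
#' reproducible from its config and base seed alone; conditions are
#' independent and merged deterministically by replicate index.
#'
#' For each condition a cognate (lacI-like) species with a PWM landscape
#' and a flat-landscape non-cognate species (mobile or immobile, per the
#' condition's protocol) are placed on a synthetic genome carrying the
#' operator site.
#'
#' @param grid experiment grid data.frame.
#' @param replicates simulations per condition.
#' @param baseSeed integer; replicate seeds are \code{baseSeed + 1 ..
#'   baseSeed + replicates}, and the synthetic genome/PWM use
#'   \code{baseSeed} itself.
#' @param duration cell-cycle duration per replicate, seconds (default
#'   3000 s, approximately the E. coli cell cycle).
#' @param stopAtFirstPassage halt each replicate at the first cognate
#'   arrival (first-passage experiments; occupancy is then not meaningful).
#' @param genome,pwm optional explicit genome and PWM; by default a
#'   circular segment of the grid's \code{lSub} with the stand-in operator
#'   and PWM is generated from \code{baseSeed}.
#' @param tau0,beta residence-time mapping for the cognate landscape.
#' @param burnin coverage burn-in per replicate, seconds.
#' @param outDir if non-\code{NULL}, write one ensemble CSV per condition
#'   plus a manifest JSON recording config hash, seeds and versions.
#' @param verbose log per-condition progress to stderr.
#' @return ensemble data.frame with columns \code{replicate}, \code{seed},
#'   \code{condition}, \code{crowding}, \code{first_passage},
#'   \code{censored}, \code{occupancy_fraction}, \code{mean_coverage}.
#' @examples
#' grid <- makeExperimentGrid(scale = 0.02, lacIAbundances = 1,
#'                            obstacles = "mobile")[1:2, ]
#' ens <- runGrid(grid, replicates = 2, baseSeed = 1, duration = 5)
#' @export
runGrid <- function(grid, replicates, baseSeed, duration = 3000,
                    stopAtFirstPassage = FALSE, genome = NULL, pwm = NULL,
                    tau0 = DEFAULT_TAU0, beta = 1, burnin = 0,
                    outDir = NULL, verbose = FALSE) {
    stopifnot(is.data.frame(grid), nrow(grid) >= 1L, replicates >= 1L)
    if (is.null(genome))
        genome <- generateGenome(grid$lSub[1], seed = baseSeed)
    if (is.null(pwm)) pwm <- generatePWM(seed = baseSeed)
    landscape <- buildLandscape(pwm, genome, tau0 = tau0, beta = beta)
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    manifest <- list(package = "fdSim",
                     version = as.character(utils::packageVersion("fdSim")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     baseSeed = baseSeed, replicates = replicates,
                     duration = duration,
                     stopAtFirstPassage = stopAtFirstPassage,
                     genomeLength = genomeLength(genome),
                     targetStart = targetStart(genome),
                     conditions = list())
    out <- list()
    for (i in seq_len(nrow(grid))) {
        cond <- grid[i, ]
        if (verbose)
            message("condition ", cond$condition, " (", i, "/", nrow(grid),
                    ")")
        species <- conditionSpecies(cond, landscape, tau0)
        seeds <- baseSeed + seq_len(replicates)
        recs <- vector("list", replicates)
        failed <- integer()
        for (r in seq_len(replicates)) {
            traj <- tryCatch(
                runSimulation(genome, species, duration = duration,
                              seed = seeds[r],
                              stopAtFirstPassage = stopAtFirstPassage,
                              burnin = burnin),
                error = function(e) e)
            if (inherits(traj, "error")) {
                warning("replicate ", r, " of ", cond$condition,
                        " failed: ", conditionMessage(traj))
                failed <- c(failed, r)
                next
            }
            recs[[r]] <- data.frame(
                replicate = r, seed = seeds[r],
                condition = cond$condition, crowding = cond$crowdingRef,
                first_passage = firstPassage(traj),
                censored = isCensored(traj),
                occupancy_fraction = occupancyFraction(traj),
                mean_coverage = meanCoverage(traj),
                stringsAsFactors = FALSE)
        }
        ens <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
        out[[i]] <- ens
        entry <- list(condition = cond$condition,
                      configHash = rlang::hash(as.list(cond)),
                      config = as.list(cond),
                      seeds = seeds,
                      complete = length(failed) == 0L,
                      failedReplicates = failed)
        if (!is.null(outDir)) {
            f <- file.path(outDir, paste0("ensemble_", cond$condition,
                                          ".csv"))
            writeEnsemble(ens, f)
            entry$file <- basename(f)
        }
        manifest$conditions[[length(manifest$conditions) + 1L]] <- entry
    }
    if (!is.null(outDir))
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    do.call(rbind, out)
}

# build the species list for one grid condition
conditionSpecies <- function(cond, landscape, tau0) {
    species <- list()
    if (cond$lacI > 0)
        species[[length(species) + 1L]] <- cognateSpecies(
            copyNumber = cond$lacI, assocRate = cond$kAssocLacI,
            landscape = landscape, tau0 = tau0)
    if (cond$tfNc > 0) {
        mobile <- cond$obstacles == "mobile"
        species[[length(species) + 1L]] <- TFSpecies(
            "nc", copyNumber = cond$tfNc, footprint = 46L,
            assocRate = if (mobile) cond$kAssocNc else 1,
            moveProbs = defaultMoveProbs("noncognate"),
            mobile = mobile, cognate = FALSE, landscape = NULL,
            tau0 = tau0)
    }
    species
}

#' Write / read an ensemble CSV
#'
#' The on-disk schema is the fixed header \code{replicate, seed, condition,
#' crowding, first_passage, censored, occupancy_fraction, mean_coverage};
#' censored replicates carry \code{NA} first-passage times.
#'
#' @param ensemble ensemble data.frame.
#' @param path CSV path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
writeEnsemble <- function(ensemble, path) {
    missing <- setdiff(ENSEMBLE_COLUMNS, names(ensemble))
    if (length(missing))
        stop("ensemble is missing columns: ", paste(missing, collapse = ", "))
    utils::write.csv(ensemble[, ENSEMBLE_COLUMNS], path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(ENSEMBLE_COLUMNS, names(df))
    if (length(missing))
        stop("schema error: missing columns ",
             paste(missing, collapse = ", "))
    df$censored <- as.logical(df$censored)
    df$first_passage <- as.numeric(df$first_passage)
    df
}

#' Summarise an ensemble into the report statistics
#'
#' Produces per-condition first-passage and occupancy boxplot summaries,
#' reach probabilities, the crowding correlations of both means, and the
#' across-condition ANOVA/Tukey table.  Conditions are compared on their
#' \code{crowding} column.
#'
#' @param ensemble ensemble data.frame (possibly several conditions).
#' @param discardCensored censoring protocol for occupancy (see
#'   \code{\link{occupancyStats}}).
#' @return a list with elements \code{conditions} (per-condition list of
#'   statistics), \code{searchTimeCorrelation},
#'   \code{occupancyCorrelation} (either may be \code{NA} with an
#'   explanatory \code{note} when fewer than three conditions or constant
#'   crowding make a correlation undefined) and \code{anovaTukey}
#'   (\code{NULL} unless at least two conditions have two or more
#'   uncensored times).
#' @export
summarizeEnsembles <- function(ensemble, discardCensored = FALSE) {
    conds <- unique(ensemble$condition)
    perCond <- lapply(conds, function(cc) {
        df <- ensemble[ensemble$condition == cc, , drop = FALSE]
        unc <- df[!df$censored, , drop = FALSE]
        occ <- occupancyStats(df, discardCensored = discardCensored)
        list(condition = cc,
             crowding = df$crowding[1],
             n = nrow(df),
             reachProbability = reachProbability(df),
             firstPassage = if (nrow(unc) > 0L) firstPassageStats(df)
                            else NULL,
             firstPassageBox = if (nrow(unc) > 0L)
                 boxplotSummary(unc$first_passage) else NULL,
             occupancy = occ,
             occupancyBox = boxplotSummary({
                 o <- df$occupancy_fraction
                 o[df$censored] <- 0
                 if (discardCensored) o <- o[!df$censored]
                 o
             }),
             meanCoverage = mean(df$mean_coverage))
    })
    names(perCond) <- conds
    crow <- vapply(perCond, `[[`, 0, "crowding")
    corOf <- function(vals) {
        ok <- !vapply(vals, is.null, TRUE)
        if (sum(ok) < 3L)
            return(list(r = NA_real_, note = "fewer than 3 conditions"))
        v <- unlist(lapply(vals[ok], `[[`, "mean"))
        r <- tryCatch(crowdingCorrelation(crow[ok], v), error = function(e)
            NA_real_)
        list(r = r,
             note = if (is.na(r)) "correlation refused (constant input)"
                    else NULL)
    }
    groups <- lapply(perCond, function(p) {
        df <- ensemble[ensemble$condition == p$condition & !ensemble$censored,
                       , drop = FALSE]
        df$first_passage
    })
    groups <- groups[vapply(groups, length, 1L) >= 2L]
    tk <- if (length(groups) >= 2L) anovaTukey(groups) else NULL
    list(conditions = perCond,
         searchTimeCorrelation = corOf(lapply(perCond, `[[`, "firstPassage")),
         occupancyCorrelation = corOf(lapply(perCond, `[[`, "occupancy")),
         anovaTukey = tk)
}

#' Write a report: summary tables, JSON and notched boxplots
#'
#' @param summary result of \code{\link{summarizeEnsembles}}.
#' @param dir output directory (created if needed).
#' @param figures also emit notched-boxplot PDFs of the first-passage and
#'   occupancy distributions.
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(summary, dir, figures = TRUE) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rows <- lapply(summary$conditions, function(p) data.frame(
        condition = p$condition, crowding = p$crowding, n = p$n,
        reach_probability = p$reachProbability,
        mean_first_passage = if (is.null(p$firstPassage)) NA_real_
                             else p$firstPassage$mean,
        var_first_passage = if (is.null(p$firstPassage)) NA_real_
                            else p$firstPassage$variance,
        mean_occupancy = p$occupancy$mean,
        var_occupancy = p$occupancy$variance,
        mean_coverage = p$meanCoverage,
        stringsAsFactors = FALSE))
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
    if (figures) {
        plotBoxes(summary, "firstPassageBox",
                  file.path(dir, "first_passage_boxplot.pdf"),
                  "first-passage time (s)")
        plotBoxes(summary, "occupancyBox",
                  file.path(dir, "occupancy_boxplot.pdf"),
                  "occupancy fraction")
    }
    invisible(dir)
}

# render notched boxplots from the precomputed summaries (vector graphics)
plotBoxes <- function(summary, field, path, ylab) {
    boxes <- lapply(summary$conditions, `[[`, field)
    keep <- !vapply(boxes, is.null, TRUE)
    if (!any(keep)) return(invisible(NULL))
    boxes <- boxes[keep]
    z <- list(
        stats = vapply(boxes, function(b)
            c(b$lowerWhisker, b$q1, b$median, b$q3, b$upperWhisker),
            numeric(5)),
        n = vapply(boxes, `[[`, 0, "n"),
        conf = vapply(boxes, function(b) c(b$notchLow, b$notchHigh),
                      numeric(2)),
        out = unlist(lapply(boxes, `[[`, "outliers")),
        group = rep(seq_along(boxes),
                    vapply(boxes, function(b) length(b$outliers), 1L)),
        names = names(boxes))
    grDevices::pdf(path, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    # for very small n the notch can exceed the box; that is expected and
    # only a rendering matter
    suppressWarnings(graphics::bxp(z, notch = TRUE, outpch = 4, ylab = ylab,
                                   las = 2, cex.axis = 0.7))
    invisible(path)
}
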