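#' Construct a genome segment
#'
#' @param seq a character string or \link[Biostrings]{DNAString} over the
#'   alphabet \code{A, C, G, T} (lowercase accepted).
#' @param targetStart 1-based left edge of the target site.
#' @param targetWidth width of the target site in bp (default 21, the lac
#'   \emph{O1} operator width).
#' @param topology \code{"circular"} (default) or \code{"linear"}.
#' @return an \linkS4class{FDGenome}.
#' @examples
#' FDGenome("ACGTACGTACGT", targetStart = 3, targetWidth = 4)
#' @export
FDGenome <- function(seq, targetStart, targetWidth = 21L,
                     topology = c("circular", "linear")) {
    topology <- match.arg(topology)
    if (is.character(seq)) {
        seq <- toupper(seq)
        bad <- gregexpr("[^ACGT]", seq)[[1]]
        if (bad[1] != -1L)
            stop(sprintf(
                "non-ACGT character '%s' at position %d",
                substr(seq, bad[1], bad[1]), bad[1]))
        seq <- Biostrings::DNAString(seq)
    }
    new("FDGenome", seq = seq, targetStart = as.integer(targetStart),
        targetWidth = as.integer(targetWidth), topology = topology)
}

#' Read a genome segment from a FASTA file
#'
#' Reads a single-record FASTA file, uppercases the sequence and rejects any
#' character outside \code{A, C, G, T} (reporting its position).  Target-site
#' coordinates are not part of FASTA and are supplied separately.
#'
#' @param path path to a FASTA file with exactly one record.
#' @inheritParams FDGenome
#' @return an \linkS4class{FDGenome}.
#' @seealso \code{\link{writeGenomeFasta}}
#' @export
readGenomeFasta <- function(path, targetStart, targetWidth = 21L,
                            topology = c("circular", "linear")) {
    if (!file.exists(path)) stop("file not found: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no FASTA record in ", path)
    if (length(set) > 1L)
        stop("expected a single FASTA record, found ", length(set))
    FDGenome(toupper(as.character(set[[1]])), targetStart, targetWidth,
             match.arg(topology))
}

#' Write a genome segment to FASTA
#'
#' @param genome an \linkS4class{FDGenome}.
#' @param path output path.
#' @param name FASTA record name.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genome, path, name = "segment") {
    set <- Biostrings::DNAStringSet(genome@seq)
    names(set) <- name
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Write the target site as a BED interval
#'
#' Emits a single BED line (0-based half-open, per the BED convention) for
#' the genome's target site.
#'
#' @param genome an \linkS4class{FDGenome}.
#' @param path output path.
#' @param chrom chromosome/segment name for the BED line.
#' @param name feature name.
#' @return \code{path}, invisibly.
#' @export
writeTargetBed <- function(genome, path, chrom = "segment", name = "target") {
    line <- sprintf("%s\t%d\t%d\t%s", chrom, genome@targetStart - 1L,
                    genome@targetStart - 1L + genome@targetWidth, name)
    writeLines(line, path)
    invisible(path)
}

#' Target-site sequence of a genome
#'
#' @param genome an \linkS4class{FDGenome}.
#' @return character, the bases under the target site.
#' @export
targetSequence <- function(genome) {
    as.character(Biostrings::subseq(
        genome@seq, genome@targetStart,
        genome@targetStart + genome@targetWidth - 1L))
}
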