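#' Construct a set of genomic intervals
#'
#' The universal coordinate container of the package: a plain data.frame with
#' columns \code{chrom}, \code{start}, \code{end}, \code{name}, \code{score},
#' \code{strand}. Coordinates are 0-based half-open (\code{[start, end)}), the
#' BED convention, everywhere in the package; 1-based inputs (e.g. GTF-style
#' gene tables) are converted on read.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; \code{start < end}.
#' @param name,score,strand optional annotation columns; defaults \code{"."},
#'   \code{0} and \code{"."}.
#' @return a data.frame with the six BED columns.
#' @examples
#' gintervals("chr1", 0, 100, name = "peakA", score = 5, strand = "+")
#' @export
gintervals <- function(chrom, start, end, name = ".", score = 0, strand = ".") {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  name = as.character(name),
                  score = as.numeric(score),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$start) | is.na(x$end)))
    stop("interval coordinates must be non-missing integers")
  if (any(x$start < 0)) stop("interval start must be >= 0")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("empty or inverted interval (start >= end) at row ", bad[1])
  if (any(!nzchar(x$chrom))) stop("chrom must be non-empty")
  invisible(x)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

# internal: 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Read a BED file into an interval table
#'
#' BED3 to BED6 dialects are accepted; absent \code{name}, \code{score} and
#' \code{strand} columns are filled with \code{"."}, \code{0} and \code{"."}.
#'
#' @param path path to a tab-separated BED file.
#' @param n_columns optional expected column count; the file must have at
#'   least this many columns.
#' @return interval data.frame in file order (see [gintervals()]).
#' @export
read_bed <- function(path, n_columns = 3L) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_seen <- lengths(fields)
  if (any(ncol_seen < max(3L, n_columns)))
    stop("malformed BED line ", which(ncol_seen < max(3L, n_columns))[1],
         ": fewer than ", max(3L, n_columns), " columns")
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(get_col(2L, NA)))
  end <- suppressWarnings(as.integer(get_col(3L, NA)))
  bad <- which(is.na(start) | is.na(end) | start < 0)
  if (length(bad)) stop("malformed BED line ", bad[1], ": bad coordinates")
  bad <- which(start >= end)
  if (length(bad)) stop("malformed BED line ", bad[1], ": start >= end")
  score <- suppressWarnings(as.numeric(get_col(5L, "0")))
  score[is.na(score)] <- 0
  gintervals(chrom = get_col(1L, NA), start = start, end = end,
             name = get_col(4L, "."), score = score,
             strand = get_col(6L, "."))
}

#' Write an interval table as BED6
#'
#' @param x interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- x[, c("chrom", "start", "end", "name", "score", "strand")]
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Find overlapping interval pairs
#'
#' Half-open semantics: touching intervals (\code{[0,100)} vs \code{[100,200)})
#' do not overlap. Strand is ignored (regulatory elements are strandless).
#'
#' @param query,subject interval data.frames.
#' @param min_bp minimum shared bases for a pair to be reported (default 1).
#' @return data.frame with columns \code{query}, \code{subject} (row indices).
#' @export
overlap <- function(query, subject, min_bp = 1L) {
  if (!nrow(query) || !nrow(subject))
    return(data.frame(query = integer(), subject = integer()))
  validate_intervals(query); validate_intervals(subject)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                minoverlap = as.integer(min_bp)))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Whole-element subtraction of one interval set from another
#'
#' Returns the elements of \code{setA} with no (>= 1 bp) overlap in
#' \code{setB}. Elements are kept or dropped whole, never clipped: applied to
#' adjacent-stage element sets this yields the stage-specific peaks/SEs.
#'
#' @param setA,setB interval data.frames.
#' @return the rows of \code{setA} that overlap nothing in \code{setB}.
#' @export
subtract_elements <- function(setA, setB) {
  if (!nrow(setA)) return(setA)
  if (!nrow(setB)) return(setA)
  hit <- overlap(setA, setB, min_bp = 1L)
  keep <- setdiff(seq_len(nrow(setA)), unique(hit$query))
  setA[keep, , drop = FALSE]
}

interval_midpoint <- function(x) {
  as.integer(floor((x$start + x$end) / 2))
}
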