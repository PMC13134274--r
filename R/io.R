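#' Construct a binned signal track
#'
#' One value per fixed-width genomic bin, anchored at \code{bin index *
#' bin_size}. Missing data is encoded as \code{NA}, distinct from a true 0.
#'
#' @param chrom chromosome name.
#' @param bin_size bin width in bp (> 0).
#' @param values numeric vector, one value per bin.
#' @return an object of class \code{signal_track}.
#' @export
signal_track <- function(chrom, bin_size, values) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom),
            bin_size > 0)
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 values = as.numeric(values)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", x$chrom, "|", length(x$values), "bins of",
      x$bin_size, "bp |", sum(is.na(x$values)), "NA\n")
  invisible(x)
}

#' Write a signal track as bedGraph
#' @param x a \code{signal_track}.
#' @param path output path.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "signal_track"))
  keep <- !is.na(x$values)
  idx <- which(keep) - 1L
  df <- data.frame(chrom = x$chrom, start = idx * x$bin_size,
                   end = (idx + 1L) * x$bin_size, value = x$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fixed-bin bedGraph into a signal track
#'
#' Only single-chromosome, bin-aligned bedGraphs are supported (the package's
#' own output format); bins absent from the file become \code{NA}.
#'
#' @param path bedGraph path.
#' @param bin_size bin width in bp.
#' @param n_bins total number of bins on the chromosome.
#' @export
read_bedgraph <- function(path, bin_size, n_bins) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  chrom <- unique(df$chrom)
  if (length(chrom) != 1L)
    stop("read_bedgraph expects a single chromosome per file")
  if (any(df$start %% bin_size != 0))
    stop("bedGraph intervals are not aligned to the bin grid")
  v <- rep(NA_real_, n_bins)
  v[df$start %/% bin_size + 1L] <- df$value
  signal_track(chrom, bin_size, v)
}

#' Construct a per-chromosome Hi-C contact matrix
#'
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param counts symmetric non-negative numeric matrix.
#' @param balanced whether iterative proportional balancing was applied.
#' @return an object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(chrom, resolution, counts, balanced = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts))
  if (any(counts < 0, na.rm = TRUE)) stop("negative contact counts")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8)
    stop("contact matrix must be symmetric")
  structure(list(chrom = chrom, resolution = as.integer(resolution),
                 counts = counts, balanced = isTRUE(balanced)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "|", nrow(x$counts), "bins @",
      x$resolution, "bp |", if (x$balanced) "balanced" else "raw", "\n")
  invisible(x)
}

#' Write a contact matrix as upper-triangular COO TSV
#'
#' Columns \code{chrom, bin_i, bin_j, count} (0-based bin indices, i <= j),
#' with a header comment carrying resolution and bin count. Zero entries are
#' omitted.
#'
#' @param x a \code{contact_matrix}.
#' @param path output path.
#' @export
write_contact_matrix <- function(x, path) {
  stopifnot(inherits(x, "contact_matrix"))
  up <- which(upper.tri(x$counts, diag = TRUE) & x$counts != 0,
              arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution=%d n_bins=%d balanced=%d",
                     x$resolution, nrow(x$counts), as.integer(x$balanced)),
             con)
  writeLines("chrom\tbin_i\tbin_j\tcount", con)
  if (nrow(up)) {
    df <- data.frame(chrom = x$chrom, bin_i = up[, 1] - 1L,
                     bin_j = up[, 2] - 1L,
                     count = x$counts[up])
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a COO TSV contact matrix
#'
#' Accepts records with \code{bin_j < bin_i} and mirrors them; duplicate
#' (i, j) records (after mirroring) are an error, as are negative counts.
#'
#' @param path COO TSV path (see [write_contact_matrix()]).
#' @param resolution bin size in bp; taken from the file header when `NULL`.
#' @param n_bins matrix dimension; taken from the header or the maximum bin
#'   index when `NULL`.
#' @export
read_contact_matrix <- function(path, resolution = NULL, n_bins = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[0-9]+", first))[[1]]
    meta <- as.list(setNames(
      as.integer(sub(".*=", "", kv)), sub("=.*", "", kv)))
    resolution <- resolution %||% meta$resolution
    n_bins <- n_bins %||% meta$n_bins
  }
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (is.null(resolution)) stop("resolution not given and absent from header")
  if (!nrow(df)) {
    if (is.null(n_bins)) stop("empty matrix with unknown dimension")
    return(contact_matrix("?", resolution, matrix(0, n_bins, n_bins)))
  }
  chrom <- unique(df$chrom)
  if (length(chrom) != 1L)
    stop("one chromosome per contact-matrix file expected")
  if (any(df$count < 0)) stop("negative contact counts in ", path)
  i <- pmin(df$bin_i, df$bin_j)
  j <- pmax(df$bin_i, df$bin_j)
  if (anyDuplicated(cbind(i, j)))
    stop("duplicate (bin_i, bin_j) records in ", path)
  n_bins <- n_bins %||% (max(j) + 1L)
  m <- matrix(0, n_bins, n_bins)
  m[cbind(i + 1L, j + 1L)] <- df$count
  m[cbind(j + 1L, i + 1L)] <- df$count
  contact_matrix(chrom, resolution, m)
}

#' Construct chromatin loop calls
#'
#' @param chrom chromosome (cis loops only).
#' @param start1,end1,start2,end2 anchor coordinates, 0-based half-open;
#'   anchor1 must not start after anchor2.
#' @param resolution calling resolution in bp.
#' @param score loop score.
#' @param name loop identifier.
#' @return data.frame of class \code{loop_calls}.
#' @export
loop_calls <- function(chrom, start1, end1, start2, end2, resolution,
                       score = 0, name = ".") {
  x <- data.frame(chrom = as.character(chrom),
                  start1 = as.integer(start1), end1 = as.integer(end1),
                  start2 = as.integer(start2), end2 = as.integer(end2),
                  name = as.character(name), score = as.numeric(score),
                  resolution = as.integer(resolution),
                  stringsAsFactors = FALSE)
  if (any(x$start1 > x$start2))
    stop("anchor1 must not start after anchor2")
  if (any(x$start1 >= x$end1 | x$start2 >= x$end2))
    stop("empty loop anchor")
  class(x) <- c("loop_calls", "data.frame")
  x
}

#' Write loops as BEDPE (+ resolution column)
#' @param x \code{loop_calls}.
#' @param path output path.
#' @export
write_bedpe <- function(x, path) {
  df <- data.frame(chrom1 = x$chrom, start1 = x$start1, end1 = x$end1,
                   chrom2 = x$chrom, start2 = x$start2, end2 = x$end2,
                   name = x$name, score = x$score, resolution = x$resolution)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BEDPE loop calls
#' @param path BEDPE path with columns chrom1,start1,end1,chrom2,start2,end2,
#'   name,score,resolution.
#' @export
read_bedpe <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 9L) stop("BEDPE must carry name, score and resolution")
  names(df)[1:9] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score", "resolution")
  if (any(df$chrom1 != df$chrom2)) stop("trans loops are not supported")
  loop_calls(df$chrom1, df$start1, df$end1, df$start2, df$end2,
             df$resolution, df$score, df$name)
}

#' Read DNA sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Construct a position weight matrix
#'
#' @param tf_name transcription-factor name.
#' @param mat L x 4 matrix of base probabilities (columns A, C, G, T); rows
#'   must sum to 1 within 1e-6. A pseudocount keeps all entries positive.
#' @param background length-4 base frequencies summing to 1.
#' @param pseudocount added to all entries before renormalising.
#' @export
pwm <- function(tf_name, mat, background = rep(0.25, 4),
                pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4L, all(mat >= 0),
            abs(sum(background) - 1) < 1e-6)
  if (any(abs(rowSums(mat) - 1) > 1e-6))
    stop("each PWM position must sum to 1")
  mat <- mat + pseudocount
  mat <- mat / rowSums(mat)
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, matrix = mat,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", x$tf_name, "| width", nrow(x$matrix),
      "| consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (per-position argmax base)
#' @param x a \code{pwm}.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[max.col(x$matrix, ties.method = "first")],
        collapse = "")
}

#' Read PWMs from MEME minimal format
#' @param path MEME-minimal motif file.
#' @return named list of \code{pwm} objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  motif_at <- grep("^MOTIF", lines)
  out <- list()
  for (m in motif_at) {
    nm <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    hdr <- m + which(startsWith(trimws(lines[(m + 1):length(lines)]),
                                "letter-probability matrix"))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    # files written by this package already carry a pseudocount; do not
    # add another on read
    out[[nm]] <- pwm(nm, mat, background = bg, pseudocount = 0)
  }
  out
}

#' Write PWMs in MEME minimal format
#' @param pwms list of \code{pwm} objects.
#' @param path output path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       pwms[[1]]$background[1], pwms[[1]]$background[2],
                       pwms[[1]]$background[3], pwms[[1]]$background[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$tf_name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1, function(r)
      sprintf(" %.8f %.8f %.8f %.8f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}
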