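#' Stitch peaks into candidate (super-)enhancer regions
#'
#' ROSE-style stitching: peaks on the same chromosome whose gap is at most
#' \code{stitch_distance} are merged transitively into one region. Region
#' signal is the summed constituent load, \code{sum(width * mean signal)},
#' approximating a read-count rank without alignments. Peaks falling fully
#' within \code{tss_exclusion} bp of a TSS can be removed before stitching
#' (disabled by default).
#'
#' @param peaks interval data.frame; \code{score} is the region-mean signal
#'   of each peak.
#' @param stitch_distance maximum gap to merge across, bp (default 12500).
#' @param tss optional interval data.frame of transcription start sites.
#' @param tss_exclusion exclusion radius around each TSS, bp (0 = off).
#' @return data.frame of stitched regions with columns chrom, start, end,
#'   name, score, strand, constituent_count, signal.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500L, tss = NULL,
                         tss_exclusion = 0L) {
  validate_intervals(peaks)
  if (tss_exclusion > 0L && !is.null(tss) && nrow(tss)) {
    mid <- interval_midpoint(tss)
    zones <- gintervals(tss$chrom, pmax(0L, mid - as.integer(tss_exclusion)),
                        mid + as.integer(tss_exclusion))
    # a peak is excluded when some zone covers it entirely
    hit <- overlap(peaks, zones)
    if (nrow(hit)) {
      covered <- hit[peaks$start[hit$query] >= zones$start[hit$subject] &
                       peaks$end[hit$query] <= zones$end[hit$subject], ]
      if (nrow(covered))
        peaks <- peaks[-unique(covered$query), , drop = FALSE]
    }
  }
  if (!nrow(peaks)) {
    out <- empty_intervals()
    out$constituent_count <- integer()
    out$signal <- numeric()
    return(out)
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  load <- (peaks$end - peaks$start) * peaks$score
  res <- list()
  for (chr in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    l <- load[peaks$chrom == chr]
    grp <- cumsum(c(1L, as.integer(
      p$start[-1] - cummax(p$end[-nrow(p)]) > stitch_distance)))
    grp <- factor(grp, levels = unique(grp))
    res[[chr]] <- data.frame(
      chrom = chr,
      start = as.vector(tapply(p$start, grp, min)),
      end = as.vector(tapply(p$end, grp, max)),
      name = ".", score = as.vector(tapply(l, grp, sum)), strand = ".",
      constituent_count = as.vector(tapply(l, grp, length)),
      signal = as.vector(tapply(l, grp, sum)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out$name <- sprintf("region_%d", seq_len(nrow(out)))
  out
}

#' Rank stitched regions and call supers by the hockey-stick cutoff
#'
#' Regions are sorted by ascending signal; both axes are rescaled to [0, 1]
#' and the cutoff is the point lying furthest below the diagonal — the point
#' where a slope-1 tangent touches the ranked-signal curve. Regions with
#' signal strictly above the cutoff signal are super (ties broken toward
#' fewer supers). With all-equal signals no supers are called, with a
#' warning.
#'
#' @param regions output of [stitch_peaks()] (>= 3 regions).
#' @return \code{regions} with added columns \code{rank} (1 = strongest
#'   signal) and \code{is_super}, and attribute \code{"cutoff_signal"}.
#' @export
rank_and_cut <- function(regions) {
  if (nrow(regions) < 3L) stop("need >= 3 regions to place a cutoff")
  s <- sort(regions$signal)
  n <- length(s)
  if (max(s) == min(s)) {
    warning("all region signals equal; no supers called")
    regions$rank <- rank(-regions$signal, ties.method = "first")
    regions$is_super <- FALSE
    attr(regions, "cutoff_signal") <- max(s)
    return(regions)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  d <- x - y
  cut_idx <- max(which(d == max(d)))   # ties -> higher cutoff, fewer supers
  cutoff <- s[cut_idx]
  regions$rank <- rank(-regions$signal, ties.method = "first")
  regions$is_super <- regions$signal > cutoff
  attr(regions, "cutoff_signal") <- cutoff
  regions
}

#' Call super-enhancers (or super-silencers) from signal peaks
#'
#' Convenience wrapper: [stitch_peaks()] then [rank_and_cut()]. Applied to
#' H3K27ac peaks this yields super-enhancers; the same machinery on
#' H3K27me3 peaks yields super-silencers.
#'
#' @inheritParams stitch_peaks
#' @export
call_super_elements <- function(peaks, stitch_distance = 12500L, tss = NULL,
                                tss_exclusion = 0L) {
  rank_and_cut(stitch_peaks(peaks, stitch_distance, tss, tss_exclusion))
}

#' Stage-specific elements by whole-element subtraction
#'
#' For each stage, keep the elements with no overlap in any other stage's
#' set (the union of all other stages).
#'
#' @param stage_sets named list of interval data.frames, one per stage.
#' @return named list of interval data.frames, same stages.
#' @export
stage_specific_elements <- function(stage_sets) {
  stopifnot(is.list(stage_sets), length(stage_sets) >= 2L)
  out <- lapply(names(stage_sets), function(s) {
    others <- do.call(rbind, lapply(
      stage_sets[setdiff(names(stage_sets), s)],
      function(d) d[, c("chrom", "start", "end", "name", "score", "strand")]))
    subtract_elements(stage_sets[[s]], others)
  })
  names(out) <- names(stage_sets)
  out
}

#' Association between per-gene enhancer count and expression
#'
#' Genes are grouped by enhancer count — Bottom (= 1), Middle (10-20),
#' Top (>= 50) — and their expression distributions summarised, with a
#' one-sided Wilcoxon rank test of Top > Bottom.
#'
#' @param enhancer_counts named integer vector gene -> enhancer count.
#' @param expression named numeric vector gene -> expression (e.g. a stage
#'   mean); names must cover the counted genes.
#' @return list with \code{groups} (per-group expression vectors),
#'   \code{summary} (n/median/mean per group) and \code{p_top_gt_bottom}.
#' @export
enhancer_count_expression <- function(enhancer_counts, expression) {
  stopifnot(all(enhancer_counts >= 0),
            all(names(enhancer_counts) %in% names(expression)))
  grp <- ifelse(enhancer_counts == 1, "Bottom",
                ifelse(enhancer_counts >= 10 & enhancer_counts <= 20, "Middle",
                       ifelse(enhancer_counts >= 50, "Top", NA)))
  groups <- lapply(c(Bottom = "Bottom", Middle = "Middle", Top = "Top"),
                   function(g) unname(expression[names(enhancer_counts)[
                     !is.na(grp) & grp == g]]))
  empty <- vapply(groups, function(v) length(v) == 0L, logical(1))
  if (any(empty)) {
    warning("empty enhancer-count group(s) omitted: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  p <- if (all(c("Top", "Bottom") %in% names(groups)))
    suppressWarnings(wilcox.test(groups$Top, groups$Bottom,
                                 alternative = "greater")$p.value)
  else NA_real_
  summary <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, median, numeric(1)),
    mean = vapply(groups, mean, numeric(1)),
    row.names = NULL)
  list(groups = groups, summary = summary, p_top_gt_bottom = p)
}
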