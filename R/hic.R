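#' Iterative proportional balancing of a contact matrix
#'
#' Simple ICE-style matrix balancing: row/column scaling is iterated until
#' every non-empty bin has (approximately) the same coverage. Empty bins are
#' left untouched and stay at zero.
#'
#' @param x a \code{contact_matrix} (raw counts).
#' @param n_iter maximum iterations (default 20).
#' @param tol convergence tolerance on the coefficient of variation of
#'   non-empty row sums (default 1e-5).
#' @return a balanced \code{contact_matrix}.
#' @export
balance_matrix <- function(x, n_iter = 20L, tol = 1e-5) {
  stopifnot(inherits(x, "contact_matrix"))
  m <- x$counts
  nz <- rowSums(m) > 0
  for (it in seq_len(n_iter)) {
    s <- rowSums(m)
    mu <- mean(s[nz])
    if (mu == 0) break
    cv <- sd(s[nz]) / mu
    if (!is.na(cv) && cv < tol) break
    f <- sqrt(s / mu)
    f[!nz | f == 0] <- 1
    m <- m / outer(f, f)
  }
  contact_matrix(x$chrom, x$resolution, m, balanced = TRUE)
}

#' Fraction of well-covered bins (Hi-C resolution QC)
#'
#' @param x a \code{contact_matrix} of raw counts.
#' @param min_contacts coverage threshold, strict \code{>} (default 1000).
#' @return fraction of bins whose row sum exceeds \code{min_contacts}.
#' @export
resolution_qc <- function(x, min_contacts = 1000L) {
  stopifnot(inherits(x, "contact_matrix"))
  mean(rowSums(x$counts) > min_contacts)
}

#' A/B compartment assignment from the leading correlation eigenvector
#'
#' Observed/expected normalisation by diagonal means, Pearson correlation
#' matrix over informative bins, leading eigenvector; the sign is oriented
#' so that bins positively correlated with \code{orientation_track} (gene
#' density or mean expression) are the active "A" compartment. Zero-coverage
#' bins are labelled NA.
#'
#' @param x a balanced \code{contact_matrix}.
#' @param orientation_track a \code{signal_track} over the same bins.
#' @return data.frame with \code{bin} (0-based), \code{eigen} and
#'   \code{compartment} ("A"/"B"/NA).
#' @export
compartment_eigenvector <- function(x, orientation_track) {
  stopifnot(inherits(x, "contact_matrix"),
            inherits(orientation_track, "signal_track"))
  m <- x$counts
  n <- nrow(m)
  stopifnot(length(orientation_track$values) == n)
  informative <- rowSums(m) > 0
  if (sum(informative) < 20L)
    stop("need >= 20 informative bins for a compartment eigenvector")
  sub <- m[informative, informative, drop = FALSE]
  k <- nrow(sub)
  # observed / expected by distance (diagonal means on the informative grid)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  expd <- as.vector(rowsum(as.vector(sub), as.vector(d))) /
    tabulate(as.vector(d) + 1L, k)
  expm <- matrix(expd[d + 1], k, k)
  oe <- ifelse(expm > 0, sub / expm, 0)
  sds <- apply(oe, 2, sd)
  if (all(sds == 0)) stop("degenerate contact matrix: O/E is constant")
  cc <- suppressWarnings(cor(oe))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  ori <- orientation_track$values[informative]
  if (sd(ev) == 0) {
    warning("constant eigenvector; compartments not separable")
    sgn <- 1
  } else {
    r <- suppressWarnings(cor(ev, ori, use = "complete.obs"))
    sgn <- if (!is.na(r) && r < 0) -1 else 1
  }
  ev <- ev * sgn
  out <- data.frame(bin = 0:(n - 1), eigen = NA_real_,
                    compartment = NA_character_,
                    stringsAsFactors = FALSE)
  out$eigen[informative] <- ev
  out$compartment[informative] <- ifelse(ev >= 0, "A", "B")
  out
}

#' Insulation-score track of a contact matrix
#'
#' For every bin, the mean of the \code{window_bins x window_bins} square of
#' contacts spanning the bin (upstream rows x downstream columns), as
#' log2 ratio to the chromosome mean, z-scored. Bins closer than
#' \code{window_bins} to either end are NA. Dips in this track mark TAD
#' boundaries. Invariant to global scaling of the matrix.
#'
#' @param x a (preferably balanced) \code{contact_matrix}.
#' @param window_bins half-window in bins (default 10, i.e. +/- 200 kb at
#'   20 kb resolution).
#' @return a \code{signal_track} of z-scored log2 insulation.
#' @export
insulation_track <- function(x, window_bins = 10L) {
  stopifnot(inherits(x, "contact_matrix"), window_bins >= 2L)
  m <- x$counts
  n <- nrow(m)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - window_bins < 1L || i + window_bins > n) next
    raw[i] <- mean(m[(i - window_bins):(i - 1L), (i + 1L):(i + window_bins)])
  }
  ok <- !is.na(raw) & raw > 0
  v <- rep(NA_real_, n)
  v[ok] <- log2(raw[ok] / mean(raw[ok]))
  mu <- mean(v[ok]); sg <- sd(v[ok])
  if (!is.na(sg) && sg > 0) v[ok] <- (v[ok] - mu) / sg else v[ok] <- 0
  signal_track(x$chrom, x$resolution, v)
}

# run-length segments of a numeric vector restricted to non-NA stretch
track_segments <- function(v) {
  idx <- which(!is.na(v))
  if (!length(idx)) return(NULL)
  vals <- v[idx]
  brk <- c(TRUE, vals[-1] != vals[-length(vals)] |
             diff(idx) != 1L)
  seg_id <- cumsum(brk)
  data.frame(first = idx[!duplicated(seg_id)],
             last = idx[!duplicated(seg_id, fromLast = TRUE)],
             value = vals[!duplicated(seg_id)])
}

#' Call TAD boundaries as prominent insulation minima
#'
#' Boundaries are local minima of the insulation track whose prominence
#' (the smaller of the rises to the flanking maxima) is at least
#' \code{delta_min} z units. Plateau minima report their leftmost bin.
#'
#' @param insulation a \code{signal_track} from [insulation_track()].
#' @param delta_min minimum prominence in z units (default 0.1).
#' @return data.frame with \code{chrom}, \code{bin} (0-based) and
#'   \code{insulation_z}.
#' @export
call_boundaries <- function(insulation, delta_min = 0.1) {
  stopifnot(inherits(insulation, "signal_track"))
  v <- insulation$values
  seg <- track_segments(v)
  out <- data.frame(chrom = character(), bin = integer(),
                    insulation_z = numeric(), stringsAsFactors = FALSE)
  if (is.null(seg) || nrow(seg) < 3L) return(out)
  ns <- nrow(seg)
  keep <- integer()
  for (j in 2:(ns - 1L)) {
    if (seg$last[j - 1] + 1L != seg$first[j] ||
        seg$last[j] + 1L != seg$first[j + 1]) next  # NA gap: not a minimum
    if (!(seg$value[j] < seg$value[j - 1] && seg$value[j] < seg$value[j + 1]))
      next
    vj <- seg$value[j]
    # prominence: highest value reached before falling below vj, each side
    rise_left <- 0
    for (k in seq(j - 1L, 1L)) {
      if (seg$value[k] < vj) break
      rise_left <- max(rise_left, seg$value[k] - vj)
    }
    rise_right <- 0
    for (k in seq(j + 1L, ns)) {
      if (seg$value[k] < vj) break
      rise_right <- max(rise_right, seg$value[k] - vj)
    }
    if (min(rise_left, rise_right) >= delta_min) keep <- c(keep, j)
  }
  if (length(keep))
    out <- data.frame(chrom = insulation$chrom,
                      bin = seg$first[keep] - 1L,
                      insulation_z = seg$value[keep],
                      stringsAsFactors = FALSE)
  out
}

#' Spearman similarity of two tracks around a boundary
#'
#' Correlates the (2 * flank_bins + 1)-bin windows of two insulation tracks
#' centred on the same boundary bin; NA bins are dropped pairwise and at
#' least 11 valid pairs are required.
#'
#' @param boundary_bin 0-based bin index of the boundary.
#' @param trackA,trackB \code{signal_track}s on the same bin grid.
#' @param flank_bins bins on each side of the boundary (default 10).
#' @return Spearman rho, or NA when the window is unusable.
#' @export
boundary_similarity <- function(boundary_bin, trackA, trackB,
                                flank_bins = 10L) {
  i <- boundary_bin + 1L
  n <- length(trackA$values)
  stopifnot(length(trackB$values) == n)
  if (i - flank_bins < 1L || i + flank_bins > n) {
    warning("boundary window extends past the track; returning NA")
    return(NA_real_)
  }
  w <- (i - flank_bins):(i + flank_bins)
  a <- trackA$values[w]; b <- trackB$values[w]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 11L) {
    warning("fewer than 11 valid window pairs; returning NA")
    return(NA_real_)
  }
  suppressWarnings(cor(a[ok], b[ok], method = "spearman"))
}

#' Null distribution of boundary-window similarity
#'
#' Spearman rhos of windows centred on uniformly sampled valid bins (the
#' same bin in both tracks), emulating randomly placed boundaries.
#' Deterministic given \code{seed}.
#'
#' @inheritParams boundary_similarity
#' @param n_perm number of random windows (default 1000).
#' @param seed integer seed (required).
#' @return numeric vector of rhos (NAs from degenerate windows removed).
#' @export
boundary_null <- function(trackA, trackB, n_perm = 1000L, flank_bins = 10L,
                          seed) {
  stopifnot(!missing(seed))
  n <- length(trackA$values)
  valid <- which(vapply(seq_len(n), function(i) {
    if (i - flank_bins < 1L || i + flank_bins > n) return(FALSE)
    w <- (i - flank_bins):(i + flank_bins)
    sum(!is.na(trackA$values[w]) & !is.na(trackB$values[w])) >= 11L
  }, logical(1)))
  if (!length(valid)) stop("tracks too short for any boundary window")
  set.seed(seed)
  centers <- sample(valid, n_perm, replace = TRUE)
  rhos <- vapply(centers, function(i)
    suppressWarnings(boundary_similarity(i - 1L, trackA, trackB,
                                         flank_bins)), numeric(1))
  rhos[!is.na(rhos)]
}

#' Classify stage-specific TAD boundaries
#'
#' A boundary of stage s is specific iff (1) no boundary of any adjacent
#' stage falls within \code{match_tolerance_bins} bins of it, and (2) its
#' window similarity ([boundary_similarity()]) to every adjacent stage's
#' insulation track does not exceed that stage pair's permutation-null
#' \code{alpha_quantile} ([boundary_null()]).
#'
#' @param stage_boundaries named list (stage -> data.frame from
#'   [call_boundaries()]).
#' @param tracks named list (stage -> insulation \code{signal_track}).
#' @param stage_order character vector giving stage adjacency.
#' @param match_tolerance_bins bin tolerance for criterion 1 (default 1).
#' @param alpha_quantile null quantile for criterion 2 (default 0.95).
#' @param n_perm permutations per stage pair (default 1000).
#' @param flank_bins window half-width (default 10).
#' @param seed integer seed (required).
#' @return data.frame: stage, bin, insulation_z, crit_unique, crit_rho,
#'   specific; attribute \code{"null_quantiles"} maps "s|t" -> quantile.
#' @export
classify_specific_boundaries <- function(stage_boundaries, tracks,
                                         stage_order = names(tracks),
                                         match_tolerance_bins = 1L,
                                         alpha_quantile = 0.95,
                                         n_perm = 1000L, flank_bins = 10L,
                                         seed) {
  stopifnot(!missing(seed), all(stage_order %in% names(tracks)),
            all(stage_order %in% names(stage_boundaries)))
  adj <- function(s) {
    i <- match(s, stage_order)
    stage_order[c(i - 1L, i + 1L)[c(i - 1L, i + 1L) >= 1L &
                                    c(i - 1L, i + 1L) <= length(stage_order)]]
  }
  nullq <- list()
  for (s in stage_order) for (t in adj(s)) {
    key <- paste(s, t, sep = "|")
    if (is.null(nullq[[key]])) {
      rhos <- boundary_null(tracks[[s]], tracks[[t]], n_perm = n_perm,
                            flank_bins = flank_bins,
                            seed = substream_seed(seed, paste0("null:",
                              paste(sort(c(s, t)), collapse = "|"))))
      nullq[[key]] <- as.numeric(quantile(rhos, alpha_quantile))
    }
  }
  rows <- list()
  for (s in stage_order) {
    b <- stage_boundaries[[s]]
    if (!nrow(b)) next
    crit1 <- crit2 <- logical(nrow(b))
    for (r in seq_len(nrow(b))) {
      ok1 <- TRUE; ok2 <- TRUE
      for (t in adj(s)) {
        if (any(abs(stage_boundaries[[t]]$bin - b$bin[r]) <=
                  match_tolerance_bins)) ok1 <- FALSE
        rho <- suppressWarnings(boundary_similarity(
          b$bin[r], tracks[[s]], tracks[[t]], flank_bins))
        q <- nullq[[paste(s, t, sep = "|")]]
        if (is.na(rho) || rho > q) ok2 <- FALSE
      }
      crit1[r] <- ok1; crit2[r] <- ok2
    }
    rows[[s]] <- data.frame(stage = s, bin = b$bin,
                            insulation_z = b$insulation_z,
                            crit_unique = crit1, crit_rho = crit2,
                            specific = crit1 & crit2,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(), bin = integer(),
               insulation_z = numeric(), crit_unique = logical(),
               crit_rho = logical(), specific = logical())
  rownames(out) <- NULL
  attr(out, "null_quantiles") <- unlist(nullq)
  out
}

#' TAD intervals from a boundary bin list
#'
#' Consecutive boundaries (plus the chromosome ends) delimit TADs.
#'
#' @param boundary_bins 0-based boundary bin indices.
#' @param n_bins number of bins on the chromosome.
#' @param resolution bin size, bp.
#' @param chrom chromosome name.
#' @return interval data.frame of TADs.
#' @export
tads_from_boundaries <- function(boundary_bins, n_bins, resolution, chrom) {
  cuts <- sort(unique(c(0L, as.integer(boundary_bins), n_bins)))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  keep <- ends > starts
  gintervals(chrom, starts[keep] * resolution, ends[keep] * resolution,
             name = sprintf("%s_tad_%d", chrom, seq_len(sum(keep))))
}

#' Mean intra-TAD contact strength
#'
#' Per TAD, the mean contact among the bins inside the TAD, excluding the
#' diagonal. TADs spanning fewer than 2 bins return NA.
#'
#' @param x a \code{contact_matrix}.
#' @param tads interval data.frame on the same chromosome.
#' @return numeric vector, one strength per TAD.
#' @export
intra_tad_strength <- function(x, tads) {
  stopifnot(inherits(x, "contact_matrix"))
  res <- x$resolution
  n <- nrow(x$counts)
  vapply(seq_len(nrow(tads)), function(r) {
    i0 <- tads$start[r] %/% res + 1L
    i1 <- min((tads$end[r] - 1L) %/% res + 1L, n)
    if (i1 - i0 + 1L < 2L) return(NA_real_)
    sub <- x$counts[i0:i1, i0:i1]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
}

#' Merge loop calls across resolutions
#'
#' Each anchor is re-binned to \code{merge_resolution} by its midpoint;
#' loops identical after re-binning collapse to a single call keeping the
#' maximum score. Idempotent.
#'
#' @param loop_sets a \code{loop_calls} data.frame or list of them.
#' @param merge_resolution target bin size, bp (default 25000).
#' @return merged \code{loop_calls} with merge_resolution-sized anchors.
#' @export
merge_loops <- function(loop_sets, merge_resolution = 25000L) {
  if (is.data.frame(loop_sets)) loop_sets <- list(loop_sets)
  all <- do.call(rbind, lapply(loop_sets, as.data.frame))
  if (!nrow(all))
    return(loop_calls(character(), integer(), integer(), integer(),
                      integer(), integer()))
  b1 <- ((all$start1 + all$end1) %/% 2L) %/% merge_resolution
  b2 <- ((all$start2 + all$end2) %/% 2L) %/% merge_resolution
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  key <- paste(all$chrom, lo, hi)
  best <- tapply(seq_len(nrow(all)), key, function(idx)
    idx[which.max(all$score[idx])])
  best <- sort(unname(unlist(best)))
  loop_calls(all$chrom[best],
             lo[best] * merge_resolution, (lo[best] + 1L) * merge_resolution,
             hi[best] * merge_resolution, (hi[best] + 1L) * merge_resolution,
             resolution = merge_resolution, score = all$score[best],
             name = sprintf("loop_%d", seq_along(best)))
}

#' Promoter windows around gene TSSs
#'
#' @param genes data.frame with columns chrom, tss (bp) and gene_id.
#' @param flank promoter half-width in bp (default 2000).
#' @return interval data.frame named by gene_id.
#' @export
make_promoters <- function(genes, flank = 2000L) {
  gintervals(genes$chrom, pmax(0L, genes$tss - as.integer(flank)),
             genes$tss + as.integer(flank), name = genes$gene_id)
}

#' Link enhancers to genes through merged loop anchors
#'
#' A pair is emitted when one anchor of a loop overlaps an enhancer and the
#' other anchor overlaps a promoter (>= 1 bp each). Features on the same
#' anchor only are not linked.
#'
#' @param loops merged \code{loop_calls}.
#' @param enhancers interval data.frame (names identify enhancers).
#' @param promoters interval data.frame from [make_promoters()] (names are
#'   gene ids).
#' @return data.frame: enhancer, gene_id, loop_id, distance (bp between the
#'   enhancer midpoint and the promoter centre).
#' @export
link_distal <- function(loops, enhancers, promoters) {
  empty <- data.frame(enhancer = character(), gene_id = character(),
                      loop_id = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(loops) || !nrow(enhancers) || !nrow(promoters)) return(empty)
  a1 <- gintervals(loops$chrom, loops$start1, loops$end1, name = loops$name)
  a2 <- gintervals(loops$chrom, loops$start2, loops$end2, name = loops$name)
  pair_up <- function(anch_e, anch_p) {
    he <- overlap(anch_e, enhancers)
    hp <- overlap(anch_p, promoters)
    m <- merge(he, hp, by = "query", suffixes = c("_e", "_p"))
    if (!nrow(m)) return(empty)
    tssm <- interval_midpoint(promoters)[m$subject_p]
    enhm <- interval_midpoint(enhancers)[m$subject_e]
    data.frame(enhancer = enhancers$name[m$subject_e],
               gene_id = promoters$name[m$subject_p],
               loop_id = loops$name[m$query],
               distance = abs(enhm - tssm),
               stringsAsFactors = FALSE)
  }
  out <- rbind(pair_up(a1, a2), pair_up(a2, a1))
  out <- out[!duplicated(out[, c("enhancer", "gene_id", "loop_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
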