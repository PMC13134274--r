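#' Stage ordering of duck granulosa-cell folliculogenesis
#'
#' The seven ordered follicle stages: small white (SWF), large white (LWF),
#' small yellow (SYF) prehierarchical follicles, the F5/F3/F1 hierarchical
#' follicles, and the postovulatory follicle (POF).
#' @export
FOLLICLE_STAGES <- c("SWF", "LWF", "SYF", "F5", "F3", "F1", "POF")

#' Construct a stage-labelled expression matrix
#'
#' @param values genes x samples matrix of non-negative normalised
#'   abundances; rownames are gene ids, colnames sample ids.
#' @param stage_of_sample named character vector mapping sample id -> stage
#'   label; when `NULL`, stages are parsed from sample ids of the form
#'   \code{"STAGE_rep"}.
#' @param stage_order ordered stage labels (default [FOLLICLE_STAGES]).
#' @return an object of class \code{expr_matrix}.
#' @export
expr_matrix <- function(values, stage_of_sample = NULL,
                        stage_order = FOLLICLE_STAGES) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (is.null(stage_of_sample))
    stage_of_sample <- setNames(sub("_[^_]+$", "", colnames(values)),
                                colnames(values))
  stage_of_sample <- stage_of_sample[colnames(values)]
  if (any(is.na(stage_of_sample)))
    stop("every sample needs a stage label")
  stage_order <- stage_order[stage_order %in% stage_of_sample]
  structure(list(values = values,
                 stage_of_sample = stage_of_sample,
                 stage_order = stage_order),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples |", length(x$stage_order), "stages:",
      paste(x$stage_order, collapse = " "), "\n")
  invisible(x)
}

#' Per-stage mean expression
#' @param expr an \code{expr_matrix}.
#' @param log2p1 average on the log2(x + 1) scale instead of linear.
#' @return genes x stages matrix of replicate means.
#' @export
stage_means <- function(expr, log2p1 = FALSE) {
  v <- expr$values
  if (log2p1) v <- log2(v + 1)
  out <- sapply(expr$stage_order, function(s)
    rowMeans(v[, expr$stage_of_sample == s, drop = FALSE]))
  rownames(out) <- rownames(expr$values)
  out
}

#' Write / read an expression matrix as TSV
#' @param expr an \code{expr_matrix}.
#' @param path TSV path (rows genes, columns "STAGE_rep" sample ids).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @param stage_order ordered stage labels.
#' @export
read_expression <- function(path, stage_order = FOLLICLE_STAGES) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, stage_order = stage_order)
}

#' Stage-wise differential expression
#'
#' Per-gene Welch two-sample t-test on log2(x + 1) replicate values between
#' two stages, Benjamini-Hochberg adjusted across all genes. A gene is called
#' up (down) when \code{fdr < fdr_max} and \code{log2fc} exceeds
#' \code{lfc_min} in magnitude; the fold change is computed on stage means
#' with a pseudocount of 1, so stages with zero expression are admissible.
#'
#' @param expr an \code{expr_matrix}.
#' @param stageA,stageB stage labels; log2fc is B over A.
#' @param lfc_min minimum |log2 fold change| (default 1, strict inequality;
#'   set \code{lfc_strict = FALSE} for >=).
#' @param fdr_max BH-adjusted significance level (default 0.05).
#' @param lfc_strict use strict > for the fold-change threshold.
#' @return data.frame: gene_id, log2fc, p, fdr, direction (up/down/ns).
#' @export
call_degs <- function(expr, stageA, stageB, lfc_min = 1, fdr_max = 0.05,
                      lfc_strict = TRUE) {
  a_cols <- which(expr$stage_of_sample == stageA)
  b_cols <- which(expr$stage_of_sample == stageB)
  if (length(a_cols) < 2L || length(b_cols) < 2L)
    stop("both stages need >= 2 replicates")
  la <- log2(expr$values[, a_cols, drop = FALSE] + 1)
  lb <- log2(expr$values[, b_cols, drop = FALSE] + 1)
  p <- welch_p(la, lb)
  log2fc <- log2(rowMeans(expr$values[, b_cols, drop = FALSE]) + 1) -
    log2(rowMeans(expr$values[, a_cols, drop = FALSE]) + 1)
  fdr <- p.adjust(p, method = "BH")
  pass_fc <- if (lfc_strict) abs(log2fc) > lfc_min else abs(log2fc) >= lfc_min
  direction <- ifelse(fdr < fdr_max & pass_fc,
                      ifelse(log2fc > 0, "up", "down"), "ns")
  data.frame(gene_id = rownames(expr$values), log2fc = log2fc, p = p,
             fdr = fdr, direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

# vectorised Welch t-test p-values over matrix rows; degenerate rows
# (both groups constant) get p = 1 when means agree, p = 0 otherwise.
welch_p <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  unname(p)
}

#' Fisher's exact test on DEG proportions of two stage transitions
#'
#' Two-sided exact hypergeometric p-value for the 2x2 table of DEG vs non-DEG
#' counts in two transitions.
#'
#' @param k1,n1 DEG count and total genes in transition 1.
#' @param k2,n2 same for transition 2.
#' @return two-sided exact p-value.
#' @export
deg_proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  fisher.test(tab)$p.value
}

# k-means++ seeding: spread initial centres by squared-distance sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) == 0) rep(1 / n, n) else d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
    dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

#' Cluster genes by their stage expression profile
#'
#' Rows are per-gene stage means, z-scored per gene (zero-variance genes get
#' sigma = 1 so they fall to the nearest centroid rather than erroring), then
#' k-means with k-means++ seeding, best of \code{restarts} runs by total
#' within-cluster sum of squares. Deterministic under a fixed seed.
#'
#' @param expr an \code{expr_matrix}.
#' @param genes subset of gene ids to cluster (default all).
#' @param k number of clusters (default 8).
#' @param restarts independent initialisations (default 50).
#' @param seed integer seed (required).
#' @return named integer vector gene -> cluster in 1..k, with attribute
#'   \code{"centers"} and \code{"tot_withinss"}.
#' @export
cluster_stage_profiles <- function(expr, genes = NULL, k = 8L,
                                   restarts = 50L, seed) {
  stopifnot(!missing(seed))
  sm <- stage_means(expr, log2p1 = TRUE)
  if (!is.null(genes)) {
    stopifnot(all(genes %in% rownames(sm)))
    sm <- sm[genes, , drop = FALSE]
  }
  if (k > nrow(sm)) stop("k exceeds the number of genes")
  mu <- rowMeans(sm)
  sg <- apply(sm, 1, sd)
  sg[sg == 0] <- 1
  z <- (sm - mu) / sg
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- suppressWarnings(
      kmeans(z, centers = kmeanspp_centers(z, k), iter.max = 100L,
             algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  out <- setNames(best$cluster, rownames(z))
  attr(out, "centers") <- best$centers
  attr(out, "tot_withinss") <- best$tot.withinss
  out
}

#' Stage-specificity index (tau)
#'
#' tau = sum_i (1 - x_i / x_max) / (n - 1) on log2(x + 1) stage means:
#' 0 for a flat profile, 1 for single-stage expression. All-zero profiles
#' return 0 by convention.
#'
#' @param x non-negative per-stage expression vector (>= 2 stages).
#' @param log2p1 apply the log2(x + 1) transform first (default TRUE; set
#'   FALSE when x is already on a log-like scale).
#' @return tau in [0, 1].
#' @export
tsi <- function(x, log2p1 = TRUE) {
  stopifnot(length(x) >= 2L)
  if (any(x < 0)) stop("tsi requires non-negative input")
  if (all(x == 0)) return(0)
  if (log2p1) x <- log2(x + 1)
  sum(1 - x / max(x)) / (length(x) - 1)
}

#' Cliff's delta effect size
#'
#' (#\{a > b\} - #\{a < b\}) / (|A||B|) over all cross pairs; in [-1, 1],
#' antisymmetric in its arguments.
#'
#' @param sampleA,sampleB non-empty numeric vectors.
#' @export
cliffs_delta <- function(sampleA, sampleB) {
  stopifnot(length(sampleA) > 0L, length(sampleB) > 0L)
  d <- outer(sampleA, sampleB, "-")
  mean(sign(d))
}
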