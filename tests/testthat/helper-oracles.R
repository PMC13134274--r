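# brute-force oracles, kept deliberately independent of the package's
# implementations: everything here is a direct quadratic scan or a full
# enumeration on small inputs

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start,
             start + sample.int(max_len, n, replace = TRUE),
             name = sprintf("iv%d", seq_len(n)),
             score = round(runif(n, 0, 10), 2))
}

overlap_bp <- function(a_start, a_end, b_start, b_end) {
  max(0, min(a_end, b_end) - max(a_start, b_start))
}

oracle_overlap <- function(query, subject, min_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] != subject$chrom[j]) next
    if (overlap_bp(query$start[i], query$end[i],
                   subject$start[j], subject$end[j]) >= min_bp)
      out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(), subject = integer()))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

oracle_subtract <- function(setA, setB) {
  keep <- vapply(seq_len(nrow(setA)), function(i) {
    !any(vapply(seq_len(nrow(setB)), function(j)
      setA$chrom[i] == setB$chrom[j] &&
        overlap_bp(setA$start[i], setA$end[i],
                   setB$start[j], setB$end[j]) >= 1, logical(1)))
  }, logical(1))
  setA[keep, , drop = FALSE]
}

# transitive-closure merge of peaks with gaps <= stitch_distance
oracle_stitch_groups <- function(peaks, stitch_distance) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || peaks$chrom[i] != peaks$chrom[j]) next
    gap <- max(peaks$start[i], peaks$start[j]) -
      min(peaks$end[i], peaks$end[j])
    if (gap <= stitch_distance) {
      ri <- find(i); rj <- find(j)
      parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# all-pairs binned-equality loop merging
oracle_merge_loops <- function(loops, merge_resolution) {
  b1 <- ((loops$start1 + loops$end1) %/% 2) %/% merge_resolution
  b2 <- ((loops$start2 + loops$end2) %/% 2) %/% merge_resolution
  key <- paste(loops$chrom, pmin(b1, b2), pmax(b1, b2))
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    out[[k]] <- c(sort(c(b1[idx[1]], b2[idx[1]])), max(loops$score[idx]))
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# two-sided Fisher p by full enumeration over tables with fixed margins
oracle_fisher2x2 <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  probs <- vapply(0:K, function(x) {
    if (x > n1 || K - x > n2) return(0)
    choose(n1, x) * choose(n2, K - x)
  }, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[k1 + 1]
  sum(probs[probs <= p_obs + 1e-12])
}

# one-sided hypergeometric tail by direct summation
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}

# distinct TF->gene path count by explicit double loop
oracle_path_count <- function(tf_enh, enh_gene) {
  paths <- character(0)
  for (i in seq_len(nrow(tf_enh))) for (j in seq_len(nrow(enh_gene))) {
    if (tf_enh$enhancer[i] == enh_gene$enhancer[j])
      paths <- c(paths, paste(tf_enh$tf[i], enh_gene$gene_id[j]))
  }
  length(unique(paths))
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# a small cached default synthetic dataset shared across test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(seed = 20260922)
    cache
  }
})

# one full pipeline run on the shared dataset, cached across test files
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_pipeline(shared_sim(), default_run_params(seed = 777))
    cache
  }
})
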