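#' TAD-constrained enhancer-gene correlation
#'
#' Every (enhancer, gene) pair whose enhancer midpoint and gene TSS fall in
#' the same TAD is tested by the Pearson correlation of their per-stage
#' activity profiles; p-values come from the exact t transform with n - 2
#' degrees of freedom and are Benjamini-Hochberg adjusted across all tested
#' pairs genome-wide. Pairs with a constant signal or expression vector are
#' skipped (r undefined) and counted in the attributes.
#'
#' @param enh_signal enhancers x stages matrix of per-stage signal means
#'   (rownames are enhancer names).
#' @param enhancers interval data.frame whose \code{name} column matches
#'   \code{rownames(enh_signal)}.
#' @param expr_means genes x stages matrix of per-stage expression means
#'   (same stage columns as \code{enh_signal}).
#' @param gene_tss data.frame with chrom, tss, gene_id.
#' @param tads interval data.frame of TADs (names are TAD ids).
#' @param fdr_max BH threshold for retained pairs (default 0.05).
#' @param keep_all return all tested pairs instead of only significant ones.
#' @return data.frame: enhancer, gene_id, tad_id, pearson_r, p, fdr,
#'   distance_bp, mode ("proximal_in_tad"); attributes \code{n_tested} and
#'   \code{n_skipped_constant}.
#' @export
correlate_in_tad <- function(enh_signal, enhancers, expr_means, gene_tss,
                             tads, fdr_max = 0.05, keep_all = FALSE) {
  stages <- intersect(colnames(enh_signal), colnames(expr_means))
  if (length(stages) < 3L) stop("need >= 3 shared stages to correlate")
  enh_signal <- enh_signal[, stages, drop = FALSE]
  expr_means <- expr_means[, stages, drop = FALSE]
  emid <- interval_midpoint(enhancers)
  epts <- gintervals(enhancers$chrom, emid, emid + 1L, name = enhancers$name)
  gpts <- gintervals(gene_tss$chrom, gene_tss$tss, gene_tss$tss + 1L,
                     name = gene_tss$gene_id)
  he <- overlap(epts, tads)
  hg <- overlap(gpts, tads)
  pairs <- merge(he, hg, by = "subject", suffixes = c("_e", "_g"))
  if (!nrow(pairs))
    return(structure(data.frame(), n_tested = 0L, n_skipped_constant = 0L))
  es <- enh_signal[enhancers$name[pairs$query_e], , drop = FALSE]
  gs <- expr_means[gene_tss$gene_id[pairs$query_g], , drop = FALSE]
  n <- length(stages)
  const <- apply(es, 1, sd) == 0 | apply(gs, 1, sd) == 0
  r <- rep(NA_real_, nrow(pairs))
  ok <- !const
  if (any(ok)) {
    ze <- t(scale(t(es[ok, , drop = FALSE])))
    zg <- t(scale(t(gs[ok, , drop = FALSE])))
    r[ok] <- rowSums(ze * zg) / (n - 1)
  }
  r <- pmin(1, pmax(-1, r))
  t_stat <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * pt(-abs(t_stat), n - 2)
  out <- data.frame(
    enhancer = enhancers$name[pairs$query_e],
    gene_id = gene_tss$gene_id[pairs$query_g],
    tad_id = tads$name[pairs$subject],
    pearson_r = r, p = p, fdr = NA_real_,
    distance_bp = abs(emid[pairs$query_e] - gene_tss$tss[pairs$query_g]),
    mode = "proximal_in_tad", stringsAsFactors = FALSE)
  out <- out[!const, , drop = FALSE]
  out$fdr <- p.adjust(out$p, method = "BH")
  n_tested <- nrow(out)
  if (!keep_all) out <- out[out$fdr < fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tested = n_tested,
            n_skipped_constant = sum(const))
}

#' Assemble a tripartite TF-Enhancer-Target regulatory network
#'
#' @param tf_enh data.frame with columns tf, enhancer (e.g.
#'   \code{motif_enrichment()$pairs}).
#' @param enh_gene data.frame with columns enhancer, gene_id (e.g. from
#'   [correlate_in_tad()] or [link_distal()]).
#' @return object of class \code{reg_network}: the two edge layers plus the
#'   derived TF-enhancer-gene triples and distinct TF->gene paths.
#' @export
assemble_grn <- function(tf_enh, enh_gene) {
  stopifnot(all(c("tf", "enhancer") %in% names(tf_enh)),
            all(c("enhancer", "gene_id") %in% names(enh_gene)))
  tf_enh <- tf_enh[!duplicated(tf_enh[, c("tf", "enhancer")]), , drop = FALSE]
  enh_gene <- enh_gene[!duplicated(enh_gene[, c("enhancer", "gene_id")]), ,
                       drop = FALSE]
  triples <- merge(tf_enh[, c("tf", "enhancer")],
                   enh_gene[, c("enhancer", "gene_id")], by = "enhancer")
  triples <- triples[, c("tf", "enhancer", "gene_id")]
  paths <- unique(triples[, c("tf", "gene_id")])
  rownames(triples) <- rownames(paths) <- NULL
  structure(list(tf_enh = tf_enh, enh_gene = enh_gene, triples = triples,
                 paths = paths,
                 tfs = sort(unique(tf_enh$tf)),
                 enhancers = sort(unique(c(tf_enh$enhancer,
                                           enh_gene$enhancer))),
                 genes = sort(unique(enh_gene$gene_id))),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat("reg_network:", length(x$tfs), "TFs,", length(x$enhancers),
      "enhancers,", length(x$genes), "genes |",
      nrow(x$tf_enh), "TF->E edges,", nrow(x$enh_gene), "E->G edges,",
      nrow(x$paths), "TF->gene paths\n")
  invisible(x)
}

#' @export
summary.reg_network <- function(object, ...) {
  c(n_tfs = length(object$tfs), n_enhancers = length(object$enhancers),
    n_genes = length(object$genes), n_tf_enh = nrow(object$tf_enh),
    n_enh_gene = nrow(object$enh_gene), n_paths = nrow(object$paths))
}

#' Distinct TF->gene paths of a network
#' @param grn a \code{reg_network}.
#' @export
grn_paths <- function(grn) grn$paths

#' Network stability under random edge removal
#'
#' Per trial, \code{floor(removal_fraction * E)} of the network's edges
#' (both layers pooled) are removed uniformly at random; the trial score is
#' the fraction of the original TF->gene paths still connected through some
#' surviving enhancer route. The stability score is the mean over trials.
#'
#' @param grn a \code{reg_network} with >= 10 edges.
#' @param removal_fraction fraction of edges removed per trial, in (0, 1).
#' @param trials number of random removals (default 100).
#' @param seed integer seed (required).
#' @return list: stability_score, trial_scores, removal_fraction, trials,
#'   n_edges, seed.
#' @export
stability_score <- function(grn, removal_fraction = 0.1, trials = 100L,
                            seed) {
  stopifnot(!missing(seed), inherits(grn, "reg_network"))
  if (removal_fraction <= 0 || removal_fraction >= 1)
    stop("removal_fraction must lie in (0, 1)")
  e1 <- nrow(grn$tf_enh); e2 <- nrow(grn$enh_gene)
  E <- e1 + e2
  if (E < 10L) stop("network too small (< 10 edges)")
  key1 <- paste(grn$tf_enh$tf, grn$tf_enh$enhancer)
  key2 <- paste(grn$enh_gene$enhancer, grn$enh_gene$gene_id)
  tri_e1 <- match(paste(grn$triples$tf, grn$triples$enhancer), key1)
  tri_e2 <- match(paste(grn$triples$enhancer, grn$triples$gene_id), key2) + e1
  path_of_triple <- match(paste(grn$triples$tf, grn$triples$gene_id),
                          paste(grn$paths$tf, grn$paths$gene_id))
  n_paths <- nrow(grn$paths)
  n_rm <- floor(removal_fraction * E)
  set.seed(seed)
  scores <- vapply(seq_len(trials), function(tr) {
    removed <- sample.int(E, n_rm)
    alive <- !(tri_e1 %in% removed) & !(tri_e2 %in% removed)
    length(unique(path_of_triple[alive])) / n_paths
  }, numeric(1))
  list(stability_score = mean(scores), trial_scores = scores,
       removal_fraction = removal_fraction, trials = trials,
       n_edges = E, seed = seed)
}

# degree-preserving double-edge swaps on one bipartite layer
rewire_layer <- function(a, b, n_swaps) {
  E <- length(a)
  if (E < 2L) return(list(a = a, b = b))
  keys <- paste(a, b)
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(E, 2L)
    i <- ij[1]; j <- ij[2]
    if (a[i] == a[j] || b[i] == b[j]) next
    k1 <- paste(a[i], b[j]); k2 <- paste(a[j], b[i])
    if (k1 %in% keys || k2 %in% keys) next
    keys[i] <- k1; keys[j] <- k2
    tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
  }
  list(a = a, b = b)
}

#' Permutation test of network wiring against degree-matched nulls
#'
#' Null networks are produced by degree-preserving double-edge swaps within
#' each bipartite layer (\code{swap_factor * E} attempted swaps per layer
#' per replicate), isolating the wiring from the degree sequence. The test
#' statistic is the number of distinct TF->gene paths and
#' \code{p = (1 + #\{null >= observed\}) / (n_perm + 1)}.
#'
#' @param grn a \code{reg_network}.
#' @param n_perm number of null replicates (default 1000).
#' @param seed integer seed (required).
#' @param swap_factor attempted swaps per edge (default 10).
#' @return list: p, observed, null (vector of null statistics), n_perm,
#'   seed.
#' @export
permutation_test <- function(grn, n_perm = 1000L, seed, swap_factor = 10L) {
  stopifnot(!missing(seed), inherits(grn, "reg_network"))
  if (nrow(grn$tf_enh) < 2L || nrow(grn$enh_gene) < 2L) {
    warning("layers too small to rewire; returning NA")
    return(list(p = NA_real_, observed = nrow(grn$paths),
                null = numeric(0), n_perm = n_perm, seed = seed))
  }
  obs <- nrow(grn$paths)
  a1 <- grn$tf_enh$tf; b1 <- grn$tf_enh$enhancer
  a2 <- grn$enh_gene$enhancer; b2 <- grn$enh_gene$gene_id
  deg <- function(v) sort(table(v))
  d_a1 <- deg(a1); d_b1 <- deg(b1); d_a2 <- deg(a2); d_b2 <- deg(b2)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(r) {
    l1 <- rewire_layer(a1, b1, swap_factor * length(a1))
    l2 <- rewire_layer(a2, b2, swap_factor * length(a2))
    stopifnot(identical(deg(l1$a), d_a1), identical(deg(l1$b), d_b1),
              identical(deg(l2$a), d_a2), identical(deg(l2$b), d_b2))
    tri <- merge(data.frame(tf = l1$a, enhancer = l1$b),
                 data.frame(enhancer = l2$a, gene_id = l2$b),
                 by = "enhancer")
    nrow(unique(tri[, c("tf", "gene_id")]))
  }, numeric(1))
  list(p = (1 + sum(null_stats >= obs)) / (n_perm + 1), observed = obs,
       null = null_stats, n_perm = n_perm, seed = seed)
}

#' Extract core transcription factors from a regulatory network
#'
#' A TF is core iff (1) its motif is significantly enriched (raw
#' hypergeometric p < \code{p_max}) in dynamic enhancers against the
#' remaining enhancers, and (2) it is differentially expressed in at least
#' one adjacent-stage contrast AND at least \code{co_min} of its target
#' genes share the TF's expression cluster. TFs absent from the expression
#' clustering fail criterion 2.
#'
#' @param grn a \code{reg_network}.
#' @param dynamic_seqs named character vector: sequences of dynamic
#'   enhancers (gained/lost between adjacent stages).
#' @param background_seqs named character vector: sequences of the
#'   remaining (non-dynamic) enhancers.
#' @param pwms named list of \code{pwm}s covering the network's TFs.
#' @param tf_is_deg named logical: TF -> is a DEG in >= 1 adjacent contrast.
#' @param clusters named integer vector gene -> expression cluster (must
#'   include TF gene ids for criterion 2).
#' @param co_min minimum fraction of targets co-clustered with the TF
#'   (default 0.3).
#' @param p_max motif-enrichment threshold (default 1e-5).
#' @param score_fraction passed to [scan_pwm()].
#' @return data.frame per TF: tf, enrichment_p, criterion1, is_deg,
#'   co_cluster_fraction, criterion2, core.
#' @export
extract_core_tfs <- function(grn, dynamic_seqs, background_seqs, pwms,
                             tf_is_deg, clusters, co_min = 0.3,
                             p_max = 1e-5, score_fraction = 0.8) {
  stopifnot(inherits(grn, "reg_network"))
  tfs <- grn$tfs
  enr <- motif_enrichment(dynamic_seqs, background_seqs,
                          pwms[intersect(names(pwms), tfs)],
                          p_max = p_max, score_fraction = score_fraction)
  p_of <- setNames(enr$table$p, enr$table$tf)
  out <- lapply(tfs, function(tf) {
    p1 <- if (tf %in% names(p_of)) p_of[[tf]] else NA_real_
    c1 <- !is.na(p1) && p1 < p_max
    deg <- isTRUE(tf_is_deg[[tf]])
    targets <- grn$paths$gene_id[grn$paths$tf == tf]
    cof <- if (tf %in% names(clusters) && length(targets)) {
      tcl <- clusters[intersect(targets, names(clusters))]
      if (length(tcl)) mean(tcl == clusters[[tf]]) else 0
    } else NA_real_
    c2 <- deg && !is.na(cof) && cof >= co_min
    data.frame(tf = tf, enrichment_p = p1, criterion1 = c1, is_deg = deg,
               co_cluster_fraction = cof, criterion2 = c2,
               core = c1 && c2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map GWAS loci to genes through enhancers
#'
#' Two-step join: locus -> enhancer by interval overlap, enhancer -> gene
#' through an enhancer-gene link table.
#'
#' @param gwas_loci interval data.frame (point or interval loci; names
#'   identify loci).
#' @param enhancers interval data.frame (names identify enhancers).
#' @param links data.frame with columns enhancer, gene_id and optionally
#'   mode and pearson_r.
#' @return data.frame: locus, enhancer, gene_id, mode, r.
#' @export
variant_to_gene <- function(gwas_loci, enhancers, links) {
  empty <- data.frame(locus = character(), enhancer = character(),
                      gene_id = character(), mode = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  if (!nrow(gwas_loci) || !nrow(enhancers) || !nrow(links)) return(empty)
  hit <- overlap(gwas_loci, enhancers)
  if (!nrow(hit)) return(empty)
  lk <- data.frame(enhancer = links$enhancer, gene_id = links$gene_id,
                   mode = if ("mode" %in% names(links)) links$mode else NA,
                   r = if ("pearson_r" %in% names(links)) links$pearson_r
                   else NA_real_, stringsAsFactors = FALSE)
  m <- merge(data.frame(locus = gwas_loci$name[hit$query],
                        enhancer = enhancers$name[hit$subject],
                        stringsAsFactors = FALSE),
             lk, by = "enhancer")
  out <- m[, c("locus", "enhancer", "gene_id", "mode", "r")]
  out <- out[order(out$locus, out$enhancer, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
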