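#' Adjusted Rand index between two partitions
#'
#' @param a,b equal-length label vectors.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Recovery metrics of a pipeline run against the planted truth
#'
#' Compares every layer of a [run_pipeline()] result with the generator's
#' manifest: DEG recall, cluster agreement (ARI on planted archetype
#' genes), super-enhancer recall, boundary-classifier sensitivity and
#' false-flag rate, compartment label accuracy, distal-link recovery,
#' TF->gene path precision/recall/F1 and core-TF extraction.
#'
#' @param sim a \code{follireg_sim} dataset (with \code{$truth}).
#' @param res result list from [run_pipeline()] on that dataset.
#' @return named list of scalar metrics.
#' @export
evaluate_recovery <- function(sim, res) {
  truth <- sim$truth
  stages <- sim$config$stages

  ## DEG recall over planted up/down genes, all adjacent contrasts pooled
  hit <- 0L; tot <- 0L
  for (key in names(truth$deg_truth)) {
    d <- res$degs[[key]]
    up <- unlist(truth$deg_truth[[key]]$up)
    dn <- unlist(truth$deg_truth[[key]]$down)
    tot <- tot + length(up) + length(dn)
    hit <- hit + sum(d$direction[match(up, d$gene_id)] == "up") +
      sum(d$direction[match(dn, d$gene_id)] == "down")
  }
  deg_recall <- if (tot) hit / tot else NA_real_

  ## clustering ARI on the planted archetype genes present in the result
  cl_truth <- unlist(truth$cluster_labels)
  planted <- names(cl_truth)[cl_truth > 0]
  common <- intersect(planted, names(res$clusters))
  cluster_ari <- adjusted_rand_index(cl_truth[common],
                                     res$clusters[common])

  ## SE recall: planted SE regions present in a stage that are called super
  se_hit <- 0L; se_tot <- 0L
  se_df <- as.data.frame(truth$se_regions)
  for (st in stages) {
    present <- se_df[se_df$stage %in% c("all", st), , drop = FALSE]
    sup <- res$se[[st]][res$se[[st]]$is_super, , drop = FALSE]
    se_tot <- se_tot + nrow(present)
    if (nrow(present) && nrow(sup))
      se_hit <- se_hit + length(unique(overlap(
        gintervals(present$chrom, present$start, present$end),
        sup)$query))
  }
  se_recall <- if (se_tot) se_hit / se_tot else NA_real_

  ## boundary classifier: sensitivity on planted specific boundaries,
  ## false-flag rate on planted shared boundaries
  spec <- as.data.frame(truth$specific_boundaries)
  cls <- do.call(rbind, lapply(names(res$classified), function(ch)
    cbind(chrom = ch, res$classified[[ch]])))
  flagged <- cls[cls$specific, , drop = FALSE]
  sens_hit <- vapply(seq_len(nrow(spec)), function(i)
    any(flagged$chrom == spec$chrom[i] & flagged$stage == spec$stage[i] &
          abs(flagged$bin - spec$bin[i]) <= 1L), logical(1))
  boundary_sensitivity <- mean(sens_hit)
  shared_flagged <- 0L; shared_tot <- 0L
  for (ch in names(truth$shared_boundaries)) {
    sb <- unlist(truth$shared_boundaries[[ch]])
    shared_tot <- shared_tot + length(sb)
    fl <- flagged[flagged$chrom == ch, , drop = FALSE]
    if (nrow(fl))
      shared_flagged <- shared_flagged +
        sum(vapply(sb, function(b) any(abs(fl$bin - b) <= 1L), logical(1)))
  }
  boundary_false_flag <- if (shared_tot) shared_flagged / shared_tot else NA

  ## compartment accuracy over informative bins
  acc <- c()
  for (ch in names(res$compartments)) {
    cp <- res$compartments[[ch]]
    lab_truth <- unlist(truth$compartments[[ch]])
    ok <- !is.na(cp$compartment)
    acc <- c(acc, cp$compartment[ok] == lab_truth[ok])
  }
  compartment_accuracy <- mean(acc)

  ## distal loop links: recall of planted pairs, spurious links elsewhere
  lt <- as.data.frame(truth$loop_truth)
  found <- paste(res$distal_links$enhancer, res$distal_links$gene_id)
  loop_recall <- mean(paste(lt$enhancer, lt$gene_id) %in% found)
  # decoy loops were planted clear of enhancers and promoters: any link
  # they produce is a spurious anchor assignment
  decoy_loops <- sim$loops[grepl("^decoy", sim$loops$name), , drop = FALSE]
  enh_iv <- gintervals(sim$enhancers$chrom, sim$enhancers$start,
                       sim$enhancers$end, name = sim$enhancers$name)
  prom <- make_promoters(sim$genes, sim$config$promoter_flank)
  loop_spurious <- nrow(link_distal(
    merge_loops(decoy_loops, res$params$merge_resolution), enh_iv, prom))

  ## GRN TF->gene path F1 against planted triples
  tri <- as.data.frame(truth$planted_triples)
  truth_paths <- unique(paste(tri$tf, tri$gene_id))
  pred_paths <- paste(res$grn$paths$tf, res$grn$paths$gene_id)
  tp <- sum(pred_paths %in% truth_paths)
  precision <- if (length(pred_paths)) tp / length(pred_paths) else 0
  recall <- tp / length(truth_paths)
  grn_f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0

  ## core-TF extraction
  core_called <- res$core_tfs$tf[res$core_tfs$core]
  core_tf_recall <- mean(unlist(truth$core_tfs) %in% core_called)
  decoy_tfs_called <- sum(core_called %in% unlist(truth$decoy_tfs))

  ## GWAS: planted in-enhancer loci recovered with >= 1 target gene
  gw <- as.data.frame(truth$gwas_truth)
  gwas_recall <- if (nrow(gw))
    mean(gw$name %in% res$variants$locus) else NA_real_

  list(deg_recall = deg_recall,
       cluster_ari = cluster_ari,
       se_recall = se_recall,
       boundary_sensitivity = boundary_sensitivity,
       boundary_false_flag = boundary_false_flag,
       compartment_accuracy = compartment_accuracy,
       loop_link_recall = loop_recall,
       loop_link_spurious = loop_spurious,
       grn_path_precision = precision,
       grn_path_recall = recall,
       grn_path_f1 = grn_f1,
       core_tf_recall = core_tf_recall,
       decoy_tfs_called = decoy_tfs_called,
       gwas_locus_recall = gwas_recall,
       stability_score = if (!is.null(res$stability))
         res$stability$stability_score else NA_real_,
       permutation_p = res$permutation$p)
}
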