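#' Default pipeline parameters
#'
#' All thresholds used by [run_pipeline()], with the study's stated values
#' as defaults: |log2FC| > 1 and FDR < 0.05 for DEGs, 8 expression
#' clusters, ROSE stitch distance 12.5 kb, +/- 10-bin (200 kb) boundary
#' windows with a 1,000-draw permutation null, 25 kb loop merging,
#' enhancer-gene correlation FDR < 0.05, motif enrichment P < 1e-5, 10%
#' edge removal for stability and 1,000 network permutations.
#'
#' @param seed master seed for every stochastic stage (required).
#' @return named list of parameters.
#' @export
default_run_params <- function(seed) {
  stopifnot(!missing(seed))
  list(seed = seed,
       lfc_min = 1, fdr_max = 0.05,
       k_clusters = 8L, kmeans_restarts = 25L,
       stitch_distance = 12500L, tss_exclusion = 0L,
       window_bins = 10L, delta_min = 0.1, flank_bins = 10L,
       n_perm_boundary = 1000L, match_tolerance_bins = 1L,
       alpha_quantile = 0.95,
       merge_resolution = 25000L, promoter_flank = 2000L,
       corr_fdr = 0.05, motif_p = 1e-5, score_fraction = 0.8,
       removal_fraction = 0.1, stability_trials = 100L,
       n_perm_grn = 1000L, swap_factor = 10L, co_min = 0.3)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a list with the same layers as [simulate_dataset()] (including
#'   the truth manifest when \code{truth.json} is present).
#' @export
read_dataset <- function(dir) {
  p <- function(...) file.path(dir, ...)
  if (!file.exists(p("expression.tsv"))) stop("missing input: ",
                                              p("expression.tsv"))
  cfg <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  cfg$chrom_lengths <- unlist(cfg$chrom_lengths)
  stages <- cfg$stages
  es <- read.table(p("enh_signal.tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE)
  prof_e <- as.matrix(es[, -1]); rownames(prof_e) <- es[[1]]
  peaks <- function(mark) {
    out <- lapply(stages, function(st)
      read_bed(p("peaks", sprintf("%s_%s.bed", mark, st)), 6L))
    names(out) <- stages
    out
  }
  hic <- list()
  for (st in cfg$hic_stages) {
    hic[[st]] <- list()
    for (ch in names(cfg$chrom_lengths))
      hic[[st]][[ch]] <- read_contact_matrix(
        p("hic", sprintf("%s_%s.coo.tsv", st, ch)))
  }
  truth <- if (file.exists(p("truth.json")))
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else NULL
  list(config = cfg,
       genes = read.table(p("genes.tsv"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE),
       expression = read_expression(p("expression.tsv"), stages),
       enhancers = {
         b <- read_bed(p("enhancers.bed"), 4L)
         b
       },
       enh_profiles = prof_e,
       peaks_k27ac = peaks("H3K27ac"),
       peaks_k27me3 = peaks("H3K27me3"),
       hic = hic,
       loops = read_bedpe(p("loops.bedpe")),
       sequences = read_fasta(p("enhancers.fa")),
       pwms = read_meme(p("pwms.meme")),
       gwas_loci = read_bed(p("gwas_loci.bed"), 4L),
       truth = truth)
}

#' Enhancers whose activity changes between adjacent stages
#'
#' An enhancer is dynamic when, for some adjacent stage pair, it overlaps a
#' peak in exactly one of the two stages (gained or lost activity).
#'
#' @param enhancers interval data.frame of enhancer elements.
#' @param peaks_by_stage named list of per-stage peak interval data.frames.
#' @param stage_order ordered stage labels.
#' @return logical vector along \code{enhancers} rows.
#' @export
dynamic_enhancers <- function(enhancers, peaks_by_stage,
                              stage_order = names(peaks_by_stage)) {
  pres <- sapply(stage_order, function(st)
    seq_len(nrow(enhancers)) %in%
      overlap(enhancers, peaks_by_stage[[st]])$query)
  dyn <- rep(FALSE, nrow(enhancers))
  for (i in seq_len(length(stage_order) - 1L))
    dyn <- dyn | (pres[, i] != pres[, i + 1L])
  dyn
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes every stage on a dataset from [simulate_dataset()] or
#' [read_dataset()]: adjacent-stage differential expression and expression
#' clustering; per-stage ROSE super-enhancer/silencer calling with
#' stage-specific elements; Hi-C balancing, insulation, boundary calling
#' and the permutation-based stage-specific boundary classifier;
#' compartment eigenvectors; intra-TAD contact strength; multi-resolution
#' loop merging and loop-anchored distal linking; TAD-constrained
#' enhancer-gene correlation, motif enrichment, network assembly with
#' stability/permutation statistics, core-TF extraction and
#' GWAS-variant-to-gene mapping.
#'
#' @param ds dataset list (see [read_dataset()]) or a directory path.
#' @param params parameter list from [default_run_params()].
#' @param out_dir optional directory for TSV/BED/JSON outputs and the run
#'   manifest.
#' @return a named list of stage results.
#' @export
run_pipeline <- function(ds, params, out_dir = NULL) {
  if (is.character(ds)) ds <- read_dataset(ds)
  pr <- params
  stages <- ds$config$stages
  hic_stages <- ds$config$hic_stages
  chroms <- names(ds$config$chrom_lengths)
  res <- ds$config$resolution
  n_bins <- as.integer(unlist(ds$config$chrom_lengths) %/% res)
  names(n_bins) <- chroms
  log_counts <- list()

  ## expression: DEGs per adjacent contrast + clustering of DEG genes
  degs <- list()
  for (i in seq_len(length(stages) - 1L)) {
    key <- paste(stages[i], stages[i + 1L], sep = "_")
    degs[[key]] <- call_degs(ds$expression, stages[i], stages[i + 1L],
                             lfc_min = pr$lfc_min, fdr_max = pr$fdr_max)
  }
  deg_genes <- unique(unlist(lapply(degs, function(d)
    d$gene_id[d$direction != "ns"])))
  clusters <- cluster_stage_profiles(
    ds$expression, genes = deg_genes, k = pr$k_clusters,
    restarts = pr$kmeans_restarts,
    seed = substream_seed(pr$seed, "kmeans"))
  tf_is_deg <- setNames(rownames(ds$expression$values) %in% deg_genes,
                        rownames(ds$expression$values))

  ## elements: SE / SS calling per stage, stage-specific sets
  se <- lapply(ds$peaks_k27ac, function(p)
    call_super_elements(p, pr$stitch_distance,
                        tss_exclusion = pr$tss_exclusion))
  ss <- lapply(ds$peaks_k27me3, function(p)
    call_super_elements(p, pr$stitch_distance,
                        tss_exclusion = pr$tss_exclusion))
  se_super <- lapply(se, function(r) r[r$is_super, , drop = FALSE])
  se_specific <- stage_specific_elements(se_super)

  ## Hi-C: balance, insulation, boundaries, specific-boundary classifier
  insul <- list(); bounds <- list(); balanced <- list()
  for (st in hic_stages) {
    insul[[st]] <- list(); bounds[[st]] <- list(); balanced[[st]] <- list()
    for (ch in chroms) {
      bm <- balance_matrix(ds$hic[[st]][[ch]])
      balanced[[st]][[ch]] <- bm
      # insulation on raw counts: the score is a within/around coverage
      # ratio and needs no balancing, and ICE on strongly block-enriched
      # matrices imprints a shallow dip at the centre of large TADs
      insul[[st]][[ch]] <- insulation_track(ds$hic[[st]][[ch]],
                                            pr$window_bins)
      bounds[[st]][[ch]] <- call_boundaries(insul[[st]][[ch]], pr$delta_min)
    }
  }
  classified <- list()
  for (ch in chroms) {
    classified[[ch]] <- classify_specific_boundaries(
      stage_boundaries = lapply(bounds, `[[`, ch),
      tracks = lapply(insul, `[[`, ch),
      stage_order = hic_stages,
      match_tolerance_bins = pr$match_tolerance_bins,
      alpha_quantile = pr$alpha_quantile,
      n_perm = pr$n_perm_boundary, flank_bins = pr$flank_bins,
      seed = substream_seed(pr$seed, paste0("boundary:", ch)))
  }

  ## compartments: first Hi-C stage, oriented by gene density
  compartments <- list()
  for (ch in chroms) {
    dens <- tabulate(ds$genes$tss[ds$genes$chrom == ch] %/% res + 1L,
                     n_bins[ch])
    compartments[[ch]] <- compartment_eigenvector(
      balanced[[hic_stages[1]]][[ch]],
      signal_track(ch, res, as.numeric(dens)))
  }

  ## TADs (first Hi-C stage boundaries) + intra-TAD strength per stage
  tads <- do.call(rbind, lapply(chroms, function(ch)
    tads_from_boundaries(bounds[[hic_stages[1]]][[ch]]$bin, n_bins[ch],
                         res, ch)))
  intra <- lapply(balanced, function(bst)
    unlist(lapply(chroms, function(ch)
      intra_tad_strength(bst[[ch]], tads[tads$chrom == ch, ]))))

  ## loops: merge across resolutions, link enhancers to promoters
  merged_loops <- merge_loops(ds$loops, pr$merge_resolution)
  promoters <- make_promoters(ds$genes, pr$promoter_flank)
  enh_iv <- if ("name" %in% names(ds$enhancers) &&
                !all(ds$enhancers$name == "."))
    gintervals(ds$enhancers$chrom, ds$enhancers$start, ds$enhancers$end,
               name = ds$enhancers$name)
  else gintervals(ds$enhancers$chrom, ds$enhancers$start, ds$enhancers$end,
                  name = sprintf("enh_%03d", seq_len(nrow(ds$enhancers))))
  distal_links <- link_distal(merged_loops, enh_iv, promoters)

  ## GRN: TAD-constrained correlation, motif enrichment, assembly
  expr_means <- stage_means(ds$expression, log2p1 = TRUE)
  gene_tss <- ds$genes[, c("chrom", "tss", "gene_id")]
  eg <- correlate_in_tad(ds$enh_profiles, enh_iv, expr_means, gene_tss,
                         tads, fdr_max = pr$corr_fdr)
  linked_enh <- unique(eg$enhancer)
  target_seqs <- ds$sequences[intersect(linked_enh, names(ds$sequences))]
  background_seqs <- ds$sequences[setdiff(names(ds$sequences), linked_enh)]
  enr <- motif_enrichment(target_seqs, background_seqs, ds$pwms,
                          p_max = pr$motif_p,
                          score_fraction = pr$score_fraction)
  grn <- assemble_grn(enr$pairs, eg)
  stab <- if (nrow(grn$tf_enh) + nrow(grn$enh_gene) >= 10L)
    stability_score(grn, pr$removal_fraction, pr$stability_trials,
                    seed = substream_seed(pr$seed, "stability"))
  else NULL
  perm <- permutation_test(grn, n_perm = pr$n_perm_grn,
                           seed = substream_seed(pr$seed, "permutation"),
                           swap_factor = pr$swap_factor)

  ## core TFs: motif enrichment in dynamic enhancers + DEG/co-clustering
  dyn <- dynamic_enhancers(enh_iv, ds$peaks_k27ac, stages)
  all_clusters <- cluster_stage_profiles(
    ds$expression, genes = NULL, k = pr$k_clusters,
    restarts = pr$kmeans_restarts,
    seed = substream_seed(pr$seed, "kmeans_all"))
  core <- extract_core_tfs(
    grn,
    dynamic_seqs = ds$sequences[enh_iv$name[dyn]],
    background_seqs = ds$sequences[enh_iv$name[!dyn]],
    pwms = ds$pwms, tf_is_deg = tf_is_deg, clusters = all_clusters,
    co_min = pr$co_min, p_max = pr$motif_p,
    score_fraction = pr$score_fraction)

  ## GWAS loci -> enhancer -> gene
  links_all <- rbind(
    data.frame(enhancer = eg$enhancer, gene_id = eg$gene_id,
               mode = "proximal_in_tad", pearson_r = eg$pearson_r,
               stringsAsFactors = FALSE),
    if (nrow(distal_links))
      data.frame(enhancer = distal_links$enhancer,
                 gene_id = distal_links$gene_id, mode = "distal_loop",
                 pearson_r = NA_real_, stringsAsFactors = FALSE))
  variants <- variant_to_gene(ds$gwas_loci, enh_iv, links_all)

  result <- list(
    params = pr,
    degs = degs, deg_genes = deg_genes, clusters = clusters,
    se = se, ss = ss, se_specific = se_specific,
    insulation = insul, boundaries = bounds, classified = classified,
    compartments = compartments, tads = tads, intra_tad = intra,
    merged_loops = merged_loops, distal_links = distal_links,
    eg_pairs = eg, enrichment = enr, grn = grn,
    stability = stab, permutation = perm,
    dynamic = setNames(dyn, enh_iv$name), core_tfs = core,
    variants = variants)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# serialise the headline tables + a machine-readable run manifest
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  for (key in names(result$degs))
    write.table(result$degs[[key]], p(sprintf("degs_%s.tsv", key)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(result$clusters),
                         cluster = as.integer(result$clusters)),
              p("clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (st in names(result$se))
    write.table(result$se[[st]][order(result$se[[st]]$rank), ],
                p(sprintf("se_rank_%s.tsv", st)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  cls <- do.call(rbind, lapply(names(result$classified), function(ch)
    cbind(chrom = ch, result$classified[[ch]])))
  write.table(cls, p("boundaries.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  comp <- do.call(rbind, lapply(names(result$compartments), function(ch)
    cbind(chrom = ch, result$compartments[[ch]])))
  write.table(comp, p("compartments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bedpe(result$merged_loops, p("merged_loops.bedpe"))
  write.table(result$eg_pairs, p("enhancer_gene_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$distal_links, p("distal_links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$enrichment$table, p("motif_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$core_tfs, p("core_tfs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$variants, p("variant_to_gene.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(
    params = result$params,
    counts = list(
      degs_per_contrast = vapply(result$degs, function(d)
        sum(d$direction != "ns"), numeric(1)),
      supers_per_stage = vapply(result$se, function(r) sum(r$is_super),
                                numeric(1)),
      specific_boundaries = sum(cls$specific),
      merged_loops = nrow(result$merged_loops),
      eg_pairs = nrow(result$eg_pairs),
      distal_links = nrow(result$distal_links),
      grn = as.list(summary(result$grn)),
      core_tfs = sum(result$core_tfs$core),
      gwas_hits = nrow(result$variants)),
    stability = if (!is.null(result$stability))
      result$stability$stability_score else NA,
    permutation_p = result$permutation$p)
  jsonlite::write_json(manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
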