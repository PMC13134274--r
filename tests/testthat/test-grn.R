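test_that("PWM scanning finds the consensus at maximal score on both
           strands and matches an exhaustive rescan", {
  p <- consensus_pwm("TFX", "ACGTACGTAC")
  hits <- scan_pwm(c(s1 = "ACGTACGTAC"), p)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos, 1L)
  expect_equal(hits$strand, "+")
  lo <- log2(p$matrix / 0.25)
  expect_equal(hits$score, sum(apply(lo, 1, max)))
  # reverse complement scores identically on the minus strand
  rc <- revcomp_chr("ACGTACGTAC")
  hits_rc <- scan_pwm(setNames(rc, "s1"), p)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)
  # sequences shorter than the motif yield nothing; N windows skipped
  expect_equal(nrow(scan_pwm(c(a = "ACGT"), p)), 0L)
  expect_equal(nrow(scan_pwm(c(a = "ACGTNCGTAC"), p)), 0L)
  # strand symmetry on random sequences: hits on a sequence equal
  # strand-flipped hits on its reverse complement
  set.seed(21)
  seqs <- setNames(vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1)), sprintf("r%d", 1:20))
  seqs[5] <- paste0(substr(seqs[5], 1, 100), "ACGTACGTAC",
                    substr(seqs[5], 111, 300))
  h_fwd <- scan_pwm(seqs, p, score_fraction = 0.7)
  h_rc <- scan_pwm(setNames(vapply(seqs, revcomp_chr, character(1)),
                            names(seqs)), p, score_fraction = 0.7)
  expect_equal(nrow(h_fwd), nrow(h_rc))
  expect_equal(sort(table(h_fwd$seq_name)), sort(table(h_rc$seq_name)))
  # exhaustive position-by-position oracle on one sequence
  s <- seqs[[5]]
  lo_f <- log2(p$matrix / 0.25)
  max_s <- sum(apply(lo_f, 1, max))
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  brute <- 0L
  for (str in c("f", "r")) {
    m <- if (str == "f") lo_f else
      log2(pwm_revcomp(p)$matrix / 0.25)
    for (i in 1:(nchar(s) - 9)) {
      sc <- sum(m[cbind(1:10, codes[i:(i + 9)])])
      if (!is.na(sc) && sc >= 0.7 * max_s) brute <- brute + 1L
    }
  }
  expect_equal(sum(h_fwd$seq_name == "r5"), brute)
})

test_that("motif enrichment applies the hypergeometric tail", {
  p <- consensus_pwm("TFY", "GGGACGTACC")
  set.seed(22)
  mk <- function(n, with_motif) {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
      if (with_motif(i)) s <- paste0(substr(s, 1, 50), "GGGACGTACC",
                                     substr(s, 61, 200))
      s
    }, character(1))
  }
  tgt <- setNames(mk(100, function(i) i <= 80), sprintf("t%d", 1:100))
  bgd <- setNames(mk(100, function(i) i <= 5), sprintf("b%d", 1:100))
  r <- motif_enrichment(tgt, bgd, list(TFY = p))
  expect_lt(r$table$p, 1e-5)
  expect_true(r$table$enriched)
  expect_gte(nrow(r$pairs), 80)
  # the p-value equals the direct hypergeometric tail sum
  kt <- r$table$hits_target; kb <- r$table$hits_background
  expect_equal(r$table$p,
               oracle_hyper_tail(kt, kt + kb, 200, 100), tolerance = 1e-9)
  # identical hit rates in target and background: no enrichment
  t_eq <- setNames(mk(60, function(i) i <= 15), sprintf("u%d", 1:60))
  b_eq <- setNames(mk(60, function(i) i <= 15), sprintf("v%d", 1:60))
  r0 <- motif_enrichment(t_eq, b_eq, list(TFY = p))
  expect_gte(r0$table$p, 0.3)
  expect_error(motif_enrichment(character(0), bgd, list(TFY = p)), "empty")
  # zero hits anywhere -> p = 1
  pz <- consensus_pwm("TFZ", "ATATATATAT")
  none <- c(x = "GGGGGGGGGGGGGGGGGGGG", y = "CCCCCCCCCCCCCCCCCCCC")
  expect_equal(motif_enrichment(none[1], none[2],
                                list(TFZ = pz))$table$p, 1)
})

test_that("correlate_in_tad obeys the TAD constraint and finds planted
           pairs", {
  stages <- FOLLICLE_STAGES
  tads <- gintervals("chr1", c(0, 1e6), c(1e6, 2e6),
                     name = c("tadA", "tadB"))
  gene_tss <- data.frame(chrom = "chr1", tss = c(5e5, 15e5),
                         gene_id = c("g_in", "g_out"))
  prof <- c(1, 2, 5, 3, 1, 0.5, 0.5)
  expr_means <- rbind(g_in = prof, g_out = rev(prof))
  colnames(expr_means) <- stages
  enh <- gintervals("chr1", 4e5, 4.01e5, name = "e1")
  es <- matrix(prof, 1, 7, dimnames = list("e1", stages))
  r <- correlate_in_tad(es, enh, expr_means, gene_tss, tads,
                        keep_all = TRUE)
  # only the same-TAD gene is tested; identical profile gives r = 1
  expect_equal(r$gene_id, "g_in")
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_equal(attr(r, "n_tested"), 1L)
  # constant profile is skipped and counted
  es2 <- rbind(es, e2 = rep(2, 7))
  enh2 <- rbind(enh, gintervals("chr1", 6e5, 6.01e5, name = "e2"))
  r2 <- correlate_in_tad(es2, enh2, expr_means, gene_tss, tads,
                         keep_all = TRUE)
  expect_equal(attr(r2, "n_skipped_constant"), 1L)
  # planted generator truth: every planted enhancer-target pair is
  # significant at FDR < 0.05 with high sensitivity
  sim <- shared_sim()
  cuts <- lapply(sim$truth$shared_boundaries, unlist)
  tads_all <- do.call(rbind, lapply(names(cuts), function(ch)
    tads_from_boundaries(cuts[[ch]], 500L, 20000L, ch)))
  enh_iv <- gintervals(sim$enhancers$chrom, sim$enhancers$start,
                       sim$enhancers$end, name = sim$enhancers$name)
  eg <- correlate_in_tad(sim$enh_profiles, enh_iv,
                         stage_means(sim$expression, log2p1 = TRUE),
                         sim$genes[, c("chrom", "tss", "gene_id")],
                         tads_all)
  tri <- sim$truth$planted_triples
  found <- paste(eg$enhancer, eg$gene_id) %in%
    paste(tri$enhancer, tri$gene_id)
  sens <- mean(paste(tri$enhancer, tri$gene_id) %in%
                 paste(eg$enhancer, eg$gene_id))
  expect_gte(sens, 0.8)
})

test_that("correlate_in_tad controls the FDR on null data", {
  # no planted correlation: 500 enhancer-gene pairs across 7 stages
  set.seed(23)
  stages <- FOLLICLE_STAGES
  n <- 500
  tads <- gintervals("chr1", (0:(n - 1)) * 1e5, (1:n) * 1e5,
                     name = sprintf("t%d", 1:n))
  gene_tss <- data.frame(chrom = "chr1", tss = (0:(n - 1)) * 1e5 + 5e4,
                         gene_id = sprintf("g%d", 1:n))
  enh <- gintervals("chr1", (0:(n - 1)) * 1e5 + 1e4,
                    (0:(n - 1)) * 1e5 + 1.1e4, name = sprintf("e%d", 1:n))
  es <- matrix(rnorm(n * 7), n, 7, dimnames = list(enh$name, stages))
  gm <- matrix(abs(rnorm(n * 7, 5)), n, 7,
               dimnames = list(gene_tss$gene_id, stages))
  r <- correlate_in_tad(es, enh, gm, gene_tss, tads)
  expect_lte(nrow(r) / attr(r, "n_tested"), 0.1)
})

test_that("GRN assembly is tripartite and path counting matches brute
           force", {
  te <- data.frame(tf = "TF1", enhancer = "E1")
  eg <- data.frame(enhancer = "E1", gene_id = "G1")
  g <- assemble_grn(te, eg)
  expect_equal(nrow(g$paths), 1L)
  expect_equal(summary(g)[["n_paths"]], 1L)
  # disjoint enhancers: zero paths
  g0 <- assemble_grn(te, data.frame(enhancer = "E2", gene_id = "G1"))
  expect_equal(nrow(g0$paths), 0L)
  # random networks vs explicit double loop
  set.seed(24)
  for (i in 1:3) {
    te2 <- unique(data.frame(
      tf = sample(sprintf("TF%d", 1:8), 60, TRUE),
      enhancer = sample(sprintf("E%d", 1:25), 60, TRUE)))
    eg2 <- unique(data.frame(
      enhancer = sample(sprintf("E%d", 1:25), 50, TRUE),
      gene_id = sample(sprintf("G%d", 1:20), 50, TRUE)))
    g2 <- assemble_grn(te2, eg2)
    expect_equal(nrow(g2$paths), oracle_path_count(te2, eg2))
  }
})

test_that("stability score has exact limits, star expectation and
           monotonicity", {
  set.seed(25)
  te <- data.frame(tf = sprintf("TF%d", 1:6),
                   enhancer = rep("HUB", 6))
  eg <- data.frame(enhancer = c(rep("HUB", 4), "E2", "E3"),
                   gene_id = sprintf("G%d", 1:6))
  g <- assemble_grn(te, eg)
  # near-zero removal: nothing removed, score exactly 1
  s0 <- stability_score(g, removal_fraction = 1e-6, trials = 20, seed = 1)
  expect_equal(s0$stability_score, 1)
  expect_error(stability_score(g, removal_fraction = 0, trials = 5,
                               seed = 1), "removal_fraction")
  # star network: every path dies with its own E->G edge or the shared
  # TF->E edge; exact expectation by hypergeometric enumeration
  te_star <- data.frame(tf = "TF1", enhancer = sprintf("E%d", 1:9))
  eg_star <- data.frame(enhancer = sprintf("E%d", 1:9),
                        gene_id = sprintf("G%d", 1:9))
  g_star <- assemble_grn(te_star, eg_star)
  E <- 18; k <- floor(0.1 * E)   # 1 edge removed
  # a path survives iff neither of its 2 edges is the removed one
  expected <- (E - 2) / E
  s_star <- stability_score(g_star, 0.1, trials = 4000, seed = 2)
  expect_equal(s_star$stability_score, expected, tolerance = 0.02)
  # monotone non-increasing in the removal fraction
  s_by_f <- vapply(c(0.05, 0.1, 0.2), function(f)
    stability_score(g_star, f, trials = 400, seed = 3)$stability_score,
    numeric(1))
  expect_true(all(diff(s_by_f) <= 0))
})

test_that("permutation test preserves degrees, is seeded, calibrated on
           random graphs and powered on modular ones", {
  set.seed(26)
  rand_net <- function() {
    te <- unique(data.frame(
      tf = sample(sprintf("TF%d", 1:10), 50, TRUE),
      enhancer = sample(sprintf("E%d", 1:25), 50, TRUE)))
    eg <- unique(data.frame(
      enhancer = sample(sprintf("E%d", 1:25), 45, TRUE),
      gene_id = sample(sprintf("G%d", 1:18), 45, TRUE)))
    assemble_grn(te, eg)
  }
  g <- rand_net()
  r1 <- permutation_test(g, n_perm = 50, seed = 7)
  r2 <- permutation_test(g, n_perm = 50, seed = 7)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p, r2$p)
  # degree preservation is asserted inside every replicate; a run
  # completing without error certifies it
  expect_true(is.numeric(r1$null) && length(r1$null) == 50)

  # calibration: p roughly uniform over random networks
  ps <- vapply(1:30, function(i)
    permutation_test(rand_net(), n_perm = 60,
                     seed = 100 + i)$p, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.85)

  # power: every TF binds a shared gene-rich enhancer while the layer
  # also carries many single-TF enhancers without targets; rewired nulls
  # strand some TFs away from the shared hubs and lose paths
  te_mod <- rbind(
    data.frame(tf = sprintf("TF%d", 1:5), enhancer = "S1"),
    data.frame(tf = sprintf("TF%d", 6:10), enhancer = "S2"),
    data.frame(tf = rep(sprintf("TF%d", 1:10), each = 9),
               enhancer = sprintf("D%d", 1:90)))
  eg_mod <- expand.grid(enhancer = c("S1", "S2"),
                        gene_id = sprintf("G%d", 1:10),
                        stringsAsFactors = FALSE)
  g_mod <- assemble_grn(te_mod, eg_mod)
  r_mod <- permutation_test(g_mod, n_perm = 300, seed = 11)
  expect_lte(r_mod$p, 0.05)
  # tiny layers: NA with warning
  g_tiny <- assemble_grn(data.frame(tf = "a", enhancer = "e"),
                         data.frame(enhancer = "e", gene_id = "g"))
  expect_warning(r_t <- permutation_test(g_tiny, n_perm = 5, seed = 1),
                 "too small")
  expect_true(is.na(r_t$p))
})

test_that("core-TF extraction applies both criteria", {
  sim <- shared_sim()
  # build the needed inputs from the generator layers directly
  enh_iv <- gintervals(sim$enhancers$chrom, sim$enhancers$start,
                       sim$enhancers$end, name = sim$enhancers$name)
  dyn <- dynamic_enhancers(enh_iv, sim$peaks_k27ac,
                           sim$config$stages)
  grn <- assemble_grn(
    data.frame(tf = sim$truth$planted_triples$tf,
               enhancer = sim$truth$planted_triples$enhancer),
    data.frame(enhancer = sim$truth$planted_triples$enhancer,
               gene_id = sim$truth$planted_triples$gene_id))
  tf_is_deg <- setNames(
    rownames(sim$expression$values) %in% unlist(lapply(
      sim$truth$deg_truth, function(x) c(x$up, x$down))),
    rownames(sim$expression$values))
  clusters <- sim$truth$cluster_labels
  core <- extract_core_tfs(grn, sim$sequences[enh_iv$name[dyn]],
                           sim$sequences[enh_iv$name[!dyn]],
                           sim$pwms, tf_is_deg, clusters)
  expect_true(all(sim$truth$core_tfs %in% core$tf[core$core]))
  # a TF with flat expression fails criterion 2 even when enriched
  tf_flat <- setNames(rep(FALSE, length(tf_is_deg)), names(tf_is_deg))
  core2 <- extract_core_tfs(grn, sim$sequences[enh_iv$name[dyn]],
                            sim$sequences[enh_iv$name[!dyn]],
                            sim$pwms, tf_flat, clusters)
  expect_equal(sum(core2$core), 0L)
  # a TF absent from the clustering fails criterion 2
  cl_missing <- clusters[setdiff(names(clusters), sim$truth$core_tfs)]
  core3 <- extract_core_tfs(grn, sim$sequences[enh_iv$name[dyn]],
                            sim$sequences[enh_iv$name[!dyn]],
                            sim$pwms, tf_is_deg, cl_missing)
  expect_equal(sum(core3$core), 0L)
})

test_that("variant_to_gene equals the brute-force two-step join", {
  set.seed(27)
  enh <- random_intervals(40)
  loci_in <- gintervals(enh$chrom[1:10],
                        (enh$start[1:10] + enh$end[1:10]) %/% 2,
                        (enh$start[1:10] + enh$end[1:10]) %/% 2 + 1,
                        name = sprintf("rs%d", 1:10))
  loci_out <- gintervals("chr3", 1:40 * 1000, 1:40 * 1000 + 1,
                         name = sprintf("rx%d", 1:40))
  loci <- rbind(loci_in, loci_out)
  links <- data.frame(enhancer = sample(enh$name, 25, TRUE),
                      gene_id = sample(sprintf("g%d", 1:12), 25, TRUE),
                      mode = "proximal_in_tad",
                      pearson_r = runif(25, -1, 1))
  got <- variant_to_gene(loci, enh, links)
  # brute force join
  want <- 0L
  for (i in seq_len(nrow(loci))) for (j in seq_len(nrow(enh))) {
    if (loci$chrom[i] != enh$chrom[j]) next
    if (loci$start[i] < enh$end[j] && loci$end[i] > enh$start[j])
      want <- want + sum(links$enhancer == enh$name[j])
  }
  expect_equal(nrow(got), want)
  # a locus outside every enhancer yields no rows
  expect_equal(nrow(variant_to_gene(
    gintervals("chr9", 5, 6, name = "solo"), enh, links)), 0L)
})
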