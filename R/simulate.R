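#' Default configuration of the synthetic multi-omics generator
#'
#' The defaults define the study conditions every recovery test runs under:
#' a 2 x 10 Mb genome binned at 20 kb, the 7 ordered follicle stages with
#' 4 expression replicates, Hi-C at SYF/F5/F1, 8 stage-profile archetypes,
#' ROSE-scale element sets with planted super-enhancers, block TAD matrices
#' with stage-specific boundaries and a compartment checkerboard, loops at
#' 3 resolutions and PWM consensus occurrences planted in enhancer
#' sequences.
#'
#' @return a named list of generator parameters.
#' @export
default_sim_config <- function() {
  list(
    chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
    resolution = 20000L,
    stages = FOLLICLE_STAGES,
    n_reps = 4L,
    hic_stages = c("SYF", "F5", "F1"),
    n_genes = 600L,
    n_clusters = 8L,
    genes_per_cluster = 50L,
    expr_noise_sd = 0.3,
    enh_noise_sd = 0.15,
    n_core_tfs = 5L,
    n_decoy_tfs = 20L,
    n_targets_per_tf = 12L,
    n_distal_links = 30L,
    n_enhancers = 500L,
    enh_width = 500L,
    n_bg_peaks = 150L,
    n_se_shared = 10L,
    n_se_specific_per_stage = 2L,
    se_constituents = 4L,
    n_ss_shared = 6L,
    n_ss_specific_per_stage = 1L,
    n_bg_peaks_k27me3 = 100L,
    tad_size_range = c(15L, 35L),
    tad_enrichment = 3,
    comp_enrichment = 1.5,
    hic_depth = 80,
    decay_exponent = 1.0,
    n_specific_boundaries = 2L,   # per Hi-C stage per chromosome
    loop_resolutions = c(10000L, 20000L, 25000L),
    n_decoy_loops = 60L,
    n_gwas_in_enh = 12L,
    n_gwas_bg = 28L,
    motif_width = 10L,
    peak_presence_threshold = 1.0,
    promoter_flank = 2000L,
    min_element_gap = 13000L      # > ROSE stitch distance, keeps sites apart
  )
}

# stage-profile archetypes (log2 activity over the 7 ordered stages):
# prehierarchical-high, SWF peak, SYF peak, hierarchical-high, F5 peak,
# F1 peak, POF peak, late-rising
archetype_profiles <- function() {
  m <- rbind(c(3, 3, 3, 0.5, 0.5, 0.5, 0.5),
             c(4, 1, 0.5, 0.5, 0.5, 0.5, 0.5),
             c(0.5, 1, 4, 1, 0.5, 0.5, 0.5),
             c(0.5, 0.5, 0.5, 3, 3, 3, 0.5),
             c(0.5, 0.5, 1, 4, 1, 0.5, 0.5),
             c(0.5, 0.5, 0.5, 0.5, 1, 4, 1),
             c(0.5, 0.5, 0.5, 0.5, 0.5, 1, 4),
             c(0.5, 0.5, 1, 1.5, 2, 3, 3.5))
  colnames(m) <- FOLLICLE_STAGES
  m
}

# rejection-sample a site of `width` bp on [lo, hi) keeping `min_gap` bp of
# clearance from every interval in `occ` (2-column matrix start/end)
place_site <- function(occ, width, lo, hi, min_gap, avoid = NULL,
                       tries = 400L) {
  for (t in seq_len(tries)) {
    s <- floor(runif(1, lo, hi - width))
    e <- s + width
    clash <- nrow(occ) && any(s < occ[, 2] + min_gap & e > occ[, 1] - min_gap)
    if (!clash && !is.null(avoid) && nrow(avoid))
      clash <- any(s < avoid[, 2] & e > avoid[, 1])
    if (!clash) return(c(s, e))
  }
  NULL
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a PWM concentrated on a consensus sequence
#'
#' @param tf_name TF name.
#' @param consensus consensus DNA string.
#' @param major probability of the consensus base at each position.
#' @export
consensus_pwm <- function(tf_name, consensus, major = 0.85) {
  b <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - major) / 3, length(b), 4)
  m[cbind(seq_along(b), b)] <- major
  pwm(tf_name, m)
}

#' Generate a synthetic multi-omics dataset with planted ground truth
#'
#' Emulates the study design end-to-end: stage-archetype expression with
#' TF->target co-expression, per-stage H3K27ac/H3K27me3 peaks with planted
#' super-enhancers/silencers and stage-specific elements, per-stage binned
#' Hi-C matrices (distance decay x TAD enrichment x compartment
#' checkerboard, Poisson counts) with boundaries planted in exactly one
#' stage, loop calls at three resolutions mediating planted distal
#' enhancer-gene links, enhancer sequences with planted PWM consensus
#' occurrences, and GWAS loci inside linked enhancers. All randomness flows
#' from \code{seed} through named substreams, so the dataset is
#' byte-reproducible and individual layers can be regenerated alone.
#'
#' @param seed master integer seed (required).
#' @param config parameter list from [default_sim_config()].
#' @param out_dir optional directory; when given, all layers are written in
#'   the package's interchange formats plus a \code{truth.json} manifest.
#' @return a list with the in-memory dataset layers and a \code{truth}
#'   manifest of everything planted.
#' @export
simulate_dataset <- function(seed, config = default_sim_config(),
                             out_dir = NULL) {
  stopifnot(!missing(seed))
  cfg <- config
  n_se_total <- cfg$n_se_shared +
    cfg$n_se_specific_per_stage * length(cfg$stages)
  if (n_se_total > cfg$n_enhancers)
    stop("infeasible config: more super-enhancer regions than enhancers")
  need_bp <- (cfg$n_enhancers + cfg$n_bg_peaks) *
    (cfg$min_element_gap + 2000) + n_se_total * 40000
  if (need_bp > 0.85 * sum(cfg$chrom_lengths))
    stop("infeasible config: elements do not fit the genome")
  chroms <- names(cfg$chrom_lengths)
  res <- cfg$resolution
  n_bins <- setNames(as.integer(cfg$chrom_lengths %/% res), chroms)
  stages <- cfg$stages

  ## ---- genome layer: TADs, boundaries, compartments, genes -------------
  genome <- with_substream(seed, "genome", {
    shared_bnd <- list(); spec_bnd <- list(); comp <- list()
    for (ch in chroms) {
      sizes <- integer()
      while (sum(sizes) < n_bins[ch])
        sizes <- c(sizes, sample(cfg$tad_size_range[1]:cfg$tad_size_range[2],
                                 1L))
      cuts <- cumsum(sizes)
      cuts <- cuts[cuts < n_bins[ch]]
      shared_bnd[[ch]] <- cuts
      # compartment label per TAD, alternating in runs of two TADs
      n_tads <- length(cuts) + 1L
      tad_lab <- rep(rep(c("A", "B"), each = 2L),
                     length.out = n_tads)
      bin_tad <- findInterval(seq_len(n_bins[ch]) - 1L, cuts) + 1L
      comp[[ch]] <- tad_lab[bin_tad]
      # stage-specific boundaries: split large TADs, one stage each. The
      # split sits off-centre: balanced block matrices carry a shallow
      # insulation dip at the centre of large TADs in every stage, and a
      # split planted there would collide with that artifact.
      tad_start <- c(0L, cuts); tad_end <- c(cuts, n_bins[ch])
      big <- which(tad_end - tad_start >= 25L)
      big <- setdiff(big, c(1L, length(tad_start)))  # keep clear of chrom ends
      need <- cfg$n_specific_boundaries * length(cfg$hic_stages)
      if (length(big) < need)
        stop("infeasible config: too few large TADs for specific boundaries")
      chosen <- sample(big, need)
      split_at <- vapply(chosen, function(k) {
        sz <- tad_end[k] - tad_start[k]
        off <- setdiff(10:(sz - 10L), (sz %/% 2L - 2L):(sz %/% 2L + 2L))
        tad_start[k] + if (length(off) == 1L) off else sample(off, 1L)
      }, numeric(1))
      sb <- data.frame(
        stage = rep(cfg$hic_stages, each = cfg$n_specific_boundaries),
        chrom = ch,
        bin = as.integer(split_at),
        stringsAsFactors = FALSE)
      spec_bnd[[ch]] <- sb
    }
    spec_bnd <- do.call(rbind, spec_bnd); rownames(spec_bnd) <- NULL

    # genes: 70% of TSSs in A-compartment bins, >= 5 kb apart
    n_per_chrom <- cfg$n_genes %/% length(chroms)
    genes <- list()
    gid <- 0L
    for (ch in chroms) {
      a_bins <- which(comp[[ch]] == "A") - 1L
      b_bins <- which(comp[[ch]] == "B") - 1L
      pos <- numeric(0)
      for (i in seq_len(n_per_chrom)) {
        repeat {
          bin <- if (runif(1) < 0.7) sample(a_bins, 1L) else sample(b_bins, 1L)
          p <- bin * res + sample.int(res, 1L) - 1L
          if (!length(pos) || min(abs(pos - p)) >= 5000) break
        }
        pos <- c(pos, p)
        gid <- gid + 1L
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene_%03d", gid), chrom = ch,
          tss = as.integer(p),
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, genes)
    list(shared_bnd = shared_bnd, spec_bnd = spec_bnd, comp = comp,
         genes = genes)
  })
  genes <- genome$genes
  # finest TAD partition (shared + every stage's specific boundaries); one
  # cell never straddles a boundary called in any Hi-C stage
  cell_cuts <- lapply(chroms, function(ch)
    sort(unique(c(genome$shared_bnd[[ch]],
                  genome$spec_bnd$bin[genome$spec_bnd$chrom == ch]))) * res)
  names(cell_cuts) <- chroms
  gene_cell <- vapply(seq_len(nrow(genes)), function(i)
    paste0(genes$chrom[i], ":",
           findInterval(genes$tss[i], cell_cuts[[genes$chrom[i]]])),
    character(1))

  ## ---- expression layer ------------------------------------------------
  exprl <- with_substream(seed, "expression", {
    arch <- archetype_profiles()
    cl <- rep(0L, cfg$n_genes)
    picked <- sample.int(cfg$n_genes, cfg$n_clusters * cfg$genes_per_cluster)
    cl[picked] <- rep(seq_len(cfg$n_clusters), each = cfg$genes_per_cluster)
    # a gene is a good regulatory target when few (ideally no) other genes
    # of its archetype share its TAD cell: the planted enhancer then
    # co-varies with (essentially) one gene in its TAD
    cellmates <- vapply(seq_len(cfg$n_genes), function(g)
      sum(cl == cl[g] & gene_cell == gene_cell[g]) - 1L, integer(1))
    prof <- matrix(0, cfg$n_genes, length(stages),
                   dimnames = list(genes$gene_id, stages))
    for (g in seq_len(cfg$n_genes)) {
      prof[g, ] <- if (cl[g] == 0L) rep(runif(1, 1, 3), length(stages))
      else arch[cl[g], ] + runif(1, 0, 0.5)
    }
    # core TFs: stage-peaked archetypes; decoys: flat background genes
    peaked <- c(2L, 3L, 5L, 6L, 7L)[seq_len(cfg$n_core_tfs)]
    core_tfs <- vapply(peaked, function(a)
      sample(genes$gene_id[cl == a], 1L), character(1))
    decoy_tfs <- sample(genes$gene_id[cl == 0L], cfg$n_decoy_tfs)
    targets <- lapply(seq_along(core_tfs), function(i) {
      idx <- setdiff(which(cl == peaked[i]),
                     match(core_tfs[i], genes$gene_id))
      if (length(idx) < cfg$n_targets_per_tf)
        stop("infeasible config: archetype smaller than targets per TF")
      ord <- idx[order(cellmates[idx], sample.int(length(idx)))]
      genes$gene_id[ord[seq_len(cfg$n_targets_per_tf)]]
    })
    names(targets) <- core_tfs
    vals <- matrix(0, cfg$n_genes, length(stages) * cfg$n_reps)
    colnames(vals) <- paste(rep(stages, each = cfg$n_reps),
                            rep(seq_len(cfg$n_reps), length(stages)),
                            sep = "_")
    rownames(vals) <- genes$gene_id
    for (s in seq_along(stages)) for (r in seq_len(cfg$n_reps))
      vals[, (s - 1L) * cfg$n_reps + r] <-
        2^(prof[, s] + rnorm(cfg$n_genes, 0, cfg$expr_noise_sd))
    # planted DEG directions from the noiseless profiles
    deg_truth <- list()
    for (i in seq_len(length(stages) - 1L)) {
      a <- stages[i]; b <- stages[i + 1L]
      lfc <- log2((2^prof[, b] + 1) / (2^prof[, a] + 1))
      deg_truth[[paste(a, b, sep = "_")]] <-
        list(up = genes$gene_id[lfc > 1], down = genes$gene_id[lfc < -1])
    }
    list(cl = cl, prof = prof, vals = vals, core_tfs = core_tfs,
         decoy_tfs = decoy_tfs, targets = targets, deg_truth = deg_truth)
  })
  expression <- expr_matrix(exprl$vals, stage_order = stages)

  ## ---- element layer: enhancers, peaks, SE/SS sites --------------------
  elements <- with_substream(seed, "elements", {
    occ <- lapply(chroms, function(ch) matrix(numeric(0), 0, 2))
    names(occ) <- chroms
    occ_me3 <- occ
    prom <- lapply(chroms, function(ch) {
      g <- genes[genes$chrom == ch, ]
      cbind(g$tss - 3000, g$tss + 3000)
    })
    names(prom) <- chroms
    gap <- cfg$min_element_gap

    # SE / SS cluster sites first (largest footprint)
    make_clusters <- function(n, label, stage_of, occ_list, avoid) {
      out <- list()
      for (i in seq_len(n)) {
        ch <- sample(chroms, 1L)
        site <- place_site(occ_list[[ch]], 25000, 0,
                           cfg$chrom_lengths[ch], gap, avoid[[ch]])
        if (is.null(site)) stop("could not place element cluster")
        occ_list[[ch]] <- rbind(occ_list[[ch]], site)
        # constituents inside the site
        w <- 1200L
        gaps <- sample(3000:6000, cfg$se_constituents - 1L, replace = TRUE)
        starts <- site[1] + cumsum(c(0L, gaps + w))
        out[[i]] <- list(name = sprintf("%s_%d", label, i), chrom = ch,
                         start = site[1], end = site[2],
                         stage = stage_of[i],
                         const_start = as.integer(starts),
                         const_end = as.integer(starts + w))
      }
      list(sites = out, occ = occ_list)
    }
    se_stage <- c(rep("all", cfg$n_se_shared),
                  rep(stages, each = cfg$n_se_specific_per_stage))
    r1 <- make_clusters(length(se_stage), "SE", se_stage, occ, prom)
    se_sites <- r1$sites; occ <- r1$occ
    ss_stage <- c(rep("all", cfg$n_ss_shared),
                  rep(stages, each = cfg$n_ss_specific_per_stage))
    r2 <- make_clusters(length(ss_stage), "SS", ss_stage, occ_me3, prom)
    ss_sites <- r2$sites; occ_me3 <- r2$occ

    # placement uses the finest partition so a planted proximal pair never
    # straddles a boundary called in any stage
    cell_of <- function(ch, pos) findInterval(pos, cell_cuts[[ch]])

    enh <- list(); k <- 0L
    add_enh <- function(ch, site, type, target, tf) {
      k <<- k + 1L
      enh[[k]] <<- data.frame(
        name = sprintf("enh_%03d", k), chrom = ch,
        start = as.integer(site[1]), end = as.integer(site[2]),
        type = type, target_gene = target, tf = tf,
        stringsAsFactors = FALSE)
    }
    # proximal (same-TAD) enhancers for every core-TF target
    triples <- list()
    for (tf in exprl$core_tfs) {
      for (g in exprl$targets[[tf]]) {
        gi <- genes[genes$gene_id == g, ]
        cuts <- c(0, cell_cuts[[gi$chrom]], cfg$chrom_lengths[gi$chrom])
        cell <- cell_of(gi$chrom, gi$tss)
        lo <- cuts[cell + 1L]; hi <- cuts[cell + 2L]
        site <- place_site(occ[[gi$chrom]], cfg$enh_width, lo, hi, gap,
                           prom[[gi$chrom]])
        if (is.null(site)) stop("could not place a proximal enhancer")
        occ[[gi$chrom]] <- rbind(occ[[gi$chrom]], site)
        add_enh(gi$chrom, site, "proximal", g, tf)
        triples[[length(triples) + 1L]] <-
          data.frame(tf = tf, enhancer = enh[[k]]$name, gene_id = g,
                     stringsAsFactors = FALSE)
      }
    }
    # distal enhancers linked through loops
    distal_genes <- sample(setdiff(genes$gene_id,
                                   unlist(exprl$targets)),
                           cfg$n_distal_links)
    for (g in distal_genes) {
      gi <- genes[genes$gene_id == g, ]
      repeat {
        off <- sample(c(-1, 1), 1L) * sample(200000:1500000, 1L)
        lo <- gi$tss + off
        if (lo > 50000 && lo + cfg$enh_width <
              cfg$chrom_lengths[gi$chrom] - 50000) break
      }
      site <- place_site(occ[[gi$chrom]], cfg$enh_width,
                         max(0, lo - 40000), lo + 40000, gap,
                         prom[[gi$chrom]])
      if (is.null(site))
        site <- place_site(occ[[gi$chrom]], cfg$enh_width, 0,
                           cfg$chrom_lengths[gi$chrom], gap,
                           prom[[gi$chrom]])
      occ[[gi$chrom]] <- rbind(occ[[gi$chrom]], site)
      add_enh(gi$chrom, site, "distal", g, NA_character_)
    }
    # decoy enhancers
    n_decoy <- cfg$n_enhancers - k
    for (i in seq_len(n_decoy)) {
      ch <- sample(chroms, 1L)
      site <- place_site(occ[[ch]], cfg$enh_width, 0,
                         cfg$chrom_lengths[ch], gap, prom[[ch]])
      if (is.null(site)) stop("could not place a decoy enhancer")
      occ[[ch]] <- rbind(occ[[ch]], site)
      add_enh(ch, site, "decoy", NA_character_, NA_character_)
    }
    enh <- do.call(rbind, enh)

    # per-enhancer per-stage activity profile (log2 a.u.)
    prof_e <- matrix(0, nrow(enh), length(stages),
                     dimnames = list(enh$name, stages))
    for (i in seq_len(nrow(enh))) {
      prof_e[i, ] <- if (enh$type[i] == "decoy")
        runif(1, 1.5, 3) + rnorm(length(stages), 0, 0.1)
      else pmax(0.1, exprl$prof[enh$target_gene[i], ] +
                  rnorm(length(stages), 0, cfg$enh_noise_sd))
    }

    # background scattered peaks (present in every stage, low signal)
    bg <- list()
    for (i in seq_len(cfg$n_bg_peaks)) {
      ch <- sample(chroms, 1L)
      site <- place_site(occ[[ch]], 800, 0, cfg$chrom_lengths[ch], gap)
      if (is.null(site)) stop("could not place a background peak")
      occ[[ch]] <- rbind(occ[[ch]], site)
      bg[[i]] <- data.frame(name = sprintf("bgpk_%03d", i), chrom = ch,
                            start = as.integer(site[1]),
                            end = as.integer(site[2]),
                            score = rexp(1) + 0.2, stringsAsFactors = FALSE)
    }
    bg <- do.call(rbind, bg)
    bg_me3 <- list()
    for (i in seq_len(cfg$n_bg_peaks_k27me3)) {
      ch <- sample(chroms, 1L)
      site <- place_site(occ_me3[[ch]], 800, 0, cfg$chrom_lengths[ch], gap)
      if (is.null(site)) stop("could not place a background peak")
      occ_me3[[ch]] <- rbind(occ_me3[[ch]], site)
      bg_me3[[i]] <- data.frame(name = sprintf("bgme_%03d", i), chrom = ch,
                                start = as.integer(site[1]),
                                end = as.integer(site[2]),
                                score = rexp(1) + 0.2,
                                stringsAsFactors = FALSE)
    }
    bg_me3 <- do.call(rbind, bg_me3)

    # per-stage constituent signals of SE/SS clusters
    cluster_signal <- function(sites) {
      lapply(sites, function(s) {
        sig <- matrix(0, cfg$se_constituents, length(stages),
                      dimnames = list(NULL, stages))
        on_stages <- if (s$stage == "all") stages else s$stage
        for (st in on_stages)
          sig[, st] <- 15 + rexp(cfg$se_constituents, 1 / 2)
        sig
      })
    }
    se_sig <- cluster_signal(se_sites)
    ss_sig <- cluster_signal(ss_sites)

    # assemble per-stage peak tables
    peaks_of_stage <- function(st, mark) {
      rows <- list()
      if (mark == "H3K27ac") {
        on <- prof_e[, st] >= cfg$peak_presence_threshold
        if (any(on))
          rows$enh <- gintervals(enh$chrom[on], enh$start[on], enh$end[on],
                                 name = enh$name[on], score = prof_e[on, st])
        rows$bg <- gintervals(bg$chrom, bg$start, bg$end, name = bg$name,
                              score = bg$score)
        sites <- se_sites; sigs <- se_sig
      } else {
        rows$bg <- gintervals(bg_me3$chrom, bg_me3$start, bg_me3$end,
                              name = bg_me3$name, score = bg_me3$score)
        sites <- ss_sites; sigs <- ss_sig
      }
      for (i in seq_along(sites)) {
        s <- sites[[i]]
        if (s$stage != "all" && s$stage != st) next
        rows[[s$name]] <- gintervals(
          s$chrom, s$const_start, s$const_end,
          name = sprintf("%s_c%d", s$name, seq_along(s$const_start)),
          score = sigs[[i]][, st])
      }
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out[order(out$chrom, out$start), , drop = FALSE]
    }
    peaks_k27ac <- lapply(setNames(stages, stages), peaks_of_stage,
                          mark = "H3K27ac")
    peaks_k27me3 <- lapply(setNames(stages, stages), peaks_of_stage,
                           mark = "H3K27me3")
    site_df <- function(sites) do.call(rbind, lapply(sites, function(s)
      data.frame(name = s$name, chrom = s$chrom, start = s$start,
                 end = s$end, stage = s$stage, stringsAsFactors = FALSE)))
    list(enh = enh, prof_e = prof_e,
         triples = do.call(rbind, triples),
         peaks_k27ac = peaks_k27ac, peaks_k27me3 = peaks_k27me3,
         se_regions = site_df(se_sites), ss_regions = site_df(ss_sites))
  })
  enh <- elements$enh

  ## ---- Hi-C layer ------------------------------------------------------
  hic <- with_substream(seed, "hic", {
    out <- list()
    for (st in cfg$hic_stages) {
      out[[st]] <- list()
      for (ch in chroms) {
        n <- n_bins[ch]
        cuts <- sort(unique(c(genome$shared_bnd[[ch]],
                              genome$spec_bnd$bin[
                                genome$spec_bnd$chrom == ch &
                                  genome$spec_bnd$stage == st])))
        tid <- findInterval(seq_len(n) - 1L, cuts)
        comp <- genome$comp[[ch]]
        D <- abs(outer(seq_len(n), seq_len(n), "-"))
        mu <- cfg$hic_depth * (1 / (1 + D))^cfg$decay_exponent
        mu <- mu * ifelse(outer(tid, tid, "=="), cfg$tad_enrichment, 1)
        mu <- mu * ifelse(outer(comp, comp, "=="), cfg$comp_enrichment, 1)
        cnt <- matrix(0, n, n)
        up <- upper.tri(cnt, diag = TRUE)
        cnt[up] <- rpois(sum(up), mu[up])
        cnt <- cnt + t(cnt) - diag(diag(cnt))
        out[[st]][[ch]] <- contact_matrix(ch, res, cnt)
      }
    }
    out
  })

  ## ---- loop layer ------------------------------------------------------
  loopsl <- with_substream(seed, "loops", {
    distal <- enh[enh$type == "distal", ]
    rows <- list(); truth <- list()
    for (i in seq_len(nrow(distal))) {
      gi <- genes[genes$gene_id == distal$target_gene[i], ]
      emid <- (distal$start[i] + distal$end[i]) %/% 2L
      sc <- runif(1, 5, 15)
      for (r in cfg$loop_resolutions) {
        b_e <- emid %/% r; b_p <- gi$tss %/% r
        a <- sort(c(b_e, b_p))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = gi$chrom, start1 = a[1] * r, end1 = (a[1] + 1L) * r,
          start2 = a[2] * r, end2 = (a[2] + 1L) * r,
          name = sprintf("true_%d_%d", i, r), score = sc, resolution = r,
          stringsAsFactors = FALSE)
      }
      truth[[i]] <- data.frame(enhancer = distal$name[i],
                               gene_id = distal$target_gene[i],
                               stringsAsFactors = FALSE)
    }
    # decoy loops with anchors clear of enhancers and promoters
    prom_zone <- lapply(chroms, function(ch) {
      g <- genes[genes$chrom == ch, ]
      e <- enh[enh$chrom == ch, ]
      rbind(cbind(g$tss - cfg$promoter_flank, g$tss + cfg$promoter_flank),
            cbind(e$start, e$end))
    })
    names(prom_zone) <- chroms
    for (i in seq_len(cfg$n_decoy_loops)) {
      repeat {
        ch <- sample(chroms, 1L)
        r <- sample(cfg$loop_resolutions, 1L)
        nb <- as.integer(cfg$chrom_lengths[ch] %/% r)
        b1 <- sample.int(nb - 120L, 1L)
        b2 <- b1 + sample(10:100, 1L)
        z <- prom_zone[[ch]]
        mres <- max(cfg$loop_resolutions)
        # the anchor must stay clear of enhancers/promoters even after
        # midpoint re-binning to the coarsest (merge) resolution
        clear <- function(b) {
          mb <- ((b * r + (b + 1L) * r) %/% 2L) %/% mres
          !any(b * r < z[, 2] & (b + 1L) * r > z[, 1]) &&
            !any(mb * mres < z[, 2] & (mb + 1L) * mres > z[, 1])
        }
        if (clear(b1) && clear(b2)) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start1 = b1 * r, end1 = (b1 + 1L) * r,
        start2 = b2 * r, end2 = (b2 + 1L) * r,
        name = sprintf("decoy_%d", i), score = runif(1, 1, 8),
        resolution = r, stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, rows)
    list(loops = loop_calls(all$chrom, all$start1, all$end1, all$start2,
                            all$end2, all$resolution, all$score, all$name),
         truth = do.call(rbind, truth))
  })

  ## ---- sequence layer --------------------------------------------------
  seql <- with_substream(seed, "sequences", {
    width <- cfg$motif_width
    tf_names <- c(exprl$core_tfs, exprl$decoy_tfs)
    cons <- setNames(vapply(tf_names, function(x) random_dna(width),
                            character(1)), tf_names)
    pwms <- lapply(tf_names, function(tf) consensus_pwm(tf, cons[[tf]]))
    names(pwms) <- tf_names
    seqs <- setNames(vapply(seq_len(nrow(enh)), function(i)
      random_dna(cfg$enh_width), character(1)), enh$name)
    plant <- function(seq, motif, times = 2L) {
      w <- nchar(motif)
      spots <- sample(seq(1L, nchar(seq) - w, by = w + 5L), times)
      for (s in spots) substr(seq, s, s + w - 1L) <- motif
      seq
    }
    for (i in seq_len(nrow(elements$triples))) {
      e <- elements$triples$enhancer[i]
      seqs[[e]] <- plant(seqs[[e]], cons[[elements$triples$tf[i]]])
    }
    decoy_enh <- enh$name[enh$type == "decoy"]
    for (tf in exprl$decoy_tfs)
      for (e in sample(decoy_enh, 2L))
        seqs[[e]] <- plant(seqs[[e]], cons[[tf]], times = 1L)
    list(seqs = seqs, pwms = pwms, consensus = cons)
  })

  ## ---- GWAS layer ------------------------------------------------------
  gwasl <- with_substream(seed, "gwas", {
    linked <- enh[enh$type %in% c("proximal", "distal"), ]
    pick <- linked[sample.int(nrow(linked), cfg$n_gwas_in_enh), ]
    mid <- (pick$start + pick$end) %/% 2L
    loci <- data.frame(chrom = pick$chrom, start = mid, end = mid + 1L,
                       in_enhancer = pick$name, stringsAsFactors = FALSE)
    for (i in seq_len(cfg$n_gwas_bg)) {
      repeat {
        ch <- sample(chroms, 1L)
        p <- sample.int(cfg$chrom_lengths[ch] - 1L, 1L)
        e <- enh[enh$chrom == ch, ]
        if (!any(p >= e$start & p < e$end)) break
      }
      loci <- rbind(loci, data.frame(chrom = ch, start = p, end = p + 1L,
                                     in_enhancer = NA_character_,
                                     stringsAsFactors = FALSE))
    }
    loci$name <- sprintf("rs_%03d", seq_len(nrow(loci)))
    loci
  })
  gwas_loci <- gintervals(gwasl$chrom, gwasl$start, gwasl$end,
                          name = gwasl$name)

  truth <- list(
    seed = seed,
    shared_boundaries = genome$shared_bnd,
    specific_boundaries = genome$spec_bnd,
    compartments = genome$comp,
    cluster_labels = setNames(exprl$cl, genes$gene_id),
    core_tfs = exprl$core_tfs,
    decoy_tfs = exprl$decoy_tfs,
    tf_targets = exprl$targets,
    deg_truth = exprl$deg_truth,
    gene_profiles = exprl$prof,
    planted_triples = elements$triples,
    se_regions = elements$se_regions,
    ss_regions = elements$ss_regions,
    loop_truth = loopsl$truth,
    gwas_truth = gwasl[!is.na(gwasl$in_enhancer),
                       c("name", "in_enhancer")],
    motif_consensus = seql$consensus)

  sim <- list(config = cfg, seed = seed,
              genes = cbind(genes,
                            cluster = exprl$cl,
                            tf_role = ifelse(
                              genes$gene_id %in% exprl$core_tfs, "core",
                              ifelse(genes$gene_id %in% exprl$decoy_tfs,
                                     "decoy", NA_character_))),
              expression = expression,
              enhancers = enh,
              enh_profiles = elements$prof_e,
              peaks_k27ac = elements$peaks_k27ac,
              peaks_k27me3 = elements$peaks_k27me3,
              hic = hic,
              loops = loopsl$loops,
              sequences = seql$seqs,
              pwms = seql$pwms,
              gwas_loci = gwas_loci,
              truth = truth)
  class(sim) <- "follireg_sim"
  if (!is.null(out_dir)) write_dataset(sim, out_dir)
  sim
}

#' @export
print.follireg_sim <- function(x, ...) {
  cat("synthetic folliculogenesis dataset | seed", x$seed, "\n")
  cat(" ", nrow(x$genes), "genes,", nrow(x$enhancers), "enhancers,",
      length(x$peaks_k27ac), "stages,", length(x$hic), "Hi-C stages\n")
  invisible(x)
}

#' Write a simulated dataset to disk in the package's interchange formats
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "hic"), showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write.table(sim$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_expression(sim$expression, p("expression.tsv"))
  write.table(data.frame(enhancer = rownames(sim$enh_profiles),
                         sim$enh_profiles, check.names = FALSE),
              p("enh_signal.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bed(gintervals(sim$enhancers$chrom, sim$enhancers$start,
                       sim$enhancers$end, name = sim$enhancers$name),
            p("enhancers.bed"))
  for (st in names(sim$peaks_k27ac)) {
    write_bed(sim$peaks_k27ac[[st]],
              p("peaks", sprintf("H3K27ac_%s.bed", st)))
    write_bed(sim$peaks_k27me3[[st]],
              p("peaks", sprintf("H3K27me3_%s.bed", st)))
  }
  for (st in names(sim$hic)) for (ch in names(sim$hic[[st]]))
    write_contact_matrix(sim$hic[[st]][[ch]],
                         p("hic", sprintf("%s_%s.coo.tsv", st, ch)))
  write_bedpe(sim$loops, p("loops.bedpe"))
  write_fasta(sim$sequences, p("enhancers.fa"))
  write_meme(sim$pwms, p("pwms.meme"))
  write_bed(sim$gwas_loci, p("gwas_loci.bed"))
  truth <- sim$truth
  truth$gene_profiles <- cbind(
    data.frame(gene_id = rownames(truth$gene_profiles)),
    as.data.frame(truth$gene_profiles))
  # named atomic vectors serialise as bare arrays; keep their names by
  # converting to objects
  truth$cluster_labels <- as.list(truth$cluster_labels)
  truth$motif_consensus <- as.list(truth$motif_consensus)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg_out <- sim$config
  cfg_out$chrom_lengths <- as.list(cfg_out$chrom_lengths)
  jsonlite::write_json(cfg_out, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
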