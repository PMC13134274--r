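# small structured contact matrix: block TADs on a distance-decay
# background, optionally with a compartment checkerboard
toy_matrix <- function(n = 120, cuts = c(40, 80), depth = 200,
                       tad_fc = 3, comp = NULL, comp_fc = 1.5,
                       noise = TRUE) {
  tid <- findInterval(seq_len(n) - 1, cuts)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- depth / (1 + D)
  mu <- mu * ifelse(outer(tid, tid, "=="), tad_fc, 1)
  if (!is.null(comp))
    mu <- mu * ifelse(outer(comp, comp, "=="), comp_fc, 1)
  m <- if (noise) {
    x <- matrix(0, n, n); up <- upper.tri(x, diag = TRUE)
    x[up] <- rpois(sum(up), mu[up]); x + t(x) - diag(diag(x))
  } else mu
  contact_matrix("chrT", 20000L, m)
}

test_that("resolution_qc counts strictly covered bins", {
  m0 <- contact_matrix("c", 1e4L, matrix(0, 5, 5))
  expect_equal(resolution_qc(m0), 0)
  m1 <- contact_matrix("c", 1e4L, diag(1001, 5))
  expect_equal(resolution_qc(m1, 1000), 1)
  expect_equal(resolution_qc(m1, 1001), 0)   # strict >
  set.seed(1)
  x <- matrix(rpois(400, 60), 20, 20); x <- x + t(x)
  m <- contact_matrix("c", 1e4L, x)
  expect_equal(resolution_qc(m, 2400), mean(rowSums(x) > 2400))
})

test_that("balancing equalises coverage and preserves symmetry", {
  set.seed(2)
  m <- toy_matrix(n = 60, cuts = 30)
  b <- balance_matrix(m)
  expect_true(b$balanced)
  s <- rowSums(b$counts)
  expect_lt(sd(s[s > 0]) / mean(s[s > 0]), 1e-3)
  expect_equal(b$counts, t(b$counts))
})

test_that("compartment eigenvector recovers a planted checkerboard", {
  set.seed(3)
  comp <- rep(rep(c("A", "B"), each = 30), 2)
  m <- balance_matrix(toy_matrix(n = 120, cuts = c(30, 60, 90),
                                 comp = comp, comp_fc = 3))
  ori <- signal_track("chrT", 20000L,
                      ifelse(comp == "A", 1, 0) + rnorm(120, 0, 0.2))
  cp <- compartment_eigenvector(m, ori)
  ok <- !is.na(cp$compartment)
  expect_gte(mean(cp$compartment[ok] == comp[ok]), 0.95)
  # flipping the orientation track flips every label
  ori_neg <- signal_track("chrT", 20000L, -ori$values)
  cp2 <- compartment_eigenvector(m, ori_neg)
  expect_true(all(cp2$compartment[ok] != cp$compartment[ok]))
  # global matrix scaling leaves labels unchanged
  m2 <- contact_matrix(m$chrom, m$resolution, 7 * m$counts, balanced = TRUE)
  cp3 <- compartment_eigenvector(m2, ori)
  expect_equal(cp3$compartment, cp$compartment)
  # degenerate inputs
  ori30 <- signal_track("c", 1e4L, rnorm(30))
  expect_error(compartment_eigenvector(
    contact_matrix("c", 1e4L, matrix(0, 30, 30)), ori30), "informative")
})

test_that("insulation dips at block joints, is flat on uniform matrices and
           scale-invariant", {
  set.seed(4)
  m <- toy_matrix(n = 120, cuts = c(40, 80), noise = FALSE)
  it <- insulation_track(m, window_bins = 10L)
  b <- call_boundaries(it, delta_min = 0.1)
  expect_true(all(vapply(c(40, 80), function(t)
    any(abs(b$bin - t) <= 1), logical(1))))
  expect_lte(nrow(b), 3)
  # uniform matrix: flat track, no boundaries
  u <- contact_matrix("c", 1e4L, matrix(5, 60, 60))
  itu <- insulation_track(u)
  expect_true(all(abs(itu$values[!is.na(itu$values)]) < 1e-9))
  expect_equal(nrow(call_boundaries(itu)), 0L)
  # doubling all counts leaves the track unchanged
  m2 <- contact_matrix(m$chrom, m$resolution, 2 * m$counts)
  expect_equal(insulation_track(m2)$values, it$values, tolerance = 1e-12)
  # edge bins are NA
  expect_true(all(is.na(it$values[1:10])))
})

test_that("call_boundaries applies the prominence rule with leftmost ties", {
  v <- rep(0, 40)
  v[20] <- -1                       # single V dip, depth 1
  tr <- signal_track("c", 1e4L, v)
  b <- call_boundaries(tr, delta_min = 0.5)
  expect_equal(b$bin, 19L)          # 0-based
  # plateau minimum reports its leftmost bin
  v2 <- rep(0, 40); v2[18:21] <- -1
  b2 <- call_boundaries(signal_track("c", 1e4L, v2), delta_min = 0.5)
  expect_equal(b2$bin, 17L)
  # a dip shallower than delta_min is not called
  v3 <- rep(0, 40); v3[20] <- -0.05
  expect_equal(nrow(call_boundaries(signal_track("c", 1e4L, v3), 0.1)), 0L)
  expect_equal(nrow(call_boundaries(signal_track("c", 1e4L, rep(1, 40)))),
               0L)
})

test_that("eight planted boundaries are recovered exactly on a clean
           chromosome", {
  set.seed(5)
  cuts <- c(30, 65, 95, 130, 170, 200, 240, 270)
  m <- toy_matrix(n = 300, cuts = cuts, depth = 400)
  b <- call_boundaries(insulation_track(m), delta_min = 0.1)
  hits <- vapply(cuts, function(t) min(abs(b$bin - t)), numeric(1))
  expect_true(all(hits <= 1))
  extras <- vapply(b$bin, function(x) min(abs(cuts - x)), numeric(1))
  expect_equal(sum(extras > 1), 0L)
})

test_that("boundary_similarity is a windowed Spearman with NA handling", {
  set.seed(6)
  v <- rnorm(60)
  ta <- signal_track("c", 1e4L, v)
  expect_equal(boundary_similarity(30, ta, ta), 1)
  tb <- signal_track("c", 1e4L, -v)
  expect_equal(boundary_similarity(30, ta, tb), -1)
  # ties: equals rank-then-Pearson with average ranks
  va <- c(rnorm(18), rep(0.5, 3))[sample.int(21)]
  vb <- c(rnorm(15), rep(-0.2, 6))[sample.int(21)]
  ta2 <- signal_track("c", 1e4L, c(rep(NA, 5), va, rep(NA, 5)))
  tb2 <- signal_track("c", 1e4L, c(rep(NA, 5), vb, rep(NA, 5)))
  got <- boundary_similarity(15, ta2, tb2)
  expect_equal(got, cor(rank(va), rank(vb)), tolerance = 1e-12)
  # too few valid pairs -> NA with warning
  ta3 <- signal_track("c", 1e4L, c(rep(NA, 15), rnorm(45)))
  expect_warning(r <- boundary_similarity(12, ta3, ta3), "11 valid")
  expect_true(is.na(r))
  expect_warning(r2 <- boundary_similarity(3, ta, ta), "past the track")
  expect_true(is.na(r2))
})

test_that("boundary_null is seeded, concentrated for identical tracks and
           centred for independent noise", {
  set.seed(7)
  v <- rnorm(400)
  ta <- signal_track("c", 1e4L, v)
  null_same <- boundary_null(ta, ta, n_perm = 200, seed = 1)
  expect_gte(quantile(null_same, 0.95), 0.99)
  tb <- signal_track("c", 1e4L, rnorm(400))
  null_ind <- boundary_null(ta, tb, n_perm = 1000, seed = 2)
  expect_lt(abs(mean(null_ind)), 0.05)
  expect_identical(boundary_null(ta, tb, n_perm = 100, seed = 9),
                   boundary_null(ta, tb, n_perm = 100, seed = 9))
})

test_that("classifier flags planted specific boundaries and nothing on
           matched tracks", {
  set.seed(8)
  # three stages, one boundary present only in stage 2
  cuts_shared <- c(50, 100, 150)
  mk <- function(extra) {
    m <- toy_matrix(n = 200, cuts = sort(c(cuts_shared, extra)),
                    depth = 300)
    insulation_track(m)
  }
  tracks <- list(s1 = mk(NULL), s2 = mk(75), s3 = mk(NULL))
  bounds <- lapply(tracks, call_boundaries)
  cls <- classify_specific_boundaries(bounds, tracks,
                                      stage_order = c("s1", "s2", "s3"),
                                      n_perm = 200, seed = 5)
  hit <- cls[cls$stage == "s2" & abs(cls$bin - 75) <= 1, ]
  expect_true(nrow(hit) == 1 && hit$specific)
  # shared boundaries are not flagged
  shared_rows <- cls[vapply(cls$bin, function(b)
    any(abs(cuts_shared - b) <= 1), logical(1)), ]
  expect_true(all(!shared_rows$specific))
  # identical tracks in all stages: nothing is specific
  tracks_eq <- list(a = tracks$s1, b = tracks$s1, c = tracks$s1)
  bounds_eq <- lapply(tracks_eq, call_boundaries)
  cls_eq <- classify_specific_boundaries(bounds_eq, tracks_eq,
                                         stage_order = c("a", "b", "c"),
                                         n_perm = 100, seed = 6)
  expect_true(all(!cls_eq$specific))
})

test_that("intra-TAD strength: uniform value, planted enrichment, linearity", {
  u <- contact_matrix("chrT", 20000L, matrix(4, 60, 60))
  tads <- gintervals("chrT", c(0, 400000), c(400000, 1200000))
  expect_equal(intra_tad_strength(u, tads), c(4, 4))
  # TAD smaller than 2 bins
  tiny <- gintervals("chrT", 0, 20000)
  expect_true(is.na(intra_tad_strength(u, tiny)))
  set.seed(9)
  m <- balance_matrix(toy_matrix(n = 120, cuts = c(40, 80), tad_fc = 3))
  tads2 <- gintervals("chrT", c(0, 40, 80) * 20000,
                      c(40, 80, 120) * 20000)
  s_in <- intra_tad_strength(m, tads2)
  inter <- mean(m$counts[1:40, 81:120])
  expect_true(all(s_in > 2 * inter))
  m2 <- contact_matrix(m$chrom, m$resolution, 2 * m$counts, balanced = TRUE)
  expect_equal(intra_tad_strength(m2, tads2), 2 * s_in)
})

test_that("merge_loops collapses by midpoint re-binning, matches the oracle
           and is idempotent", {
  # same loop at 10 kb and 25 kb with midpoints in the same 25 kb bins
  l1 <- loop_calls("chr1", 110000, 120000, 510000, 520000, 10000L, 3, "a")
  l2 <- loop_calls("chr1", 100000, 125000, 500000, 525000, 25000L, 5, "b")
  m <- merge_loops(list(l1, l2))
  expect_equal(nrow(m), 1L)
  expect_equal(m$score, 5)         # max score kept
  expect_equal(m$start1, 100000L)
  expect_equal(m$end1, 125000L)
  # different 25 kb bins stay apart
  l3 <- loop_calls("chr1", 150000, 160000, 510000, 520000, 10000L, 1, "c")
  expect_equal(nrow(merge_loops(list(l1, l3))), 2L)
  # random loop sets vs brute-force binned equality
  set.seed(10)
  n <- 80
  a1 <- sample.int(2e6, n); a2 <- a1 + sample.int(1e6, n) + 50000
  r <- sample(c(10000L, 20000L, 25000L), n, TRUE)
  ll <- loop_calls(sample(c("chr1", "chr2"), n, TRUE),
                   (a1 %/% r) * r, (a1 %/% r + 1) * r,
                   (a2 %/% r) * r, (a2 %/% r + 1) * r,
                   r, runif(n, 0, 10), sprintf("l%d", 1:n))
  got <- merge_loops(ll)
  want <- oracle_merge_loops(ll, 25000L)
  expect_equal(nrow(got), nrow(want))
  expect_equal(sort(got$score), unname(sort(want[, 3])))
  # idempotence
  expect_equal(merge_loops(got)[, c("chrom", "start1", "start2", "score")],
               got[, c("chrom", "start1", "start2", "score")],
               ignore_attr = TRUE)
})

test_that("link_distal pairs enhancer and promoter across anchors only", {
  loops <- loop_calls("chr1", 100000, 125000, 500000, 525000, 25000L,
                      5, "L1")
  enh <- gintervals("chr1", 110000, 111000, name = "E1")
  prom <- gintervals("chr1", 509000, 513000, name = "G1")
  got <- link_distal(loops, enh, prom)
  expect_equal(got$enhancer, "E1")
  expect_equal(got$gene_id, "G1")
  expect_equal(got$distance,
               abs((110000 + 111000) %/% 2 - (509000 + 513000) %/% 2))
  # both features on the same anchor: no pair
  prom_same <- gintervals("chr1", 120000, 124000, name = "G2")
  expect_equal(nrow(link_distal(loops, enh, prom_same)), 0L)
  # planted generator truth: every distal link recovered, decoy loops
  # produce nothing
  sim <- shared_sim()
  merged <- merge_loops(sim$loops)
  enh_iv <- gintervals(sim$enhancers$chrom, sim$enhancers$start,
                       sim$enhancers$end, name = sim$enhancers$name)
  promoters <- make_promoters(sim$genes)
  links <- link_distal(merged, enh_iv, promoters)
  lt <- sim$truth$loop_truth
  expect_true(all(paste(lt$enhancer, lt$gene_id) %in%
                    paste(links$enhancer, links$gene_id)))
  decoys <- merge_loops(sim$loops[grepl("^decoy", sim$loops$name), ])
  expect_equal(nrow(link_distal(decoys, enh_iv, promoters)), 0L)
})
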