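# Synthetic-data generators: bit-identical regeneration and planted
# ground-truth recovery.

test_that("generators regenerate bit-identically from (seed, params)", {
  expect_identical(simulate_peaksets(seed = 5),
                   simulate_peaksets(seed = 5))
  expect_identical(simulate_super_enhancer_landscape(seed = 5),
                   simulate_super_enhancer_landscape(seed = 5))
  expect_identical(simulate_expression_and_links(n_enhancers = 40,
                                                 seed = 5),
                   simulate_expression_and_links(n_enhancers = 40,
                                                 seed = 5))
  expect_identical(simulate_activity_correlation(seed = 5),
                   simulate_activity_correlation(seed = 5))
  expect_identical(simulate_perturb(n_cells = 100, n_genes = 20,
                                    seed = 5),
                   simulate_perturb(n_cells = 100, n_genes = 20,
                                    seed = 5))
  # a different seed changes the draw
  expect_false(identical(simulate_peaksets(seed = 5),
                         simulate_peaksets(seed = 6)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_peaksets(seed = 9))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("peakset generator plants recoverable consensus structure", {
  for (seed in c(1, 7)) {
    pk <- simulate_peaksets(n_shared = 80, n_private_per_sample = 40,
                            jitter_bp = 200, seed = seed)
    cons <- consensus_intervals(pk$h3k27ac, 3)
    expect_equal(n_intervals(cons), 80)
    enh <- mapply(call_putative_enhancers, pk$h3k27ac, pk$h3k4me1,
                  SIMPLIFY = FALSE)
    expect_equal(build_catalog(enh)$n_common, 80)
  }
  # private-only landscape has an empty all-sample consensus
  pk0 <- simulate_peaksets(n_shared = 0, n_private_per_sample = 30,
                           seed = 2)
  expect_equal(n_intervals(consensus_intervals(pk0$h3k27ac, 3)), 0)
  # zero jitter: consensus intervals equal the planted loci exactly
  pkz <- simulate_peaksets(n_shared = 25, n_private_per_sample = 0,
                           jitter_bp = 0, seed = 3)
  cons <- as.data.frame(consensus_intervals(pkz$h3k27ac, 3))
  sl <- pkz$manifest$shared_loci
  sl <- sl[order(sl$chrom, sl$pos), ]
  expect_equal(cons$start, sl$pos)
  expect_equal(cons$end, sl$pos + sl$width)
})

test_that("super-enhancer generator yields exact recovery", {
  for (seed in 1:5) {
    k <- sample(0:12, 1)
    se <- simulate_super_enhancer_landscape(k_clusters = k, seed = seed)
    ses <- call_super_enhancers(se$peaks)
    expect_equal(nrow(ses), k)
    expect_equal(ses$start, se$manifest$cluster_spans$start)
    expect_equal(ses$end, se$manifest$cluster_spans$end)
  }
  # spans forced below the size threshold are rejected
  below <- simulate_super_enhancer_landscape(
    k_clusters = 4, span_range = c(14999, 14999), seed = 8)
  expect_equal(nrow(call_super_enhancers(below$peaks)), 0)
})

test_that("expression/link generator hits planted fractions exactly", {
  xl <- simulate_expression_and_links(n_enhancers = 200, seed = 6)
  bins <- bin_expression(xl$fpkm)
  # planted bins recovered exactly from FPKM bounds
  for (b in names(xl$manifest$planted)) {
    planted_genes <- grep(paste0("^G_", toupper(substr(b, 1, 2))),
                          names(bins), value = TRUE)
    if (length(planted_genes))
      expect_true(all(bins[planted_genes] == b))
  }
  links <- associate_by_window(xl$enhancers, xl$genes)
  fr <- association_fractions(links, xl$enhancers, bins)
  expect_equal(stats::setNames(fr$fraction, fr$bin),
               xl$manifest$expected_fractions)
  # zero target -> no links in that bin
  xl0 <- simulate_expression_and_links(
    n_enhancers = 50, bin_fractions = c(inactive = 0, low = 0, mid = 0,
                                        high = 0.2), seed = 2)
  fr0 <- association_fractions(
    associate_by_window(xl0$enhancers, xl0$genes), xl0$enhancers,
    bin_expression(xl0$fpkm))
  expect_equal(fr0$fraction[fr0$bin == "low"], 0)
  expect_equal(fr0$fraction[fr0$bin == "high"], 0.2)
})

test_that("activity generator plants a recoverable activity axis", {
  act <- simulate_activity_correlation(rho = 0.9, noise_sd = 0.2,
                                       seed = 11)
  sc <- compute_tscores(act$fpkm, act$signature)
  expect_gt(cor(sc$t_score, act$manifest$delta, method = "spearman"),
            0.9)
  # rho ~ 1 with no noise on the target: r near 1 against delta
  act1 <- simulate_activity_correlation(rho = 0.999, seed = 12)
  r <- correlate_activity(act1$manifest$delta,
                          act1$fpkm[act1$target_gene, ])$r
  expect_gt(r, 0.99)
})

test_that("perturb generator plants class proportions and fold changes", {
  sim <- simulate_perturb(n_cells = 4000, seed = 13)
  asg <- assign_grnas(sim$dataset)
  fr <- attr(asg, "class_fractions")
  expect_equal(unname(fr["singlet"]), 0.567, tolerance = 0.05)
  expect_equal(unname(fr["multiplet"]), 0.270, tolerance = 0.08)
  # assignment agrees with the manifest's planted classes
  expect_equal(unname(asg$multiplicity_class),
               unname(sim$manifest$classes))
  expect_equal(asg$grna, unname(sim$manifest$cell_grna))
})
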