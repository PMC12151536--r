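# Expression binning, TSS-window and loop association, fractions.

test_that("bin_expression applies boundary rules exactly", {
  x <- c(A = 15.0, B = 14.99, C = 4.99, D = 0.99, E = 0, F = 1.0,
         G = 5.0)
  bins <- bin_expression(x)
  expect_equal(as.character(bins[c("A", "B", "C", "D", "E", "F", "G")]),
               c("high", "mid", "low", "inactive", "inactive", "low",
                 "mid"))
  expect_error(bin_expression(c(A = -1)), "non-negative")
  # bins partition: every gene in exactly one bin
  set.seed(5)
  m <- matrix(runif(600, 0, 40), nrow = 200,
              dimnames = list(sprintf("g%d", 1:200), NULL))
  b <- bin_expression(m)
  expect_equal(sum(table(b)), 200)
  # direct threshold enumeration oracle
  mu <- rowMeans(m)
  expect_equal(unname(table(b)["high"]), sum(mu >= 15))
  expect_equal(unname(table(b)["inactive"]), sum(mu < 1))
  expect_equal(unname(table(b)["low"]), sum(mu >= 1 & mu < 5))
})

test_that("window association boundary arithmetic (midpoint and edge)", {
  enh <- canonicalize(interval_set("chr1", 49000, 51000))  # midpoint 50000
  g <- gene_models(c("in", "out", "inside"), "chr1", c("+", "+", "+"),
                   c(149999, 150001, 50000))
  links <- associate_by_window(enh, g, 100000, "midpoint")
  expect_setequal(links$gene_id, c("in", "inside"))
  expect_equal(links$distance[links$gene_id == "in"], 99999)
  # edge mode: TSS inside the enhancer -> distance 0
  le <- associate_by_window(enh, g, 100000, "edge")
  expect_equal(le$distance[le$gene_id == "inside"], 0)
  expect_error(associate_by_window(enh, g, 0), "positive")
})

test_that("window association equals the all-pairs oracle and is
           monotone in window size", {
  set.seed(21)
  for (rep in 1:25) {
    enh_df <- random_intervals(20, len = 400000, max_w = 3000)
    enh <- canonicalize(set_from_df(enh_df))
    ng <- 15
    genes <- gene_models(sprintf("g%d", 1:ng),
                         sample(c("chr1", "chr2"), ng, TRUE),
                         sample(c("+", "-"), ng, TRUE),
                         sample.int(400000, ng))
    anchor <- sample(c("midpoint", "edge"), 1)
    w <- sample(c(20000, 50000, 100000), 1)
    got <- associate_by_window(enh, genes, w, anchor)
    exp <- oracle_window_links(as.data.frame(enh), genes, w, anchor)
    expect_equal(nrow(got), nrow(exp))
    expect_equal(sort(paste(got$enhancer_id, got$gene_id)),
                 sort(paste(enhancer_ids(enh)[exp$i], exp$gene_id)))
    expect_equal(sort(got$distance), sort(exp$distance))
    # monotonicity: enlarging the window never removes a link
    bigger <- associate_by_window(enh, genes, w + 30000, anchor)
    expect_true(all(paste(got$enhancer_id, got$gene_id) %in%
                      paste(bigger$enhancer_id, bigger$gene_id)))
  }
})

test_that("loop association links opposite anchors only and is
           anchor-symmetric", {
  enh <- canonicalize(interval_set("chr1", c(10000, 200000),
                                   c(12000, 202000)))
  genes <- gene_models(c("target", "same_anchor"), "chr1", c("+", "+"),
                       c(100500, 10500))
  loops <- chromatin_loops("chr1", 10000, 13000, 100000, 101000)
  links <- associate_by_loop(enh, genes, loops)
  expect_equal(nrow(links), 1)
  expect_equal(links$gene_id, "target")
  expect_equal(links$evidence, "loop")
  # swapping anchors gives the same links
  swapped <- chromatin_loops("chr1", 100000, 101000, 10000, 13000)
  expect_equal(as.data.frame(associate_by_loop(enh, genes, swapped)),
               as.data.frame(links))
  # enhancer and TSS in the same anchor only -> not linked
  expect_false("same_anchor" %in% links$gene_id)
  # anchors on different chromosomes rejected at load
  expect_error(chromatin_loops("chr1", 0, 10, 100, 200,
                               chrom_b = "chr2"), "same chromosome")
  expect_error(chromatin_loops("chr1", 0, 100, 50, 200), "not overlap")
})

test_that("a TSS-anchored loop to an upstream enhancer yields one link", {
  # one anchor at a gene TSS, the other ~90 kb upstream over an enhancer
  tss <- 500000
  genes <- gene_models("PLCL2", "chr3", "+", tss)
  enh <- canonicalize(interval_set("chr3", tss - 91000, tss - 89000))
  loops <- chromatin_loops("chr3", tss - 92000, tss - 88000,
                           tss - 2000, tss + 2000)
  links <- associate_by_loop(enh, genes, loops)
  expect_equal(nrow(links), 1)
  expect_equal(links$gene_id, "PLCL2")
})

test_that("combine_evidence marks dual-support pairs as 'both'", {
  enh <- canonicalize(interval_set("chr1", 10000, 12000))
  genes <- gene_models(c("near", "far"), "chr1", c("+", "+"),
                       c(50000, 300000))
  w <- associate_by_window(enh, genes, 100000)
  loops <- chromatin_loops("chr1", 9000, 13000, c(49000, 299000),
                           c(51000, 301000))
  l <- associate_by_loop(enh, genes, loops)
  comb <- combine_evidence(w, l)
  expect_equal(comb$evidence[comb$gene_id == "near"], "both")
  expect_equal(comb$evidence[comb$gene_id == "far"], "loop")
})

test_that("association_fractions counts enhancers with >= 1 link per bin", {
  enh <- canonicalize(interval_set("chr1",
                                   c(0, 300000, 600000, 900000),
                                   c(2000, 302000, 602000, 902000)))
  genes <- gene_models(c("h1", "h2", "l1"), "chr1", rep("+", 3),
                       c(1000, 301000, 301500))
  bins <- factor(c(h1 = "high", h2 = "high", l1 = "low"),
                 levels = c("inactive", "low", "mid", "high"))
  links <- associate_by_window(enh, genes, 100000)
  fr <- association_fractions(links, enh, bins)
  expect_equal(fr$fraction[fr$bin == "high"], 0.5)  # 2 of 4 enhancers
  expect_equal(fr$fraction[fr$bin == "low"], 0.25)
  expect_equal(fr$fraction[fr$bin == "mid"], 0)
  no_links <- associate_by_window(
    canonicalize(interval_set("chrZ", 0, 100)), genes, 1000)
  fr0 <- association_fractions(
    no_links, canonicalize(interval_set("chrZ", 0, 100)), bins)
  expect_true(all(fr0$fraction == 0))
  expect_error(association_fractions(
    links, interval_set(character(), numeric(), numeric(),
                        canonical = TRUE), bins), "empty")
})

test_that("gene model construction and TSS-from-span rules", {
  expect_error(gene_models(c("a", "a"), c("chr1", "chr1"), c("+", "+"),
                           c(0, 1)), "duplicate")
  expect_error(gene_models("a", "chr1", "*", 0), "strand")
  p <- withr::local_tempfile()
  writeLines(c("chr1\t1000\t2000\tgplus\t0\t+",
               "chr1\t3000\t4000\tgminus\t0\t-"), p)
  g <- read_genes(p, "bed")
  expect_equal(g$tss[g$gene_id == "gplus"], 1000)
  expect_equal(g$tss[g$gene_id == "gminus"], 3999)
})
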