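test_that("segment-to-gene mapping is the overlap-weighted mean", {
  genes <- data.frame(gene = c("gIn", "gSplit", "gGap"),
                      chrom = c(1, 1, 1),
                      start = c(10, 100, 500),
                      end = c(20, 200, 510))
  segs <- data.frame(sample = "s1",
                     chrom = 1,
                     start = c(0, 100, 125),
                     end = c(50, 125, 300),
                     seg_mean = c(-0.5, 0.0, -1.0))
  m <- map_segments_to_genes(segs, genes)
  expect_equal(m["gIn", "s1"], -0.5)           # full containment
  expect_equal(m["gSplit", "s1"], -0.75)       # 25% at 0, 75% at -1
  expect_true(is.na(m["gGap", "s1"]))          # unsegmented gap
})

test_that("SEG files round-trip through the 1-based/0-based conversion", {
  segs <- data.frame(sample = "s1", chrom = 1L, start = c(0L, 100L),
                     end = c(100L, 200L), seg_mean = c(0, -1))
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(segs, path)
  back <- read_seg(path)
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)
  writeLines(c("a\tb\tc", "1\t2\t3"), path)
  expect_error(read_seg(path), "malformed SEG")
})

test_that("two-group Wilcoxon matches enumeration and flags q below threshold", {
  vals <- rbind(a = c(1, 2, 3, 4, 5, 6),
                b = c(2, 1, 3, 5, 4, 6))
  colnames(vals) <- paste0("s", 1:6)
  labels <- setNames(rep(c("IN", "MM"), each = 3), colnames(vals))
  res <- two_group_locus_test(vals, labels, c("IN", "MM"))
  expect_equal(res$p[res$feature == "a"], 0.1)   # (1,2,3) vs (4,5,6)
  expect_true(all(res$q >= res$p))
  # identical multisets across groups: p = 1
  same <- rbind(x = c(5, 6, 7, 5, 6, 7))
  colnames(same) <- colnames(vals)
  expect_equal(two_group_locus_test(same, labels, c("IN", "MM"))$p, 1)
})

test_that("exact Wilcoxon branch equals assignment enumeration for small groups", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    vals <- matrix(c(x, y), 1,
                   dimnames = list("f", paste0("s", seq_len(n1 + n2))))
    labels <- setNames(rep(c("A", "B"), c(n1, n2)), colnames(vals))
    res <- two_group_locus_test(vals, labels, c("A", "B"))
    expect_equal(res$p, wilcox_by_enumeration(x, y), tolerance = 1e-12)
  }
})

test_that("abundance filter keeps rows above 10% in at least 5 samples", {
  vals <- rbind(keep = c(0.2, 0.15, 0.12, 0.3, 0.11, 0.05, 0.01, 0.02,
                         0.3, 0.2),
                drop = c(0.2, 0.15, 0.12, 0.3, 0.05, 0.05, 0.01, 0.02,
                         0.04, 0.06))
  colnames(vals) <- paste0("s", 1:10)
  labels <- setNames(rep(c("IN", "MM"), each = 5), colnames(vals))
  res <- two_group_locus_test(vals, labels, c("IN", "MM"),
                              abundance_filter = TRUE)
  expect_identical(res$feature, "keep")
})

test_that("the mutation Fisher test reproduces the published worked example", {
  # 4 of 44 MM carriers vs 0 of 68 IN carriers
  samples <- c(paste0("MM", 1:44), paste0("IN", 1:68))
  mut <- matrix(0L, 1, 112, dimnames = list("FREM1", samples))
  mut[1, 1:4] <- 1L
  labels <- setNames(rep(c("MM", "IN"), c(44, 68)), samples)
  res <- mutation_fisher_test(mut, labels, c("MM", "IN"))
  expect_equal(signif(res$p, 2), 0.022)
  expect_equal(res$carriers_1, 4)
  expect_equal(res$n_2, 68)
  # empty margin: p = 1
  mut0 <- matrix(0L, 1, 112, dimnames = list("none", samples))
  expect_equal(mutation_fisher_test(mut0, labels, c("MM", "IN"))$p, 1)
})

test_that("two-sided Fisher equals hypergeometric enumeration for small margins", {
  set.seed(3)
  for (i in 1:40) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    samples <- paste0("s", seq_len(n1 + n2))
    mut <- matrix(0L, 1, n1 + n2, dimnames = list("g", samples))
    mut[1, c(seq_len(k1), n1 + seq_len(k2))] <- 1L
    labels <- setNames(rep(c("A", "B"), c(n1, n2)), samples)
    res <- mutation_fisher_test(mut, labels, c("A", "B"))
    expect_equal(res$p, fisher_by_enumeration(k1, n1, k2, n2),
                 tolerance = 1e-9)
  }
})

test_that("carrier matrices ignore silent variant classes", {
  maf <- data.frame(sample = c("s1", "s1", "s2", "s3"),
                    gene = c("TP53", "VHL", "TP53", "TP53"),
                    variant_class = c("Missense", "Silent",
                                      "Frame_Shift_Del", "Silent"))
  m <- build_mutation_matrix(maf, paste0("s", 1:4))
  expect_equal(unname(m["TP53", ]), c(1L, 1L, 0L, 0L))
  expect_false("VHL" %in% rownames(m))
})

test_that("CNA-expression correlation matches hand-computed Pearson values", {
  cna <- matrix(c(0, 1, 2, 3,
                  0, 0, 0, 0,
                  0, 1, 2, 3), 3, 4, byrow = TRUE,
                dimnames = list(c("g1", "gflat", "g2"), paste0("s", 1:4)))
  ex <- matrix(c(1, 3, 2, 5,
                 1, 2, 3, 4,
                 1, 3, 5, 7), 3, 4, byrow = TRUE,
               dimnames = dimnames(cna))
  expr <- expression_matrix(ex, scale = "linear")
  res <- suppressWarnings(cna_expression_correlation(cna, expr))
  expect_equal(res$r[res$gene == "g1"], 5.5 / sqrt(5 * 8.75),
               tolerance = 1e-9)   # hand covariance formula, ~0.83
  expect_equal(res$r[res$gene == "g2"], 1)      # expr = 2*cna + 1
  expect_true(is.na(res$r[res$gene == "gflat"]))
  expect_warning(cna_expression_correlation(cna, expr), "constant")
})

test_that("per-cohort correlations are computed alongside the overall one", {
  set.seed(2)
  cna <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  expr <- expression_matrix(abs(cna * 2 + rnorm(40, sd = 0.1)),
                            scale = "linear")
  labels <- setNames(rep(c("IN", "MM"), each = 5), paste0("s", 1:10))
  res <- cna_expression_correlation(cna, expr, labels)
  expect_setequal(unique(res$cohort), c("all", "IN", "MM"))
  expect_equal(sum(res$cohort == "all"), 4)
})

test_that("pathway enrichment is the hypergeometric upper tail over the background", {
  coll <- list(sets = list(path1 = paste0("g", 1:4),
                           outside = paste0("x", 1:3)),
               background = paste0("g", 1:10))
  sig <- paste0("g", c(1, 2, 5, 6, 7))
  res <- suppressMessages(pathway_enrichment(sig, coll))
  expect_equal(res$p[res$set == "path1"], 186 / 252, tolerance = 1e-12)
  expect_false("outside" %in% res$set)   # empty after background intersection
  # significant genes outside the background are dropped before testing
  expect_message(pathway_enrichment(c(sig, "zz"), coll), "outside the background")
  res2 <- suppressMessages(pathway_enrichment(c(sig, "zz"), coll))
  expect_equal(res2$p, res$p)
  # empty significant list: p = 1 everywhere
  res0 <- pathway_enrichment(character(0), coll)
  expect_true(all(res0$p == 1))
  expect_error(pathway_enrichment(sig, list(sets = list(), background = NULL)),
               "empty background")
})

test_that("GMT parsing returns named gene sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tg1\tg2\tg3", "SET_B\tdesc\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("SET_A", "SET_B"))
  expect_identical(sets$SET_B, c("g2", "g4"))
})
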