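test_that("local duplication counting matches hand enumeration", {
  expect_equal(local_gene_duplications(LETTERS[1:11]), 0)
  expect_equal(local_gene_duplications(
    c("A", "A", "B", "C", "D", "E", "F", "G", "H", "I", "J")), 2)
  expect_equal(local_gene_duplications(
    c("A", "A", "A", LETTERS[2:10])), 3)
  # fewer genes than the window: one truncated window
  expect_equal(local_gene_duplications(c("A", "B", "A")), 2)
})

test_that("duplications found with a small window are a subset of a larger window's", {
  set.seed(31)
  fams <- sample(paste0("f", 1:40), 120, replace = TRUE)
  for (w in c(5, 8)) {
    expect_lte(local_gene_duplications(fams, window_size = w),
               local_gene_duplications(fams, window_size = 10))
  }
  # a coarser step can only lose pairs near the window-span limit, never
  # gain; adjacent (tandem) duplicates are found at any step below the
  # window because consecutive windows always overlap them
  expect_lte(local_gene_duplications(fams, step = 3),
             local_gene_duplications(fams, step = 1))
  tandem <- c("A", "A", LETTERS[3:12], "B", "B", LETTERS[15:24])
  for (st in c(1, 3, 8))
    expect_equal(local_gene_duplications(tandem, step = st), 4)
})

mk_feats <- function(te_mids, gene_mids, te_class = "DNA") {
  rbind(
    if (length(te_mids))
      data.frame(kind = "te", start = te_mids - 100, end = te_mids + 100,
                 strand = "+", family_id = "DNAf1", te_class = te_class,
                 ltr_len = NA, is_solo = FALSE, gene_id = NA),
    if (length(gene_mids))
      data.frame(kind = "gene", start = gene_mids - 100, end = gene_mids + 100,
                 strand = "+", family_id = "f", te_class = NA,
                 ltr_len = NA, is_solo = FALSE, gene_id = NA))
}

test_that("per-block TE counts use the midpoint rule and flag empty denominators", {
  blocks <- data.frame(chrom_I = "c_I", chrom_D = "c_D",
                       start_I = 0, end_I = 1e4, start_D = 0, end_D = 1e4,
                       orient = 1L, n_pairs = 4, ratio = 1, block_id = 1L)
  aI <- list(c_I = mk_feats(seq(500, 6500, by = 1000), 8000))
  aD <- list(c_D = mk_feats(seq(500, 6500, by = 1000), 8000))
  s <- block_te_stats(blocks, aI, aD)
  expect_equal(s$te_count_I, 7)
  expect_equal(s$te_ratio, 1.0)
  empty <- block_te_stats(blocks, list(c_I = mk_feats(numeric(0), 500)),
                          list(c_D = mk_feats(numeric(0), 500)))
  expect_true(is.na(empty$te_ratio))
})

test_that("R-squared of count vs size ratios behaves at the extremes and under noise", {
  mk_stats <- function(size, cnt) {
    data.frame(block_id = seq_along(size), te_ratio = cnt,
               gene_ratio = 1, size_ratio = size)
  }
  size <- seq(0.8, 1.6, length.out = 20)
  expect_equal(ratio_correlation(mk_stats(size, size * 2), "te"), 1,
               ignore_attr = TRUE)
  expect_equal(ratio_correlation(mk_stats(size, rep(1, 20)), "te"), 0,
               ignore_attr = TRUE)
  expect_error(ratio_correlation(mk_stats(1, 1), "te"), "at least 3")
  # analytic expectation: R^2 -> var(size) / (var(size) + sigma^2)
  sigma <- 0.1
  expected <- stats::var(size) / (stats::var(size) + sigma^2)
  set.seed(12)
  r2 <- replicate(100, ratio_correlation(
    mk_stats(size, size + rnorm(20, 0, sigma)), "te"))
  expect_equal(mean(r2), expected, tolerance = 0.1)
})

test_that("composition tables count per class with exact totals", {
  f <- rbind(mk_feats(c(500, 1500), numeric(0), "DNA"),
             mk_feats(c(2500, 3500, 4500), numeric(0), "LTR"))
  regions <- data.frame(chrom = "c", start = 0, end = 1e4, label = "inverted")
  tab <- composition_table(list(c = f), list(c = f), regions, regions)
  expect_equal(tab$ratio, c(1, 1))
  expect_equal(sum(tab$count_I), sum(f$kind == "te"))
  empty <- composition_table(list(c = f), list(c = f), regions[0, ],
                             regions[0, ])
  expect_equal(nrow(empty), 0)
  # exclusion removes the chromosome from the totals
  tab2 <- composition_table(list(c = f), list(c = f), regions, regions,
                            excluded_chromosomes = "c")
  expect_equal(nrow(tab2), 0)
})
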