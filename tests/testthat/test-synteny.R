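mk_genes <- function(fams, chrom = "c", ids = NULL) {
  n <- length(fams)
  data.frame(gene_id = if (is.null(ids)) sprintf("%s_g%02d", chrom, 1:n)
             else ids,
             chrom = chrom, start = (1:n) * 1000, end = (1:n) * 1000 + 500,
             family_id = fams, stringsAsFactors = FALSE)
}

test_that("single-copy families give a perfect 1:1 pairing", {
  fams <- paste0("f", 1:8)
  p <- find_homolog_pairs(mk_genes(fams, "cI"), mk_genes(fams, "cD"))
  expect_equal(nrow(p), 8)
  expect_equal(p$idx_D, p$idx_I)
})

test_that("equal-score ties pick the lexicographically smaller target id", {
  gi <- mk_genes("famX", "cI", ids = "q1")
  gd <- mk_genes(c("famX", "famX"), "cD", ids = c("t_b", "t_a"))
  p <- find_homolog_pairs(gi, gd)
  expect_equal(nrow(p), 1)
  expect_equal(p$gene_id_D, "t_a")
})

test_that("simple collinear and reversed runs chain into single blocks", {
  p <- data.frame(chrom_I = "cI", chrom_D = "cD", idx_I = 1:6, idx_D = 1:6,
                  start_I = 1:6 * 1000, end_I = 1:6 * 1000 + 500,
                  start_D = 1:6 * 1000, end_D = 1:6 * 1000 + 500)
  b <- chain_synteny_blocks(p, min_pairs = 3)
  expect_equal(nrow(b), 1)
  expect_equal(b$orient, 1L)
  expect_equal(b$n_pairs, 6L)

  p2 <- data.frame(chrom_I = "cI", chrom_D = "cD", idx_I = 1:3,
                   idx_D = c(6, 5, 4),
                   start_I = 1:3 * 1000, end_I = 1:3 * 1000 + 500,
                   start_D = c(6, 5, 4) * 1000, end_D = c(6, 5, 4) * 1000 + 500)
  b2 <- chain_synteny_blocks(p2, min_pairs = 3)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$orient, -1L)
})

test_that("chaining matches exhaustive maximal-chain enumeration on random instances", {
  set.seed(20)
  for (trial in 1:200) {
    n <- sample(10:50, 1)
    inst <- random_pair_instance(n, grid = 25)
    got <- chain_synteny_blocks(inst, max_gap = 3, min_pairs = 3)
    want <- oracle_blocks(inst, max_gap = 3, min_pairs = 3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$start_I), , drop = FALSE]
      gg <- got[order(got$start_I),
                c("start_I", "end_I", "start_D", "end_D", "orient",
                  "n_pairs")]
      rownames(gg) <- rownames(want) <- NULL
      gg$orient <- as.integer(gg$orient)
      want$orient <- as.integer(want$orient)
      gg$n_pairs <- as.integer(gg$n_pairs)
      want$n_pairs <- as.integer(want$n_pairs)
      expect_equal(gg, want, info = paste("trial", trial))
    }
  }
})

test_that("block spans never overlap within a genome", {
  set.seed(77)
  for (trial in 1:20) {
    inst <- random_pair_instance(40, grid = 20)
    b <- chain_synteny_blocks(inst, max_gap = 4, min_pairs = 3)
    if (nrow(b) > 1) {
      b <- b[order(b$start_I), ]
      expect_true(all(b$start_I[-1] >= b$end_I[-nrow(b)]))
      b <- b[order(b$start_D), ]
      expect_true(all(b$start_D[-1] >= b$end_D[-nrow(b)]))
    }
  }
})

test_that("inversion detection reports reverse runs and nothing else", {
  mkb <- function(orients) {
    n <- length(orients)
    data.frame(chrom_I = "cI", chrom_D = "cD",
               start_I = (1:n) * 1e4, end_I = (1:n) * 1e4 + 9e3,
               start_D = (1:n) * 1e4, end_D = (1:n) * 1e4 + 9e3,
               orient = orients, n_pairs = 5,
               ratio = 1, block_id = 1:n)
  }
  expect_equal(nrow(detect_inversions(mkb(rep(1L, 5)))), 0)
  one <- detect_inversions(mkb(c(1L, -1L, 1L)))
  expect_equal(nrow(one), 1)
  expect_equal(one$start_I, 2e4)
  expect_equal(one$end_I, 2.9e4)
})

test_that("the planted inversion is recovered from annotation alone", {
  fx <- tiny_inversion_fixture()
  pair <- fx$pair
  gI <- state_gene_table(pair$genome_I[[1]])
  gD <- state_gene_table(pair$genome_D[[1]])
  hp <- find_homolog_pairs(gI, gD)
  # pairing agrees with the simulator's ortholog truth for single-copy
  # families (duplicated families are legitimately ambiguous for a top-hit
  # scorer)
  single <- names(which(table(gI$family_id) == 1))
  hp1 <- hp[hp$gene_id_I %in% gI$gene_id[gI$family_id %in% single], ]
  expect_true(all(hp1$gene_id_I == hp1$gene_id_D))

  blocks <- chain_synteny_blocks(hp)
  inv <- detect_inversions(blocks)
  expect_equal(nrow(inv), 1)
  planted <- fx$truth$inversion
  jacc <- function(s1, e1, s2, e2)
    max(0, min(e1, e2) - max(s1, s2)) / (max(e1, e2) - min(s1, s2))
  expect_gte(jacc(inv$start_D, inv$end_D, planted$start,
                  pair$genome_D[[1]]$length), 0.9)
})

test_that("size ratios reproduce printed chromosome-pair values", {
  expect_equal(round(size_ratio(137414913, 107035537), 2), 1.28)
  expect_equal(size_ratio(5, 5), 1)
  # combined rearranged chromosomes, reported in the rearranged-over-intact
  # direction
  expect_equal(round(size_ratio(79126724 + 49462234,
                                126351151 + 129606920), 2), 0.50)
  expect_error(size_ratio(1, 0), "zero")
})

test_that("ratio summary aggregates by category and flags empties", {
  b <- data.frame(chrom_I = "cI", chrom_D = "cD",
                  start_I = c(0, 2e4), end_I = c(1e4, 3e4),
                  start_D = c(0, 2e4), end_D = c(1e4, 3e4),
                  orient = c(1L, -1L), n_pairs = 5, ratio = 1,
                  block_id = 1:2)
  inv <- data.frame(chrom_I = "cI", chrom_D = "cD", start_I = 2e4,
                    end_I = 3e4, start_D = 2e4, end_D = 3e4, n_blocks = 1)
  s <- region_ratio_summary(b, inv)
  expect_equal(s$inverted_ratio, 1)
  expect_equal(s$non_inverted_ratio, 1)
  s2 <- region_ratio_summary(b[0, ], inv)
  expect_true(is.na(s2$inverted_ratio))
})
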