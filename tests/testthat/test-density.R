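mk_annot <- function(mids, L) {
  n <- length(mids)
  data.frame(kind = rep("gene", n), start = mids - 50, end = mids + 50,
             strand = rep("+", n), family_id = rep(NA, n),
             te_class = rep(NA, n), ltr_len = rep(NA, n),
             is_solo = rep(FALSE, n), gene_id = rep(NA, n))
}

test_that("partitions are equal with the remainder absorbed by the last one", {
  tr <- partition_gene_density(mk_annot(numeric(0), 5e7)[0, ], 5e7, 500)
  expect_equal(unique(tr$end - tr$start), 1e5)
  tr2 <- partition_gene_density(mk_annot(numeric(0), 5e7)[0, ], 5e7 + 300, 500)
  expect_equal((tr2$end - tr2$start)[500], 1e5 + 300)
  expect_error(partition_gene_density(mk_annot(1, 100), 100, 500), "shorter")
})

test_that("density is genes per 100 kb by midpoint assignment", {
  a <- mk_annot(c(150e3, 151e3, 152e3, 153e3, 154e3), 1e6)
  tr <- partition_gene_density(a, 1e6, 10)
  expect_equal(tr$density[2], 5.0)
  expect_equal(sum(tr$count), 5)
})

test_that("mean density recovers the genome-wide density on uniform genes", {
  set.seed(9)
  for (r in 1:10) {
    n <- 400
    L <- 2e6
    a <- mk_annot(sort(runif(n, 100, L - 100)), L)
    tr <- partition_gene_density(a, L, 100)
    expect_equal(sum(tr$count), n)  # exact integer recovery
    expect_equal(mean(tr$density), n / (L / 1e5), tolerance = 0.01)
  }
})

test_that("density differences subtract by partition index and are antisymmetric", {
  a <- mk_annot(c(1e5, 2e5, 3e5), 1e6)
  b <- mk_annot(c(1e5, 5e5), 1.2e6)  # different length: paired by index
  ta <- partition_gene_density(a, 1e6, 20)
  tb <- partition_gene_density(b, 1.2e6, 20)
  d1 <- density_difference(ta, tb)
  d2 <- density_difference(tb, ta)
  expect_equal(d1$difference, -d2$difference)
  expect_equal(density_difference(ta, ta)$difference, rep(0, 20))
  tz <- ta; tz$density <- 0
  expect_equal(density_difference(ta, tz)$difference, ta$density)
  expect_error(density_difference(ta, partition_gene_density(a, 1e6, 10)),
               "different")
})

test_that("density differences concentrate inside the inverted span", {
  pair <- tiny_pair()
  stI <- pair$genome_I[[1]]; stD <- pair$genome_D[[1]]
  ti <- partition_gene_density(stI$features, stI$length, 50)
  td <- partition_gene_density(stD$features, stD$length, 50)
  dd <- density_difference(ti, td)
  inv_from <- ceiling(pair$inversion_plan$start / stD$length * 50)
  big <- rank(-abs(dd$difference)) <= 10   # 10 largest |difference|
  inside <- seq_len(50) >= inv_from
  # enrichment of large differences inside the inversion
  orr <- (sum(big & inside) / max(1, sum(big & !inside))) /
    max(1e-9, sum(!big & inside) / sum(!big & !inside))
  expect_gt(orr, 2)
})

test_that("gradient disruption scores rank U-shaped, flat and disrupted tracks", {
  n <- 50
  mk <- function(d) {
    data.frame(chrom = "c", partition = 1:n, start = (0:(n - 1)) * 1e4,
               end = (1:n) * 1e4, count = 0, density = d)
  }
  u <- abs(seq(-1, 1, length.out = n))          # perfect V/U template
  expect_lt(gradient_disruption_score(mk(u)), 0.05)
  expect_equal(gradient_disruption_score(mk(rep(2, n))), 1)
  disrupted <- c(u[1:25], rev(u[26:50]))        # one terminal half reversed
  expect_gt(gradient_disruption_score(mk(disrupted)),
            gradient_disruption_score(mk(u)))
})

test_that("marey profiles compute local rates and flag violations", {
  mk <- data.frame(chrom = "c1", pos_bp = c(0, 1e6), cm = c(0, 5))
  pr <- marey_recombination_profile(mk, window = 2e5)
  expect_equal(unique(round(pr$profile$cm_per_mb, 6)), 5)
  expect_true(all(diff(pr$profile$cm) >= 0))
  bad <- data.frame(chrom = "c1", pos_bp = c(0, 5e5, 1e6), cm = c(0, 4, 3))
  pr2 <- marey_recombination_profile(bad, window = 2e5)
  expect_equal(nrow(pr2$violations), 1)
  expect_error(marey_recombination_profile(
    data.frame(chrom = "c1", pos_bp = 1, cm = 0)), "at least 2")
})
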