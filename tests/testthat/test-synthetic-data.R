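test_that("a written bundle round-trips to the in-memory feature tilings", {
  pair <- tiny_pair()
  dir <- withr::local_tempdir()
  bundle <- write_genome_pair(pair, dir, divergence = 0, n_markers = 40,
                              seed = 3L)
  back <- read_genome_pair(bundle)
  for (ln in c("I", "D")) {
    st <- pair[[paste0("genome_", ln)]][[1]]
    got <- back[[paste0("annot_", ln)]][[paste0(st$chrom, "_", ln)]]
    want <- st$features
    # FASTA length matches the state
    expect_equal(sum(Biostrings::width(back[[paste0("seq_", ln)]])),
                 st$length)
    # genes and TEs identical (spacers are reconstructed from gaps and may
    # merge adjacent spacer features; their total bp must agree)
    cols <- c("kind", "start", "end", "strand", "family_id", "te_class",
              "ltr_len", "is_solo")
    gw <- want[want$kind != "spacer", cols]
    gg <- got[got$kind != "spacer", cols]
    rownames(gw) <- rownames(gg) <- NULL
    expect_equal(gg, gw)
    expect_equal(sum((got$end - got$start)[got$kind == "spacer"]),
                 sum((want$end - want$start)[want$kind == "spacer"]))
  }
  # alignment blocks + unaligned segments partition each genome exactly
  bl <- back$alignment_blocks
  segs <- extract_unaligned_segments(bl, pair$genome_I[[1]]$length,
                                     pair$genome_D[[1]]$length)
  expect_equal(sum(bl$end_I - bl$start_I) + sum(segs$I$length),
               pair$genome_I[[1]]$length)
  expect_equal(sum(bl$end_D - bl$start_D) + sum(segs$D$length),
               pair$genome_D[[1]]$length)
})

test_that("a zero-generation inversion appears as a single reverse alignment block", {
  cfg <- quick_config(n_generations = 0)
  plan <- default_inversion_plan(cfg)
  pair <- simulate_divergent_pair(cfg, plan)
  bl <- alignment_blocks_from_truth(pair$genome_I[[1]], pair$genome_D[[1]],
                                    cfg$chromosome_length)
  rev_bl <- bl[bl$orient == -1, ]
  expect_equal(nrow(rev_bl), 1)
  expect_equal(rev_bl$start_D, pair$inversion_plan$start)
  expect_equal(rev_bl$end_D, pair$inversion_plan$end)
  expect_equal(rev_bl$start_I, pair$inversion_plan$start)
})

test_that("marker maps integrate the profile and stay monotone", {
  m <- recomb_map(5e5, total_cm = 90)
  set.seed(5)
  mk <- sample_marker_map(m, 60, chrom = "c1")
  expect_equal(nrow(mk), 60)
  expect_true(all(diff(mk$cm) >= 0))
  expect_equal(mk$cm[60], 90, tolerance = 0.005)
  # uniform map: equally spaced markers get equally spaced cM
  mu <- recomb_map(5e5, floor = 1, total_cm = 100)
  pos <- seq(0, 5e5 - 1, length.out = 11)
  cm <- cumulative_cm_at(mu, pos)
  expect_equal(diff(cm), rep(10, 10), tolerance = 0.01)
  # logistic map: distal quartile accumulates more cM per bp than proximal
  prof <- marey_recombination_profile(mk, window = 5e4)$profile
  q <- stats::quantile(prof$pos_bp, c(0.25, 0.75))
  distal <- prof$cm_per_mb[prof$pos_bp < q[1] | prof$pos_bp > q[2]]
  prox <- prof$cm_per_mb[prof$pos_bp >= q[1] & prof$pos_bp <= q[2]]
  expect_gt(mean(distal), mean(prox))
})

test_that("sequence synthesis respects feature structure", {
  fx <- solo_fixture()
  st <- fx$chrom
  seq <- fx$seq
  expect_equal(length(seq), st$length)
  # at zero divergence the two termini of an intact element are identical
  f <- st$features
  el <- f[f$kind == "te" & !is.na(f$ltr_len), ][1, ]
  t5 <- Biostrings::subseq(seq, el$start + 1, el$start + el$ltr_len)
  t3 <- Biostrings::subseq(seq, el$end - el$ltr_len + 1, el$end)
  expect_equal(as.character(t5), as.character(t3))
  # a planted solo LTR carries exactly the terminus sequence of its family
  solo <- f[f$is_solo, ][1, ]
  same_fam <- f[f$kind == "te" & !is.na(f$ltr_len) &
                  f$family_id == solo$family_id, ][1, ]
  ss <- Biostrings::subseq(seq, solo$start + 1, solo$end)
  ts <- Biostrings::subseq(seq, same_fam$start + 1,
                           same_fam$start + same_fam$ltr_len)
  expect_equal(as.character(ss), as.character(ts))
})

test_that("the fixture registry provides documented ground truth", {
  expect_error(make_fixture("unknown"), "arg")
  fx <- solo_fixture()
  expect_equal(fx$truth$intact, 5L)
  expect_equal(fx$truth$solo, 3L)
  ti <- tiny_inversion_fixture()
  expect_false(is.null(ti$truth$inversion))
  nr <- make_fixture("no-rearrangement")
  expect_null(nr$truth$inversion)
  pairs <- find_homolog_pairs(state_gene_table(nr$pair$genome_I[[1]]),
                              state_gene_table(nr$pair$genome_D[[1]]))
  blocks <- chain_synteny_blocks(pairs)
  expect_equal(nrow(detect_inversions(blocks)), 0)
})
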