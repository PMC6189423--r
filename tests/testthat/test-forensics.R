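test_that("unaligned segments are the exact complement of aligned blocks", {
  bl <- data.frame(chrom_I = "cI", chrom_D = "cD",
                   start_I = 200, end_I = 800, start_D = 100, end_D = 700,
                   orient = 1L)
  segs <- extract_unaligned_segments(bl, 1000, 700)
  expect_equal(segs$I$start, c(0, 800))
  expect_equal(segs$I$end, c(200, 1000))
  expect_equal(nrow(segs$D), 1)  # block covers D up to 700 except [0,100)
  full <- extract_unaligned_segments(
    transform(bl, start_I = 0, end_I = 1000, start_D = 0, end_D = 700),
    1000, 700)
  expect_equal(nrow(full$I), 0)
  over <- rbind(bl, transform(bl, start_I = 700, end_I = 900))
  expect_error(extract_unaligned_segments(over, 1000, 700), "overlapping")
})

test_that("one generation of deletions is recovered exactly as unaligned segments", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 3e5,
                    lambda_illegit = 3e-4, lambda_unequal = 0,
                    lambda_insert = 0, rng_seed = 2L)
  anc <- build_ancestral_chromosome(cfg, 1)
  set.seed(8)
  d <- step_generation(anc, cfg)
  expect_gt(nrow(d$events), 3)
  quiet <- anc  # lineage I with no events
  bl <- alignment_blocks_from_truth(quiet, d, anc$length)
  segs <- extract_unaligned_segments(bl, anc$length, d$length)
  # the I-side gaps are exactly the deletion spans (single generation:
  # event coordinates are ancestral coordinates)
  ev <- d$events[order(d$events$start), ]
  expect_equal(segs$I$start, ev$start)
  expect_equal(segs$I$end, ev$end)
  expect_equal(nrow(segs$D), 0)
})

test_that("length bins use half-open intervals and report the 1 kb split", {
  segs <- data.frame(length = c(10, 999, 1000))
  b <- bin_unaligned_lengths(segs, edges = c(0, 1000))
  expect_equal(b$bins$n, c(2, 1))
  expect_equal(b$split$n, c(2, 1))
  expect_equal(b$split$total_bp, c(1009, 1000))
  z <- bin_unaligned_lengths(segs[0, , drop = FALSE])
  expect_true(all(z$bins$n == 0) && all(z$split$total_bp == 0))
})

test_that("flanking-repeat calls follow the length, distance and direction rules", {
  cfgf <- flanking_config()
  rep2 <- function(l1, l2, t1, t2, c1, c2, s1, s2, seg = c(1000, 5000))
    data.frame(start = c(seg[1] - 10 - l1, seg[2] - 80),
               end = c(seg[1] - 10, seg[2] - 80 + l2),
               template = c(t1, t2), class = c(c1, c2),
               strand = c(s1, s2))
  # 60 bp same-template same-strand repeats at 10 and 80 bp -> identical
  expect_equal(classify_flanking_repeats(1000, 5000,
    rep2(60, 60, "T1", "T1", "LTR", "LTR", "+", "+"), cfgf), "identical")
  # below the 50 bp length threshold -> none
  expect_equal(classify_flanking_repeats(1000, 5000,
    rep2(45, 45, "T1", "T1", "LTR", "LTR", "+", "+"), cfgf), "none")
  # same family, different template -> similar; opposite strands -> none
  expect_equal(classify_flanking_repeats(1000, 5000,
    rep2(60, 60, "T1", "T2", "LTR", "LTR", "+", "+"), cfgf), "similar")
  expect_equal(classify_flanking_repeats(1000, 5000,
    rep2(60, 60, "T1", "T1", "LTR", "LTR", "+", "-"), cfgf), "none")
  # beyond 100 bp of the endpoint -> none
  far <- rep2(60, 60, "T1", "T1", "LTR", "LTR", "+", "+")
  far$end[1] <- 1000 - 150; far$start[1] <- far$end[1] - 60
  expect_equal(classify_flanking_repeats(1000, 5000, far, cfgf), "none")
})

test_that("mechanism fractions by count and bp agree on equal-length segments", {
  segs <- data.frame(length = rep(2000, 10),
                     flanking_call = c(rep("identical", 2), rep("none", 8)))
  rep_ <- mechanism_fraction_report(segs)
  expect_equal(rep_$count_fraction, rep_$bp_fraction)
  expect_equal(rep_$count_fraction[rep_$flanking_call == "identical"], 0.2)
  none <- mechanism_fraction_report(
    data.frame(length = 1:3 * 100, flanking_call = "none"))
  expect_equal(none$count_fraction[none$flanking_call %in%
                                     c("identical", "similar")], c(0, 0))
})

test_that("the planted solo-LTR fixture is inventoried exactly", {
  fx <- solo_fixture()
  inv <- ltr_inventory(fx$seq, fx$chrom$features)
  expect_equal(inv$intact, 5L)
  expect_equal(inv$solo, 3L)
  expect_equal(inv$solo_per_intact, 0.6)
})

test_that("a genome with only intact elements yields zero solo calls", {
  fx <- solo_fixture()
  f <- fx$chrom$features
  f <- f[!f$is_solo, , drop = FALSE]
  # rebuild a tiling without the solos (replace them with spacers)
  all_f <- fx$chrom$features
  all_f$kind[all_f$is_solo] <- "spacer"
  all_f$is_solo <- FALSE
  all_f$family_id[all_f$kind == "spacer"] <- NA
  all_f$te_class[all_f$kind == "spacer"] <- NA
  st <- chrom_state(all_f, fx$chrom$recomb, chrom = "chrQ")
  seq <- synthesize_chrom_seq(st, seed = 99L, divergence = 0)
  inv <- ltr_inventory(seq, st$features)
  expect_equal(inv$intact, 5L)
  expect_equal(inv$solo, 0L)
})

test_that("solo-LTR inventory equals the event ledger under unequal-only dynamics", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 5e5,
                    lambda_illegit = 0, lambda_insert = 0,
                    lambda_unequal = 3e-3, n_generations = 200,
                    generations_per_step = 5, rng_seed = 6L)
  st <- build_ancestral_chromosome(cfg, 1)
  set.seed(13)
  for (i in 1:40) st <- step_generation(st, cfg, gens = 5)
  n_events <- sum(st$events$kind == "unequal_intrastrand_deletion")
  expect_gt(n_events, 0)
  f <- st$features
  # every event left exactly one solo-LTR feature
  expect_equal(sum(f$is_solo), n_events)
  # sequence search uses intact elements as queries, so it can only see
  # solos whose family retains an intact copy (here: all families do,
  # making the inventory equal the full ledger)
  intact_fams <- unique(f$family_id[f$kind == "te" & !is.na(f$ltr_len)])
  n_queryable <- sum(f$is_solo & f$family_id %in% intact_fams)
  seq <- synthesize_chrom_seq(st, seed = 5L, divergence = 0)
  inv <- ltr_inventory(seq, st$features)
  expect_equal(inv$solo, n_queryable)
  expect_equal(n_queryable, n_events)
})
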