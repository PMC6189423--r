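test_that("ancestral chromosome tiles the interval with the expected gradients", {
  cfg <- quick_config()
  st <- build_ancestral_chromosome(cfg, 1)
  expect_s3_class(st, "chrom_state")
  f <- st$features
  expect_equal(f$start[1], 0)
  expect_equal(f$end[nrow(f)], cfg$chromosome_length)
  expect_true(all(f$start[-1] == f$end[-nrow(f)])) # gap/overlap free

  # brute-force per-partition counts: TE density anti-correlated with genes
  tg <- partition_gene_density(f, st$length, 50)
  tt <- partition_gene_density(f, st$length, 50, kind = "te")
  expect_lt(stats::cor(tg$count, tt$count, method = "spearman"), 0)

  # U shape: outer tenths denser in genes than the middle fifth
  n <- nrow(tg)
  outer <- c(seq_len(n / 10), (n - n / 10 + 1):n)
  middle <- ((2 * n / 5) + 1):(3 * n / 5)
  expect_gt(mean(tg$density[outer]), mean(tg$density[middle]))
})

test_that("zero TE placement weight yields a TE-free chromosome", {
  st <- build_ancestral_chromosome(quick_config(te_base = 0), 1)
  expect_equal(sum(st$features$kind == "te"), 0)
})

test_that("ancestor construction is deterministic under a fixed seed", {
  cfg <- quick_config()
  a <- build_ancestral_chromosome(cfg, 1)
  b <- build_ancestral_chromosome(cfg, 1)
  expect_identical(a$features, b$features)
})

test_that("a chromosome too short for its content is a degenerate-config error", {
  expect_error(build_ancestral_chromosome(
    sim_config(n_chromosomes = 1, chromosome_length = 150), 1),
    "degenerate")
})

test_that("a step with all rates zero only advances the generation counter", {
  cfg <- quick_config(lambda_illegit = 0, lambda_unequal = 0,
                      lambda_insert = 0)
  st <- build_ancestral_chromosome(cfg, 1)
  set.seed(1)
  st2 <- step_generation(st, cfg)
  expect_identical(st2$features, st$features)
  expect_equal(st2$generation, st$generation + 1L)
  expect_equal(nrow(st2$events), 0)
})

test_that("an unequal intrastrand event converts one intact element to a solo LTR", {
  cfg <- quick_config(lambda_illegit = 0, lambda_insert = 0,
                      lambda_unequal = 0.05)
  st <- build_ancestral_chromosome(cfg, 1)
  k <- sum(st$features$kind == "te" & !is.na(st$features$ltr_len))
  expect_gt(k, 0)
  set.seed(4)
  st2 <- st
  while (!nrow(st2$events)) st2 <- step_generation(st2, cfg)
  ev <- st2$events[1, ]
  expect_equal(unique(st2$events$kind), "unequal_intrastrand_deletion")
  n_ev <- nrow(st2$events)
  expect_equal(sum(st2$features$kind == "te" & !is.na(st2$features$ltr_len)),
               k - n_ev)
  expect_equal(sum(st2$features$is_solo), n_ev)
  # removed: internal region plus one terminus; retained: one terminus
  expect_equal(st2$length, st$length + sum(st2$events$length_change))
  solo <- st2$features[st2$features$is_solo, ][1, ]
  info <- te_family_info(solo$family_id)
  expect_equal(solo$end - solo$start, info$ltr_len)
  expect_equal(ev$length_change, -(info$length - info$ltr_len))
})

test_that("event ledger, gene protection and truth replay hold over a full simulation", {
  pair <- tiny_pair()
  anc <- pair$ancestor[[1]]
  for (ln in c("I", "D")) {
    st <- pair[[paste0("genome_", ln)]][[1]]
    # ledger identity
    expect_equal(st$length, anc$length + sum(st$events$length_change))
    # tiling invariant
    expect_silent(validate_chrom_state(st))
    # gene bp invariant under protection
    expect_equal(gene_bp(st), gene_bp(anc))
    # replaying the truth log reproduces the genome exactly
    expect_identical(replay_events(anc, st$events)$features, st$features)
  }
})

test_that("the same config and seed reproduce the simulation exactly", {
  cfg <- quick_config(n_generations = 50)
  p1 <- simulate_divergent_pair(cfg, default_inversion_plan(cfg))
  p2 <- simulate_divergent_pair(cfg, default_inversion_plan(cfg))
  expect_identical(p1$genome_D[[1]]$features, p2$genome_D[[1]]$features)
  expect_identical(p1$genome_I[[1]]$events, p2$genome_I[[1]]$events)
})

test_that("a zero-generation pair differs only by the planned inversions", {
  cfg <- quick_config(n_generations = 0)
  plan <- default_inversion_plan(cfg)
  pair <- simulate_divergent_pair(cfg, plan)
  expect_identical(pair$genome_I[[1]]$features, pair$ancestor[[1]]$features)
  manual <- apply_inversion(pair$ancestor[[1]], plan$start, plan$end)
  expect_identical(pair$genome_D[[1]]$features, manual$features)
})

test_that("doubling the recombination intensity doubles the expected loss", {
  # the deletion intensity enters only as lambda * c(p), and c is capped at
  # 1, so a uniformly doubled map is realized by doubling lambda on a
  # uniform map; total loss is kept small so compounding is negligible
  base <- sim_config(n_chromosomes = 1, chromosome_length = 2e5,
                     gene_base = 0, map_floor = 1,
                     lambda_unequal = 0, lambda_insert = 0,
                     lambda_illegit = 2e-6, n_generations = 300,
                     generations_per_step = 10)
  dbl <- base
  dbl$lambda_illegit <- 2 * base$lambda_illegit
  st0 <- build_ancestral_chromosome(base, 1)
  loss <- function(cfg, seed) {
    st <- st0
    set.seed(seed)
    for (i in 1:30) st <- step_generation(st, cfg, gens = 10)
    2e5 - st$length
  }
  half <- vapply(1:40, function(s) loss(base, s), numeric(1))
  full <- vapply(1:40, function(s) loss(dbl, s + 1000), numeric(1))
  # two-sided t-test of ratio = 2 must not reject at alpha = 0.01
  tt <- stats::t.test(full, 2 * half)
  expect_gt(tt$p.value, 0.01)
  expect_equal(mean(full) / mean(half), 2, tolerance = 0.15)
})

test_that("expected loss from a span is monotone in the recombination rate", {
  base <- sim_config(n_chromosomes = 1, chromosome_length = 1.5e5,
                     gene_base = 0, lambda_unequal = 0, lambda_insert = 0,
                     lambda_illegit = 2e-5, generations_per_step = 10)
  st0 <- build_ancestral_chromosome(base, 1)
  loss <- function(floor_c, seed) {
    st <- st0
    st$recomb$floor <- floor_c
    set.seed(seed)
    for (i in 1:20) st <- step_generation(st, base, gens = 10)
    1.5e5 - st$length
  }
  means <- vapply(c(0.2, 0.6, 1.0), function(fl)
    mean(vapply(1:15, function(s) loss(fl, s), numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("relocating pericentromeric material to a distal position increases its loss", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 4e5,
                    lambda_unequal = 0, lambda_insert = 0,
                    generations_per_step = 10)
  anc <- build_ancestral_chromosome(cfg, 1)
  cen <- 0.5 * anc$length
  # move a 60 kb pericentromeric span to the telomeric end
  reloc <- apply_relocation(anc, cen - 3e4, cen + 3e4,
                            insert_at = anc$length)
  run <- function(st, seed) {
    set.seed(seed)
    for (i in 1:100) st <- step_generation(st, cfg, gens = 10)
    st$length
  }
  final_ctl <- vapply(1:10, function(s) run(anc, s), numeric(1))
  final_rel <- vapply(1:10, function(s) run(reloc, s), numeric(1))
  expect_lt(mean(final_rel), mean(final_ctl))
})
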