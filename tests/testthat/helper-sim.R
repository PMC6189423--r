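# Shared fixtures and oracles for the suite. Heavy objects are built once
# per test run and memoised in this environment.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# small quick config for unit tests
quick_config <- function(n_generations = 300, ...) {
  sim_config(n_chromosomes = 1, chromosome_length = 3e5,
             n_generations = n_generations, generations_per_step = 5,
             rng_seed = 11L, ...)
}

# gene table straight from a chromosome state
state_gene_table <- function(st) {
  f <- st$features[st$features$kind == "gene", , drop = FALSE]
  data.frame(gene_id = f$gene_id, chrom = st$chrom, start = f$start,
             end = f$end, family_id = f$family_id, stringsAsFactors = FALSE)
}

# a small evolved pair with one terminal-arm inversion, shared across tests
tiny_pair <- function() memo("tiny_pair", function() {
  cfg <- quick_config()
  simulate_divergent_pair(cfg, default_inversion_plan(cfg))
})

tiny_inversion_fixture <- function() memo("tiny_inversion_fixture",
                                          function() make_fixture("tiny-inversion"))

solo_fixture <- function() memo("solo_fixture",
                                function() make_fixture("solo-ltr-planted"))

# ---- independent chaining oracle: exhaustive chain enumeration ------------

# all collinear chains (index sequences into the sorted pair table) for one
# orientation; strictly monotone in both genomes, index gaps <= max_gap
enumerate_chains <- function(qi, ti, sign, max_gap) {
  tt <- if (sign > 0) ti else -ti
  n <- length(qi)
  res <- list()
  extend <- function(chain) {
    res[[length(res) + 1]] <<- chain
    i <- chain[length(chain)]
    succ <- which(qi > qi[i] & tt > tt[i] &
                    (qi - qi[i]) <= max_gap & (tt - tt[i]) <= max_gap)
    for (j in succ) extend(c(chain, j))
  }
  for (i in seq_len(n)) extend(i)
  res
}

lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# greedy extraction over the exhaustively enumerated chains, mirroring the
# documented selection rule (longest; forward beats reverse at ties;
# lexicographically smallest index sequence)
oracle_blocks <- function(pairs, max_gap, min_pairs) {
  cp <- pairs[order(pairs$idx_I, pairs$idx_D), , drop = FALSE]
  avail <- rep(TRUE, nrow(cp))
  chains <- list()
  repeat {
    idx <- which(avail)
    if (length(idx) < min_pairs) break
    qi <- cp$idx_I[idx]; ti <- cp$idx_D[idx]
    pick <- function(sign) {
      ch <- enumerate_chains(qi, ti, sign, max_gap)
      lens <- lengths(ch)
      cand <- ch[lens == max(lens)]
      best <- cand[[1]]
      for (c2 in cand[-1]) if (lex_less(c2, best)) best <- c2
      best
    }
    fwd <- pick(+1); rev_ <- pick(-1)
    use_fwd <- length(fwd) >= length(rev_)
    ch <- if (use_fwd) fwd else rev_
    if (length(ch) < min_pairs) break
    chains[[length(chains) + 1]] <- list(rows = idx[ch],
                                         orient = if (use_fwd) 1L else -1L)
    avail[idx[ch]] <- FALSE
  }
  spans <- lapply(chains, function(ch) {
    r <- cp[ch$rows, ]
    list(si = min(r$start_I), ei = max(r$end_I),
         sd = min(r$start_D), ed = max(r$end_D))
  })
  kept <- logical(length(chains))
  for (i in seq_along(chains)) {
    ok <- TRUE
    for (j in which(kept)) {
      if (spans[[i]]$si < spans[[j]]$ei && spans[[i]]$ei > spans[[j]]$si) ok <- FALSE
      if (spans[[i]]$sd < spans[[j]]$ed && spans[[i]]$ed > spans[[j]]$sd) ok <- FALSE
    }
    kept[i] <- ok
  }
  chains <- chains[kept]
  do.call(rbind, lapply(chains, function(ch) {
    r <- cp[ch$rows, ]
    data.frame(start_I = min(r$start_I), end_I = max(r$end_I),
               start_D = min(r$start_D), end_D = max(r$end_D),
               orient = ch$orient, n_pairs = length(ch$rows))
  }))
}

# random pair instance on a gene-index grid with bp extents
random_pair_instance <- function(n_pairs, grid = 20) {
  qi <- sample.int(grid, n_pairs, replace = TRUE)
  ti <- sample.int(grid, n_pairs, replace = TRUE)
  d <- unique(data.frame(idx_I = qi, idx_D = ti))
  d <- d[order(d$idx_I, d$idx_D), , drop = FALSE]
  # one pair per query gene, as produced by top-hit pairing
  d <- d[!duplicated(d$idx_I), , drop = FALSE]
  data.frame(chrom_I = "cI", chrom_D = "cD", idx_I = d$idx_I,
             idx_D = d$idx_D,
             start_I = d$idx_I * 1000, end_I = d$idx_I * 1000 + 500,
             start_D = d$idx_D * 1000, end_D = d$idx_D * 1000 + 500,
             stringsAsFactors = FALSE)
}

# ---- shared replicate study for the simulation-based acceptance checks ----
# 30 independent seeds of the default loss-dominated study condition:
# one 1 Mbp chromosome, one terminal-arm inversion, 2000 generations
# (10-generation sampling steps).

acceptance_seed_summary <- function(seed) {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 1e6,
                    n_generations = 2000, generations_per_step = 10,
                    rng_seed = seed)
  pair <- simulate_divergent_pair(cfg, default_inversion_plan(cfg))
  stI <- pair$genome_I[[1]]; stD <- pair$genome_D[[1]]
  hp <- find_homolog_pairs(state_gene_table(stI), state_gene_table(stD))
  blocks <- chain_synteny_blocks(hp, max_pairs_per_block = 12)
  invs <- detect_inversions(blocks)
  summ <- region_ratio_summary(blocks, invs)
  pb <- summ$per_block
  annotI <- stats::setNames(list(stI$features), stI$chrom)
  annotD <- stats::setNames(list(stD$features), stD$chrom)
  stats_tbl <- block_te_stats(blocks, annotI, annotD)
  r2 <- c(te = tryCatch(as.numeric(ratio_correlation(stats_tbl, "te")),
                        error = function(e) NA_real_),
          gene = tryCatch(as.numeric(ratio_correlation(stats_tbl, "gene")),
                          error = function(e) NA_real_))
  invb <- pb[pb$inverted, , drop = FALSE]
  spear <- if (nrow(invb) >= 4)
    suppressWarnings(stats::cor(invb$start_D, invb$ratio,
                                method = "spearman"))
  else NA_real_
  list(inv_I = sum(invb$end_I - invb$start_I),
       inv_D = sum(invb$end_D - invb$start_D),
       non_I = sum((pb$end_I - pb$start_I)[!pb$inverted]),
       non_D = sum((pb$end_D - pb$start_D)[!pb$inverted]),
       te_r2 = r2[["te"]], gene_r2 = r2[["gene"]], spearman = spear)
}

acceptance_replicates <- function(seeds = 1:30) {
  memo("acceptance_replicates", function()
    lapply(seeds, acceptance_seed_summary))
}
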