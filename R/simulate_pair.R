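#' Simulate a divergent genome pair
#'
#' Builds an ancestral genome from `config`, applies the planned inversions
#' to lineage D at generation 0, then evolves both lineages independently
#' for `config$n_generations` under the forward model. Lineage I keeps the
#' ancestral arrangement (the unrearranged genome); lineage D carries the
#' inversions, whose formerly pericentromeric TE-rich contents are thereby
#' exposed to high distal recombination and preferentially lost.
#'
#' The two lineages (and each chromosome within them) use independent child
#' RNG streams derived from `config$rng_seed`, so lineage I's trajectory is
#' unaffected by lineage D's draw count.
#'
#' @param config a [sim_config()].
#' @param inversion_plan data frame with columns `chrom` (index), `start`,
#'   `end` (bp on the ancestral chromosome), applied to lineage D at
#'   generation 0; NULL for no rearrangement.
#' @return a list of class `sim_pair` with elements `genome_I`, `genome_D`
#'   (lists of [chrom_state()]), `ancestor`, `inversion_plan` (snapped
#'   spans), `config`.
#' @export
simulate_divergent_pair <- function(config, inversion_plan = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ancestor <- lapply(seq_len(config$n_chromosomes), function(i)
    build_ancestral_chromosome(config, i))
  names(ancestor) <- vapply(ancestor, `[[`, "", "chrom")

  genome_I <- ancestor
  genome_D <- ancestor
  plan_out <- NULL
  if (!is.null(inversion_plan) && nrow(inversion_plan)) {
    for (r in seq_len(nrow(inversion_plan))) {
      ci <- inversion_plan$chrom[r]
      st <- genome_D[[ci]]
      n_ev <- nrow(st$events)
      st <- apply_inversion(st, inversion_plan$start[r],
                            inversion_plan$end[r], snap = TRUE,
                            gene_protection = config$gene_protection)
      ev <- st$events[nrow(st$events), ]
      plan_out <- rbind(plan_out,
                        data.frame(chrom = ci, start = ev$start, end = ev$end))
      genome_D[[ci]] <- st
    }
  }

  evolve <- function(genome, lineage) {
    for (i in seq_along(genome)) {
      set.seed(.child_seed(config$rng_seed, lineage, i))
      st <- genome[[i]]
      gleft <- config$n_generations
      step <- config$generations_per_step
      while (gleft > 0) {
        g <- min(step, gleft)
        st <- step_generation(st, config, gens = g)
        gleft <- gleft - g
      }
      validate_chrom_state(st)
      genome[[i]] <- st
    }
    genome
  }
  genome_I <- evolve(genome_I, "I")
  genome_D <- evolve(genome_D, "D")

  structure(list(genome_I = genome_I, genome_D = genome_D,
                 ancestor = ancestor, inversion_plan = plan_out,
                 config = config),
            class = "sim_pair")
}

#' @export
print.sim_pair <- function(x, ...) {
  li <- sum(vapply(x$genome_I, `[[`, 0, "length"))
  ld <- sum(vapply(x$genome_D, `[[`, 0, "length"))
  cat(sprintf("sim_pair: %d chromosome(s), %d generations\n  genome I %.0f bp, genome D %.0f bp (I/D = %.3f)\n",
              length(x$genome_I), x$config$n_generations, li, ld, li / ld))
  if (!is.null(x$inversion_plan)) {
    cat("  planned inversions (lineage D):\n")
    for (r in seq_len(nrow(x$inversion_plan)))
      cat(sprintf("    chrom %d: [%.0f, %.0f)\n", x$inversion_plan$chrom[r],
                  x$inversion_plan$start[r], x$inversion_plan$end[r]))
  }
  invisible(x)
}

#' Ortholog truth table of a simulated pair
#'
#' Under gene protection genes are indestructible, so every ancestral gene
#' survives in both lineages; this table gives each gene's coordinates in
#' both final genomes.
#'
#' @param pair a `sim_pair`.
#' @return data frame: gene_id, family_id, chrom, start/end/strand in each
#'   genome (suffixes `_I`, `_D`).
#' @export
ortholog_truth <- function(pair) {
  pull <- function(genome, suf) {
    out <- do.call(rbind, lapply(genome, function(st) {
      f <- st$features[st$features$kind == "gene", , drop = FALSE]
      data.frame(gene_id = f$gene_id, family_id = f$family_id,
                 chrom = st$chrom, start = f$start, end = f$end,
                 strand = f$strand, stringsAsFactors = FALSE)
    }))
    names(out)[3:6] <- paste0(c("chrom", "start", "end", "strand"), suf)
    out
  }
  merge(pull(pair$genome_I, "_I"), pull(pair$genome_D, "_D"),
        by = c("gene_id", "family_id"), sort = TRUE)
}
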