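#' Build an ancestral chromosome
#'
#' Lays features down along the chromosome with location-dependent placement
#' weights: the gene weight follows the relative recombination rate `c(p)`
#' (high distally) and the TE weight follows `1 - c(p)` (high proximally),
#' so the emitted chromosome shows the U-shaped gene-density gradient and
#' anti-correlated, pericentromere-enriched TE density expected of an
#' unrearranged plant chromosome.
#'
#' @param config a [sim_config()].
#' @param chrom_index 1-based chromosome index (`<= n_chromosomes`).
#' @param seed integer seed for this chromosome's placement draws; defaults
#'   to a child stream of `config$rng_seed`.
#' @return a [chrom_state()] whose features tile `[0, chromosome_length)`.
#' @export
build_ancestral_chromosome <- function(config, chrom_index = 1L,
                                       seed = .child_seed(config$rng_seed,
                                                          "ancestor",
                                                          chrom_index)) {
  stopifnot(inherits(config, "sim_config"),
            chrom_index >= 1, chrom_index <= config$n_chromosomes)
  L <- config$chromosome_length
  map <- .config_map(config)
  chrom_name <- sprintf("chr%02d", chrom_index)

  feats <- .with_seed(seed, {
    rows <- vector("list", 4096)
    n <- 0L
    pos <- 0
    gene_i <- 0L
    fam_i <- 0L
    last_fam <- NA_character_
    while (pos < L) {
      cv <- recombination_rate_at(map, pos)
      w_gene <- config$gene_base *
        (config$gene_floor + (1 - config$gene_floor) * cv)
      w_te <- config$te_base *
        (config$te_floor + (1 - config$te_floor) * (1 - cv))
      # intergenic spacer is also proximally enriched: distal euchromatin is
      # gene-dense with little dispensable sequence
      w_sp <- config$spacer_weight * (0.35 + 0.65 * (1 - cv))
      w <- c(gene = w_gene, te = w_te, spacer = w_sp)
      kind <- sample(names(w), 1, prob = w)
      if (kind == "gene") {
        len <- round(stats::rlnorm(1, log(config$gene_mean_len),
                                   config$gene_sd_log))
        gene_i <- gene_i + 1L
        if (!is.na(last_fam) && stats::runif(1) < config$dup_prob) {
          fam <- last_fam
        } else {
          fam_i <- fam_i + 1L
          fam <- sprintf("fam_%s_%04d", chrom_name, fam_i)
        }
        last_fam <- fam
        row <- .feature_row("gene", pos, pos + len,
                            strand = sample(c("+", "-"), 1),
                            family_id = fam,
                            gene_id = sprintf("g_%s_%04d", chrom_name, gene_i))
      } else if (kind == "te") {
        te <- .draw_te_family()
        row <- .feature_row("te", pos, pos + te$length,
                            strand = sample(c("+", "-"), 1),
                            family_id = te$family_id, te_class = te$te_class,
                            ltr_len = te$ltr_len)
      } else {
        len <- 200 + round(stats::rexp(1, 1 / config$spacer_mean_len))
        row <- .feature_row("spacer", pos, pos + len)
      }
      # a feature that does not fit is replaced by terminal spacer so no
      # gene or TE is ever emitted truncated
      if (row$end > L) row <- .feature_row("spacer", pos, L)
      if (row$end > row$start) {
        n <- n + 1L
        if (n > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[n]] <- row
        pos <- row$end
      }
    }
    do.call(rbind, rows[seq_len(n)])
  })

  if (config$gene_base > 0 && !any(feats$kind == "gene"))
    stop("degenerate config: chromosome too short to place a gene")
  if (config$te_base > 0 && !any(feats$kind == "te"))
    stop("degenerate config: chromosome too short to place a TE")
  chrom_state(feats, map, chrom = chrom_name)
}
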