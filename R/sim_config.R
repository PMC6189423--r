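#' Simulator configuration
#'
#' Collects every tunable of the forward model in one validated list. The
#' defaults describe a desk-scale study condition: 1 Mbp chromosomes with a
#' U-shaped gene gradient and pericentromere-enriched TEs, evolved for 2,000
#' generations under loss-dominated dynamics (recombination-scaled
#' illegitimate deletions, a minority of unequal intrastrand events on intact
#' LTR retrotransposons, and slow proximal TE insertion).
#'
#' Event rates:
#' \describe{
#'   \item{lambda_illegit}{illegitimate deletions per bp per unit relative
#'     recombination rate per generation.}
#'   \item{lambda_unequal}{unequal intrastrand events per intact LTR element
#'     per unit relative recombination rate (at the element midpoint) per
#'     generation; each converts the element to a solo LTR.}
#'   \item{lambda_insert}{TE insertions per bp per generation, weighted by
#'     `1 - c(p)/max(c)` so insertions accumulate proximally.}
#' }
#' Deletion lengths follow a truncated discrete power law
#' `P(l) proportional to l^-del_alpha` on `1..del_max`: short deletions
#' dominate counts while long (>= 1 kb) deletions dominate removed bp.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length ancestral chromosome length in bp.
#' @param centromere_frac,map_mid,map_scale,map_floor,total_cm recombination
#'   map shape, see [recomb_map()].
#' @param gene_base,gene_floor gene placement weight is
#'   `gene_base * (gene_floor + (1-gene_floor) * c(p))`: genes concentrate
#'   distally, giving the U-shaped density gradient.
#' @param te_base,te_floor TE placement weight is
#'   `te_base * (te_floor + (1-te_floor) * (1-c(p)))`: TEs concentrate
#'   proximally.
#' @param spacer_weight constant weight for intergenic spacer placement.
#' @param gene_mean_len,gene_sd_log gene length lognormal parameters.
#' @param spacer_mean_len mean spacer length (exponential + 200 bp minimum).
#' @param dup_prob probability that a new gene reuses the previous gene's
#'   family (tandem duplication), seeding local gene duplications.
#' @param lambda_illegit,lambda_unequal,lambda_insert per-generation event
#'   rates, see Details.
#' @param del_alpha,del_max deletion length power-law exponent and truncation.
#' @param gene_protection if TRUE (default), no deletion may remove gene bp
#'   (offending draws are re-drawn up to 10 times, then skipped) and
#'   insertions land only in spacer/TE intervals.
#' @param rng_seed integer seed; the two lineages use independent child
#'   streams derived from it.
#' @param n_generations generations to evolve each lineage.
#' @param generations_per_step generations collapsed into one thinned-Poisson
#'   sampling step (an approximation exact in the small-rate limit; the
#'   default 1 draws every generation separately).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chromosome_length = 1e6,
                       centromere_frac = 0.5,
                       map_mid = 0.6, map_scale = 0.08, map_floor = 0.02,
                       total_cm = 120,
                       gene_base = 0.5, gene_floor = 0.25,
                       te_base = 0.6, te_floor = 0.10,
                       spacer_weight = 0.25,
                       gene_mean_len = 2000, gene_sd_log = 0.25,
                       spacer_mean_len = 1500,
                       dup_prob = 0.12,
                       lambda_illegit = 1.5e-5,
                       lambda_unequal = 5e-5,
                       lambda_insert = 1e-9,
                       del_alpha = 1.6, del_max = 10000,
                       gene_protection = TRUE,
                       rng_seed = 1L,
                       n_generations = 2000L,
                       generations_per_step = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chromosomes >= 1, chromosome_length > 0,
              lambda_illegit >= 0, lambda_unequal >= 0, lambda_insert >= 0,
              del_alpha > 0, del_max >= 1,
              n_generations >= 0, generations_per_step >= 1,
              gene_base >= 0, te_base >= 0, spacer_weight > 0)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d chromosome(s) x %.2g bp, %d generations\n",
                     "  rates: illegit %.3g /bp/c/gen, unequal %.3g /element/c/gen, insert %.3g /bp/gen\n",
                     "  deletion lengths ~ l^-%.2f truncated at %d bp (mean %.1f bp)\n"),
              x$n_chromosomes, x$chromosome_length, x$n_generations,
              x$lambda_illegit, x$lambda_unequal, x$lambda_insert,
              x$del_alpha, as.integer(x$del_max), deletion_length_mean(x)))
  invisible(x)
}

# normalized power-law pmf over 1..del_max
.del_pmf <- function(config) {
  l <- seq_len(config$del_max)
  w <- l^(-config$del_alpha)
  w / sum(w)
}

#' Mean deletion length under a configuration
#'
#' Exact mean of the truncated discrete power law; together with
#' `lambda_illegit` and the local recombination rate this gives the expected
#' per-bp fractional loss rate `rho = lambda_illegit * c * mean_length`.
#' @param config a [sim_config()].
#' @return numeric scalar, bp.
#' @export
deletion_length_mean <- function(config) {
  sum(seq_len(config$del_max) * .del_pmf(config))
}

# evaluate the chromosome's recombination map from a config
.config_map <- function(config) {
  recomb_map(config$chromosome_length,
             centromere_frac = config$centromere_frac,
             mid = config$map_mid, scale = config$map_scale,
             floor = config$map_floor, total_cm = config$total_cm)
}

# deterministic child seed per (seed, lineage, chromosome); kept < 2^31
.child_seed <- function(seed, lineage, chrom_index) {
  h <- (as.numeric(seed) * 48271 + sum(utf8ToInt(lineage)) * 7907 +
          chrom_index * 104729) %% 2147483647
  as.integer(h)
}

# run expr with a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
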