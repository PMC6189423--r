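#' Deterministic test fixtures
#'
#' Small, fully reproducible genome-pair fixtures with documented ground
#' truth, used by the test-suite and worked examples. Registry:
#' \describe{
#'   \item{"no-rearrangement"}{one 300 kb chromosome pair, no inversion,
#'     200 generations of quiet loss-dominated evolution; the synteny stage
#'     finds no inverted blocks.}
#'   \item{"tiny-inversion"}{one 400 kb chromosome pair with a terminal
#'     inversion planted at generation 0 covering the distal 55% of the
#'     chromosome, 400 generations; `truth$inversion` holds the snapped
#'     planted span (genome D coordinates).}
#'   \item{"solo-ltr-planted"}{a single hand-built chromosome with 5 intact
#'     LTR retrotransposons and 3 planted solo LTRs (zero divergence), plus
#'     its sequence; `truth$intact = 5`, `truth$solo = 3`.}
#' }
#'
#' @param name fixture name from the registry.
#' @return a list of class `synshrink_fixture`: `name`, `truth`, and either
#'   `pair` (a `sim_pair`) or `chrom` + `seq` for the planted single
#'   chromosome.
#' @export
make_fixture <- function(name = c("no-rearrangement", "tiny-inversion",
                                  "solo-ltr-planted")) {
  name <- match.arg(name)
  if (name == "no-rearrangement") {
    cfg <- sim_config(n_chromosomes = 1, chromosome_length = 3e5,
                      n_generations = 200, generations_per_step = 5,
                      rng_seed = 42L)
    pair <- simulate_divergent_pair(cfg)
    return(structure(list(name = name, pair = pair,
                          truth = list(inversion = NULL)),
                     class = "synshrink_fixture"))
  }
  if (name == "tiny-inversion") {
    # a flatter gene gradient than the study default keeps homolog anchors
    # dense across the whole inverted span, so detection accuracy can be
    # scored tightly against the planted truth
    cfg <- sim_config(n_chromosomes = 1, chromosome_length = 4e5,
                      n_generations = 400, generations_per_step = 5,
                      gene_floor = 0.45, rng_seed = 7L)
    plan <- data.frame(chrom = 1, start = 0.52 * 4e5, end = 4e5)
    pair <- simulate_divergent_pair(cfg, plan)
    return(structure(list(name = name, pair = pair,
                          truth = list(inversion = pair$inversion_plan)),
                     class = "synshrink_fixture"))
  }
  # solo-ltr-planted: hand-built tiling, zero generations, zero divergence
  fams <- c("LTRf1", "LTRf2", "LTRf3", "LTRf1", "LTRf2")
  solo_fams <- c("LTRf1", "LTRf2", "LTRf3")
  rows <- list()
  pos <- 0
  gi <- 0L
  push <- function(row) { rows[[length(rows) + 1]] <<- row; pos <<- row$end }
  spacer <- function(len) push(.feature_row("spacer", pos, pos + len))
  gene <- function(len = 2000) {
    gi <<- gi + 1L
    push(.feature_row("gene", pos, pos + len, strand = "+",
                      family_id = sprintf("fam_planted_%02d", gi),
                      gene_id = sprintf("g_planted_%02d", gi)))
  }
  spacer(3000)
  for (i in seq_along(fams)) {
    info <- te_family_info(fams[i])
    push(.feature_row("te", pos, pos + info$length, strand = "+",
                      family_id = fams[i], te_class = "LTR",
                      ltr_len = info$ltr_len))
    gene(); spacer(2500)
  }
  for (i in seq_along(solo_fams)) {
    info <- te_family_info(solo_fams[i])
    push(.feature_row("te", pos, pos + info$ltr_len, strand = "+",
                      family_id = solo_fams[i], te_class = "LTR",
                      is_solo = TRUE))
    spacer(1800)
  }
  gene(); spacer(4000)
  f <- do.call(rbind, rows)
  st <- chrom_state(f, recomb_map(f$end[nrow(f)]), chrom = "chrP")
  seq <- synthesize_chrom_seq(st, seed = 99L, divergence = 0)
  structure(list(name = name, chrom = st, seq = seq,
                 truth = list(intact = 5L, solo = 3L)),
            class = "synshrink_fixture")
}
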