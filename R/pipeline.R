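# End-to-end pipeline: simulate -> serialize -> synteny -> density -> TE
# metrics -> deletion forensics -> rate estimation, with TSV hand-off
# between stages and a machine-readable run manifest.

#' Default terminal-inversion plan for a configuration
#'
#' One inversion on chromosome 1 covering the full right arm from just
#' distal of the centromere to the telomere: the formerly pericentromeric
#' TE-rich material is carried to the distal end (high recombination) and
#' the formerly distal gene-rich material becomes pericentromeric, while the
#' centromere itself stays outside the inverted span.
#' @param config a [sim_config()].
#' @return data frame `chrom`, `start`, `end`.
#' @export
default_inversion_plan <- function(config) {
  L <- config$chromosome_length
  data.frame(chrom = 1, start = (config$centromere_frac + 0.02) * L, end = L)
}

#' Run the full analysis pipeline on a simulated pair
#'
#' Executes the stages `simulate` (generate + serialize a genome pair),
#' `synteny` (homolog pairing, block chaining, inversion detection),
#' `density` (partition tracks and differences), `te` (per-block TE/gene
#' stats, ratio correlations, composition), `forensics` (unaligned
#' segments, length bins, flanking classification, solo-LTR inventory) and
#' `rate` (relative reduction rates per inverted region). Each stage writes
#' TSV outputs under `out_dir` and later stages consume earlier stages'
#' files; a JSON manifest records parameters, per-stage status and file
#' checksums. Disabled stages are marked "skipped"; the rate stage needs
#' only the synteny outputs, not forensics.
#'
#' @param out_dir output directory.
#' @param config a [sim_config()].
#' @param inversion_plan inversions applied to lineage D at generation 0;
#'   defaults to [default_inversion_plan()].
#' @param stages character vector of stages to run.
#' @param divergence,n_markers serialization parameters, see
#'   [write_genome_pair()].
#' @param block_genes sub-block size (pairs) for within-region ratio
#'   profiling, see `max_pairs_per_block` in [chain_synteny_blocks()].
#' @param max_gap,min_pairs chaining parameters.
#' @return list of class `synshrink_run`: stage results, output paths and
#'   the manifest.
#' @export
run_pipeline <- function(out_dir,
                         config = sim_config(),
                         inversion_plan = default_inversion_plan(config),
                         stages = c("simulate", "synteny", "density", "te",
                                    "forensics", "rate"),
                         divergence = 0, n_markers = 100,
                         block_genes = 12, max_gap = 5, min_pairs = 4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- stats::setNames(rep("skipped", 6),
                            c("simulate", "synteny", "density", "te",
                              "forensics", "rate"))
  res <- list()
  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  need <- function(file, stage) {
    if (is.null(file) || (is.character(file) && !file.exists(file)))
      stop("stage '", stage, "' is missing its upstream contract file: ",
           if (is.character(file)) file else "(in-memory input)")
  }

  if ("simulate" %in% stages) {
    pair <- simulate_divergent_pair(config, inversion_plan)
    bundle <- write_genome_pair(pair, file.path(out_dir, "bundle"),
                                divergence = divergence,
                                n_markers = n_markers,
                                seed = config$rng_seed)
    res$pair <- pair
    res$bundle <- bundle
    status["simulate"] <- "complete"
  } else {
    bundle <- file.path(out_dir, "bundle")
  }

  data <- NULL
  load_data <- function() {
    if (is.null(data)) {
      need(if (is.character(bundle)) file.path(bundle, "genome_I.fa")
           else bundle$fasta_I, "synteny")
      data <<- read_genome_pair(bundle)
    }
    data
  }

  if ("synteny" %in% stages) {
    d <- load_data()
    pairs <- find_homolog_pairs(gene_table(d$annot_I), gene_table(d$annot_D))
    blocks <- chain_synteny_blocks(pairs, max_gap = max_gap,
                                   min_pairs = min_pairs,
                                   max_pairs_per_block = block_genes)
    invs <- detect_inversions(blocks)
    res$pairs <- pairs
    res$blocks <- blocks
    res$inversions <- invs
    tsv(blocks, "synteny_blocks.tsv")
    tsv(invs, "inverted_regions.tsv")
    summ <- region_ratio_summary(blocks, invs)
    res$ratio_summary <- summ
    tsv(data.frame(category = c("inverted", "non_inverted"),
                   ratio = c(summ$inverted_ratio, summ$non_inverted_ratio)),
        "region_ratios.tsv")
    status["synteny"] <- "complete"
  }

  if ("density" %in% stages) {
    d <- load_data()
    n_part <- max(10, min(500, floor(config$chromosome_length / 2000)))
    tracks <- list()
    for (ch in names(d$annot_I)) {
      chD <- sub("_I$", "_D", ch)
      ti <- partition_gene_density(d$annot_I[[ch]],
                                   sum(Biostrings::width(d$seq_I[ch])),
                                   n_partitions = n_part, chrom = ch)
      td <- partition_gene_density(d$annot_D[[chD]],
                                   sum(Biostrings::width(d$seq_D[chD])),
                                   n_partitions = n_part, chrom = chD)
      tracks[[ch]] <- list(I = ti, D = td, diff = density_difference(ti, td))
    }
    res$density <- tracks
    tsv(do.call(rbind, lapply(tracks, `[[`, "I")), "density_I.tsv")
    tsv(do.call(rbind, lapply(tracks, `[[`, "D")), "density_D.tsv")
    if (!is.null(d$markers))
      res$marey <- marey_recombination_profile(d$markers)
    status["density"] <- "complete"
  }

  if ("te" %in% stages) {
    need(file.path(out_dir, "synteny_blocks.tsv"), "te")
    d <- load_data()
    blocks <- utils::read.table(file.path(out_dir, "synteny_blocks.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    stats_tbl <- block_te_stats(blocks, d$annot_I, d$annot_D)
    res$block_stats <- stats_tbl
    tsv(stats_tbl, "block_te_stats.tsv")
    r2 <- c(te = tryCatch(as.numeric(ratio_correlation(stats_tbl, "te")),
                          error = function(e) NA_real_),
            gene = tryCatch(as.numeric(ratio_correlation(stats_tbl, "gene")),
                            error = function(e) NA_real_))
    res$ratio_r2 <- r2
    invs <- utils::read.table(file.path(out_dir, "inverted_regions.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    # inverted regions as labeled; the complement of the inverted spans on
    # each chromosome as non-inverted
    regmaker <- function(side) {
      seqs <- if (side == "I") d$seq_I else d$seq_D
      lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
      inv <- if (nrow(invs))
        data.frame(chrom = invs[[paste0("chrom_", side)]],
                   start = invs[[paste0("start_", side)]],
                   end = invs[[paste0("end_", side)]], label = "inverted",
                   stringsAsFactors = FALSE)
      else NULL
      non <- do.call(rbind, lapply(names(lens), function(ch) {
        iv <- inv[if (is.null(inv)) logical(0) else inv$chrom == ch, ,
                  drop = FALSE]
        gs <- c(0, if (!is.null(iv) && nrow(iv)) iv$end[order(iv$start)])
        ge <- c(if (!is.null(iv) && nrow(iv)) iv$start[order(iv$start)],
                lens[[ch]])
        keep <- ge > gs
        if (!any(keep)) return(NULL)
        data.frame(chrom = ch, start = gs[keep], end = ge[keep],
                   label = "non_inverted", stringsAsFactors = FALSE)
      }))
      rbind(inv, non)
    }
    res$composition <- composition_table(d$annot_I, d$annot_D,
                                         regmaker("I"), regmaker("D"))
    tsv(res$composition, "te_composition.tsv")
    dup <- vapply(names(d$annot_I), function(ch) {
      g <- d$annot_I[[ch]]
      local_gene_duplications(g$family_id[g$kind == "gene"])
    }, integer(1))
    res$local_dups_I <- dup
    status["te"] <- "complete"
  }

  if ("forensics" %in% stages) {
    d <- load_data()
    need(bundle_path <- if (is.character(bundle))
      file.path(bundle, "alignment_blocks.tsv")
      else bundle$alignment_blocks, "forensics")
    bl <- utils::read.table(bundle_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    seg_all <- list(); reports <- list()
    for (ch in unique(bl$chrom_I)) {
      chb <- bl[bl$chrom_I == ch, , drop = FALSE]
      chI <- paste0(ch, "_I"); chD <- paste0(chb$chrom_D[1], "_D")
      segs <- extract_unaligned_segments(
        chb |> transform(chrom_I = chI, chrom_D = chD),
        sum(Biostrings::width(d$seq_I[chI])),
        sum(Biostrings::width(d$seq_D[chD])))
      for (side in c("I", "D")) {
        s <- segs[[side]]
        annot <- if (side == "I") d$annot_I[[chI]] else d$annot_D[[chD]]
        s <- segment_te_composition(s, annot)
        rep_tab <- repeat_annotation(annot)
        s$flanking_call <- vapply(seq_len(nrow(s)), function(i)
          classify_flanking_repeats(s$start[i], s$end[i], rep_tab),
          character(1))
        seg_all[[paste(ch, side)]] <- s
      }
    }
    segs <- do.call(rbind, seg_all)
    res$unaligned <- segs
    tsv(segs, "unaligned_segments.tsv")
    long_I <- segs[segs$genome == "I" & segs$length >= 1000, , drop = FALSE]
    res$mechanism <- mechanism_fraction_report(long_I)
    tsv(res$mechanism, "mechanism_fractions.tsv")
    res$length_bins <- lapply(split(segs, segs$genome), bin_unaligned_lengths)
    status["forensics"] <- "complete"
  }

  if ("rate" %in% stages) {
    need(file.path(out_dir, "inverted_regions.tsv"), "rate")
    invs <- utils::read.table(file.path(out_dir, "inverted_regions.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (nrow(invs)) {
      regions <- data.frame(region = paste0(invs$chrom_I, ":",
                                            round(invs$start_I)),
                            a = invs$end_I - invs$start_I,
                            b = invs$end_D - invs$start_D)
      res$rates <- per_region_rates(regions, config$n_generations)
    } else {
      res$rates <- per_region_rates(data.frame(a = 1, b = 1), 1)[0, ]
    }
    tsv(res$rates, "reduction_rates.tsv")
    status["rate"] <- "complete"
  }

  files <- list.files(out_dir, pattern = "\\.tsv$", recursive = TRUE,
                      full.names = TRUE)
  manifest <- list(package = "synshrink",
                   version = as.character(utils::packageVersion("synshrink")),
                   seed = config$rng_seed,
                   parameters = list(chromosome_length = config$chromosome_length,
                                     n_generations = config$n_generations,
                                     lambda_illegit = config$lambda_illegit,
                                     lambda_unequal = config$lambda_unequal,
                                     lambda_insert = config$lambda_insert,
                                     divergence = divergence,
                                     block_genes = block_genes,
                                     max_gap = max_gap,
                                     min_pairs = min_pairs),
                   stages = as.list(status),
                   checksums = as.list(tools::md5sum(files) |>
                                         stats::setNames(basename(files))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  class(res) <- "synshrink_run"
  res
}
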