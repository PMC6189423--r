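# Serialization of simulated genome pairs: FASTA + GFF3 + TSV truth tables,
# and the matching readers. GFF3 is 1-based closed (standard); internal
# coordinates are 0-based half-open.

# GRanges of one chromosome's features for GFF3 export (genes as
# gene/mRNA/CDS skeletons; TEs with long_terminal_repeat children)
.features_to_granges <- function(st, seqname) {
  f <- st$features
  rows <- list()
  add <- function(type, start, end, strand, id, parent = NA_character_,
                  family = NA_character_, te_class = NA_character_,
                  solo = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, start = start + 1, end = end, strand = strand, ID = id,
      Parent = parent, family_id = family, te_class = te_class,
      solo = as.character(solo), stringsAsFactors = FALSE)
  }
  gi <- 0L; ti <- 0L
  for (i in seq_len(nrow(f))) {
    if (f$kind[i] == "gene") {
      gi <- gi + 1L
      id <- f$gene_id[i]
      add("gene", f$start[i], f$end[i], f$strand[i], id,
          family = f$family_id[i])
      add("mRNA", f$start[i], f$end[i], f$strand[i], paste0(id, ".1"), id)
      add("CDS", f$start[i], f$end[i], f$strand[i], paste0(id, ".1.cds"),
          paste0(id, ".1"))
    } else if (f$kind[i] == "te") {
      ti <- ti + 1L
      id <- sprintf("te_%s_%04d", seqname, ti)
      add("transposable_element", f$start[i], f$end[i], f$strand[i], id,
          family = f$family_id[i], te_class = f$te_class[i],
          solo = isTRUE(f$is_solo[i]))
      if (!is.na(f$ltr_len[i])) {
        l <- f$ltr_len[i]
        add("long_terminal_repeat", f$start[i], f$start[i] + l,
            f$strand[i], paste0(id, ".ltr5"), id)
        add("long_terminal_repeat", f$end[i] - l, f$end[i],
            f$strand[i], paste0(id, ".ltr3"), id)
      }
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(seqname,
                               IRanges::IRanges(d$start, d$end),
                               strand = d$strand)
  S4Vectors::mcols(gr)$type <- d$type
  S4Vectors::mcols(gr)$ID <- d$ID
  S4Vectors::mcols(gr)$Parent <- d$Parent
  S4Vectors::mcols(gr)$family_id <- d$family_id
  S4Vectors::mcols(gr)$te_class <- d$te_class
  S4Vectors::mcols(gr)$solo <- d$solo
  S4Vectors::mcols(gr)$phase <- ifelse(d$type == "CDS", 0L, NA_integer_)
  gr
}

#' Read an annotation file back into feature tilings
#'
#' Parses a GFF3 written by [write_genome_pair()] (1-based closed
#' coordinates converted to internal 0-based half-open), reconstructs per
#' chromosome the gene/TE features with family labels, TE classes, LTR
#' termini and solo flags, and fills unannotated gaps with spacer features
#' so the result tiles `[0, length)` exactly. Features whose coordinates
#' exceed the stated chromosome length are a validation error; unknown
#' feature types are ignored.
#'
#' @param path GFF3 file path.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp),
#'   e.g. from the companion FASTA.
#' @return named list of feature data frames, one per chromosome.
#' @export
read_annotation <- function(path, chrom_lengths) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr)
  d$Parent <- if ("Parent" %in% names(d))
    vapply(as.list(d$Parent), function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
  else rep(NA_character_, nrow(d))
  for (col in c("family_id", "te_class", "solo"))
    if (!col %in% names(d)) d[[col]] <- rep(NA_character_, nrow(d))
  out <- list()
  for (chrom in names(chrom_lengths)) {
    dc <- d[d$seqnames == chrom, , drop = FALSE]
    L <- chrom_lengths[[chrom]]
    if (nrow(dc) && any(dc$end > L))
      stop("feature coordinates exceed chromosome length in ", chrom)
    rows <- list()
    ltr_by_parent <- dc[dc$type == "long_terminal_repeat", , drop = FALSE]
    for (i in which(dc$type == "gene")) {
      rows[[length(rows) + 1]] <-
        .feature_row("gene", dc$start[i] - 1, dc$end[i],
                     strand = as.character(dc$strand[i]),
                     family_id = dc$family_id[i], gene_id = dc$ID[i])
    }
    for (i in which(dc$type == "transposable_element")) {
      kids <- ltr_by_parent[ltr_by_parent$Parent == dc$ID[i], , drop = FALSE]
      ltr <- if (nrow(kids) == 2) kids$end[1] - kids$start[1] + 1 else NA_real_
      rows[[length(rows) + 1]] <-
        .feature_row("te", dc$start[i] - 1, dc$end[i],
                     strand = as.character(dc$strand[i]),
                     family_id = dc$family_id[i], te_class = dc$te_class[i],
                     ltr_len = ltr,
                     is_solo = identical(dc$solo[i], "TRUE"))
    }
    f <- do.call(rbind, rows)
    f <- f[order(f$start), , drop = FALSE]
    # fill gaps with spacers to recover the tiling
    gaps_s <- c(0, f$end)
    gaps_e <- c(f$start, L)
    keep <- gaps_e > gaps_s
    if (any(keep)) {
      sp <- .feature_row("spacer", gaps_s[keep], gaps_e[keep])
      f <- rbind(f, sp)
      f <- f[order(f$start), , drop = FALSE]
    }
    rownames(f) <- NULL
    out[[chrom]] <- f
  }
  out
}

#' Sample a genetic-map marker table from a recombination map
#'
#' Marker physical positions are drawn uniformly; each marker's cumulative
#' genetic distance is the integral of the relative rate profile scaled to
#' the map's total cM, plus optional Gaussian noise (monotonicity is
#' restored by a running maximum when noise is added).
#'
#' @param map a [recomb_map()].
#' @param n_markers number of markers (>= 2).
#' @param chrom chromosome id for the output table.
#' @param noise_cm standard deviation of cM noise (0 = exact integral).
#' @param length chromosome length (defaults to the map's).
#' @return data frame: `marker`, `chrom`, `pos_bp`, `cm`.
#' @export
sample_marker_map <- function(map, n_markers, chrom = "chr01", noise_cm = 0,
                              length = map$chromosome_length) {
  if (n_markers < 2) stop("need at least 2 markers")
  pos <- sort(c(0, length - 1,
                floor(stats::runif(max(0, n_markers - 2), 1, length - 1))))
  pos <- pos[seq_len(n_markers)]
  cm <- cumulative_cm_at(map, pos, length)
  if (noise_cm > 0) cm <- cummax(cm + stats::rnorm(n_markers, 0, noise_cm))
  data.frame(marker = sprintf("m_%s_%03d", chrom, seq_len(n_markers)),
             chrom = chrom, pos_bp = pos, cm = cm, stringsAsFactors = FALSE)
}

#' Serialize a simulated genome pair to a file bundle
#'
#' Writes, under `out_dir`: FASTA sequences for both genomes (chromosomes
#' named `<chrom>_I` / `<chrom>_D`, 80-column), GFF3 annotations carrying
#' kind, family, TE class, LTR termini and solo flags, a genetic-map marker
#' table (genome D), truth-derived pairwise alignment blocks, the event-log
#' truth tables and the ortholog table.
#'
#' @param pair a `sim_pair` from [simulate_divergent_pair()].
#' @param out_dir output directory (created if needed).
#' @param divergence per-TE-copy substitution rate at sequence synthesis
#'   (0 makes repeat copies exact template substrings).
#' @param n_markers markers per chromosome for the genetic map.
#' @param seed seed for sequence synthesis and marker sampling.
#' @return list of class `genome_pair_bundle` with the file paths and
#'   chromosome lengths.
#' @export
write_genome_pair <- function(pair, out_dir, divergence = 0.02,
                              n_markers = 100, seed = 1L) {
  stopifnot(inherits(pair, "sim_pair"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta_I = file.path(out_dir, "genome_I.fa"),
    fasta_D = file.path(out_dir, "genome_D.fa"),
    gff_I = file.path(out_dir, "genome_I.gff3"),
    gff_D = file.path(out_dir, "genome_D.gff3"),
    marker_map = file.path(out_dir, "marker_map.tsv"),
    alignment_blocks = file.path(out_dir, "alignment_blocks.tsv"),
    events_I = file.path(out_dir, "events_I.tsv"),
    events_D = file.path(out_dir, "events_D.tsv"),
    orthologs = file.path(out_dir, "orthologs.tsv"))

  lens <- list()
  for (lineage in c("I", "D")) {
    genome <- pair[[paste0("genome_", lineage)]]
    seqs <- list(); grs <- list()
    for (i in seq_along(genome)) {
      st <- genome[[i]]
      nm <- paste0(st$chrom, "_", lineage)
      seqs[[nm]] <- synthesize_chrom_seq(
        st, seed = .child_seed(seed, paste0("seq", lineage), i),
        divergence = divergence)
      grs[[nm]] <- .features_to_granges(st, nm)
      lens[[lineage]] <- c(lens[[lineage]],
                           stats::setNames(st$length, nm))
    }
    ss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(ss, paths[[paste0("fasta_", lineage)]],
                                width = 80)
    rtracklayer::export(do.call(c, unname(grs)),
                        paths[[paste0("gff_", lineage)]], format = "gff3")
    ev <- do.call(rbind, lapply(genome, function(st)
      cbind(chrom = st$chrom, st$events)))
    utils::write.table(ev, paths[[paste0("events_", lineage)]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  mk <- .with_seed(.child_seed(seed, "markers", 0L), {
    do.call(rbind, lapply(pair$genome_D, function(st)
      sample_marker_map(st$recomb, n_markers,
                        chrom = paste0(st$chrom, "_D"),
                        length = st$length)))
  })
  utils::write.table(mk, paths$marker_map, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  bl <- do.call(rbind, lapply(seq_along(pair$genome_I), function(i)
    alignment_blocks_from_truth(pair$genome_I[[i]], pair$genome_D[[i]],
                                pair$ancestor[[i]]$length)))
  utils::write.table(bl, paths$alignment_blocks, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ortholog_truth(pair), paths$orthologs, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  structure(c(paths, list(lengths_I = lens$I, lengths_D = lens$D)),
            class = "genome_pair_bundle")
}

#' Read a serialized genome pair bundle
#'
#' @param bundle a `genome_pair_bundle` (or a directory path containing one
#'   written by [write_genome_pair()]).
#' @return list with `seq_I`, `seq_D` (`DNAStringSet`s), `annot_I`,
#'   `annot_D` (feature tilings per chromosome), `markers`,
#'   `alignment_blocks`, `events_I`, `events_D`, `orthologs`.
#' @export
read_genome_pair <- function(bundle) {
  if (is.character(bundle)) {
    d <- bundle
    bundle <- list(fasta_I = file.path(d, "genome_I.fa"),
                   fasta_D = file.path(d, "genome_D.fa"),
                   gff_I = file.path(d, "genome_I.gff3"),
                   gff_D = file.path(d, "genome_D.gff3"),
                   marker_map = file.path(d, "marker_map.tsv"),
                   alignment_blocks = file.path(d, "alignment_blocks.tsv"),
                   events_I = file.path(d, "events_I.tsv"),
                   events_D = file.path(d, "events_D.tsv"),
                   orthologs = file.path(d, "orthologs.tsv"))
  }
  for (p in c("fasta_I", "fasta_D", "gff_I", "gff_D"))
    if (!file.exists(bundle[[p]]))
      stop("missing bundle file: ", bundle[[p]])
  seq_I <- Biostrings::readDNAStringSet(bundle$fasta_I)
  seq_D <- Biostrings::readDNAStringSet(bundle$fasta_D)
  names(seq_I) <- sub(" .*", "", names(seq_I))
  names(seq_D) <- sub(" .*", "", names(seq_D))
  rd <- function(p) if (file.exists(p))
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  else NULL
  list(seq_I = seq_I, seq_D = seq_D,
       annot_I = read_annotation(bundle$gff_I, Biostrings::width(seq_I) |>
                                   stats::setNames(names(seq_I))),
       annot_D = read_annotation(bundle$gff_D, Biostrings::width(seq_D) |>
                                   stats::setNames(names(seq_D))),
       markers = rd(bundle$marker_map),
       alignment_blocks = rd(bundle$alignment_blocks),
       events_I = rd(bundle$events_I), events_D = rd(bundle$events_D),
       orthologs = rd(bundle$orthologs))
}

#' Gene table of one genome's annotation
#'
#' Flattens a per-chromosome feature list into the gene table consumed by
#' [find_homolog_pairs()].
#' @param annot named list of feature data frames.
#' @return data frame: `gene_id`, `chrom`, `start`, `end`, `family_id`.
#' @export
gene_table <- function(annot) {
  do.call(rbind, lapply(names(annot), function(ch) {
    f <- annot[[ch]]
    g <- f[f$kind == "gene", , drop = FALSE]
    data.frame(gene_id = g$gene_id, chrom = ch, start = g$start,
               end = g$end, family_id = g$family_id,
               stringsAsFactors = FALSE)
  }))
}
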