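# Gene-density partition tracks, inter-genome density differences, U-shape
# diagnostics and Marey-map recombination profiles.

#' Gene-density track over equal chromosome partitions
#'
#' Divides the chromosome into `n_partitions` equal partitions (any
#' remainder of the integer division is added to the final partition) and
#' reports gene density as genes per 100 kb per partition. A gene is
#' assigned to the partition containing its midpoint.
#'
#' @param annotation feature data frame (needs `kind`, `start`, `end`); any
#'   table with gene rows works.
#' @param chromosome_length chromosome length in bp.
#' @param n_partitions number of partitions (default 500).
#' @param chrom chromosome id carried through to the output.
#' @param kind which feature kind to count (default "gene"; use "te" for TE
#'   density tracks).
#' @return data frame of class `density_track`: `chrom`, `partition`,
#'   `start`, `end`, `count`, `density` (features per 100 kb).
#' @export
partition_gene_density <- function(annotation, chromosome_length,
                                   n_partitions = 500, chrom = "chr",
                                   kind = "gene") {
  if (chromosome_length < n_partitions)
    stop("chromosome shorter than the number of partitions")
  plen <- floor(chromosome_length / n_partitions)
  starts <- (seq_len(n_partitions) - 1) * plen
  ends <- starts + plen
  ends[n_partitions] <- chromosome_length  # remainder goes to the last one
  g <- annotation[annotation$kind == kind, , drop = FALSE]
  mid <- (g$start + g$end) / 2
  pidx <- pmin(findInterval(mid, starts), n_partitions)
  cnt <- tabulate(pidx, nbins = n_partitions)
  out <- data.frame(chrom = chrom, partition = seq_len(n_partitions),
                    start = starts, end = ends, count = cnt,
                    density = cnt / (ends - starts) * 1e5,
                    stringsAsFactors = FALSE)
  class(out) <- c("density_track", class(out))
  out
}

#' Per-partition gene-density difference between two genomes
#'
#' Partitions are paired by index (the i-th partition of one genome with the
#' i-th of the other, even when chromosome lengths differ) and the genome-D
#' density is subtracted from the genome-I density.
#'
#' @param track_I,track_D [partition_gene_density()] tracks with equal
#'   `n_partitions`.
#' @return data frame: `partition`, `density_I`, `density_D`, `difference`.
#' @export
density_difference <- function(track_I, track_D) {
  if (nrow(track_I) != nrow(track_D))
    stop("tracks have different numbers of partitions")
  data.frame(partition = track_I$partition,
             density_I = track_I$density, density_D = track_D$density,
             difference = track_I$density - track_D$density)
}

#' Disruption score of the U-shaped density gradient
#'
#' An unrearranged chromosome shows gene density rising from the centromere
#' toward both telomeres; this scores how far a track departs from that
#' template as `1 - rho`, where `rho` is the Spearman correlation between
#' the per-partition density and the distance of the partition midpoint from
#' the chromosome midpoint. 0 = perfect U shape, values near 1 = no
#' gradient (a constant track is reported as exactly 1), up to 2 = fully
#' reversed gradient.
#'
#' @param track a [partition_gene_density()] track (>= 10 partitions).
#' @return numeric score in `[0, 2]`.
#' @export
gradient_disruption_score <- function(track) {
  if (nrow(track) < 10) stop("need at least 10 partitions")
  midpos <- (track$start + track$end) / 2
  template <- abs(midpos - max(track$end) / 2)
  if (stats::sd(track$density) == 0) return(1)
  rho <- stats::cor(track$density, template, method = "spearman")
  1 - rho
}

#' Marey-map recombination profile from a marker table
#'
#' Sorts markers by physical position, flags genetic-distance decreases and
#' duplicated positions, and computes the local recombination rate (cM/Mb)
#' by finite differences over physical windows.
#'
#' @param markers data frame with columns `chrom`, `pos_bp`, `cm`
#'   (cumulative genetic distance).
#' @param window window size in bp for the local-rate profile.
#' @return list of class `marey_profile` with `profile` (per window:
#'   `chrom`, `pos_bp` midpoint, `cm` interpolated cumulative distance,
#'   `cm_per_mb`) and `violations` (marker rows where cM decreases or
#'   positions duplicate).
#' @export
marey_recombination_profile <- function(markers, window = 1e5) {
  stopifnot(all(c("chrom", "pos_bp", "cm") %in% names(markers)))
  out <- list(); viol <- list()
  for (m in split(markers, markers$chrom)) {
    if (nrow(m) < 2) stop("need at least 2 markers per chromosome")
    m <- m[order(m$pos_bp), , drop = FALSE]
    bad <- which(diff(m$cm) < 0 | diff(m$pos_bp) == 0)
    if (length(bad))
      viol[[length(viol) + 1]] <- m[bad + 1, , drop = FALSE]
    grid <- seq(min(m$pos_bp), max(m$pos_bp), by = window)
    if (grid[length(grid)] < max(m$pos_bp)) grid <- c(grid, max(m$pos_bp))
    cmg <- stats::approx(m$pos_bp, m$cm, xout = grid, ties = "ordered",
                         rule = 2)$y
    cmg <- cummax(cmg)  # enforce monotone cumulative distance
    rate <- diff(cmg) / (diff(grid) / 1e6)
    out[[length(out) + 1]] <-
      data.frame(chrom = m$chrom[1],
                 pos_bp = (grid[-1] + grid[-length(grid)]) / 2,
                 cm = cmg[-1], cm_per_mb = rate, stringsAsFactors = FALSE)
  }
  structure(list(profile = do.call(rbind, out),
                 violations = if (length(viol)) do.call(rbind, viol)
                              else markers[0, ]),
            class = "marey_profile")
}
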