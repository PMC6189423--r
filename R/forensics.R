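# Deletion-mechanism forensics: unaligned segments between aligned blocks,
# length binning, TE composition of segments, flanking-repeat
# classification (unequal intrastrand vs illegitimate recombination), and
# solo/intact LTR inventories.

#' Extract unaligned segments from pairwise alignment blocks
#'
#' The unaligned fraction of each genome is the complement of its aligned
#' block spans within `[0, chromosome length)`; per genome, aligned plus
#' unaligned bp always equals the region length.
#'
#' @param blocks alignment block table (columns `start_I`, `end_I`,
#'   `start_D`, `end_D`, plus `chrom_I`/`chrom_D`), e.g. from
#'   [alignment_blocks_from_truth()].
#' @param length_I,length_D chromosome (region) lengths in bp.
#' @return list with data frames `I` and `D`: `genome`, `chrom`, `start`,
#'   `end`, `length`.
#' @export
extract_unaligned_segments <- function(blocks, length_I, length_D) {
  one <- function(starts, ends, L, genome, chrom) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
      stop("overlapping alignment blocks in genome ", genome)
    gs <- c(0, ends)
    ge <- c(starts, L)
    keep <- ge > gs
    data.frame(genome = rep(genome, sum(keep)),
               chrom = rep(chrom, sum(keep)), start = gs[keep],
               end = ge[keep], length = ge[keep] - gs[keep],
               stringsAsFactors = FALSE)
  }
  list(I = one(blocks$start_I, blocks$end_I, length_I, "I",
               if (nrow(blocks)) blocks$chrom_I[1] else NA_character_),
       D = one(blocks$start_D, blocks$end_D, length_D, "D",
               if (nrow(blocks)) blocks$chrom_D[1] else NA_character_))
}

#' Bin unaligned segments by length
#'
#' Counts and total bp per half-open length interval `[edge_i, edge_{i+1})`;
#' an open-ended final bin is added automatically, and the aggregate
#' short/long split below/at-or-above `split_at` is always reported.
#'
#' @param segments data frame with a `length` column.
#' @param edges strictly increasing bin edges (bp).
#' @param split_at headline split point (default 1000 bp).
#' @return list with `bins` (interval, n, total_bp) and `split`
#'   (short/long n and total_bp).
#' @export
bin_unaligned_lengths <- function(segments,
                                  edges = c(0, 100, 1000, 10000),
                                  split_at = 1000) {
  stopifnot(all(diff(edges) > 0))
  len <- segments$length
  brk <- c(edges, Inf)
  idx <- findInterval(len, brk)
  lab <- paste0("[", brk[-length(brk)], ",", brk[-1], ")")
  bins <- data.frame(interval = lab,
                     n = tabulate(idx, nbins = length(lab)),
                     total_bp = vapply(seq_along(lab), function(i)
                       sum(len[idx == i]), numeric(1)))
  split <- data.frame(class = c("short", "long"),
                      n = c(sum(len < split_at), sum(len >= split_at)),
                      total_bp = c(sum(len[len < split_at]),
                                   sum(len[len >= split_at])))
  list(bins = bins, split = split)
}

#' TE-class composition of unaligned segments
#'
#' Intersects each segment with the TE features of its chromosome and sums
#' overlapping bp per TE class.
#'
#' @param segments unaligned segment data frame (`start`, `end`).
#' @param feats feature data frame of the same chromosome.
#' @return input segments with one `bp_<class>` column per TE class present
#'   and `bp_te` (total TE bp).
#' @export
segment_te_composition <- function(segments, feats) {
  te <- feats[feats$kind == "te", , drop = FALSE]
  classes <- sort(unique(te$te_class))
  for (cl in classes) segments[[paste0("bp_", cl)]] <- 0
  segments$bp_te <- 0
  for (i in seq_len(nrow(segments))) {
    ov <- pmin(segments$end[i], te$end) - pmax(segments$start[i], te$start)
    pos <- ov > 0
    if (any(pos)) {
      by_cl <- tapply(ov[pos], te$te_class[pos], sum)
      for (cl in names(by_cl))
        segments[[paste0("bp_", cl)]][i] <- by_cl[[cl]]
      segments$bp_te[i] <- sum(ov[pos])
    }
  }
  segments
}

#' Flanking-repeat classification configuration
#'
#' Thresholds for calling the deletion mechanism from the repeats flanking
#' an unaligned segment: repeats of at least `min_repeat_len` bp lying
#' within `max_endpoint_distance` bp of each endpoint, optionally required
#' to be in the same direction (strand) at the two ends.
#' @param min_repeat_len minimum repeat length (bp).
#' @param max_endpoint_distance maximum distance from segment endpoint (bp).
#' @param require_same_direction require equal strands at the two ends.
#' @return a list of class `flanking_config`.
#' @export
flanking_config <- function(min_repeat_len = 50, max_endpoint_distance = 100,
                            require_same_direction = TRUE) {
  stopifnot(min_repeat_len > 0, max_endpoint_distance > 0)
  structure(list(min_repeat_len = min_repeat_len,
                 max_endpoint_distance = max_endpoint_distance,
                 require_same_direction = require_same_direction),
            class = "flanking_config")
}

# distance from an interval to a point (0 when the point is inside)
.interval_point_dist <- function(start, end, p) {
  pmax(0, pmax(start - p, p - end))
}

#' Classify the flanking repeats of an unaligned segment
#'
#' Calls "identical" when a qualifying repeat with the same template id
#' (and, if required, the same strand) lies within the endpoint distance of
#' *each* end of the segment — the signature of unequal intrastrand
#' recombination between direct repeats. Calls "similar" when the two ends
#' only share a repeat class/family, and "none" otherwise; identical takes
#' precedence over similar.
#'
#' @param seg_start,seg_end segment interval (bp).
#' @param repeats repeat annotation data frame: `start`, `end`, `template`
#'   (repeat/template identity), `class`, `strand`.
#' @param config a [flanking_config()].
#' @return "identical", "similar" or "none".
#' @export
classify_flanking_repeats <- function(seg_start, seg_end, repeats,
                                      config = flanking_config()) {
  r <- repeats[(repeats$end - repeats$start) >= config$min_repeat_len, ,
               drop = FALSE]
  if (!nrow(r)) return("none")
  near_l <- .interval_point_dist(r$start, r$end, seg_start) <=
    config$max_endpoint_distance
  near_r <- .interval_point_dist(r$start, r$end, seg_end) <=
    config$max_endpoint_distance
  L <- r[near_l, , drop = FALSE]
  R <- r[near_r, , drop = FALSE]
  if (!nrow(L) || !nrow(R)) return("none")
  pairs <- merge(L[, c("template", "class", "strand")],
                 R[, c("template", "class", "strand")],
                 by = NULL)  # cartesian
  if (config$require_same_direction)
    pairs <- pairs[pairs$strand.x == pairs$strand.y, , drop = FALSE]
  if (!nrow(pairs)) return("none")
  if (any(pairs$template.x == pairs$template.y)) return("identical")
  if (any(pairs$class.x == pairs$class.y)) return("similar")
  "none"
}

#' Mechanism fractions over classified segments
#'
#' @param segments data frame with `length` and `flanking_call` columns
#'   (typically the >= 1 kb unaligned segments).
#' @return data frame per call: `n`, `count_fraction`, `bp`, `bp_fraction`;
#'   all fractions NA when the input is empty.
#' @export
mechanism_fraction_report <- function(segments) {
  calls <- c("identical", "similar", "none")
  n <- vapply(calls, function(cl) sum(segments$flanking_call == cl),
              numeric(1))
  bp <- vapply(calls, function(cl)
    sum(segments$length[segments$flanking_call == cl]), numeric(1))
  tot_n <- sum(n); tot_bp <- sum(bp)
  data.frame(flanking_call = calls, n = n,
             count_fraction = if (tot_n > 0) n / tot_n else NA_real_,
             bp = bp,
             bp_fraction = if (tot_bp > 0) bp / tot_bp else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Repeat annotation table from a feature tiling
#'
#' Expands TE features into the repeat records used by flanking
#' classification: one record per non-LTR TE, and separate records for the
#' two terminal repeats and the internal region of each intact LTR element
#' (termini share the element's family template id).
#'
#' @param feats feature data frame.
#' @return data frame: `start`, `end`, `template`, `class`, `strand`.
#' @export
repeat_annotation <- function(feats) {
  te <- feats[feats$kind == "te", , drop = FALSE]
  if (!nrow(te))
    return(data.frame(start = numeric(0), end = numeric(0),
                      template = character(0), class = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(nrow(te))) {
    if (!is.na(te$ltr_len[i])) {
      l <- te$ltr_len[i]
      rows[[length(rows) + 1]] <- data.frame(
        start = c(te$start[i], te$start[i] + l, te$end[i] - l),
        end = c(te$start[i] + l, te$end[i] - l, te$end[i]),
        template = c(paste0(te$family_id[i], ":LTR"),
                     paste0(te$family_id[i], ":INT"),
                     paste0(te$family_id[i], ":LTR")),
        class = te$te_class[i], strand = te$strand[i],
        stringsAsFactors = FALSE)
    } else {
      tmpl <- if (isTRUE(te$is_solo[i])) paste0(te$family_id[i], ":LTR")
              else paste0(te$family_id[i],
                          if (identical(te$te_class[i], "LTR")) ":INT" else "")
      rows[[length(rows) + 1]] <- data.frame(
        start = te$start[i], end = te$end[i], template = tmpl,
        class = te$te_class[i], strand = te$strand[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Solo vs intact LTR inventory by sequence search
#'
#' For each intact LTR retrotransposon the terminal-repeat sequence is
#' extracted from the genome and searched against the region at full length
#' and the configured identity (default 100%, i.e. exact matching; 0.95 or
#' 0.90 allow proportional mismatches). Matches that do not overlap any
#' intact-element footprint are counted as solo LTRs.
#'
#' @param genome_seq a `Biostrings::DNAString` (or string) of the
#'   chromosome.
#' @param feats feature data frame of that chromosome (intact LTR elements
#'   carry `ltr_len`).
#' @param regions data frame `start`, `end`, `region` labels; NULL for the
#'   whole chromosome.
#' @param identity minimum sequence identity of a match (1 = exact).
#' @return data frame per region: `region`, `intact`, `solo`,
#'   `solo_per_intact` (NA when no intact elements lie in the region).
#' @export
ltr_inventory <- function(genome_seq, feats, regions = NULL, identity = 1) {
  if (!methods::is(genome_seq, "DNAString"))
    genome_seq <- Biostrings::DNAString(genome_seq)
  if (is.null(regions))
    regions <- data.frame(start = 0, end = length(genome_seq),
                          region = "whole")
  intact <- feats[feats$kind == "te" & !is.na(feats$ltr_len), , drop = FALSE]
  # one query per family: termini of the same family share a template
  matches <- NULL
  if (nrow(intact)) {
    fams <- !duplicated(intact$family_id)
    for (i in which(fams)) {
      pat <- Biostrings::subseq(genome_seq, intact$start[i] + 1,
                                intact$start[i] + intact$ltr_len[i])
      mm <- floor((1 - identity) * length(pat))
      for (p in list(pat, Biostrings::reverseComplement(pat))) {
        hits <- Biostrings::matchPattern(p, genome_seq, max.mismatch = mm)
        if (length(hits))
          matches <- rbind(matches,
                           data.frame(start = BiocGenerics::start(hits) - 1,
                                      end = BiocGenerics::end(hits)))
      }
    }
  }
  if (!is.null(matches)) matches <- unique(matches)
  out <- lapply(seq_len(nrow(regions)), function(r) {
    rs <- regions$start[r]; re <- regions$end[r]
    mid_int <- (intact$start + intact$end) / 2
    n_int <- sum(mid_int >= rs & mid_int < re)
    n_solo <- 0L
    if (!is.null(matches) && nrow(matches)) {
      inreg <- (matches$start + matches$end) / 2 >= rs &
        (matches$start + matches$end) / 2 < re
      m <- matches[inreg, , drop = FALSE]
      if (nrow(m) && nrow(intact)) {
        keep <- vapply(seq_len(nrow(m)), function(i)
          !any(m$start[i] < intact$end & m$end[i] > intact$start),
          logical(1))
        m <- m[keep, , drop = FALSE]
      }
      n_solo <- nrow(m)
    }
    data.frame(region = regions$region[r], intact = n_int, solo = n_solo,
               solo_per_intact = if (n_int > 0) n_solo / n_int else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
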