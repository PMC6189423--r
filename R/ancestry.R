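# Ancestral-coordinate bookkeeping: replaying an event log as an interval
# map from the current chromosome to ancestral coordinates. Intersecting
# the maps of the two lineages yields truth-derived pairwise alignment
# blocks (every ancestral bp surviving in both genomes) without any sequence
# alignment.

#' Ancestral segment map of an evolved chromosome
#'
#' Replays an event log on an interval map of the ancestral chromosome and
#' returns the final chromosome as an ordered list of segments, each either
#' a surviving ancestral interval (with orientation) or an inserted,
#' non-ancestral stretch. Cross-chromosome relocations are not supported by
#' this map.
#'
#' @param length ancestral chromosome length (bp).
#' @param events an event log from a simulated chromosome.
#' @return data frame: `cur_start`, `cur_end` (current coordinates),
#'   `anc_start`, `anc_end` (NA for inserted segments), `orient` (+1/-1).
#' @export
ancestry_map <- function(length, events) {
  if (nrow(events) && any(events$kind == "relocation"))
    stop("ancestry_map does not support relocation events")
  # segment list as parallel vectors: length, ancestral interval (NA for
  # inserted material), orientation
  sl <- length; sa <- 0; sb <- length; so <- 1L

  cur_starts <- function() c(0, cumsum(sl))[seq_along(sl)]

  # split segments at all current-coordinate positions in `pos`
  split_all <- function(pos) {
    for (p in sort(unique(pos))) {
      cs <- cur_starts()
      i <- findInterval(p, cs)
      if (i >= 1 && i <= length(sl) && p > cs[i] && p < cs[i] + sl[i]) {
        off <- p - cs[i]
        n <- length(sl)
        ins <- function(v, a, b) c(v[seq_len(i - 1)], a, b,
                                   v[seq_len(n)[-seq_len(i)]])
        a <- sa[i]; b <- sb[i]
        if (is.na(a)) {               # inserted material
          sa <<- ins(sa, NA_real_, NA_real_)
          sb <<- ins(sb, NA_real_, NA_real_)
        } else if (so[i] == 1L) {     # forward: left maps to [a, a+off)
          sa <<- ins(sa, a, a + off)
          sb <<- ins(sb, a + off, b)
        } else {                      # reverse: left maps to [b-off, b)
          sa <<- ins(sa, b - off, a)
          sb <<- ins(sb, b, b - off)
        }
        so <<- ins(so, so[i], so[i])
        sl <<- ins(sl, off, sl[i] - off)
      }
    }
  }

  for (g in sort(unique(events$generation))) {
    ev <- events[events$generation == g, , drop = FALSE]
    for (i in which(ev$kind == "inversion")) {
      split_all(c(ev$start[i], ev$end[i]))
      cs <- cur_starts()
      idx <- which(cs >= ev$start[i] & (cs + sl) <= ev$end[i])
      r <- rev(idx)
      sl[idx] <- sl[r]; sa[idx] <- sa[r]; sb[idx] <- sb[r]
      so[idx] <- -so[r]
    }
    dl <- ev[ev$kind %in% c("illegitimate_deletion",
                            "unequal_intrastrand_deletion"), , drop = FALSE]
    if (nrow(dl)) {
      dl <- dl[order(dl$start), , drop = FALSE]
      split_all(c(dl$start, dl$end))
      cs <- cur_starts()
      j <- findInterval(cs, dl$start)
      deleted <- j >= 1 & cs < dl$end[pmax(j, 1)]
      sl <- sl[!deleted]; sa <- sa[!deleted]; sb <- sb[!deleted]
      so <- so[!deleted]
    }
    insev <- ev[ev$kind == "insertion", , drop = FALSE]
    if (nrow(insev)) {
      # positions are post-deletion-of-this-generation current coordinates
      if (nrow(dl)) {
        cumdel <- c(0, cumsum(dl$end - dl$start))
        insev$start <- insev$start -
          cumdel[findInterval(insev$start, dl$end) + 1]
      }
      insev <- insev[order(insev$start, decreasing = TRUE), , drop = FALSE]
      for (k in seq_len(nrow(insev))) {
        split_all(insev$start[k])
        cs <- cur_starts()
        i <- sum(cs + sl <= insev$start[k])  # segments entirely before pos
        n <- length(sl)
        at <- function(v, x) c(v[seq_len(i)], x, v[seq_len(n)[-seq_len(i)]])
        sl <- at(sl, insev$ins_length[k])
        sa <- at(sa, NA_real_); sb <- at(sb, NA_real_); so <- at(so, 1L)
      }
    }
  }
  cs <- c(0, cumsum(sl))[seq_along(sl)]
  data.frame(cur_start = cs, cur_end = cs + sl, anc_start = sa, anc_end = sb,
             orient = so)
}

#' Truth-derived alignment blocks between the two lineages
#'
#' Intersects the ancestral segment maps of the same chromosome in lineage I
#' and lineage D: every ancestral interval surviving in both genomes becomes
#' one aligned block with coordinates in each genome and a combined
#' orientation. Adjacent blocks contiguous in ancestor and in both genomes
#' are merged, so a clean inversion appears as a single reverse-orientation
#' block.
#'
#' @param chrom_I,chrom_D the evolved [chrom_state()]s of one chromosome in
#'   the two lineages.
#' @param ancestor_length ancestral length of that chromosome (bp).
#' @return data frame: `chrom_I`, `start_I`, `end_I`, `chrom_D`, `start_D`,
#'   `end_D`, `orient`, `anc_start`, `anc_end`, sorted by `start_I`.
#' @export
alignment_blocks_from_truth <- function(chrom_I, chrom_D, ancestor_length) {
  mi <- ancestry_map(ancestor_length, chrom_I$events)
  md <- ancestry_map(ancestor_length, chrom_D$events)
  mi <- mi[!is.na(mi$anc_start), , drop = FALSE]
  md <- md[!is.na(md$anc_start), , drop = FALSE]
  ri <- IRanges::IRanges(mi$anc_start + 1, mi$anc_end)
  rd <- IRanges::IRanges(md$anc_start + 1, md$anc_end)
  ov <- IRanges::findOverlaps(ri, rd)
  qi <- S4Vectors::queryHits(ov)
  sj <- S4Vectors::subjectHits(ov)
  os <- pmax(mi$anc_start[qi], md$anc_start[sj])
  oe <- pmin(mi$anc_end[qi], md$anc_end[sj])
  cur_from_anc <- function(m, idx, os, oe) {
    s <- ifelse(m$orient[idx] == 1L,
                m$cur_start[idx] + (os - m$anc_start[idx]),
                m$cur_start[idx] + (m$anc_end[idx] - oe))
    cbind(s, s + (oe - os))
  }
  ci <- cur_from_anc(mi, qi, os, oe)
  cd <- cur_from_anc(md, sj, os, oe)
  bl <- data.frame(chrom_I = chrom_I$chrom, start_I = ci[, 1], end_I = ci[, 2],
                   chrom_D = chrom_D$chrom, start_D = cd[, 1], end_D = cd[, 2],
                   orient_I = mi$orient[qi], orient_D = md$orient[sj],
                   anc_start = os, anc_end = oe, stringsAsFactors = FALSE)
  bl <- bl[order(bl$anc_start), , drop = FALSE]
  # merge blocks contiguous in ancestor and in both current genomes
  if (nrow(bl) > 1) {
    keepfirst <- c(TRUE, !(bl$anc_start[-1] == bl$anc_end[-nrow(bl)] &
      bl$orient_I[-1] == bl$orient_I[-nrow(bl)] &
      bl$orient_D[-1] == bl$orient_D[-nrow(bl)] &
      ifelse(bl$orient_I[-1] == 1L,
             bl$start_I[-1] == bl$end_I[-nrow(bl)],
             bl$end_I[-1] == bl$start_I[-nrow(bl)]) &
      ifelse(bl$orient_D[-1] == 1L,
             bl$start_D[-1] == bl$end_D[-nrow(bl)],
             bl$end_D[-1] == bl$start_D[-nrow(bl)])))
    grp <- cumsum(keepfirst)
    bl <- do.call(rbind, lapply(split(bl, grp), function(b) {
      data.frame(chrom_I = b$chrom_I[1], start_I = min(b$start_I),
                 end_I = max(b$end_I), chrom_D = b$chrom_D[1],
                 start_D = min(b$start_D), end_D = max(b$end_D),
                 orient_I = b$orient_I[1], orient_D = b$orient_D[1],
                 anc_start = min(b$anc_start), anc_end = max(b$anc_end),
                 stringsAsFactors = FALSE)
    }))
  }
  bl$orient <- bl$orient_I * bl$orient_D
  bl <- bl[order(bl$start_I),
           c("chrom_I", "start_I", "end_I", "chrom_D", "start_D", "end_D",
             "orient", "anc_start", "anc_end")]
  rownames(bl) <- NULL
  bl
}
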