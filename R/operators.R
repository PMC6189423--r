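# Rearrangement operators: inversion and relocation.
# Both conserve total bp and the multiset of feature identities; endpoints
# snap to the nearest feature boundary by default so no feature is ever
# split by a rearrangement (deletions, by contrast, do fragment TEs).

# all internal feature boundaries incl. 0 and L
.boundaries <- function(features) c(features$start, features$end[nrow(features)])

# snap a position to the nearest feature boundary
.snap_to_boundary <- function(features, pos) {
  b <- .boundaries(features)
  b[which.min(abs(b - pos))]
}

# index range of features fully within [start, end); start/end must be
# boundaries
.rows_in_span <- function(features, start, end) {
  which(features$start >= start & features$end <= end)
}

.check_breakpoint <- function(features, pos, gene_protection) {
  b <- .boundaries(features)
  if (pos %in% b) return(invisible(TRUE))
  i <- findInterval(pos, features$start)
  if (gene_protection && features$kind[i] == "gene")
    stop("protected breakpoint: position ", pos, " falls inside a gene")
  stop("breakpoint at ", pos, " does not fall on a feature boundary; ",
       "use snap = TRUE")
}

#' Invert a chromosomal segment
#'
#' Reverses the order and strand of all features within `[start, end)`.
#' Endpoints are snapped to the nearest feature boundary (`snap = TRUE`,
#' default); with `snap = FALSE` non-boundary endpoints are an error, a
#' protected-breakpoint error when they fall inside a gene under gene
#' protection. Total length and the multiset of (kind, family, length)
#' feature identities are unchanged; an inversion event is appended to the
#' log.
#'
#' @param chrom a [chrom_state()].
#' @param start,end inversion span in bp (0-based half-open).
#' @param snap snap endpoints to the nearest feature boundary.
#' @param gene_protection governs the error raised for a non-boundary
#'   breakpoint inside a gene when `snap = FALSE`.
#' @return the modified `chrom_state`.
#' @export
apply_inversion <- function(chrom, start, end, snap = TRUE,
                            gene_protection = TRUE) {
  stopifnot(inherits(chrom, "chrom_state"),
            start >= 0, end <= chrom$length, start < end)
  f <- chrom$features
  if (snap) {
    start <- .snap_to_boundary(f, start)
    end <- .snap_to_boundary(f, end)
    if (start >= end) stop("inversion span collapsed after boundary snapping")
  } else {
    .check_breakpoint(f, start, gene_protection)
    .check_breakpoint(f, end, gene_protection)
  }
  idx <- .rows_in_span(f, start, end)
  seg <- f[rev(idx), , drop = FALSE]
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  lens <- seg$end - seg$start
  seg$start <- start + c(0, cumsum(lens))[seq_along(lens)]
  seg$end <- seg$start + lens
  f[idx, ] <- seg
  chrom$features <- f
  ev <- empty_event_log()[0, ]
  ev[1, c("generation", "kind", "start", "end", "length_change")] <-
    list(chrom$generation, "inversion", start, end, 0)
  chrom$events <- rbind(chrom$events, ev)
  validate_chrom_state(chrom)
  chrom
}

#' Relocate a chromosomal segment
#'
#' Moves the features within `span = [start, end)` of one chromosome to an
#' insertion point, either within the same chromosome (`chrom_b = NULL`) or
#' into a second chromosome. Feature kind, family and strand are retained;
#' combined length is conserved; relocation events are appended to the
#' log(s). Endpoints snap to the nearest feature boundary.
#'
#' @param chrom_a source [chrom_state()].
#' @param start,end source span in bp.
#' @param chrom_b destination `chrom_state`, or NULL for a within-chromosome
#'   move.
#' @param insert_at insertion point (bp) in the destination, interpreted in
#'   the destination's pre-move coordinates.
#' @param snap snap span endpoints and insertion point to feature boundaries.
#' @return for cross-chromosome moves, `list(a = , b = )`; for
#'   within-chromosome moves, the modified `chrom_state`.
#' @export
apply_relocation <- function(chrom_a, start, end, chrom_b = NULL, insert_at,
                             snap = TRUE) {
  stopifnot(inherits(chrom_a, "chrom_state"), start >= 0,
            end <= chrom_a$length, start < end)
  fa <- chrom_a$features
  if (snap) {
    start <- .snap_to_boundary(fa, start)
    end <- .snap_to_boundary(fa, end)
  } else {
    .check_breakpoint(fa, start, TRUE)
    .check_breakpoint(fa, end, TRUE)
  }
  within <- is.null(chrom_b)
  idx <- .rows_in_span(fa, start, end)
  moved <- fa[idx, , drop = FALSE]
  span_len <- end - start
  rest <- fa[-idx, , drop = FALSE]
  lens <- rest$end - rest$start
  rest$start <- c(0, cumsum(lens))[seq_len(nrow(rest))]
  rest$end <- rest$start + lens

  dest <- if (within) rest else chrom_b$features
  if (within && insert_at > start && insert_at < end)
    stop("insertion point lies inside the relocated span")
  ins_at <- insert_at
  if (within && insert_at >= end) ins_at <- insert_at - span_len
  if (snap) {
    ins_at <- .snap_to_boundary(dest, ins_at)
  } else {
    .check_breakpoint(dest, ins_at, TRUE)
  }
  before <- dest[dest$end <= ins_at, , drop = FALSE]
  after <- dest[dest$start >= ins_at, , drop = FALSE]
  mlens <- moved$end - moved$start
  moved$start <- ins_at + c(0, cumsum(mlens))[seq_along(mlens)]
  moved$end <- moved$start + mlens
  after$start <- after$start + span_len
  after$end <- after$end + span_len
  newdest <- rbind(before, moved, after)

  ev_out <- empty_event_log()[0, ]
  ev_out[1, c("generation", "kind", "start", "end", "length_change", "aux")] <-
    list(chrom_a$generation, "relocation", start, end, 0, ins_at)

  if (within) {
    chrom_a$features <- newdest
    chrom_a$events <- rbind(chrom_a$events, ev_out)
    validate_chrom_state(chrom_a)
    return(chrom_a)
  }
  chrom_a$features <- rest
  chrom_a$length <- chrom_a$length - span_len
  chrom_a$events <- rbind(chrom_a$events, transform(ev_out,
                                                    length_change = -span_len))
  chrom_b$features <- newdest
  chrom_b$length <- chrom_b$length + span_len
  ev_in <- ev_out
  ev_in[1, c("start", "end", "length_change")] <-
    list(ins_at, ins_at + span_len, span_len)
  chrom_b$events <- rbind(chrom_b$events, ev_in)
  validate_chrom_state(chrom_a)
  validate_chrom_state(chrom_b)
  list(a = chrom_a, b = chrom_b)
}
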