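#' Chromosome state container
#'
#' A simulated chromosome is an ordered, gap-free tiling of features
#' (genes, transposable elements, spacers) over `[0, length)`, carried as a
#' data frame with 0-based half-open coordinates, plus the chromosome's
#' recombination map, a generation counter and an event log.
#'
#' Feature columns:
#' \describe{
#'   \item{kind}{"gene", "te" or "spacer".}
#'   \item{start,end}{0-based half-open interval.}
#'   \item{strand}{"+" or "-".}
#'   \item{family_id}{gene family or TE family (template) label.}
#'   \item{te_class}{TE class ("LTR", "DNA", "LINE", "SINE",
#'     "low_complexity", "simple_repeat", "other"); NA for non-TEs.}
#'   \item{ltr_len}{length in bp of each terminal repeat for intact LTR
#'     retrotransposons (the 5' LTR occupies `[start, start+ltr_len)` and the
#'     3' LTR `[end-ltr_len, end)`); NA otherwise.}
#'   \item{is_solo}{TRUE for a solo LTR (a lone terminal repeat).}
#'   \item{gene_id}{stable ancestral gene identifier; NA for non-genes.}
#' }
#'
#' @param features feature data frame as described above.
#' @param recomb a [recomb_map()].
#' @param chrom chromosome name.
#' @param generation generation counter.
#' @param events event-log data frame (see [empty_event_log()]).
#' @return an object of class `chrom_state`.
#' @export
chrom_state <- function(features, recomb, chrom = "chr01", generation = 0L,
                        events = empty_event_log()) {
  st <- structure(list(features = features,
                       length = if (nrow(features)) features$end[nrow(features)] else 0,
                       recomb = recomb,
                       chrom = chrom,
                       generation = as.integer(generation),
                       events = events),
                  class = "chrom_state")
  validate_chrom_state(st)
  st
}

#' Empty event log
#'
#' One row per simulated event. `start`/`end` are in the coordinates of the
#' state at the beginning of the generation in which the event occurred (all
#' events of a generation are drawn against that state and applied
#' simultaneously), so replaying the log generation by generation
#' reconstructs the chromosome exactly. For unequal intrastrand deletions,
#' `solo_start`/`solo_end` record the retained solo-LTR interval (the
#' mechanism evidence). For insertions the `ins_*` columns describe the
#' inserted feature.
#' @return zero-row event-log data frame.
#' @export
empty_event_log <- function() {
  data.frame(generation = integer(0), kind = character(0),
             start = numeric(0), end = numeric(0),
             length_change = numeric(0),
             solo_start = numeric(0), solo_end = numeric(0),
             ins_family = character(0), ins_te_class = character(0),
             ins_length = numeric(0), ins_ltr_len = numeric(0),
             ins_strand = character(0),
             aux = numeric(0),
             stringsAsFactors = FALSE)
}

#' Validate the tiling invariants of a chromosome state
#'
#' Checks that features tile `[0, length)` with no gaps or overlaps, that all
#' intervals are non-empty, and that LTR annotation is internally consistent.
#' @param st a `chrom_state`.
#' @return `st`, invisibly; errors on violation.
#' @export
validate_chrom_state <- function(st) {
  f <- st$features
  if (!nrow(f)) stop("chromosome has no features")
  if (any(f$end <= f$start)) stop("empty or inverted feature interval")
  if (f$start[1] != 0) stop("tiling does not start at 0")
  if (nrow(f) > 1 && any(f$start[-1] != f$end[-nrow(f)]))
    stop("features do not tile the chromosome (gap or overlap)")
  if (abs(st$length - f$end[nrow(f)]) > 0)
    stop("stated length disagrees with tiling")
  bad <- !is.na(f$ltr_len) & (f$kind != "te" | is.na(f$te_class) |
                                f$te_class != "LTR" |
                                2 * f$ltr_len > (f$end - f$start))
  if (any(bad)) stop("inconsistent LTR terminus annotation")
  if (any(f$is_solo & !is.na(f$ltr_len)))
    stop("a solo LTR cannot carry an intact terminus pair")
  invisible(st)
}

#' @export
print.chrom_state <- function(x, ...) {
  f <- x$features
  cat(sprintf("chrom_state %s: %.0f bp, %d features (%d genes, %d TEs, %d spacers), generation %d, %d logged events\n",
              x$chrom, x$length, nrow(f), sum(f$kind == "gene"),
              sum(f$kind == "te"), sum(f$kind == "spacer"),
              x$generation, nrow(x$events)))
  invisible(x)
}

#' Total gene bp in a chromosome state
#' @param st a `chrom_state`.
#' @return numeric, summed gene feature length.
#' @export
gene_bp <- function(st) {
  f <- st$features
  sum((f$end - f$start)[f$kind == "gene"])
}

# row template used everywhere a feature data frame is assembled
.feature_row <- function(kind, start, end, strand = "+", family_id = NA_character_,
                         te_class = NA_character_, ltr_len = NA_real_,
                         is_solo = FALSE, gene_id = NA_character_) {
  data.frame(kind = kind, start = start, end = end, strand = strand,
             family_id = family_id, te_class = te_class, ltr_len = ltr_len,
             is_solo = is_solo, gene_id = gene_id, stringsAsFactors = FALSE)
}
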