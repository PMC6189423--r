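# TE counts and composition per syntenic block/region, TE-vs-size-ratio
# correlation, and local gene-duplication counting.

# count features (midpoint rule) inside a span
.count_in_span <- function(feats, start, end, kind = "te") {
  f <- feats[feats$kind == kind, , drop = FALSE]
  mid <- (f$start + f$end) / 2
  sum(mid >= start & mid < end)
}

#' Per-block TE and gene counts with ratios
#'
#' A TE (or gene) is counted inside a block span when its midpoint lies in
#' the span. Ratios with a zero denominator are reported as NA.
#'
#' @param blocks block table from [chain_synteny_blocks()].
#' @param annot_I,annot_D named lists of feature data frames, one per
#'   chromosome.
#' @return data frame: `block_id`, counts in both genomes, `te_ratio`,
#'   `gene_ratio`, `size_ratio`.
#' @export
block_te_stats <- function(blocks, annot_I, annot_D) {
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    fi <- annot_I[[b$chrom_I]]; fd <- annot_D[[b$chrom_D]]
    te_i <- .count_in_span(fi, b$start_I, b$end_I, "te")
    te_d <- .count_in_span(fd, b$start_D, b$end_D, "te")
    g_i <- .count_in_span(fi, b$start_I, b$end_I, "gene")
    g_d <- .count_in_span(fd, b$start_D, b$end_D, "gene")
    data.frame(block_id = b$block_id, chrom_I = b$chrom_I,
               te_count_I = te_i, te_count_D = te_d,
               gene_count_I = g_i, gene_count_D = g_d,
               te_ratio = if (te_d > 0) te_i / te_d else NA_real_,
               gene_ratio = if (g_d > 0) g_i / g_d else NA_real_,
               size_ratio = b$ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' R-squared between count ratios and block size ratios
#'
#' Ordinary least-squares coefficient of determination between the chosen
#' per-block count ratio (TE or gene) and the block size ratio; blocks with
#' undefined ratios are excluded (and counted in the attribute
#' `n_excluded`).
#'
#' @param stats_tbl output of [block_te_stats()].
#' @param which "te" or "gene".
#' @return numeric R-squared with attribute `n_excluded`.
#' @export
ratio_correlation <- function(stats_tbl, which = c("te", "gene")) {
  which <- match.arg(which)
  x <- stats_tbl[[paste0(which, "_ratio")]]
  y <- stats_tbl$size_ratio
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 blocks with defined ratios")
  r2 <- if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) 0
        else stats::cor(x[ok], y[ok])^2
  attr(r2, "n_excluded") <- sum(!ok)
  r2
}

#' TE composition table for labeled region sets
#'
#' Counts TEs per class (midpoint rule) within each labeled region set in
#' both genomes and reports the I/D count ratio per class, excluding the
#' requested chromosomes.
#'
#' @param annot_I,annot_D named lists of feature data frames per chromosome.
#' @param regions_I,regions_D data frames `chrom`, `start`, `end`, `label`
#'   describing corresponding region sets in each genome (labels typically
#'   "inverted"/"non_inverted").
#' @param excluded_chromosomes chromosomes dropped from the counts (applies
#'   to each genome's own chromosome names).
#' @return data frame: `label`, `te_class`, `count_I`, `count_D`, `ratio`.
#' @export
composition_table <- function(annot_I, annot_D, regions_I, regions_D,
                              excluded_chromosomes = character(0)) {
  count_set <- function(annot, regions) {
    regions <- regions[!(regions$chrom %in% excluded_chromosomes), ,
                       drop = FALSE]
    cnt <- list()
    for (r in seq_len(nrow(regions))) {
      f <- annot[[regions$chrom[r]]]
      te <- f[f$kind == "te", , drop = FALSE]
      mid <- (te$start + te$end) / 2
      sel <- mid >= regions$start[r] & mid < regions$end[r]
      if (any(sel))
        cnt[[length(cnt) + 1]] <-
          data.frame(label = regions$label[r], te_class = te$te_class[sel],
                     stringsAsFactors = FALSE)
    }
    if (!length(cnt))
      return(data.frame(label = character(0), te_class = character(0),
                        n = integer(0)))
    d <- do.call(rbind, cnt)
    stats::aggregate(list(n = rep(1L, nrow(d))),
                     d[, c("label", "te_class")], sum)
  }
  ci <- count_set(annot_I, regions_I)
  cd <- count_set(annot_D, regions_D)
  tab <- merge(ci, cd, by = c("label", "te_class"), all = TRUE,
               suffixes = c("_I", "_D"))
  if (!nrow(tab))
    return(data.frame(label = character(0), te_class = character(0),
                      count_I = integer(0), count_D = integer(0),
                      ratio = numeric(0)))
  tab$n_I[is.na(tab$n_I)] <- 0L
  tab$n_D[is.na(tab$n_D)] <- 0L
  names(tab)[names(tab) == "n_I"] <- "count_I"
  names(tab)[names(tab) == "n_D"] <- "count_D"
  tab$ratio <- ifelse(tab$count_D > 0, tab$count_I / tab$count_D, NA_real_)
  tab[order(tab$label, tab$te_class), , drop = FALSE]
}

#' Count locally duplicated genes
#'
#' Slides a window of `window_size` genes with step `step` along an ordered
#' gene list; in each window, genes sharing a family with another window
#' member are recorded. The count is the number of distinct genes ever
#' recorded (each gene counted once, however many windows it appears in).
#'
#' @param family_labels character vector of family labels in gene order
#'   along a chromosome.
#' @param window_size window size in genes (default 10).
#' @param step step in genes (default 1).
#' @return integer count of locally duplicated genes.
#' @examples
#' local_gene_duplications(c("A","A","B","C","D","E","F","G","H","I","J"))  # 2
#' @export
local_gene_duplications <- function(family_labels, window_size = 10,
                                    step = 1) {
  stopifnot(window_size >= 2, step >= 1)
  n <- length(family_labels)
  if (!n) return(0L)
  recorded <- logical(n)
  starts <- if (n <= window_size) 1L
            else unique(c(seq(1L, n - window_size + 1L, by = step),
                          n - window_size + 1L))  # final window always taken
  for (s in starts) {
    w <- s:min(s + window_size - 1L, n)
    fam <- family_labels[w]
    dup <- fam %in% fam[duplicated(fam)]
    recorded[w[dup]] <- TRUE
  }
  sum(recorded)
}
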