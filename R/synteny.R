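# Homolog pairing, collinear block chaining, inversion detection and
# syntenic-block size ratios between two annotated genomes.

#' Pair homologous genes between two genomes
#'
#' For each query gene in genome I the single best target in genome D is
#' retained (top hit), with deterministic tie-breaking: highest score, then
#' lexicographically smallest target id. The default scorer declares two
#' genes homologous when their family labels match (score 1); a k-mer
#' sequence-identity scorer is available when gene sequences are supplied.
#'
#' @param genes_I,genes_D data frames with columns `gene_id`, `chrom`,
#'   `start`, `end`, `family_id` (and `seq` for the kmer scorer).
#' @param scorer "family" (default) or "kmer".
#' @param score_threshold minimum score for a pair to be kept (family match
#'   scores 1; kmer scores are shared 8-mer fractions in `[0, 1]`).
#' @param k k-mer size for the sequence scorer.
#' @return data frame of pairs: query/target ids, chromosomes, gene-order
#'   indices (`idx_I`, `idx_D`, per chromosome), coordinates and score.
#' @export
find_homolog_pairs <- function(genes_I, genes_D, scorer = c("family", "kmer"),
                               score_threshold = 0.5, k = 8) {
  scorer <- match.arg(scorer)
  if (!nrow(genes_I) || !nrow(genes_D)) return(.empty_pairs())
  genes_I <- genes_I[order(genes_I$chrom, genes_I$start), , drop = FALSE]
  genes_D <- genes_D[order(genes_D$chrom, genes_D$start), , drop = FALSE]
  genes_I$idx <- stats::ave(genes_I$start, genes_I$chrom,
                            FUN = seq_along)
  genes_D$idx <- stats::ave(genes_D$start, genes_D$chrom,
                            FUN = seq_along)

  if (scorer == "family") {
    hits <- merge(genes_I[, c("gene_id", "family_id")],
                  genes_D[, c("gene_id", "family_id")],
                  by = "family_id", suffixes = c("_I", "_D"))
    hits$score <- 1
  } else {
    kmers <- function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      unique(substring(s, 1:(n - k + 1), k:n))
    }
    ki <- lapply(genes_I$seq, kmers)
    kd <- lapply(genes_D$seq, kmers)
    hits <- do.call(rbind, lapply(seq_len(nrow(genes_I)), function(i) {
      sc <- vapply(kd, function(x)
        length(intersect(ki[[i]], x)) / max(1, length(ki[[i]])), numeric(1))
      ok <- which(sc >= score_threshold)
      if (!length(ok)) return(NULL)
      data.frame(family_id = genes_I$family_id[i],
                 gene_id_I = genes_I$gene_id[i],
                 gene_id_D = genes_D$gene_id[ok], score = sc[ok],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(hits)) return(.empty_pairs())
  }
  hits <- hits[hits$score >= score_threshold, , drop = FALSE]
  if (!nrow(hits)) return(.empty_pairs())
  # top hit per query: highest score, then lexicographically smallest target
  hits <- hits[order(hits$gene_id_I, -hits$score, hits$gene_id_D), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits$gene_id_I), , drop = FALSE]

  ii <- match(hits$gene_id_I, genes_I$gene_id)
  id <- match(hits$gene_id_D, genes_D$gene_id)
  out <- data.frame(gene_id_I = hits$gene_id_I, gene_id_D = hits$gene_id_D,
                    chrom_I = genes_I$chrom[ii], chrom_D = genes_D$chrom[id],
                    idx_I = genes_I$idx[ii], idx_D = genes_D$idx[id],
                    start_I = genes_I$start[ii], end_I = genes_I$end[ii],
                    start_D = genes_D$start[id], end_D = genes_D$end[id],
                    score = hits$score, stringsAsFactors = FALSE)
  out <- out[order(out$chrom_I, out$idx_I), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_pairs <- function() {
  data.frame(gene_id_I = character(0), gene_id_D = character(0),
             chrom_I = character(0), chrom_D = character(0),
             idx_I = numeric(0), idx_D = numeric(0),
             start_I = numeric(0), end_I = numeric(0),
             start_D = numeric(0), end_D = numeric(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

# best collinear chain over pairs (qi strictly increasing; ti strictly
# monotone with the requested sign), unit score per pair, hard index gap cap
# in both genomes. Returns indices into `pairs` (rows assumed sorted by
# (qi, ti)). Ties broken toward the lexicographically smallest index
# sequence, so the result is unique.
.best_chain <- function(qi, ti, sign, max_gap) {
  n <- length(qi)
  if (!n) return(integer(0))
  tt <- if (sign > 0) ti else -ti
  len <- rep(1L, n)
  chain <- lapply(seq_len(n), function(i) i)
  for (i in seq_len(n)) {
    pred <- which(qi < qi[i] & tt < tt[i] &
                    (qi[i] - qi) <= max_gap & (tt[i] - tt) <= max_gap)
    for (j in pred) {
      cand_len <- len[j] + 1L
      cand <- c(chain[[j]], i)
      if (cand_len > len[i] ||
          (cand_len == len[i] && .lex_less(cand, chain[[i]]))) {
        len[i] <- cand_len
        chain[[i]] <- cand
      }
    }
  }
  maxlen <- max(len)
  cand <- which(len == maxlen)
  best <- chain[[cand[1]]]
  for (i in cand[-1]) if (.lex_less(chain[[i]], best)) best <- chain[[i]]
  best
}

.lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Chain homolog pairs into collinear synteny blocks
#'
#' Greedy extraction of maximal collinear chains by dynamic programming:
#' repeatedly find the longest chain of pairs monotone in both genomes
#' (forward or reverse) with gene-index gaps at most `max_gap` on both
#' sides, remove its pairs, and repeat while chains of at least `min_pairs`
#' remain. Ties are broken deterministically (forward orientation first,
#' then lexicographically smallest pair-index sequence). Blocks whose
#' coordinate spans overlap an earlier (higher-scoring) block in either
#' genome are dropped, mirroring manual curation of overlapping blocks.
#' Long chains can optionally be segmented into consecutive sub-blocks of at
#' most `max_pairs_per_block` pairs for within-region ratio profiling.
#'
#' @param pairs pair table from [find_homolog_pairs()] (one chromosome pair
#'   at a time, or any table with `idx_I`/`idx_D` plus coordinates).
#' @param max_gap maximum gene-index gap between consecutive chain members,
#'   in both genomes.
#' @param min_pairs minimum pairs per reported block.
#' @param max_pairs_per_block segment chains longer than this into
#'   consecutive sub-blocks (default Inf: no segmentation).
#' @return data frame of blocks: chromosomes, bp spans in both genomes
#'   (from first to last member gene extent), `orient` (+1/-1), `n_pairs`,
#'   `ratio` = span_I/span_D, and `block_id`.
#' @export
chain_synteny_blocks <- function(pairs, max_gap = 5, min_pairs = 4,
                                 max_pairs_per_block = Inf) {
  if (!nrow(pairs)) return(.empty_blocks())
  out <- list()
  for (cp in split(pairs, list(pairs$chrom_I, pairs$chrom_D), drop = TRUE)) {
    cp <- cp[order(cp$idx_I, cp$idx_D), , drop = FALSE]
    avail <- rep(TRUE, nrow(cp))
    chains <- list()
    repeat {
      idx <- which(avail)
      if (length(idx) < min_pairs) break
      qi <- cp$idx_I[idx]; ti <- cp$idx_D[idx]
      fwd <- .best_chain(qi, ti, +1, max_gap)
      rev_ <- .best_chain(qi, ti, -1, max_gap)
      use_fwd <- length(fwd) >= length(rev_)   # forward wins ties
      ch <- if (use_fwd) fwd else rev_
      if (length(ch) < min_pairs) break
      chains[[length(chains) + 1]] <-
        list(rows = idx[ch], orient = if (use_fwd) 1L else -1L)
      avail[idx[ch]] <- FALSE
    }
    if (!length(chains)) next
    # drop blocks whose spans overlap an earlier (higher-scoring) block
    spans <- lapply(chains, function(ch) {
      r <- cp[ch$rows, ]
      list(si = min(r$start_I), ei = max(r$end_I),
           sd = min(r$start_D), ed = max(r$end_D))
    })
    kept <- logical(length(chains))
    for (i in seq_along(chains)) {
      ok <- TRUE
      for (j in which(kept)) {
        if (spans[[i]]$si < spans[[j]]$ei && spans[[i]]$ei > spans[[j]]$si) ok <- FALSE
        if (spans[[i]]$sd < spans[[j]]$ed && spans[[i]]$ed > spans[[j]]$sd) ok <- FALSE
      }
      kept[i] <- ok
    }
    chains <- chains[kept]
    for (ch in chains) {
      rows <- ch$rows
      pieces <- if (is.finite(max_pairs_per_block))
        split(rows, ceiling(seq_along(rows) / max_pairs_per_block))
      else list(rows)
      for (pc in pieces) {
        if (length(pc) < 2) next
        r <- cp[pc, ]
        out[[length(out) + 1]] <- data.frame(
          chrom_I = r$chrom_I[1], chrom_D = r$chrom_D[1],
          start_I = min(r$start_I), end_I = max(r$end_I),
          start_D = min(r$start_D), end_D = max(r$end_D),
          orient = ch$orient, n_pairs = length(pc),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.empty_blocks())
  bl <- do.call(rbind, out)
  bl <- bl[order(bl$chrom_I, bl$start_I), , drop = FALSE]
  bl$ratio <- (bl$end_I - bl$start_I) / (bl$end_D - bl$start_D)
  bl$block_id <- seq_len(nrow(bl))
  rownames(bl) <- NULL
  bl
}

.empty_blocks <- function() {
  data.frame(chrom_I = character(0), chrom_D = character(0),
             start_I = numeric(0), end_I = numeric(0),
             start_D = numeric(0), end_D = numeric(0),
             orient = integer(0), n_pairs = integer(0), ratio = numeric(0),
             block_id = integer(0), stringsAsFactors = FALSE)
}

#' Detect inverted regions from synteny blocks
#'
#' Scans the blocks of one chromosome pair in genome-I order for maximal
#' runs of reverse-orientation blocks, allowing up to `skip_tolerance`
#' interleaved forward blocks inside a run, and reports each run's merged
#' span in both genomes.
#'
#' @param blocks block table from [chain_synteny_blocks()].
#' @param skip_tolerance forward blocks tolerated inside a reverse run.
#' @return data frame: chromosomes, merged `start_I`/`end_I`,
#'   `start_D`/`end_D`, `n_blocks`.
#' @export
detect_inversions <- function(blocks, skip_tolerance = 0) {
  if (!nrow(blocks)) return(.empty_inversions())
  out <- list()
  for (cp in split(blocks, list(blocks$chrom_I, blocks$chrom_D),
                   drop = TRUE)) {
    cp <- cp[order(cp$start_I), , drop = FALSE]
    i <- 1
    while (i <= nrow(cp)) {
      if (cp$orient[i] == -1L) {
        j <- i
        skips <- 0
        last_rev <- i
        while (j < nrow(cp)) {
          if (cp$orient[j + 1] == -1L) {
            j <- j + 1; last_rev <- j
          } else if (skips < skip_tolerance) {
            j <- j + 1; skips <- skips + 1
          } else break
        }
        run <- cp[i:last_rev, , drop = FALSE]
        run <- run[run$orient == -1L, , drop = FALSE]
        out[[length(out) + 1]] <- data.frame(
          chrom_I = run$chrom_I[1], chrom_D = run$chrom_D[1],
          start_I = min(run$start_I), end_I = max(run$end_I),
          start_D = min(run$start_D), end_D = max(run$end_D),
          n_blocks = nrow(run), stringsAsFactors = FALSE)
        i <- last_rev + 1
      } else i <- i + 1
    }
  }
  if (!length(out)) return(.empty_inversions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_inversions <- function() {
  data.frame(chrom_I = character(0), chrom_D = character(0),
             start_I = numeric(0), end_I = numeric(0),
             start_D = numeric(0), end_D = numeric(0),
             n_blocks = integer(0), stringsAsFactors = FALSE)
}

#' Size ratio of two corresponding regions
#'
#' @param len_I,len_D region lengths in bp (genome I over genome D).
#' @return `len_I / len_D`, unrounded (round only at presentation).
#' @examples
#' round(size_ratio(137414913, 107035537), 2)  # 1.28
#' @export
size_ratio <- function(len_I, len_D) {
  if (any(len_D == 0)) stop("division by zero region length")
  len_I / len_D
}

#' Aggregate size-ratio summary for inverted vs non-inverted regions
#'
#' Labels each block by overlap of its genome-D span with the detected
#' inverted regions (majority of the block span), excludes the requested
#' chromosomes, and reports the aggregate ratio `sum(span_I)/sum(span_D)`
#' separately for inverted and non-inverted blocks, plus the per-block
#' ratio sequence ordered along genome D for gradient inspection.
#'
#' @param blocks block table from [chain_synteny_blocks()].
#' @param inverted_regions region table from [detect_inversions()].
#' @param excluded_chromosomes chromosome names (genome I side) to exclude.
#' @return list with `inverted_ratio`, `non_inverted_ratio` (NA when a
#'   category is empty), `excluded_chromosomes` and `per_block` (blocks with
#'   an `inverted` flag, ordered along genome D).
#' @export
region_ratio_summary <- function(blocks, inverted_regions,
                                 excluded_chromosomes = character(0)) {
  bl <- blocks[!(blocks$chrom_I %in% excluded_chromosomes), , drop = FALSE]
  inv <- logical(nrow(bl))
  if (nrow(inverted_regions)) {
    for (r in seq_len(nrow(inverted_regions))) {
      reg <- inverted_regions[r, ]
      ovl <- pmin(bl$end_D, reg$end_D) - pmax(bl$start_D, reg$start_D)
      inv <- inv | (bl$chrom_D == reg$chrom_D &
                      ovl > (bl$end_D - bl$start_D) / 2)
    }
  }
  agg <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(bl$end_I[sel] - bl$start_I[sel]) /
      sum(bl$end_D[sel] - bl$start_D[sel])
  }
  per_block <- bl[order(bl$chrom_D, bl$start_D), , drop = FALSE]
  per_block$inverted <- inv[order(bl$chrom_D, bl$start_D)]
  list(inverted_ratio = agg(inv), non_inverted_ratio = agg(!inv),
       excluded_chromosomes = excluded_chromosomes, per_block = per_block)
}
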