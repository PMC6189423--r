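# Sequence synthesis for simulated genomes. Gene sequences are keyed by the
# ancestral gene id (orthologs share sequence across lineages); TE copies
# are drawn from per-family templates with configurable per-copy divergence
# (so "identical repeat" vs "same family" classification and solo-LTR
# sequence search are exercisable on the emitted FASTA); spacers are random.

.BASES <- c("A", "C", "G", "T")

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# deterministic gene sequence from the ancestral gene id
.gene_seq <- function(gene_id, len) {
  .with_seed(.name_seed(gene_id) + 7L, {
    body <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
    if (len >= 3) paste0("ATG", substr(body, 4, len)) else body
  })
}

# mutate a sequence string with the given substitution rate
.mutate_seq <- function(s, rate) {
  n <- nchar(s)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- sample(.BASES, k, replace = TRUE)
  paste(ch, collapse = "")
}

#' Synthesize the DNA sequence of a simulated chromosome
#'
#' Genes get coding-like sequence shared between orthologs (keyed by
#' ancestral gene id); TE features get their family template (prefix for
#' fragments; terminal-repeat prefix for solo LTRs) with `divergence`
#' per-copy substitutions; spacers are random. With `divergence = 0` all
#' copies of a family are exact template substrings, so full-length 100%
#' identity terminus matching recovers every solo LTR.
#'
#' @param st a [chrom_state()].
#' @param seed integer seed for per-copy mutations and spacer sequence.
#' @param divergence per-copy TE substitution rate (default 0.02).
#' @return a `Biostrings::DNAString` of length `st$length`.
#' @export
synthesize_chrom_seq <- function(st, seed = 1L, divergence = 0.02) {
  f <- st$features
  pieces <- .with_seed(seed, {
    vapply(seq_len(nrow(f)), function(i) {
      len <- f$end[i] - f$start[i]
      if (f$kind[i] == "gene") {
        .gene_seq(f$gene_id[i], len)
      } else if (f$kind[i] == "te") {
        tmpl <- .te_template_seq(f$family_id[i])
        s <- if (isTRUE(f$is_solo[i])) {
          info <- te_family_info(f$family_id[i])
          substr(tmpl, 1, min(len, info$ltr_len))
        } else substr(tmpl, 1, len)
        if (nchar(s) < len)  # copy longer than template (shouldn't happen)
          s <- paste0(s, paste(sample(.BASES, len - nchar(s), replace = TRUE),
                               collapse = ""))
        if (f$strand[i] == "-") s <- .revcomp(s)
        if (divergence > 0) .mutate_seq(s, divergence) else s
      } else {
        paste(sample(.BASES, len, replace = TRUE), collapse = "")
      }
    }, character(1))
  })
  Biostrings::DNAString(paste(pieces, collapse = ""))
}
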