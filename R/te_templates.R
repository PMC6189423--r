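# TE family registry and per-family sequence templates.
#
# Every TE copy in a simulated genome descends from a family template, so
# homology search and repeat matching on the emitted sequences are
# meaningful: copies of the same family share a template string, LTR
# retrotransposon templates have the structure LTR | internal | LTR with the
# two terminal repeats identical, and per-copy divergence (substitutions) is
# applied only at serialization time.

.TE_CLASSES <- c("DNA", "LTR", "LINE", "SINE", "low_complexity",
                 "simple_repeat", "other")

# sampling weights of classes for newly placed/inserted TEs
.TE_CLASS_WEIGHTS <- c(DNA = 0.25, LTR = 0.45, LINE = 0.13, SINE = 0.05,
                       low_complexity = 0.04, simple_repeat = 0.07,
                       other = 0.01)

.TE_FAMILY_POOL <- list(
  DNA = paste0("DNAf", 1:5),
  LTR = paste0("LTRf", 1:6),
  LINE = paste0("LINEf", 1:4),
  SINE = paste0("SINEf", 1:3),
  low_complexity = paste0("LCf", 1:2),
  simple_repeat = paste0("SRf", 1:2),
  other = "OTHf1"
)

# deterministic integer from a family name (template identity must not
# depend on simulation order)
.name_seed <- function(s) {
  v <- utf8ToInt(s)
  as.integer(sum(v * seq_along(v) * 131) %% 2147483647L)
}

#' TE family template geometry
#'
#' Deterministic per-family template lengths; for LTR families the terminal
#' repeat length is included (termini are identical direct repeats).
#' @param family family label from the built-in pool.
#' @return list with `te_class`, `length` (full intact copy length, bp) and
#'   `ltr_len` (terminal repeat length, NA for non-LTR classes).
#' @export
te_family_info <- function(family) {
  cls <- names(Filter(function(p) family %in% p, .TE_FAMILY_POOL))
  if (!length(cls)) stop("unknown TE family: ", family)
  .with_seed(.name_seed(family), {
    if (cls == "LTR") {
      ltr <- round(stats::runif(1, 500, 1200))
      internal <- round(stats::runif(1, 2500, 5000))
      list(te_class = cls, length = 2 * ltr + internal, ltr_len = ltr)
    } else {
      len <- switch(cls,
                    DNA = round(stats::runif(1, 800, 2500)),
                    LINE = round(stats::runif(1, 2500, 4500)),
                    SINE = round(stats::runif(1, 200, 400)),
                    low_complexity = round(stats::runif(1, 300, 600)),
                    simple_repeat = round(stats::runif(1, 300, 600)),
                    other = round(stats::runif(1, 500, 1500)))
      list(te_class = cls, length = len, ltr_len = NA_real_)
    }
  })
}

# template DNA string for one family (character scalar)
.te_template_seq <- function(family) {
  info <- te_family_info(family)
  .with_seed(.name_seed(family) + 17L, {
    if (info$te_class == "LTR") {
      ltr <- paste(sample(c("A", "C", "G", "T"), info$ltr_len, replace = TRUE),
                   collapse = "")
      internal <- paste(sample(c("A", "C", "G", "T"),
                               info$length - 2 * info$ltr_len, replace = TRUE),
                        collapse = "")
      paste0(ltr, internal, ltr)
    } else if (info$te_class %in% c("simple_repeat", "low_complexity")) {
      unit <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                    collapse = "")
      substr(strrep(unit, ceiling(info$length / 6)), 1, info$length)
    } else {
      paste(sample(c("A", "C", "G", "T"), info$length, replace = TRUE),
            collapse = "")
    }
  })
}

# draw one TE family (class sampled by weight); returns feature fields
.draw_te_family <- function() {
  cls <- sample(names(.TE_CLASS_WEIGHTS), 1, prob = .TE_CLASS_WEIGHTS)
  fam <- sample(.TE_FAMILY_POOL[[cls]], 1)
  info <- te_family_info(fam)
  list(family_id = fam, te_class = cls, length = info$length,
       ltr_len = info$ltr_len)
}
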