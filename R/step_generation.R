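# Per-generation dynamics: thinned-Poisson event sampling and a single
# vectorized rebuild of the feature tiling. All events of a step are drawn
# against the state at the start of the step and applied simultaneously
# (exact in the small-rate limit); colliding draws are dropped
# deterministically and never logged, so the event-log ledger identity
# (final length = initial length + sum of length_change) holds exactly.

# --- event application ------------------------------------------------------

# Apply simultaneous deletions / solo-LTR conversions / insertions to a
# feature tiling. `dels`: data.frame(start,end) sorted non-overlapping, in
# current coordinates (conversion spans included). `conv_rows`: feature row
# indices converted to solo LTRs. `ins`: data.frame(pos, family_id, te_class,
# length, ltr_len, strand), pos in current coordinates outside deletions.
.apply_events_to_features <- function(f, dels = NULL, conv_rows = integer(0),
                                      ins = NULL) {
  L <- f$end[nrow(f)]
  if (!is.null(dels) && nrow(dels)) {
    breaks <- sort(unique(c(f$start, L, dels$start, dels$end)))
    as_ <- breaks[-length(breaks)]
    ae_ <- breaks[-1]
    fidx <- findInterval(as_, f$start)
    j <- findInterval(as_, dels$start)
    deleted <- j >= 1 & as_ < dels$end[pmax(j, 1)]
    as_ <- as_[!deleted]; ae_ <- ae_[!deleted]; fidx <- fidx[!deleted]
    cumdel <- c(0, cumsum(dels$end - dels$start))
    shift <- cumdel[findInterval(as_, dels$end) + 1]
    ns <- as_ - shift
    ne <- ae_ - shift
    runs <- rle(fidx)
    ridx <- cumsum(runs$lengths)            # last atom of each run
    rstart <- ridx - runs$lengths + 1       # first atom of each run
    nf <- f[runs$values, , drop = FALSE]
    nf$start <- ns[rstart]
    nf$end <- ne[ridx]
    # features that lost bp are damaged: intact-LTR annotation is dropped
    shrunk <- (nf$end - nf$start) <
      (f$end[runs$values] - f$start[runs$values])
    nf$ltr_len[shrunk] <- NA_real_
    if (length(conv_rows)) {
      hit <- match(conv_rows, runs$values)
      hit <- hit[!is.na(hit)]
      nf$is_solo[hit] <- TRUE
      nf$ltr_len[hit] <- NA_real_
    }
    rownames(nf) <- NULL
    f <- nf
  }
  if (!is.null(ins) && nrow(ins)) {
    # map old positions to post-deletion coordinates
    if (!is.null(dels) && nrow(dels)) {
      cumdel <- c(0, cumsum(dels$end - dels$start))
      ins$pos <- ins$pos - cumdel[findInterval(ins$pos, dels$end) + 1]
    }
    ins <- ins[order(ins$pos, decreasing = TRUE), , drop = FALSE]
    for (k in seq_len(nrow(ins))) {
      p <- ins$pos[k]
      ilen <- ins$length[k]
      i <- findInterval(p, f$start)
      newrow <- .feature_row("te", p, p + ilen, strand = ins$strand[k],
                             family_id = ins$family_id[k],
                             te_class = ins$te_class[k],
                             ltr_len = ins$ltr_len[k])
      host <- f[i, , drop = FALSE]
      if (p > host$start) {
        left <- host; left$end <- p
        right <- host; right$start <- p
        # splitting an intact LTR element damages it
        left$ltr_len <- NA_real_; right$ltr_len <- NA_real_
        pre <- if (i > 1) f[seq_len(i - 1), , drop = FALSE] else f[0, ]
        post <- if (i < nrow(f)) f[(i + 1):nrow(f), , drop = FALSE] else f[0, ]
        f <- rbind(pre, left, newrow, right, post)
        shift_from <- i + 2L  # the right-hand host piece shifts too
      } else {
        pre <- if (i > 1) f[seq_len(i - 1), , drop = FALSE] else f[0, ]
        post <- f[i:nrow(f), , drop = FALSE]
        f <- rbind(pre, newrow, post)
        shift_from <- i + 1L
      }
      if (shift_from <= nrow(f)) {
        sel <- shift_from:nrow(f)
        f$start[sel] <- f$start[sel] + ilen
        f$end[sel] <- f$end[sel] + ilen
      }
      rownames(f) <- NULL
    }
  }
  f
}

# keep spans (sorted by priority order) that do not overlap an earlier kept
# span; returns logical keep vector
.keep_nonoverlapping <- function(start, end) {
  n <- length(start)
  keep <- logical(n)
  if (!n) return(keep)
  ord <- seq_len(n)                 # priority = draw order
  kept_s <- numeric(0); kept_e <- numeric(0)
  for (i in ord) {
    if (!length(kept_s) || all(end[i] <= kept_s | start[i] >= kept_e)) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, start[i]); kept_e <- c(kept_e, end[i])
    }
  }
  keep
}

# TRUE for spans overlapping any gene feature
.overlaps_gene <- function(f, start, end) {
  g <- f[f$kind == "gene", , drop = FALSE]
  if (!nrow(g) || !length(start)) return(logical(length(start)))
  vapply(seq_along(start), function(i)
    any(start[i] < g$end & end[i] > g$start), logical(1))
}

#' Advance a chromosome by one (or more) generations
#'
#' Draws and applies one step of the forward model:
#' \itemize{
#'   \item illegitimate deletions with per-bp intensity
#'     `lambda_illegit * c(p)`, lengths from the truncated power law;
#'   \item unequal intrastrand events per intact LTR element with intensity
#'     `lambda_unequal * c(midpoint)`, each converting the element into a
#'     solo LTR (the 5' terminus is retained, the internal region and 3'
#'     terminus are removed);
#'   \item TE insertions with per-bp intensity
#'     `lambda_insert * (1 - c(p)/max(c))`, landing only in spacer/TE
#'     intervals.
#' }
#' Under gene protection a deletion overlapping a gene is re-drawn up to 10
#' times and then skipped, so gene bp is invariant. The net length change of
#' the step equals the sum of `length_change` over the events appended to
#' the log.
#'
#' @param chrom a [chrom_state()].
#' @param config a [sim_config()].
#' @param gens number of generations collapsed into this step (see
#'   `generations_per_step` in [sim_config()]).
#' @return the advanced `chrom_state`.
#' @export
step_generation <- function(chrom, config, gens = 1L) {
  f <- chrom$features
  L <- chrom$length
  map <- chrom$recomb
  cv_at <- function(p) recombination_rate_at(map, p, length = L)
  gene_s <- f$start[f$kind == "gene"]
  gene_e <- f$end[f$kind == "gene"]
  f_start <- f$start
  f_kind <- f$kind

  # --- illegitimate deletions (thinned Poisson, cmax = 1) ---
  del_s <- numeric(0); del_e <- numeric(0)
  if (config$lambda_illegit > 0) {
    m <- stats::rpois(1, config$lambda_illegit * L * gens)
    if (m > 0) {
      cdf <- cumsum(.del_pmf(config))
      for (k in seq_len(m)) {
        for (attempt in 1:10) {
          pos <- floor(stats::runif(1, 0, L))
          if (stats::runif(1) >= cv_at(pos)) break  # thinning rejection
          len <- findInterval(stats::runif(1), cdf) + 1
          s <- pos; e <- min(pos + len, L)
          if (e <= s) break
          if (config$gene_protection && length(gene_s) &&
              any(s < gene_e & e > gene_s)) next
          del_s <- c(del_s, s); del_e <- c(del_e, e)
          break
        }
      }
    }
  }

  # --- unequal intrastrand recombination on intact LTR elements ---
  conv_rows <- integer(0); conv_s <- numeric(0); conv_e <- numeric(0)
  solo_s <- numeric(0); solo_e <- numeric(0)
  if (config$lambda_unequal > 0) {
    intact <- which(f$kind == "te" & !is.na(f$ltr_len))
    if (length(intact)) {
      midp <- (f$start[intact] + f$end[intact]) / 2
      pr <- pmin(1, config$lambda_unequal * cv_at(midp) * gens)
      hit <- intact[stats::runif(length(intact)) < pr]
      if (length(hit)) {
        conv_rows <- hit
        conv_s <- f$start[hit] + f$ltr_len[hit]
        conv_e <- f$end[hit]
        solo_s <- f$start[hit]
        solo_e <- f$start[hit] + f$ltr_len[hit]
      }
    }
  }

  # resolve collisions: draw order is the priority order
  all_s <- c(del_s, conv_s); all_e <- c(del_e, conv_e)
  keep <- .keep_nonoverlapping(all_s, all_e)
  n_ill <- length(del_s)
  ill_keep <- keep[seq_len(n_ill)]
  cv_keep <- if (n_ill > 0) keep[-seq_len(n_ill)] else keep
  dels <- data.frame(start = all_s[keep], end = all_e[keep])
  dels <- dels[order(dels$start), , drop = FALSE]
  conv_rows <- conv_rows[cv_keep]
  solo_s <- solo_s[cv_keep]; solo_e <- solo_e[cv_keep]

  # --- insertions (weight 1 - c/cmax; spacer/TE hosts only) ---
  ins <- NULL
  if (config$lambda_insert > 0) {
    m <- stats::rpois(1, config$lambda_insert * L * gens)
    if (m > 0) {
      rows <- list()
      for (k in seq_len(m)) {
        for (attempt in 1:10) {
          pos <- floor(stats::runif(1, 0, L))
          if (stats::runif(1) >= (1 - cv_at(pos))) break
          host <- f_kind[findInterval(pos, f_start)]
          if (host == "gene") next
          if (nrow(dels) && any(pos >= dels$start & pos < dels$end)) next
          te <- .draw_te_family()
          rows[[length(rows) + 1]] <-
            data.frame(pos = pos, family_id = te$family_id,
                       te_class = te$te_class, length = te$length,
                       ltr_len = if (is.na(te$ltr_len)) NA_real_ else te$ltr_len,
                       strand = sample(c("+", "-"), 1),
                       stringsAsFactors = FALSE)
          break
        }
      }
      if (length(rows)) ins <- do.call(rbind, rows)
    }
  }

  newf <- .apply_events_to_features(f, dels, conv_rows, ins)
  gen_new <- chrom$generation + as.integer(gens)

  # --- event log ---
  logs <- list()
  if (any(ill_keep)) {
    s <- del_s[ill_keep]; e <- del_e[ill_keep]
    logs$ill <- data.frame(generation = gen_new, kind = "illegitimate_deletion",
                           start = s, end = e, length_change = -(e - s),
                           solo_start = NA_real_, solo_end = NA_real_,
                           ins_family = NA_character_, ins_te_class = NA_character_,
                           ins_length = NA_real_, ins_ltr_len = NA_real_,
                           ins_strand = NA_character_,
                           aux = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(conv_rows)) {
    cs <- f$start[conv_rows] + f$ltr_len[conv_rows]
    ce <- f$end[conv_rows]
    logs$uneq <- data.frame(generation = gen_new,
                            kind = "unequal_intrastrand_deletion",
                            start = cs, end = ce, length_change = -(ce - cs),
                            solo_start = solo_s, solo_end = solo_e,
                            ins_family = NA_character_, ins_te_class = NA_character_,
                            ins_length = NA_real_, ins_ltr_len = NA_real_,
                            ins_strand = NA_character_,
                            aux = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(ins)) {
    logs$ins <- data.frame(generation = gen_new, kind = "insertion",
                           start = ins$pos, end = ins$pos,
                           length_change = ins$length,
                           solo_start = NA_real_, solo_end = NA_real_,
                           ins_family = ins$family_id,
                           ins_te_class = ins$te_class,
                           ins_length = ins$length, ins_ltr_len = ins$ltr_len,
                           ins_strand = ins$strand,
                           aux = NA_real_, stringsAsFactors = FALSE)
  }
  chrom$features <- newf
  chrom$length <- newf$end[nrow(newf)]
  chrom$generation <- gen_new
  if (length(logs)) chrom$events <- rbind(chrom$events, do.call(rbind, logs))
  chrom
}

#' Replay a logged event history on an ancestral chromosome
#'
#' Applies the events of an event log generation by generation using the
#' same composite machinery as [step_generation()]; replaying a simulation's
#' truth log on its ancestor reproduces the final chromosome exactly.
#'
#' @param ancestor the ancestral [chrom_state()].
#' @param events an event log (from a simulated chromosome).
#' @return the reconstructed `chrom_state`.
#' @export
replay_events <- function(ancestor, events) {
  chrom <- ancestor
  if (!nrow(events)) return(chrom)
  for (g in sort(unique(events$generation))) {
    ev <- events[events$generation == g, , drop = FALSE]
    for (i in which(ev$kind == "inversion"))
      chrom <- apply_inversion(chrom, ev$start[i], ev$end[i], snap = FALSE)
    for (i in which(ev$kind == "relocation"))
      chrom <- apply_relocation(chrom, ev$start[i], ev$end[i],
                                insert_at = ev$aux[i], snap = FALSE)
    dl <- ev[ev$kind %in% c("illegitimate_deletion",
                            "unequal_intrastrand_deletion"), , drop = FALSE]
    insev <- ev[ev$kind == "insertion", , drop = FALSE]
    if (nrow(dl) || nrow(insev)) {
      f <- chrom$features
      conv <- dl[dl$kind == "unequal_intrastrand_deletion", , drop = FALSE]
      conv_rows <- if (nrow(conv))
        vapply(conv$solo_start, function(s) which(f$start == s)[1], integer(1))
      else integer(0)
      dels <- dl[order(dl$start), c("start", "end"), drop = FALSE]
      ins <- if (nrow(insev))
        data.frame(pos = insev$start, family_id = insev$ins_family,
                   te_class = insev$ins_te_class, length = insev$ins_length,
                   ltr_len = insev$ins_ltr_len, strand = insev$ins_strand,
                   stringsAsFactors = FALSE)
      else NULL
      chrom$features <- .apply_events_to_features(f, dels, conv_rows, ins)
      chrom$length <- chrom$features$end[nrow(chrom$features)]
    }
    chrom$generation <- as.integer(g)
  }
  chrom
}
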