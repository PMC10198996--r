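#' Filter footprint reads for the occupancy analysis
#'
#' Keeps uniquely mapped reads of length `min_len` to `max_len` that do not
#' overlap the non-coding-RNA blacklist.
#'
#' @param reads data.frame of footprint reads ([read_sam()]).
#' @param min_len,max_len inclusive read-length bounds (defaults 26 and 32).
#' @export
filter_reads <- function(reads, min_len = 26L, max_len = 32L) {
  keep <- reads$unique & !reads$blacklisted &
    reads$len >= min_len & reads$len <= max_len
  reads[keep, , drop = FALSE]
}

#' P-site genomic position of a footprint read
#'
#' The P-site is the 12th nucleotide from the 5' end for reads of 26-29 nt
#' and the 13th for reads of 30-32 nt. On the minus strand the 5' end is the
#' rightmost aligned base, so the offset runs leftward.
#'
#' @param pos leftmost aligned position (1-based), vectorised.
#' @param len read length in nt (26-32).
#' @param strand `"+"` or `"-"`.
#' @return integer vector of genomic P-site positions.
#' @export
psite_position <- function(pos, len, strand) {
  if (any(len < 26L | len > 32L)) stop("read length outside 26-32")
  off <- ifelse(len <= 29L, 11L, 12L)   # 0-based offset from the 5' end
  ifelse(strand == "+", pos + off, (pos + len - 1L) - off)
}

#' Build a per-base P-site RPM track from filtered reads
#'
#' Per-base P-site counts are scaled to reads per million so every track sums
#' to 1e6 across the genome.
#'
#' @param reads filtered footprint reads ([filter_reads()]).
#' @param sample_id track label (defaults to the reads' sample).
#' @return a `psite_track`: list with `sample_id`, `rpm` (contig -> named
#'   numeric vector keyed by position), `total_retained_reads`, `scale`.
#' @export
build_rpm_track <- function(reads, sample_id = NULL) {
  if (nrow(reads) == 0) stop("cannot normalise a track with zero retained reads")
  if (is.null(sample_id)) sample_id <- reads$sample_id[1]
  p <- psite_position(reads$pos, reads$len, reads$strand)
  scale <- 1e6 / nrow(reads)
  rpm <- lapply(split(p, reads$contig), function(pp) {
    tab <- table(pp)
    stats::setNames(as.numeric(tab) * scale, names(tab))
  })
  structure(list(sample_id = sample_id, rpm = rpm,
                 total_retained_reads = nrow(reads), scale = scale),
            class = "psite_track")
}

#' @export
print.psite_track <- function(x, ...) {
  cat(sprintf("<psite_track %s: %d reads over %d contig(s)>\n",
              x$sample_id, x$total_retained_reads, length(x$rpm)))
  invisible(x)
}

#' RPM values of a track at given positions (0 where no P-site landed)
#' @param track a `psite_track`.
#' @param contig contig name.
#' @param pos integer vector of positions; `NA` positions give 0.
#' @export
track_values <- function(track, contig, pos) {
  v <- track$rpm[[contig]]
  out <- numeric(length(pos))
  if (is.null(v)) return(out)
  hit <- v[as.character(pos)]
  out[!is.na(hit)] <- hit[!is.na(hit)]
  out
}

#' Ribosome occupancy of one codon
#'
#' Sums the RPM at the first and second nucleotide of the codon and the
#' nucleotide before the first, to tolerate cleavage error. "Before" and
#' "second" are transcript-directional: on the minus strand the genomic
#' positions mirror. When a transcript is supplied the three positions are
#' walked in transcript space (splice-aware); otherwise they are the
#' genomically adjacent bases.
#'
#' @param track a `psite_track`.
#' @param contig contig name (ignored when `tx` is given).
#' @param codon_first_base genomic position of the codon's first nucleotide,
#'   or a transcript position when `tx` is given.
#' @param strand `"+"` or `"-"` (ignored when `tx` is given).
#' @param tx optional `transcript_model`; `codon_first_base` is then a
#'   transcript coordinate and the window follows the spliced transcript.
#' @return occupancy (RPM) of the codon.
#' @export
codon_occupancy <- function(track, contig, codon_first_base, strand = "+",
                            tx = NULL) {
  if (!is.null(tx)) {
    tpos <- codon_first_base + c(-1L, 0L, 1L)
    tpos <- tpos[tpos >= 1L & tpos <= tx_length(tx)]
    g <- tx_to_genome(tx, tpos)
    return(sum(track_values(track, tx$contig, g)))
  }
  p <- codon_first_base
  sum(track_values(track, contig, c(p - 1L, p, p + 1L)))
}

#' Per-(sample, anchor, offset) codon occupancy records
#'
#' For each track and each anchor codon, computes the occupancy of codons at
#' offsets `-window .. +window` (in codons) around the anchor, walking the
#' spliced transcript. Offsets whose codon extends outside the transcript are
#' dropped (bookkeeping kept by absence).
#'
#' @param tracks list of `psite_track`s.
#' @param anchors data.frame with `anchor_id`, `transcript_id`, `tpos`
#'   (transcript coordinate of the anchor codon's first base).
#' @param transcripts named list of `transcript_model`s.
#' @param window half-width in codons (default 10).
#' @return data.frame `sample_id`, `anchor_id`, `offset`, `rpm`.
#' @export
occupancy_table <- function(tracks, anchors, transcripts, window = 10L) {
  rows <- list()
  for (tr in tracks) {
    for (a in seq_len(nrow(anchors))) {
      tx <- transcripts[[anchors$transcript_id[a]]]
      if (is.null(tx)) stop("unknown transcript ", anchors$transcript_id[a])
      L <- tx_length(tx)
      for (k in -window:window) {
        t0 <- anchors$tpos[a] + 3L * k
        if (t0 < 1L || t0 + 2L > L) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = tr$sample_id, anchor_id = anchors$anchor_id[a],
          offset = k,
          rpm = codon_occupancy(tr, NULL, t0, tx = tx),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(sample_id = character(),
                                       anchor_id = character(),
                                       offset = integer(), rpm = numeric()))
  do.call(rbind, rows)
}

#' Metagene profile around anchor codons
#'
#' Aggregates codon occupancies into a mean-RPM-per-offset profile per group:
#' first the mean over anchors within each sample, then the mean over samples
#' (equal sample weighting).
#'
#' @param tracks list of `psite_track`s.
#' @param anchors anchors data.frame (see [occupancy_table()]).
#' @param transcripts named list of `transcript_model`s.
#' @param groups data.frame `sample_id`, `anchor_id`, `group` assigning each
#'   (sample, anchor) pair to a group; unassigned pairs are dropped.
#' @param window half-width in codons (default 10).
#' @return data.frame `group`, `offset`, `mean_rpm`, `n_anchors`, `n_samples`.
#' @export
metagene <- function(tracks, anchors, transcripts, groups, window = 10L) {
  occ <- occupancy_table(tracks, anchors, transcripts, window)
  occ <- merge(occ, groups, by = c("sample_id", "anchor_id"))
  if (nrow(occ) == 0)
    return(data.frame(group = character(), offset = integer(),
                      mean_rpm = numeric(), n_anchors = integer(),
                      n_samples = integer()))
  per_sample <- stats::aggregate(rpm ~ group + offset + sample_id, occ, mean)
  prof <- stats::aggregate(rpm ~ group + offset, per_sample, mean)
  names(prof)[names(prof) == "rpm"] <- "mean_rpm"
  meta <- stats::aggregate(anchor_id ~ group + offset, occ,
                           function(v) length(unique(v)))
  prof$n_anchors <- meta$anchor_id[match(paste(prof$group, prof$offset),
                                         paste(meta$group, meta$offset))]
  ns <- stats::aggregate(sample_id ~ group + offset, per_sample, length)
  prof$n_samples <- ns$sample_id[match(paste(prof$group, prof$offset),
                                       paste(ns$group, ns$offset))]
  prof[order(prof$group, prof$offset), ]
}

#' Exact two-sided signed-rank p-value (ties via average ranks)
#'
#' Enumerates the null distribution of the signed-rank statistic through its
#' generating function over doubled ranks, so tied absolute differences are
#' handled exactly. Zero differences are dropped beforehand.
#'
#' @param d numeric vector of paired differences (zeros already removed).
#' @return two-sided p-value.
#' @keywords internal
exact_signed_rank_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled ranks are integers
  W2 <- sum(r2[d > 0])
  # polynomial prod (1 + z^r) over doubled ranks; coefficients = counts
  coef <- c(1, rep(0, sum(r2)))
  for (r in r2) {
    shifted <- c(rep(0, r), coef[seq_len(length(coef) - r)])
    coef <- coef + shifted
  }
  total <- 2^length(r2)
  p_le <- sum(coef[seq_len(W2 + 1L)]) / total
  p_ge <- sum(coef[(W2 + 1L):length(coef)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Compare occupancy between two anchor classes
#'
#' Paired mode runs a two-sided Wilcoxon signed-rank test on matched
#' (sample, anchor) occupancy pairs — exact (full enumeration, tie-aware) for
#' up to `exact_n` informative pairs, normal approximation with continuity
#' correction beyond. Unpaired mode runs a Wilcoxon rank-sum test. The fold
#' ratio is `mean(a) / mean(b)`.
#'
#' @param occ_a,occ_b numeric occupancy vectors; in paired mode element `i`
#'   of each belongs to the same (sample, anchor) pair.
#' @param paired logical.
#' @param exact_n largest number of nonzero differences handled exactly in
#'   paired mode (default 25).
#' @return list `statistic`, `p_value`, `fold_ratio`, `n`, `method`.
#' @export
compare_anchor_classes <- function(occ_a, occ_b, paired = TRUE, exact_n = 25L) {
  fold <- mean(occ_a) / mean(occ_b)
  if (paired) {
    stopifnot(length(occ_a) == length(occ_b))
    d <- occ_a - occ_b
    d <- d[d != 0]
    if (length(d) == 0) {
      warning("all paired differences are zero; p = 1")
      return(list(statistic = 0, p_value = 1, fold_ratio = fold,
                  n = 0L, method = "wilcoxon_signed_rank_degenerate"))
    }
    W <- sum(rank(abs(d))[d > 0])
    if (length(d) <= exact_n) {
      p <- exact_signed_rank_p(d)
      meth <- "wilcoxon_signed_rank_exact"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                                correct = TRUE))
      p <- wt$p.value
      meth <- "wilcoxon_signed_rank_normal"
    }
    list(statistic = W, p_value = p, fold_ratio = fold, n = length(d),
         method = meth)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(occ_a, occ_b))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         fold_ratio = fold, n = length(occ_a) + length(occ_b),
         method = "wilcoxon_rank_sum")
  }
}
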