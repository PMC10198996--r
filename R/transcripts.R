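#' Transcript models and coordinate mapping
#'
#' A `transcript_model` is the frame of reference for all 5'UTR logic: an
#' ordered exon structure on a contig, a strand, and the genomic positions of
#' the first and last CDS base (in transcript orientation, stop codon
#' included). Internal coordinates are 1-based closed on the forward genome
#' strand, the Bioconductor convention; transcript coordinates are 1-based
#' along the spliced transcript in 5' to 3' direction.
#'
#' @param transcript_id,gene_id identifiers.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic, 1-based
#'   closed), non-overlapping. May be given in any order; stored sorted by
#'   genomic start.
#' @param cds_start_g genomic position of the first CDS base in transcript
#'   orientation (the `A` of the start codon), or `NA` for non-coding.
#' @param cds_end_g genomic position of the last CDS base in transcript
#'   orientation (last base of the stop codon), or `NA`.
#' @param biotype free-text biotype tag.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds_start_g = NA_integer_, cds_end_g = NA_integer_,
                             biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) stop("exon with end < start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  tx <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id, contig = contig,
    strand = strand, exons = exons,
    cds_start_g = as.integer(cds_start_g), cds_end_g = as.integer(cds_end_g),
    biotype = biotype), class = "transcript_model")
  if (!is.na(tx$cds_start_g) && is.na(genome_to_tx(tx, tx$cds_start_g)))
    stop("CDS start not inside an exon of ", transcript_id)
  if (!is.na(tx$cds_end_g) && is.na(genome_to_tx(tx, tx$cds_end_g)))
    stop("CDS end not inside an exon of ", transcript_id)
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s strand %s, %d exon(s), %d nt>\n",
              x$transcript_id, x$gene_id, x$contig,
              paste0(min(x$exons$start), "-", max(x$exons$end)),
              x$strand, nrow(x$exons), tx_length(x)))
  invisible(x)
}

#' Spliced transcript length in nucleotides
#' @param tx a `transcript_model`.
#' @export
tx_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1L)

# exons in transcript (5'->3') order
tx_exons_5to3 <- function(tx) {
  if (tx$strand == "+") tx$exons else tx$exons[rev(seq_len(nrow(tx$exons))), , drop = FALSE]
}

#' Map transcript coordinates to genomic coordinates
#'
#' @param tx a `transcript_model`.
#' @param tpos integer vector of 1-based transcript positions.
#' @return integer vector of genomic positions; `NA` outside `[1, tx_length]`.
#' @export
tx_to_genome <- function(tx, tpos) {
  ex <- tx_exons_5to3(tx)
  w <- ex$end - ex$start + 1L
  cum <- cumsum(w)
  lo <- c(0L, cum[-length(cum)])
  i <- findInterval(tpos - 1L, cum) + 1L   # exon index per position
  ok <- !is.na(tpos) & tpos >= 1L & tpos <= cum[length(cum)]
  out <- rep(NA_integer_, length(tpos))
  off <- tpos[ok] - lo[i[ok]] - 1L
  out[ok] <- if (tx$strand == "+") ex$start[i[ok]] + off else ex$end[i[ok]] - off
  out
}

#' Map genomic coordinates to transcript coordinates
#'
#' @param tx a `transcript_model`.
#' @param gpos integer vector of genomic positions.
#' @return integer vector of transcript positions; `NA` for non-exonic bases.
#' @export
genome_to_tx <- function(tx, gpos) {
  ex <- tx_exons_5to3(tx)
  w <- ex$end - ex$start + 1L
  lo <- c(0L, cumsum(w)[-length(w)])
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(gpos) & gpos >= ex$start[i] & gpos <= ex$end[i]
    if (!any(hit)) next
    out[hit] <- if (tx$strand == "+") lo[i] + (gpos[hit] - ex$start[i] + 1L)
                else lo[i] + (ex$end[i] - gpos[hit] + 1L)
  }
  out
}

#' Transcript coordinate of the first CDS base (the start codon A)
#' @param tx a `transcript_model`.
#' @export
cds_start_tpos <- function(tx) {
  if (is.na(tx$cds_start_g)) return(NA_integer_)
  genome_to_tx(tx, tx$cds_start_g)
}

#' Transcript coordinate of the last CDS base (last base of the stop codon)
#' @param tx a `transcript_model`.
#' @export
cds_end_tpos <- function(tx) {
  if (is.na(tx$cds_end_g)) return(NA_integer_)
  genome_to_tx(tx, tx$cds_end_g)
}

#' 5'UTR length of a transcript in nucleotides
#' @param tx a `transcript_model`.
#' @export
utr5_length <- function(tx) {
  s <- cds_start_tpos(tx)
  if (is.na(s)) NA_integer_ else s - 1L
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

#' Reverse-complement a DNA string (character in, character out)
#' @param s character scalar over `A,C,G,T,N` (alignment gaps `-` pass
#'   through).
#' @export
revcomp <- function(s) {
  paste(rev(unname(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]])), collapse = "")
}

complement_base <- function(b) unname(COMPLEMENT[b])

#' Spliced transcript sequence in transcript orientation
#'
#' @param tx a `transcript_model`.
#' @param genome a named `DNAStringSet` (or named character vector) containing
#'   `tx$contig`.
#' @return character scalar; 5' to 3' transcript sequence.
#' @export
tx_sequence <- function(tx, genome) {
  cs <- genome_seq(genome, tx$contig)
  parts <- substring(cs, tx$exons$start, tx$exons$end)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

# fetch a contig as a plain character string from DNAStringSet or character
genome_seq <- function(genome, contig) {
  if (is.character(genome)) {
    if (!contig %in% names(genome)) stop("contig not in genome: ", contig)
    return(genome[[contig]])
  }
  if (!contig %in% names(genome)) stop("contig not in genome: ", contig)
  as.character(genome[[contig]])
}

#' Genomic CDS intervals of a set of transcripts (union view)
#'
#' Used for the "located in any known coding sequence" exclusion: the union of
#' per-exon CDS intervals across all annotated transcripts.
#'
#' @param transcripts list of `transcript_model`s.
#' @return data.frame with columns `contig`, `start`, `end` (1-based closed).
#' @export
cds_genomic_intervals <- function(transcripts) {
  rows <- lapply(transcripts, function(tx) {
    if (is.na(tx$cds_start_g)) return(NULL)
    t1 <- cds_start_tpos(tx); t2 <- cds_end_tpos(tx)
    g <- tx_to_genome(tx, seq.int(t1, t2))
    # contiguous genomic runs of the spliced CDS
    g <- sort(g)
    brk <- c(0L, which(diff(g) != 1L), length(g))
    data.frame(contig = tx$contig,
               start = g[brk[-length(brk)] + 1L],
               end = g[brk[-1L]])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(contig = character(), start = integer(), end = integer()) else out
}

# TRUE for each position inside any CDS interval
in_cds_union <- function(cds, contig, pos) {
  if (nrow(cds) == 0) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(cds$contig == contig & cds$start <= pos[i] & cds$end >= pos[i])
  }, logical(1))
}
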