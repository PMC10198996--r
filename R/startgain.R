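STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Classify one SNV against one transcript as a start-gain candidate
#'
#' A call is returned iff all of the following hold: (1) the SNV lies in the
#' transcript's 5'UTR (exonic, upstream of the annotated start in transcript
#' coordinates); (2) substituting the alternate allele into the
#' transcript-oriented sequence creates an `ATG` triplet at a position
#' covering the variant base, the reference triplet not being `ATG`; (3) that
#' triplet is in frame with the downstream coding sequence; (4) no stop codon
#' occurs in that frame strictly between the novel AUG and the annotated
#' start; (5) the SNV's genomic position is not inside any annotated CDS of
#' any transcript. When one substitution creates `ATG` at more than one
#' covering triplet, the 5'-most in-frame one is reported (scanning-model
#' default).
#'
#' @param snv list or one-row data.frame with `contig`, `pos`, `ref`, `alt`
#'   (forward-strand alleles).
#' @param tx a `transcript_model` with annotated CDS and nonempty 5'UTR.
#' @param genome named genome the annotation refers to.
#' @param cds_union data.frame from [cds_genomic_intervals()] over all
#'   annotated transcripts (the "any known coding sequence" exclusion).
#' @return a list describing the call, or `NULL` if any rule fails.
#' @export
classify_snv <- function(snv, tx, genome, cds_union) {
  if (snv$contig != tx$contig) return(NULL)
  if (is.na(tx$cds_start_g)) return(NULL)
  cstart <- cds_start_tpos(tx)
  if (is.na(cstart) || cstart <= 1L) return(NULL)   # no 5'UTR
  tpos <- genome_to_tx(tx, snv$pos)
  if (is.na(tpos) || tpos >= cstart) return(NULL)   # rule 1
  seq <- tx_sequence(tx, genome)
  ref_t <- if (tx$strand == "+") snv$ref else complement_base(snv$ref)
  alt_t <- if (tx$strand == "+") snv$alt else complement_base(snv$alt)
  if (substring(seq, tpos, tpos) != ref_t)
    stop("SNV ref allele inconsistent with genome at ", snv$contig, ":", snv$pos)
  mut <- seq
  substring(mut, tpos, tpos) <- alt_t
  # rule 2 + 3: in-frame ATG created at a triplet covering the variant base
  cand <- (tpos - 2L):tpos
  cand <- cand[cand >= 1L & (cand + 2L) < cstart & (cstart - cand) %% 3L == 0L]
  cand <- sort(cand)
  hit <- NA_integer_
  for (s in cand) {
    if (substring(mut, s, s + 2L) == "ATG" && substring(seq, s, s + 2L) != "ATG") {
      hit <- s; break                                # 5'-most wins
    }
  }
  if (is.na(hit)) {
    # out-of-frame creation is still not a call; distinguish nothing here
    return(NULL)
  }
  # rule 4: no stop strictly between novel AUG and canonical start
  if (hit + 3L <= cstart - 3L) {
    between <- seq.int(hit + 3L, cstart - 3L, by = 3L)
    trips <- substring(mut, between, between + 2L)
    if (any(trips %in% STOP_CODONS)) return(NULL)
  }
  # rule 5: not inside any annotated CDS
  if (in_cds_union(cds_union, snv$contig, snv$pos)) return(NULL)
  novel_nt <- cstart - hit - 3L
  stopifnot((cstart - hit) %% 3L == 0L, novel_nt >= 0L)
  list(transcript_id = tx$transcript_id, contig = snv$contig, pos = snv$pos,
       ref = snv$ref, alt = snv$alt,
       novel_start_tpos = hit, canonical_start_tpos = cstart,
       novel_start_g = tx_to_genome(tx, hit),
       strand = tx$strand,
       novel_cds_len_nt = novel_nt, novel_cds_len_codons = novel_nt %/% 3L)
}

#' Call start-gain SNVs for a whole variant set against an annotation
#'
#' Runs [classify_snv()] for every (SNV, transcript) pair whose contigs match,
#' attaching carrier sets and allele frequencies from the genotypes. Calls are
#' per (SNV, transcript); use `unique(calls$variant_id)` for the SNV-level
#' view.
#'
#' @param snvs an `snv_set` from [read_vcf()].
#' @param transcripts list of `transcript_model`s.
#' @param genome named genome.
#' @param autosomes contig names counted as autosomal (default `1:22`, with
#'   or without a `chr` prefix).
#' @return data.frame of start-gain calls, one row per (SNV, transcript).
#' @export
call_start_gains <- function(snvs, transcripts, genome,
                             autosomes = c(as.character(1:22), paste0("chr", 1:22))) {
  cds_union <- cds_genomic_intervals(transcripts)
  rows <- list()
  for (i in seq_len(nrow(snvs$sites))) {
    snv <- snvs$sites[i, ]
    for (tx in transcripts) {
      cl <- classify_snv(snv, tx, genome, cds_union)
      if (is.null(cl)) next
      carriers <- snv_carriers(snvs, i)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = snv$variant_id, transcript_id = cl$transcript_id,
        contig = cl$contig, pos = cl$pos, ref = cl$ref, alt = cl$alt,
        strand = cl$strand,
        novel_start_tpos = cl$novel_start_tpos,
        canonical_start_tpos = cl$canonical_start_tpos,
        novel_start_g = cl$novel_start_g,
        novel_cds_len_nt = cl$novel_cds_len_nt,
        novel_cds_len_codons = cl$novel_cds_len_codons,
        n_carriers = length(carriers),
        carriers = paste(carriers, collapse = ","),
        allele_frequency = snv_allele_frequency(snvs, i),
        autosomal = snv$contig %in% autosomes,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(variant_id = character(), transcript_id = character()))
  do.call(rbind, rows)
}

#' Population summary of start-gain calls
#'
#' Per-call allele frequencies, the per-individual burden of novel start
#' codons carried (an individual carries a call if it has at least one
#' alternate haplotype), and quantiles of the novel-CDS length, computed on
#' the deduplicated per-SNV view.
#'
#' @param calls data.frame from [call_start_gains()].
#' @param snvs the `snv_set` the calls came from.
#' @return list with `per_call` (variant, AF), `per_individual`
#'   (sample, n_carried), and `novel_cds_len_quantiles`.
#' @export
population_summary <- function(calls, snvs) {
  if (nrow(calls) == 0)
    return(list(per_call = data.frame(), per_individual = data.frame(
      sample = snvs$samples, n_carried = 0L),
      novel_cds_len_quantiles = stats::quantile(numeric())))
  snv_view <- calls[!duplicated(calls$variant_id), , drop = FALSE]
  per_call <- data.frame(variant_id = snv_view$variant_id,
                         allele_frequency = snv_view$allele_frequency)
  counts <- stats::setNames(integer(length(snvs$samples)), snvs$samples)
  for (vid in snv_view$variant_id) {
    i <- match(vid, snvs$sites$variant_id)
    cs <- snv_carriers(snvs, i)
    counts[cs] <- counts[cs] + 1L
  }
  list(per_call = per_call,
       per_individual = data.frame(sample = names(counts),
                                   n_carried = unname(counts)),
       novel_cds_len_quantiles = stats::quantile(snv_view$novel_cds_len_nt))
}

#' Filter start-gain calls for the occupancy analysis
#'
#' Keeps calls with at least `min_codons` codons between the novel and
#' original start codon, at least `min_carriers` carrier individuals, and an
#' autosomal contig.
#'
#' @param calls data.frame from [call_start_gains()].
#' @param min_codons minimum codon gap (default 5).
#' @param min_carriers minimum carriers (default 3).
#' @return the kept subset of `calls`.
#' @export
filter_for_occupancy <- function(calls, min_codons = 5L, min_carriers = 3L) {
  if (nrow(calls) == 0) return(calls)
  keep <- calls$novel_cds_len_codons >= min_codons &
    calls$n_carriers >= min_carriers & calls$autosomal
  calls[keep, , drop = FALSE]
}

#' Classify a transcript under the 50-nt nonsense-mediated-decay rule
#'
#' A transcript is a predicted NMD target when its stop codon ends more than
#' `max_distance` nucleotides upstream of the 3'-most splice-generated
#' exon-exon junction. Single-exon transcripts have no junction and are never
#' predicted NMD (distance `NA`).
#'
#' @param tx a `transcript_model` with annotated CDS.
#' @param max_distance rule threshold in nt; prediction requires a distance
#'   strictly greater than this (default 50).
#' @return list `transcript_id`, `stop_codon_tpos` (last base),
#'   `last_junction_tpos`, `distance_nt`, `nmd_predicted`.
#' @export
nmd_classify <- function(tx, max_distance = 50L) {
  if (is.na(tx$cds_end_g)) stop("transcript without annotated stop codon")
  stop_t <- cds_end_tpos(tx)
  if (is.na(stop_t) || stop_t > tx_length(tx)) stop("stop codon outside transcript")
  n_ex <- nrow(tx$exons)
  if (n_ex < 2) {
    return(list(transcript_id = tx$transcript_id, stop_codon_tpos = stop_t,
                last_junction_tpos = NA_integer_, distance_nt = NA_integer_,
                nmd_predicted = FALSE))
  }
  ex <- tx_exons_5to3(tx)
  w <- ex$end - ex$start + 1L
  junction <- sum(w[-n_ex])   # transcript coord of last base before final exon
  d <- junction - stop_t
  list(transcript_id = tx$transcript_id, stop_codon_tpos = stop_t,
       last_junction_tpos = junction, distance_nt = d,
       nmd_predicted = d > max_distance)
}
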