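#' Keep only one-to-one (reciprocal single hit) alignment blocks
#'
#' A block survives iff every base of its target interval and every base of
#' its query interval is covered by exactly one block genome-wide, i.e.
#' single coverage on both sides.
#'
#' @param blocks list of pairwise blocks from [read_maf()].
#' @return the surviving subset of `blocks`.
#' @export
filter_one_to_one <- function(blocks) {
  if (!length(blocks)) return(blocks)
  side_cov <- function(side) {
    key <- vapply(blocks, function(b) b[[side]]$contig, character(1))
    ir <- IRanges::IRanges(
      vapply(blocks, function(b) b[[side]]$start, integer(1)),
      vapply(blocks, function(b) b[[side]]$end, integer(1)))
    lapply(split(ir, key), IRanges::coverage)
  }
  tc <- side_cov("target"); qc <- side_cov("query")
  single <- function(covlist, ctg, start, end) {
    rle <- covlist[[ctg]]
    v <- as.integer(S4Vectors::window(rle, start, end))
    all(v == 1L)
  }
  keep <- vapply(blocks, function(b)
    single(tc, b$target$contig, b$target$start, b$target$end) &&
      single(qc, b$query$contig, b$query$start, b$query$end), logical(1))
  blocks[keep]
}

#' Per-column coordinate map of an alignment block
#'
#' @param block a pairwise block.
#' @return list with `t_pos`, `q_pos` (forward-strand positions per column,
#'   `NA` at gaps) and `t_char`, `q_char` (aligned characters, target
#'   orientation).
#' @export
block_column_map <- function(block) {
  side_pos <- function(side) {
    ch <- strsplit(side$aln, "", fixed = TRUE)[[1]]
    pos <- rep(NA_integer_, length(ch))
    idx <- which(ch != "-")
    pos[idx] <- if (side$strand == "+") seq.int(side$start, side$end)
                else seq.int(side$end, side$start)
    list(pos = pos, ch = ch)
  }
  t <- side_pos(block$target); q <- side_pos(block$query)
  list(t_pos = t$pos, q_pos = q$pos, t_char = t$ch, q_char = q$ch)
}

#' Target-position lookup over a set of blocks
#'
#' Builds a hashed map from target genomic position to the orthologous query
#' position and allele (target orientation). Positions falling in gap columns
#' or outside any block are absent.
#'
#' @param blocks list of pairwise blocks (one-to-one filtered).
#' @return environment keyed `"contig:pos"`; values are lists `q_contig`,
#'   `q_pos`, `q_char`, `q_strand`, `block_id`.
#' @export
ortholog_lookup <- function(blocks) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (b in blocks) {
    m <- block_column_map(b)
    ok <- !is.na(m$t_pos) & !is.na(m$q_pos)
    keys <- paste0(b$target$contig, ":", m$t_pos[ok])
    vals <- mapply(function(qp, qc) list(q_contig = b$query$contig, q_pos = qp,
                                         q_char = qc,
                                         q_strand = b$query$strand,
                                         block_id = b$block_id),
                   m$q_pos[ok], m$q_char[ok], SIMPLIFY = FALSE)
    list2env(stats::setNames(vals, keys), envir = env)
  }
  env
}

orth_at <- function(lookup, contig, pos) {
  key <- paste0(contig, ":", pos)
  if (exists(key, envir = lookup, inherits = FALSE))
    get(key, envir = lookup, inherits = FALSE) else NULL
}

#' Find single-base divergent sites between target and query genomes
#'
#' One site per ungapped aligned column where the target base differs from
#' the query base; gap and N columns are excluded. Alleles are recorded in
#' target (forward-strand) orientation. Block sequences are validated against
#' the genome FASTAs.
#'
#' @param blocks one-to-one filtered pairwise blocks.
#' @param target_genome,query_genome named genomes of the two species.
#' @return data.frame `contig`, `pos`, `target_allele`, `query_allele`,
#'   `q_contig`, `q_pos`, `block_id`.
#' @export
find_divergent_sites <- function(blocks, target_genome, query_genome) {
  rows <- list()
  for (b in blocks) {
    m <- block_column_map(b)
    # validate against genomes
    tref <- substring(genome_seq(target_genome, b$target$contig),
                      b$target$start, b$target$end)
    tgot <- gsub("-", "", b$target$aln, fixed = TRUE)
    if (b$target$strand == "-") tgot <- revcomp(tgot)
    if (tgot != tref) stop("target block sequence disagrees with genome in ",
                           b$block_id)
    qref <- substring(genome_seq(query_genome, b$query$contig),
                      b$query$start, b$query$end)
    qgot <- gsub("-", "", b$query$aln, fixed = TRUE)
    if (b$query$strand == "-") qgot <- revcomp(qgot)
    if (qgot != qref) stop("query block sequence disagrees with genome in ",
                           b$block_id)
    ok <- !is.na(m$t_pos) & !is.na(m$q_pos) &
      m$t_char != m$q_char & m$t_char != "N" & m$q_char != "N"
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contig = b$target$contig, pos = m$t_pos[ok],
      target_allele = m$t_char[ok], query_allele = m$q_char[ok],
      q_contig = b$query$contig, q_pos = m$q_pos[ok],
      block_id = b$block_id, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(contig = character(), pos = integer(),
                      target_allele = character(), query_allele = character(),
                      q_contig = character(), q_pos = integer(),
                      block_id = character()))
  out <- do.call(rbind, rows)
  out[order(out$contig, out$pos), ]
}

#' Attach gorilla/orangutan alleles to human-chimp divergent sites
#'
#' @param sites data.frame from [find_divergent_sites()] (human vs chimp).
#' @param gorilla_lookup,orang_lookup [ortholog_lookup()]s of the human-
#'   gorilla and human-orangutan one-to-one blocks.
#' @return `sites` with `gorilla_allele` and `orangutan_allele` columns
#'   (`NA` where no one-to-one alignment covers the site).
#' @export
annotate_outgroups <- function(sites, gorilla_lookup, orang_lookup) {
  get_allele <- function(lk, contig, pos) {
    o <- orth_at(lk, contig, pos)
    if (is.null(o)) NA_character_ else o$q_char
  }
  sites$gorilla_allele <- mapply(get_allele, contig = sites$contig,
                                 pos = sites$pos,
                                 MoreArgs = list(lk = gorilla_lookup))
  sites$orangutan_allele <- mapply(get_allele, contig = sites$contig,
                                   pos = sites$pos,
                                   MoreArgs = list(lk = orang_lookup))
  sites
}

# is a chimp genomic position inside the 5'UTR of any chimp transcript?
chimp_5utr_transcript <- function(chimp_transcripts, contig, pos) {
  for (ctx in chimp_transcripts) {
    if (ctx$contig != contig || is.na(ctx$cds_start_g)) next
    t <- genome_to_tx(ctx, pos)
    cs <- cds_start_tpos(ctx)
    if (!is.na(t) && !is.na(cs) && t < cs) return(ctx$transcript_id)
  }
  NULL
}

#' Call fixed species-specific start codons from divergent sites
#'
#' For each human transcript start codon, collects the human-chimp divergent
#' sites inside its 3-nt triplet and emits a call iff every such site passes:
#' the chimp orthologous position lies in the 5'UTR of a chimp transcript,
#' gorilla and orangutan both carry a non-human allele (missing outgroup
#' alignment drops the candidate), and the site is monomorphic across the
#' population VCF (absent, or present with every called genotype homozygous
#' reference). Candidates failing a rule are reported with a reason code.
#'
#' @param sites divergent sites with outgroup alleles ([annotate_outgroups()]).
#' @param human_transcripts,chimp_transcripts named lists of
#'   `transcript_model`s.
#' @param chimp_lookup [ortholog_lookup()] of the human-chimp blocks.
#' @param snvs population `snv_set` used for the fixation check.
#' @return list with `calls` (list of hss_call lists) and `rejected`
#'   (data.frame `transcript_id`, `reason`).
#' @export
call_species_starts <- function(sites, human_transcripts, chimp_transcripts,
                                chimp_lookup, snvs) {
  calls <- list()
  rejected <- list()
  reject <- function(tid, reason)
    data.frame(transcript_id = tid, reason = reason, stringsAsFactors = FALSE)
  for (tx in human_transcripts) {
    if (is.na(tx$cds_start_g)) next
    cs <- cds_start_tpos(tx)
    trip_g <- tx_to_genome(tx, cs + 0:2)
    hit <- sites[sites$contig == tx$contig & sites$pos %in% trip_g, ,
                 drop = FALSE]
    if (nrow(hit) == 0) next
    tid <- tx$transcript_id
    # rule 3: outgroup polarisation, per divergent position
    if (any(is.na(hit$gorilla_allele)) || any(is.na(hit$orangutan_allele))) {
      rejected[[length(rejected) + 1L]] <- reject(tid, "outgroup_missing"); next
    }
    if (any(hit$gorilla_allele == hit$target_allele) ||
        any(hit$orangutan_allele == hit$target_allele)) {
      rejected[[length(rejected) + 1L]] <- reject(tid, "outgroup_shared"); next
    }
    # rule 4: fixation in the population
    poly <- FALSE
    for (p in hit$pos) {
      j <- which(snvs$sites$contig == tx$contig & snvs$sites$pos == p)
      if (length(j) && any(snvs$haplo[j, ] == 1, na.rm = TRUE)) poly <- TRUE
    }
    if (poly) {
      rejected[[length(rejected) + 1L]] <- reject(tid, "polymorphic"); next
    }
    # rule 2: chimp ortholog of the start codon in a chimp 5'UTR
    ctid <- chimp_5utr_transcript(chimp_transcripts, hit$q_contig[1],
                                  hit$q_pos[1])
    if (is.null(ctid)) {
      rejected[[length(rejected) + 1L]] <- reject(tid, "chimp_not_5utr"); next
    }
    ctx <- chimp_transcripts[[ctid]]
    # ancestral start: human position orthologous to the chimp start codon
    hasc_tpos <- NA_integer_
    chimp_start_g <- ctx$cds_start_g
    # reverse lookup: scan the block that carried the site
    rev_hit <- orth_rev_at(chimp_lookup, hit$q_contig[1], chimp_start_g)
    if (!is.null(rev_hit) && rev_hit$t_contig == tx$contig)
      hasc_tpos <- genome_to_tx(tx, rev_hit$t_pos)
    novel_nt <- NA_integer_
    in_frame <- FALSE
    if (!is.na(hasc_tpos)) {
      in_frame <- (hasc_tpos - cs) %% 3L == 0L && hasc_tpos > cs
      if (in_frame) novel_nt <- hasc_tpos - cs - 3L
    }
    calls[[length(calls) + 1L]] <- list(
      transcript_id = tid, contig = tx$contig, strand = tx$strand,
      hssc_tpos = cs, hssc_g = tx$cds_start_g,
      hasc_tpos = hasc_tpos, in_frame = in_frame,
      chimp_transcript_id = ctid,
      divergent_positions = hit$pos,
      human_alleles = hit$target_allele, chimp_alleles = hit$query_allele,
      fixed_in_population = TRUE,
      novel_cds_len_nt = novel_nt,
      novel_cds_len_codons = if (is.na(novel_nt)) NA_integer_
                             else novel_nt %/% 3L,
      cug_origin = NA)
  }
  list(calls = calls,
       rejected = if (length(rejected)) do.call(rbind, rejected)
                  else data.frame(transcript_id = character(),
                                  reason = character()))
}

# reverse lookup (query pos -> target pos); built lazily and cached
orth_rev_at <- function(lookup, q_contig, q_pos) {
  if (!exists(".rev", envir = lookup, inherits = FALSE)) {
    rev <- new.env(hash = TRUE, parent = emptyenv())
    for (key in ls(lookup)) {
      v <- get(key, envir = lookup, inherits = FALSE)
      tc <- sub(":.*$", "", key); tp <- as.integer(sub("^.*:", "", key))
      assign(paste0(v$q_contig, ":", v$q_pos),
             list(t_contig = tc, t_pos = tp), envir = rev)
    }
    assign(".rev", rev, envir = lookup)
  }
  rev <- get(".rev", envir = lookup, inherits = FALSE)
  key <- paste0(q_contig, ":", q_pos)
  if (exists(key, envir = rev, inherits = FALSE))
    get(key, envir = rev, inherits = FALSE) else NULL
}

#' Flag whether a species-specific start codon arose from CUG
#'
#' Reads the chimp triplet orthologous to the human start codon in
#' human-transcript orientation; `CTG` marks a CUG-origin codon. If any of
#' the three positions is unaligned the flag is `NA` and the call retained.
#'
#' @param call an hss_call from [call_species_starts()].
#' @param human_transcripts named list of human `transcript_model`s.
#' @param chimp_lookup [ortholog_lookup()] of the human-chimp blocks.
#' @return the call with `cug_origin` and `chimp_triplet` set.
#' @export
flag_cug_origin <- function(call, human_transcripts, chimp_lookup) {
  tx <- human_transcripts[[call$transcript_id]]
  trip_g <- tx_to_genome(tx, call$hssc_tpos + 0:2)
  ch <- vapply(trip_g, function(p) {
    o <- orth_at(chimp_lookup, tx$contig, p)
    if (is.null(o)) NA_character_ else o$q_char
  }, character(1))
  if (anyNA(ch)) {
    call$cug_origin <- NA
    call$chimp_triplet <- NA_character_
    return(call)
  }
  # chars are forward-strand but already in transcript order: complement
  # each base (no reversal) on the minus strand
  if (tx$strand == "-") ch <- complement_base(ch)
  trip <- paste(ch, collapse = "")
  call$chimp_triplet <- trip
  call$cug_origin <- identical(trip, "CTG")
  call
}

#' Four-anchor site panel for the species-level occupancy analysis
#'
#' For each call emits the four anchor codons evaluated for ribosome
#' occupancy: the human species-specific start (hSSC), the human ancestral
#' start (hASC, the human position orthologous to the chimp start codon), the
#' chimp ortholog of the hSSC (cOSC), and the chimp start codon itself (cSC).
#' Anchors that cannot be lifted through the alignment are flagged missing
#' (`NA` tpos). The `analyzable` flag requires at least `min_codons` codons
#' between hSSC and hASC.
#'
#' @param calls list of hss_calls (CUG-flagged).
#' @param human_transcripts,chimp_transcripts named transcript lists.
#' @param chimp_lookup [ortholog_lookup()] of the human-chimp blocks.
#' @param min_codons analyzability threshold (default 5).
#' @return data.frame `call_id`, `anchor_id`, `anchor_class`, `species`,
#'   `transcript_id`, `tpos`, `analyzable`, `cug_origin`.
#' @export
hssc_site_panel <- function(calls, human_transcripts, chimp_transcripts,
                            chimp_lookup, min_codons = 5L) {
  rows <- list()
  for (call in calls) {
    tx <- human_transcripts[[call$transcript_id]]
    ctx <- chimp_transcripts[[call$chimp_transcript_id]]
    analyzable <- !is.na(call$novel_cds_len_codons) &&
      call$novel_cds_len_codons >= min_codons
    o <- orth_at(chimp_lookup, tx$contig, call$hssc_g)
    cosc_tpos <- if (is.null(o)) NA_integer_ else genome_to_tx(ctx, o$q_pos)
    csc_tpos <- cds_start_tpos(ctx)
    add <- function(class, species, tid, tpos) {
      rows[[length(rows) + 1L]] <<- data.frame(
        call_id = call$transcript_id,
        anchor_id = paste0(call$transcript_id, ".", class),
        anchor_class = class, species = species, transcript_id = tid,
        tpos = tpos, analyzable = analyzable,
        cug_origin = call$cug_origin, stringsAsFactors = FALSE)
    }
    add("hSSC", "human", tx$transcript_id, call$hssc_tpos)
    add("hASC", "human", tx$transcript_id, call$hasc_tpos)
    add("cOSC", "chimpanzee", ctx$transcript_id, cosc_tpos)
    add("cSC", "chimpanzee", ctx$transcript_id, csc_tpos)
  }
  if (!length(rows))
    return(data.frame(call_id = character(), anchor_id = character(),
                      anchor_class = character(), species = character(),
                      transcript_id = character(), tpos = integer(),
                      analyzable = logical(), cug_origin = logical()))
  do.call(rbind, rows)
}

#' Tabular view of species-specific start-codon calls
#' @param calls list of hss_calls.
#' @return one row per call.
#' @export
hss_calls_table <- function(calls) {
  if (!length(calls))
    return(data.frame(transcript_id = character()))
  do.call(rbind, lapply(calls, function(c) data.frame(
    transcript_id = c$transcript_id, contig = c$contig, strand = c$strand,
    hssc_tpos = c$hssc_tpos, hssc_g = c$hssc_g, hasc_tpos = c$hasc_tpos,
    in_frame = c$in_frame, chimp_transcript_id = c$chimp_transcript_id,
    divergent_positions = paste(c$divergent_positions, collapse = ","),
    novel_cds_len_nt = c$novel_cds_len_nt,
    novel_cds_len_codons = c$novel_cds_len_codons,
    cug_origin = c$cug_origin,
    chimp_triplet = if (is.null(c$chimp_triplet)) NA_character_
                    else c$chimp_triplet,
    stringsAsFactors = FALSE)))
}
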