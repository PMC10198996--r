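#' Read a FASTA file into a named DNAStringSet
#'
#' Sequences are upper-cased and input order is preserved. Contig names are
#' the first whitespace-delimited word of each header.
#'
#' @param path FASTA file.
#' @param species_tag optional species label stored as an attribute.
#' @return a named `DNAStringSet` with attribute `species_tag`.
#' @export
read_fasta <- function(path, species_tag = NA_character_) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) stop("duplicate contig name in ", path)
  if (any(Biostrings::width(x) == 0)) stop("zero-length sequence in ", path)
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- nm
  attr(out, "species_tag") <- species_tag
  out
}

#' Write sequences to FASTA
#' @param seqs named `DNAStringSet` or named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Read transcript models from a GFF3 annotation
#'
#' Expects `mRNA`/`transcript` features with `ID`, and `exon`/`CDS` children
#' keyed by `Parent`. GFF's 1-based inclusive coordinates are kept (internal
#' convention is 1-based closed); minus-strand transcripts get their exons in
#' 5' to 3' transcript order through the accessors. CDS features are expected
#' to include the stop codon.
#'
#' @param path GFF3 file.
#' @param genome optional genome used only for validation.
#' @return named list of `transcript_model`s keyed by transcript id.
#' @export
read_gff3 <- function(path, genome = NULL) {
  g <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(g)
  df$Parent <- vapply(as.list(g$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  is_tx <- df$type %in% c("mRNA", "transcript")
  txdf <- df[is_tx, , drop = FALSE]
  if (nrow(txdf) == 0) stop("no mRNA/transcript features in ", path)
  out <- list()
  for (i in seq_len(nrow(txdf))) {
    tid <- txdf$ID[i]
    strand <- as.character(txdf$strand[i])
    if (!strand %in% c("+", "-")) stop("missing strand for transcript ", tid)
    kids <- df[!is.na(df$Parent) & df$Parent == tid, , drop = FALSE]
    ex <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0) ex <- txdf[i, c("start", "end"), drop = FALSE]
    cds <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    cds_start_g <- cds_end_g <- NA_integer_
    if (nrow(cds) > 0) {
      for (k in seq_len(nrow(cds)))
        if (!any(ex$start <= cds$start[k] & ex$end >= cds$end[k]))
          stop("CDS not contained in exons for transcript ", tid)
      if (strand == "+") { cds_start_g <- min(cds$start); cds_end_g <- max(cds$end) }
      else               { cds_start_g <- max(cds$end);   cds_end_g <- min(cds$start) }
    }
    bt <- if ("biotype" %in% names(txdf) && !is.na(txdf$biotype[i]))
      txdf$biotype[i] else "protein_coding"
    out[[tid]] <- transcript_model(
      transcript_id = tid,
      gene_id = if (!is.na(txdf$Parent[i])) txdf$Parent[i] else tid,
      contig = as.character(txdf$seqnames[i]), strand = strand, exons = ex,
      cds_start_g = cds_start_g, cds_end_g = cds_end_g, biotype = bt)
  }
  out
}

#' Write transcript models as GFF3
#' @param transcripts list of `transcript_model`s.
#' @param path output file.
#' @export
write_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  genes <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  for (gid in genes) {
    txs <- Filter(function(t) t$gene_id == gid, transcripts)
    lo <- min(vapply(txs, function(t) min(t$exons$start), 0))
    hi <- max(vapply(txs, function(t) max(t$exons$end), 0))
    tx1 <- txs[[1]]
    lines <- c(lines, sprintf("%s\tstartscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              tx1$contig, lo, hi, tx1$strand, gid))
    for (tx in txs) {
      tid <- tx$transcript_id
      lines <- c(lines, sprintf(
        "%s\tstartscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=%s",
        tx$contig, min(tx$exons$start), max(tx$exons$end), tx$strand, tid,
        gid, tx$biotype))
      for (k in seq_len(nrow(tx$exons)))
        lines <- c(lines, sprintf(
          "%s\tstartscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          tx$contig, tx$exons$start[k], tx$exons$end[k], tx$strand, tid, k, tid))
      if (!is.na(tx$cds_start_g)) {
        t1 <- cds_start_tpos(tx); t2 <- cds_end_tpos(tx)
        gpos <- sort(tx_to_genome(tx, seq.int(t1, t2)))
        brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
        ph <- 0L
        segs <- data.frame(start = gpos[brk[-length(brk)] + 1L], end = gpos[brk[-1L]])
        for (k in seq_len(nrow(segs)))
          lines <- c(lines, sprintf(
            "%s\tstartscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
            tx$contig, segs$start[k], segs$end[k], tx$strand, ph, tid, tid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read biallelic SNVs and genotypes from a VCF
#'
#' Multiallelic records are split into one biallelic record per alternate
#' allele (other alternates recoded as reference); indel alleles are skipped
#' with a count. Genotypes must be diploid; missing haplotypes become `NA`
#' and are excluded from allele-frequency denominators downstream.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @return an `snv_set`: list with `sites` (data.frame `variant_id`, `contig`,
#'   `pos`, `ref`, `alt`), `haplo` (integer matrix, sites x 2N haplotypes,
#'   0/1/NA), `samples`, and `n_skipped_indels`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  samples <- colnames(gt)[-1]
  n <- length(samples)
  sites <- list(); haps <- list(); skipped <- 0L
  for (r in seq_len(nrow(fix))) {
    gts <- sub(":.*$", "", gt[r, -1])
    gts[is.na(gts)] <- ".|."   # fully missing genotype
    parts <- strsplit(gts, "[/|]")
    if (any(lengths(parts) != 2)) stop("genotype ploidy != 2 at row ", r)
    hp <- matrix(unlist(parts), nrow = 2)  # 2 x n, allele index strings
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      if (nchar(fix$REF[r]) != 1L || nchar(alts[k]) != 1L || alts[k] == "*") {
        skipped <- skipped + 1L; next
      }
      hv <- ifelse(hp == ".", NA_integer_, as.integer(hp == as.character(k)))
      vid <- if (!is.na(fix$ID[r]) && fix$ID[r] != ".") {
        if (length(alts) > 1) paste0(fix$ID[r], "_alt", k) else fix$ID[r]
      } else paste0(fix$CHROM[r], "_", fix$POS[r], "_", fix$REF[r], "_", alts[k])
      sites[[length(sites) + 1L]] <- data.frame(
        variant_id = vid, contig = fix$CHROM[r], pos = as.integer(fix$POS[r]),
        ref = fix$REF[r], alt = alts[k], stringsAsFactors = FALSE)
      haps[[length(haps) + 1L]] <- as.vector(hv)  # a1,b1,a2,b2,...
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(variant_id = character(), contig = character(), pos = integer(),
               ref = character(), alt = character())
  haplo <- if (length(haps)) do.call(rbind, haps) else
    matrix(integer(), 0, 2 * n)
  colnames(haplo) <- paste0(rep(samples, each = 2), c(".1", ".2"))
  structure(list(sites = sites, haplo = haplo, samples = samples,
                 n_skipped_indels = skipped), class = "snv_set")
}

#' @export
print.snv_set <- function(x, ...) {
  cat(sprintf("<snv_set: %d biallelic SNVs x %d individuals (%d indel alleles skipped)>\n",
              nrow(x$sites), length(x$samples), x$n_skipped_indels))
  invisible(x)
}

#' Alternate-allele frequency of one SNV (missing haplotypes excluded)
#' @param snvs an `snv_set`.
#' @param i row index into `snvs$sites`.
#' @export
snv_allele_frequency <- function(snvs, i) {
  h <- snvs$haplo[i, ]
  called <- sum(!is.na(h))
  if (called == 0) return(NA_real_)
  sum(h, na.rm = TRUE) / called
}

#' Individuals carrying at least one alternate haplotype of one SNV
#' @param snvs an `snv_set`.
#' @param i row index into `snvs$sites`.
#' @export
snv_carriers <- function(snvs, i) {
  h <- snvs$haplo[i, ]
  m <- matrix(h, nrow = 2)
  snvs$samples[colSums(m == 1, na.rm = TRUE) > 0]
}

#' Read pairwise alignment blocks from a MAF file
#'
#' The first `s` line of each block is the target species, the second the
#' query. Coordinates are converted from MAF's 0-based, strand-relative starts
#' to internal 1-based closed forward-strand intervals; the aligned text is
#' kept as printed (target orientation).
#'
#' @param path MAF file.
#' @return list of `pairwise_block`s: `block_id`, per-side `species`,
#'   `contig`, `start`, `end`, `strand`, `aln` (gapped sequence).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list(); cur <- NULL; bid <- 0L
  flush <- function(cur) {
    if (is.null(cur) || length(cur) < 2) return(NULL)
    if (length(cur) != 2) stop("MAF block with ", length(cur), " s-lines; expected 2")
    if (nchar(cur[[1]]$aln) != nchar(cur[[2]]$aln))
      stop("MAF block with unequal row lengths")
    for (side in cur) {
      ungapped <- gsub("-", "", side$aln, fixed = TRUE)
      if (nchar(ungapped) != side$size) stop("MAF size disagrees with sequence")
    }
    list(target = cur[[1]], query = cur[[2]])
  }
  parse_s <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    src <- f[2]; start0 <- as.integer(f[3]); size <- as.integer(f[4])
    strand <- f[5]; srcSize <- as.integer(f[6]); text <- f[7]
    if (strand == "+") { s1 <- start0 + 1L; e1 <- start0 + size }
    else { s1 <- srcSize - start0 - size + 1L; e1 <- srcSize - start0 }
    list(species = sub("\\..*$", "", src),
         contig = sub("^[^.]*\\.", "", src),
         start = s1, end = e1, strand = strand, size = size,
         src_size = srcSize, aln = toupper(text))
  }
  for (l in lines) {
    if (startsWith(l, "a")) {
      b <- flush(cur)
      if (!is.null(b)) { bid <- bid + 1L; b$block_id <- paste0("blk", bid); blocks[[bid]] <- b }
      cur <- list()
    } else if (startsWith(l, "s")) {
      cur[[length(cur) + 1L]] <- parse_s(l)
    }
  }
  b <- flush(cur)
  if (!is.null(b)) { bid <- bid + 1L; b$block_id <- paste0("blk", bid); blocks[[bid]] <- b }
  blocks
}

#' Write pairwise alignment blocks as MAF
#' @param blocks list of blocks as returned by [read_maf()].
#' @param path output file.
#' @param src_sizes named integer vector of contig lengths per
#'   `species.contig` key, used to express minus-strand starts.
#' @export
write_maf <- function(blocks, path, src_sizes) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##maf version=1", con)
  fmt_s <- function(side) {
    key <- paste0(side$species, ".", side$contig)
    ss <- unname(src_sizes[key])
    if (is.na(ss)) stop("missing src size for ", key)
    if (side$strand == "+") start0 <- side$start - 1L
    else start0 <- ss - side$end
    sprintf("s %s %d %d %s %d %s", key, start0, side$end - side$start + 1L,
            side$strand, ss, side$aln)
  }
  for (b in blocks) {
    writeLines("a score=0", con)
    writeLines(fmt_s(b$target), con)
    writeLines(fmt_s(b$query), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read ribosome footprint alignments from SAM/BAM
#'
#' Mapping uniqueness is taken from the `NH` tag (`NH == 1`), falling back to
#' `MAPQ > 3` when `NH` is absent. If a blacklist is supplied, reads whose
#' aligned interval overlaps any blacklist interval are flagged.
#'
#' @param path SAM or BAM file.
#' @param sample_id sample label attached to every read.
#' @param blacklist optional data.frame (`contig`, `start`, `end`; 1-based
#'   closed) of non-coding-RNA regions, e.g. from [read_bed()].
#' @return data.frame of footprint reads: `sample_id`, `contig`, `pos`
#'   (leftmost, 1-based), `len`, `strand`, `unique`, `blacklisted`.
#' @export
read_sam <- function(path, sample_id = "sample", blacklist = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "mapq"), tag = "NH")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(res$pos))
  uniq <- ifelse(!is.na(nh), nh == 1L, res$mapq > 3L)
  rd <- data.frame(sample_id = sample_id,
                   contig = as.character(res$rname),
                   pos = res$pos, len = res$qwidth,
                   strand = as.character(res$strand),
                   unique = uniq, stringsAsFactors = FALSE)
  rd <- rd[!is.na(rd$pos), , drop = FALSE]
  rd$blacklisted <- flag_blacklist(rd, blacklist)
  rd
}

# TRUE where a read interval overlaps a blacklist interval
flag_blacklist <- function(reads, blacklist) {
  if (is.null(blacklist) || nrow(reads) == 0) return(rep(FALSE, nrow(reads)))
  out <- rep(FALSE, nrow(reads))
  for (ctg in unique(blacklist$contig)) {
    bl <- blacklist[blacklist$contig == ctg, , drop = FALSE]
    sel <- which(reads$contig == ctg)
    if (!length(sel)) next
    q <- IRanges::IRanges(reads$pos[sel], reads$pos[sel] + reads$len[sel] - 1L)
    s <- IRanges::IRanges(bl$start, bl$end)
    out[sel] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Write footprint reads as a SAM file
#'
#' Sequences are taken from the forward strand of the supplied genome, as SAM
#' requires; multi-mapping distractors get `NH:i:2`, all others `NH:i:1`.
#'
#' @param reads data.frame as produced by the footprint simulator (`contig`,
#'   `pos`, `len`, `strand`, `unique`).
#' @param genome named `DNAStringSet`/character genome the reads map to.
#' @param path output SAM path.
#' @export
write_sam <- function(reads, genome, path) {
  ctgs <- names(genome)
  lens <- if (is.character(genome)) nchar(genome) else Biostrings::width(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ctgs, lens))
  if (nrow(reads) == 0) { writeLines(hdr, path); return(invisible(path)) }
  seqs <- vapply(seq_len(nrow(reads)), function(i)
    substring(genome_seq(genome, reads$contig[i]), reads$pos[i],
              reads$pos[i] + reads$len[i] - 1L), character(1))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  nh <- ifelse(reads$unique, 1L, 2L)
  rows <- sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                  seq_len(nrow(reads)), flag, reads$contig, reads$pos, 255L,
                  reads$len, seqs, nh)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a BED file (intervals returned 1-based closed)
#' @param path BED3+ file.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(contig = df[[1]], start = df[[2]] + 1L, end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- df[[4]]
  if (ncol(df) >= 6) out$strand <- df[[6]]
  out
}

#' Write intervals as BED6
#' @param df data.frame with `contig`, `start`, `end` (1-based closed) and
#'   optional `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$contig, df$start - 1L, df$end, name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as a tab-separated table with header
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#' @param path input file.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
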