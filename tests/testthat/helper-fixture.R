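# Shared fixture and pipeline run, built once per test session, plus
# independent brute-force oracles used across test files.

.shared <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.shared$fx)) {
    dir <- file.path(tempdir(), "startscan_default_fixture")
    unlink(dir, recursive = TRUE)
    .shared$fx <- make_fixture(fixture_config(seed = 101L), out_dir = dir)
  }
  .shared$fx
}

default_pipeline <- function() {
  if (is.null(.shared$report)) {
    fx <- default_fixture()
    cfg <- pipeline_config(fx$paths$out_dir,
                           out_dir = file.path(fx$paths$out_dir, "out"))
    .shared$report <- suppressMessages(run_pipeline(cfg))
    .shared$pipeline_cfg <- cfg
  }
  list(report = .shared$report, cfg = .shared$pipeline_cfg)
}

# loaded inputs of the default fixture, read back through the io layer
default_inputs <- function() {
  if (is.null(.shared$inputs)) {
    fx <- default_fixture()
    d <- fx$paths$out_dir
    inp <- list(
      genome_h = read_fasta(file.path(d, "human.fa")),
      genome_c = read_fasta(file.path(d, "chimpanzee.fa")),
      genome_g = read_fasta(file.path(d, "gorilla.fa")),
      genome_o = read_fasta(file.path(d, "orangutan.fa")),
      tx_h = read_gff3(file.path(d, "human.gff3")),
      tx_c = read_gff3(file.path(d, "chimpanzee.gff3")),
      snvs = read_vcf(file.path(d, "population.vcf")),
      blacklist = read_bed(file.path(d, "blacklist.bed")),
      maf_c = read_maf(file.path(d, "human_chimpanzee.maf")),
      maf_g = read_maf(file.path(d, "human_gorilla.maf")),
      maf_o = read_maf(file.path(d, "human_orangutan.maf")))
    .shared$inputs <- inp
  }
  .shared$inputs
}

# species-level calling chain on the default fixture, cached
species_calls <- function() {
  if (is.null(.shared$species)) {
    inp <- default_inputs()
    bc <- filter_one_to_one(inp$maf_c)
    bg <- filter_one_to_one(inp$maf_g)
    bo <- filter_one_to_one(inp$maf_o)
    lk_c <- ortholog_lookup(bc)
    lk_g <- ortholog_lookup(bg)
    lk_o <- ortholog_lookup(bo)
    sites <- annotate_outgroups(find_divergent_sites(bc, inp$genome_h,
                                                     inp$genome_c),
                                lk_g, lk_o)
    res <- call_species_starts(sites, inp$tx_h, inp$tx_c, lk_c, inp$snvs)
    calls <- lapply(res$calls, flag_cug_origin, human_transcripts = inp$tx_h,
                    chimp_lookup = lk_c)
    panel <- hssc_site_panel(calls, inp$tx_h, inp$tx_c, lk_c)
    .shared$species <- list(calls = calls, rejected = res$rejected,
                            panel = panel, lk_c = lk_c, lk_g = lk_g,
                            blocks_c = bc)
  }
  .shared$species
}

# per-base exon walk: independent of the interval arithmetic in the package
walk_tx_map <- function(tx) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  g <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i]))
  if (tx$strand == "-") g <- rev(g)
  g   # g[t] = genomic position of transcript base t
}

walk_tx_seq <- function(tx, genome) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  cs <- strsplit(as.character(genome[[tx$contig]]), "")[[1]]
  map <- walk_tx_map(tx)
  ch <- cs[map]
  if (tx$strand == "-") ch <- unname(comp[ch])
  paste(ch, collapse = "")
}

# brute-force start-gain oracle: pure string logic over the transcript
# sequence built by the per-base walk; returns the novel AUG tpos or NA
oracle_startgain <- function(tx, genome, all_tx, tpos, alt_t) {
  seq <- walk_tx_seq(tx, genome)
  map <- walk_tx_map(tx)
  cstart <- which(map == tx$cds_start_g)
  if (length(cstart) != 1 || tpos >= cstart) return(NA_integer_)
  mut <- seq
  substr(mut, tpos, tpos) <- alt_t
  # CDS-union exclusion, recomputed by brute force
  gpos <- map[tpos]
  for (other in all_tx) {
    if (other$contig != tx$contig || is.na(other$cds_start_g)) next
    omap <- walk_tx_map(other)
    c1 <- which(omap == other$cds_start_g); c2 <- which(omap == other$cds_end_g)
    if (gpos %in% omap[c1:c2]) return(NA_integer_)
  }
  stops <- c("TAA", "TAG", "TGA")
  for (s in seq_len(cstart - 3L)) {
    if ((cstart - s) %% 3L != 0L) next
    if (!(tpos >= s && tpos <= s + 2L)) next
    if (substr(mut, s, s + 2L) != "ATG" || substr(seq, s, s + 2L) == "ATG")
      next
    blocked <- FALSE
    w <- s + 3L
    while (w <= cstart - 3L) {
      if (substr(mut, w, w + 2L) %in% stops) { blocked <- TRUE; break }
      w <- w + 3L
    }
    if (!blocked) return(s)
  }
  NA_integer_
}

# exact two-sided signed-rank p by full enumeration of sign assignments
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  p_le <- mean(Wnull <= W + 1e-9)
  p_ge <- mean(Wnull >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# random codon frequency vector (Dirichlet)
random_pi <- function() {
  x <- stats::rgamma(61, shape = 1)
  x / sum(x)
}
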