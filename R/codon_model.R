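#' Construct a codon alignment, dropping unusable columns
#'
#' Columns containing a gap, an `N`, or a stop codon in any taxon are removed
#' and counted: orthologs of a novel CDS need not be coding in the other
#' genomes, so stops are expected occasionally and are not an error.
#'
#' @param codons character matrix, rows = taxa (rownames required), columns =
#'   aligned codons (3-character strings; `---` for a gap).
#' @param source_cds_ids provenance identifiers.
#' @param source_len_nt length in nt of the source CDS before column
#'   filtering (used by the concatenation length threshold).
#' @return a `codon_alignment`: `taxa`, `codons`, `n_codons`,
#'   `source_cds_ids`, `source_len_nt`, `n_dropped_columns`.
#' @export
codon_alignment <- function(codons, source_cds_ids = character(),
                            source_len_nt = 3L * ncol(codons)) {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  tab <- codon_tables()
  ok <- apply(codons, 2, function(col)
    all(col %in% tab$codons))
  dropped <- sum(!ok)
  codons <- codons[, ok, drop = FALSE]
  structure(list(taxa = rownames(codons), codons = codons,
                 n_codons = ncol(codons), source_cds_ids = source_cds_ids,
                 source_len_nt = source_len_nt,
                 n_dropped_columns = dropped),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment: %d taxa x %d codons (%d columns dropped)>\n",
              length(x$taxa), x$n_codons, x$n_dropped_columns))
  invisible(x)
}

#' Extract the novel-CDS codon alignment for one species-specific start call
#'
#' Slices the human novel CDS (both start codons excluded) into codons and
#' reads the orthologous chimpanzee and gorilla bases through the alignment
#' columns, in human-transcript orientation. Codon columns with a gap, `N`,
#' or stop in any taxon are dropped with a count.
#'
#' @param call an hss_call with `novel_cds_len_nt >= 3` and `in_frame`.
#' @param human_tx the human `transcript_model` of the call.
#' @param human_genome named human genome.
#' @param chimp_lookup,gorilla_lookup [ortholog_lookup()]s of the one-to-one
#'   blocks against chimp and gorilla.
#' @return a `codon_alignment` with taxa human, chimpanzee, gorilla, or
#'   `NULL` (with a message) when no complete codon column survives.
#' @export
extract_novel_cds_alignment <- function(call, human_tx, human_genome,
                                        chimp_lookup, gorilla_lookup) {
  if (is.na(call$novel_cds_len_nt) || call$novel_cds_len_nt < 3L) return(NULL)
  seq <- tx_sequence(human_tx, human_genome)
  t0 <- call$hssc_tpos + 3L
  t1 <- call$hasc_tpos - 1L
  tpos <- seq.int(t0, t1)
  gpos <- tx_to_genome(human_tx, tpos)
  fetch <- function(lookup) {
    vapply(gpos, function(p) {
      o <- orth_at(lookup, human_tx$contig, p)
      if (is.null(o)) NA_character_ else o$q_char
    }, character(1))
  }
  hchar <- strsplit(seq, "", fixed = TRUE)[[1]][tpos]
  cchar <- fetch(chimp_lookup)
  gchar <- fetch(gorilla_lookup)
  if (human_tx$strand == "-") {  # lookup chars are forward-strand
    cchar <- ifelse(is.na(cchar), NA, complement_base(cchar))
    gchar <- ifelse(is.na(gchar), NA, complement_base(gchar))
  }
  n_cod <- length(tpos) %/% 3L
  tocodons <- function(ch) {
    ch[is.na(ch)] <- "-"
    vapply(seq_len(n_cod), function(k)
      paste(ch[(3 * k - 2):(3 * k)], collapse = ""), character(1))
  }
  m <- rbind(human = tocodons(hchar), chimpanzee = tocodons(cchar),
             gorilla = tocodons(gchar))
  aln <- codon_alignment(m, source_cds_ids = call$transcript_id,
                         source_len_nt = call$novel_cds_len_nt)
  if (aln$n_codons < 1L) {
    message("no complete codon column for ", call$transcript_id,
            "; alignment skipped")
    return(NULL)
  }
  aln
}

#' Concatenate codon alignments above a source-length threshold
#'
#' Keeps alignments whose source CDS is strictly longer than `min_len_nt`
#' and concatenates their columns; provenance is preserved.
#'
#' @param alignments list of `codon_alignment`s with identical taxa order.
#' @param min_len_nt strict lower bound on source CDS length (default 15).
#' @return a single `codon_alignment`.
#' @export
concatenate_alignments <- function(alignments, min_len_nt = 15L) {
  keep <- Filter(function(a) a$source_len_nt > min_len_nt, alignments)
  if (!length(keep)) stop("no alignment longer than ", min_len_nt, " nt")
  taxa <- keep[[1]]$taxa
  for (a in keep) stopifnot(identical(a$taxa, taxa))
  m <- do.call(cbind, lapply(keep, `[[`, "codons"))
  rownames(m) <- taxa
  dropped <- sum(vapply(keep, `[[`, 0L, "n_dropped_columns"))
  out <- codon_alignment(m,
    source_cds_ids = unlist(lapply(keep, `[[`, "source_cds_ids")),
    source_len_nt = sum(vapply(keep, `[[`, 0L, "source_len_nt")))
  out$n_dropped_columns <- dropped
  out
}

# site patterns: list(patt = 3 x npat 0-based codon index matrix, wt)
codon_patterns <- function(aln) {
  tab <- codon_tables()
  idx <- matrix(match(aln$codons, tab$codons) - 1L, nrow = length(aln$taxa))
  key <- apply(idx, 2, paste, collapse = ",")
  uk <- unique(key)
  patt <- idx[, match(uk, key), drop = FALSE]
  wt <- as.numeric(table(key)[uk])
  list(patt = patt, wt = wt)
}

#' Log-likelihood of a codon alignment under a branch model
#'
#' Felsenstein pruning on the unrooted 3-taxon star tree: the likelihood of
#' each column is the sum over root states of the root frequency times the
#' product of branch transition probabilities; columns are independent.
#'
#' @param aln a `codon_alignment` (3 taxa).
#' @param kappa transition/transversion ratio.
#' @param omegas numeric vector of one omega per taxon/branch, in
#'   `aln$taxa` order.
#' @param tvec branch lengths in expected substitutions per codon, in
#'   `aln$taxa` order.
#' @param pi codon frequencies (61).
#' @return log-likelihood.
#' @export
codon_log_likelihood <- function(aln, kappa, omegas, tvec, pi) {
  stopifnot(length(omegas) == length(aln$taxa),
            length(tvec) == length(aln$taxa))
  tab <- codon_tables()
  cp <- codon_patterns(aln)
  .codon_loglik_cpp(pi, kappa, omegas, tvec, cp$patt, cp$wt,
                    tab$single_diff * 1L, tab$is_transition * 1L,
                    tab$is_synonymous * 1L)
}

#' Branch transition probability matrix of the codon model
#'
#' @param kappa,omega,pi model parameters (see [build_rate_matrix()]).
#' @param t branch length in expected substitutions per codon.
#' @return 61 x 61 stochastic matrix.
#' @export
codon_pmatrix <- function(kappa, omega, pi, t) {
  tab <- codon_tables()
  P <- .codon_pmat_cpp(pi, kappa, omega, t, tab$single_diff * 1L,
                       tab$is_transition * 1L, tab$is_synonymous * 1L)
  dimnames(P) <- list(tab$codons, tab$codons)
  P
}

#' Fit a codon branch model by maximum likelihood
#'
#' Maximises the pruning log-likelihood over kappa, the background omega,
#' an optional independent foreground omega on one branch, and the three
#' branch lengths, using bounded quasi-Newton optimisation on log-scale
#' parameters from a deterministic grid of starting points. Codon
#' frequencies are fixed from the data (F3x4) or uniform.
#'
#' @param aln a `codon_alignment` with at least 2 codon columns.
#' @param foreground `"none"` for a single shared omega, or one of the taxa
#'   names for a branch-specific foreground omega.
#' @param pi_method `"f3x4"` (default) or `"uniform"`.
#' @param n_starts number of starting points (default 5).
#' @param control passed to [stats::optim()].
#' @return a `kaks_fit`: `log_likelihood`, `kappa`, `omega0`, `omega1`
#'   (`NA` when `foreground == "none"`), `branch_lengths`, `foreground`,
#'   `pi`, `convergence`, `n_params`.
#' @export
fit_codon_model <- function(aln, foreground = c("none", "human",
                                                "chimpanzee", "gorilla"),
                            pi_method = c("f3x4", "uniform"), n_starts = 5L,
                            control = list()) {
  foreground <- match.arg(foreground)
  pi_method <- match.arg(pi_method)
  if (aln$n_codons < 2L) stop("need at least 2 codon columns")
  stopifnot(foreground == "none" || foreground %in% aln$taxa)
  pi <- if (pi_method == "f3x4") f3x4_frequencies(aln)
        else uniform_codon_frequencies()
  tab <- codon_tables()
  cp <- codon_patterns(aln)
  single <- tab$single_diff * 1L; tsm <- tab$is_transition * 1L
  syn <- tab$is_synonymous * 1L
  nb <- length(aln$taxa)
  has_fg <- foreground != "none"
  fg_idx <- if (has_fg) match(foreground, aln$taxa) else 0L
  unpack <- function(par) {
    kappa <- exp(par[1]); om0 <- exp(par[2])
    k <- 2L
    om1 <- NA_real_
    if (has_fg) { k <- 3L; om1 <- exp(par[3]) }
    tvec <- exp(par[(k + 1):(k + nb)])
    omegas <- rep(om0, nb)
    if (has_fg) omegas[fg_idx] <- om1
    list(kappa = kappa, omega0 = om0, omega1 = om1, omegas = omegas,
         tvec = tvec)
  }
  nll <- function(par) {
    p <- unpack(par)
    -.codon_loglik_cpp(pi, p$kappa, p$omegas, p$tvec, cp$patt, cp$wt,
                       single, tsm, syn)
  }
  # data-informed branch-length start: mean pairwise codon difference
  pdiff <- mean(vapply(seq_len(nb), function(i)
    mean(aln$codons[i, ] != aln$codons[(i %% nb) + 1L, ]), 0))
  t0 <- max(0.02, pdiff)
  base <- c(log(2), log(0.5), if (has_fg) log(0.5), rep(log(t0), nb))
  jitter_grid <- list(
    numeric(length(base)),
    c(0, log(4), if (has_fg) 0, rep(0, nb)),
    c(0, log(0.2), if (has_fg) log(4), rep(log(0.3), nb)),
    c(log(2), 0, if (has_fg) log(0.2), rep(log(3), nb)),
    c(-log(2), log(2), if (has_fg) log(2), rep(0, nb)))
  starts <- lapply(jitter_grid[seq_len(min(n_starts, length(jitter_grid)))],
                   function(j) base + j)
  lb <- c(log(1e-3), log(1e-4), if (has_fg) log(1e-4), rep(log(1e-6), nb))
  ub <- c(log(100), log(50), if (has_fg) log(50), rep(log(20), nb))
  # explore every start at loose tolerance, then polish the best one
  loose <- utils::modifyList(list(maxit = 200L, factr = 1e10), control)
  tight <- utils::modifyList(list(maxit = 500L, factr = 1e5), control)
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, nll, method = "L-BFGS-B", lower = lb,
                            upper = ub, control = loose), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("codon model optimisation failed on all starts")
  polished <- try(stats::optim(best$par, nll, method = "L-BFGS-B", lower = lb,
                               upper = ub, control = tight), silent = TRUE)
  if (!inherits(polished, "try-error") && polished$value <= best$value)
    best <- polished
  p <- unpack(best$par)
  structure(list(log_likelihood = -best$value, kappa = p$kappa,
                 omega0 = p$omega0, omega1 = p$omega1,
                 branch_lengths = stats::setNames(p$tvec, aln$taxa),
                 foreground = foreground, pi = pi,
                 pi_method = pi_method,
                 convergence = best$convergence,
                 n_params = length(best$par)),
            class = "kaks_fit")
}

#' @export
print.kaks_fit <- function(x, ...) {
  cat(sprintf("<kaks_fit fg=%s lnL=%.4f kappa=%.3f omega0=%.3f%s>\n",
              x$foreground, x$log_likelihood, x$kappa, x$omega0,
              if (!is.na(x$omega1)) sprintf(" omega1=%.3f", x$omega1) else ""))
  invisible(x)
}

#' Likelihood-ratio test of nested codon branch models
#'
#' @param null_fit,alt_fit `kaks_fit`s; the null must be nested in the
#'   alternative with one fewer omega parameter.
#' @param tol tolerance for a slightly negative statistic caused by
#'   optimisation round-off (default 1e-4); larger deficits error.
#' @return list `statistic`, `df`, `p_value`, `null_fit`, `alt_fit`.
#' @export
codon_lrt <- function(null_fit, alt_fit, tol = 1e-4) {
  stat <- 2 * (alt_fit$log_likelihood - null_fit$log_likelihood)
  if (stat < -tol) stop("alternative fit worse than null: optimiser failure")
  stat <- max(stat, 0)
  df <- alt_fit$n_params - null_fit$n_params
  stopifnot(df == 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       null_fit = null_fit, alt_fit = alt_fit)
}

#' Simulate a codon alignment on the 3-taxon star tree
#'
#' The root codon is drawn from `pi`; each tip evolves independently under
#' its branch-specific transition matrix. Rates into stop codons are zero by
#' construction, so no stop ever appears.
#'
#' @param tvec named branch lengths (taxa names become alignment rows).
#' @param kappa transition/transversion ratio.
#' @param omegas per-branch omega, same order as `tvec`.
#' @param pi codon frequencies (61).
#' @param n_codons number of independent columns.
#' @return a `codon_alignment`.
#' @export
simulate_codon_alignment <- function(tvec, kappa, omegas, pi, n_codons) {
  tab <- codon_tables()
  taxa <- names(tvec)
  stopifnot(!is.null(taxa), length(omegas) == length(tvec))
  root <- sample.int(61, n_codons, replace = TRUE, prob = pi)
  m <- matrix("", nrow = length(taxa), ncol = n_codons,
              dimnames = list(taxa, NULL))
  for (b in seq_along(tvec)) {
    P <- codon_pmatrix(kappa, omegas[b], pi, tvec[b])
    tip <- integer(n_codons)
    for (r in unique(root)) {
      sel <- root == r
      tip[sel] <- sample.int(61, sum(sel), replace = TRUE, prob = P[r, ])
    }
    m[b, ] <- tab$codons[tip]
  }
  codon_alignment(m)
}
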