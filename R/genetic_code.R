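# Cached structural tables for the 61 sense codons of the standard code.
.codon_env <- new.env(parent = emptyenv())

#' Structural tables of the standard genetic code
#'
#' Returns (and caches) the 61 sense codons with, for every ordered codon
#' pair differing at exactly one position, whether the change is a
#' transition and whether it is synonymous. These tables parameterise the
#' Goldman-Yang style rate matrix.
#'
#' @return list: `codons` (61 codon strings), `aa` (amino acids),
#'   `single_diff`, `is_transition`, `is_synonymous` (61 x 61 logical
#'   matrices; the latter two only meaningful where `single_diff`).
#' @export
codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  nuc <- c("T", "C", "A", "G")
  codons64 <- apply(expand.grid(n3 = nuc, n2 = nuc, n1 = nuc)[, 3:1], 1, paste,
                    collapse = "")
  gc <- Biostrings::GENETIC_CODE[codons64]
  sense <- gc != "*"
  codons <- codons64[sense]
  aa <- unname(gc[sense])
  n <- length(codons)
  mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  single <- matrix(FALSE, n, n); ts <- matrix(FALSE, n, n)
  syn <- matrix(FALSE, n, n)
  for (p in 1:3) {
    same_other <- matrix(TRUE, n, n)
    for (q in setdiff(1:3, p))
      same_other <- same_other & outer(mat[, q], mat[, q], "==")
    diff_p <- outer(mat[, p], mat[, p], "!=")
    hit <- same_other & diff_p
    single[hit] <- TRUE
    tr <- outer(purine[mat[, p]], purine[mat[, p]], "==")
    ts[hit] <- tr[hit]
  }
  syn <- outer(aa, aa, "==")
  diag(single) <- FALSE
  tab <- list(codons = codons, aa = aa, single_diff = single,
              is_transition = ts, is_synonymous = syn)
  .codon_env$tab <- tab
  tab
}

#' Goldman-Yang style codon substitution rate matrix
#'
#' Off-diagonal rates for codon pairs differing at one position are
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]`; pairs differing at
#' more than one position get rate zero. Rows sum to zero and the matrix is
#' scaled so the expected number of substitutions per codon per unit branch
#' length is one. States with zero frequency are restricted out of the
#' support (zero rates, excluded from the scaling).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi codon frequencies over the 61 sense codons (sums to 1).
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61,
            abs(sum(pi) - 1) < 1e-8, all(pi >= 0))
  tab <- codon_tables()
  Q <- matrix(0, 61, 61, dimnames = list(tab$codons, tab$codons))
  Q[tab$single_diff] <- 1
  Q[tab$single_diff & tab$is_transition] <- kappa
  Q[tab$single_diff & !tab$is_synonymous] <-
    Q[tab$single_diff & !tab$is_synonymous] * omega
  Q <- sweep(Q, 2, pi, "*")
  Q[pi == 0, ] <- 0    # support restriction
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate > 0) Q <- Q / rate
  Q
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies (with a 0.5 pseudocount per
#' nucleotide so no codon gets probability zero), multiplied across the three
#' codon positions, stop codons removed, renormalised over the 61 sense
#' codons.
#'
#' @param aln a `codon_alignment`.
#' @return numeric vector of 61 frequencies named by codon.
#' @export
f3x4_frequencies <- function(aln) {
  tab <- codon_tables()
  nuc <- c("T", "C", "A", "G")
  cod <- as.vector(aln$codons)
  m <- do.call(rbind, strsplit(cod, "", fixed = TRUE))
  f <- sapply(1:3, function(p) {
    cnt <- table(factor(m[, p], levels = nuc)) + 0.5
    as.numeric(cnt / sum(cnt))
  })
  rownames(f) <- nuc
  cm <- do.call(rbind, strsplit(tab$codons, "", fixed = TRUE))
  pi <- f[cm[, 1], 1] * f[cm[, 2], 2] * f[cm[, 3], 3]
  pi <- pi / sum(pi)
  stats::setNames(pi, tab$codons)
}

#' Uniform frequencies over the 61 sense codons
#' @export
uniform_codon_frequencies <- function() {
  tab <- codon_tables()
  stats::setNames(rep(1 / 61, 61), tab$codons)
}
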