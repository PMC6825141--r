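## Goldman-Yang (GY94) codon substitution machinery shared by the
## branch-site likelihood and the codon-alignment simulator.

#' Sense-codon tables for the standard genetic code
#'
#' Returns the 61 sense codons (stops excluded), their encoded amino acids,
#' and a 61 x 61 integer matrix classifying every ordered single-nucleotide
#' codon change: 0 = not reachable in one step, 1 = synonymous transversion,
#' 2 = synonymous transition, 3 = nonsynonymous transversion,
#' 4 = nonsynonymous transition. Cached after first call.
#'
#' @return list with `codons` (character 61), `aa` (character 61),
#'   `kind` (integer 61 x 61 matrix).
#' @export
codon_tables <- function() {
  if (!is.null(.tauselect_env$codon_tables)) return(.tauselect_env$codon_tables)
  bases <- c("T", "C", "A", "G")
  # canonical nested order: first base slowest
  all64 <- character(64)
  i <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1L
    all64[i] <- paste0(b1, b2, b3)
  }
  gc <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc[all64])
  sense <- aa64 != "*"
  codons <- all64[sense]
  aa <- aa64[sense]
  n <- length(codons)
  stopifnot(n == 61L)
  cmat <- do.call(rbind, strsplit(codons, ""))
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  kind <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    diffs <- cmat[rep(i, n), , drop = FALSE] != cmat
    ndiff <- rowSums(diffs)
    one <- which(ndiff == 1L)
    for (j in one) {
      pos <- which(diffs[j, ])
      ts <- is_transition(cmat[i, pos], cmat[j, pos])
      syn <- aa[i] == aa[j]
      kind[i, j] <- if (syn && ts) 2L else if (syn) 1L
        else if (ts) 4L else 3L
    }
  }
  dimnames(kind) <- list(codons, codons)
  out <- list(codons = codons, aa = aa, kind = kind)
  .tauselect_env$codon_tables <- out
  out
}

#' Unscaled GY94 instantaneous rate matrix
#'
#' Off-diagonal rates for codons i -> j differing at one position:
#' `pi_j` (synonymous transversion), `kappa * pi_j` (synonymous transition),
#' `omega * pi_j` (nonsynonymous transversion), `omega * kappa * pi_j`
#' (nonsynonymous transition); zero for multi-nucleotide changes. Rows sum
#' to zero. No rate normalization is applied here (see
#' [bs_scale_factor()]).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi stationary codon frequencies over the 61 sense codons (sums to 1).
#' @return 61 x 61 rate matrix.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L, all(pi > 0))
  ct <- codon_tables()
  mult <- c(1, kappa, omega, omega * kappa)
  Q <- matrix(0, 61L, 61L, dimnames = dimnames(ct$kind))
  nz <- ct$kind > 0L
  Q[nz] <- mult[ct$kind[nz]] * rep(pi, each = 61L)[nz]
  diag(Q) <- -rowSums(Q)
  Q
}

# Mean substitution rate at stationarity of the unscaled matrix.
gy94_rate <- function(kappa, omega, pi) {
  -sum(pi * diag(gy94_rate_matrix(kappa, omega, pi)))
}

#' Joint scale factor for branch-site rate matrices
#'
#' All class matrices (background and foreground) are divided by the
#' class-proportion-weighted mean background rate, so a branch length of 1
#' equals one expected substitution per codon on background branches.
#'
#' @param kappa,pi as in [gy94_rate_matrix()].
#' @param omega0 purifying-class omega in (0, 1].
#' @param props length-4 class proportions (p0, p1, p2a, p2b).
#' @return positive scalar.
#' @export
bs_scale_factor <- function(kappa, omega0, props, pi) {
  r0 <- gy94_rate(kappa, omega0, pi)
  r1 <- gy94_rate(kappa, 1, pi)
  (props[1] + props[3]) * r0 + (props[2] + props[4]) * r1
}

#' Branch-site model A site-class proportions
#'
#' From the free parameters `p0`, `p1` derives
#' `p2a = (1 - p0 - p1) * p0 / (p0 + p1)` and
#' `p2b = (1 - p0 - p1) * p1 / (p0 + p1)`.
#'
#' @param p0,p1 non-negative with `p0 + p1 <= 1` and `p0 + p1 > 0`.
#' @return named numeric of length 4 summing to 1.
#' @export
bs_class_props <- function(p0, p1) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 > 0, p0 + p1 <= 1 + 1e-12)
  rest <- max(0, 1 - p0 - p1)
  p2a <- rest * p0 / (p0 + p1)
  p2b <- rest * p1 / (p0 + p1)
  c(p0 = p0, p1 = p1, p2a = p2a, p2b = p2b)
}

# omega per class on background / foreground branches.
# classes: 0 -> (w0, w0); 1 -> (1, 1); 2a -> (w0, w2); 2b -> (1, w2)
bs_class_omegas <- function(omega0, omega2) {
  list(background = c(omega0, 1, omega0, 1),
       foreground = c(omega0, 1, omega2, omega2))
}

#' Eigendecomposition of a reversible GY94 generator
#'
#' Exploits reversibility: `S = D Q D^-1` with `D = diag(sqrt(pi))` is
#' symmetric, so `P(t) = A exp(Lambda t) B` with `A = D^-1 V`,
#' `B = t(V) D`. Numerically stable for all t.
#'
#' @param Q rate matrix from [gy94_rate_matrix()] (optionally pre-scaled).
#' @param pi its stationary distribution.
#' @return list `(A, B, lambda)`.
#' @export
gy94_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(A = es$vectors / d, B = t(es$vectors) * rep(d, each = length(d)),
       lambda = es$values)
}

#' Transition probability matrix from a cached eigendecomposition
#'
#' @param eig result of [gy94_eigen()].
#' @param t branch length (>= 0), on the scale of the decomposed generator.
#' @param normalize if TRUE, clamp small negative entries at 0 and renormalize
#'   rows to sum to exactly 1 (used by the simulator).
#' @return 61 x 61 stochastic matrix.
#' @export
gy94_pmat <- function(eig, t, normalize = FALSE) {
  stopifnot(t >= 0)
  P <- eig$A %*% (exp(eig$lambda * t) * eig$B)
  P[P < 0] <- 0
  if (normalize) P <- P / rowSums(P)
  P
}

#' Codon frequency models estimated from an alignment
#'
#' `equal`: 1/61 each. `F1x4`: codon frequency proportional to the product of
#' overall nucleotide frequencies at its three positions. `F3x4`: product of
#' position-specific nucleotide frequencies. Stop codons are excluded and the
#' result renormalized; frequencies are bounded away from zero.
#'
#' @param aln named character vector of aligned codon sequences (gaps `-`
#'   allowed), or NULL for `model = "equal"`.
#' @param model one of "F1x4", "equal", "F3x4".
#' @param floor minimum frequency before renormalization.
#' @return numeric length 61, names = sense codons, summing to 1.
#' @export
codon_frequencies <- function(aln = NULL, model = c("F1x4", "equal", "F3x4"),
                              floor = 1e-4) {
  model <- match.arg(model)
  ct <- codon_tables()
  if (model == "equal") {
    return(setNames(rep(1 / 61, 61), ct$codons))
  }
  stopifnot(!is.null(aln))
  chars <- strsplit(toupper(paste(aln, collapse = "")), "")[[1]]
  keep <- chars %in% c("A", "C", "G", "T")
  pos <- ((seq_along(chars) - 1L) %% 3L) + 1L
  cmat <- do.call(rbind, strsplit(ct$codons, ""))
  if (model == "F1x4") {
    f <- table(factor(chars[keep], levels = c("A", "C", "G", "T")))
    f <- as.numeric(f) / sum(f)
    names(f) <- c("A", "C", "G", "T")
    pi <- f[cmat[, 1]] * f[cmat[, 2]] * f[cmat[, 3]]
  } else {
    pi <- rep(1, 61)
    for (p in 1:3) {
      fp <- table(factor(chars[keep & pos == p], levels = c("A", "C", "G", "T")))
      fp <- as.numeric(fp) / sum(fp)
      names(fp) <- c("A", "C", "G", "T")
      pi <- pi * fp[cmat[, p]]
    }
  }
  pi <- pmax(as.numeric(pi), floor)
  setNames(pi / sum(pi), ct$codons)
}

# Map aligned codon sequences to a taxa x sites matrix of sense-codon
# indices (1..61); NA for gapped/ambiguous codons. Internal stop codons in
# fully resolved codons are an error.
codon_index_matrix <- function(aln) {
  ct <- codon_tables()
  lens <- unique(nchar(aln))
  if (length(lens) != 1L) stop("aligned sequences differ in length")
  if (lens %% 3L != 0L) stop("alignment length not divisible by 3")
  nsites <- lens %/% 3L
  out <- matrix(NA_integer_, length(aln), nsites,
                dimnames = list(names(aln), NULL))
  for (i in seq_along(aln)) {
    s <- toupper(aln[[i]])
    cods <- substring(s, 3L * seq_len(nsites) - 2L, 3L * seq_len(nsites))
    idx <- match(cods, ct$codons)
    resolved <- !grepl("[^ACGT]", cods)
    if (any(resolved & is.na(idx))) {
      stop("internal stop codon in sequence '", names(aln)[i], "' at codon ",
           which(resolved & is.na(idx))[1])
    }
    idx[!resolved] <- NA_integer_
    out[i, ] <- idx
  }
  out
}
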