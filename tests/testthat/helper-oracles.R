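# Independent oracles used to validate the implementation. Each is written
# from first principles (definitions, enumeration, closed forms) and shares
# no code path with the functions it checks.

# N50 by definition: the length at which the cumulative sum of descending
# lengths first reaches half the total.
oracle_n50 <- function(lens) {
  sl <- sort(lens, decreasing = TRUE)
  half <- sum(as.numeric(lens)) / 2
  acc <- 0
  for (l in sl) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# Exclusive intersection counts by full 2^k enumeration of subsets.
oracle_intersections <- function(prof) {
  k <- ncol(prof)
  tissues <- colnames(prof)
  out <- list()
  for (mask in 1:(2^k - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(k - 1))))
    cnt <- 0
    for (g in seq_len(nrow(prof))) {
      if (all(prof[g, ] == sel)) cnt <- cnt + 1
    }
    if (cnt > 0) {
      out[[paste(tissues[sel], collapse = "+")]] <- cnt
    }
  }
  out
}

# Hypergeometric upper tail P(X >= k) by explicit choose() summation.
oracle_hyper_tail <- function(k, K, N, n) {
  tot <- 0
  for (x in k:min(n, K)) {
    tot <- tot + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  tot
}

# Two-sample KS D by a direct ECDF sweep over the pooled support.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), 0)))
}

# Best hit per query by a per-query scan applying the tie-break chain.
oracle_best_hits <- function(hits) {
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    h <- h[h$e_value == min(h$e_value), , drop = FALSE]
    h <- h[h$bit_score == max(h$bit_score), , drop = FALSE]
    h <- h[order(h$subject_id), , drop = FALSE]
    out[[q]] <- h[1, ]
  }
  do.call(rbind, out)
}

# Exhaustive branch-site log-likelihood by enumeration of all internal-node
# codon assignments, with transition matrices from Matrix::expm and the rate
# matrix rebuilt from Biostrings::GENETIC_CODE.
oracle_branch_site_lnL <- function(aln, tree, params) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("T", "C", "A", "G")
  all64 <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    all64 <- c(all64, paste0(b1, b2, b3))
  }
  codons <- all64[gc[all64] != "*"]
  aa <- unname(gc[codons])
  pi <- params$pi[codons]
  pi <- pi / sum(pi)
  ts_pair <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  cm <- do.call(rbind, strsplit(codons, ""))
  Qof <- function(kappa, omega) {
    Q <- matrix(0, 61, 61)
    for (i in 1:61) for (j in 1:61) {
      if (i == j) next
      d <- which(cm[i, ] != cm[j, ])
      if (length(d) != 1) next
      Q[i, j] <- pi[j] * (if (ts_pair(cm[i, d], cm[j, d])) kappa else 1) *
        (if (aa[i] != aa[j]) omega else 1)
    }
    diag(Q) <- -rowSums(Q)
    Q
  }
  p0 <- params$p0; p1 <- params$p1
  props <- c(p0, p1, (1 - p0 - p1) * p0 / (p0 + p1),
             (1 - p0 - p1) * p1 / (p0 + p1))
  Q0 <- Qof(params$kappa, params$omega0)
  Q1 <- Qof(params$kappa, 1)
  sc <- (props[1] + props[3]) * (-sum(pi * diag(Q0))) +
    (props[2] + props[4]) * (-sum(pi * diag(Q1)))
  Qs <- list(Q0 / sc, Q1 / sc, Qof(params$kappa, params$omega2) / sc)
  bg <- c(1, 2, 1, 2); fg <- c(1, 2, 3, 3)
  tr <- ape::reorder.phylo(tree, "postorder")
  fgn <- attr(tree, "foreground")
  ntip <- length(tr$tip.label)
  E <- tr$edge; L <- tr$edge.length
  internals <- unique(E[, 1])
  m <- length(internals)
  grid <- as.matrix(expand.grid(rep(list(1:61), m)))
  colnames(grid) <- as.character(internals)
  root <- E[nrow(E), 1]
  nsites <- nchar(aln[[1]]) / 3
  obs <- sapply(tr$tip.label, function(tp) {
    cods <- substring(toupper(aln[[tp]]), 3 * (1:nsites) - 2, 3 * (1:nsites))
    match(cods, codons)  # NA for gaps/ambiguity
  })
  obs <- matrix(obs, nrow = nsites, dimnames = list(NULL, tr$tip.label))
  lnL <- 0
  Pcls <- lapply(1:4, function(cl) {
    lapply(seq_len(nrow(E)), function(e) {
      w <- if (!is.na(fgn) && E[e, 2] == fgn) fg[cl] else bg[cl]
      as.matrix(Matrix::expm(Qs[[w]] * L[e]))
    })
  })
  for (s in 1:nsites) {
    tot <- 0
    for (cl in 1:4) {
      if (props[cl] == 0) next
      pr <- pi[grid[, as.character(root)]]
      for (e in seq_len(nrow(E))) {
        from <- grid[, as.character(E[e, 1])]
        child <- E[e, 2]
        if (child <= ntip) {
          oc <- obs[s, tr$tip.label[child]]
          if (is.na(oc)) next  # missing tip data: message is 1
          pr <- pr * Pcls[[cl]][[e]][cbind(from, oc)]
        } else {
          pr <- pr * Pcls[[cl]][[e]][cbind(from, grid[, as.character(child)])]
        }
      }
      tot <- tot + props[cl] * sum(pr)
    }
    lnL <- lnL + log(tot)
  }
  lnL
}

# Random gap-free codon alignment (sense codons only), uniform over codons.
random_codon_alignment <- function(taxa, n_codons) {
  ct <- codon_tables()
  setNames(vapply(taxa, function(t) {
    paste(sample(ct$codons, n_codons, replace = TRUE), collapse = "")
  }, ""), taxa)
}
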