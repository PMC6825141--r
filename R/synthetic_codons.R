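## Simulation of codon alignments under the branch-site site-class model,
## plus the 9-leaf fixture tree used throughout tests and examples.

#' Symmetric 9-leaf fixture tree with a tagged foreground terminal branch
#'
#' A balanced 8-leaf core plus an outgroup; terminal branches 0.1, internal
#' branches 0.05, and a longer (0.3) focal terminal branch tagged as the
#' branch-site foreground. Branch lengths are expected substitutions per
#' codon on background branches.
#'
#' @param foreground tip carrying the `#1` tag (default `t1`).
#' @param fg_length length of the foreground terminal branch.
#' @return `phylo` with attribute `foreground` (see [read_tree()]).
#' @export
fixture_tree <- function(foreground = "t1", fg_length = 0.3) {
  nwk <- paste0("((((t1:0.1,t2:0.1):0.05,(t3:0.1,t4:0.1):0.05):0.05,",
                "((t5:0.1,t6:0.1):0.05,(t7:0.1,t8:0.1):0.05):0.05):0.05,",
                "t9:0.2);")
  tr <- read_tree(nwk)
  i <- match(foreground, tr$tip.label)
  if (is.na(i)) stop("unknown foreground tip: ", foreground)
  tr$edge.length[tr$edge[, 2] == i] <- fg_length
  attr(tr, "foreground") <- i
  tr
}

#' Specification for the branch-site codon-alignment simulator
#'
#' Parameterizes branch-site model A: site classes 0 (omega0 everywhere),
#' 1 (neutral everywhere), 2a (omega0 background, omega2 foreground) and
#' 2b (neutral background, omega2 foreground) with proportions
#' `(p0, p1, p2a, p2b)` derived from `p0`, `p1` (see [bs_class_props()]).
#'
#' @param tree `phylo` with a tagged foreground branch (required when
#'   `omega2 != 1`); e.g. [fixture_tree()].
#' @param kappa transition/transversion ratio (> 0), default 2.
#' @param omega0 purifying omega in (0, 1], default 0.2.
#' @param omega2 foreground omega (>= 1) of classes 2a/2b; 1 simulates the
#'   null model.
#' @param p0,p1 free class proportions, defaults 0.7 / 0.15.
#' @param pi codon frequencies over the 61 sense codons (default uniform);
#'   must be strictly positive and is checked against stop-codon entries.
#' @param n_codons alignment length in codons, default 300.
#' @param rng_seed mandatory integer seed.
#' @return object of class `codon_sim_spec`.
#' @export
codon_sim_spec <- function(tree, kappa = 2, omega0 = 0.2, omega2 = 4,
                           p0 = 0.7, p1 = 0.15, pi = NULL, n_codons = 300,
                           rng_seed = 1L) {
  ct <- codon_tables()
  if (is.null(pi)) pi <- setNames(rep(1 / 61, 61), ct$codons)
  if (!is.null(names(pi))) {
    stops <- setdiff(names(pi), ct$codons)
    if (length(stops)) stop("pi contains stop-codon entries: ",
                            paste(stops, collapse = ", "))
    pi <- pi[ct$codons]
  }
  stopifnot(length(pi) == 61, all(pi > 0), abs(sum(pi) - 1) < 1e-8,
            kappa > 0, omega0 > 0, omega0 <= 1, omega2 >= 1,
            p0 >= 0, p1 >= 0, p0 + p1 <= 1, p0 + p1 > 0, n_codons >= 1)
  if (omega2 != 1 && is.na(attr(tree, "foreground"))) {
    stop("omega2 != 1 requires a tagged foreground branch")
  }
  props <- bs_class_props(p0, p1)
  stopifnot(all(props >= 0), abs(sum(props) - 1) < 1e-12)
  structure(list(tree = tree, kappa = kappa, omega0 = omega0, omega2 = omega2,
                 p0 = p0, p1 = p1, pi = setNames(as.numeric(pi), ct$codons),
                 n_codons = as.integer(n_codons),
                 rng_seed = as.integer(rng_seed)),
            class = "codon_sim_spec")
}

#' Simulate a codon alignment under the branch-site model
#'
#' Per site a class is drawn from `(p0, p1, p2a, p2b)`; the root codon is
#' drawn from `pi`; evolution along each branch uses transition probabilities
#' `exp(Q t)` where Q carries the class- and branch-role-appropriate omega.
#' Matrix exponentials are computed once per (branch, omega) pair and cached;
#' each P(t) has rows summing to 1 within 1e-10 before row renormalization.
#' Only sense codons are ever emitted. Deterministic given the seed.
#'
#' @param spec a [codon_sim_spec()].
#' @return list with `alignment` (named character vector, gap-free, length
#'   `3 * n_codons`) and `site_classes` (character vector in
#'   `c("0","1","2a","2b")`).
#' @export
simulate_codon_alignment <- function(spec) {
  stopifnot(inherits(spec, "codon_sim_spec"))
  set.seed(spec$rng_seed)
  ct <- codon_tables()
  tr <- ape::reorder.phylo(spec$tree, "postorder")
  fg_node <- attr(spec$tree, "foreground")
  nt <- length(tr$tip.label)
  nnode <- nt + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  props <- bs_class_props(spec$p0, spec$p1)
  omg <- bs_class_omegas(spec$omega0, spec$omega2)
  scale <- bs_scale_factor(spec$kappa, spec$omega0, props, spec$pi)
  eigs <- lapply(unique(c(omg$background, omg$foreground)), function(w) {
    gy94_eigen(gy94_rate_matrix(spec$kappa, w, spec$pi) / scale, spec$pi)
  })
  names(eigs) <- as.character(unique(c(omg$background, omg$foreground)))
  pcache <- new.env(parent = emptyenv())
  getP <- function(len, w) {
    key <- paste0(format(len, digits = 15), "|", w)
    if (is.null(pcache[[key]])) {
      P <- gy94_pmat(eigs[[as.character(w)]], len, normalize = FALSE)
      if (max(abs(rowSums(P) - 1)) > 1e-10) {
        stop("transition matrix rows deviate from 1 beyond tolerance")
      }
      pcache[[key]] <- P / rowSums(P)
    }
    pcache[[key]]
  }
  nsites <- spec$n_codons
  classes <- sample(4L, nsites, replace = TRUE, prob = props)
  states <- matrix(NA_integer_, nnode, nsites)
  states[root, ] <- sample.int(61L, nsites, replace = TRUE, prob = spec$pi)
  # preorder = reversed postorder edge sweep
  for (e in rev(seq_len(nrow(tr$edge)))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    role <- if (!is.na(fg_node) && child == fg_node) "foreground" else "background"
    len <- tr$edge.length[e]
    for (cl in 1:4) {
      sel <- which(classes == cl)
      if (!length(sel)) next
      P <- getP(len, omg[[role]][cl])
      ps <- states[parent, sel]
      for (s in unique(ps)) {
        ss <- sel[ps == s]
        states[child, ss] <- sample.int(61L, length(ss), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  aln <- vapply(seq_len(nt), function(i) {
    paste(ct$codons[states[i, ]], collapse = "")
  }, "")
  names(aln) <- tr$tip.label
  list(alignment = aln, site_classes = c("0", "1", "2a", "2b")[classes])
}
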