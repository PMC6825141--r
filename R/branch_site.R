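## Branch-site positive-selection machinery: codon-column masking,
## Felsenstein-pruning log-likelihood under branch-site model A, maximum-
## likelihood fitting of null/alternative, the LRT, and the two-aligner scan.

#' Mask gap-ridden codon columns of an alignment
#'
#' Codon columns whose per-column gap fraction (fraction of taxa with any
#' gap character in the codon) exceeds `max_gap_fraction` are removed; runs
#' of surviving columns shorter than `min_block_codons` consecutive codons
#' are then removed as well. Output length stays divisible by 3.
#'
#' @param aln named character vector of aligned codon sequences.
#' @param max_gap_fraction maximum tolerated gap fraction per codon column
#'   (default 0: strict).
#' @param min_block_codons minimum surviving block length in codons.
#' @return masked alignment (named character vector) with attribute
#'   `kept_codons` (indices of retained codon columns).
#' @export
mask_alignment <- function(aln, max_gap_fraction = 0, min_block_codons = 5) {
  stopifnot(length(aln) >= 2, max_gap_fraction >= 0, max_gap_fraction <= 1,
            min_block_codons >= 1)
  lens <- unique(nchar(aln))
  if (length(lens) != 1L || lens %% 3L != 0L) {
    stop("alignment rows must share a length divisible by 3")
  }
  nsites <- lens %/% 3L
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  gapped <- matrix(FALSE, length(aln), nsites)
  for (p in 1:3) {
    gapped <- gapped | (m[, 3L * seq_len(nsites) - 3L + p, drop = FALSE] == "-")
  }
  gapfrac <- colMeans(gapped)
  keep <- gapfrac <= max_gap_fraction
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block_codons] <- FALSE
  keep <- inverse.rle(r)
  if (!any(keep)) stop("no columns survive masking")
  cols <- as.vector(outer(1:3, 3L * (which(keep) - 1L), "+"))
  cols <- sort(cols)
  out <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(aln)
  structure(out, kept_codons = which(keep))
}

# Pattern-compress a codon index matrix: returns list(idx = taxa x npat,
# weights = pattern multiplicities).
compress_patterns <- function(codidx) {
  key <- apply(codidx, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(idx = codidx[, first, drop = FALSE], weights = w)
}

#' Branch-site model A log-likelihood
#'
#' GY94-style codon model with four site classes: 0 (omega0 on all
#' branches), 1 (neutral), 2a (omega0 background / omega2 foreground),
#' 2b (neutral background / omega2 foreground). Rate matrices are jointly
#' scaled so the class-proportion-weighted mean background rate at
#' stationarity is 1. The per-site likelihood is the class-proportion
#' mixture of Felsenstein-pruning likelihoods; gapped or ambiguous codons
#' contribute a unit partial likelihood (missing data). Under the null,
#' omega2 is fixed at 1.
#'
#' @param aln named character vector of aligned codon sequences; all taxa
#'   must appear in the tree.
#' @param tree `phylo` with exactly one tagged foreground branch
#'   (attribute `foreground`; see [read_tree()]).
#' @param params list with `kappa`, `omega0`, `omega2`, `p0`, `p1`, `pi`
#'   (61 sense-codon frequencies).
#' @param null if TRUE, `omega2` is overridden to 1.
#' @param edge_lengths optional replacement branch lengths (ordered as the
#'   postorder edge matrix of the tree); defaults to the tree's own.
#' @return total log-likelihood (numeric scalar).
#' @export
branch_site_lnL <- function(aln, tree, params, null = FALSE,
                            edge_lengths = NULL) {
  ctx <- bs_context(aln, tree)
  bs_lnL_core(ctx, params, null = null, edge_lengths = edge_lengths)
}

# Precompute everything that does not depend on model parameters:
# postorder tree, foreground node, compressed site patterns.
bs_context <- function(aln, tree) {
  fg_node <- attr(tree, "foreground")
  if (is.null(fg_node) || is.na(fg_node)) {
    stop("tree must carry exactly one foreground branch tag")
  }
  if (!all(names(aln) %in% tree$tip.label) ||
      !all(tree$tip.label %in% names(aln))) {
    stop("alignment taxa and tree tips do not match")
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  codidx <- codon_index_matrix(aln[tr$tip.label])
  list(tr = tr, fg_node = fg_node, ntip = length(tr$tip.label),
       root = tr$edge[nrow(tr$edge), 1],
       pats = compress_patterns(codidx))
}

bs_lnL_core <- function(ctx, params, null = FALSE, edge_lengths = NULL) {
  omega2 <- if (null) 1 else params$omega2
  stopifnot(params$kappa > 0, params$omega0 > 0, params$omega0 <= 1,
            omega2 >= 1)
  pi <- params$pi
  stopifnot(length(pi) == 61, all(pi > 0))
  pi <- pi / sum(pi)
  tr <- ctx$tr
  ntip <- ctx$ntip
  root <- ctx$root
  fg_node <- ctx$fg_node
  pats <- ctx$pats
  elen <- if (is.null(edge_lengths)) tr$edge.length else edge_lengths
  stopifnot(length(elen) == nrow(tr$edge), all(elen >= 0))
  props <- bs_class_props(params$p0, params$p1)
  codidx0 <- pats$idx
  codidx0[is.na(codidx0)] <- 0L
  lnL <- bs_lnL_cpp(ctx$tr$edge, elen, ntip, root,
                    if (is.na(fg_node)) 0L else fg_node,
                    codidx0, pats$weights, codon_tables()$kind,
                    params$kappa, params$omega0, omega2,
                    unname(props), unname(pi))
  if (!is.finite(lnL)) {
    stop("non-finite likelihood (degenerate parameters or data)")
  }
  lnL
}

# Transform helpers: proportions (p0, p1) <-> unconstrained (x1, x2).
props_to_x <- function(p0, p1) {
  p2 <- max(1 - p0 - p1, 1e-8)
  c(log(max(p0, 1e-8) / p2), log(max(p1, 1e-8) / p2))
}
x_to_props <- function(x1, x2) {
  e1 <- exp(x1)
  e2 <- exp(x2)
  s <- 1 + e1 + e2
  c(p0 = e1 / s, p1 = e2 / s)
}

#' Maximum-likelihood fit of the branch-site model
#'
#' Optimizes `kappa`, `omega0`, the class proportions and (under the
#' alternative) `omega2 >= 1` on transformed scales with a bounded
#' quasi-Newton routine (`nlminb`), with seeded random restarts. Branch
#' lengths are handled per `branch_mode`: `"scale"` (default) re-optimizes a
#' global scale factor of the input branch lengths plus the foreground
#' branch length under each hypothesis; `"fixed"` keeps them as supplied;
#' `"full"` frees every branch length.
#'
#' @param aln,tree as in [branch_site_lnL()].
#' @param null fit the null (omega2 = 1) instead of the alternative.
#' @param freq codon-frequency model (see [codon_frequencies()]).
#' @param branch_mode one of "scale", "fixed", "full".
#' @param restarts number of seeded random restarts (>= 1).
#' @param seed integer seed controlling restart jitter.
#' @param control passed to `nlminb`.
#' @param init optional named numeric vector of transformed starting values
#'   (names as in the fit's `par`); used to warm-start, e.g. the alternative
#'   from the null MLE.
#' @return list with `lnL`, `params` (kappa, omega0, omega2, p0, p1, pi),
#'   `edge_lengths`, `par` (transformed MLE vector), `convergence`
#'   (0 = converged), `restart_lnLs`.
#' @export
branch_site_fit <- function(aln, tree, null = FALSE,
                            freq = c("F1x4", "equal", "F3x4"),
                            branch_mode = c("scale", "fixed", "full"),
                            restarts = 2, seed = 1L,
                            control = list(iter.max = 200, eval.max = 400,
                                           rel.tol = 1e-8),
                            init = NULL) {
  freq <- match.arg(freq)
  branch_mode <- match.arg(branch_mode)
  pi <- codon_frequencies(aln, model = freq)
  ctx <- bs_context(aln, tree)
  tr <- ctx$tr
  fg_edge <- which(tr$edge[, 2] == ctx$fg_node)
  base_len <- tr$edge.length
  nedge <- length(base_len)

  build <- function(theta) {
    kappa <- exp(theta[["lkappa"]])
    omega0 <- exp(theta[["lomega0"]])
    pr <- x_to_props(theta[["x1"]], theta[["x2"]])
    omega2 <- if (null) 1 else 1 + exp(theta[["lomega2m1"]])
    elen <- switch(branch_mode,
      fixed = base_len,
      scale = {
        el <- base_len * exp(theta[["lscale"]])
        el[fg_edge] <- exp(theta[["lfg"]])
        el
      },
      full = exp(theta[paste0("lb", seq_len(nedge))]))
    list(params = list(kappa = kappa, omega0 = omega0, omega2 = omega2,
                       p0 = unname(pr[1]), p1 = unname(pr[2]), pi = pi),
         elen = elen)
  }
  objective <- function(theta) {
    b <- build(theta)
    -tryCatch(bs_lnL_core(ctx, b$params, null = null, edge_lengths = b$elen),
              error = function(e) -Inf)
  }

  # bounds keep the search inside the numerically distinguishable region:
  # p-ratios within e^16, omega2 within [1.0005, 100]
  start0 <- c(lkappa = log(2), lomega0 = log(0.5),
              x1 = props_to_x(0.75, 0.15)[1], x2 = props_to_x(0.75, 0.15)[2])
  lower <- c(lkappa = log(0.05), lomega0 = log(1e-3), x1 = -8, x2 = -8)
  upper <- c(lkappa = log(50), lomega0 = 0, x1 = 8, x2 = 8)
  if (!null) {
    start0 <- c(start0, lomega2m1 = log(0.5))
    lower <- c(lower, lomega2m1 = log(5e-4))
    upper <- c(upper, lomega2m1 = log(99))
  }
  if (branch_mode == "scale") {
    start0 <- c(start0, lscale = 0,
                lfg = log(max(base_len[fg_edge], 1e-4)))
    lower <- c(lower, lscale = -4, lfg = log(1e-6))
    upper <- c(upper, lscale = 4, lfg = log(10))
  } else if (branch_mode == "full") {
    bl <- log(pmax(base_len, 1e-4))
    names(bl) <- paste0("lb", seq_len(nedge))
    start0 <- c(start0, bl)
    lower <- c(lower, setNames(rep(log(1e-6), nedge), names(bl)))
    upper <- c(upper, setNames(rep(log(10), nedge), names(bl)))
  }

  if (!is.null(init)) {
    common <- intersect(names(init), names(start0))
    start0[common] <- pmin(pmax(init[common], lower[common]), upper[common])
  }
  set.seed(as.integer(seed))
  best <- NULL
  lnLs <- numeric(0)
  for (r in seq_len(max(1, restarts))) {
    st <- start0
    if (r > 1) {
      jit <- rnorm(length(st), 0, 0.5)
      st <- pmin(pmax(st + jit, lower), upper)
    }
    fit <- tryCatch(nlminb(st, objective, lower = lower, upper = upper,
                           control = control),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    lnLs <- c(lnLs, -fit$objective)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(list(lnL = NA_real_, params = NULL, edge_lengths = NULL,
                par = NULL, convergence = 1L, restart_lnLs = lnLs))
  }
  b <- build(best$par)
  list(lnL = -best$objective, params = b$params, edge_lengths = b$elen,
       par = best$par, convergence = best$convergence, restart_lnLs = lnLs)
}

#' Branch-site likelihood-ratio test for positive selection
#'
#' Fits the null (omega2 fixed at 1) and the alternative (omega2 free,
#' >= 1, warm-started from the null fit), forms
#' `LRT = 2 (lnL_alt - lnL_null)` clamped at 0, and computes the p-value
#' from a chi-squared reference with 1 df (default, conservative) or the
#' 1:1 mixture of a point mass at 0 and chi-squared(1).
#'
#' @param aln,tree as in [branch_site_lnL()].
#' @param p_reference "chisq1" (default) or "mixture".
#' @inheritParams branch_site_fit
#' @return list of class `branch_site_result`: `lnL_null`, `lnL_alt`,
#'   `lrt`, `p_value`, `mle_null`, `mle_alt`, `converged`.
#' @export
branch_site_test <- function(aln, tree, freq = c("F1x4", "equal", "F3x4"),
                             branch_mode = c("scale", "fixed", "full"),
                             restarts = 2, seed = 1L,
                             p_reference = c("chisq1", "mixture")) {
  freq <- match.arg(freq)
  branch_mode <- match.arg(branch_mode)
  p_reference <- match.arg(p_reference)
  fit0 <- branch_site_fit(aln, tree, null = TRUE, freq = freq,
                          branch_mode = branch_mode, restarts = restarts,
                          seed = seed)
  # warm-start the alternative from the null MLE, with omega2 near 1
  init1 <- if (!is.null(fit0$par)) c(fit0$par, lomega2m1 = log(0.5)) else NULL
  fit1 <- branch_site_fit(aln, tree, null = FALSE, freq = freq,
                          branch_mode = branch_mode, restarts = restarts,
                          seed = seed + 1L, init = init1)
  converged <- isTRUE(fit0$convergence == 0) && isTRUE(fit1$convergence == 0) &&
    is.finite(fit0$lnL) && is.finite(fit1$lnL)
  lrt <- if (is.finite(fit0$lnL) && is.finite(fit1$lnL)) {
    max(0, 2 * (fit1$lnL - fit0$lnL))
  } else NA_real_
  p <- if (is.na(lrt)) NA_real_ else if (p_reference == "chisq1") {
    pchisq(lrt, df = 1, lower.tail = FALSE)
  } else {
    if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  structure(list(lnL_null = fit0$lnL, lnL_alt = fit1$lnL, lrt = lrt,
                 p_value = p,
                 mle_null = fit0$params, mle_alt = fit1$params,
                 converged = converged),
            class = "branch_site_result")
}

#' Two-aligner positive-selection scan with FDR control
#'
#' Runs the branch-site test per gene on each aligner variant's masked
#' alignment, applies Benjamini-Hochberg FDR within each variant, and
#' reports the intersection of the significant sets — genes significant
#' under both alignment programs. Genes missing one variant are excluded
#' and listed in `skipped`.
#'
#' @param alignments_by_variant named list (one element per aligner variant)
#'   of named lists of alignments (gene -> alignment).
#' @param trees named list of tagged gene trees (gene -> `phylo`).
#' @param q_max FDR threshold (default 0.05).
#' @param ... passed to [branch_site_test()].
#' @return list with `selected` (gene ids significant in every variant),
#'   `tables` (per-variant data.frames: gene, lnL_null, lnL_alt, lrt, p, q,
#'   omega2_hat, converged), `skipped`.
#' @export
selection_scan <- function(alignments_by_variant, trees, q_max = 0.05, ...) {
  stopifnot(length(alignments_by_variant) >= 1)
  variants <- names(alignments_by_variant)
  genes_all <- lapply(alignments_by_variant, names)
  genes <- Reduce(intersect, genes_all)
  genes <- intersect(genes, names(trees))
  skipped <- setdiff(unique(unlist(genes_all)), genes)
  tables <- list()
  sig <- NULL
  for (v in variants) {
    rows <- lapply(genes, function(g) {
      res <- branch_site_test(alignments_by_variant[[v]][[g]], trees[[g]], ...)
      data.frame(gene = g, lnL_null = res$lnL_null, lnL_alt = res$lnL_alt,
                 lrt = res$lrt, p = res$p_value,
                 omega2_hat = if (!is.null(res$mle_alt)) res$mle_alt$omega2 else NA_real_,
                 converged = res$converged, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- p.adjust(tab$p, method = "BH")
    tables[[v]] <- tab
    vs <- tab$gene[!is.na(tab$q) & tab$q < q_max]
    sig <- if (is.null(sig)) vs else intersect(sig, vs)
  }
  list(selected = sort(sig), tables = tables, skipped = sort(skipped))
}
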