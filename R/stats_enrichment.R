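## Overrepresentation and comparative statistics: hypergeometric GO
## enrichment with BH FDR, Spearman correlation (asymptotic or permutation),
## bootstrap group comparison, one-way ANOVA with Tukey HSD.

#' GO term overrepresentation (one-sided hypergeometric test)
#'
#' For every term annotated to at least `min_genes` study genes, computes
#' the hypergeometric upper-tail probability `P(X >= k)` of drawing `k`
#' study hits in a study set of size `n` given `K` background hits among
#' `N` background genes, then Benjamini-Hochberg-adjusts across tested
#' terms.
#'
#' @param study_genes character vector (must be a subset of the background).
#' @param background_genes character vector of background gene ids.
#' @param gene2terms data.frame with columns `gene`, `term` (flat labels;
#'   no ontology propagation is performed).
#' @param min_genes minimum study hits for a term to be tested (default 3).
#' @return data.frame sorted by `q` then `p`: `term`, `k` (study hits),
#'   `n` (study size), `K` (background hits), `N` (background size),
#'   `p`, `q`.
#' @export
go_overrepresentation <- function(study_genes, background_genes, gene2terms,
                                  min_genes = 3) {
  stopifnot(all(c("gene", "term") %in% colnames(gene2terms)),
            nrow(gene2terms) > 0, min_genes >= 1)
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  off <- setdiff(study_genes, background_genes)
  if (length(off)) {
    stop("study genes absent from background: ", paste(off, collapse = ", "))
  }
  g2t <- unique(gene2terms[gene2terms$gene %in% background_genes,
                           c("gene", "term")])
  N <- length(background_genes)
  n <- length(study_genes)
  Ktab <- table(g2t$term)
  ktab <- table(g2t$term[g2t$gene %in% study_genes])
  terms <- names(ktab)[ktab >= min_genes]
  if (!length(terms)) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  k <- as.integer(ktab[terms])
  K <- as.integer(Ktab[terms])
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N, p = p,
                    q = p.adjust(p, method = "BH"), stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with asymptotic or permutation p-value
#'
#' Ranks use average ties; rho is the Pearson correlation of the ranks.
#' The asymptotic p-value uses the t approximation with n - 2 df; the
#' permutation p-value counts seeded shuffles of `y` with `|rho*| >= |rho|`
#' (add-one correction).
#'
#' @param x,y equal-length numeric vectors (n >= 3), neither constant.
#' @param method "asymptotic" (default) or "permutation".
#' @param n_perm number of permutations.
#' @param seed integer seed (permutation method).
#' @return list with `rho` and `p_value`.
#' @export
spearman <- function(x, y, method = c("asymptotic", "permutation"),
                     n_perm = 9999, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("rho undefined for a constant vector")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (method == "asymptotic") {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  } else {
    set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(cor(rx, sample(ry))) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(rho = rho, p_value = min(p, 1))
}

#' Bootstrap comparison of two groups of values
#'
#' Resamples each group with replacement `B` times; reports group means,
#' percentile 95% confidence intervals, the CI of the mean difference, and
#' a two-sided bootstrap p-value
#' `2 * min(frac(diff* <= 0), frac(diff* >= 0))`, floored at `2/B` and
#' capped at 1. Bit-reproducible under a fixed seed.
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return list of class `bootstrap_comparison`: `mean_a`, `mean_b`,
#'   `ci_a`, `ci_b`, `diff`, `ci_diff`, `p_value`, `B`, `seed`.
#' @export
bootstrap_compare <- function(values_a, values_b, B = 10000, seed = 1L) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1, B >= 2)
  set.seed(as.integer(seed))
  na <- length(values_a)
  nb <- length(values_b)
  ma <- colMeans(matrix(values_a[sample.int(na, na * B, replace = TRUE)], na, B))
  mb <- colMeans(matrix(values_b[sample.int(nb, nb * B, replace = TRUE)], nb, B))
  d <- ma - mb
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  p <- min(max(p, 2 / B), 1)
  structure(list(mean_a = mean(values_a), mean_b = mean(values_b),
                 ci_a = unname(quantile(ma, c(0.025, 0.975))),
                 ci_b = unname(quantile(mb, c(0.025, 0.975))),
                 diff = mean(values_a) - mean(values_b),
                 ci_diff = unname(quantile(d, c(0.025, 0.975))),
                 p_value = p, B = B, seed = as.integer(seed)),
            class = "bootstrap_comparison")
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values numeric response.
#' @param group_labels grouping factor/character of the same length; at
#'   least 2 groups with at least 2 values each.
#' @return list with `F`, `df` (c(between, within)), `p_value`, and `tukey`
#'   (data.frame: comparison, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, group_labels) {
  g <- factor(group_labels)
  stopifnot(length(values) == length(g))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  fit <- aov(values ~ g)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = s[["F value"]][1], df = c(s[["Df"]][1], s[["Df"]][2]),
       p_value = s[["Pr(>F)"]][1], tukey = tukey)
}
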