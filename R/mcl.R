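## Markov clustering of an all-vs-all similarity graph and the single-copy
## ortholog filter.

#' Build a similarity graph from weighted edges
#'
#' Nodes are arbitrary ids (for orthology, `"species|gene"`). Self-edges are
#' dropped; duplicate/reciprocal edges keep the maximum weight; weights are
#' capped (e-value 0 convention: `-log10(e)` capped at 200).
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (> 0).
#' @param nodes optional extra node ids (isolated nodes allowed).
#' @param cap weight cap.
#' @return list of class `similarity_graph` with `nodes` and `edges`.
#' @export
similarity_graph <- function(edges, nodes = NULL, cap = 200) {
  stopifnot(all(c("from", "to", "weight") %in% colnames(edges)))
  if (nrow(edges) && any(edges$weight <= 0)) stop("edge weights must be > 0")
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges$weight <- pmin(edges$weight, cap)
  if (nrow(edges)) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste(a, b, sep = "\r")
    w <- tapply(edges$weight, key, max)
    uk <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(uk, `[`, "", 1),
                        to = vapply(uk, `[`, "", 2),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' Convert BLAST hits between species to a similarity graph
#'
#' Edge weight is `-log10(e_value)` capped at `cap`; non-positive weights
#' (e >= 1) are dropped. Node ids are `"species|gene"`.
#'
#' @param hits data.frame with `query_id`, `subject_id`, `e_value`.
#' @param species_of named character vector mapping sequence id -> species.
#' @param cap weight cap (default 200).
#' @return `similarity_graph`.
#' @export
blast_to_graph <- function(hits, species_of, cap = 200) {
  qs <- species_of[hits$query_id]
  ss <- species_of[hits$subject_id]
  if (anyNA(qs) || anyNA(ss)) stop("sequence id missing from species_of")
  w <- -log10(pmax(hits$e_value, 10^(-cap)))
  keep <- w > 0
  similarity_graph(data.frame(from = paste(qs, hits$query_id, sep = "|")[keep],
                              to = paste(ss, hits$subject_id, sep = "|")[keep],
                              weight = w[keep], stringsAsFactors = FALSE),
                   nodes = paste(species_of, names(species_of), sep = "|"),
                   cap = cap)
}

#' Markov clustering (MCL)
#'
#' Canonical MCL on the column-stochastic similarity matrix: self-loops set
#' to each node's maximum incident weight (1 for isolated nodes), then
#' alternating expansion (matrix squaring) and inflation (elementwise power,
#' pruning of entries below `prune`, column renormalization) until the matrix
#' changes by less than `tol` or `max_iter` is reached. Clusters are the
#' connected components of the limit matrix's support; the result does not
#' depend on node input order.
#'
#' @param graph a [similarity_graph()].
#' @param inflation inflation exponent (> 1), default 1.5.
#' @param prune entries below this are zeroed each iteration.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the max absolute change.
#' @return list of clusters (character vectors of node ids), ordered by
#'   decreasing size then lexicographically.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, prune = 1e-5,
                        max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(graph, "similarity_graph"), inflation > 1)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) return(list())
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Mexp <- M %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    dead <- cs == 0
    if (any(dead)) {  # pruning removed a whole column: restore its maximum
      mx <- apply(Mexp[, dead, drop = FALSE], 2, which.max)
      Minf[cbind(mx, which(dead))] <- 1
      cs[dead] <- 1
    }
    Mnew <- sweep(Minf, 2, cs, "/")
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) break
  }
  S <- (M > 0) | (t(M) > 0)
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- which(S[u, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  cl <- split(nodes, comp)
  cl <- lapply(cl, sort)
  ord <- order(-lengths(cl), vapply(cl, `[`, "", 1))
  unname(cl[ord])
}

#' Keep only single-copy ortholog groups
#'
#' Retains groups with exactly one member per required species and no other
#' members (node ids `"species|gene"`).
#'
#' @param groups list of clusters from [mcl_cluster()].
#' @param required_species character vector of species that must each
#'   contribute exactly one gene.
#' @param sep species/gene separator in node ids.
#' @return filtered list of groups.
#' @export
single_copy_filter <- function(groups, required_species, sep = "|") {
  stopifnot(length(required_species) >= 1)
  keep <- vapply(groups, function(g) {
    sp <- sub(paste0("\\", sep, ".*$"), "", g)
    length(g) == length(required_species) &&
      setequal(sp, required_species) && !anyDuplicated(sp)
  }, TRUE)
  groups[keep]
}
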