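## Expression profiling: TPM quantification, presence/absence calls,
## level bins, exclusive tissue intersections, per-tissue unique genes.

#' Convert a count matrix to transcripts per million (TPM)
#'
#' `TPM_g = 1e6 * (c_g / L_g) / sum_h (c_h / L_h)`, per tissue column.
#' Every column of the result sums to 1e6.
#'
#' @param counts genes x tissues matrix of non-negative counts.
#' @param lengths positive gene lengths (bp), one per row of `counts`; a
#'   named vector is matched to rownames.
#' @return genes x tissues TPM matrix.
#' @export
to_tpm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) {
    stop("need one gene length per row of the count matrix")
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be positive")
  }
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("tissue column with no mapped reads: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Call tissue presence/absence
#'
#' A gene is present in a tissue iff its TPM is at least `threshold`
#' (values strictly below the threshold are absent).
#'
#' @param expr TPM matrix (genes x tissues).
#' @param threshold presence threshold, default 1 TPM.
#' @return logical matrix of the same shape.
#' @export
presence <- function(expr, threshold = 1) {
  stopifnot(threshold > 0)
  expr >= threshold
}

#' Bin expression levels of present cells
#'
#' Present cells are classed `low` (presence threshold up to but excluding
#' the first edge), `medium` (inclusive between the edges), or `high`
#' (strictly above the second edge); absent cells are `absent`. Defaults:
#' low [1, 10), medium [10, 50], high (50, Inf).
#'
#' @param expr TPM matrix.
#' @param presence_threshold TPM at or above which a cell is present.
#' @param edges two increasing bin edges; both edges fall in `medium`.
#' @return character matrix with values in
#'   `c("absent", "low", "medium", "high")`.
#' @export
bin_levels <- function(expr, presence_threshold = 1, edges = c(10, 50)) {
  stopifnot(length(edges) == 2, edges[1] < edges[2],
            presence_threshold <= edges[1])
  out <- matrix("absent", nrow(expr), ncol(expr), dimnames = dimnames(expr))
  out[expr >= presence_threshold] <- "low"
  out[expr >= edges[1]] <- "medium"
  out[expr > edges[2]] <- "high"
  out
}

#' Exclusive tissue-set intersections (UpSet-style counts)
#'
#' Each gene present in at least one tissue is counted in exactly one
#' subset: its exact presence pattern. Counts over all patterns therefore
#' sum to the number of present genes.
#'
#' @param prof logical presence matrix (genes x tissues) from [presence()].
#' @return data.frame with `tissues` (pattern label, tissue names joined by
#'   `+` in column order), `degree` (pattern size) and `count`, sorted by
#'   decreasing count.
#' @export
exclusive_intersections <- function(prof) {
  stopifnot(is.logical(prof), ncol(prof) >= 1)
  tissues <- colnames(prof)
  somewhere <- rowSums(prof) > 0
  pm <- prof[somewhere, , drop = FALSE]
  key <- apply(pm, 1, function(r) paste(tissues[r], collapse = "+"))
  tab <- table(key)
  out <- data.frame(tissues = names(tab),
                    degree = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$tissues), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-tissue ranked lists of uniquely expressed genes
#'
#' Genes present in exactly one tissue, ranked by TPM in that tissue
#' (descending; ties broken by gene id).
#'
#' @param prof logical presence matrix.
#' @param expr matching TPM matrix.
#' @param top_n maximum genes per tissue (>= 1).
#' @return named list (one element per tissue) of data.frames with `gene`
#'   and `tpm`.
#' @export
unique_genes <- function(prof, expr, top_n = 10) {
  stopifnot(top_n >= 1, identical(dim(prof), dim(expr)))
  uniq <- rowSums(prof) == 1
  out <- list()
  for (j in seq_len(ncol(prof))) {
    sel <- which(uniq & prof[, j])
    if (length(sel)) {
      g <- rownames(expr)[sel]
      v <- expr[sel, j]
      ord <- order(-v, g)
      take <- head(ord, top_n)
      out[[colnames(prof)[j]]] <- data.frame(gene = g[take], tpm = unname(v[take]),
                                             stringsAsFactors = FALSE)
    } else {
      out[[colnames(prof)[j]]] <- data.frame(gene = character(),
                                             tpm = numeric(),
                                             stringsAsFactors = FALSE)
    }
  }
  out
}
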