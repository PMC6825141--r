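## Steroidogenic-pathway panel: per-gene expression/specificity report,
## stagewise specificity trend, and 17bHSD isoform clustering.

#' Default steroidogenic panel configuration
#'
#' Ordered pathway stages — steroid synthesis (StAR, P450scc, CYP17,
#' 3bHSD1), later conversion (SRD5A1, SRD5A2, AROM) and receptor binding
#' (AR, ESR1, ESR2, GPER1) — plus the 17bHSD isoform list kept separate
#' because isoform function is uncertain. A case-insensitive synonym map
#' reconciles common aliases (e.g. AROM = CYP19A1).
#'
#' @param stages named list of gene-symbol vectors in pathway order.
#' @param isoforms 17bHSD isoform symbols.
#' @param synonyms named character vector mapping alias -> panel symbol,
#'   merged with the built-in map.
#' @return list of class `panel_config`.
#' @export
panel_config <- function(stages = list(
                           synthesis = c("StAR", "P450scc", "CYP17", "3bHSD1"),
                           conversion = c("SRD5A1", "SRD5A2", "AROM"),
                           receptor = c("AR", "ESR1", "ESR2", "GPER1")),
                         isoforms = c("17bHSD1", "17bHSD2", "17bHSD4",
                                      "17bHSD7", "17bHSD8", "17bHSD12",
                                      "17bHSD13"),
                         synonyms = NULL) {
  builtin <- c(STAR = "StAR", CYP11A1 = "P450scc", CYP17A1 = "CYP17",
               HSD3B1 = "3bHSD1", CYP19A1 = "AROM", NR3C4 = "AR",
               GPR30 = "GPER1")
  syn <- c(synonyms, builtin)
  syn <- syn[!duplicated(toupper(names(syn)))]
  all_symbols <- unlist(stages, use.names = FALSE)
  if (anyDuplicated(toupper(all_symbols))) stop("duplicate panel symbols")
  structure(list(stages = stages, isoforms = isoforms, synonyms = syn),
            class = "panel_config")
}

# Case-insensitive symbol lookup honoring the synonym map; returns row
# indices into `ids` (NA where absent).
match_symbols <- function(symbols, ids, synonyms) {
  up_ids <- toupper(ids)
  hit <- match(toupper(symbols), up_ids)
  alias_for <- function(sym) names(synonyms)[toupper(synonyms) == toupper(sym)]
  for (i in which(is.na(hit))) {
    al <- alias_for(symbols[i])
    if (length(al)) {
      m <- match(toupper(al), up_ids)
      m <- m[!is.na(m)]
      if (length(m)) hit[i] <- m[1]
    }
  }
  hit
}

#' Steroidogenic panel expression/specificity report
#'
#' Joins per-tissue TPM and tau for every panel gene; symbols missing from
#' the expression matrix are reported with `missing = TRUE` rather than
#' dropped. Per-stage mean tau is computed over present genes.
#'
#' @param expr TPM matrix (genes x tissues).
#' @param tau_records data.frame from [tau_table()] covering `expr`'s genes.
#' @param config a [panel_config()].
#' @return list of class `panel_report`: `genes` (data.frame with stage,
#'   symbol, missing, tau, max_tissue and one column per tissue),
#'   `stage_tau` (stage, n_present, mean_tau).
#' @export
panel_profile <- function(expr, tau_records, config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  stage_names <- names(config$stages)
  rows <- list()
  for (si in seq_along(config$stages)) {
    for (sym in config$stages[[si]]) {
      idx <- match_symbols(sym, rownames(expr), config$synonyms)
      row <- data.frame(stage = stage_names[si], stage_index = si,
                        symbol = sym, missing = is.na(idx),
                        tau = NA_real_, max_tissue = NA_character_,
                        stringsAsFactors = FALSE)
      tpm <- setNames(rep(NA_real_, ncol(expr)), colnames(expr))
      if (!is.na(idx)) {
        gene_id <- rownames(expr)[idx]
        tr <- tau_records[tau_records$gene == gene_id, , drop = FALSE]
        if (nrow(tr)) {
          row$tau <- tr$tau[1]
          row$max_tissue <- tr$max_tissue[1]
        }
        tpm[] <- expr[idx, ]
      }
      rows[[length(rows) + 1L]] <- cbind(row, as.data.frame(as.list(tpm)))
    }
  }
  genes <- do.call(rbind, rows)
  stage_tau <- do.call(rbind, lapply(seq_along(stage_names), function(si) {
    v <- genes$tau[genes$stage_index == si & !genes$missing & !is.na(genes$tau)]
    data.frame(stage = stage_names[si], n_present = length(v),
               mean_tau = if (length(v)) mean(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(genes = genes, stage_tau = stage_tau), class = "panel_report")
}

#' Stagewise specificity trend
#'
#' Spearman correlation between pathway stage index and per-gene tau over
#' present panel genes: a negative rho means specificity decreases along
#' the pathway from synthesis to receptor binding.
#'
#' @param report a [panel_report()] from [panel_profile()].
#' @param ... passed to [spearman()].
#' @return list with `rho` and `p_value`.
#' @export
stage_trend <- function(report, ...) {
  stopifnot(inherits(report, "panel_report"))
  g <- report$genes[!report$genes$missing & !is.na(report$genes$tau), ]
  if (length(unique(g$stage_index)) < 2) {
    stop("need genes in at least 2 stages")
  }
  spearman(g$stage_index, g$tau, ...)
}

#' Cluster isoforms by tissue expression profile
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance) of `log2(TPM + 1)`-transformed tissue profiles, cut at `k`
#' clusters. Deterministic given input row order.
#'
#' @param expr TPM matrix restricted to the isoform rows (>= 2 rows).
#' @param k number of clusters (2 by default; must not exceed the number
#'   of isoforms).
#' @param transform "log2" (default) or "raw".
#' @param linkage linkage method for `hclust`.
#' @return list with `clusters` (named integer vector), `order`
#'   (dendrogram leaf order), `hclust`.
#' @export
cluster_isoforms <- function(expr, k = 2, transform = c("log2", "raw"),
                             linkage = "complete") {
  transform <- match.arg(transform)
  stopifnot(is.matrix(expr), nrow(expr) >= 2)
  if (k > nrow(expr)) stop("k exceeds the number of isoforms")
  m <- if (transform == "log2") base::log2(expr + 1) else expr
  hc <- hclust(dist(m, method = "euclidean"), method = linkage)
  list(clusters = cutree(hc, k = k), order = hc$order, hclust = hc)
}
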