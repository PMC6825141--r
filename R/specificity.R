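## Tissue-specificity index tau: computation, classification, housekeeping
## calibration, and per-max-tissue summaries.

#' Tissue-specificity index tau for one expression profile
#'
#' `tau = sum_i (1 - x_i / max_j x_j) / (n - 1)` after flooring every value
#' at `floor` (low/no expression is set to the floor so that sampling noise
#' in unexpressed tissues does not inflate specificity). A profile floored
#' everywhere (no tissue above the floor) returns tau = 0 with attribute
#' `no_expression = TRUE`.
#'
#' @param x per-tissue expression values (TPM), length >= 2.
#' @param floor flooring constant (default 2 TPM).
#' @param log2 if TRUE, compute tau on `log2(floored values)` instead of the
#'   raw floored values.
#' @return tau in [0, 1].
#' @export
compute_tau <- function(x, floor = 2, log2 = FALSE) {
  if (length(x) < 2L) stop("tau needs at least 2 tissues")
  if (any(is.na(x)) || any(x < 0)) stop("expression values must be >= 0")
  stopifnot(floor > 0)
  x <- pmax(x, floor)
  if (log2) x <- base::log2(x)
  mx <- max(x)
  if (mx <= if (log2) base::log2(floor) else floor) {
    return(structure(0, no_expression = TRUE))
  }
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Classify a tau value
#'
#' Broadly expressed below the lower cut-off, highly tissue-specific above
#' the upper cut-off, moderate in the inclusive band between them.
#'
#' @param tau numeric vector of tau values in [0, 1].
#' @param broad,high class cut-offs (defaults 0.3 and 0.8).
#' @return character vector in `c("broad", "moderate", "high")`.
#' @export
classify_tau <- function(tau, broad = 0.3, high = 0.8) {
  stopifnot(broad < high)
  ifelse(tau < broad, "broad", ifelse(tau > high, "high", "moderate"))
}

#' Score every gene of an expression matrix
#'
#' @param expr TPM matrix (genes x tissues).
#' @param floor,log2 passed to [compute_tau()].
#' @param broad,high passed to [classify_tau()].
#' @return data.frame with `gene`, `tau`, `max_tissue` (ties broken by
#'   column order, flagged in `max_tie`), `specificity_class`,
#'   `summed_log_expression` (= log10 of the row's total TPM + 1), and
#'   `no_expression`.
#' @export
tau_table <- function(expr, floor = 2, log2 = FALSE, broad = 0.3, high = 0.8) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  taus <- numeric(nrow(expr))
  noexp <- logical(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    t <- compute_tau(expr[i, ], floor = floor, log2 = log2)
    taus[i] <- as.numeric(t)
    noexp[i] <- isTRUE(attr(t, "no_expression"))
  }
  imax <- apply(expr, 1, which.max)
  tie <- apply(expr, 1, function(r) sum(r == max(r)) > 1L)
  data.frame(gene = rownames(expr), tau = taus,
             max_tissue = colnames(expr)[imax], max_tie = tie,
             specificity_class = classify_tau(taus, broad, high),
             summed_log_expression = log10(rowSums(expr) + 1),
             no_expression = noexp, stringsAsFactors = FALSE)
}

#' Compare two tau distributions (housekeeping calibration)
#'
#' Two-sample Kolmogorov-Smirnov test: D is the maximum absolute difference
#' between the empirical CDFs, with the asymptotic two-sided p-value. Used
#' to check the broad/high cut-offs by contrasting the most abundant unique
#' gene per tissue against housekeeping genes.
#'
#' @param tau_a,tau_b non-empty numeric vectors of tau values.
#' @return list with `D` and `p_value`.
#' @export
calibrate_cutoffs <- function(tau_a, tau_b) {
  stopifnot(length(tau_a) >= 1, length(tau_b) >= 1)
  kt <- suppressWarnings(ks.test(tau_a, tau_b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Summarize tau by the tissue of maximal expression
#'
#' Genes are grouped by `max_tissue`; per group the count `n_max`, mean tau
#' and its normal-approximation 95% confidence interval
#' (mean +/- 1.96 * SE) are reported. Group counts sum to the number of
#' scored genes.
#'
#' @param records data.frame from [tau_table()].
#' @param tissue_order optional tissue ordering for the output rows.
#' @return data.frame with `tissue`, `n_max`, `mean_tau`, `ci_lower`,
#'   `ci_upper`.
#' @export
tau_by_max_tissue <- function(records, tissue_order = NULL) {
  stopifnot(all(c("tau", "max_tissue") %in% colnames(records)))
  tissues <- if (is.null(tissue_order)) sort(unique(records$max_tissue)) else tissue_order
  rows <- lapply(tissues, function(ts) {
    v <- records$tau[records$max_tissue == ts]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    se <- if (n > 1L) sd(v) / sqrt(n) else 0
    data.frame(tissue = ts, n_max = n, mean_tau = m,
               ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
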