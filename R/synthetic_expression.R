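## Seeded generators for multi-tissue expression matrices with known
## specificity classes and for BLAST-like hit tables with known filter truth.

#' Specification for the multi-tissue expression simulator
#'
#' Defaults emulate a six-tissue bulk design (brain, blood, ovary, spleen,
#' liver, muscle; one pooled library per tissue) with three gene classes:
#' housekeeping genes expressed near-uniformly across tissues, tissue-specific
#' genes expressed in a single target tissue with at most a sub-presence
#' "leak" elsewhere, and intermediate genes expressed at moderate levels in a
#' few tissues.
#'
#' @param tissues tissue names (order defines the matrix columns).
#' @param n_housekeeping,n_tissue_specific,n_intermediate class sizes.
#' @param hk_meanlog,hk_sdlog log-normal location/scale of housekeeping
#'   baseline TPM (per gene); `hk_tissue_sdlog` is the per-tissue biological
#'   jitter on the log scale.
#' @param ts_meanlog,ts_sdlog log-normal location/scale of the on-target TPM
#'   of tissue-specific genes.
#' @param leak_tpm off-target expression of tissue-specific genes (kept below
#'   the presence threshold so these genes stay unique to their tissue).
#' @param dropout probability that an off-target tissue drops to exactly zero
#'   instead of the leak level.
#' @param int_meanlog,int_sdlog location/scale for intermediate genes;
#'   `int_tissues` is the range of tissues they occupy.
#' @param meanlog_length,sdlog_length log-normal gene-length distribution (bp).
#' @param library_size expected mapped reads per tissue.
#' @param dispersion negative-binomial dispersion of counts around their
#'   expected value (variance = mu + dispersion * mu^2); 0 gives the
#'   noise-free deterministic limit.
#' @param rng_seed mandatory integer seed.
#' @return object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(tissues = c("brain", "blood", "ovary",
                                            "spleen", "liver", "muscle"),
                                n_housekeeping = 300,
                                n_tissue_specific = 400,
                                n_intermediate = 300,
                                hk_meanlog = log(100), hk_sdlog = 0.6,
                                hk_tissue_sdlog = 0.05,
                                ts_meanlog = log(300), ts_sdlog = 0.8,
                                leak_tpm = 0.2, dropout = 0.2,
                                int_meanlog = log(50), int_sdlog = 0.7,
                                int_tissues = c(2L, 4L),
                                meanlog_length = log(1300), sdlog_length = 0.6,
                                library_size = 2e7, dispersion = 0.005,
                                rng_seed = 1L) {
  spec <- list(tissues = tissues, n_housekeeping = n_housekeeping,
               n_tissue_specific = n_tissue_specific,
               n_intermediate = n_intermediate,
               hk_meanlog = hk_meanlog, hk_sdlog = hk_sdlog,
               hk_tissue_sdlog = hk_tissue_sdlog,
               ts_meanlog = ts_meanlog, ts_sdlog = ts_sdlog,
               leak_tpm = leak_tpm, dropout = dropout,
               int_meanlog = int_meanlog, int_sdlog = int_sdlog,
               int_tissues = as.integer(int_tissues),
               meanlog_length = meanlog_length, sdlog_length = sdlog_length,
               library_size = library_size, dispersion = dispersion,
               rng_seed = as.integer(rng_seed))
  with(spec, stopifnot(length(tissues) >= 2,
                       n_housekeeping >= 0, n_tissue_specific >= 0,
                       n_intermediate >= 0,
                       hk_sdlog >= 0, ts_sdlog >= 0, int_sdlog >= 0,
                       hk_tissue_sdlog >= 0,
                       dropout >= 0, dropout <= 1, leak_tpm >= 0,
                       dispersion >= 0, library_size > 0,
                       all(int_tissues >= 1), all(int_tissues <= length(tissues))))
  if (with(spec, n_housekeeping + n_tissue_specific + n_intermediate) == 0) {
    stop("spec generates zero genes")
  }
  structure(spec, class = "expression_sim_spec")
}

#' Simulate a multi-tissue count matrix with known ground truth
#'
#' Builds an expected-abundance matrix per the spec, normalizes each tissue
#' column to an expected TPM scale (columns sum to 1e6), then draws
#' negative-binomial counts around length- and library-size-proportional
#' means. Deterministic given `spec$rng_seed`.
#'
#' @param spec an [expression_sim_spec()].
#' @return list with `counts` (genes x tissues integer matrix), `lengths`
#'   (named gene lengths, bp), `expected_tpm` (deterministic truth matrix,
#'   columns sum to 1e6), and `truth` (data.frame: gene, class, target_tissue,
#'   expected on-target TPM).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$rng_seed)
  nt <- length(spec$tissues)
  n_hk <- spec$n_housekeeping
  n_ts <- spec$n_tissue_specific
  n_int <- spec$n_intermediate
  n <- n_hk + n_ts + n_int
  genes <- sprintf("g%05d", seq_len(n))
  cls <- rep(c("housekeeping", "tissue_specific", "intermediate"),
             c(n_hk, n_ts, n_int))
  target <- rep(NA_character_, n)
  mu <- matrix(0, n, nt, dimnames = list(genes, spec$tissues))
  if (n_hk > 0) {
    base <- rlnorm(n_hk, spec$hk_meanlog, spec$hk_sdlog)
    jitter <- matrix(rlnorm(n_hk * nt, 0, spec$hk_tissue_sdlog), n_hk, nt)
    mu[seq_len(n_hk), ] <- base * jitter
  }
  leak_cells <- NULL
  if (n_ts > 0) {
    idx <- n_hk + seq_len(n_ts)
    tt <- rep_len(seq_len(nt), n_ts)  # round-robin keeps tissue totals balanced
    target[idx] <- spec$tissues[tt]
    on <- rlnorm(n_ts, spec$ts_meanlog, spec$ts_sdlog)
    off <- matrix(0, n_ts, nt)
    keepleak <- matrix(runif(n_ts * nt) >= spec$dropout, n_ts, nt)
    keepleak[cbind(seq_len(n_ts), tt)] <- FALSE
    off[cbind(seq_len(n_ts), tt)] <- on
    mu[idx, ] <- off
    leak_cells <- which(keepleak, arr.ind = TRUE)
    leak_cells[, 1] <- leak_cells[, 1] + n_hk
  }
  if (n_int > 0) {
    idx <- n_hk + n_ts + seq_len(n_int)
    for (i in seq_len(n_int)) {
      k <- sample(seq(spec$int_tissues[1], spec$int_tissues[2]), 1)
      ts <- sample(nt, k)
      mu[idx[i], ts] <- rlnorm(k, spec$int_meanlog, spec$int_sdlog)
    }
  }
  # expected TPM: per-tissue compositional normalization to 1e6. Off-target
  # leak of tissue-specific genes is pinned at leak_tpm on the final TPM
  # scale (it is specified relative to the presence threshold), then the
  # tiny leak mass is renormalized away.
  tot <- colSums(mu)
  if (any(tot == 0)) stop("a tissue has zero expected expression; enlarge spec")
  expected_tpm <- sweep(mu, 2, tot, "/") * 1e6
  if (!is.null(leak_cells) && nrow(leak_cells) && spec$leak_tpm > 0) {
    expected_tpm[leak_cells] <- spec$leak_tpm
    expected_tpm <- sweep(expected_tpm, 2, colSums(expected_tpm), "/") * 1e6
  }
  lengths <- setNames(round(rlnorm(n, spec$meanlog_length, spec$sdlog_length)) + 100,
                      genes)
  # counts: mean proportional to TPM * length, scaled to the library size
  counts <- matrix(0L, n, nt, dimnames = dimnames(mu))
  for (j in seq_len(nt)) {
    w <- expected_tpm[, j] * lengths
    m <- w / sum(w) * spec$library_size
    counts[, j] <- if (spec$dispersion > 0) {
      rnbinom(n, mu = m, size = 1 / spec$dispersion)
    } else {
      round(m)  # degenerate noise-free limit
    }
  }
  on_target <- ifelse(is.na(target), NA_real_,
                      expected_tpm[cbind(seq_len(n), match(target, spec$tissues))])
  truth <- data.frame(gene = genes, class = cls, target_tissue = target,
                      expected_on_tpm = on_target, stringsAsFactors = FALSE)
  list(counts = counts, lengths = lengths, expected_tpm = expected_tpm,
       truth = truth)
}

#' Simulate a BLAST-like hit table with known filter truth
#'
#' Draws a mixture of confident hits (high identity and coverage) and
#' spurious hits, and records for each row whether it passes the reference
#' annotation filter, so filter implementations can be checked against
#' generator bookkeeping.
#'
#' @param n_queries number of query transcripts (one hit row each).
#' @param p_good mixture weight of the confident component.
#' @param good_identity,bad_identity Beta shape pairs for identity/100 in the
#'   two components.
#' @param good_coverage,bad_coverage Beta shape pairs for coverage.
#' @param identity_min,coverage_min,e_max reference thresholds recorded in
#'   the truth.
#' @param rng_seed integer seed.
#' @return list with `hits` (data.frame in [read_blast_tab()] layout) and
#'   `truth` (data.frame: query_id, passes, plus the thresholds used);
#'   `sum(truth$passes)` is the expected retained count.
#' @export
simulate_blast_hits <- function(n_queries, p_good = 0.6,
                                good_identity = c(40, 4),
                                bad_identity = c(12, 8),
                                good_coverage = c(18, 4),
                                bad_coverage = c(3, 6),
                                identity_min = 70, coverage_min = 0.5,
                                e_max = 1e-10, rng_seed = 1L) {
  stopifnot(n_queries >= 0, p_good >= 0, p_good <= 1)
  set.seed(as.integer(rng_seed))
  good <- runif(n_queries) < p_good
  ident <- numeric(n_queries)
  cover <- numeric(n_queries)
  ident[good] <- 100 * stats::rbeta(sum(good), good_identity[1], good_identity[2])
  ident[!good] <- 100 * stats::rbeta(sum(!good), bad_identity[1], bad_identity[2])
  cover[good] <- stats::rbeta(sum(good), good_coverage[1], good_coverage[2])
  cover[!good] <- stats::rbeta(sum(!good), bad_coverage[1], bad_coverage[2])
  evalue <- 10^ifelse(good, runif(n_queries, -180, -15), runif(n_queries, -30, 1))
  slen <- pmax(50L, round(rlnorm(n_queries, log(450), 0.5)))
  alen <- pmax(10L, round(cover * slen))
  cover <- alen / slen
  qid <- sprintf("tx%05d", seq_len(max(n_queries, 0)))
  sid <- sprintf("prot%05d", sample.int(max(n_queries, 1), n_queries, replace = TRUE))
  hits <- data.frame(query_id = qid, subject_id = sid,
                     percent_identity = round(ident, 2),
                     alignment_length = alen,
                     mismatches = round(alen * (1 - ident / 100)),
                     gap_opens = 0L,
                     q_start = 1L, q_end = alen * 3L,
                     s_start = 1L, s_end = alen,
                     e_value = evalue, bit_score = round(alen * ident / 50, 1),
                     subject_length = slen,
                     subject_gene = toupper(sid),
                     stringsAsFactors = FALSE)
  hits$coverage <- hits$alignment_length / hits$subject_length
  passes <- hits$e_value < e_max &
    hits$percent_identity >= identity_min & hits$coverage >= coverage_min
  truth <- data.frame(query_id = qid, passes = passes,
                      identity_min = identity_min, coverage_min = coverage_min,
                      e_max = e_max, stringsAsFactors = FALSE)
  list(hits = hits, truth = truth)
}
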