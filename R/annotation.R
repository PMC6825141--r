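## Annotation confidence filtering, transcript->gene assignment, greedy
## redundancy collapse, and assembly summary statistics.

#' Confidence-filter BLAST hits
#'
#' Retains rows with `e_value < e_max`, `percent_identity >= identity_min`
#' and `coverage >= coverage_min` ("at least" thresholds are inclusive).
#' Idempotent; tightening any threshold can only shrink the retained set.
#'
#' @param hits data.frame from [read_blast_tab()] (needs `percent_identity`,
#'   `coverage`, `e_value`).
#' @param e_max e-value cut-off (exclusive), default 1e-10.
#' @param identity_min minimum percent identity, default 70.
#' @param coverage_min minimum subject (full-length protein) coverage,
#'   default 0.5.
#' @return filtered data.frame (possibly empty).
#' @export
filter_hits <- function(hits, e_max = 1e-10, identity_min = 70,
                        coverage_min = 0.5) {
  stopifnot(e_max > 0, identity_min >= 0, identity_min <= 100,
            coverage_min >= 0, coverage_min <= 1)
  keep <- hits$e_value < e_max &
    hits$percent_identity >= identity_min &
    !is.na(hits$coverage) & hits$coverage >= coverage_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best hit per transcript (gene assignment)
#'
#' Per query keeps the row with the lowest e-value; ties go to the highest
#' bit score, then to the lexicographically smallest subject id, so the
#' assignment is deterministic.
#'
#' @param hits filtered hit table.
#' @return data.frame, one row per query, with a `gene` column (the subject
#'   gene symbol where provided, else the subject id).
#' @export
best_hit_per_transcript <- function(hits) {
  if (nrow(hits) == 0L) {
    out <- hits
    out$gene <- character(0)
    return(out)
  }
  ord <- order(hits$query_id, hits$e_value, -hits$bit_score, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  best <- h[!duplicated(h$query_id), , drop = FALSE]
  best$gene <- ifelse(!is.na(best$subject_gene) & nzchar(best$subject_gene),
                      best$subject_gene, best$subject_id)
  rownames(best) <- NULL
  best
}

# Canonical k-mer set of a nucleotide sequence (k-mer vs its reverse
# complement, lexicographic minimum), as a character vector of distinct k-mers.
canonical_kmers <- function(seq, k = 8L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  comp <- chartr("ACGT", "TGCA", kmers)
  rc <- vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
  unique(pmin(kmers, rc))
}

# Containment identity estimate between two canonical k-mer sets:
# shared distinct k-mers over the smaller set's distinct k-mer count.
kmer_identity <- function(ka, kb) {
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Collapse largely redundant sequences by greedy clustering
#'
#' Sequences are sorted by length (descending; ties by id) and processed in
#' order: each joins the first existing cluster whose representative (the
#' cluster founder) shares estimated identity at or above the threshold,
#' otherwise it founds a new cluster. Identity is estimated by canonical
#' k-mer containment (identical sequences score exactly 1).
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param identity_threshold clustering threshold in (0, 1], default 0.95.
#' @param k k-mer size for the identity estimate.
#' @return list with `representatives` (ids of cluster founders) and
#'   `membership` (named character: sequence id -> representative id).
#' @export
collapse_redundancy <- function(seqs, identity_threshold = 0.95, k = 8L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character(0)
  rep_kmers <- list()
  membership <- character(length(seqs))
  names(membership) <- ids
  for (id in ids) {
    km <- canonical_kmers(seqs[[id]], k)
    assigned <- NA_character_
    for (r in reps) {
      if (kmer_identity(km, rep_kmers[[r]]) >= identity_threshold) {
        assigned <- r
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      rep_kmers[[id]] <- km
      assigned <- id
    }
    membership[[id]] <- assigned
  }
  list(representatives = reps, membership = membership)
}

#' Assembly summary statistics
#'
#' N50 is the length L such that contigs of length >= L cover at least half
#' of the total assembled bases (computed by sorting lengths in decreasing
#' order and scanning the cumulative sum). GC percent is computed over
#' unambiguous A/C/G/T bases only.
#'
#' @param seqs non-empty named character vector of nucleotide sequences.
#' @return list with `n`, `total_bases`, `mean_length`, `median_length`,
#'   `n50`, `gc_percent`.
#' @export
assembly_stats <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence set")
  lens <- nchar(seqs)
  sl <- sort(lens, decreasing = TRUE)
  cum <- cumsum(as.numeric(sl))
  n50 <- sl[which(cum >= cum[length(cum)] / 2)[1]]
  chars <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
  acgt <- chars[chars %in% c("A", "C", "G", "T")]
  gc <- 100 * sum(acgt %in% c("G", "C")) / length(acgt)
  list(n = length(seqs), total_bases = sum(as.numeric(lens)),
       mean_length = mean(lens), median_length = stats::median(lens),
       n50 = unname(n50), gc_percent = gc)
}
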