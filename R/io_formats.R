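## Readers/writers for every external format the pipeline touches.
## Sequence sets are plain named character vectors (ids -> sequences);
## expression tables are numeric matrices (genes x tissues); trees are
## ape "phylo" objects carrying a "foreground" attribute.

#' Read a FASTA file into a named character vector
#'
#' One element per record, names taken from the full header line (up to the
#' first whitespace), sequences uppercased with whitespace removed.
#'
#' @param path FASTA file.
#' @param alphabet optional validation: "nucleotide" restricts to IUPAC
#'   nucleotide codes plus `-`, "protein" to amino-acid codes plus `-`;
#'   "any" (default) skips validation.
#' @return named character vector (a sequence set).
#' @export
read_fasta <- function(path, alphabet = c("any", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id: ", ids[!nzchar(seqs)][1])
  }
  pat <- switch(alphabet,
                any = NULL,
                nucleotide = "[^ACGTURYSWKMBDHVN-]",
                protein = "[^ACDEFGHIKLMNPQRSTVWYBXZJUO*-]")
  if (!is.null(pat)) {
    bad <- grepl(pat, seqs)
    if (any(bad)) stop("invalid ", alphabet, " characters in: ", ids[bad][1])
  }
  setNames(seqs, ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a genes x tissues expression (or count) table
#'
#' TSV with a header row of tissue names and gene ids in the first column.
#' Columns are reordered to `tissue_order`; every tissue in `tissue_order`
#' must be present and no unknown tissues are allowed.
#'
#' @param path TSV file.
#' @param tissue_order character vector of tissue names defining column order.
#' @return numeric matrix, rownames = gene ids, colnames = `tissue_order`.
#' @export
read_expression_table <- function(path, tissue_order) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus tissues")
  genes <- as.character(df[[1]])
  tissues <- colnames(df)[-1]
  unknown <- setdiff(tissues, tissue_order)
  if (length(unknown)) {
    stop("unknown tissue in header: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(tissue_order, tissues)
  if (length(missing)) {
    stop("tissue missing from header: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(df[, tissue_order, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")  # coercion NAs handled below
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing/non-numeric value at gene '", genes[bad[1]], "', tissue '",
         tissue_order[bad[2]], "'")
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative value at gene '", genes[bad[1]], "', tissue '",
         tissue_order[bad[2]], "'")
  }
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output file.
#' @param id_column name for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, id_column = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.blast_cols <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' Read a BLAST tabular (outfmt-6-style) hit file
#'
#' Standard 12 columns; an optional 13th column is the subject (full-length
#' protein) length and an optional 14th the subject gene symbol. Coverage is
#' `alignment_length / subject_length` when a subject length is available and
#' no explicit coverage is supplied.
#'
#' @param path TSV file, no header. An empty file yields an empty table.
#' @return data.frame with the 12 standard columns plus `subject_length`,
#'   `subject_gene`, `coverage` (NA where underivable).
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), alignment_length = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      e_value = numeric(), bit_score = numeric(),
                      subject_length = numeric(), subject_gene = character(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    stop("malformed BLAST line ", which(nf < 12L)[1], ": fewer than 12 fields")
  }
  get <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    raw <- get(i)
    bad <- is.na(v) & !is.na(raw)
    if (any(bad)) stop("malformed BLAST line ", which(bad)[1],
                       ": non-numeric ", what)
    v
  }
  df <- data.frame(query_id = get(1), subject_id = get(2),
                   percent_identity = num(3, "percent identity"),
                   alignment_length = as.integer(num(4, "alignment length")),
                   mismatches = as.integer(num(5, "mismatches")),
                   gap_opens = as.integer(num(6, "gap opens")),
                   q_start = as.integer(num(7, "q.start")),
                   q_end = as.integer(num(8, "q.end")),
                   s_start = as.integer(num(9, "s.start")),
                   s_end = as.integer(num(10, "s.end")),
                   e_value = num(11, "e-value"),
                   bit_score = num(12, "bit score"),
                   stringsAsFactors = FALSE)
  df$subject_length <- if (any(nf >= 13L)) suppressWarnings(as.numeric(get(13))) else NA_real_
  df$subject_gene <- if (any(nf >= 14L)) get(14) else NA_character_
  if (any(df$percent_identity < 0 | df$percent_identity > 100, na.rm = TRUE)) {
    stop("percent identity outside [0,100] at line ",
         which(df$percent_identity < 0 | df$percent_identity > 100)[1])
  }
  if (any(df$e_value < 0, na.rm = TRUE)) {
    stop("negative e-value at line ", which(df$e_value < 0)[1])
  }
  df$coverage <- ifelse(!is.na(df$subject_length) & df$subject_length > 0,
                        df$alignment_length / df$subject_length, NA_real_)
  df
}

#' Write a BLAST-style hit table as 14-column TSV
#'
#' @param hits data.frame as produced by [read_blast_tab()] or
#'   [simulate_blast_hits()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  cols <- c(.blast_cols, "subject_length", "subject_gene")
  stopifnot(all(cols %in% colnames(hits)))
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Newick tree, honoring the PAML "#1" foreground tag
#'
#' At most one node or tip label may carry a `#1` suffix marking the branch
#' above it as the foreground branch of a branch-site test. The tag is
#' stripped from the label and recorded in the `foreground` attribute of the
#' returned tree (the ape node number of the branch's child end; `NA` if
#' untagged).
#'
#' @param x path to a Newick file, or a Newick string.
#' @param default_length if not NULL, branches without lengths get this value;
#'   otherwise missing branch lengths are an error.
#' @return `ape::phylo` with attribute `foreground`.
#' @export
read_tree <- function(x, default_length = NULL) {
  txt <- if (file.exists(x) && !grepl(";", x)) paste(readLines(x), collapse = "") else x
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick input")
  labels <- c(tr$tip.label, if (!is.null(tr$node.label)) tr$node.label else
    rep("", tr$Nnode))
  tagged <- grepl("#1$", labels) | grepl("\\s*#\\s*1$", labels)
  if (sum(tagged) > 1L) {
    stop("more than one '#1' foreground tag: ",
         paste(sub("\\s*#\\s*1$", "", labels[tagged]), collapse = ", "))
  }
  fg <- if (any(tagged)) which(tagged) else NA_integer_
  tr$tip.label <- sub("\\s*#\\s*1$", "", tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- sub("\\s*#\\s*1$", "", tr$node.label)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    if (is.null(default_length)) {
      stop("tree has missing branch lengths (set default_length to impute)")
    }
    if (is.null(tr$edge.length)) tr$edge.length <- rep(default_length, nrow(tr$edge))
    tr$edge.length[is.na(tr$edge.length)] <- default_length
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  if (!is.na(fg) && !(fg %in% tr$edge[, 2])) {
    stop("foreground tag on the root is not a branch")
  }
  attr(tr, "foreground") <- fg
  tr
}

#' Write a tree to Newick, restoring the "#1" foreground tag
#'
#' @param tree `phylo` with optional `foreground` attribute.
#' @param path output file, or NULL to return the Newick string.
#' @return the Newick string, invisibly if written to file.
#' @export
write_tree <- function(tree, path = NULL) {
  fg <- attr(tree, "foreground")
  tr <- tree
  if (!is.null(fg) && !is.na(fg)) {
    if (fg <= length(tr$tip.label)) {
      tr$tip.label[fg] <- paste0(tr$tip.label[fg], "#1")
    } else {
      if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
      k <- fg - length(tr$tip.label)
      tr$node.label[k] <- paste0(tr$node.label[k], "#1")
    }
  }
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read and validate a run configuration (YAML)
#'
#' Thresholds absent from the file take the defaults used throughout the
#' package: presence at TPM >= 1, tau floor 2, tau class cut-offs 0.3/0.8,
#' annotation filter 70% identity / 0.5 coverage / e < 1e-10, expression bin
#' edges at 10 and 50.
#'
#' @param path YAML file; must name `tissue_order` and `rng_seed`.
#' @return validated named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(presence_tpm = 1, tau_floor = 2, tau_broad_cutoff = 0.3,
                   tau_high_cutoff = 0.8, identity_min = 70, coverage_min = 0.5,
                   evalue_max = 1e-10, bin_edges = c(10, 50))
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$tissue_order) || length(cfg$tissue_order) < 1L) {
    stop("config must define tissue_order")
  }
  if (is.null(cfg$rng_seed)) stop("config must define rng_seed")
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  with(cfg, {
    stopifnot(presence_tpm >= 0, tau_floor > 0,
              tau_broad_cutoff > 0, tau_broad_cutoff < tau_high_cutoff,
              tau_high_cutoff < 1, identity_min >= 0, identity_min <= 100,
              coverage_min >= 0, coverage_min <= 1, evalue_max > 0,
              length(bin_edges) == 2, bin_edges[1] < bin_edges[2])
  })
  cfg
}

#' Render a run configuration for verbatim logging
#'
#' @param cfg list from [read_run_config()].
#' @return character vector of "key: value" lines.
#' @export
format_run_config <- function(cfg) {
  vapply(names(cfg), function(nm) {
    paste0(nm, ": ", paste(format(cfg[[nm]]), collapse = ", "))
  }, "")
}
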