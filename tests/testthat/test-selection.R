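triangle <- function(nodes, w = 10) {
  data.frame(from = nodes[c(1, 1, 2)], to = nodes[c(2, 3, 3)], weight = w,
             stringsAsFactors = FALSE)
}

test_that("MCL separates disconnected components and keeps singletons", {
  g <- similarity_graph(rbind(triangle(c("a1", "a2", "a3")),
                              triangle(c("b1", "b2", "b3"))),
                        nodes = "lonely")
  cl <- mcl_cluster(g)
  has_cluster <- function(cl, x) any(vapply(cl, identical, logical(1), x))
  expect_length(cl, 3L)
  expect_true(has_cluster(cl, c("a1", "a2", "a3")))
  expect_true(has_cluster(cl, c("b1", "b2", "b3")))
  expect_true(has_cluster(cl, "lonely"))
  expect_length(mcl_cluster(similarity_graph(
    data.frame(from = character(), to = character(), weight = numeric()))), 0L)
})

test_that("MCL recovers a planted two-block partition", {
  blocks <- list(paste0("x", 1:8), paste0("y", 1:8))
  edges <- list()
  for (b in blocks) {
    for (i in 1:7) for (j in (i + 1):8) {
      edges[[length(edges) + 1]] <- data.frame(from = b[i], to = b[j],
                                               weight = 50)
    }
  }
  for (i in 1:8) for (j in 1:8) {
    edges[[length(edges) + 1]] <- data.frame(from = blocks[[1]][i],
                                             to = blocks[[2]][j],
                                             weight = 0.1)
  }
  g <- similarity_graph(do.call(rbind, edges))
  cl <- mcl_cluster(g, inflation = 1.5)
  has_cluster <- function(cl, x) any(vapply(cl, identical, logical(1), x))
  expect_length(cl, 2L)
  expect_true(has_cluster(cl, sort(blocks[[1]])))
  expect_true(has_cluster(cl, sort(blocks[[2]])))
})

test_that("MCL clustering is invariant to node input order", {
  set.seed(9)
  edges <- rbind(triangle(c("n1", "n2", "n3"), 5),
                 triangle(c("n4", "n5", "n6"), 8),
                 data.frame(from = "n3", to = "n4", weight = 0.2))
  g1 <- similarity_graph(edges)
  g2 <- similarity_graph(edges[sample(nrow(edges)), c(2, 1, 3)] |>
                           setNames(c("from", "to", "weight")))
  expect_identical(mcl_cluster(g1), mcl_cluster(g2))
})

test_that("similarity weights from BLAST are capped and self-hits dropped", {
  hits <- data.frame(query_id = c("g1", "g1", "g2"),
                     subject_id = c("g1", "g2", "g3"),
                     e_value = c(0, 0, 1e-5), stringsAsFactors = FALSE)
  sp <- c(g1 = "spA", g2 = "spB", g3 = "spC")
  g <- blast_to_graph(hits, sp)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(max(g$edges$weight), 200)
  expect_equal(min(g$edges$weight), 5)
})

test_that("single-copy filter demands exactly one gene per species", {
  sp <- paste0("sp", 1:9)
  full <- paste(sp, "g", sep = "|")
  groups <- list(full,                         # kept
                 full[-1],                     # missing a species
                 c(full, "sp1|g2"),            # duplicated species
                 c(full[-9], "sp1|g2"))        # duplicate + missing
  out <- single_copy_filter(groups, sp)
  expect_identical(out, list(full))
})

test_that("masking removes gap-ridden codon columns and short blocks", {
  aln <- c(a = strrep("ATGGCC", 6), b = strrep("ATGGCC", 6))
  expect_equal(unname(c(mask_alignment(aln))), unname(aln),
               ignore_attr = TRUE)
  # one gapped codon among 12: strict masking drops exactly that column
  a <- strrep("ATG", 12)
  b <- paste0(strrep("ATG", 5), "A-G", strrep("ATG", 6))
  masked <- mask_alignment(c(a = a, b = b), max_gap_fraction = 0,
                           min_block_codons = 5)
  expect_equal(attr(masked, "kept_codons"), setdiff(1:12, 6))
  expect_equal(nchar(masked[["a"]]), 33)
  # block rule: surviving run shorter than the minimum is dropped too
  b2 <- paste0(strrep("ATG", 3), "A-G", strrep("ATG", 8))
  masked2 <- mask_alignment(c(a = a, b = b2), 0, 5)
  expect_equal(attr(masked2, "kept_codons"), 5:12)
  expect_error(mask_alignment(c(a = "---", b = "---")), "survive")
})

test_that("masking agrees with a brute-force column scan", {
  set.seed(20)
  tr <- fixture_tree()
  sim <- simulate_codon_alignment(codon_sim_spec(tr, n_codons = 80,
                                                 rng_seed = 5))
  aln <- sim$alignment
  # inject random gaps codon-wise
  m <- do.call(rbind, strsplit(aln, ""))
  for (k in 1:60) {
    i <- sample(nrow(m), 1)
    s <- sample(80, 1)
    m[i, (3 * s - 2):(3 * s)] <- "-"
  }
  aln2 <- setNames(apply(m, 1, paste, collapse = ""), names(aln))
  for (mg in c(0, 0.2, 0.5)) {
    masked <- mask_alignment(aln2, mg, min_block_codons = 3)
    gapfrac <- sapply(1:80, function(s) {
      mean(apply(m[, (3 * s - 2):(3 * s), drop = FALSE] == "-", 1, any))
    })
    keep <- gapfrac <= mg
    r <- rle(keep)
    r$values[r$values & r$lengths < 3] <- FALSE
    expect_equal(attr(masked, "kept_codons"), which(inverse.rle(r)))
    # surviving columns obey the gap threshold
    expect_true(all(gapfrac[attr(masked, "kept_codons")] <= mg))
    expect_equal(nchar(masked[[1]]) %% 3, 0)
    expect_lte(nchar(masked[[1]]), nchar(aln2[[1]]))
  }
})

test_that("zero-length branches with identical sequences give pi likelihoods", {
  tr <- read_tree("((A#1:0,B:0):0,C:0);")
  ct <- codon_tables()
  aln <- setNames(rep(paste(ct$codons[c(1, 5, 9)], collapse = ""), 3),
                  c("A", "B", "C"))
  pi <- setNames(rep(1 / 61, 61), ct$codons)
  params <- list(kappa = 2, omega0 = 0.5, omega2 = 2, p0 = 0.6, p1 = 0.2,
                 pi = pi)
  expect_equal(branch_site_lnL(aln, tr, params), 3 * log(1 / 61),
               tolerance = 1e-10)
})

test_that("likelihood contract errors are raised", {
  tr <- read_tree("((A:0.1,B:0.1):0.05,C:0.2);")  # no foreground tag
  aln <- random_codon_alignment(c("A", "B", "C"), 4)
  params <- list(kappa = 2, omega0 = 0.5, omega2 = 2, p0 = 0.6, p1 = 0.2,
                 pi = setNames(rep(1 / 61, 61), codon_tables()$codons))
  expect_error(branch_site_lnL(aln, tr, params), "foreground")
  tr2 <- read_tree("((A#1:0.1,B:0.1):0.05,C:0.2);")
  expect_error(branch_site_lnL(aln[c("A", "B")], tr2, params), "taxa")
  withstop <- aln
  substr(withstop[["A"]], 1, 3) <- "TAA"
  expect_error(branch_site_lnL(withstop, tr2, params), "stop codon")
})

test_that("null and alternative likelihoods are nested", {
  tr <- fixture_tree()
  sim <- simulate_codon_alignment(codon_sim_spec(tr, n_codons = 60,
                                                 rng_seed = 77))
  params <- list(kappa = 2, omega0 = 0.3, omega2 = 3, p0 = 0.6, p1 = 0.2,
                 pi = codon_frequencies(sim$alignment, "F1x4"))
  l_alt <- branch_site_lnL(sim$alignment, tr, params)
  l_null <- branch_site_lnL(sim$alignment, tr, params, null = TRUE)
  p1eq <- params
  p1eq$omega2 <- 1
  expect_equal(branch_site_lnL(sim$alignment, tr, p1eq), l_null,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(l_alt, l_null)))
})

test_that("identical sequences yield a null test result", {
  tr <- read_tree("((A#1:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  ct <- codon_tables()
  set.seed(2)
  s <- paste(sample(ct$codons, 30, replace = TRUE), collapse = "")
  aln <- setNames(rep(s, 4), c("A", "B", "C", "D"))
  res <- branch_site_test(aln, tr, restarts = 1, seed = 3)
  expect_lt(res$lrt, 0.05)   # numerical slop only, no real signal
  expect_gt(res$p_value, 0.8)
})

test_that("the mixture reference halves the chi-squared p-value", {
  tr <- fixture_tree()
  sim <- simulate_codon_alignment(codon_sim_spec(tr, omega2 = 6, p0 = 0.5,
                                                 p1 = 0.2, n_codons = 150,
                                                 rng_seed = 40))
  r1 <- branch_site_test(sim$alignment, tr, restarts = 1, seed = 1)
  r2 <- branch_site_test(sim$alignment, tr, restarts = 1, seed = 1,
                         p_reference = "mixture")
  expect_gt(r1$lrt, 0)
  expect_equal(r2$p_value, r1$p_value / 2, tolerance = 1e-9)
  expect_gte(r1$lnL_alt, r1$lnL_null - 1e-6)
})

test_that("selection_scan intersects per-variant significant sets", {
  tr6 <- read_tree(paste0("(((A#1:0.25,B:0.1):0.05,(C:0.1,D:0.1):0.05):0.05,",
                          "(E:0.1,F:0.1):0.05);"))
  genes <- c("gPos1", "gPos2", "gNull", "gHalf")
  mk <- function(omega2, seed) {
    simulate_codon_alignment(codon_sim_spec(tr6, omega2 = omega2, p0 = 0.5,
                                            p1 = 0.2, n_codons = 150,
                                            rng_seed = seed))$alignment
  }
  v1 <- list(gPos1 = mk(9, 1), gPos2 = mk(9, 2), gNull = mk(1, 3),
             gHalf = mk(9, 4))
  v2 <- list(gPos1 = mk(9, 5), gPos2 = mk(9, 6), gNull = mk(1, 7),
             gHalf = mk(1, 8),  # signal washed out in the second aligner
             gOrphan = mk(9, 9))
  trees <- setNames(rep(list(tr6), 5), c(genes, "gOrphan"))
  scan <- selection_scan(list(prank = v1, macse = v2), trees, q_max = 0.05,
                         restarts = 1, seed = 11)
  expect_true(all(c("gPos1", "gPos2") %in% scan$selected))
  expect_false("gNull" %in% scan$selected)
  expect_false("gHalf" %in% scan$selected)   # significant in one variant only
  expect_equal(scan$skipped, "gOrphan")      # missing from the first variant
  expect_true(all(c("prank", "macse") %in% names(scan$tables)))
  expect_true(all(scan$tables$prank$q >= scan$tables$prank$p, na.rm = TRUE))
})
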