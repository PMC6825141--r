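test_that("expression simulator is deterministic under a fixed seed", {
  spec <- expression_sim_spec(n_housekeeping = 40, n_tissue_specific = 40,
                              n_intermediate = 20, rng_seed = 5)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a, b)
  spec2 <- expression_sim_spec(n_housekeeping = 40, n_tissue_specific = 40,
                               n_intermediate = 20, rng_seed = 6)
  expect_false(identical(simulate_expression(spec2)$counts, a$counts))
})

test_that("housekeeping-only noise-free spec gives constant TPM rows", {
  spec <- expression_sim_spec(n_housekeeping = 30, n_tissue_specific = 0,
                              n_intermediate = 0, hk_tissue_sdlog = 0,
                              dispersion = 0, rng_seed = 2)
  sim <- simulate_expression(spec)
  tpm <- to_tpm(sim$counts, sim$lengths)
  expect_true(all(apply(tpm, 1, function(r) diff(range(r))) < 1e-9))
})

test_that("a spec with zero genes is rejected", {
  expect_error(expression_sim_spec(n_housekeeping = 0, n_tissue_specific = 0,
                                   n_intermediate = 0), "zero genes")
})

test_that("expected TPM truth columns sum to one million", {
  sim <- simulate_expression(expression_sim_spec(rng_seed = 9))
  expect_equal(unname(colSums(sim$expected_tpm)), rep(1e6, 6),
               tolerance = 1e-9)
})

test_that("truth labels carry class and target tissue", {
  sim <- simulate_expression(expression_sim_spec(
    n_housekeeping = 10, n_tissue_specific = 12, n_intermediate = 5,
    rng_seed = 3))
  expect_equal(table(sim$truth$class)[["tissue_specific"]], 12)
  ts <- sim$truth[sim$truth$class == "tissue_specific", ]
  expect_false(anyNA(ts$target_tissue))
  # on-target expected TPM is the max of the gene's expected profile
  for (i in seq_len(nrow(ts))) {
    row <- sim$expected_tpm[ts$gene[i], ]
    expect_equal(unname(row[ts$target_tissue[i]]), max(row))
  }
})

test_that("blast-hit simulator bookkeeping matches the filter", {
  sim <- simulate_blast_hits(500, rng_seed = 11)
  kept <- filter_hits(sim$hits, e_max = 1e-10, identity_min = 70,
                      coverage_min = 0.5)
  expect_equal(nrow(kept), sum(sim$truth$passes))
  expect_setequal(kept$query_id, sim$truth$query_id[sim$truth$passes])
  # degenerate mixtures
  all_good <- simulate_blast_hits(50, p_good = 1,
                                  good_identity = c(1000, 1e-6),
                                  good_coverage = c(1000, 1e-6), rng_seed = 1)
  expect_true(all(all_good$truth$passes))
  # identities concentrated near 60: nothing can pass the 70% filter
  all_bad <- simulate_blast_hits(50, p_good = 0,
                                 bad_identity = c(600, 400), rng_seed = 1)
  expect_false(any(all_bad$truth$passes))
  expect_equal(nrow(filter_hits(all_bad$hits)), 0L)
})

test_that("codon simulator is deterministic and emits no stop codons", {
  tr <- fixture_tree()
  spec <- codon_sim_spec(tr, n_codons = 60, rng_seed = 21)
  a <- simulate_codon_alignment(spec)
  expect_identical(a, simulate_codon_alignment(spec))
  ct <- codon_tables()
  for (s in a$alignment) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_true(all(cods %in% ct$codons))
  }
  expect_true(all(a$site_classes %in% c("0", "1", "2a", "2b")))
})

test_that("zero branch lengths copy the root codon to every tip", {
  tr <- read_tree("((A#1:0,B:0):0,C:0);")
  sim <- simulate_codon_alignment(codon_sim_spec(tr, n_codons = 40,
                                                 rng_seed = 4))
  expect_equal(unname(sim$alignment["A"]), unname(sim$alignment["B"]))
  expect_equal(unname(sim$alignment["A"]), unname(sim$alignment["C"]))
})

test_that("pi with stop-codon entries is rejected", {
  tr <- fixture_tree()
  pi <- setNames(rep(1 / 62, 62), c(codon_tables()$codons, "TAA"))
  expect_error(codon_sim_spec(tr, pi = pi), "stop")
})

test_that("codon frequencies converge to pi over long branches", {
  tr <- read_tree("(A:40,B#1:40);")
  ct <- codon_tables()
  set.seed(33)
  g <- rgamma(61, 5, 1)
  pi <- setNames(g / sum(g), ct$codons)
  sim <- simulate_codon_alignment(codon_sim_spec(tr, pi = pi,
                                                 n_codons = 10000,
                                                 omega2 = 1, rng_seed = 12))
  for (taxon in c("A", "B")) {
    s <- sim$alignment[[taxon]]
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    counts <- table(factor(cods, levels = ct$codons))
    expect_gt(chisq.test(counts, p = pi)$p.value, 0.01)
  }
})

test_that("p0 = 1 collapses to the single-class omega0 model", {
  # with every site in class 0, omega2 must be irrelevant: the generated
  # data coincide with a null single-class run under the same seed
  tr <- fixture_tree()
  a <- simulate_codon_alignment(codon_sim_spec(tr, omega2 = 8, p0 = 1, p1 = 0,
                                               n_codons = 500, rng_seed = 8))
  b <- simulate_codon_alignment(codon_sim_spec(tr, omega2 = 1, p0 = 1, p1 = 0,
                                               n_codons = 500, rng_seed = 8))
  expect_true(all(a$site_classes == "0"))
  expect_identical(a$alignment, b$alignment)
})

test_that("cached transition matrices have rows summing to one", {
  ct <- codon_tables()
  pi <- setNames(rep(1 / 61, 61), ct$codons)
  Q <- gy94_rate_matrix(2, 0.3, pi)
  eig <- gy94_eigen(Q, pi)
  for (t in c(0, 0.01, 0.3, 2, 50)) {
    P <- gy94_pmat(eig, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
})
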