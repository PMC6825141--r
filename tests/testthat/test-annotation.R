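make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               percent_identity = as.numeric(r[[3]]),
               alignment_length = 50L, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = 150L, s_start = 1L, s_end = 50L,
               e_value = as.numeric(r[[4]]), bit_score = as.numeric(r[[5]]),
               subject_length = 100, subject_gene = toupper(r[[2]]),
               coverage = as.numeric(r[[6]]), stringsAsFactors = FALSE)
  }))
}

test_that("filter_hits honors inclusive identity/coverage and exclusive e-value", {
  h <- make_hits(list("q1", "s1", 70.0, 1e-20, 100, 0.50),
                 list("q2", "s2", 69.9, 1e-20, 100, 0.90),
                 list("q3", "s3", 95.0, 1e-10, 100, 0.90),
                 list("q4", "s4", 95.0, 1e-12, 100, 0.49))
  kept <- filter_hits(h, e_max = 1e-10, identity_min = 70, coverage_min = 0.5)
  expect_identical(kept$query_id, "q1")
})

test_that("filter_hits is idempotent and monotone in its thresholds", {
  sim <- simulate_blast_hits(300, rng_seed = 2)
  f1 <- filter_hits(sim$hits)
  expect_identical(filter_hits(f1), f1)
  tighter <- filter_hits(sim$hits, identity_min = 80, coverage_min = 0.6,
                         e_max = 1e-20)
  expect_true(all(tighter$query_id %in% f1$query_id))
  expect_lte(nrow(tighter), nrow(f1))
})

test_that("best_hit_per_transcript applies the stated tie-break chain", {
  h <- make_hits(list("q1", "s1", 90, 1e-5, 100, 0.9),
                 list("q1", "s2", 90, 1e-9, 100, 0.9),
                 list("q2", "sA", 90, 1e-8, 100, 0.9),
                 list("q2", "sB", 90, 1e-8, 200, 0.9),
                 list("q3", "sZ", 90, 1e-8, 100, 0.9),
                 list("q3", "sA", 90, 1e-8, 100, 0.9))
  best <- best_hit_per_transcript(h)
  expect_equal(best$subject_id[best$query_id == "q1"], "s2")
  expect_equal(best$subject_id[best$query_id == "q2"], "sB")
  expect_equal(best$subject_id[best$query_id == "q3"], "sA")
})

test_that("best hits agree with a brute-force scan on random tables", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 120
    h <- data.frame(query_id = sample(paste0("q", 1:25), n, replace = TRUE),
                    subject_id = sample(paste0("s", 1:40), n, replace = TRUE),
                    percent_identity = runif(n, 50, 100),
                    alignment_length = 50L, mismatches = 0L, gap_opens = 0L,
                    q_start = 1L, q_end = 150L, s_start = 1L, s_end = 50L,
                    e_value = 10^sample(seq(-30, -5, 5), n, replace = TRUE),
                    bit_score = sample(seq(50, 300, 50), n, replace = TRUE),
                    subject_length = 100, subject_gene = NA_character_,
                    coverage = 0.5, stringsAsFactors = FALSE)
    got <- best_hit_per_transcript(h)
    want <- oracle_best_hits(h)
    got <- got[order(got$query_id), ]
    expect_equal(got$subject_id, want$subject_id)
    expect_equal(got$e_value, want$e_value)
  }
})

test_that("collapse_redundancy merges duplicates and splits unrelated sequences", {
  s <- c(a = paste(rep("ACGTTGCA", 10), collapse = ""),
         b = paste(rep("ACGTTGCA", 10), collapse = ""))
  res <- collapse_redundancy(s, 0.95)
  expect_length(res$representatives, 1L)
  expect_equal(unname(table(res$membership)[[1]]), 2L)
  s2 <- c(a = strrep("ACGT", 20), b = strrep("AACC", 20))
  expect_length(collapse_redundancy(s2, 0.5)$representatives, 2L)
})

test_that("threshold 1.0 merges only exact-identity estimates", {
  set.seed(3)
  base <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  mutated <- base
  substr(mutated, 100, 100) <- if (substr(base, 100, 100) == "A") "C" else "A"
  res <- collapse_redundancy(c(x = base, y = base, z = mutated), 1.0)
  expect_equal(unname(res$membership[["y"]]), res$membership[["x"]])
  expect_length(res$representatives, 2L)
})

test_that("greedy clustering matches a brute-force oracle", {
  set.seed(21)
  for (rep in 1:3) {
    pool <- replicate(6, paste(sample(c("A", "C", "G", "T"), 150,
                                      replace = TRUE), collapse = ""))
    seqs <- character(20)
    for (i in 1:20) {
      s <- sample(pool, 1)
      nmut <- sample(0:12, 1)
      pos <- sample(nchar(s), nmut)
      sv <- strsplit(s, "")[[1]]
      sv[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      seqs[i] <- paste(sv, collapse = "")
    }
    names(seqs) <- sprintf("s%02d", 1:20)
    res <- collapse_redundancy(seqs, 0.95, k = 8)
    # oracle: same greedy order, identity recomputed from scratch
    ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
    kset <- function(s) {
      n <- nchar(s)
      km <- substring(s, 1:(n - 7), 8:n)
      rc <- vapply(strsplit(chartr("ACGT", "TGCA", km), ""),
                   function(x) paste(rev(x), collapse = ""), "")
      unique(ifelse(km < rc, km, rc))
    }
    reps <- character(0)
    memb <- character(0)
    for (id in ids) {
      found <- NA
      for (r in reps) {
        ka <- kset(seqs[[id]]); kb <- kset(seqs[[r]])
        if (length(intersect(ka, kb)) / min(length(ka), length(kb)) >= 0.95) {
          found <- r; break
        }
      }
      if (is.na(found)) { reps <- c(reps, id); found <- id }
      memb[[id]] <- found
    }
    expect_identical(res$representatives, reps)
    expect_identical(res$membership, memb)
  }
})

test_that("assembly_stats matches hand computations", {
  one <- c(a = strrep("A", 100))
  st <- assembly_stats(one)
  expect_equal(st$n50, 100)
  expect_equal(st$mean_length, 100)
  lens <- c(4, 3, 3, 2, 2, 2)
  seqs <- setNames(vapply(lens, function(l) strrep("A", l), ""),
                   paste0("s", 1:6))
  expect_equal(assembly_stats(seqs)$n50, 3)
  expect_equal(assembly_stats(c(a = "ATGC"))$gc_percent, 50)
  expect_error(assembly_stats(character(0)), "empty")
  # ambiguity codes excluded from GC
  expect_equal(assembly_stats(c(a = "ATGCNN"))$gc_percent, 50)
})

test_that("N50 agrees with the cumulative-sum oracle on random length sets", {
  set.seed(99)
  for (rep in 1:200) {
    lens <- sample(50:5000, sample(1:40, 1), replace = TRUE)
    seqs <- setNames(vapply(lens, function(l) strrep("A", l), ""),
                     paste0("s", seq_along(lens)))
    expect_equal(assembly_stats(seqs)$n50, oracle_n50(lens))
  }
})
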