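test_that("pairwise identity basics", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  # terminal gaps are free: a contained sequence aligns at identity 1
  expect_equal(pairwise_identity("AAAACGT", "ACGT"), 1.0)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
  withr::with_seed(5, {
    a <- random_dna_seq(60); b <- random_dna_seq(60)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  })
})

test_that("pairwise identity equals the quadratic DP oracle", {
  withr::with_seed(6, {
    for (k in 1:200) {
      a <- random_dna_seq(sample(20:50, 1))
      b <- random_dna_seq(sample(20:50, 1))
      expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
                   info = paste("pair", k))
    }
  })
})

test_that("greedy clustering degenerate cases", {
  recs <- tibble::tibble(id = paste0("r", 1:5),
                         sequence = rep(strrep("ACGT", 15), 5))
  cl <- greedy_cluster(recs, 0.97)
  expect_equal(nrow(cl$otus), 1L)
  expect_setequal(cl$otus$members[[1]], recs$id)

  withr::with_seed(7, {
    distinct <- tibble::tibble(id = paste0("r", 1:10),
                               sequence = replicate(10, random_dna_seq(60)))
  })
  cl2 <- greedy_cluster(distinct, 0.97)
  expect_equal(nrow(cl2$otus), 10L)
  expect_error(greedy_cluster(distinct, 0), "threshold")
  expect_error(
    greedy_cluster(tibble::tibble(id = c("a", "a"),
                                  sequence = c("ACGT", "ACGT")), 0.9),
    "duplicate")
})

test_that("greedy first-hit rule follows the hand-traced A,B,C case", {
  base <- strrep("ACGT", 25)            # 100 bp
  mut <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- ifelse(ch[pos] == "A", "C", "A")
    paste(ch, collapse = "")
  }
  A <- mut(base, c(1, 5))       # 0.98 to base
  B <- base
  C <- mut(base, c(50, 60))     # 0.98 to base, 0.96 to A
  expect_equal(pairwise_identity(A, B), 0.98)
  expect_equal(pairwise_identity(B, C), 0.98)
  expect_lt(pairwise_identity(A, C), 0.97)
  recs <- tibble::tibble(id = c("A", "B", "C"), sequence = c(A, B, C))
  cl <- greedy_cluster(recs, 0.97, ordering = "input")
  expect_equal(nrow(cl$otus), 2L)
  expect_setequal(cl$otus$members[[1]], c("A", "B"))
  expect_identical(cl$otus$representative_id[1], "A")
  expect_setequal(cl$otus$members[[2]], "C")
})

test_that("greedy clustering equals the brute-force oracle on permutations", {
  withr::with_seed(8, {
    for (trial in 1:6) {
      n <- sample(4:6, 1)
      # mixture of related and unrelated sequences near the threshold
      base <- random_dna_seq(60)
      seqs <- vapply(seq_len(n), function(i) {
        if (i <= n / 2) {
          ch <- strsplit(base, "")[[1]]
          k <- sample(0:3, 1)
          if (k > 0) {
            pos <- sample(60, k)
            ch[pos] <- vapply(ch[pos], function(b) {
              sample(setdiff(c("A", "C", "G", "T"), b), 1)
            }, character(1))
          }
          paste(ch, collapse = "")
        } else random_dna_seq(60)
      }, character(1))
      thr <- sample(c(0.95, 0.97), 1)
      idmat <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
        oracle_identity(seqs[i], seqs[j])
      }))
      perms <- combinat_perms(n)
      for (p in perms[sample(length(perms), min(24, length(perms)))]) {
        recs <- tibble::tibble(id = sprintf("s%02d", p), sequence = seqs[p])
        cl <- greedy_cluster(recs, thr, ordering = "input")
        want <- oracle_greedy(idmat[p, p, drop = FALSE], thr)
        got <- otu_membership(cl)
        got_idx <- match(got$representative_id[match(recs$id, got$id)],
                         recs$id)
        expect_identical(got_idx, want,
                         info = paste("trial", trial))
      }
    }
  })
})

test_that("every member meets the threshold to its representative", {
  spec <- default_community_spec(n_genera = 2, species_per_genus = 4,
                                 copies_per_species = 5, seed = 43)
  refs <- build_reference_taxa(spec)
  comm <- simulate_community(refs, spec)
  cl <- greedy_cluster(tibble::tibble(id = comm$id, sequence = comm$its1),
                       0.97)
  mem <- otu_membership(cl)
  seq_of <- setNames(comm$its1, comm$id)
  ident <- pairwise_identity(seq_of[mem$id], seq_of[mem$representative_id])
  expect_true(all(ident >= 0.97 - 1e-9))
  # partition invariant
  expect_setequal(mem$id, comm$id)
  expect_equal(anyDuplicated(mem$id), 0L)
})

test_that("OTU counts are non-decreasing in the threshold", {
  spec <- default_community_spec(n_genera = 2, species_per_genus = 5,
                                 copies_per_species = 4, seed = 47)
  refs <- build_reference_taxa(spec)
  comm <- simulate_community(refs, spec)
  recs <- tibble::tibble(id = comm$id, sequence = comm$its2)
  sweep <- cluster_sweep(recs, seq(0.91, 0.99, by = 0.02))
  counts <- vapply(sweep, function(cl) nrow(cl$otus), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("otu_table counts members per sample with conserved totals", {
  members <- list(c("a1", "a2", "b1"), c("b2", "b3"), "a3")
  cl <- make_clustering(members)
  sample_of <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B",
                 b3 = "B")
  tab <- otu_table(cl, sample_of)
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(sum(tab), 6L)
  expect_equal(unname(rowSums(tab)), c(3L, 2L, 1L))
  expect_equal(tab["OTU_00001", "A"], 2L)
  expect_equal(tab["OTU_00003", "B"], 0L)
  # single sample: one column equal to OTU sizes
  one <- otu_table(cl, setNames(rep("S", 6), names(sample_of)))
  expect_equal(unname(one[, 1]), c(3L, 2L, 1L))
  # disjoint samples give a block-diagonal table
  blocks <- make_clustering(list(c("a1", "a2"), c("b1", "b2")))
  tb <- otu_table(blocks, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(unname(tb), matrix(c(2L, 0L, 0L, 2L), 2))
  expect_error(otu_table(cl, sample_of[-1]), "no sample")
})

test_that("dereplication collapses duplicates and restores them", {
  withr::with_seed(22, {
    u <- replicate(4, random_dna_seq(60))
  })
  recs <- tibble::tibble(id = sprintf("r%02d", 1:9),
                         sequence = u[c(1, 1, 1, 2, 2, 3, 4, 4, 1)])
  plain <- greedy_cluster(recs, 0.97)
  derep <- greedy_cluster(recs, 0.97, dereplicate = TRUE)
  expect_equal(nrow(derep$otus), nrow(plain$otus))
  expect_setequal(derep$universe, recs$id)
  mem <- otu_membership(derep)
  # identical sequences always share an OTU
  for (k in 1:4) {
    ids <- recs$id[recs$sequence == u[k]]
    expect_equal(dplyr::n_distinct(mem$otu_id[mem$id %in% ids]), 1L)
  }
})

test_that("otu maps round-trip through the TSV interchange format", {
  members <- list(c("x1", "x2"), c("y1"))
  cl <- make_clustering(members, reps = c("x2", "y1"), region = "ITS1",
                        threshold = 0.97)
  f <- tempfile(fileext = ".tsv")
  write_otu_map(cl, f)
  back <- read_otu_map(f, threshold = 0.97, region = "ITS1")
  expect_identical(back$otus$representative_id, cl$otus$representative_id)
  expect_identical(back$otus$members, cl$otus$members)
  expect_setequal(back$universe, cl$universe)
})
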