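lin6 <- function(sp, genus = "G", phylum = "P") {
  sprintf("p__%s;c__C;o__O;f__F;g__%s;s__%s", phylum, genus, sp)
}

test_that("best_hits finds exact matches and applies the tie policy", {
  db <- tibble::tibble(
    accession = c("ACC2", "ACC1", "ACC3"),
    sequence = c("ACGTACGTACGTACGTACGT", "TTTTCCCCGGGGAAAATTTT",
                 "ACGTACGTACGTACGTACGA"),
    lineage = c(lin6("sp1"), lin6("sp2"), lin6("sp3")))
  q <- tibble::tibble(id = "q1", sequence = "TTTTCCCCGGGGAAAATTTT",
                      accession = "ACC1", lineage = lin6("sp2"))
  hit <- best_hits(q, db)
  expect_identical(hit$hit_accession, "ACC1")
  expect_equal(hit$identity, 1.0)
  expect_true(hit$same_accession)
  # two references tied at identity 1 -> lexicographically smallest accession
  dup <- tibble::tibble(
    accession = c("B_ACC", "A_ACC"),
    sequence = rep("ACGTACGTACGTACGTACGT", 2),
    lineage = c(lin6("spX"), lin6("spX")))
  hit2 <- best_hits(tibble::tibble(id = "q", sequence = dup$sequence[1],
                                   accession = "B_ACC",
                                   lineage = lin6("spX")), dup)
  expect_identical(hit2$hit_accession, "A_ACC")
  expect_false(hit2$same_accession)
  expect_true(hit2$same_species)
})

test_that("best_hits agrees with an exhaustive R scan on a toy db", {
  withr::with_seed(15, {
    db <- tibble::tibble(
      accession = sprintf("ACC%02d", sample(20)),
      sequence = replicate(20, random_dna_seq(sample(40:60, 1))),
      lineage = lin6(sprintf("sp%02d", 1:20)))
    queries <- tibble::tibble(
      id = sprintf("q%d", 1:8),
      sequence = c(db$sequence[3], replicate(7, random_dna_seq(50))),
      accession = c(db$accession[3], rep(NA, 7)),
      lineage = lin6(sprintf("q%d", 1:8)))
  })
  hits <- best_hits(queries, db)
  for (i in seq_len(nrow(queries))) {
    ids <- vapply(db$sequence, function(r) {
      oracle_identity(queries$sequence[i], r)
    }, numeric(1))
    best <- max(ids)
    cand <- db$accession[abs(ids - best) < 1e-12]
    expect_true(hits$hit_accession[i] %in% cand, info = paste("query", i))
    expect_equal(hits$identity[i], best, info = paste("query", i))
  }
  # db order never changes the outcome
  perm <- withr::with_seed(16, sample(nrow(db)))
  hits2 <- best_hits(queries, db[perm, ])
  expect_identical(hits$hit_accession, hits2$hit_accession)
})

test_that("self-return drops on collisions; agreement bounds self-return", {
  # unique references: every query returns itself
  withr::with_seed(17, {
    db <- tibble::tibble(accession = sprintf("A%02d", 1:10),
                         sequence = replicate(10, random_dna_seq(60)),
                         lineage = lin6(sprintf("sp%d", 1:10)))
  })
  self <- tibble::tibble(id = db$accession, sequence = db$sequence,
                         accession = db$accession, lineage = db$lineage)
  expect_equal(self_return_rate(self, db), 1.0)
  # identical references A,B: the query from B is beaten to A by tie policy
  twin <- db
  twin$sequence[2] <- twin$sequence[1]
  q2 <- tibble::tibble(id = "q", sequence = twin$sequence[2],
                       accession = twin$accession[2],
                       lineage = twin$lineage[2])
  expect_equal(self_return_rate(q2, twin), 0)
  # same species under two accessions: self-return 0, agreement 1
  twin$lineage[2] <- twin$lineage[1]
  q2$lineage <- twin$lineage[2]
  hits <- best_hits(q2, twin)
  expect_equal(self_return_rate(hits), 0)
  expect_equal(species_agreement_rate(hits), 1)
  # invariant on a random query set
  withr::with_seed(18, {
    q <- tibble::tibble(id = paste0("q", 1:20),
                        sequence = c(db$sequence[sample(10, 10,
                                                        replace = TRUE)],
                                     replicate(10, random_dna_seq(60))))
    q$accession <- db$accession[sample(10, 20, replace = TRUE)]
    q$lineage <- db$lineage[match(q$accession, db$accession)]
  })
  h <- best_hits(q, db)
  expect_gte(species_agreement_rate(h), self_return_rate(h))
})

test_that("leave-one-out mode never returns the query's own record", {
  withr::with_seed(24, {
    db <- tibble::tibble(accession = sprintf("A%02d", 1:6),
                         sequence = replicate(6, random_dna_seq(50)),
                         lineage = lin6(sprintf("sp%d", 1:6)))
  })
  q <- tibble::tibble(id = db$accession, sequence = db$sequence,
                      accession = db$accession, lineage = db$lineage)
  with_self <- best_hits(q, db)
  expect_true(all(with_self$same_accession))
  loo <- best_hits(q, db, exclude_self = TRUE)
  expect_true(all(!loo$same_accession))
  expect_true(all(loo$identity < 1))
})

test_that("a region that collapses species pairs has lower self-return", {
  withr::with_seed(19, {
    n <- 20
    its2 <- replicate(n, random_dna_seq(60))
    its1 <- its2
    # 30% of species pairs share identical ITS1
    for (k in seq(1, 6, by = 2)) its1[k + 1] <- its1[k]
    its1 <- vapply(seq_len(n), function(i) {
      if (i > 6) random_dna_seq(60) else its1[i]
    }, character(1))
    acc <- sprintf("A%02d", 1:n)
    db1 <- tibble::tibble(accession = acc, sequence = its1,
                          lineage = lin6(sprintf("sp%d", 1:n)))
    db2 <- tibble::tibble(accession = acc, sequence = its2,
                          lineage = lin6(sprintf("sp%d", 1:n)))
    q1 <- tibble::tibble(id = acc, sequence = its1, accession = acc,
                         lineage = db1$lineage)
    q2 <- tibble::tibble(id = acc, sequence = its2, accession = acc,
                         lineage = db2$lineage)
    expect_lt(self_return_rate(q1, db1), self_return_rate(q2, db2))
  })
})

test_that("rank_composition is monotone and respects identity floors", {
  hits <- tibble::tibble(
    query_id = paste0("q", 1:4),
    identity = c(1, 0.99, 0.96, 0.90),
    hit_lineage = c(lin6("sp1"), lin6("sp2"),
                    "p__P;c__C;o__O;f__F;g__;s__",
                    "p__P;c__;o__;f__;g__;s__"))
  out <- rank_composition(hits)
  expect_equal(out$classified_pct + out$unclassified_pct, rep(100, 6))
  byrank <- setNames(out$classified_pct, out$rank)
  expect_equal(unname(byrank["phylum"]), 100)
  expect_equal(unname(byrank["genus"]), 50)
  expect_lte(unname(byrank["genus"]), unname(byrank["family"]))
  # identical full-lineage hits -> 100% everywhere
  all100 <- rank_composition(hits[1:2, ])
  expect_true(all(all100$classified_pct == 100))
  # an identity floor reclassifies weak hits
  floored <- rank_composition(hits, floors = c(phylum = 0.95))
  expect_equal(floored$classified_pct[floored$rank == "phylum"], 75)
  expect_equal(out$n_taxa[out$rank == "phylum"], 1L)
})

test_that("exact Mann-Whitney matches enumeration and wilcox.test", {
  same <- mann_whitney(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$p_value, 1)
  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)   # 2/C(6,3) * ... exact two-sided
  withr::with_seed(20, {
    for (k in 1:10) {
      x <- rnorm(sample(3:5, 1)); y <- rnorm(sample(3:5, 1))
      ours <- mann_whitney(x, y)
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$p_value, ref$p.value, info = paste("case", k))
      expect_equal(ours$statistic, unname(ref$statistic))
    }
  })
  # ties: against a direct permutation enumeration with midranks
  x <- c(1, 2, 2); y <- c(2, 3, 4)
  ours <- mann_whitney(x, y)
  pooled <- c(x, y); r <- rank(pooled)
  u_obs <- sum(r[1:3]) - 6
  us <- apply(combn(6, 3), 2, function(k) sum(r[k]) - 6)
  want <- min(1, 2 * min(mean(us <= u_obs + 1e-9),
                         mean(us >= u_obs - 1e-9)))
  expect_equal(ours$p_value, want)
})

test_that("differential_taxa screens group pairs with exact tests", {
  ab <- tibble::tibble(
    taxon = rep(c("t1", "t2"), each = 6),
    sample = rep(paste0("s", 1:6), 2),
    abundance = c(10, 11, 12, 1, 2, 3,    # separated for t1
                  5, 5, 5, 5, 5, 5))      # flat for t2
  groups <- c(s1 = "A", s2 = "A", s3 = "A", s4 = "B", s5 = "B", s6 = "B")
  out <- differential_taxa(ab, groups)
  expect_equal(nrow(out), 2L)
  expect_equal(out$p_value[out$taxon == "t1"], 0.1)
  expect_equal(out$p_value[out$taxon == "t2"], 1)
  expect_error(differential_taxa(ab, groups[1:3]), "no group")
  expect_error(differential_taxa(ab, setNames(rep("A", 6), names(groups))),
               "2 groups")
})

test_that("Fisher rate test matches hypergeometric enumeration", {
  expect_equal(rate_difference_test(5, 10, 5, 10)$p_value, 1.0)
  out <- rate_difference_test(10, 10, 0, 10)
  expect_equal(out$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  withr::with_seed(21, {
    for (k in 1:20) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
      expect_equal(rate_difference_test(k1, n1, k2, n2)$p_value,
                   oracle_fisher_p(k1, n1, k2, n2),
                   tolerance = 1e-9,
                   info = sprintf("(%d/%d vs %d/%d)", k1, n1, k2, n2))
    }
  })
  expect_error(rate_difference_test(1, 0, 0, 5), "positive")
  expect_error(rate_difference_test(6, 5, 0, 5), "0 <= k <= n")
})
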