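test_that("zero rates collapse congeneric species onto the genus ancestor", {
  lineages <- c("p__P;c__C;o__O;f__F;g__G;s__G_sp1",
                "p__P;c__C;o__O;f__F;g__G;s__G_sp2")
  rp <- list(ITS1 = region_params(80, 0, 0.5, 0, 0),
             `5.8S` = region_params(50, 0, 0.5, 0, 0),
             ITS2 = region_params(80, 0, 0.55, 0, 0))
  spec <- community_spec(lineages, region_params = rp, seed = 11)
  refs <- build_reference_taxa(spec)
  expect_identical(refs$its1[1], refs$its1[2])
  expect_identical(refs$r58s[1], refs$r58s[2])
  expect_identical(refs$its2[1], refs$its2[2])
  expect_identical(refs$sequence[1], refs$sequence[2])

  comm <- simulate_community(refs, spec)
  expect_true(all(comm$sequence == refs$sequence[1]))
})

test_that("simulated copies conserve the requested counts and encode ids", {
  spec <- tiny_zero_rate_spec(n_species = 2, copies = 1, seed = 3)
  samples <- tibble::tibble(sample = c("sA", "sA", "sB"),
                            species = c("G1_sp1", "G2_sp1", "G1_sp1"),
                            copies = c(3L, 2L, 4L))
  spec <- community_spec(spec$lineages, region_params = spec$region_params,
                         samples = samples, seed = 3)
  refs <- build_reference_taxa(spec)
  comm <- simulate_community(refs, spec)
  expect_equal(nrow(comm), 9L)
  expect_equal(sum(comm$sample == "sA"), 5L)
  expect_equal(sum(comm$sample == "sA" & comm$species == "G1_sp1"), 3L)
  expect_true(all(startsWith(comm$id[comm$sample == "sB"], "sB.")))
  expect_false(anyDuplicated(comm$id) > 0)
})

test_that("unknown species in a sample profile is an error", {
  spec <- tiny_zero_rate_spec(n_species = 2)
  expect_error(
    community_spec(spec$lineages, region_params = spec$region_params,
                   samples = tibble::tibble(sample = "s", species = "nope",
                                            copies = 1L)),
    "unknown species")
})

test_that("intraspecies substitution fraction recovers the configured rate", {
  lineages <- "p__P;c__C;o__O;f__F;g__G;s__G_sp1"
  rate <- 0.02
  rp <- list(ITS1 = region_params(177, 0, 0.5, 0, rate),
             `5.8S` = region_params(60, 0, 0.5, 0, 0),
             ITS2 = region_params(182, 0, 0.55, 0, 0))
  spec <- community_spec(lineages, region_params = rp,
                         samples = tibble::tibble(sample = "s",
                                                  species = "G_sp1",
                                                  copies = 1000L),
                         seed = 5)
  refs <- build_reference_taxa(spec)
  comm <- simulate_community(refs, spec)
  ref_chars <- strsplit(refs$its1, "")[[1]]
  subs <- vapply(strsplit(comm$its1, ""), function(ch) {
    sum(ch != ref_chars)
  }, numeric(1))
  n_sites <- length(ref_chars) * nrow(comm)
  phat <- sum(subs) / n_sites
  se <- sqrt(rate * (1 - rate) / n_sites)
  expect_lt(abs(phat - rate), 3 * se)
  # the untouched regions stay identical
  expect_true(all(comm$its2 == refs$its2))
})

test_that("generated region GC is close to its target", {
  spec <- default_community_spec(seed = 21)
  refs <- build_reference_taxa(spec)
  expect_true(all(abs(gc_content(refs$its1) - 0.50) <= 0.1))
  expect_true(all(abs(gc_content(refs$its2) - 0.55) <= 0.1))
})

test_that("default region lengths follow the canonical ITS anatomy", {
  rp <- default_region_params()
  expect_equal(rp$ITS1$mean_length, 177)
  expect_equal(rp$ITS2$mean_length, 182)
  total <- rp$ITS1$mean_length + rp[["5.8S"]]$mean_length +
    rp$ITS2$mean_length
  expect_equal(total, 517)
  # empirical check across many independent genera
  spec <- default_community_spec(n_genera = 60, species_per_genus = 1,
                                 copies_per_species = 1, seed = 9)
  refs <- build_reference_taxa(spec)
  its_len <- nchar(refs$its1) + nchar(refs$r58s) + nchar(refs$its2)
  se <- sqrt(45^2 + 30^2) / sqrt(60)
  expect_lt(abs(mean(its_len) - 517), 3 * se + 1)
})

test_that("faster ITS1 yields lower congeneric identity than ITS2", {
  # oracle: per-site mismatch fraction (lengths are equal within a genus)
  hamming_identity <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    mean(ca == cb)
  }
  wins <- 0L
  for (sd in 1:20) {
    rp <- list(ITS1 = region_params(120, 0, 0.5, 0.10, 0),
               `5.8S` = region_params(50, 0, 0.5, 0, 0),
               ITS2 = region_params(120, 0, 0.55, 0.05, 0))
    spec <- community_spec(make_lineages(10, 5), region_params = rp,
                           seed = sd)
    refs <- build_reference_taxa(spec)
    genus <- lineage_rank(refs$lineage, "genus")
    id1 <- id2 <- numeric(0)
    for (g in unique(genus)) {
      idx <- which(genus == g)
      for (i in idx) {
        for (j in idx) {
          if (i < j) {
            id1 <- c(id1, hamming_identity(refs$its1[i], refs$its1[j]))
            id2 <- c(id2, hamming_identity(refs$its2[i], refs$its2[j]))
          }
        }
      }
    }
    if (mean(id1) < mean(id2)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("generation is deterministic given spec and seed", {
  spec <- default_community_spec(n_genera = 2, species_per_genus = 3,
                                 copies_per_species = 4, seed = 33)
  r1 <- build_reference_taxa(spec)
  r2 <- build_reference_taxa(spec)
  expect_identical(r1, r2)
  c1 <- simulate_community(r1, spec)
  c2 <- simulate_community(r2, spec)
  expect_identical(c1, c2)
  reads1 <- simulate_reads(c1, seed = 7)
  reads2 <- simulate_reads(c2, seed = 7)
  expect_identical(reads1, reads2)
  # byte-identical FASTA/FASTQ
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_its_fasta(c1, f1); write_its_fasta(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  q1 <- tempfile(fileext = ".fastq"); q2 <- tempfile(fileext = ".fastq")
  write_reads_fastq(reads1, q1); write_reads_fastq(reads2, q2)
  expect_identical(readLines(q1), readLines(q2))
  # a different seed changes the community
  r3 <- build_reference_taxa(spec, seed = 34)
  expect_false(identical(r1$sequence, r3$sequence))
})

test_that("error-free reads are exactly barcode + primer + template", {
  spec <- tiny_zero_rate_spec(n_species = 3, copies = 2, seed = 2)
  samples <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 3),
    species = rep(spec$species, 2), copies = 2L)
  spec <- community_spec(spec$lineages, region_params = spec$region_params,
                         samples = samples, seed = 2)
  refs <- build_reference_taxa(spec)
  comm <- simulate_community(refs, spec)
  bc <- make_barcodes(unique(comm$sample), seed = 5)
  reads <- simulate_reads(comm, error_rate = 0, indel_rate = 0,
                          barcodes = bc, seed = 5)
  expect_identical(
    reads$sequence,
    paste0(bc[comm$sample], its_primers()[["ITS5"]], comm$sequence))
  expect_true(all(nchar(bc) == 6L))
  expect_true(all(substr(reads$sequence, 1, 6) == bc[reads$sample]))
  expect_identical(nchar(reads$sequence), nchar(reads$quality))
})

test_that("read substitution count matches the binomial expectation", {
  spec <- tiny_zero_rate_spec(n_species = 4, copies = 20, seed = 8)
  refs <- build_reference_taxa(spec)
  comm <- simulate_community(refs, spec)
  bc <- make_barcodes(unique(comm$sample), seed = 8)
  clean <- simulate_reads(comm, error_rate = 0, indel_rate = 0,
                          barcodes = bc, seed = 8)
  noisy <- simulate_reads(comm, error_rate = 0.01, indel_rate = 0,
                          barcodes = bc, seed = 8)
  subs <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$sequence, noisy$sequence))
  n <- sum(nchar(clean$sequence))
  expect_gt(n, 10000)
  se <- sqrt(n * 0.01 * 0.99)
  expect_lt(abs(subs - n * 0.01), 3 * se)
})

test_that("read filter rejects by length, quality, N and tag — exactly", {
  bc <- c(s1 = "ACGTAC")
  primer <- "GGAAGT"
  good_tail <- strrep("ACGT", 25)
  mkq <- function(len, q) strrep(intToUtf8(q + 33L), len)
  reads <- tibble::tibble(
    id = c("ok", "short", "lowq", "hasN", "badtag"),
    sequence = c(paste0("ACGTAC", primer, good_tail),          # 112 bp
                 substr(paste0("ACGTAC", primer, good_tail), 1, 59),
                 paste0("ACGTAC", primer, good_tail),
                 paste0("ACGTAC", primer, "N", good_tail),
                 paste0("TTTTTT", primer, good_tail)),
    quality = c(mkq(112, 35), mkq(59, 35), mkq(112, 30), mkq(113, 35),
                mkq(112, 35))
  )
  out <- filter_reads(reads, barcodes = bc, primer = primer)
  expect_identical(out$kept$id, "ok")
  expect_identical(out$kept$sample, "s1")
  expect_identical(out$kept$sequence, good_tail)  # tag trimmed
  rej <- setNames(out$rejected$reason, out$rejected$id)
  expect_identical(unname(rej["short"]), "length")
  expect_identical(unname(rej["lowq"]), "quality")   # mean q == 30 rejected
  expect_identical(unname(rej["hasN"]), "ambiguous")
  expect_identical(unname(rej["badtag"]), "tag")
  # partition property
  expect_setequal(c(out$kept$id, out$rejected$id), reads$id)
})

test_that("filter enumerates multiple reasons and handles empty input", {
  bc <- c(s1 = "ACGTAC")
  read <- tibble::tibble(id = "bad", sequence = "NNNN",
                         quality = strrep("!", 4))
  out <- filter_reads(read, barcodes = bc, primer = "GG")
  expect_identical(out$rejected$reason, "length,quality,ambiguous,tag")
  empty <- filter_reads(read[0, ], barcodes = bc, primer = "GG")
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$rejected), 0L)
})

test_that("community spec YAML round-trips", {
  spec <- default_community_spec(n_genera = 2, species_per_genus = 2,
                                 copies_per_species = 3, seed = 17)
  f <- tempfile(fileext = ".yaml")
  write_community_spec(spec, f)
  back <- read_community_spec(f)
  expect_identical(back$lineages, spec$lineages)
  expect_equal(back$region_params, spec$region_params)
  expect_equal(back$samples, spec$samples)
  expect_identical(back$seed, spec$seed)
  refs1 <- build_reference_taxa(spec)
  refs2 <- build_reference_taxa(back)
  expect_identical(refs1, refs2)
})
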