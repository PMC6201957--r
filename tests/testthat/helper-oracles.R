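# Independent reference implementations used as oracles.  These are plain-R
# re-implementations of the definitions (full matrices, explicit loops),
# deliberately sharing no code with the package internals.

# Semi-global identity: full DP matrices with traceback.  Unit scoring,
# free terminal gaps, tie policy diagonal > up > left, endpoint = maximal
# score over last row/column with bottom-right-most preference.
oracle_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  D <- matrix(0L, n + 1, m + 1)
  if (n > 0 && m > 0) {
    for (i in 2:(n + 1)) {
      for (j in 2:(m + 1)) {
        sd <- S[i - 1, j - 1] + (if (A[i - 1] == B[j - 1]) 1 else -1)
        su <- S[i - 1, j] - 1
        sl <- S[i, j - 1] - 1
        best <- sd; d <- 0L
        if (su > best) { best <- su; d <- 1L }
        if (sl > best) { best <- sl; d <- 2L }
        S[i, j] <- best; D[i, j] <- d
      }
    }
  }
  bi <- 0; bj <- m; bs <- -Inf
  for (i in 0:n) {
    s <- S[i + 1, m + 1]
    if (s > bs || (s == bs && (i > bi || (i == bi && m > bj)))) {
      bs <- s; bi <- i; bj <- m
    }
  }
  for (j in 0:m) {
    s <- S[n + 1, j + 1]
    if (s > bs || (s == bs && (n > bi || (n == bi && j > bj)))) {
      bs <- s; bi <- n; bj <- j
    }
  }
  i <- bi; j <- bj; matches <- 0; cols <- 0
  while (i > 0 && j > 0) {
    d <- D[i + 1, j + 1]
    if (d == 0L) {
      if (A[i] == B[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (d == 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  if (cols == 0) 0 else matches / cols
}

# Brute-force first-hit greedy clustering over a precomputed identity
# matrix (rows/cols follow the processing order).
oracle_greedy <- function(idmat, threshold) {
  n <- nrow(idmat)
  centroids <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (cc in centroids) {
      if (idmat[i, cc] >= threshold - 1e-9) { hit <- cc; break }
    }
    if (hit == 0L) { centroids <- c(centroids, i); hit <- i }
    assign[i] <- hit
  }
  assign
}

# Direct evaluation of A = sum(m)/N from member lists.
oracle_commonality <- function(mem1, rep1, mem2) {
  N <- length(unlist(mem1))
  total <- 0
  for (k in seq_along(mem1)) {
    holds <- vapply(mem2, function(mm) rep1[k] %in% mm, logical(1))
    j <- which(holds)
    if (length(j) == 1) {
      total <- total + length(intersect(mem1[[k]], mem2[[j]]))
    }
  }
  total / N
}

# Naive UPGMA: returns the merge heights (sorted) for a distance matrix.
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i < j && d[active[i], active[j]] < bd) {
          bd <- d[active[i], active[j]]; best <- c(active[i], active[j])
        }
      }
    }
    heights <- c(heights, bd / 2)
    a <- best[1]; b <- best[2]
    # average-linkage update into slot a
    for (k in active) {
      if (k != a && k != b) {
        d[a, k] <- d[k, a] <-
          (sizes[a] * d[a, k] + sizes[b] * d[b, k]) / (sizes[a] + sizes[b])
      }
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  sort(heights)
}

# Exact two-sided Fisher p by enumeration of all tables with the observed
# margins: sum the probabilities of tables no more probable than observed.
oracle_fisher_p <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  lo <- max(0, k - n2); hi <- min(k, n1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(n1, x) + lchoose(n2, k - x) - lchoose(n1 + n2, k))
  }, numeric(1))
  obs <- probs[k1 - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_dna_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Build an otu_clustering object directly from member lists (for
# commonality tests on arbitrary partitions).
make_clustering <- function(members, reps = NULL, region = NA_character_,
                            threshold = NA_real_) {
  if (is.null(reps)) {
    reps <- vapply(members, function(m) m[[1]], character(1))
  }
  structure(list(
    otus = tibble::tibble(
      otu_id = sprintf("OTU_%05d", seq_along(members)),
      representative_id = reps,
      members = members
    ),
    threshold = threshold, region = region,
    universe = unlist(members, use.names = FALSE),
    ordering = "input", best_hit = FALSE
  ), class = "otu_clustering")
}

# Random partition of ids with a random representative per block.
random_partition <- function(ids, k = NULL) {
  n <- length(ids)
  k <- k %||% sample.int(n, 1)
  grp <- sample.int(k, n, replace = TRUE)
  grp <- match(grp, unique(grp))          # drop empty blocks
  members <- unname(split(ids, grp))
  reps <- vapply(members, function(m) sample(m, 1), character(1))
  make_clustering(members, reps)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# All permutations of 1..n as a list of integer vectors.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in 0:(n - 1)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

# A tiny community for fast pipeline tests: every species its own genus,
# so with all rates zero each species is one OTU everywhere.
tiny_zero_rate_spec <- function(n_species = 4, copies = 5, seed = 1) {
  lineages <- vapply(seq_len(n_species), function(g) {
    sprintf("p__P%d;c__C%d;o__O%d;f__F%d;g__G%d;s__G%d_sp1",
            g, g, g, g, g, g)
  }, character(1))
  rp <- list(
    ITS1 = region_params(60, 0, 0.5, 0, 0),
    `5.8S` = region_params(50, 0, 0.5, 0, 0),
    ITS2 = region_params(60, 0, 0.55, 0, 0)
  )
  community_spec(lineages, region_params = rp, seed = seed,
                 copies_default = copies)
}
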