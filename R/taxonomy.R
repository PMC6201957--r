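#' Best-hit search of queries against a reference database
#'
#' Exhaustive identity scan (every query aligned to every reference with
#' the semi-global identity of [pairwise_identity()]).  The hit is the
#' reference with maximal identity; ties are broken by the longer aligned
#' span, then by the lexicographically smallest accession, so the result is
#' deterministic and independent of database order.
#'
#' @param queries Data frame with `id` and `sequence`; an `accession`
#'   column gives each query's source accession and a `lineage` column its
#'   true lineage (both used for the resolution rates).
#' @param db Data frame with `accession` (unique), `sequence` and
#'   `lineage`.
#' @param exclude_self Leave-one-out mode: a query never hits the database
#'   record carrying its own source accession (off by default — the
#'   standard self-search includes the query's own record).
#' @return Tibble with one row per query: `query_id`, `source_accession`,
#'   `hit_accession`, `identity`, `columns`, `hit_lineage`,
#'   `same_accession`, `same_species`.
#' @export
best_hits <- function(queries, db, exclude_self = FALSE) {
  assert_seq_df(queries, c("id", "sequence"), "queries")
  assert_seq_df(db, c("accession", "sequence"), "db")
  if (nrow(db) == 0L) stop("db must be non-empty")
  if (anyDuplicated(db$accession)) stop("db accessions must be unique")
  if (any(!nzchar(queries$sequence))) stop("empty query sequence")
  db <- db[radix_order(db$accession), ]
  excl <- rep(NA_integer_, nrow(queries))
  if (exclude_self) {
    if (!"accession" %in% names(queries)) {
      stop("exclude_self needs a query accession column")
    }
    excl <- match(queries$accession, db$accession)
    if (nrow(db) < 2L) stop("leave-one-out needs at least 2 references")
  }
  hits <- cpp_best_hits(queries$sequence, db$sequence, excl)
  idx <- as.integer(hits[, "ref_index"])
  src <- if ("accession" %in% names(queries)) queries$accession else
    NA_character_
  qsp <- if ("lineage" %in% names(queries)) {
    lineage_rank(queries$lineage, "species")
  } else NA_character_
  hit_lin <- if ("lineage" %in% names(db)) db$lineage[idx] else
    NA_character_
  hsp <- if ("lineage" %in% names(db)) lineage_rank(hit_lin, "species") else
    NA_character_
  tibble(
    query_id = queries$id,
    source_accession = src,
    hit_accession = db$accession[idx],
    identity = unname(hits[, "identity"]),
    columns = as.integer(unname(hits[, "columns"])),
    hit_lineage = hit_lin,
    same_accession = src == db$accession[idx],
    same_species = qsp == hsp
  )
}

#' Self-return rate of a marker against its reference database
#'
#' Fraction of queries whose best hit is their own source record (the same
#' accession).  The database includes the query's own record — this is a
#' full-database self-search, the standard measure of a region's
#' identification power; identical references mean a query can be beaten
#' to its own accession by the tie policy.
#'
#' @param queries Data frame of region records carrying `accession` (their
#'   source), or a precomputed [best_hits()] result (then `db` is omitted).
#' @param db Reference database (see [best_hits()]).
#' @return Fraction in `[0, 1]`.
#' @export
self_return_rate <- function(queries, db = NULL) {
  hits <- resolve_hits(queries, db)
  if (any(is.na(hits$source_accession))) {
    stop("queries must carry their source accession")
  }
  mean(hits$same_accession)
}

#' Species-agreement rate against a reference database
#'
#' Fraction of queries whose best hit belongs to the same species binomial
#' as the query's source.  Always at least the self-return rate (the same
#' accession implies the same species).
#'
#' @inheritParams self_return_rate
#' @return Fraction in `[0, 1]`.
#' @export
species_agreement_rate <- function(queries, db = NULL) {
  hits <- resolve_hits(queries, db)
  if (any(is.na(hits$same_species))) {
    stop("queries and db must carry species lineages")
  }
  mean(hits$same_species)
}

resolve_hits <- function(queries, db) {
  if (is.null(db)) {
    if (!all(c("same_accession", "same_species") %in% names(queries))) {
      stop("pass a best_hits() result, or queries plus db")
    }
    return(queries)
  }
  best_hits(queries, db)
}

#' Classified/unclassified composition per taxonomic rank
#'
#' A query is classified at a rank iff its best hit's lineage has a named
#' (non-"unclassified") value at that rank and the hit identity reaches the
#' rank's identity floor (all floors default to 0: pure best-hit transfer).
#'
#' @param hits A [best_hits()] result.
#' @param ranks Ranks to report (default all six).
#' @param floors Named numeric vector of per-rank identity floors, e.g.
#'   `c(genus = 0.95)`; unnamed ranks get 0.
#' @return Tibble with one row per rank: `rank`, `n_taxa` (distinct
#'   classified values), `classified_pct`, `unclassified_pct` (percentages
#'   summing to 100).
#' @export
rank_composition <- function(hits, ranks = LINEAGE_RANKS, floors = NULL) {
  ranks <- match.arg(ranks, LINEAGE_RANKS, several.ok = TRUE)
  lin <- parse_lineage(hits$hit_lineage)
  purrr::map_dfr(ranks, function(r) {
    floor_r <- if (!is.null(floors) && r %in% names(floors)) floors[[r]]
    else 0
    val <- lin[[r]]
    ok <- !is.na(val) & val != "unclassified" & hits$identity >= floor_r
    tibble(rank = r,
           n_taxa = dplyr::n_distinct(val[ok]),
           classified_pct = 100 * mean(ok),
           unclassified_pct = 100 * mean(!ok))
  })
}

#' Exact Mann-Whitney U test by permutation enumeration
#'
#' Two-sided Mann-Whitney U.  For small samples (both sizes at most
#' `exact_max`) the null distribution of U is enumerated over all
#' assignments of the pooled values (ties handled by midranks), and
#' `p = min(1, 2 min(P(U <= u), P(U >= u)))`.  Larger samples use the
#' normal approximation of [stats::wilcox.test()].
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for which the exact enumeration is
#'   used (default 8).
#' @return One-row tibble: `statistic` (U for the first sample), `p_value`,
#'   `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups need at least one value")
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(k) sum(r[k]) - n1 * (n1 + 1) / 2)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u1 + eps), mean(us >= u1 - eps)))
    method <- "exact permutation"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    method <- "normal approximation"
  }
  tibble(statistic = u1, p_value = p, method = method)
}

#' Rank-sum screen for taxa differing between sample groups
#'
#' Applies the Mann-Whitney U test ([mann_whitney()]) to every taxon and
#' every pair of groups; exact enumeration at the small group sizes typical
#' of field studies, normal approximation otherwise.
#'
#' @param abundance Long tibble with columns `taxon`, `sample`,
#'   `abundance`, or a taxa-by-sample matrix with dimnames.
#' @param groups Mapping sample -> group: named character vector or data
#'   frame with `sample` and `group` columns.  At least two groups, each
#'   with at least one sample.
#' @param exact_max Passed to [mann_whitney()].
#' @return Tibble with one row per taxon x group pair: `taxon`, `group1`,
#'   `group2`, `statistic`, `p_value`, `method`, and BH-adjusted
#'   `p_adjusted` (within each group pair).
#' @export
differential_taxa <- function(abundance, groups, exact_max = 8L) {
  if (is.matrix(abundance)) {
    abundance <- as_tibble(abundance, rownames = "taxon") |>
      tidyr::pivot_longer(-"taxon", names_to = "sample",
                          values_to = "abundance")
  }
  assert_seq_df(abundance, c("taxon", "sample", "abundance"), "abundance")
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample)
  unmapped <- setdiff(unique(abundance$sample), names(groups))
  if (length(unmapped)) {
    stop("no group for sample(s): ", paste(unmapped, collapse = ", "))
  }
  gl <- sort(unique(unname(groups)), method = "radix")
  if (length(gl) < 2L) stop("need at least 2 groups")
  abundance$group <- unname(groups[abundance$sample])
  pairs <- combn(gl, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(gp) {
    purrr::map_dfr(split(abundance, abundance$taxon), function(d) {
      xv <- d$abundance[d$group == gp[1]]
      yv <- d$abundance[d$group == gp[2]]
      if (length(xv) == 0L || length(yv) == 0L) {
        stop("group with zero samples for taxon ", d$taxon[1])
      }
      dplyr::bind_cols(tibble(taxon = d$taxon[1], group1 = gp[1],
                              group2 = gp[2]),
                       mann_whitney(xv, yv, exact_max))
    })
  })
  out |>
    dplyr::group_by(.data$group1, .data$group2) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, "BH")) |>
    dplyr::ungroup()
}

#' Fisher's exact test for a difference between two rates
#'
#' Two-sided Fisher's exact test on the 2x2 table `(k1, n1-k1; k2, n2-k2)`,
#' with the two-sided p-value computed by summing tables whose probability
#' does not exceed the observed one.
#'
#' @param k1,n1 Successes and total in the first group.
#' @param k2,n2 Successes and total in the second group.
#' @return One-row tibble: `p_value`, `rate1`, `rate2`, `odds_ratio`.
#' @export
rate_difference_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("totals must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("successes must satisfy 0 <= k <= n")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  fit <- fisher.test(tab)
  tibble(p_value = fit$p.value, rate1 = k1 / n1, rate2 = k2 / n2,
         odds_ratio = unname(fit$estimate))
}
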