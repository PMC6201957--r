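#' Find the OTU of a second clustering that contains a representative
#'
#' Cross-clustering matching follows the representative-containment rule:
#' the match for an OTU of clustering 1 is the unique OTU of clustering 2
#' whose members contain clustering 1's representative sequence (ids are
#' compared after applying `key`, so `read1/ITS1` and `read1/ITS2` refer to
#' the same underlying read).  This is deliberately not maximum-overlap
#' matching; see [otu_commonality()].
#'
#' @param clustering2 An `otu_clustering`.
#' @param representative_id Representative sequence id from the other
#'   clustering.
#' @param key Function mapping ids to shared keys (default strips a
#'   trailing `/REGION` suffix).
#' @return The matching `otu_id`, or `NA` if the representative's key is
#'   absent from clustering 2's universe.
#' @export
match_otu <- function(clustering2, representative_id,
                      key = strip_read_key) {
  stopifnot(inherits(clustering2, "otu_clustering"))
  mem <- otu_membership(clustering2)
  hit <- match(key(representative_id), key(mem$id))
  mem$otu_id[hit]
}

#' Cross-clustering OTU commonality (the statistic A)
#'
#' For two clusterings of the same underlying reads, every OTU `i` of
#' database 1 is matched to the OTU of database 2 containing its
#' representative sequence; `m_i` is the number of reads shared by the two
#' matched OTUs (0 when the representative is absent from database 2).
#' The commonality is `A = sum(m_i) / N` with `N` the number of reads in
#' database 1.  `A(c, c) = 1` for any clustering; `A` is directional and
#' both directions are generally different, so callers should report both
#' (see [region_commonality()]).
#'
#' @param c1,c2 `otu_clustering` objects (database 1 and database 2).
#' @param key Shared-key function applied to ids before comparison
#'   (default strips a trailing `/REGION` suffix, so the ITS/ITS1/ITS2
#'   records cut from one read are identified).
#' @param restrict_shared Recompute on the intersection of the two
#'   universes instead of all of database 1 (`N` then counts shared reads
#'   only).
#' @param mode `"representative"` (the default, and the definition of the
#'   statistic) or `"max_overlap"`, a sensitivity-analysis variant that
#'   matches each OTU to the database-2 OTU sharing the most reads (ties:
#'   smallest `otu_id`).
#' @return An object of class `otu_commonality` with fields `A`, `N`, `n`
#'   (OTUs in database 1), `sum_m`, `per_otu` (tibble of per-OTU matches),
#'   `threshold_pair` and `direction`.  Supports [tidy()] and [glance()].
#' @export
otu_commonality <- function(c1, c2, key = strip_read_key,
                            restrict_shared = FALSE,
                            mode = c("representative", "max_overlap")) {
  stopifnot(inherits(c1, "otu_clustering"), inherits(c2, "otu_clustering"))
  if (length(c1$universe) == 0L) stop("database 1 universe is empty")
  mode <- match.arg(mode)

  u1 <- key(c1$universe)
  mem2 <- otu_membership(c2)
  k2 <- key(mem2$id)
  otu2_of <- setNames(mem2$otu_id, k2)

  shared <- NULL
  if (restrict_shared) shared <- intersect(u1, k2)

  per <- purrr::pmap_dfr(
    list(c1$otus$otu_id, c1$otus$representative_id, c1$otus$members),
    function(oid, rep_id, members) {
      mk <- key(members)
      if (restrict_shared) mk <- mk[mk %in% shared]
      if (mode == "representative") {
        hit <- unname(otu2_of[key(rep_id)])
        m <- if (is.na(hit)) 0L else sum(k2[otu2_of == hit] %in% mk)
      } else {
        counts <- table(otu2_of[k2 %in% mk])
        if (length(counts) == 0L) {
          hit <- NA_character_; m <- 0L
        } else {
          best <- sort(names(counts)[counts == max(counts)])[1]
          hit <- best; m <- as.integer(counts[best])
        }
      }
      tibble(otu1_id = oid, representative_id = rep_id,
             size = length(mk), matched_otu2 = hit, m = m)
    })

  N <- if (restrict_shared) length(shared) else length(u1)
  structure(list(
    A = sum(per$m) / N, N = N, n = nrow(c1$otus), sum_m = sum(per$m),
    per_otu = per,
    threshold_pair = c(c1$threshold, c2$threshold),
    direction = c(db1 = c1$region %||% NA_character_,
                  db2 = c2$region %||% NA_character_)
  ), class = "otu_commonality")
}

#' @export
print.otu_commonality <- function(x, ...) {
  cat("<otu_commonality> A = ", format(x$A, digits = 4),
      " (sum m = ", x$sum_m, ", N = ", x$N, ", n = ", x$n, " OTUs; ",
      x$direction[1], " vs ", x$direction[2], ")\n", sep = "")
  invisible(x)
}

#' Commonality between every ordered pair of region clusterings
#'
#' Computes the directed statistic `A` for all ordered pairs of the given
#' clusterings and, since the two directions of a pair generally differ,
#' also the symmetrized pair mean used when a single number per region pair
#' is wanted.
#'
#' @param clusterings Named list of `otu_clustering` objects (names are the
#'   region labels, e.g. `ITS`, `ITS1`, `ITS2`).
#' @param key,restrict_shared Passed to [otu_commonality()].
#' @return Tibble with one row per ordered pair: `db1`, `db2`, `t1`, `t2`,
#'   `N`, `n_otus`, `sum_m`, `A`, plus `A_pair_mean`, the mean of the two
#'   directions of the unordered pair.
#' @export
region_commonality <- function(clusterings, key = strip_read_key,
                               restrict_shared = FALSE) {
  labs <- names(clusterings)
  stopifnot(length(labs) >= 2L, !is.null(labs))
  rows <- list()
  for (i in labs) {
    for (j in labs) {
      if (i == j) next
      cm <- otu_commonality(clusterings[[i]], clusterings[[j]], key,
                            restrict_shared)
      rows[[paste(i, j)]] <- tibble(
        db1 = i, db2 = j,
        t1 = cm$threshold_pair[1], t2 = cm$threshold_pair[2],
        N = cm$N, n_otus = cm$n, sum_m = cm$sum_m, A = cm$A
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  pair_key <- purrr::map2_chr(out$db1, out$db2,
                              ~ paste(sort(c(.x, .y)), collapse = "|"))
  out |>
    dplyr::mutate(pair = pair_key) |>
    dplyr::group_by(.data$pair) |>
    dplyr::mutate(A_pair_mean = mean(.data$A)) |>
    dplyr::ungroup() |>
    dplyr::select(-"pair")
}

#' Distinct species per OTU
#'
#' Counts, for every OTU, the number of distinct species binomials among
#' its members, and the mean over OTUs — the species-lumping measure of a
#' marker at a given clustering threshold.
#'
#' @param clustering An `otu_clustering`.
#' @param lineage_of Mapping id -> lineage: named character vector or data
#'   frame with `id` and `lineage` columns.  Ids are compared after
#'   stripping region suffixes.  Every member must have a lineage with a
#'   species field.
#' @return List with `mean_species` (numeric) and `per_otu` (tibble of
#'   `otu_id`, `size`, `n_species`).
#' @export
species_per_otu <- function(clustering, lineage_of) {
  stopifnot(inherits(clustering, "otu_clustering"))
  if (is.data.frame(lineage_of)) {
    lineage_of <- setNames(lineage_of$lineage, lineage_of$id)
  }
  names(lineage_of) <- strip_read_key(names(lineage_of))
  species_of <- setNames(lineage_rank(lineage_of, "species"),
                         names(lineage_of))
  per <- purrr::pmap_dfr(
    list(clustering$otus$otu_id, clustering$otus$members),
    function(oid, members) {
      sp <- species_of[strip_read_key(members)]
      if (any(is.na(sp))) {
        stop("member without species lineage in ", oid)
      }
      tibble(otu_id = oid, size = length(members),
             n_species = dplyr::n_distinct(sp))
    })
  list(mean_species = mean(per$n_species), per_otu = per)
}
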