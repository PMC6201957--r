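#' Pairwise sequence identity (semi-global alignment)
#'
#' Identity under a global alignment with free terminal gaps (unit
#' match/mismatch/gap scoring): matches divided by the number of alignment
#' columns, excluding columns spanned only by terminal gaps.  Symmetric in
#' its arguments.
#'
#' @param a,b Character vectors of sequences (recycled to a common length).
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
pairwise_identity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("sequences must be non-empty")
  }
  unname(cpp_identity_pairs(a, b)[, "identity"])
}

#' Greedy centroid OTU clustering at an identity threshold
#'
#' UCLUST-style greedy clustering: records are processed in a fixed order;
#' each record joins the first existing centroid whose identity to it is at
#' least `threshold`, otherwise it founds a new OTU and becomes its
#' centroid (representative).  The default ordering is length-descending,
#' then abundance-descending (when an `abundance` column is present), then
#' lexicographic id; `ordering = "input"` preserves the given order.
#'
#' @param records Data frame with `id` and `sequence` columns (ids unique);
#'   optional `abundance` column for the ordering policy.
#' @param threshold Identity threshold in `(0, 1]` (conventionally
#'   0.91-0.99; 0.97 is the standard species-proxy level).
#' @param ordering `"length"` (default) or `"input"`.
#' @param best_hit Assign to the best-identity centroid above threshold
#'   instead of the first (sensitivity-analysis mode).
#' @param dereplicate Collapse identical sequences before clustering (the
#'   duplicates join their exemplar's OTU afterwards); duplicates count as
#'   abundance for the ordering policy.  Off by default.
#' @param region Optional region label (`"ITS"`, `"ITS1"`, `"ITS2"`)
#'   attached to the result.
#' @return An object of class `otu_clustering`: a list with `otus` (tibble
#'   of `otu_id`, `representative_id`, `members` list-column in processing
#'   order), `threshold`, `region`, `universe` (the clustered ids) and
#'   `ordering`.  Supports [tidy()] and [glance()].
#' @export
greedy_cluster <- function(records, threshold = 0.97,
                           ordering = c("length", "input"),
                           best_hit = FALSE, dereplicate = FALSE,
                           region = NULL) {
  assert_seq_df(records)
  if (nrow(records) == 0L) stop("records must be non-empty")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (anyDuplicated(records$id)) stop("duplicate record ids")
  ordering <- match.arg(ordering)

  if (dereplicate) {
    seqs_up <- toupper(records$sequence)
    grp <- match(seqs_up, unique(seqs_up))
    exemplar <- !duplicated(grp)
    uniq <- records[exemplar, , drop = FALSE]
    uniq$abundance <- as.integer(table(grp)[as.character(grp[exemplar])])
    cl <- greedy_cluster(uniq, threshold, ordering, best_hit,
                         dereplicate = FALSE, region = region)
    dup_of <- setNames(records$id[exemplar][grp], records$id)
    cl$otus$members <- lapply(cl$otus$members, function(m) {
      unlist(lapply(m, function(ex) {
        names(dup_of)[dup_of == ex]
      }), use.names = FALSE)
    })
    cl$universe <- unlist(cl$otus$members, use.names = FALSE)
    return(cl)
  }

  ord <- seq_len(nrow(records))
  if (ordering == "length") {
    ab <- if ("abundance" %in% names(records)) records$abundance
          else rep(0, nrow(records))
    ord <- radix_order(-nchar(records$sequence), -xtfrm(ab), records$id)
  }
  ids <- records$id[ord]
  seqs <- toupper(records$sequence[ord])

  assign <- cpp_greedy_cluster(seqs, threshold, best_hit)
  cent_order <- unique(assign)              # first-appearance order
  otu_of <- match(assign, cent_order)
  otus <- tibble(
    otu_id = sprintf("OTU_%05d", seq_along(cent_order)),
    representative_id = ids[cent_order],
    members = unname(split(ids, factor(otu_of, seq_along(cent_order))))
  )
  structure(list(otus = otus, threshold = threshold,
                 region = region %||% NA_character_,
                 universe = ids, ordering = ordering,
                 best_hit = best_hit),
            class = "otu_clustering")
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat("<otu_clustering> ", nrow(x$otus), " OTUs over ",
      length(x$universe), " sequences at ",
      format(100 * x$threshold), "% identity",
      if (!is.na(x$region)) paste0(" [", x$region, "]"), "\n", sep = "")
  invisible(x)
}

#' Per-sequence OTU membership
#'
#' @param clustering An `otu_clustering`.
#' @return Tibble with columns `id`, `otu_id`, `representative_id`.
#' @export
otu_membership <- function(clustering) {
  stopifnot(inherits(clustering, "otu_clustering"))
  tidyr::unnest(
    dplyr::select(clustering$otus, "otu_id", "representative_id", "members"),
    "members"
  ) |>
    dplyr::rename(id = "members") |>
    dplyr::select("id", "otu_id", "representative_id")
}

#' OTU-by-sample count table
#'
#' @param clustering An `otu_clustering`.
#' @param sample_of Mapping from sequence id to sample: a named character
#'   vector or a data frame with `id` and `sample` columns.  Every clustered
#'   id must be mapped.
#' @return Integer matrix (OTUs x samples); row sums are OTU sizes and the
#'   grand total is the universe size.
#' @export
otu_table <- function(clustering, sample_of) {
  stopifnot(inherits(clustering, "otu_clustering"))
  if (is.data.frame(sample_of)) {
    sample_of <- setNames(sample_of$sample, sample_of$id)
  }
  unmapped <- setdiff(clustering$universe, names(sample_of))
  if (length(unmapped)) {
    stop("no sample for id(s): ", paste(head(unmapped, 5), collapse = ", "))
  }
  mem <- otu_membership(clustering)
  smp <- sample_of[mem$id]
  samples <- sort(unique(unname(smp)), method = "radix")
  tab <- table(factor(mem$otu_id, clustering$otus$otu_id),
               factor(smp, samples))
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  mat
}

#' Cluster the same records across several thresholds
#'
#' @param records As for [greedy_cluster()].
#' @param thresholds Numeric vector of identity thresholds.
#' @param ... Passed to [greedy_cluster()].
#' @return Named list of `otu_clustering` objects (names = thresholds).
#' @export
cluster_sweep <- function(records, thresholds = seq(0.91, 0.99, by = 0.01),
                          ...) {
  setNames(
    lapply(thresholds, function(t) greedy_cluster(records, t, ...)),
    format(thresholds)
  )
}
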