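#' Tidy an OTU clustering
#'
#' @param x An `otu_clustering`.
#' @param ... Unused.
#' @return One row per OTU: `otu_id`, `representative_id`, `size`.
#' @export
tidy.otu_clustering <- function(x, ...) {
  tibble(otu_id = x$otus$otu_id,
         representative_id = x$otus$representative_id,
         size = lengths(x$otus$members))
}

#' @rdname tidy.otu_clustering
#' @return `glance()`: one row with `n_otus`, `n_seq`, `threshold`,
#'   `region`, `ordering`.
#' @export
glance.otu_clustering <- function(x, ...) {
  tibble(n_otus = nrow(x$otus), n_seq = length(x$universe),
         threshold = x$threshold, region = x$region, ordering = x$ordering)
}

#' Tidy a commonality result
#'
#' @param x An `otu_commonality`.
#' @param ... Unused.
#' @return `tidy()`: the per-OTU match table (`otu1_id`,
#'   `representative_id`, `size`, `matched_otu2`, `m`).
#' @export
tidy.otu_commonality <- function(x, ...) x$per_otu

#' @rdname tidy.otu_commonality
#' @return `glance()`: one row with `db1`, `db2`, `t1`, `t2`, `N`,
#'   `n_otus`, `sum_m`, `A`.
#' @export
glance.otu_commonality <- function(x, ...) {
  tibble(db1 = unname(x$direction[1]), db2 = unname(x$direction[2]),
         t1 = x$threshold_pair[1], t2 = x$threshold_pair[2],
         N = x$N, n_otus = x$n, sum_m = x$sum_m, A = x$A)
}
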