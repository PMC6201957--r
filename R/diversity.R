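#' Bias-corrected Chao1 richness estimator
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and `F2` are the
#' numbers of singleton and doubleton OTUs.  Always at least `S_obs`.
#'
#' @param counts Positive integer abundances, one per observed OTU.
#' @return The Chao1 estimate (numeric scalar).
#' @export
#' @examples
#' chao1(c(5, 3, 4))      # no singletons: 3
#' chao1(c(1, 1, 2, 5))   # 4 + 2*1/(2*2) = 4.5
chao1 <- function(counts) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  if (any(counts < 1)) stop("counts must all be >= 1")
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` over relative OTU abundances, natural log by
#' default.
#'
#' @param counts Positive abundances, one per observed OTU.
#' @param base Logarithm base (default `exp(1)`; 2 and 10 are the usual
#'   alternatives).
#' @return The Shannon index (numeric scalar, >= 0).
#' @export
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
#' shannon(10)             # 0
shannon <- function(counts, base = exp(1)) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  if (any(counts <= 0)) stop("counts must all be positive")
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity from an OTU table
#'
#' @param table OTU-by-sample count matrix (see [otu_table()]).
#' @param base Logarithm base for the Shannon index.
#' @return Tibble with one row per sample: `sample`, `s_obs`, `chao1`,
#'   `shannon`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  if (is.null(colnames(table))) stop("table needs sample column names")
  purrr::map_dfr(colnames(table), function(s) {
    counts <- table[, s]
    counts <- counts[counts > 0]
    if (length(counts) == 0L) stop("sample ", s, " has zero counts")
    tibble(sample = s, s_obs = length(counts),
           chao1 = chao1(counts), shannon = shannon(counts, base))
  })
}

#' Between-sample dendrogram from OTU composition
#'
#' Bray-Curtis dissimilarity on per-sample relative abundances, clustered
#' by average linkage (UPGMA) by default.  Sample columns are ordered
#' lexicographically before clustering so the result is deterministic.
#'
#' @param table OTU-by-sample count matrix with at least two samples, each
#'   with at least one count.
#' @param method Dissimilarity passed to [vegan::vegdist()] (default
#'   `"bray"`).
#' @param linkage Agglomeration method passed to [stats::hclust()] (default
#'   `"average"`, i.e. UPGMA).
#' @return An [ape::as.phylo()] tree over the samples; serialise with
#'   [write_newick()].
#' @export
sample_dendrogram <- function(table, method = "bray", linkage = "average") {
  if (ncol(table) < 2L) stop("need at least 2 samples")
  if (any(colSums(table) == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(table)[colSums(table) == 0], collapse = ", "))
  }
  table <- table[, sort(colnames(table), method = "radix"), drop = FALSE]
  rel <- sweep(table, 2, colSums(table), "/")
  d <- vegan::vegdist(t(rel), method = method)
  ape::as.phylo(hclust(d, method = linkage))
}

#' Write a tree in newick format
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
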