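#' GC content of DNA sequences
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases are excluded from both the
#' numerator and the denominator.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
#' @examples
#' gc_content(c("GGCC", "ATAT", "ATGCNN"))
gc_content <- function(sequence) {
  s <- toupper(sequence)
  gc <- stringr::str_count(s, "[GC]")
  acgt <- stringr::str_count(s, "[ACGT]")
  if (any(acgt == 0L)) {
    stop("sequence with no unambiguous base (all-N?) at position ",
         which(acgt == 0L)[1])
  }
  gc / acgt
}

seq_lengths <- function(records) {
  if (is.data.frame(records)) {
    assert_seq_df(records, "sequence")
    nchar(records$sequence)
  } else if (is.character(records)) {
    nchar(records)
  } else {
    as.numeric(records)
  }
}

#' Count sequences below/within/above a length band
#'
#' The conventional extreme-length filter: sequences strictly shorter than
#' `low` or strictly longer than `high` bp are the extremes.
#'
#' @param records Data frame with a `sequence` column, a character vector of
#'   sequences, or a numeric vector of lengths.
#' @param low,high Band bounds in bp (defaults 100 and 600).
#' @return One-row tibble: `below`, `within`, `above`, `n`,
#'   `fraction_extreme`.
#' @export
length_class_counts <- function(records, low = 100L, high = 600L) {
  if (low >= high) stop("low must be < high")
  len <- seq_lengths(records)
  if (length(len) == 0L) stop("records must be non-empty")
  below <- sum(len < low)
  above <- sum(len > high)
  tibble(below = below, within = length(len) - below - above,
         above = above, n = length(len),
         fraction_extreme = (below + above) / length(len))
}

#' Count sequences with extreme GC content
#'
#' Sequences with GC strictly below `low` or strictly above `high` are the
#' extremes (defaults 20% and 80%).
#'
#' @param records Data frame with a `sequence` column, a character vector of
#'   sequences, or a numeric vector of GC fractions.
#' @param low,high GC band bounds as fractions.
#' @return One-row tibble: `below`, `within`, `above`, `n`,
#'   `fraction_extreme`.
#' @export
gc_extreme_counts <- function(records, low = 0.20, high = 0.80) {
  if (low >= high) stop("low must be < high")
  gc <- if (is.numeric(records)) records else {
    gc_content(if (is.data.frame(records)) records$sequence else records)
  }
  if (length(gc) == 0L) stop("records must be non-empty")
  below <- sum(gc < low)
  above <- sum(gc > high)
  tibble(below = below, within = length(gc) - below - above, above = above,
         n = length(gc), fraction_extreme = (below + above) / length(gc))
}

#' Length and GC summaries per taxonomic group
#'
#' One row per distinct value of the chosen rank (lineages lacking the rank
#' are grouped under `"unclassified"`): count, length summary, mean GC, and
#' the fractions of sequences with extreme length (`< len_low` / `> len_high`
#' bp) and extreme GC (`< gc_low` / `> gc_high`).
#'
#' @param records Data frame with `sequence` and `lineage` columns.
#' @param rank Taxonomic rank to group by.
#' @param len_low,len_high,gc_low,gc_high Extreme-value thresholds.
#' @return Tibble of per-group summaries.
#' @export
group_summary <- function(records, rank = "phylum",
                          len_low = 100L, len_high = 600L,
                          gc_low = 0.20, gc_high = 0.80) {
  assert_seq_df(records, c("sequence", "lineage"))
  rank <- match.arg(rank, LINEAGE_RANKS)
  if (any(is.na(records$lineage))) {
    stop("every record needs a lineage")
  }
  grp <- lineage_rank(records$lineage, rank)
  grp[is.na(grp) | grp == ""] <- "unclassified"
  tibble(group = grp,
         len = nchar(records$sequence),
         gc = gc_content(records$sequence)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_length = mean(.data$len),
      min_length = min(.data$len),
      max_length = max(.data$len),
      mean_gc = mean(.data$gc),
      pct_length_extreme = mean(.data$len < len_low | .data$len > len_high),
      pct_gc_extreme = mean(.data$gc < gc_low | .data$gc > gc_high),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
}

#' Two-sample t test (classical pooled-variance form)
#'
#' Student's equal-variance t by default (`var_equal = FALSE` gives Welch).
#' Degenerate inputs follow fixed conventions: two identical constant
#' samples give `t = 0, p = 1`; zero pooled variance with unequal means
#' gives `p = 0` with infinite `t`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (Student's t) or not (Welch).
#' @return One-row tibble: `statistic`, `p_value`, `df`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) {
      return(tibble(statistic = 0, p_value = 1, df = df,
                    mean_x = mean(x), mean_y = mean(y)))
    }
    return(tibble(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0,
                  df = df, mean_x = mean(x), mean_y = mean(y)))
  }
  fit <- t.test(x, y, var.equal = var_equal)
  tibble(statistic = unname(fit$statistic), p_value = fit$p.value,
         df = unname(fit$parameter), mean_x = mean(x), mean_y = mean(y))
}
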