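DNA_BASES <- c("A", "C", "G", "T")

LINEAGE_RANKS <- c("phylum", "class", "order", "family", "genus", "species")
RANK_PREFIXES <- c(phylum = "p", class = "c", order = "o", family = "f",
                   genus = "g", species = "s")

# Deterministic child seed derived from a top-level seed and an operation tag,
# kept below 2^31 so it is always a valid R integer seed.
split_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_child_seed <- function(seed, tag, code) {
  withr::with_seed(split_seed(seed, tag), code)
}

#' Parse semicolon-delimited taxonomy lineages
#'
#' Lineages follow the UNITE-style 6-rank convention
#' `p__Phylum;c__Class;o__Order;f__Family;g__Genus;s__Genus_species`
#' (the kingdom field of FASTA headers is stripped on read).
#'
#' @param lineage Character vector of lineage strings.
#' @return A tibble with one row per lineage and one column per rank
#'   (`phylum` ... `species`); missing or empty fields become `NA`.
#' @export
#' @examples
#' parse_lineage("p__Ascomycota;c__C1;o__O1;f__F1;g__G1;s__G1_sp1")
parse_lineage <- function(lineage) {
  parts <- stringr::str_split(lineage, ";")
  rows <- purrr::map(parts, function(p) {
    vals <- rep(NA_character_, 6)
    p <- p[nzchar(p)]
    for (i in seq_along(LINEAGE_RANKS)) {
      if (i <= length(p)) {
        v <- sub("^[a-z]__", "", p[i])
        if (nzchar(v)) vals[i] <- v
      }
    }
    vals
  })
  out <- do.call(rbind, rows)
  colnames(out) <- LINEAGE_RANKS
  as_tibble(out)
}

#' Extract one rank from lineage strings
#'
#' @param lineage Character vector of 6-rank lineage strings.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return Character vector of rank values (`NA` where absent).
#' @export
lineage_rank <- function(lineage, rank) {
  rank <- match.arg(rank, LINEAGE_RANKS)
  parse_lineage(lineage)[[rank]]
}

make_lineage <- function(phylum, class, order, family, genus, species) {
  paste0("p__", phylum, ";c__", class, ";o__", order, ";f__", family,
         ";g__", genus, ";s__", species)
}

assert_lineage6 <- function(lineage) {
  nfield <- lengths(stringr::str_split(lineage, ";"))
  if (any(nfield != 6L)) {
    stop("lineage paths must have exactly 6 ranks (phylum..species); found ",
         paste(unique(nfield[nfield != 6L]), collapse = ", "), " field(s)",
         call. = FALSE)
  }
  invisible(lineage)
}

# i.i.d. bases with P(G or C) = gc; the generator's GC model.
random_dna <- function(n_seq, lengths, gc) {
  lengths <- rep_len(lengths, n_seq)
  purrr::map_chr(lengths, function(L) {
    is_gc <- runif(L) < gc
    b <- ifelse(is_gc,
                sample(c("G", "C"), L, replace = TRUE),
                sample(c("A", "T"), L, replace = TRUE))
    paste(b, collapse = "")
  })
}

# Per-site independent substitution to a uniformly chosen different base.
mutate_sites <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  purrr::map_chr(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate)
    if (length(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
      s <- paste(ch, collapse = "")
    }
    s
  })
}

# Integer lengths from a normal truncated below at `min_len` (inverse-CDF
# truncation, so no rejection loop), rounded.
draw_lengths <- function(n, mean, sd, min_len = 10L) {
  if (sd <= 0) return(rep(as.integer(round(max(mean, min_len))), n))
  lo <- pnorm(min_len - 0.5, mean, sd)
  as.integer(pmax(round(qnorm(runif(n, lo, 1), mean, sd)), min_len))
}

phred_to_int <- function(quality) {
  purrr::map(quality, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(scores) {
  purrr::map_chr(scores, function(v) intToUtf8(v + 33L))
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Strip a trailing /SUFFIX so that the ITS/ITS1/ITS2 records cut from one
# full-length read share a key (ids without a suffix pass through).
strip_read_key <- function(ids) sub("/[^/]*$", "", ids)

radix_order <- function(...) order(..., method = "radix")

assert_seq_df <- function(df, cols = c("id", "sequence"), what = "records") {
  if (!is.data.frame(df)) stop(what, " must be a data frame", call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
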