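#' Standard ITS amplification primers
#'
#' The two primers conventionally used to amplify the full ITS region:
#' ITS5 anneals at the 18S 3' end and ITS4 in the 28S 5' region.
#'
#' @return Named character vector with elements `ITS5` and `ITS4`.
#' @export
its_primers <- function() {
  c(ITS5 = "GGAAGTAAAAGTCGTAACAAGG",
    ITS4 = "ATCCTCCGCTTATTGATATGC")
}

#' Deterministic per-sample barcodes
#'
#' @param samples Character vector of sample ids.
#' @param width Barcode length in bp (default 6, the conventional tag size).
#' @param seed Integer seed.
#' @return Named character vector of distinct barcodes, one per sample.
#' @export
make_barcodes <- function(samples, width = 6L, seed = 1L) {
  samples <- unique(samples)
  with_child_seed(seed, "make_barcodes", {
    bc <- character(0)
    while (length(bc) < length(samples)) {
      cand <- random_dna(length(samples) * 2L, width, 0.5)
      bc <- unique(c(bc, cand))
    }
    setNames(bc[seq_along(samples)], samples)
  })
}

apply_read_errors <- function(seqs, error_rate, indel_rate) {
  if (error_rate <= 0 && indel_rate <= 0) return(seqs)
  purrr::map_chr(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (error_rate > 0) {
      hit <- which(runif(length(ch)) < error_rate)
      if (length(hit)) {
        ch[hit] <- vapply(ch[hit], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1))
      }
    }
    if (indel_rate > 0) {
      u <- runif(length(ch))
      del <- u < indel_rate / 2
      ins <- u >= indel_rate / 2 & u < indel_rate
      if (any(del) || any(ins)) {
        out <- ch
        out[del] <- ""
        if (any(ins)) {
          out[ins] <- paste0(sample(DNA_BASES, sum(ins), replace = TRUE),
                             ch[ins])
        }
        return(paste(out, collapse = ""))
      }
    }
    paste(ch, collapse = "")
  })
}

#' Simulate 454-style amplicon reads from community sequences
#'
#' Each community record yields one read: `barcode + primer + template`,
#' optionally truncated to `max_length`, with substitutions and indels
#' applied at the stated per-base rates over the whole read.  Per-base
#' qualities follow a two-component mixture: most reads draw phred scores
#' around a high mean, while a configurable fraction are low-quality reads
#' whose mean falls below the conventional trim threshold, so the quality
#' filter has work to do.
#'
#' @param community Output of [simulate_community()] (columns `id`,
#'   `sample`, `sequence`; `species`/`lineage` are carried through).
#' @param error_rate Substitution probability per base (`0 <= rate < 0.5`).
#' @param indel_rate Indel probability per base (half insertions, half
#'   deletions).
#' @param barcodes Named character vector `sample -> barcode`; generated
#'   with [make_barcodes()] when `NULL`.
#' @param primer Primer string prepended after the barcode (default ITS5,
#'   reading the template in its stored forward orientation).
#' @param low_quality_fraction Fraction of reads drawn from the low-quality
#'   mixture component.
#' @param max_length Optional read-length cap (3' truncation).
#' @param seed Integer seed.
#' @return Tibble of FASTQ-ready reads: `id`, `sample`, `sequence`,
#'   `quality` (phred+33), plus any `species`/`lineage`/`accession` columns
#'   of the input.
#' @export
simulate_reads <- function(community, error_rate = 0.005,
                           indel_rate = 5e-4, barcodes = NULL,
                           primer = its_primers()[["ITS5"]],
                           low_quality_fraction = 0.1,
                           max_length = NULL, seed = 1L) {
  assert_seq_df(community, c("id", "sample", "sequence"), "community")
  if (nrow(community) == 0L) stop("community must be non-empty")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  if (is.null(barcodes)) {
    barcodes <- make_barcodes(unique(community$sample), seed = seed)
  }
  missing <- setdiff(unique(community$sample), names(barcodes))
  if (length(missing)) {
    stop("no barcode for sample(s): ", paste(missing, collapse = ", "))
  }
  with_child_seed(seed, "simulate_reads", {
    raw <- paste0(barcodes[community$sample], primer, community$sequence)
    if (!is.null(max_length)) raw <- substr(raw, 1L, max_length)
    seqs <- apply_read_errors(raw, error_rate, indel_rate)
    lens <- nchar(seqs)
    bad <- runif(length(seqs)) < low_quality_fraction
    mu <- ifelse(bad, 26, 37)
    quality <- int_to_phred(purrr::map2(lens, mu, function(L, m) {
      pmin(pmax(as.integer(round(rnorm(L, m, 3))), 2L), 40L)
    }))
    out <- tibble(id = community$id, sample = community$sample,
                  sequence = seqs, quality = quality)
    for (col in intersect(c("species", "lineage", "accession"),
                          names(community))) {
      out[[col]] <- community[[col]]
    }
    out
  })
}

#' Quality/tag filter for amplicon reads
#'
#' Implements the conventional 454 read-trimming rule: a read is rejected
#' iff it is shorter than `min_length`, its quality score is at most
#' `min_quality`, it contains an ambiguous base (N), or its barcode+primer
#' prefix is not an exact match to a known tag.  All applicable rejection
#' reasons are enumerated per read.  Kept reads are demultiplexed by
#' barcode and returned with the barcode+primer prefix trimmed.
#'
#' @param reads Tibble with `id`, `sequence`, `quality` (and optionally
#'   `sample`, carried through for bookkeeping).
#' @param min_length Minimum raw read length in bp (default 60).
#' @param min_quality Quality threshold; reads with score `<= min_quality`
#'   are rejected (default 30).
#' @param barcodes Named character vector `sample -> barcode`.
#' @param primer Primer expected immediately after the barcode.
#' @param quality_mode `"mean"` (default) applies the threshold to the mean
#'   read quality; `"window"` applies it to the minimum sliding-window mean
#'   (the alternative reading of the trimming rule).
#' @param window Window width for `quality_mode = "window"`.
#' @return A list with tibbles `kept` (columns `id`, `sample` assigned from
#'   the barcode, trimmed `sequence` and `quality`, `raw_length`) and
#'   `rejected` (`id`, `reason` — comma-joined among
#'   `length`, `quality`, `ambiguous`, `tag`).  `kept` and `rejected`
#'   partition the input.
#' @export
filter_reads <- function(reads, min_length = 60L, min_quality = 30,
                         barcodes, primer = its_primers()[["ITS5"]],
                         quality_mode = c("mean", "window"), window = 50L) {
  assert_seq_df(reads, c("id", "sequence", "quality"), "reads")
  quality_mode <- match.arg(quality_mode)
  if (nrow(reads) == 0L) {
    empty <- reads[0, ]
    return(list(kept = tibble(id = character(), sample = character(),
                              sequence = character(), quality = character(),
                              raw_length = integer()),
                rejected = tibble(id = character(), reason = character())))
  }
  seqs <- reads$sequence
  lens <- nchar(seqs)
  qints <- phred_to_int(reads$quality)

  qscore <- vapply(qints, function(q) {
    if (length(q) == 0L) return(0)
    if (quality_mode == "mean") return(mean(q))
    if (length(q) <= window) return(mean(q))
    min(vapply(seq_len(length(q) - window + 1L),
               function(i) mean(q[i:(i + window - 1L)]), numeric(1)))
  }, numeric(1))

  tags <- paste0(barcodes, primer)
  tag_idx <- rep(NA_integer_, length(seqs))
  for (k in seq_along(tags)) {
    hit <- is.na(tag_idx) & startsWith(seqs, tags[k])
    tag_idx[hit] <- k
  }

  bad_len <- lens < min_length
  bad_q <- qscore <= min_quality
  bad_n <- grepl("N", seqs, fixed = TRUE)
  bad_tag <- is.na(tag_idx)

  reason <- purrr::pmap_chr(list(bad_len, bad_q, bad_n, bad_tag),
    function(l, q, n, t) {
      paste(c("length", "quality", "ambiguous", "tag")[c(l, q, n, t)],
            collapse = ",")
    })
  reject <- nzchar(reason)

  kept_idx <- which(!reject)
  trim <- nchar(tags)[tag_idx[kept_idx]]
  kept <- tibble(
    id = reads$id[kept_idx],
    sample = names(barcodes)[tag_idx[kept_idx]],
    sequence = substr(seqs[kept_idx], trim + 1L, lens[kept_idx]),
    quality = substr(reads$quality[kept_idx], trim + 1L, lens[kept_idx]),
    raw_length = lens[kept_idx]
  )
  for (col in intersect(c("species", "lineage", "accession"), names(reads))) {
    kept[[col]] <- reads[[col]][kept_idx]
  }
  rejected <- tibble(id = reads$id[reject], reason = reason[reject])
  list(kept = kept, rejected = rejected)
}
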