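#' Conserved anchor motifs delimiting the ITS1 and ITS2 spacers
#'
#' The full-length fungal ITS region sits between the 18S (SSU) and 28S (LSU)
#' rRNA genes and contains the conserved 5.8S gene between the two variable
#' spacers: `SSU — ITS1 — 5.8S — ITS2 — LSU`.  An `anchor_set` holds four
#' short conserved motifs — the SSU 3' tail, the 5.8S head and tail, and the
#' LSU head — that delimit the spacers, plus the per-motif mismatch budget
#' used when locating them.  This motif-based scheme plays the role that
#' profile-HMM scanners play in production pipelines; it is exactly testable
#' and self-contained.
#'
#' @param ssu_tail,r58s_head,r58s_tail,lsu_head Motif strings over A,C,G,T.
#' @param max_mismatch Maximum Hamming mismatches tolerated per motif
#'   (must be smaller than every motif length).
#' @return An object of class `anchor_set`.
#' @seealso [extract_its()], [locate_anchor()]
#' @export
anchor_set <- function(ssu_tail, r58s_head, r58s_tail, lsu_head,
                       max_mismatch = 2L) {
  motifs <- c(ssu_tail = ssu_tail, r58s_head = r58s_head,
              r58s_tail = r58s_tail, lsu_head = lsu_head)
  if (any(!nzchar(motifs))) stop("anchor motifs must be non-empty")
  if (any(grepl("[^ACGT]", motifs))) {
    stop("anchor motifs must be over A,C,G,T")
  }
  if (max_mismatch >= min(nchar(motifs))) {
    stop("max_mismatch must be smaller than every motif length")
  }
  structure(list(ssu_tail = ssu_tail, r58s_head = r58s_head,
                 r58s_tail = r58s_tail, lsu_head = lsu_head,
                 max_mismatch = as.integer(max_mismatch)),
            class = "anchor_set")
}

#' @rdname anchor_set
#' @details `default_anchors()` returns motifs modelled on conserved rDNA
#'   segments: the 18S 3' end, the 5.8S 5' and 3' ends, and the 28S 5' region
#'   (which contains the reverse complement of the ITS4 priming site).  In
#'   the synthetic communities generated by this package these motifs occur
#'   verbatim at the stated positions, so extraction is exact by construction
#'   on error-free input.
#' @export
default_anchors <- function(max_mismatch = 2L) {
  anchor_set(
    ssu_tail  = "TCCGTAGGTGAACCTGCGG",
    r58s_head = "AACTTTCAACAACGGATCTC",
    r58s_tail = "GCATCGATGAAGAACGCAGC",
    lsu_head  = "GCATATCAATAAGCGGAGGA",
    max_mismatch = max_mismatch
  )
}

#' Locate a motif in sequences by minimal Hamming distance
#'
#' Slides the motif along each sequence and reports the leftmost position
#' whose Hamming distance to the motif is minimal and at most `max_mismatch`.
#'
#' @param sequence Character vector of DNA sequences.
#' @param motif A single motif string (A,C,G,T).
#' @param max_mismatch Maximum Hamming distance accepted.
#' @return Integer vector of 1-based start positions (`NA` when no window is
#'   within `max_mismatch`, or when the motif is longer than the sequence).
#' @export
#' @examples
#' locate_anchor(c("AAACGTAAA", "TTTTTTT"), "ACGT", 0)
locate_anchor <- function(sequence, motif, max_mismatch = 0L) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop("motif must be a single non-empty string")
  }
  hits <- cpp_anchor_scan(sequence, motif)
  pos <- unname(hits[, "position"])
  mis <- unname(hits[, "mismatches"])
  ok <- pos > 0L & !is.na(mis) & mis <= max_mismatch
  as.integer(ifelse(ok, pos, NA_integer_))
}

#' Split full-length ITS sequences into ITS1 and ITS2
#'
#' Decomposes each record into `ITS1 = (end of SSU tail, start of 5.8S head)`
#' and `ITS2 = (end of 5.8S tail, start of LSU head)` using the anchor
#' motifs.  `status` records which side succeeded: `"full"`, `"its1_only"`,
#' `"its2_only"` or `"failed"`.  Anchors found out of order give `"failed"`;
#' a zero-length spacer span degrades the status on that side.  Extraction of
#' one record never depends on the others.
#'
#' @param records Data frame with columns `id` and `sequence`; other columns
#'   are carried through unchanged.
#' @param anchors An [anchor_set()].
#' @param try_revcomp When `TRUE`, records for which all four anchors fail
#'   are retried on the reverse complement (off by default; input is assumed
#'   forward-oriented).
#' @return A tibble with one row per record: `id`, `status`, the extracted
#'   `its1`, `its2` and `its_full` sequences (`NA` when absent), and 1-based
#'   inclusive coordinates `ssu_start/ssu_end`, `its1_start/its1_end`,
#'   `r58s_start/r58s_end`, `its2_start/its2_end` on the input sequence.
#'   Use [write_extraction_table()] for the 0-based half-open TSV export.
#' @export
extract_its <- function(records, anchors = default_anchors(),
                        try_revcomp = FALSE) {
  assert_seq_df(records)
  if (nrow(records) == 0L) stop("records must be non-empty")
  seqs <- toupper(records$sequence)
  res <- extract_its_core(seqs, anchors)
  if (try_revcomp && any(res$status == "failed")) {
    idx <- which(res$status == "failed" & is.na(res$ssu_start) &
                   is.na(res$r58s_start))
    if (length(idx)) {
      rc <- extract_its_core(revcomp(seqs[idx]), anchors)
      better <- rc$status != "failed"
      if (any(better)) {
        rc$orientation <- "reverse"
        res[idx[better], names(rc)] <- rc[better, ]
      }
    }
  }
  out <- dplyr::bind_cols(tibble(id = records$id), res)
  extra <- setdiff(names(records), c("id", "sequence", names(out)))
  if (length(extra)) out <- dplyr::bind_cols(out, records[extra])
  out
}

extract_its_core <- function(seqs, anchors) {
  mm <- anchors$max_mismatch
  s_pos <- locate_anchor(seqs, anchors$ssu_tail, mm)
  h_pos <- locate_anchor(seqs, anchors$r58s_head, mm)
  t_pos <- locate_anchor(seqs, anchors$r58s_tail, mm)
  l_pos <- locate_anchor(seqs, anchors$lsu_head, mm)
  s_end <- s_pos + nchar(anchors$ssu_tail) - 1L
  t_end <- t_pos + nchar(anchors$r58s_tail) - 1L

  # order consistency among the anchors that were found:
  # ssu < 5.8S head <= 5.8S tail < lsu
  pos_list <- list(s_end, h_pos, t_pos, l_pos)
  n <- length(seqs)
  ordered_ok <- rep(TRUE, n)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      a <- pos_list[[i]]; b <- pos_list[[j]]
      bad <- !is.na(a) & !is.na(b) & a >= b
      ordered_ok <- ordered_ok & !bad
    }
  }

  its1_start <- s_end + 1L
  its1_end <- h_pos - 1L
  its2_start <- t_end + 1L
  its2_end <- l_pos - 1L

  its1_ok <- ordered_ok & !is.na(s_pos) & !is.na(h_pos) &
    its1_end >= its1_start
  its2_ok <- ordered_ok & !is.na(t_pos) & !is.na(l_pos) &
    its2_end >= its2_start
  full_ok <- its1_ok & its2_ok & !is.na(t_pos) & !is.na(h_pos)

  status <- dplyr::case_when(
    full_ok ~ "full",
    its1_ok ~ "its1_only",
    its2_ok ~ "its2_only",
    TRUE ~ "failed"
  )

  its1 <- ifelse(its1_ok, substr(seqs, its1_start, its1_end), NA_character_)
  its2 <- ifelse(its2_ok, substr(seqs, its2_start, its2_end), NA_character_)
  its_full <- ifelse(full_ok, substr(seqs, its1_start, its2_end),
                     NA_character_)

  tibble(
    status = status,
    its1 = its1, its2 = its2, its_full = its_full,
    ssu_start = ifelse(its1_ok, s_pos, NA_integer_),
    ssu_end = ifelse(its1_ok, s_end, NA_integer_),
    its1_start = ifelse(its1_ok, its1_start, NA_integer_),
    its1_end = ifelse(its1_ok, its1_end, NA_integer_),
    r58s_start = ifelse(full_ok, h_pos, NA_integer_),
    r58s_end = ifelse(full_ok, t_end, NA_integer_),
    its2_start = ifelse(its2_ok, its2_start, NA_integer_),
    its2_end = ifelse(its2_ok, its2_end, NA_integer_)
  )
}

#' Write a per-record extraction table as TSV
#'
#' Emits `id`, `status` and the four region intervals (SSU tail, ITS1, 5.8S,
#' ITS2) in 0-based half-open coordinates, the convention used by the
#' package's on-disk interchange formats.
#'
#' @param extraction Result of [extract_its()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_extraction_table <- function(extraction, path) {
  to0 <- function(s) ifelse(is.na(s), NA_integer_, s - 1L)
  out <- tibble(
    id = extraction$id, status = extraction$status,
    ssu_begin = to0(extraction$ssu_start), ssu_end = extraction$ssu_end,
    its1_begin = to0(extraction$its1_start), its1_end = extraction$its1_end,
    r58s_begin = to0(extraction$r58s_start), r58s_end = extraction$r58s_end,
    its2_begin = to0(extraction$its2_start), its2_end = extraction$its2_end
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
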