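#' Read and write taxonomy-annotated FASTA
#'
#' Headers follow the UNITE-style convention
#' `>id|accession|k__Fungi;p__...;c__...;o__...;f__...;g__...;s__...`;
#' the kingdom field is stripped into the 6-rank `lineage` column on read.
#' A header without `|` separators yields only an `id`.
#'
#' @param path File path.
#' @return `read_its_fasta()`: tibble with `id`, `accession`, `lineage`,
#'   `sequence`.
#' @export
read_its_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  fields <- stringr::str_split_fixed(names(x), stringr::fixed("|"), 3)
  lineage <- sub("^k__[^;]*;", "", fields[, 3])
  tibble(
    id = fields[, 1],
    accession = ifelse(nzchar(fields[, 2]), fields[, 2], NA_character_),
    lineage = ifelse(nzchar(lineage), lineage, NA_character_),
    sequence = unname(as.character(x))
  )
}

#' @rdname read_its_fasta
#' @param records Data frame with `id` and `sequence`; optional
#'   `accession` and `lineage` columns are embedded in the headers.
#' @return `write_its_fasta()`: `path`, invisibly.
#' @export
write_its_fasta <- function(records, path) {
  assert_seq_df(records)
  acc <- records[["accession"]] %||% rep("", nrow(records))
  acc[is.na(acc)] <- ""
  lin <- records[["lineage"]] %||% rep("", nrow(records))
  tax <- ifelse(is.na(lin) | !nzchar(lin), "", paste0("k__Fungi;", lin))
  headers <- paste(records$id, acc, tax, sep = "|")
  plain <- !nzchar(acc) & !nzchar(tax)
  headers[plain] <- records$id[plain]
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ reads (phred+33)
#'
#' @param path File path.
#' @return `read_reads_fastq()`: tibble with `id`, `sequence`, `quality`.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(id = names(x), sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @rdname read_reads_fastq
#' @param reads Data frame with `id`, `sequence`, `quality`.
#' @return `write_reads_fastq()`: `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  assert_seq_df(reads, c("id", "sequence", "quality"), "reads")
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}

#' Read and write OTU membership maps
#'
#' The interchange format for clusterings is a 3-column TSV:
#' `otu_id <TAB> representative_id <TAB> comma-separated member ids`, so
#' commonality can be computed on externally produced clusterings too.
#'
#' @param clustering An `otu_clustering`.
#' @param path File path.
#' @return `write_otu_map()`: `path`, invisibly.
#' @export
write_otu_map <- function(clustering, path) {
  stopifnot(inherits(clustering, "otu_clustering"))
  out <- data.frame(
    otu_id = clustering$otus$otu_id,
    representative_id = clustering$otus$representative_id,
    members = vapply(clustering$otus$members, paste, character(1),
                     collapse = ",")
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_map
#' @param threshold,region Metadata to attach to the reconstructed
#'   clustering (the TSV itself does not carry them).
#' @return `read_otu_map()`: an `otu_clustering`.
#' @export
read_otu_map <- function(path, threshold = NA_real_, region = NULL) {
  d <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = "character")
  members <- strsplit(d$members, ",", fixed = TRUE)
  otus <- tibble(otu_id = d$otu_id,
                 representative_id = d$representative_id,
                 members = members)
  structure(list(otus = otus, threshold = threshold,
                 region = region %||% NA_character_,
                 universe = unlist(members, use.names = FALSE),
                 ordering = "external", best_hit = FALSE),
            class = "otu_clustering")
}

#' Read and write community specifications as YAML
#'
#' The on-disk schema mirrors [community_spec()]: top-level keys
#' `lineages` (list of 6-rank strings), `region_params` (map region ->
#' `{mean_length, sd_length, gc_target, interspecies_rate,
#' intraspecies_rate}`), `anchors` (`{ssu_tail, r58s_head, r58s_tail,
#' lsu_head, max_mismatch}`), `samples` (list of `{sample, species,
#' copies}` rows) and `seed`.
#'
#' @param spec A [community_spec()].
#' @param path File path.
#' @return `write_community_spec()`: `path`, invisibly;
#'   `read_community_spec()`: a [community_spec()].
#' @export
write_community_spec <- function(spec, path) {
  stopifnot(inherits(spec, "community_spec"))
  obj <- list(
    lineages = as.list(spec$lineages),
    region_params = purrr::map(spec$region_params, unclass),
    anchors = unclass(spec$anchors),
    samples = purrr::pmap(spec$samples, function(sample, species, copies) {
      list(sample = sample, species = species, copies = copies)
    }),
    seed = spec$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_community_spec
#' @export
read_community_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  rp <- purrr::map(obj$region_params, function(p) do.call(region_params, p))
  an <- do.call(anchor_set, obj$anchors)
  samples <- purrr::map_dfr(obj$samples, as_tibble)
  community_spec(unlist(obj$lineages), region_params = rp, anchors = an,
                 samples = samples, seed = obj$seed)
}
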