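REGIONS <- c("ITS", "ITS1", "ITS2")

# Long table of per-region records derived from an extraction result:
# one row per (record, region) with the region suffix appended to the id,
# so records cut from the same read share a key downstream.
region_records <- function(extraction, meta = NULL) {
  pick <- list(ITS = "its_full", ITS1 = "its1", ITS2 = "its2")
  rows <- purrr::imap(pick, function(col, lab) {
    ok <- !is.na(extraction[[col]]) & nzchar(extraction[[col]])
    out <- tibble(id = paste0(extraction$id[ok], "/", lab),
                  source_id = extraction$id[ok],
                  region = lab,
                  sequence = extraction[[col]][ok])
    out
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(meta)) {
    keep <- intersect(c("id", "sample", "species", "lineage", "accession"),
                      names(meta))
    out <- dplyr::left_join(out, dplyr::rename(meta[keep],
                                               source_id = "id"),
                            by = "source_id")
  }
  out
}

run_log <- function(messages, verbose) {
  if (verbose) message(messages)
  messages
}

write_tsv_file <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' In-silico marker comparison on a reference-derived community
#'
#' Runs the full database-comparison study on a synthetic community:
#' simulate references and copies, extract ITS1/ITS2/full ITS, profile
#' lengths and GC per region, cluster every region across the threshold
#' sweep, compute pooled alpha diversity, the directed commonality A
#' between all region pairs (threshold diagonal plus the 0.97 vs 0.98/0.99
#' cross pairs), species-per-OTU, and the taxonomic resolution rates
#' (self-return on reference regions; species agreement for community
#' copies).  All randomness derives from `seed`, so a rerun writes a
#' byte-identical bundle.
#'
#' @param spec A [community_spec()] (default: the standard study
#'   community).
#' @param thresholds Identity thresholds for the clustering sweep.
#' @param default_threshold Threshold used for the headline tables.
#' @param out_dir Optional directory; when given, every intermediate table
#'   is written (TSV/FASTA/newick + JSON manifest) so any stage can be
#'   rerun from files.
#' @param seed Integer seed (defaults to the spec's).
#' @param verbose Emit per-stage record counts.
#' @return An object of class `marker_report`: a list with elements
#'   `refs`, `community`, `extraction`, `metrics`, `clusterings` (nested
#'   list region -> threshold), `diversity`, `commonality`,
#'   `species_per_otu`, `taxonomy`, `log` and `config`.
#' @export
run_insilico_comparison <- function(spec = default_community_spec(),
                                    thresholds = seq(0.91, 0.99, by = 0.01),
                                    default_threshold = 0.97,
                                    out_dir = NULL, seed = spec$seed,
                                    verbose = FALSE) {
  stopifnot(inherits(spec, "community_spec"))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  if (!default_threshold %in% thresholds) {
    thresholds <- sort(unique(c(thresholds, default_threshold)))
  }
  logs <- character()

  refs <- build_reference_taxa(spec, seed)
  community <- simulate_community(refs, spec, seed)
  logs <- c(logs, run_log(sprintf(
    "simulated %d references, %d community copies",
    nrow(refs), nrow(community)), verbose))

  extraction <- extract_its(community, spec$anchors)
  regions <- region_records(extraction, community)
  n_by_region <- table(regions$region)
  logs <- c(logs, run_log(sprintf(
    "extraction: %d/%d full; region records ITS=%d ITS1=%d ITS2=%d",
    sum(extraction$status == "full"), nrow(extraction),
    n_by_region[["ITS"]], n_by_region[["ITS1"]], n_by_region[["ITS2"]]),
    verbose))
  for (lab in REGIONS) {
    if (!lab %in% regions$region) {
      stop("zero sequences survived extraction for region ", lab)
    }
  }

  metrics <- marker_metrics(regions)

  clusterings <- purrr::map(setNames(REGIONS, REGIONS), function(lab) {
    recs <- regions[regions$region == lab, c("id", "sequence")]
    cluster_sweep(recs, thresholds, region = lab)
  })
  otu_counts <- purrr::imap_dfr(clusterings, function(sw, lab) {
    tibble(region = lab, threshold = thresholds,
           n_otus = vapply(sw, function(cl) nrow(cl$otus), integer(1)))
  })
  logs <- c(logs, run_log(sprintf(
    "OTUs at %.2f: ITS=%d ITS1=%d ITS2=%d", default_threshold,
    n_otus_at(clusterings, "ITS", default_threshold),
    n_otus_at(clusterings, "ITS1", default_threshold),
    n_otus_at(clusterings, "ITS2", default_threshold)), verbose))

  key <- format(default_threshold)
  diversity <- purrr::imap_dfr(clusterings, function(sw, lab) {
    sizes <- lengths(sw[[key]]$otus$members)
    tibble(region = lab, threshold = default_threshold,
           s_obs = length(sizes), chao1 = chao1(sizes),
           shannon = shannon(sizes))
  })

  commonality <- purrr::map_dfr(format(thresholds), function(k) {
    region_commonality(purrr::map(clusterings, k))
  })
  cross <- purrr::map_dfr(intersect(c("0.98", "0.99"), format(thresholds)),
    function(k) {
      region_commonality(list(
        ITS1 = clusterings$ITS1[[k]],
        ITS2 = clusterings$ITS2[[key]],
        ITS = clusterings$ITS[[key]]
      ))
    })
  commonality <- dplyr::bind_rows(commonality, cross)

  lineage_map <- setNames(community$lineage, community$id)
  spo <- purrr::imap_dfr(clusterings, function(sw, lab) {
    purrr::imap_dfr(sw, function(cl, k) {
      tibble(region = lab, threshold = as.numeric(k),
             mean_species = species_per_otu(cl, lineage_map)$mean_species)
    })
  })

  taxonomy <- marker_taxonomy(refs, regions, spec)
  logs <- c(logs, run_log(sprintf(
    "self-return: ITS=%.3f ITS1=%.3f ITS2=%.3f",
    rate_of(taxonomy, "ITS", "self_return"),
    rate_of(taxonomy, "ITS1", "self_return"),
    rate_of(taxonomy, "ITS2", "self_return")), verbose))

  report <- structure(list(
    refs = refs, community = community, extraction = extraction,
    regions = regions, metrics = metrics, clusterings = clusterings,
    otu_counts = otu_counts, diversity = diversity,
    commonality = commonality, species_per_otu = spo,
    taxonomy = taxonomy, log = logs,
    config = list(mode = "insilico", thresholds = thresholds,
                  default_threshold = default_threshold, seed = seed,
                  n_species = length(spec$species))
  ), class = "marker_report")

  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

n_otus_at <- function(clusterings, lab, threshold) {
  nrow(clusterings[[lab]][[format(threshold)]]$otus)
}

rate_of <- function(taxonomy, lab, what) {
  taxonomy$rates$value[taxonomy$rates$region == lab &
                         taxonomy$rates$measure == what]
}

marker_metrics <- function(regions) {
  by_region <- regions |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_length = mean(nchar(.data$sequence)),
      min_length = min(nchar(.data$sequence)),
      max_length = max(nchar(.data$sequence)),
      mean_gc = mean(gc_content(.data$sequence)),
      .groups = "drop"
    )
  lab1 <- regions$sequence[regions$region == "ITS1"]
  lab2 <- regions$sequence[regions$region == "ITS2"]
  tests <- dplyr::bind_rows(
    dplyr::mutate(two_sample_t(nchar(lab1), nchar(lab2)),
                  comparison = "length ITS1 vs ITS2"),
    dplyr::mutate(two_sample_t(gc_content(lab1), gc_content(lab2)),
                  comparison = "gc ITS1 vs ITS2")
  )
  extremes <- purrr::map_dfr(split(regions, regions$region),
    function(d) {
      dplyr::bind_cols(
        tibble(region = d$region[1]),
        dplyr::rename_with(length_class_counts(d), ~ paste0("len_", .x)),
        dplyr::rename_with(gc_extreme_counts(d), ~ paste0("gc_", .x))
      )
    })
  group <- if ("lineage" %in% names(regions) &&
               !any(is.na(regions$lineage))) {
    purrr::map_dfr(split(regions, regions$region), function(d) {
      dplyr::mutate(group_summary(d, "phylum"), region = d$region[1],
                    .before = 1)
    })
  } else NULL
  list(by_region = by_region, tests = tests, extremes = extremes,
       by_group = group)
}

reference_region_dbs <- function(refs, spec) {
  ref_ext <- extract_its(refs, spec$anchors)
  ref_regions <- region_records(ref_ext, refs)
  purrr::map(setNames(REGIONS, REGIONS), function(lab) {
    d <- ref_regions[ref_regions$region == lab, ]
    tibble(accession = d$accession, sequence = d$sequence,
           lineage = d$lineage, id = d$id)
  })
}

marker_taxonomy <- function(refs, regions, spec) {
  dbs <- reference_region_dbs(refs, spec)
  rates <- purrr::map_dfr(REGIONS, function(lab) {
    db <- dbs[[lab]]
    self_q <- tibble(id = db$id, sequence = db$sequence,
                     accession = db$accession, lineage = db$lineage)
    hits_self <- best_hits(self_q, db)
    qq <- regions[regions$region == lab, ]
    hits_comm <- best_hits(
      tibble(id = qq$id, sequence = qq$sequence,
             accession = qq$accession, lineage = qq$lineage), db)
    dplyr::bind_rows(
      tibble(region = lab, measure = "self_return",
             value = self_return_rate(hits_self), n = nrow(self_q)),
      tibble(region = lab, measure = "species_agreement",
             value = species_agreement_rate(hits_comm), n = nrow(qq))
    )
  })
  hits_full <- best_hits(
    dplyr::rename(regions[regions$region == "ITS",
                          c("id", "sequence", "accession", "lineage")],
                  lineage = "lineage"),
    dbs$ITS
  )
  comp <- rank_composition(hits_full)
  list(rates = rates, rank_composition = comp, dbs = dbs)
}

#' Multi-sample amplicon marker comparison
#'
#' Runs the sequencing-survey arm on simulated 454-style reads: simulate
#' community and reads, apply the read filter, demultiplex, extract the
#' regions, cluster each region (reads from all samples pooled) at the
#' given threshold, compute per-sample Chao1/Shannon, the pooled
#' commonality between the regions, a Bray-Curtis/UPGMA sample dendrogram
#' per region, and a rank-sum screen for genera that differ between sample
#' groups.  Samples losing every read are dropped with a warning.
#'
#' @param spec A [community_spec()] with a multi-sample profile (see
#'   [sample_profiles()]).
#' @param groups Mapping sample -> group (named character vector or data
#'   frame); when `NULL`, taken from `attr(spec$samples, "groups")` if
#'   present.
#' @param threshold Clustering threshold (default 0.97).
#' @param error_rate,indel_rate,low_quality_fraction Read-simulator
#'   parameters (see [simulate_reads()]).
#' @param min_length,min_quality Read-filter parameters.
#' @param out_dir Optional bundle directory, as in
#'   [run_insilico_comparison()].
#' @param seed Integer seed.
#' @param verbose Emit per-stage record counts.
#' @return An object of class `amplicon_report` (list with `reads`,
#'   `filter`, `extraction`, `clusterings`, `otu_tables`, `diversity`,
#'   `commonality`, `dendrograms`, `differential`, `log`, `config`).
#' @export
run_amplicon_comparison <- function(spec, groups = NULL, threshold = 0.97,
                                    error_rate = 0.005, indel_rate = 5e-4,
                                    low_quality_fraction = 0.1,
                                    min_length = 60L, min_quality = 30,
                                    out_dir = NULL, seed = spec$seed,
                                    verbose = FALSE) {
  stopifnot(inherits(spec, "community_spec"))
  groups <- groups %||% attr(spec$samples, "groups")
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample)
  logs <- character()

  refs <- build_reference_taxa(spec, seed)
  community <- simulate_community(refs, spec, seed)
  barcodes <- make_barcodes(unique(community$sample), seed = seed)
  reads <- simulate_reads(community, error_rate = error_rate,
                          indel_rate = indel_rate, barcodes = barcodes,
                          low_quality_fraction = low_quality_fraction,
                          seed = seed)
  filt <- filter_reads(reads, min_length = min_length,
                       min_quality = min_quality, barcodes = barcodes)
  logs <- c(logs, run_log(sprintf(
    "reads: %d raw -> %d kept (%s)", nrow(reads), nrow(filt$kept),
    paste(names(table(filt$rejected$reason)),
          table(filt$rejected$reason), sep = "=", collapse = " ")),
    verbose))

  dead <- setdiff(unique(community$sample), unique(filt$kept$sample))
  if (length(dead)) {
    warning("sample(s) with zero surviving reads dropped: ",
            paste(dead, collapse = ", "))
    groups <- groups[setdiff(names(groups), dead)]
  }

  extraction <- extract_its(filt$kept, spec$anchors)
  regions <- region_records(extraction, filt$kept)
  logs <- c(logs, run_log(sprintf(
    "extraction: full-length ITS in %d/%d kept reads",
    sum(extraction$status == "full"), nrow(extraction)), verbose))

  clusterings <- purrr::map(setNames(REGIONS, REGIONS), function(lab) {
    recs <- regions[regions$region == lab, c("id", "sequence")]
    if (nrow(recs) == 0L) {
      stop("zero sequences survived extraction for region ", lab)
    }
    greedy_cluster(recs, threshold, region = lab)
  })

  sample_of_region <- setNames(regions$sample, regions$id)
  otu_tables <- purrr::map(clusterings, otu_table,
                           sample_of = sample_of_region)
  diversity <- purrr::imap_dfr(otu_tables, function(tab, lab) {
    dplyr::mutate(alpha_diversity(tab), region = lab, .before = 1)
  })
  commonality <- region_commonality(clusterings)
  dendrograms <- purrr::map(otu_tables, function(tab) {
    if (ncol(tab) >= 2L) sample_dendrogram(tab) else NULL
  })

  differential <- NULL
  if (!is.null(groups) && dplyr::n_distinct(unname(groups)) >= 2L) {
    q <- regions[regions$region == "ITS", ]
    hits <- best_hits(
      tibble(id = q$id, sequence = q$sequence, accession = q$accession,
             lineage = q$lineage),
      reference_region_dbs(refs, spec)$ITS
    )
    genus <- lineage_rank(hits$hit_lineage, "genus")
    ab <- tibble(taxon = genus, sample = q$sample) |>
      dplyr::count(.data$taxon, .data$sample, name = "n_reads") |>
      tidyr::complete(.data$taxon, sample = unique(q$sample),
                      fill = list(n_reads = 0L)) |>
      dplyr::group_by(.data$sample) |>
      dplyr::mutate(abundance = 100 * .data$n_reads /
                      sum(.data$n_reads)) |>
      dplyr::ungroup() |>
      dplyr::select("taxon", "sample", "abundance")
    differential <- differential_taxa(ab, groups)
  }

  report <- structure(list(
    refs = refs, community = community, reads = reads, filter = filt,
    extraction = extraction, regions = regions,
    clusterings = clusterings, otu_tables = otu_tables,
    diversity = diversity, commonality = commonality,
    dendrograms = dendrograms, differential = differential,
    log = logs,
    config = list(mode = "amplicon", threshold = threshold, seed = seed,
                  error_rate = error_rate, groups = groups)
  ), class = "amplicon_report")

  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

#' @export
print.marker_report <- function(x, ...) {
  cat("<marker_report> in-silico comparison: ",
      x$config$n_species, " species, ", nrow(x$community),
      " sequences, thresholds ",
      paste(range(x$config$thresholds), collapse = "-"), "\n", sep = "")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.amplicon_report <- function(x, ...) {
  cat("<amplicon_report> ", nrow(x$reads), " reads, ",
      nrow(x$filter$kept), " kept, threshold ",
      format(x$config$threshold), "\n", sep = "")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Group-structured multi-sample abundance profiles
#'
#' Builds the sample profile of the amplicon study: per-sample expected
#' copy counts drawn log-normally around a base abundance, with the sample
#' groups of a presence/absence field design — a depauperate group keeps
#' only a fraction of the species pool, and a marker genus is enriched in
#' one group so the differential screen has a planted signal.
#'
#' @param species Character vector of species names (see
#'   [community_spec()]).
#' @param n_per_group Named integer vector: samples per group (default
#'   `c(Os = 6, NOs = 3, MP = 1)`).
#' @param mean_copies Mean copies per species per sample.
#' @param depauperate_group Group keeping only `depauperate_fraction` of
#'   species.
#' @param depauperate_fraction Fraction of species present in that group.
#' @param marker_species Species up-weighted (x5) in the first group;
#'   default: every species of the first genus.
#' @param seed Integer seed.
#' @return Tibble `(sample, species, copies)` with a `groups` attribute
#'   (named character vector sample -> group).
#' @export
sample_profiles <- function(species,
                            n_per_group = c(Os = 6L, NOs = 3L, MP = 1L),
                            mean_copies = 5,
                            depauperate_group = "MP",
                            depauperate_fraction = 0.4,
                            marker_species = NULL, seed = 1L) {
  groups_vec <- rep(names(n_per_group), n_per_group)
  samples <- paste0(groups_vec, stats::ave(seq_along(groups_vec),
                                           groups_vec, FUN = seq_along))
  if (is.null(marker_species)) {
    genus <- sub("_sp[0-9]+$", "", species)
    marker_species <- species[genus == genus[1]]
  }
  with_child_seed(seed, "sample_profiles", {
    keep_dep <- sample(species, max(1L, round(depauperate_fraction *
                                                length(species))))
    rows <- purrr::map2_dfr(samples, groups_vec, function(smp, grp) {
      lambda <- mean_copies * stats::rlnorm(length(species), 0, 0.5)
      lambda[species %in% marker_species & grp == names(n_per_group)[1]] <-
        lambda[species %in% marker_species & grp == names(n_per_group)[1]] * 5
      if (grp == depauperate_group) {
        lambda[!species %in% keep_dep] <- 0
      }
      tibble(sample = smp, species = species, copies = rpois(
        length(species), lambda))
    })
    # guarantee every species appears somewhere
    tot <- rows |> dplyr::group_by(.data$species) |>
      dplyr::summarise(n = sum(.data$copies), .groups = "drop")
    missing <- tot$species[tot$n == 0]
    if (length(missing)) {
      rows$copies[rows$sample == samples[1] &
                    rows$species %in% missing] <- 1L
    }
    structure(rows, groups = setNames(groups_vec, samples))
  })
}

#' Write every table of a report to a directory
#'
#' @param report A `marker_report` or `amplicon_report`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_its_fasta(report$refs, file.path(out_dir, "references.fasta"))
  write_its_fasta(report$community, file.path(out_dir, "community.fasta"))
  write_extraction_table(report$extraction,
                         file.path(out_dir, "extraction.tsv"))
  if (!is.null(report$reads)) {
    write_reads_fastq(report$reads, file.path(out_dir, "reads.fastq"))
    write_tsv_file(report$filter$rejected, out_dir, "rejected_reads.tsv")
  }
  if (!is.null(report$metrics)) {
    write_tsv_file(report$metrics$by_region, out_dir, "region_metrics.tsv")
    write_tsv_file(report$metrics$extremes, out_dir, "extreme_counts.tsv")
  }
  if (!is.null(report$otu_counts)) {
    write_tsv_file(report$otu_counts, out_dir, "otu_counts.tsv")
  }
  cls <- report$clusterings
  for (lab in names(cls)) {
    obj <- cls[[lab]]
    if (inherits(obj, "otu_clustering")) {
      write_otu_map(obj, file.path(out_dir,
                                   paste0("otus_", lab, ".tsv")))
    } else {
      for (k in names(obj)) {
        write_otu_map(obj[[k]], file.path(
          out_dir, paste0("otus_", lab, "_", k, ".tsv")))
      }
    }
  }
  write_tsv_file(report$diversity, out_dir, "diversity.tsv")
  write_tsv_file(report$commonality, out_dir, "commonality.tsv")
  if (!is.null(report$species_per_otu)) {
    write_tsv_file(report$species_per_otu, out_dir, "species_per_otu.tsv")
  }
  if (!is.null(report$taxonomy)) {
    write_tsv_file(report$taxonomy$rates, out_dir, "taxonomy_rates.tsv")
    write_tsv_file(report$taxonomy$rank_composition, out_dir,
                   "rank_composition.tsv")
  }
  if (!is.null(report$dendrograms)) {
    for (lab in names(report$dendrograms)) {
      if (!is.null(report$dendrograms[[lab]])) {
        write_newick(report$dendrograms[[lab]],
                     file.path(out_dir, paste0("dendrogram_", lab, ".nwk")))
      }
    }
  }
  if (!is.null(report$differential)) {
    write_tsv_file(report$differential, out_dir, "differential_taxa.tsv")
  }
  manifest <- list(
    package = "spacerclust",
    version = as.character(utils::packageVersion("spacerclust")),
    config = report$config, log = report$log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
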