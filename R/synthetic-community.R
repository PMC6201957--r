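#' Per-region simulation parameters
#'
#' Describes one rDNA region (ITS1, 5.8S or ITS2) of the synthetic world:
#' its length distribution, target GC content, and substitution rates
#' between species (per speciation from the genus ancestor) and within
#' species (per individual rDNA copy).
#'
#' @param mean_length Mean region length in bp (>= 10).
#' @param sd_length Standard deviation of the length draw in bp (>= 0);
#'   lengths are drawn from a normal truncated at the minimum length and
#'   rounded to integers.
#' @param gc_target Target GC fraction in `[0, 1]`; bases are drawn i.i.d.
#'   with `P(G or C) = gc_target`.
#' @param interspecies_rate Substitutions per site separating a species from
#'   its genus ancestor.
#' @param intraspecies_rate Substitutions per site separating an individual
#'   rDNA copy from its species reference.
#' @return An object of class `region_params`.
#' @export
region_params <- function(mean_length, sd_length = 0, gc_target = 0.5,
                          interspecies_rate = 0, intraspecies_rate = 0) {
  if (mean_length < 10) stop("mean_length must be >= 10")
  if (sd_length < 0) stop("sd_length must be non-negative")
  if (gc_target < 0 || gc_target > 1) stop("gc_target must be in [0, 1]")
  if (interspecies_rate < 0 || intraspecies_rate < 0) {
    stop("substitution rates must be non-negative")
  }
  structure(list(mean_length = mean_length, sd_length = sd_length,
                 gc_target = gc_target,
                 interspecies_rate = interspecies_rate,
                 intraspecies_rate = intraspecies_rate),
            class = "region_params")
}

#' @rdname region_params
#' @details `default_region_params()` encodes the field's empirical
#'   contrasts as simulation knobs: mean lengths 177 bp (ITS1), 158 bp
#'   (5.8S) and 182 bp (ITS2), totalling 517 bp of spacer+5.8S; ITS2 GC
#'   above ITS1 GC; ITS1 substitution rates twice those of ITS2 (ITS1
#'   evolves faster); and a fully conserved 5.8S (zero rates), which keeps
#'   the anchor motifs intact.  Interspecific rates are set so congeneric
#'   ITS2 divergence lands near the conventional 97% clustering threshold —
#'   the regime in which marker choice matters.
#' @export
default_region_params <- function() {
  list(
    ITS1 = region_params(177, 45, 0.50,
                         interspecies_rate = 0.032,
                         intraspecies_rate = 0.013),
    `5.8S` = region_params(158, 0, 0.50, 0, 0),
    ITS2 = region_params(182, 30, 0.55,
                         interspecies_rate = 0.016,
                         intraspecies_rate = 0.0065)
  )
}

#' Synthetic fungal community specification
#'
#' Bundles everything the generator needs: the taxonomy (one 6-rank lineage
#' per species), per-region simulation parameters, the anchor motifs the
#' references must contain, the per-sample expected copy counts, and the
#' top-level seed (split deterministically per operation).
#'
#' @param lineages Character vector of unique 6-rank lineage paths
#'   (`p__...;c__...;o__...;f__...;g__...;s__...`).
#' @param region_params Named list with elements `ITS1`, `5.8S`, `ITS2`,
#'   each a [region_params()].
#' @param anchors An [anchor_set()]; the 5.8S must be long enough to hold
#'   its head and tail motifs.
#' @param samples Tibble with columns `sample`, `species`, `copies` giving
#'   per-sample copy counts; defaults to a single pooled sample `"S1"` with
#'   `copies_default` copies of every species.  Every species must appear in
#'   at least one sample.
#' @param seed Integer seed.
#' @param copies_default Copies per species for the default sample profile.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(lineages,
                           region_params = default_region_params(),
                           anchors = default_anchors(),
                           samples = NULL, seed = 1L,
                           copies_default = 20L) {
  assert_lineage6(lineages)
  if (anyDuplicated(lineages)) stop("lineages must be unique")
  stopifnot(all(c("ITS1", "5.8S", "ITS2") %in% names(region_params)))
  species <- parse_lineage(lineages)$species
  if (anyDuplicated(species)) stop("species binomials must be unique")
  p58 <- region_params[["5.8S"]]
  min58 <- nchar(anchors$r58s_head) + nchar(anchors$r58s_tail)
  if (p58$mean_length < min58) {
    stop("5.8S mean_length (", p58$mean_length,
         ") too short to hold its anchor motifs (need >= ", min58, ")")
  }
  if (is.null(samples)) {
    samples <- tibble(sample = "S1", species = species,
                      copies = as.integer(copies_default))
  }
  assert_seq_df(samples, c("sample", "species", "copies"), "samples")
  unknown <- setdiff(samples$species, species)
  if (length(unknown)) {
    stop("sample profile names unknown species: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  covered <- unique(samples$species[samples$copies > 0])
  if (!all(species %in% covered)) {
    stop("every species must appear in at least one sample")
  }
  structure(list(lineages = lineages, species = species,
                 region_params = region_params, anchors = anchors,
                 samples = as_tibble(samples), seed = as.integer(seed)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec> ", length(x$species), " species, ",
      dplyr::n_distinct(x$samples$sample), " sample(s), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Generate a hierarchical taxonomy for the standard community
#'
#' Genus `g` receives its own family and (paired) order/class, and genera
#' alternate between two phyla, so every rank from phylum to species is
#' populated.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus.
#' @return Character vector of 6-rank lineages.
#' @export
make_lineages <- function(n_genera = 5L, species_per_genus = 10L) {
  phyla <- c("Ascomycota", "Basidiomycota")
  unlist(lapply(seq_len(n_genera), function(g) {
    ph <- phyla[(g - 1L) %% 2L + 1L]
    cl <- paste0("Class", (g - 1L) %/% 2L + 1L)
    or <- paste0("Order", g)
    fa <- paste0("Family", g)
    ge <- paste0("Genus", g)
    vapply(seq_len(species_per_genus), function(k) {
      make_lineage(ph, cl, or, fa, ge, paste0(ge, "_sp", k))
    }, character(1))
  }))
}

#' The package's standard study community
#'
#' 5 genera of 10 species each (50 species), 20 rDNA copies per species in a
#' single pooled sample, default region parameters and anchors.  These are
#' the fixed conditions under which the marker comparison is studied.
#'
#' @param n_genera,species_per_genus Taxonomy shape.
#' @param copies_per_species Copies of each species in the pooled sample.
#' @param samples Optional explicit sample profile (see [community_spec()]).
#' @param seed Integer seed.
#' @return A [community_spec()].
#' @export
default_community_spec <- function(n_genera = 5L, species_per_genus = 10L,
                                   copies_per_species = 20L, samples = NULL,
                                   seed = 1L) {
  community_spec(make_lineages(n_genera, species_per_genus),
                 samples = samples, seed = seed,
                 copies_default = copies_per_species)
}

draw_region <- function(p, n = 1L, min_len = 10L) {
  lens <- draw_lengths(n, p$mean_length, p$sd_length, min_len)
  # keep the ancestral draw close to the GC target so that downstream
  # mutation cannot push a region outside the documented +/- 0.1 band
  purrr::map_chr(lens, function(L) {
    for (i in 1:25) {
      s <- random_dna(1L, L, p$gc_target)
      if (abs(gc_content(s) - p$gc_target) <= 0.05) return(s)
    }
    s
  })
}

#' Build reference sequences for every species
#'
#' Species within a genus share a genus ancestor whose ITS1, 5.8S and ITS2
#' are drawn from the region parameters; each species' regions are the
#' ancestor's mutated at the region's `interspecies_rate`.  Every reference
#' is `flank5 + ITS1 + 5.8S + ITS2 + flank3`, where the flanks end/begin
#' with the SSU-tail and LSU-head anchors and the 5.8S begins and ends with
#' its anchor motifs, so extraction is exact by construction.
#'
#' @param spec A [community_spec()].
#' @param seed Seed (defaults to the spec's).
#' @return A tibble with one row per species: `id`, `accession`, `species`,
#'   `lineage`, the ground-truth regions `its1`, `r58s`, `its2`, the flanks,
#'   and the full-length `sequence`.
#' @export
build_reference_taxa <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "community_spec"))
  rp <- spec$region_params
  an <- spec$anchors
  lin <- parse_lineage(spec$lineages)
  with_child_seed(seed, "build_reference_taxa", {
    flank5 <- paste0(random_dna(1L, 30L, 0.5), an$ssu_tail)
    flank3 <- paste0(an$lsu_head, random_dna(1L, 30L, 0.5))
    core_len <- rp[["5.8S"]]$mean_length -
      nchar(an$r58s_head) - nchar(an$r58s_tail)

    genera <- unique(lin$genus)
    anc <- setNames(vector("list", length(genera)), genera)
    for (g in genera) {
      anc[[g]] <- list(
        its1 = draw_region(rp$ITS1),
        r58s = paste0(an$r58s_head,
                      if (core_len > 0) random_dna(1L, core_len,
                                                   rp[["5.8S"]]$gc_target)
                      else "",
                      an$r58s_tail),
        its2 = draw_region(rp$ITS2)
      )
    }

    n <- length(spec$species)
    its1 <- its2 <- r58s <- character(n)
    for (i in seq_len(n)) {
      a <- anc[[lin$genus[i]]]
      its1[i] <- mutate_sites(a$its1, rp$ITS1$interspecies_rate)
      r58s[i] <- mutate_sites(a$r58s, rp[["5.8S"]]$interspecies_rate)
      its2[i] <- mutate_sites(a$its2, rp$ITS2$interspecies_rate)
    }

    tibble(
      id = spec$species,
      accession = sprintf("SC%06d", seq_len(n)),
      species = spec$species,
      lineage = spec$lineages,
      flank5 = flank5, its1 = its1, r58s = r58s, its2 = its2,
      flank3 = flank3,
      sequence = paste0(flank5, its1, r58s, its2, flank3)
    )
  })
}

#' Simulate a multi-sample community of full-length rDNA copies
#'
#' For every `(sample, species)` row of the spec's profile, emits exactly
#' the requested number of copies; each copy is the species reference with
#' its ITS1/5.8S/ITS2 independently mutated at the region's
#' `intraspecies_rate` (flanks are conserved).  Record ids encode sample,
#' species and copy number.
#'
#' @param refs Output of [build_reference_taxa()].
#' @param spec The [community_spec()].
#' @param seed Seed (defaults to the spec's).
#' @return Tibble with columns `id`, `sample`, `species`, `lineage`, the
#'   per-copy ground-truth regions `its1`, `r58s`, `its2`, and the
#'   full-length `sequence`.
#' @export
simulate_community <- function(refs, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "community_spec"))
  missing <- setdiff(spec$samples$species, refs$species)
  if (length(missing)) {
    stop("sample profile requests species absent from refs: ",
         paste(head(missing, 5), collapse = ", "))
  }
  rp <- spec$region_params
  ref_idx <- match(spec$samples$species, refs$species)
  with_child_seed(seed, "simulate_community", {
    rows <- purrr::pmap(
      list(spec$samples$sample, spec$samples$species,
           spec$samples$copies, ref_idx),
      function(smp, sp, k, ri) {
        if (k <= 0) return(NULL)
        r <- refs[ri, ]
        its1 <- mutate_sites(rep(r$its1, k), rp$ITS1$intraspecies_rate)
        r58s <- mutate_sites(rep(r$r58s, k), rp[["5.8S"]]$intraspecies_rate)
        its2 <- mutate_sites(rep(r$its2, k), rp$ITS2$intraspecies_rate)
        tibble(
          id = sprintf("%s.%s.%03d", smp, sp, seq_len(k)),
          sample = smp, species = sp, lineage = r$lineage,
          accession = r$accession,
          its1 = its1, r58s = r58s, its2 = its2,
          sequence = paste0(r$flank5, its1, r58s, its2, r$flank3)
        )
      })
    dplyr::bind_rows(rows)
  })
}
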