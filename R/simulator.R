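#' Simulation configuration
#'
#' Bundles the parameters of the synthetic allele-catalog and
#' hybridization-signal generator. Defaults describe a desk-scale study:
#' three loci of eight serotype families with four closely related
#' alleles each (serotype founders 25 substitutions from the locus root,
#' sibling alleles differing at a single shared polymorphic column --
#' the 1-nt within-serotype near-identity that makes typing hard),
#' 300 nt sequences, 10% of the sequence shared across loci (the
#' substrate for probe masking), and lognormal signal noise around a
#' 5,000/100 RFU positive/negative separation with per-array scale
#' variation. Base composition is uniform by default, keeping per-column
#' probe coverage homogeneous; `gc_wave = TRUE` adds AT-rich and GC-rich
#' stretches that drive the Tm length adjustment across its full
#' 20-60 nt range.
#'
#' @param n_loci Number of loci (default 3).
#' @param serotypes_per_locus Serotype families per locus (default 8).
#' @param alleles_per_serotype Alleles per serotype (default 4).
#' @param sequence_length Allele length in nt (default 300).
#' @param within_serotype_divergence Number of shared polymorphic columns
#'   per serotype at which sibling alleles differ (default 1).
#' @param between_serotype_divergence Substitutions separating each
#'   serotype founder from the locus root (default 25).
#' @param cross_locus_identity Fraction of the sequence copied verbatim
#'   across loci (default 0.10).
#' @param masked_pair Engineer a fully masked allele pair: the variant
#'   region of one allele is duplicated into every allele of the last
#'   locus, reproducing the pathology where an absent allele shows no
#'   negative probes (default FALSE; used by the masked scenario).
#' @param noise_sd Lognormal sigma of per-probe signal noise between
#'   replicate hybridizations (default 0.10, a ~10% per-probe CV --
#'   the regime in which replicate arrays correlate above 0.975).
#' @param positive_mean,negative_mean Raw RFU scale of the positive and
#'   negative signal modes (defaults 5000 and 100).
#' @param profile_sd Lognormal sigma of the smooth per-probe
#'   hybridization-efficiency profile, reproducible across arrays
#'   (default 0.25).
#' @param profile_smooth Smoothing half-width of the profile along the
#'   probe track, in probes (default 15).
#' @param scale_sd Lognormal sigma of the per-array global scale
#'   (default 0.3).
#' @param degradation_factor Global attenuation applied in the degraded
#'   scenario (default 0.25).
#' @param gc_wave Add a sinusoidal GC-content wave along the sequence
#'   (period 150 nt, GC fraction 0.2-0.8) producing AT-rich and GC-rich
#'   stretches (default FALSE: uniform composition).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `hla_sim_config`.
#' @export
sim_config <- function(n_loci = 3, serotypes_per_locus = 8,
                       alleles_per_serotype = 4, sequence_length = 300,
                       within_serotype_divergence = 1,
                       between_serotype_divergence = 25,
                       cross_locus_identity = 0.10, masked_pair = FALSE,
                       noise_sd = 0.10, positive_mean = 5000,
                       negative_mean = 100, profile_sd = 0.25,
                       profile_smooth = 15, scale_sd = 0.3,
                       degradation_factor = 0.25, gc_wave = FALSE,
                       seed = 1L) {
  if (within_serotype_divergence < 1 || between_serotype_divergence < 1) {
    rlang::abort("Divergences must be at least one substitution.",
                 class = "hlarray_config_error")
  }
  if (positive_mean <= negative_mean) {
    rlang::abort("`positive_mean` must exceed `negative_mean`.",
                 class = "hlarray_config_error")
  }
  structure(as.list(environment()), class = "hla_sim_config")
}

substitute_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic allele catalog
#'
#' Builds a catalog with controlled serotype structure: one random root
#' sequence per locus (GC content varying smoothly along the sequence),
#' serotype founders a fixed number of substitutions from the root, and
#' sibling alleles differing at a small set of shared polymorphic
#' columns. A contiguous segment of the first locus is copied into the
#' other loci to create cross-locus shared probes, and (optionally) the
#' variant region of one allele is duplicated into the last locus to
#' engineer a fully masked allele. Catalogs are gap-free, so the
#' alignment column of a probe equals its start position.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `hla_sim_catalog`: `catalog`
#'   (an [allele_catalog()]), `serogroups` (tibble `serotype`,
#'   `serogroup`), `msa` (`NULL`: columnar by construction), `masked`
#'   (`NULL` or a list naming the masked allele, its sibling and the
#'   masking locus), `config`.
#' @export
generate_allele_catalog <- function(config) {
  stopifnot(inherits(config, "hla_sim_config"))
  set.seed(config$seed)
  L <- config$sequence_length
  n_loci <- config$n_loci
  loci <- LETTERS[seq_len(n_loci)]
  # optional GC composition wave: AT-rich and GC-rich stretches
  p_gc <- if (isTRUE(config$gc_wave))
    0.5 + 0.3 * sin(2 * pi * seq_len(L) / 150) else rep(0.5, L)
  draw_root <- function() {
    strong <- stats::runif(L) < p_gc
    b <- ifelse(strong,
                ifelse(stats::runif(L) < 0.5, "G", "C"),
                ifelse(stats::runif(L) < 0.5, "A", "T"))
    b
  }
  roots <- lapply(loci, function(l) draw_root())
  names(roots) <- loci
  n_share <- round(config$cross_locus_identity * L)
  if (n_share > 0 && n_loci > 1) {
    seg <- seq(floor(L / 3), length.out = n_share)
    seg <- seg[seg <= L]
    for (l in loci[-1]) roots[[l]][seg] <- roots[[loci[1]]][seg]
  }

  alleles <- character(0); seqs <- character(0)
  masked <- NULL
  mask_window <- integer(0)
  for (li in seq_along(loci)) {
    l <- loci[li]
    d <- config$within_serotype_divergence
    G <- config$serotypes_per_locus
    # Class I polymorphism clusters in hotspots (the peptide-binding
    # groove varies in every allelic lineage), so all serotypes of a
    # locus vary inside the same hotspot region, each family at its own
    # column a few nt apart. Adjacent columns keep probe coverage of the
    # within-serotype signal homogeneous across families, and each
    # family's variant probes carry a non-root base at a column where
    # every other family is root, so they are never incidentally shared.
    # Hotspots stay one probe-length clear of the sequence ends so each
    # column is covered by a full complement of overlapping probes.
    edge <- min(60L, floor(L / 4)) + ceiling(G / 2) + 10L
    candidate_cols <- seq(edge + 1L, L - edge)
    if (config$masked_pair && li == n_loci && length(mask_window) > 0) {
      candidate_cols <- setdiff(candidate_cols,
                                c(outer(mask_window, -20:20, "+")))
    }
    centers <- integer(0)
    for (try in 1:200) {
      centers <- sort(sample(candidate_cols, d))
      if (d == 1 || min(diff(centers)) >= G + 40) break
    }
    offsets <- seq_len(G) - ceiling((G + 1) / 2)
    for (g in seq_len(G)) {
      poly_cols <- centers + offsets[g]
      founder <- roots[[l]]
      sub_sites <- sample(
        setdiff(seq_len(L), c(outer(centers, offsets, "+"))),
        config$between_serotype_divergence)
      # flank each variant column with family-private substitutions so
      # even the founder allele's probes over the hotspot differ from
      # every other family
      flanks <- unique(pmax(1L, pmin(L, c(poly_cols - 10L, poly_cols + 10L))))
      flanks <- setdiff(flanks, c(sub_sites, c(outer(centers, offsets, "+"))))
      if (length(flanks) > 0) {
        drop <- sample(setdiff(sub_sites, flanks),
                       min(length(flanks), length(sub_sites)))
        sub_sites <- c(setdiff(sub_sites, drop[seq_along(flanks)]), flanks)
      }
      founder[sub_sites] <- substitute_base(founder[sub_sites])
      if (3^d < config$alleles_per_serotype - 1) {
        rlang::abort("Too many alleles per serotype for the divergence.",
                     class = "hlarray_config_error")
      }
      variants <- list(founder)
      seen <- paste(founder[poly_cols], collapse = "")
      for (a in seq_len(config$alleles_per_serotype - 1)) {
        for (try in 1:100) {
          v <- founder
          v[poly_cols] <- substitute_base(v[poly_cols])
          key <- paste(v[poly_cols], collapse = "")
          if (!key %in% seen) break
        }
        if (key %in% seen) {
          rlang::abort("Could not generate distinct sibling alleles.",
                       class = "hlarray_config_error")
        }
        seen <- c(seen, key)
        variants[[a + 1]] <- v
      }
      for (a in seq_along(variants)) {
        alleles <- c(alleles, sprintf("%s*%02d:%02d", l, g, a))
        seqs <- c(seqs, paste(variants[[a]], collapse = ""))
      }
      if (config$masked_pair && li == 1 && g == 1) {
        # window covering every probe that overlaps the variant columns
        mask_window <- max(1, min(poly_cols) - (60 - 1)):
          min(L, max(poly_cols) + (60 - 1))
        masked <- list(
          masked_allele = sprintf("%s*%02d:%02d", l, g, 2L),
          sibling = sprintf("%s*%02d:%02d", l, g, 1L),
          masking_locus = loci[n_loci],
          window = range(mask_window))
      }
    }
  }
  catalog <- allele_catalog(alleles, seqs)
  if (config$masked_pair && !is.null(masked)) {
    donor <- strsplit(
      catalog$sequence[catalog$allele == masked$masked_allele], "")[[1]]
    idx <- which(catalog$locus == masked$masking_locus)
    for (i in idx) {
      s <- strsplit(catalog$sequence[i], "")[[1]]
      s[mask_window] <- donor[mask_window]
      catalog$sequence[i] <- paste(s, collapse = "")
    }
  }
  serotypes <- unique(catalog$serotype)
  structure(
    list(catalog = catalog,
         serogroups = tibble::tibble(serotype = serotypes,
                                     serogroup = serotypes),
         msa = NULL, masked = masked, config = config),
    class = "hla_sim_catalog")
}

#' Probe hybridization efficiencies
#'
#' Hybridization efficiency depends on probe sequence and so is
#' reproducible across arrays of the same design. The simulator models
#' it as a Gaussian-smoothed random walk along each allele's probe track
#' (positive signal profiles change smoothly between overlapping
#' probes), averaged per unique probe, on the log scale. Deterministic
#' given the configuration seed.
#'
#' @param probeset An `hla_probeset`.
#' @param config An [sim_config()] object.
#' @return Named numeric vector of log-scale efficiencies per probe id.
#' @export
probe_efficiency <- function(probeset, config) {
  set.seed(config$seed + 7919L)
  pl <- probeset$placements[order(probeset$placements$allele,
                                  probeset$placements$start), ]
  grp <- factor(pl$allele, levels = unique(pl$allele))
  half <- max(1L, as.integer(config$profile_smooth))
  w <- stats::dnorm(seq(-half, half), sd = half / 2)
  w <- w / sum(w)
  eff <- unlist(lapply(split(seq_len(nrow(pl)), grp), function(idx) {
    x <- stats::rnorm(length(idx))
    if (length(x) > 2 * half + 1) {
      sm <- stats::filter(x, w, sides = 2)
      sm[is.na(sm)] <- stats::median(sm, na.rm = TRUE)
      x <- as.numeric(sm)
    }
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else
      x * config$profile_sd / s
  }), use.names = FALSE)
  pl$eff <- eff
  out <- tapply(pl$eff, pl$probe_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Simulate one hybridized array
#'
#' A unique probe is positive iff its sequence occurs in at least one
#' present allele -- including placements in other loci, which is how
#' masking emerges. Positive probes sit around `positive_mean` times
#' their reproducible efficiency profile, negative probes around
#' `negative_mean`; multiplicative lognormal noise and a per-array
#' global scale are applied on top. The degraded scenario attenuates
#' the whole array; the mixed scenario sums the noiseless signals of
#' two genotypes before noise.
#'
#' @param genotype Character vector of present alleles (at most two per
#'   locus; empty for a negative control).
#' @param probeset An `hla_probeset`.
#' @param catalog The matching [allele_catalog()] tibble.
#' @param config An [sim_config()] object.
#' @param scenario One of `"clean"`, `"homozygous"`, `"close-alleles"`,
#'   `"masked"`, `"degraded"`, `"mixed"`, `"negative-control"`,
#'   `"replicate"` (a label; only `"degraded"` and `"mixed"` change the
#'   signal model).
#' @param array_id Array identifier.
#' @param efficiency Precomputed [probe_efficiency()] vector (computed
#'   on the fly if `NULL`).
#' @param genotype2 Second genotype for the mixed scenario.
#' @return A raw [array_signals()] tibble with attributes `scenario` and
#'   `truth` (the sorted present alleles).
#' @export
simulate_array <- function(genotype, probeset, catalog, config,
                           scenario = "clean", array_id = "array",
                           efficiency = NULL, genotype2 = NULL) {
  if (scenario != "mixed") {
    check_sim_genotype(genotype, catalog)
  } else {
    check_sim_genotype(genotype, catalog)
    check_sim_genotype(genotype2 %||%
      rlang::abort("Mixed scenario needs `genotype2`.",
                   class = "hlarray_genotype_error"), catalog)
  }
  if (is.null(efficiency)) efficiency <- probe_efficiency(probeset, config)
  ids <- probeset$probes$probe_id
  base_signal <- function(g) {
    present <- unique(
      probeset$placements$probe_id[probeset$placements$allele %in% g])
    pos <- ids %in% present
    ifelse(pos,
           config$positive_mean * exp(efficiency[ids]),
           config$negative_mean)
  }
  s <- base_signal(genotype)
  if (scenario == "mixed") s <- s + base_signal(genotype2)
  n <- length(s)
  if (config$noise_sd > 0) s <- s * exp(stats::rnorm(n, 0, config$noise_sd))
  if (config$scale_sd > 0) s <- s * exp(stats::rnorm(1, 0, config$scale_sd))
  if (scenario == "degraded") s <- s * config$degradation_factor
  out <- array_signals(ids, s, array_id = array_id, stage = "raw")
  attr(out, "scenario") <- scenario
  attr(out, "truth") <- sort(unique(c(genotype, genotype2)))
  out
}

check_sim_genotype <- function(genotype, catalog) {
  if (length(genotype) == 0) return(invisible(genotype))
  missing <- setdiff(genotype, catalog$allele)
  if (length(missing) > 0) {
    rlang::abort(paste0("Genotype alleles not in catalog: ",
                        paste(missing, collapse = ", ")),
                 class = "hlarray_genotype_error")
  }
  loci <- catalog$locus[match(genotype, catalog$allele)]
  if (any(table(loci) > 2)) {
    rlang::abort("More than two alleles at one locus.",
                 class = "hlarray_genotype_error")
  }
  invisible(genotype)
}

draw_genotype <- function(catalog, scenario = "clean",
                          masked = NULL) {
  loci <- unique(catalog$locus)
  pick_clean <- function(l) {
    sts <- sample(unique(catalog$serotype[catalog$locus == l]), 2)
    vapply(sts, function(st) {
      sample(catalog$allele[catalog$serotype == st], 1)
    }, character(1), USE.NAMES = FALSE)
  }
  if (scenario == "negative-control") return(character(0))
  g <- unlist(lapply(loci[-1], pick_clean), use.names = FALSE)
  first <- loci[1]
  head_alleles <- switch(
    scenario,
    "homozygous" = sample(catalog$allele[catalog$locus == first], 1),
    "close-alleles" = {
      st <- sample(unique(catalog$serotype[catalog$locus == first]), 1)
      sample(catalog$allele[catalog$serotype == st], 2)
    },
    "masked" = masked$sibling %||%
      rlang::abort("Masked scenario requires a masked-pair catalog.",
                   class = "hlarray_config_error"),
    pick_clean(first))
  sort(c(head_alleles, g))
}

#' Generate a reproducible simulated cohort
#'
#' Draws genotypes and simulates one raw array per sample, with a truth
#' manifest recording scenario and present alleles. The `"replicate"`
#' scenario reuses the previous sample's genotype with independent
#' noise, producing the replicate pairs used for reproducibility
#' checks. Scenario proportions must sum to 1; counts are assigned
#' deterministically (largest remainder) and scenarios are laid out in
#' blocks in the order given.
#'
#' @param config An [sim_config()] object.
#' @param n_samples Number of arrays.
#' @param scenario_mix Named numeric vector of scenario proportions
#'   (default all clean).
#' @param sim_catalog Optional [generate_allele_catalog()] output to
#'   reuse; generated from `config` if `NULL`.
#' @param probeset Optional matching `hla_probeset`.
#' @return A list of class `hla_sim_dataset`: `samples` (named list of
#'   raw [array_signals()]), `manifest` (tibble `sample_id`, `scenario`,
#'   `truth`, `replicate_of`), `catalog`, `probeset`, `serogroups`,
#'   `masked`, `efficiency`, `config`.
#' @export
generate_dataset <- function(config, n_samples,
                             scenario_mix = c(clean = 1),
                             sim_catalog = NULL, probeset = NULL) {
  if (abs(sum(scenario_mix) - 1) > 1e-8) {
    rlang::abort("Scenario proportions must sum to 1.",
                 class = "hlarray_config_error")
  }
  if (is.null(sim_catalog)) sim_catalog <- generate_allele_catalog(config)
  catalog <- sim_catalog$catalog
  if (is.null(probeset)) probeset <- build_probe_set(catalog)
  efficiency <- probe_efficiency(probeset, config)

  counts <- floor(scenario_mix * n_samples)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    extra <- order(scenario_mix * n_samples - counts,
                   decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  scenarios <- rep(names(counts), counts)

  set.seed(config$seed + 104729L)
  samples <- list()
  manifest <- list()
  last_geno <- NULL
  last_id <- NA_character_
  for (i in seq_len(n_samples)) {
    sc <- scenarios[i]
    id <- sprintf("S%03d", i)
    replicate_of <- NA_character_
    g2 <- NULL
    if (sc == "replicate" && !is.null(last_geno)) {
      g <- last_geno
      replicate_of <- last_id
    } else {
      g <- draw_genotype(catalog, if (sc == "replicate") "clean" else sc,
                         masked = sim_catalog$masked)
      if (sc == "mixed") g2 <- draw_genotype(catalog, "clean")
      last_geno <- g
      last_id <- id
    }
    samples[[id]] <- simulate_array(
      g, probeset, catalog, config, scenario = sc, array_id = id,
      efficiency = efficiency, genotype2 = g2)
    manifest[[i]] <- tibble::tibble(
      sample_id = id, scenario = sc,
      truth = paste(sort(unique(c(g, g2))), collapse = ","),
      replicate_of = replicate_of)
  }
  structure(
    list(samples = samples, manifest = dplyr::bind_rows(manifest),
         catalog = catalog, probeset = probeset,
         serogroups = sim_catalog$serogroups,
         masked = sim_catalog$masked,
         efficiency = efficiency, config = config),
    class = "hla_sim_dataset")
}
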