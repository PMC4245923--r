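# Shared fixtures, built lazily and cached for the whole test run.
# All catalogs and arrays are generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# deterministic tiny catalog: 2 loci x 2 serotypes x 2 alleles, 150 nt
small_config <- function(...) {
  sim_config(n_loci = 2, serotypes_per_locus = 2, alleles_per_serotype = 2,
             sequence_length = 150, seed = 7L, ...)
}

noise_free <- function(config) {
  config$noise_sd <- 0
  config$scale_sd <- 0
  config$profile_sd <- 0
  config
}

fix_small <- function() {
  cached("small", {
    cfg <- small_config()
    sc <- generate_allele_catalog(cfg)
    list(config = cfg, sim = sc, catalog = sc$catalog,
         probeset = build_probe_set(sc$catalog))
  })
}

# default study-condition catalog (3 x 8 x 4) shared across tests
fix_default <- function() {
  cached("default", {
    cfg <- sim_config(seed = 42L)
    sc <- generate_allele_catalog(cfg)
    list(config = cfg, sim = sc, catalog = sc$catalog,
         probeset = build_probe_set(sc$catalog))
  })
}

# a single-allele catalog whose probe track is exactly `n` fixed-length
# probes; handy for hand-built signal tracks
track_catalog <- function(n = 5, len = 20, seed = 1) {
  set.seed(seed)
  seqlen <- len + n - 1
  allele_catalog("A*01:01",
                 paste(sample(c("A", "C", "G", "T"), seqlen, TRUE),
                       collapse = ""))
}

track_probeset <- function(n = 5, len = 20, seed = 1) {
  build_probe_set(track_catalog(n, len, seed), min_len = len, max_len = len)
}

signals_for <- function(probeset, values, array_id = "arr",
                        stage = "normalized") {
  array_signals(probeset$probes$probe_id, values, array_id = array_id,
                stage = stage)
}

# independent oracle for the melting temperature (counts bases directly)
oracle_tm <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  64.9 + 41 * (sum(b == "G") + sum(b == "C") - 16.4) / length(b)
}

# independent brute-force oracle for Tm-driven length adjustment
oracle_adjust <- function(sequence, start, target_tm = 64.2,
                          min_len = 20, max_len = 60) {
  n <- nchar(sequence)
  best <- NULL
  for (L in min_len:min(max_len, n - start)) {
    tm <- oracle_tm(substring(sequence, start + 1, start + L))
    if (is.null(best) || abs(tm - target_tm) < best$dev - 1e-12) {
      best <- list(length = L, tm = tm, dev = abs(tm - target_tm))
    }
  }
  best
}

# independent brute-force oracle for the genotype comparison score
oracle_genotype_wins <- function(g1, g2, signals, probeset) {
  sig <- stats::setNames(signals$signal, signals$probe_id)
  pl <- probeset$placements
  sum_at <- function(g) {
    out <- list()
    for (a in g) {
      rows <- pl[pl$allele == a, ]
      for (i in seq_len(nrow(rows))) {
        key <- paste(rows$locus[i], rows$start[i])
        out[[key]] <- (out[[key]] %||% 0) + sig[[rows$probe_id[i]]]
      }
    }
    out
  }
  s1 <- sum_at(g1)
  s2 <- sum_at(g2)
  keys <- union(names(s1), names(s2))
  w1 <- 0; w2 <- 0
  for (k in keys) {
    a <- s1[[k]] %||% 0
    b <- s2[[k]] %||% 0
    if (a > b) w1 <- w1 + 1
    if (b > a) w2 <- w2 + 1
  }
  c(w1, w2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
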