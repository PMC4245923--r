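# two-allele catalog whose sequences differ at a single interior site,
# so exactly `covering` alignment columns carry allele-specific probes
variant_pair <- function(len = 24, plen = 20, site = 20, seed = 4) {
  set.seed(seed)
  s1 <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  s2 <- s1
  substr(s2, site, site) <- if (substr(s1, site, site) == "A") "G" else "A"
  catalog <- allele_catalog(c("A*01:01", "A*01:02"), c(s1, s2))
  list(catalog = catalog,
       probeset = build_probe_set(catalog, min_len = plen, max_len = plen))
}

test_that("pairwise wins count differing columns won by the brighter probe", {
  vp <- variant_pair() # 5 probes each, all 5 overlap the variant site
  ps <- vp$probeset
  sig <- stats::setNames(rep(50, nrow(ps$probes)), ps$probes$probe_id)
  on1 <- ps$placements$probe_id[ps$placements$allele == "A*01:01"]
  sig[on1] <- 5000
  s <- array_signals(names(sig), sig, stage = "corrected")
  aw <- allele_avg_wins(c("A*01:01", "A*01:02"), s, ps)
  expect_equal(aw$avg_wins[aw$allele == "A*01:01"], 5)
  expect_equal(aw$avg_wins[aw$allele == "A*01:02"], 0)

  # identical probe sets leave nothing to compare
  set.seed(6)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  twins <- allele_catalog(c("B*01:01", "B*01:02"), c(seq1, seq1))
  pst <- build_probe_set(twins)
  st <- array_signals(pst$probes$probe_id,
                      rep(1000, nrow(pst$probes)), stage = "corrected")
  aw2 <- allele_avg_wins(c("B*01:01", "B*01:02"), st, pst)
  expect_equal(aw2$avg_wins, c(0, 0))

  # three alleles, one present: the present allele dominates
  fx <- fix_small()
  cfg0 <- noise_free(fx$config)
  sc0 <- generate_allele_catalog(cfg0)
  ps0 <- build_probe_set(sc0$catalog)
  fam <- sc0$catalog$allele[sc0$catalog$serotype ==
                              sc0$catalog$serotype[1]]
  present <- fam[1]
  arr <- simulate_array(c(present, sc0$catalog$allele[
    sc0$catalog$locus == "B"][1]), ps0, sc0$catalog, cfg0)
  corr <- array_signals(arr$probe_id, arr$signal, stage = "corrected")
  aw3 <- allele_avg_wins(fam, corr, ps0)
  expect_equal(aw3$allele[which.max(aw3$avg_wins)], present)
})

test_that("comparison vectors take serogroup or serotype scope by the rule", {
  fx <- fix_small()
  ps <- fx$probeset
  thr <- tibble::tibble(probe_id = ps$probes$probe_id, threshold = 500)
  sig <- signals_for(ps, rep(1000, nrow(ps$probes)), stage = "corrected")
  calls <- binarize(sig, thr)
  surviving <- tibble::tibble(locus = c("A", "A", "B"),
                              serotype = c("A*01", "A*02", "B*01"))
  groups <- tibble::tibble(serotype = c("A*01", "A*02", "B*01"),
                           serogroup = c("G1", "G1", "B*01"))
  vecs <- build_comparison_vectors(surviving, sig, calls, ps, fx$catalog,
                                   serogroups = groups)
  scopes <- vapply(vecs, function(v) v$scope, character(1))
  sgs <- vapply(vecs, function(v) v$serogroup, character(1))
  expect_equal(scopes[sgs == "G1"], "serogroup")
  expect_equal(scopes[sgs == "B*01"], "serotype")
  g1 <- vecs[[which(sgs == "G1")]]
  expect_setequal(g1$entries$allele,
                  fx$catalog$allele[fx$catalog$serotype %in%
                                      c("A*01", "A*02")])
  # canonical ordering makes vectors comparable across arrays
  expect_equal(g1$entries$allele, sort(g1$entries$allele))
})

test_that("weight selection is a strict threshold on AvgWins - Neg", {
  entries <- tibble::tibble(allele = c("A*01:01", "A*01:02", "A*01:03"),
                            avg_wins = c(30, 2, 15),
                            neg = c(5, 40, 5))
  sel <- weight_based_selection(entries, fallback = 10)
  expect_equal(sel$weight, c(25, -38, 10))
  expect_equal(sel$candidate, c(TRUE, FALSE, FALSE)) # 10 > 10 is FALSE
  # allele-specific thresholds override the fallback
  sel2 <- weight_based_selection(
    entries, fallback = 10,
    weight_thresholds = tibble::tibble(allele = "A*01:03",
                                       weight_threshold = 5))
  expect_true(sel2$candidate[3])
})

test_that("genotype wins match the brute-force positional oracle", {
  set.seed(23)
  for (rep in 1:25) {
    n_all <- sample(3:5, 1)
    len <- sample(45:60, 1)
    base <- sample(c("A", "C", "G", "T"), len, TRUE)
    seqs <- vapply(seq_len(n_all), function(i) {
      s <- base
      idx <- sample(len, 3)
      s[idx] <- vapply(s[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(s, collapse = "")
    }, character(1))
    alleles <- sprintf("A*%02d:01", seq_len(n_all))
    cat <- allele_catalog(alleles, seqs)
    ps <- build_probe_set(cat, min_len = 20, max_len = 30)
    sig <- array_signals(ps$probes$probe_id,
                         rlnorm(nrow(ps$probes), log(500), 1),
                         stage = "corrected")
    g1 <- sample(alleles, 2)
    g2 <- sample(setdiff(alleles, g1[1]), 2)
    if (setequal(g1, g2)) next
    got <- genotype_wins(g1, g2, sig, ps)
    exp <- oracle_genotype_wins(g1, g2, sig, ps)
    expect_equal(unname(got), exp)
    # antisymmetry: wins sum to the non-tied positions
    cols <- sort(unique(ps$placements$start[
      ps$placements$allele %in% c(g1, g2)]))
    expect_lte(sum(got), length(cols))
  }
  vp <- variant_pair()
  sig <- array_signals(vp$probeset$probes$probe_id,
                       rep(100, nrow(vp$probeset$probes)),
                       stage = "corrected")
  expect_error(genotype_wins(c("A*01:01"), c("A*01:01"), sig, vp$probeset),
               class = "hlarray_genotype_error")
  expect_error(
    genotype_wins(c("A*01:01", "A*01:02", "A*01:01"), "A*01:02",
                  sig, vp$probeset),
    class = "hlarray_genotype_error")
  # equal signal everywhere: all positions tie
  w <- genotype_wins("A*01:01", "A*01:02", sig, vp$probeset)
  expect_equal(unname(w), c(0, 0))
})

test_that("ambiguity removal reports every genotype within the wins margin", {
  fx <- fix_small()
  cfg0 <- noise_free(fx$config)
  sc0 <- generate_allele_catalog(cfg0)
  ps0 <- build_probe_set(sc0$catalog)
  cat0 <- sc0$catalog
  truth <- c(cat0$allele[cat0$serotype == "A*01"][1],
             cat0$allele[cat0$serotype == "A*02"][1])
  arr <- simulate_array(truth, ps0, cat0, cfg0)
  corr <- array_signals(arr$probe_id, arr$signal, stage = "corrected")
  # three candidates at locus A forces enumeration; the noise-free truth
  # must rank first
  cands <- c(truth, cat0$allele[cat0$serotype == "A*01"][2])
  gen <- resolve_ambiguity(cands, corr, ps0, margin = 20)
  expect_equal(gen$alleles[[1]], sort(truth))
  expect_true(all(gen$wins >= max(gen$wins) - 20))

  # exactly two alleles pass through without enumeration
  gen2 <- resolve_ambiguity(truth, corr, ps0)
  expect_equal(nrow(gen2), 1)
  expect_equal(gen2$alleles[[1]], sort(truth))

  expect_error(resolve_ambiguity(cands, corr, ps0, cap = 2),
               class = "hlarray_combinatorial_error")
})

test_that("population frequencies reorder only within the margin", {
  genos <- tibble::tibble(
    alleles = list(c("B*07:24", "B*35:33"), c("B*07:02", "B*35:03")),
    wins = c(50, 48))
  class(genos) <- c("hla_genotypes", class(genos))
  freqs <- tibble::tibble(allele = c("B*07:02", "B*35:03"),
                          frequency = c(0.13, 0.07))
  out <- frequency_tiebreak(genos, freqs)
  # the common pair overtakes the rare pair (floor frequency 1e-6)
  expect_equal(out$alleles[[1]], c("B*07:02", "B*35:03"))
  # no table: order unchanged
  expect_identical(frequency_tiebreak(genos, NULL), genos)
  # equal products: stable (wins order preserved)
  f2 <- tibble::tibble(allele = unlist(genos$alleles),
                       frequency = 0.1)
  out2 <- frequency_tiebreak(genos, f2)
  expect_equal(out2$wins, c(50, 48))
})
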