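negs_tbl <- function(serotype, neg, locus = "A") {
  tibble::tibble(
    allele = sprintf("%s:%02d", serotype, seq_along(neg)),
    locus = locus, serotype = serotype,
    n_probes = 300L, neg = neg)
}

test_that("Neg(ST) averages the k = min(5, N) smallest allele counts", {
  sc <- serotype_scores(negs_tbl("A*01", c(2, 5, 9)))
  expect_equal(sc$neg_st, (2 + 5 + 9) / 3)
  expect_equal(sc$k, 3L)

  sc2 <- serotype_scores(negs_tbl("A*01", c(0, 1, 2, 3, 4, 50, 60, 70)))
  expect_equal(sc2$neg_st, 2)
  expect_equal(sc2$k, 5L)

  sc3 <- serotype_scores(negs_tbl("A*01", 7))
  expect_equal(sc3$neg_st, 7)

  # the literal k = max(5, N) mode averages every allele
  sc4 <- serotype_scores(negs_tbl("A*01", c(0, 1, 2, 3, 4, 50, 60, 70)),
                         k_mode = "max")
  expect_equal(sc4$neg_st, mean(c(0, 1, 2, 3, 4, 50, 60, 70)))

  expect_error(serotype_scores(negs_tbl("A*01", numeric())),
               class = "hlarray_catalog_error")
})

test_that("serotype ranking is ascending with deterministic tie-breaks", {
  negs <- rbind(negs_tbl("A*01", c(0, 30)), negs_tbl("A*02", c(200, 250)),
                negs_tbl("A*03", c(10, 20)))
  sc <- serotype_scores(negs)
  expect_equal(sc$serotype[sc$rank == 1], "A*01")
  expect_equal(sc$serotype[sc$rank == 3], "A*02")
  expect_equal(sort(sc$rank), 1:3)

  # exact neg_st tie: smaller min allele Neg first, then the id
  tied <- rbind(negs_tbl("A*05", c(5, 15)), negs_tbl("A*04", c(10, 10)))
  sct <- serotype_scores(tied)
  expect_equal(sct$serotype[sct$rank == 1], "A*05")
  tied2 <- rbind(negs_tbl("A*05", c(10, 10)), negs_tbl("A*04", c(10, 10)))
  sct2 <- serotype_scores(tied2)
  expect_equal(sct2$serotype[sct2$rank == 1], "A*04")
})

test_that("homozygosity needs a margin of at least 20 (inclusive)", {
  ranked <- function(n1, n2) {
    serotype_scores(rbind(negs_tbl("A*01", rep(n1, 2)),
                          negs_tbl("A*02", rep(n2, 2))))
  }
  expect_true(call_homozygous(ranked(3, 30))$homozygous)   # margin 27
  expect_false(call_homozygous(ranked(3, 22))$homozygous)  # margin 19
  expect_true(call_homozygous(ranked(3, 23))$homozygous)   # margin 20 exactly
  single <- serotype_scores(negs_tbl("A*01", c(1, 2)))
  hz <- call_homozygous(single)
  expect_true(hz$homozygous)
  expect_true(hz$single_serotype)
})

test_that("redundant elimination spares the top two and exempt pairs", {
  negs <- rbind(negs_tbl("A*01", c(0, 1)), negs_tbl("A*02", c(2, 4)),
                negs_tbl("A*03", c(100, 120)), negs_tbl("A*04", c(200, 220)))
  sc <- serotype_scores(negs)
  out <- eliminate_redundant(sc, fallback = 30)
  expect_equal(sort(out$serotype[out$kept]), c("A*01", "A*02"))
  elim <- attr(out, "elimination")
  expect_setequal(elim$removed, c("A*03", "A*04"))
  expect_true(all(elim$margin > elim$limit))

  # second-ranked survives an arbitrarily large margin
  negs2 <- rbind(negs_tbl("A*01", c(0, 1)), negs_tbl("A*02", c(500, 600)))
  out2 <- eliminate_redundant(serotype_scores(negs2), fallback = 30)
  expect_true(all(out2$kept))

  # exempt (never-distinguishable) pairs pass through to genotyping
  out3 <- eliminate_redundant(
    sc, fallback = 30,
    exempt_pairs = tibble::tibble(st1 = "A*01", st2 = "A*03"))
  expect_true(out3$kept[out3$serotype == "A*03"])
  expect_false(out3$kept[out3$serotype == "A*04"])

  # pair-specific MaxDifference overrides the fallback
  out4 <- eliminate_redundant(
    sc, fallback = 30,
    max_difference = tibble::tibble(st1 = "A*01", st2 = "A*03",
                                    max_difference = 1000))
  expect_true(out4$kept[out4$serotype == "A*03"])
})

test_that("homozygosity and elimination agree with a brute-force oracle", {
  set.seed(77)
  for (rep in 1:200) {
    n_st <- sample(3:6, 1)
    negs <- do.call(rbind, lapply(seq_len(n_st), function(g) {
      negs_tbl(sprintf("A*%02d", g), sample(0:300, sample(1:6, 1), TRUE))
    }))
    sc <- serotype_scores(negs)
    # oracle: recompute scores and decisions from scratch
    o <- do.call(rbind, lapply(split(negs, negs$serotype), function(d) {
      k <- min(5, nrow(d))
      data.frame(serotype = d$serotype[1],
                 neg_st = mean(sort(d$neg)[1:k]), min_neg = min(d$neg))
    }))
    o <- o[order(o$neg_st, o$min_neg, o$serotype), ]
    expect_equal(sc$serotype, o$serotype)
    expect_equal(sc$neg_st, o$neg_st)
    expect_equal(call_homozygous(sc)$homozygous,
                 o$neg_st[2] - o$neg_st[1] >= 20)
    kept <- eliminate_redundant(sc, fallback = 30)
    expect_equal(!kept$kept,
                 kept$rank > 2 & (kept$neg_st - o$neg_st[1]) > 30)
  }
})

test_that("negative counts respect placements, including full masking", {
  fx <- fix_small()
  ps <- fx$probeset
  thr <- tibble::tibble(probe_id = ps$probes$probe_id, threshold = 500)
  all_pos <- binarize(signals_for(ps, rep(5000, nrow(ps$probes))), thr)
  n0 <- count_negatives(all_pos, ps)
  expect_true(all(n0$neg == 0))
  all_neg <- binarize(signals_for(ps, rep(1, nrow(ps$probes))), thr)
  n1 <- count_negatives(all_neg, ps)
  expect_equal(n1$neg, n1$n_probes)

  # a duplicated allele is fully masked by its twin: Neg = 0 while absent
  s <- fx$catalog$sequence[1]
  twin <- allele_catalog(c("A*01:01", "A*09:01"), c(s, s))
  ps2 <- build_probe_set(twin)
  thr2 <- tibble::tibble(probe_id = ps2$probes$probe_id, threshold = 500)
  present_first <- binarize(
    signals_for(ps2, rep(5000, nrow(ps2$probes))), thr2)
  masked <- count_negatives(present_first, ps2)
  expect_equal(masked$neg[masked$allele == "A*09:01"], 0L)

  expect_error(count_negatives(all_pos, ps, alleles = "Z*99:99"),
               class = "hlarray_catalog_error")
})

test_that("stage 1 never drops a present serotype on clean samples", {
  fx <- fix_default()
  set.seed(99)
  ds <- generate_dataset(fx$config, 30, sim_catalog = fx$sim,
                         probeset = fx$probeset)
  norms <- lapply(ds$samples, normalize_signals)
  thr <- compute_thresholds(norms, fx$probeset)
  survived <- vapply(seq_along(norms), function(i) {
    st <- serotype_stage(binarize(norms[[i]], thr), fx$probeset)
    truth <- strsplit(ds$manifest$truth[i], ",")[[1]]
    truth_st <- unique(parse_allele_name(truth)$serotype)
    all(truth_st %in% st$surviving$serotype)
  }, logical(1))
  expect_true(all(survived))
})
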