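test_that("depth normalization divides by per-bin means, fractions sum to 1", {
  counts <- tibble::tibble(
    peptide = rep(c("P1", "P2"), each = 4),
    allele = "A",
    bin = rep(c("bg", "low", "med", "high"), 2),
    replicate = "R1",
    count = c(10L, 5L, 5L, 5L, 30L, 5L, 5L, 5L)
  )
  fr <- normalize_bins(counts)
  # bg counts 10 and 30: mean 20 -> depth-normalized 0.5 and 1.5
  bg <- dplyr::filter(fr, bin == "bg")
  other <- 3  # low/med/high each normalize to 1
  expect_equal(bg$fraction, c(0.5 / (0.5 + other), 1.5 / (1.5 + other)))
  sums <- fr |>
    dplyr::group_by(peptide) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, c(1, 1))
  # uniform four-vector gives quarter fractions
  uni <- normalize_bins(tibble::tibble(
    peptide = "P", allele = "A", bin = c("bg", "low", "med", "high"),
    replicate = "R1", count = rep(7L, 4)
  ))
  expect_equal(uni$fraction, rep(0.25, 4))
})

test_that("E-score identities: 0 for background, 8 for high, 3.5 uniform", {
  esc <- compute_escore(fraction_tbl(c("P1", "P2", "P3"), rbind(
    c(1, 0, 0, 0), c(0, 0, 0, 1), c(0.25, 0.25, 0.25, 0.25)
  )))
  expect_equal(esc$raw_escore[match("P1", esc$peptide)], 0)
  expect_equal(esc$raw_escore[match("P2", esc$peptide)], 8)
  expect_equal(esc$raw_escore[match("P3", esc$peptide)], 3.5)
  # and from raw counts: a pure-background trimer among uniform fillers
  counts <- dplyr::bind_rows(
    tibble::tibble(peptide = "PUREBG", count = c(400L, 0L, 0L, 0L)),
    tibble::tibble(peptide = "PUREHI", count = c(0L, 0L, 0L, 400L)),
    tibble::tibble(peptide = "FILL1", count = rep(100L, 4)),
    tibble::tibble(peptide = "FILL2", count = rep(100L, 4))
  ) |>
    dplyr::mutate(allele = "A", replicate = "R1",
                  bin = rep(c("bg", "low", "med", "high"), 4))
  esc2 <- compute_escores(counts)
  expect_equal(esc2$raw_escore[esc2$peptide == "PUREBG"], 0)
  expect_equal(esc2$raw_escore[esc2$peptide == "PUREHI"], 8)
})

test_that("E-scores are bounded, depth-invariant, and bin-monotone", {
  set.seed(21)
  for (i in 1:20) {
    f <- stats::runif(4)
    f <- f / sum(f)
    e <- compute_escore(fraction_tbl("P", rbind(f)))$raw_escore
    expect_gte(e, 0)
    expect_lte(e, 8)
    # move mass from a lower to a higher bin: score must not decrease
    donor <- sample(1:3, 1)
    higher <- (donor + 1):4
    recipient <- higher[sample.int(length(higher), 1)]
    g <- f
    delta <- g[donor] / 2
    g[donor] <- g[donor] - delta
    g[recipient] <- g[recipient] + delta
    e2 <- compute_escore(fraction_tbl("P", rbind(g)))$raw_escore
    expect_gte(e2 + 1e-9, e)
  }
  # multiplying one bin file's counts by a constant leaves scores unchanged
  counts <- dplyr::as_tibble(tiny_counts())
  esc1 <- compute_escores(counts)
  scaled <- dplyr::mutate(counts, count = ifelse(bin == "med",
                                                 count * 17L, count))
  esc2 <- compute_escores(scaled)
  expect_equal(esc1$raw_escore, esc2$raw_escore, tolerance = 1e-12)
})

test_that("all-zero trimers are flagged missing, never zero", {
  counts <- tibble::tibble(
    peptide = rep(c("P1", "P2"), each = 4), allele = "A",
    bin = rep(c("bg", "low", "med", "high"), 2), replicate = "R1",
    count = c(5L, 5L, 5L, 5L, 0L, 0L, 0L, 0L)
  )
  esc <- compute_escores(counts)
  expect_true(is.na(esc$raw_escore[esc$peptide == "P2"]))
  expect_true(esc$missing[esc$peptide == "P2"])
  expect_false(esc$missing[esc$peptide == "P1"])
})

test_that("weights must increase; custom weights are honoured", {
  expect_error(escore_weights(0, 4, 2, 8), "increasing")
  w <- escore_weights(0, 1, 2, 3)
  uni <- fraction_tbl("P", rbind(rep(0.25, 4)))
  expect_equal(compute_escore(uni, w)$raw_escore, 1.5)
})

test_that("mode alignment converges allele modes and is idempotent", {
  # two alleles whose negative peaks sit at different locations
  set.seed(5)
  esc <- tibble::tibble(
    peptide = rep(sprintf("P%03d", 1:300), 2),
    allele = rep(c("A1", "A2"), each = 300),
    replicate = "R1",
    raw_escore = c(stats::rnorm(270, 1.0, 0.25), stats::rnorm(30, 6, 0.5),
                   stats::rnorm(270, 1.4, 0.25), stats::rnorm(30, 6, 0.5))
  )
  al <- align_alleles(esc, min_n = 50)
  sh <- alignment_shifts(al)
  expect_equal(nrow(sh), 2)
  # estimated modes converge after shifting
  realigned <- al |>
    dplyr::mutate(raw_escore = aligned_escore) |>
    align_alleles(min_n = 50)
  sh2 <- alignment_shifts(realigned)
  expect_lt(max(abs(sh2$shift)), 0.06)
  # modes were ~1.0 and ~1.4: shifts near +/-0.2 toward the median
  expect_equal(sort(sh$shift), c(-0.2, 0.2), tolerance = 0.3)
  expect_equal(sum(sh$shift), 0, tolerance = 0.12)
  # single allele: reference is its own mode -> zero shift
  one <- align_alleles(dplyr::filter(esc, allele == "A1"), min_n = 50)
  expect_equal(alignment_shifts(one)$shift, 0, tolerance = 1e-12)
  # sparse allele: flagged, zero shift
  expect_warning(
    few <- align_alleles(dplyr::slice_head(esc, n = 10), min_n = 50),
    "zero shift"
  )
  expect_true(all(alignment_shifts(few)$flagged))
})

test_that("binder calls use mode thresholds with strict inequality", {
  esc <- tibble::tibble(peptide = "P", allele = "A",
                        mean_escore = c(3.3, 3.2, 3.9, 3.8))
  single <- call_binders(esc, "single")
  expect_identical(single$binder, c(TRUE, FALSE, TRUE, TRUE))
  comb <- call_binders(esc, "combinatorial")
  expect_identical(comb$binder, c(FALSE, FALSE, TRUE, FALSE))
  expect_warning(call_binders(esc, "combinatorial", threshold = 3.2),
                 "guidance band")
  custom <- call_binders(esc, "combinatorial", threshold = 3.85)
  expect_identical(custom$binder, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("replicate QC passes identical replicates, fails independent noise", {
  set.seed(9)
  base <- tibble::tibble(peptide = sprintf("P%02d", 1:50), allele = "A")
  ident <- dplyr::bind_rows(
    dplyr::mutate(base, replicate = "R1", raw_escore = stats::runif(50, 0, 8)),
  )
  ident2 <- dplyr::mutate(ident, replicate = "R2")
  qc <- replicate_qc(dplyr::bind_rows(ident, ident2))
  expect_equal(qc$pearson_r, 1)
  expect_true(qc$pass)
  noise <- dplyr::bind_rows(
    dplyr::mutate(base, replicate = "R1", raw_escore = stats::rnorm(50)),
    dplyr::mutate(base, replicate = "R2", raw_escore = stats::rnorm(50))
  )
  qcn <- replicate_qc(noise)
  expect_false(qcn$pass)
  expect_lt(abs(qcn$pearson_r), 0.5)
  # constant vector: undefined correlation, explicit failure reason
  const <- dplyr::bind_rows(
    dplyr::mutate(base, replicate = "R1", raw_escore = 1),
    dplyr::mutate(base, replicate = "R2", raw_escore = stats::rnorm(50))
  )
  qcc <- replicate_qc(const)
  expect_false(qcc$pass)
  expect_identical(qcc$reason, "constant_scores")
})

test_that("position-frequency matrices match a direct tally oracle", {
  expect_equal(unname(build_motif(c("AAA", "AAA"))["A", ]), rep(1, 3))
  # one of each residue per column -> uniform 0.05
  peps <- vapply(1:20, function(i) {
    paste(rep(AA <- escapeseq:::AA_ALPHABET_20[i], 3), collapse = "")
  }, character(1))
  m <- build_motif(peps)
  expect_true(all(abs(m - 0.05) < 1e-12))
  set.seed(3)
  rand <- random_peptides(40, k = 9, seed = 3)
  pfm <- build_motif(rand)
  expect_equal(unname(colSums(pfm)), rep(1, 9))
  chars <- do.call(rbind, strsplit(rand, ""))
  for (j in c(1, 5, 9)) {
    tally <- table(factor(chars[, j], levels = escapeseq:::AA_ALPHABET_20))
    expect_equal(unname(pfm[, j]), unname(as.numeric(tally) / 40))
  }
  expect_error(build_motif(c("AAA", "AAAA")), "same length")
})

test_that("capture percentage is the set-intersection fraction", {
  calls <- tibble::tibble(
    peptide = rep(sprintf("P%02d", 1:10), 2),
    allele = rep(c("A1", "A2"), each = 10),
    binder = c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 10))
  )
  hits <- tibble::tibble(peptide = sprintf("P%02d", 1:10),
                         allele = "A1")
  cap <- capture_percentage(calls, hits)
  expect_equal(cap$capture[cap$allele == "A1"], 0.8)
  expect_true(is.na(cap$capture[cap$allele == "A2"]))
  expect_true(cap$flagged[cap$allele == "A2"])
  # binders superset of hits -> 1
  cap2 <- capture_percentage(dplyr::mutate(calls, binder = TRUE), hits)
  expect_equal(cap2$capture[cap2$allele == "A1"], 1)
})

test_that("quadrant classification matches a brute-force oracle", {
  thr <- 3.8
  q1 <- quadrant_classify(tibble::tibble(
    allele = "A", mut_escore = 5, wt_escore = 1), thr)
  expect_identical(as.character(q1$class), "Mut+only")
  q2 <- quadrant_classify(tibble::tibble(
    allele = "A", mut_escore = 5, wt_escore = 5), thr)
  expect_identical(as.character(q2$class), "WT+Mut+")
  set.seed(13)
  pairs <- tibble::tibble(
    allele = sample(c("A1", "A2"), 200, TRUE),
    mut_escore = stats::runif(200, 0, 8),
    wt_escore = stats::runif(200, 0, 8)
  )
  q <- quadrant_classify(pairs, thr)
  oracle <- with(pairs, ifelse(
    mut_escore > thr & wt_escore > thr, "WT+Mut+",
    ifelse(mut_escore > thr, "Mut+only",
           ifelse(wt_escore > thr, "WT+only", "WT-Mut-"))))
  expect_identical(as.character(q$class), oracle)
  qs <- quadrant_summary(q)
  tot <- qs |> dplyr::group_by(allele) |> dplyr::summarise(p = sum(percent))
  expect_equal(tot$p, c(100, 100))
})

test_that("mut/wt pairing follows library provenance", {
  prot <- toy_protein(40, seed = 12)
  lib <- design_variant_library(
    setNames(prot, "G"),
    data.frame(gene = "G", kind = "point", position = 20,
               ref = substr(prot, 20, 20), alt = "W"),
    ks = 9
  )
  esc <- tibble::tibble(
    peptide = unique(lib$peptide), allele = "A1",
    mean_escore = seq_along(unique(lib$peptide))
  )
  paired <- pair_mut_wt(esc, lib)
  expect_equal(nrow(paired), 9)
  expect_true(all(paired$mut_peptide != paired$wt_peptide))
  # dropping one wt score leaves an unpaired warning
  esc2 <- esc[esc$peptide != lib$peptide[lib$mut_wt == "wt"][1], ]
  expect_warning(p2 <- pair_mut_wt(esc2, lib), "unpaired")
  expect_equal(nrow(p2), 8)
})

test_that("sharing profiles match direct tallies", {
  calls <- tibble::tibble(
    peptide = rep(c("P1", "P2", "P3"), each = 3),
    allele = rep(c("A1", "A2", "A3"), 3),
    binder = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE)
  )
  sh <- allele_sharing(calls)
  expect_equal(sh$n_alleles[match(c("P1", "P2", "P3"), sh$peptide)],
               c(3L, 0L, 2L))
  lib <- tibble::tibble(peptide = c("P1", "P2", "P3"),
                        variant_tag = c("M1", "M1", "M2"))
  mp <- mutation_presentation(calls, lib)
  # M1 covers P1 (binder on A1) and P2 (not): one presented of two
  expect_equal(
    mp$n_presented[mp$variant_tag == "M1" & mp$allele == "A1"], 1L)
  expect_equal(
    mp$n_windows[mp$variant_tag == "M1" & mp$allele == "A1"], 2L)
})
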