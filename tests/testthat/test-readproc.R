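test_that("insert extraction honours exact-anchor matching", {
  a <- anchor_spec()
  oligo <- encode_oligo("ACDEFGHIK")$oligo
  bc <- design_barcodes(1, seed = 1)$barcode_dna
  good <- paste0(a$peptide_flank5, oligo, a$peptide_flank3,
                 a$barcode_flank5, bc, a$barcode_flank3)
  res <- extract_insert(good, a)
  expect_identical(res$status, "assigned")
  expect_identical(res$peptide_dna, oligo)
  expect_identical(res$barcode_dna, bc)
  # single-mismatch anchor: discarded, not rescued
  mut <- good
  substr(mut, 1, 1) <- if (substr(mut, 1, 1) == "A") "C" else "A"
  expect_identical(extract_insert(mut, a)$status, "no_anchor")
  # duplicated anchor is ambiguous
  dup <- paste0(a$peptide_flank5, good)
  expect_identical(extract_insert(dup, a)$status, "multi_anchor")
  # insert of 7 codons (21 nt) is outside the 8-12-mer range
  short <- paste0(a$peptide_flank5, substr(oligo, 1, 21), a$peptide_flank3,
                  a$barcode_flank5, bc, a$barcode_flank3)
  expect_identical(extract_insert(short, a)$status, "bad_insert_length")
  # batch: 10 corrupted of 100 -> 90 assigned
  reads <- rep(good, 100)
  substr(reads[1:10], 1, 1) <- "N"
  res100 <- extract_insert(reads, a)
  expect_equal(sum(res100$status == "assigned"), 90)
})

test_that("anchor specs are validated", {
  expect_error(anchor_spec(peptide_flank5 = "ACGT"), "6, 10")
  expect_error(anchor_spec(peptide_flank5 = "ACGTACGTACGTA"), "6, 10")
  expect_error(anchor_spec(peptide_flank5 = "ACGTAC",
                           peptide_flank3 = "ACGTAC"), "distinct")
})

test_that("demultiplexing conserves reads and recovers known mixtures", {
  sim <- tiny_fixture()
  counts <- tiny_counts()
  qc <- qc_report(counts)
  expect_true(all(qc$files$n_assigned + qc$files$n_discarded ==
                    qc$files$n_total))
  # per-file column sums equal assigned reads
  colsums <- dplyr::count(dplyr::as_tibble(counts),
                          bin, replicate, wt = count, name = "n")
  merged <- dplyr::inner_join(colsums,
                              dplyr::mutate(qc$files, bin = factor(bin, levels = c("bg","low","med","high"))),
                              by = c("bin", "replicate"))
  expect_equal(merged$n, merged$n_assigned)
  # noise-free demultiplexing equals the simulator's latent counts exactly
  truth <- truth_count_table(sim)
  expect_equal(as.integer(counts$count), as.integer(truth$count))
})

test_that("a known two-construct mixture lands in the right cells", {
  a <- anchor_spec()
  lib <- encode_oligo(c("ACDEFGHIK", "MSTQRVKLW"))
  bc <- design_barcodes(c("X", "Y"), seed = 2)
  mk <- function(oligo, barcode) {
    paste0(a$peptide_flank5, oligo, a$peptide_flank3,
           a$barcode_flank5, barcode, a$barcode_flank3)
  }
  dir <- withr::local_tempdir()
  f_high <- file.path(dir, "high.fastq")
  f_bg <- file.path(dir, "bg.fastq")
  writeLines(unlist(lapply(rep(mk(lib$oligo[1], bc$barcode_dna[1]), 600),
                           function(s) c("@r", s, "+", strrep("I", nchar(s))))),
             f_high)
  writeLines(unlist(lapply(rep(mk(lib$oligo[2], bc$barcode_dna[2]), 400),
                           function(s) c("@r", s, "+", strrep("I", nchar(s))))),
             f_bg)
  files <- tibble::tibble(path = c(f_high, f_bg), bin = c("high", "bg"),
                          replicate = "R1")
  counts <- count_reads(files, lib, bc, a)
  got <- dplyr::filter(dplyr::as_tibble(counts), count > 0)
  expect_equal(nrow(got), 2)
  expect_equal(
    got$count[got$peptide == "ACDEFGHIK" & got$allele == "X" &
                got$bin == "high"], 600)
  expect_equal(
    got$count[got$peptide == "MSTQRVKLW" & got$allele == "Y" &
                got$bin == "bg"], 400)
  # a barcode with one substitution is an unknown_barcode discard
  bad_bc <- bc$barcode_dna[1]
  substr(bad_bc, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                  substr(bad_bc, 3, 3))[1]
  f_bad <- file.path(dir, "bad.fastq")
  s <- mk(lib$oligo[1], bad_bc)
  writeLines(c("@r", s, "+", strrep("I", nchar(s))), f_bad)
  counts2 <- count_reads(
    tibble::tibble(path = f_bad, bin = "low", replicate = "R1"), lib, bc, a)
  reasons <- qc_report(counts2)$reasons
  expect_equal(reasons$reason, "unknown_barcode")
  expect_equal(sum(dplyr::as_tibble(counts2)$count), 0)
})

test_that("demultiplexing is invariant to read order", {
  sim <- tiny_fixture()
  f1 <- sim$files[sim$files$bin == "high" & sim$files$replicate == "R1", ]
  seqs <- readLines(f1$path)
  idx <- seq(2, length(seqs), by = 4)
  shuffled <- seqs
  set.seed(1)
  perm <- sample(idx)
  shuffled[idx] <- seqs[perm]
  dir <- withr::local_tempdir()
  p2 <- file.path(dir, "shuf.fastq")
  writeLines(shuffled, p2)
  c1 <- count_reads(f1, sim$library, sim$barcodes, sim$anchors)
  c2 <- count_reads(dplyr::mutate(f1, path = p2), sim$library,
                    sim$barcodes, sim$anchors)
  expect_equal(as.integer(c1$count), as.integer(c2$count))
})

test_that("empty FASTQ warns and yields a zero column", {
  sim <- tiny_fixture()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.fastq")
  file.create(p)
  expect_warning(
    counts <- count_reads(
      tibble::tibble(path = p, bin = "med", replicate = "R9"),
      sim$library, sim$barcodes, sim$anchors),
    "empty"
  )
  expect_equal(sum(dplyr::as_tibble(counts)$count), 0)
})

test_that("spike-in chimera rate is exact on a constructed table", {
  sp <- spikein_design(
    alleles = tibble::tibble(pool_id = c("p1", "p1", "p2", "p2"),
                             allele = c("a1", "a2", "b1", "b2")),
    peptides = tibble::tibble(pool_id = c("p1", "p2"),
                              peptide = c("PEP1", "PEP2"))
  )
  counts <- tibble::tibble(
    peptide = c("PEP1", "PEP1", "PEP2"),
    allele = c("a1", "b1", "b2"),
    bin = "high", replicate = "R1",
    count = c(180, 20, 100)
  )
  est <- estimate_recombination(counts, sp, correct = FALSE)
  expect_equal(est$raw_rate, 20 / 300)
  expect_equal(est$n_cross, 20)
  # all within-pool -> zero
  est0 <- estimate_recombination(counts[c(1, 3), ], sp,
                                 n_panel_alleles = 4)
  expect_equal(est0$chimera_rate, 0)
  expect_error(
    estimate_recombination(dplyr::mutate(counts, count = 0L), sp),
    "undefined"
  )
})

test_that("injected recombination rates are recovered within binomial CI", {
  # within-pool paired spike-in screen, swaps injected at known rates
  bc <- design_barcodes(sprintf("AL%02d", 1:6), seed = 5)
  lib <- random_library(30, barcodes = bc, seed = 5)
  peps <- lib$peptide
  pool_of_pep <- rep(c("p1", "p2"), each = 15)
  pool_of_al <- rep(c("p1", "p2"), each = 3)
  sp <- spikein_design(
    alleles = tibble::tibble(pool_id = pool_of_al, allele = bc$allele),
    peptides = tibble::tibble(pool_id = pool_of_pep, peptide = peps)
  )
  pairing <- dplyr::inner_join(sp$peptides, sp$alleles, by = "pool_id",
                               relationship = "many-to-many")
  for (rate in c(0, 0.05, 0.10)) {
    model <- sorter_model(reads_per_bin = 20000, cells_per_construct = 500,
                          recombination_rate = rate, seed = 31 + rate * 100)
    sim <- simulate_screen(lib, bc, model, replicates = 1,
                           pairing = pairing[, c("peptide", "allele")])
    counts <- count_reads(sim$files, lib, bc, sim$anchors)
    est <- estimate_recombination(counts, sp)
    n <- est$n_spikein
    # binomial CI on the detectable fraction, mapped through the correction
    detect <- 3 / 5  # (6 panel - 3 own pool) / (6 - 1)
    se <- sqrt(max(rate * detect, 1e-9) * (1 - rate * detect) / n) / detect
    expect_lt(abs(est$chimera_rate - rate), max(4 * se, 0.004))
  }
})
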