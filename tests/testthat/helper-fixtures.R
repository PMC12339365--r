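# Shared fixtures and independent oracles. The tiny simulated screen is
# built once per test run and reused.

tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(make_fixture("tiny", seed = 7))
    }
    cache
  }
})

# the 200 x 10 screen at default depth: simulated, demultiplexed, scored
# once per run (shared between the recovery and acceptance suites)
small_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- suppressWarnings(make_fixture("small", seed = 1))
      counts <- count_reads(sim$files, sim$library, sim$barcodes,
                            sim$anchors)
      esc <- align_alleles(compute_escores(counts))
      agg <- aggregate_replicates(esc)
      joined <- dplyr::inner_join(agg, sim$truth$constructs,
                                  by = c("peptide", "allele"))
      cache <<- list(sim = sim, counts = counts, esc = esc, agg = agg,
                     joined = joined)
    }
    cache
  }
})

tiny_counts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- tiny_fixture()
      cache <<- count_reads(sim$files, sim$library, sim$barcodes,
                            sim$anchors)
    }
    cache
  }
})

# brute-force all-pairs concordance: the Mann-Whitney oracle for ROC-AUC
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# direct substring enumeration of all k-windows of a sequence
substring_oracle <- function(seq, k) {
  n <- nchar(seq) - k + 1
  vapply(seq_len(n), function(i) substr(seq, i, i + k - 1), character(1))
}

# toy proteins with no repeated k-mers (generic position)
toy_protein <- function(L, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               L, replace = TRUE), collapse = "")
}

# per-trimer bin-fraction table in the shape normalize_bins() emits
fraction_tbl <- function(peptides, frac_matrix, allele = "A",
                         replicate = "R1") {
  # frac_matrix: one row per peptide, columns bg/low/med/high
  purrr::map_dfr(seq_along(peptides), function(i) {
    tibble::tibble(
      peptide = peptides[i], allele = allele, replicate = replicate,
      bin = c("bg", "low", "med", "high"),
      fraction = as.numeric(frac_matrix[i, ]), missing = FALSE
    )
  })
}
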