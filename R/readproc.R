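# Read processing: exact-anchor extraction of peptide/barcode inserts from
# FASTQ reads, assembly of the peptide x allele x bin x replicate count
# table, and spike-in based recombination estimation.

BIN_LEVELS <- c("bg", "low", "med", "high")

#' Flanking-anchor specification
#'
#' The peptide insert and the allele barcode are each located by exact
#' matches of short fixed flanking sequences (6-10 nt); anything less than
#' an exact match of both flanks discards the read.
#'
#' @param peptide_flank5,peptide_flank3 Anchors around the peptide insert.
#' @param barcode_flank5,barcode_flank3 Anchors around the allele barcode.
#' @return An object of class `anchor_spec`.
#' @export
anchor_spec <- function(peptide_flank5 = "GCAGCGGC",
                        peptide_flank3 = "GGCGGTTC",
                        barcode_flank5 = "ACCTCCGG",
                        barcode_flank3 = "CCTTAGCG") {
  a <- list(
    peptide_flank5 = peptide_flank5, peptide_flank3 = peptide_flank3,
    barcode_flank5 = barcode_flank5, barcode_flank3 = barcode_flank3
  )
  lens <- vapply(a, nchar, integer(1))
  if (any(lens < 6 | lens > 10)) {
    abort("anchor lengths must be within [6, 10] nt")
  }
  assert_dna(unlist(a), "anchor")
  if (anyDuplicated(unlist(a))) abort("anchors must be mutually distinct")
  structure(a, class = "anchor_spec")
}

locate_unique <- function(reads, anchor) {
  # start position of the anchor when it occurs exactly once, else NA with
  # a reason: 0 occurrences -> -1, >1 -> -2
  loc <- stringr::str_locate_all(reads, stringr::fixed(anchor))
  vapply(loc, function(m) {
    if (nrow(m) == 1L) m[1, 1] else if (nrow(m) == 0L) -1L else -2L
  }, integer(1))
}

#' Extract peptide and barcode inserts from reads
#'
#' Each read must contain exactly one exact occurrence of all four anchors;
#' the substrings strictly between the peptide anchors and between the
#' barcode anchors are the candidate inserts. Failures never error; every
#' read gets a status, one of `assigned`, `no_anchor`, `multi_anchor`,
#' `bad_insert_length` (peptide insert not a multiple of 3 within
#' `insert_range`, or barcode insert not a multiple of 3).
#'
#' @param reads Character vector of read sequences.
#' @param anchors An [anchor_spec()].
#' @param insert_range Allowed peptide-insert length range in nt (default
#'   24-36, i.e. 8-12 residues).
#' @return A tibble with columns `read`, `peptide_dna`, `barcode_dna`,
#'   `status`.
#' @export
extract_insert <- function(reads, anchors = anchor_spec(),
                           insert_range = c(24L, 36L)) {
  stopifnot(inherits(anchors, "anchor_spec"))
  p5 <- locate_unique(reads, anchors$peptide_flank5)
  p3 <- locate_unique(reads, anchors$peptide_flank3)
  b5 <- locate_unique(reads, anchors$barcode_flank5)
  b3 <- locate_unique(reads, anchors$barcode_flank3)
  status <- rep("assigned", length(reads))
  status[p5 == -1L | p3 == -1L | b5 == -1L | b3 == -1L] <- "no_anchor"
  status[status == "assigned" &
           (p5 == -2L | p3 == -2L | b5 == -2L | b3 == -2L)] <- "multi_anchor"
  ok <- status == "assigned"
  pep_start <- p5 + nchar(anchors$peptide_flank5)
  bc_start <- b5 + nchar(anchors$barcode_flank5)
  peptide_dna <- rep(NA_character_, length(reads))
  barcode_dna <- rep(NA_character_, length(reads))
  peptide_dna[ok] <- substr(reads[ok], pep_start[ok], p3[ok] - 1L)
  barcode_dna[ok] <- substr(reads[ok], bc_start[ok], b3[ok] - 1L)
  plen <- nchar(peptide_dna)
  blen <- nchar(barcode_dna)
  bad <- ok & (plen %% 3L != 0L | plen < insert_range[1] |
                 plen > insert_range[2] | blen %% 3L != 0L | blen == 0L)
  status[bad] <- "bad_insert_length"
  peptide_dna[status != "assigned"] <- NA_character_
  barcode_dna[status != "assigned"] <- NA_character_
  tibble(read = reads, peptide_dna = peptide_dna,
         barcode_dna = barcode_dna, status = status)
}

read_fastq_seqs <- function(path) {
  res <- tryCatch(
    as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
    error = function(e) {
      # an empty FASTQ is a warning + zero column, not an error
      if (file.exists(path) && file.size(path) == 0) return(character(0))
      abort(sprintf("cannot read FASTQ %s: %s", path, conditionMessage(e)))
    }
  )
  unname(res)
}

#' Demultiplex FASTQ files into a bin count table
#'
#' Reads each FASTQ(.gz), extracts inserts by exact anchor matching
#' ([extract_insert()]), maps the peptide insert to a designed oligo and
#' the barcode insert to a panel barcode by exact sequence identity, and
#' counts reads per (peptide, allele, bin, replicate). Unknown inserts and
#' anchor failures are categorised discards; per file, assigned +
#' discarded = total.
#'
#' @param files Data frame with columns `path`, `bin` (one of bg, low,
#'   med, high) and `replicate`.
#' @param library Encoded library from [encode_oligo()] (columns `peptide`,
#'   `oligo`).
#' @param barcodes Barcode panel from [design_barcodes()] (columns
#'   `allele`, `barcode_dna`).
#' @param anchors An [anchor_spec()].
#' @param revcomp Also scan the reverse complement of each read when the
#'   forward orientation fails (off by default).
#' @return A `bin_counts` tibble (`peptide`, `allele`, `bin`, `replicate`,
#'   `count`) on the complete library x panel grid, with attributes `qc`
#'   (per-file totals) and `discard_reasons` (per-file reason tallies),
#'   retrievable via [qc_report()].
#' @export
count_reads <- function(files, library, barcodes, anchors = anchor_spec(),
                        revcomp = FALSE) {
  files <- as_tibble(files)
  stopifnot(all(c("path", "bin", "replicate") %in% names(files)))
  if (!all(files$bin %in% BIN_LEVELS)) {
    abort(sprintf("bin must be one of: %s", paste(BIN_LEVELS, collapse = ", ")))
  }
  lib <- distinct(as_tibble(library), .data$peptide, .data$oligo)
  if (anyDuplicated(lib$oligo)) abort("library oligos are not unique")
  per_file <- purrr::pmap(files, function(path, bin, replicate, ...) {
    seqs <- read_fastq_seqs(path)
    if (length(seqs) == 0) {
      warn(sprintf("empty FASTQ: %s (zero column emitted)", path))
    }
    ext <- extract_insert(seqs, anchors)
    if (revcomp) {
      retry <- ext$status == "no_anchor"
      if (any(retry)) {
        ext2 <- extract_insert(reverse_complement(seqs[retry]), anchors)
        ext[retry, ] <- ext2
      }
    }
    pep <- lib$peptide[match(ext$peptide_dna, lib$oligo)]
    allele <- barcodes$allele[match(ext$barcode_dna, barcodes$barcode_dna)]
    status <- ext$status
    status[status == "assigned" & is.na(pep)] <- "unknown_peptide"
    status[status == "assigned" & is.na(allele)] <- "unknown_barcode"
    assigned <- status == "assigned"
    counts <- tibble(peptide = pep[assigned], allele = allele[assigned]) |>
      count(.data$peptide, .data$allele, name = "count")
    reasons <- tibble(status = status[!assigned]) |>
      count(.data$status, name = "n") |>
      rename(reason = "status")
    list(
      counts = mutate(counts, bin = bin, replicate = replicate),
      qc = tibble(
        path = path, bin = bin, replicate = replicate,
        n_total = length(seqs), n_assigned = sum(assigned),
        n_discarded = sum(!assigned)
      ),
      reasons = mutate(reasons, path = path, bin = bin, replicate = replicate)
    )
  })
  counts <- bind_rows(purrr::map(per_file, "counts"))
  grid <- tidyr::expand_grid(
    peptide = unique(lib$peptide),
    allele = unique(barcodes$allele),
    bin = factor(unique(files$bin), levels = BIN_LEVELS),
    replicate = unique(files$replicate)
  )
  out <- grid |>
    left_join(
      mutate(counts, bin = factor(.data$bin, levels = BIN_LEVELS)),
      by = c("peptide", "allele", "bin", "replicate")
    ) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    arrange(.data$peptide, .data$allele, .data$bin, .data$replicate)
  structure(
    out,
    qc = bind_rows(purrr::map(per_file, "qc")),
    discard_reasons = bind_rows(purrr::map(per_file, "reasons")),
    class = c("bin_counts", class(out))
  )
}

#' Per-file demultiplexing QC
#'
#' @param counts A `bin_counts` table from [count_reads()].
#' @return A list with elements `files` (totals per file) and `reasons`
#'   (discard-reason tallies).
#' @export
qc_report <- function(counts) {
  list(files = attr(counts, "qc"), reasons = attr(counts, "discard_reasons"))
}

#' Spike-in pool design
#'
#' Two (or more) pools of constructs with known within-pool peptide-allele
#' pairing; any read pairing a peptide from one pool with a barcode from
#' another is a recombination chimera.
#'
#' @param alleles Data frame with columns `pool_id`, `allele`.
#' @param peptides Data frame with columns `pool_id`, `peptide`.
#' @return An object of class `spikein_design`.
#' @export
spikein_design <- function(alleles, peptides) {
  alleles <- as_tibble(alleles)
  peptides <- as_tibble(peptides)
  stopifnot(all(c("pool_id", "allele") %in% names(alleles)),
            all(c("pool_id", "peptide") %in% names(peptides)))
  if (anyDuplicated(alleles$allele)) {
    abort("spike-in pools' allele sets must be disjoint")
  }
  if (anyDuplicated(peptides$peptide)) {
    abort("spike-in pools' peptide sets must be disjoint")
  }
  structure(list(alleles = alleles, peptides = peptides),
            class = "spikein_design")
}

#' Estimate the recombination (chimera) rate from spike-in reads
#'
#' Among reads carrying a spike-in peptide, any read whose allele barcode
#' does not belong to that peptide's own pool is a recombination chimera;
#' the raw rate is the mispaired fraction of spike-in reads. Because a
#' barcode swap that happens to land back inside the construct's own pool
#' is invisible, the raw fraction underestimates the true swap rate by the
#' detectability factor `(n_panel - n_pool) / (n_panel - 1)`; with
#' `correct = TRUE` (default) the estimate divides this factor out,
#' making it unbiased for a uniform-swap chimera model. `correct = FALSE`
#' reports the raw mispaired fraction.
#'
#' @param counts A `bin_counts` table (any long count table with `peptide`,
#'   `allele`, `count` works).
#' @param spikein A [spikein_design()].
#' @param correct Divide out the within-pool detectability factor.
#' @param n_panel_alleles Panel size used for the correction; defaults to
#'   the number of distinct alleles in `counts`.
#' @return An object of class `recombination_estimate`: list with
#'   `chimera_rate`, `raw_rate`, `n_spikein`, `n_cross`, and `per_pool`
#'   tibble (by peptide pool). `tidy()` returns the per-pool table.
#' @export
estimate_recombination <- function(counts, spikein, correct = TRUE,
                                   n_panel_alleles = NULL) {
  stopifnot(inherits(spikein, "spikein_design"))
  counts <- as_tibble(counts)
  if (is.null(n_panel_alleles)) {
    n_panel_alleles <- dplyr::n_distinct(counts$allele)
  }
  x <- counts |>
    inner_join(rename(spikein$peptides, pep_pool = "pool_id"),
               by = "peptide") |>
    left_join(rename(spikein$alleles, bc_pool = "pool_id"), by = "allele")
  total <- sum(x$count)
  if (total == 0) {
    abort("no spike-in reads found; chimera rate undefined")
  }
  x <- mutate(x, cross = is.na(.data$bc_pool) |
                .data$bc_pool != .data$pep_pool)
  pool_sizes <- spikein$alleles |>
    count(.data$pool_id, name = "n_alleles")
  detectability <- function(pool_id) {
    np <- pool_sizes$n_alleles[match(pool_id, pool_sizes$pool_id)]
    (n_panel_alleles - np) / (n_panel_alleles - 1)
  }
  per_pool <- x |>
    group_by(pool_id = .data$pep_pool) |>
    summarise(
      n_total = sum(.data$count),
      n_cross = sum(.data$count[.data$cross]),
      raw_rate = .data$n_cross / .data$n_total,
      .groups = "drop"
    ) |>
    mutate(chimera_rate = dplyr::case_when(
      !correct ~ .data$raw_rate,
      .data$raw_rate == 0 ~ 0,
      TRUE ~ pmin(1, .data$raw_rate / detectability(.data$pool_id))
    ))
  raw <- sum(x$count[x$cross]) / total
  overall_det <- sum(per_pool$n_total * detectability(per_pool$pool_id)) /
    sum(per_pool$n_total)
  structure(
    list(
      chimera_rate = if (!correct || raw == 0) raw
                     else min(1, raw / overall_det),
      raw_rate = raw,
      n_spikein = total,
      n_cross = sum(x$count[x$cross]),
      per_pool = per_pool
    ),
    class = "recombination_estimate"
  )
}

#' @export
print.recombination_estimate <- function(x, ...) {
  cat(sprintf(
    "Recombination estimate: %.4f (%d cross-pool of %d spike-in reads)\n",
    x$chimera_rate, x$n_cross, x$n_spikein
  ))
  invisible(x)
}

#' @rdname estimate_recombination
#' @param x A `recombination_estimate`.
#' @param ... Unused.
#' @export
tidy.recombination_estimate <- function(x, ...) {
  x$per_pool
}
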