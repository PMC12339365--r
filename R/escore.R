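# E-score computation: depth normalization, per-trimer bin fractions,
# bin-weighted score, per-allele mode alignment, binder calls, replicate
# QC, and downstream summaries (motif, capture percentage, quadrants,
# allele sharing).

#' Bin weights for the E-score
#'
#' Weights on the log scale of the sort-bin geometry: background 0, then
#' 2/4/8 for the low/medium/high bins. Must be strictly increasing from
#' background to high.
#'
#' @param bg,low,med,high Numeric weights.
#' @return Named numeric vector of class `escore_weights`.
#' @export
escore_weights <- function(bg = 0, low = 2, med = 4, high = 8) {
  w <- c(bg = bg, low = low, med = med, high = high)
  if (any(diff(w) <= 0)) {
    abort("E-score weights must be strictly increasing from bg to high")
  }
  structure(w, class = c("escore_weights", "numeric"))
}

#' Normalize bin counts to per-trimer fractions
#'
#' Two-step normalization. Step 1 (depth): within each (bin, replicate),
#' every count is divided by the mean count across all trimers
#' (peptide-allele pairs) in that bin -- sequencing-depth correction
#' without a log transform. Step 2 (per trimer): each trimer's four-bin
#' vector is divided by its sum, yielding fractions that sum to one. A
#' trimer with zero reads in all bins has no defined fractions and is
#' flagged missing (NA, never 0: zero would assert confident
#' non-presentation).
#'
#' @param counts Long count table (`peptide`, `allele`, `bin`,
#'   `replicate`, `count`), e.g. from [count_reads()].
#' @return A tibble (`peptide`, `allele`, `replicate`, `bin`, `fraction`,
#'   `missing`).
#' @export
normalize_bins <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("peptide", "allele", "bin", "replicate", "count")
                %in% names(counts)))
  if (any(counts$count < 0)) abort("negative counts")
  counts |>
    group_by(.data$bin, .data$replicate) |>
    # a bin file with no reads at all contributes zero, not 0/0
    mutate(depth_norm = if (mean(.data$count) == 0) 0
           else .data$count / mean(.data$count)) |>
    group_by(.data$peptide, .data$allele, .data$replicate) |>
    mutate(
      missing = sum(.data$count) == 0,
      fraction = if_else(.data$missing, NA_real_,
                         .data$depth_norm / sum(.data$depth_norm))
    ) |>
    ungroup() |>
    select(!c("depth_norm", "count"))
}

#' Bin-weighted E-score from bin fractions
#'
#' The E-score of a trimer is the weighted sum of its four bin fractions;
#' with the default weights it lies in \[0, 8\]: 0 when all mass sits in
#' the background bin, 8 when all mass is in the high bin.
#'
#' @param fractions Output of [normalize_bins()].
#' @param weights An [escore_weights()] vector.
#' @return A tibble (`peptide`, `allele`, `replicate`, `raw_escore`,
#'   `missing`).
#' @export
compute_escore <- function(fractions, weights = escore_weights()) {
  stopifnot(all(c("peptide", "allele", "replicate", "bin", "fraction")
                %in% names(fractions)))
  w <- tibble(bin = names(weights), w = as.numeric(weights))
  fractions |>
    mutate(bin = as.character(.data$bin)) |>
    left_join(w, by = "bin") |>
    group_by(.data$peptide, .data$allele, .data$replicate) |>
    summarise(
      raw_escore = sum(.data$fraction * .data$w),
      missing = any(.data$missing),
      .groups = "drop"
    )
}

#' Count table to E-scores in one call
#'
#' @inheritParams normalize_bins
#' @inheritParams compute_escore
#' @return See [compute_escore()].
#' @export
compute_escores <- function(counts, weights = escore_weights()) {
  compute_escore(normalize_bins(counts), weights)
}

kde_mode <- function(x, below = 4, bw = "nrd0") {
  x <- x[!is.na(x) & x < below]
  if (length(x) < 2 || sd(x) == 0) return(NA_real_)
  d <- density(x, bw = bw)
  d$x[which.max(d$y)]
}

#' Align allele score distributions on their lower-peak modes
#'
#' Per-allele E-score histograms are bimodal with a dominant negative
#' (non-presenting) peak whose location varies with the allele's intrinsic
#' surface efficiency. For each (allele, replicate) the lower-peak mode is
#' estimated by Gaussian kernel density (Silverman bandwidth) on scores
#' below `valley`, and scores are shifted additively so the modes converge
#' on the panel-median mode. Alleles with fewer than `min_n` usable scores
#' keep a zero shift and are flagged.
#'
#' @param escores Score table from [compute_escore()] (column
#'   `raw_escore`).
#' @param min_n Minimum scores below `valley` needed to estimate a mode.
#' @param valley Upper bound of the lower peak (scores above are ignored
#'   during mode estimation).
#' @param bw Kernel bandwidth rule, passed to [stats::density()].
#' @return The input with an added `aligned_escore` column; the per-allele
#'   shifts are attached as attribute `shifts` (a tibble `allele`,
#'   `replicate`, `mode`, `shift`, `flagged`) and retrievable with
#'   [alignment_shifts()] or `tidy()`.
#' @export
align_alleles <- function(escores, min_n = 50, valley = 4, bw = "nrd0") {
  escores <- as_tibble(escores)
  stopifnot("raw_escore" %in% names(escores))
  shifts <- escores |>
    group_by(.data$allele, .data$replicate) |>
    summarise(
      mode = kde_mode(.data$raw_escore, below = valley, bw = bw),
      n_low = sum(!is.na(.data$raw_escore) & .data$raw_escore < valley),
      .groups = "drop"
    ) |>
    mutate(flagged = is.na(.data$mode) | .data$n_low < min_n)
  usable <- shifts$mode[!shifts$flagged]
  reference <- if (length(usable) > 0) median(usable) else NA_real_
  shifts <- shifts |>
    mutate(shift = if_else(.data$flagged, 0, reference - .data$mode))
  if (any(shifts$flagged)) {
    warn(sprintf(
      "no mode estimated for %d allele/replicate group(s); zero shift applied",
      sum(shifts$flagged)
    ))
  }
  out <- escores |>
    left_join(select(shifts, "allele", "replicate", "shift"),
              by = c("allele", "replicate")) |>
    mutate(aligned_escore = .data$raw_escore + .data$shift) |>
    select(!c("shift"))
  structure(out,
            shifts = select(shifts, "allele", "replicate", "mode",
                            "shift", "flagged"),
            reference_mode = reference,
            class = c("aligned_escores", class(out)))
}

#' @rdname align_alleles
#' @param x An aligned score table.
#' @export
alignment_shifts <- function(x) {
  attr(x, "shifts")
}

#' @rdname align_alleles
#' @param ... Unused.
#' @export
tidy.aligned_escores <- function(x, ...) {
  attr(x, "shifts")
}

#' Average replicate E-scores after QC
#'
#' Mean of per-replicate scores (aligned when present) per (peptide,
#' allele). Alignment, when used, happens per replicate before averaging.
#'
#' @param escores Score table with `raw_escore` and optionally
#'   `aligned_escore`.
#' @return A tibble (`peptide`, `allele`, `mean_escore`, `n_replicates`).
#' @export
aggregate_replicates <- function(escores) {
  col <- if ("aligned_escore" %in% names(escores)) "aligned_escore"
         else "raw_escore"
  as_tibble(escores) |>
    group_by(.data$peptide, .data$allele) |>
    summarise(
      mean_escore = mean(.data[[col]], na.rm = TRUE),
      n_replicates = sum(!is.na(.data[[col]])),
      .groups = "drop"
    ) |>
    mutate(mean_escore = if_else(is.nan(.data$mean_escore), NA_real_,
                                 .data$mean_escore))
}

#' Default binder-call threshold per screening mode
#'
#' 3.2 for single-allele screens; 3.8 for combinatorial screens (raised
#' for the higher noise of multi-allele pools). A cutoff between 3.5 and 4
#' is considered reasonable for combinatorial data.
#'
#' @param mode `"single"` or `"combinatorial"`.
#' @return A single number.
#' @export
default_threshold <- function(mode = c("single", "combinatorial")) {
  switch(match.arg(mode), single = 3.2, combinatorial = 3.8)
}

#' Call binders by E-score threshold
#'
#' A trimer is a binder when its score is strictly greater than the
#' threshold. The score column used is, in order of preference,
#' `mean_escore`, `aligned_escore`, `raw_escore`, unless `score_col` is
#' given. Missing scores yield NA calls.
#'
#' @param escores Score table.
#' @param mode Screening mode; sets the default threshold (3.2 single,
#'   3.8 combinatorial).
#' @param threshold Override; in combinatorial mode values outside the
#'   3.5-4 guidance band trigger a warning.
#' @param score_col Name of the score column to threshold.
#' @return The input with added `binder` (logical) column; the threshold
#'   used is stored in attribute `threshold`.
#' @export
call_binders <- function(escores, mode = c("single", "combinatorial"),
                         threshold = NULL, score_col = NULL) {
  mode <- match.arg(mode)
  escores <- as_tibble(escores)
  if (is.null(threshold)) {
    threshold <- default_threshold(mode)
  } else if (mode == "combinatorial" && (threshold < 3.5 || threshold > 4)) {
    warn(sprintf(
      "combinatorial threshold %.2f outside the 3.5-4 guidance band",
      threshold
    ))
  }
  if (is.null(score_col)) {
    score_col <- intersect(c("mean_escore", "aligned_escore", "raw_escore"),
                           names(escores))[1]
    if (is.na(score_col)) abort("no score column found")
  }
  out <- mutate(escores, binder = .data[[score_col]] > threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Pairwise replicate correlation per allele
#'
#' Pearson correlation of raw E-scores between every pair of replicates
#' within each allele, on trimers scored in both. Screens are expected to
#' pass at r > `min_r` (default 0.9); a constant score vector has no
#' defined correlation and fails with a reason.
#'
#' @param escores Per-replicate score table (column `raw_escore`).
#' @param min_r Pass threshold.
#' @return A tibble (`allele`, `rep_a`, `rep_b`, `n`, `pearson_r`, `pass`,
#'   `reason`).
#' @export
replicate_qc <- function(escores, min_r = 0.9) {
  escores <- as_tibble(escores)
  reps <- sort(unique(escores$replicate))
  if (length(reps) < 2) abort("replicate_qc() needs >= 2 replicates")
  pairs <- utils::combn(as.character(reps), 2, simplify = FALSE)
  purrr::map_dfr(unique(escores$allele), function(al) {
    sub <- filter(escores, .data$allele == al)
    wide <- tidyr::pivot_wider(
      select(sub, "peptide", "replicate", "raw_escore"),
      names_from = "replicate", values_from = "raw_escore"
    )
    purrr::map_dfr(pairs, function(p) {
      x <- wide[[p[1]]]
      y <- wide[[p[2]]]
      ok <- !is.na(x) & !is.na(y)
      r <- if (sum(ok) < 3) NA_real_
           else if (sd(x[ok]) == 0 || sd(y[ok]) == 0) NA_real_
           else cor(x[ok], y[ok])
      tibble(
        allele = al, rep_a = p[1], rep_b = p[2], n = sum(ok),
        pearson_r = r,
        pass = !is.na(r) & r > min_r,
        reason = case_when(
          sum(ok) < 3 ~ "too_few_pairs",
          is.na(r) ~ "constant_scores",
          r > min_r ~ NA_character_,
          TRUE ~ "low_correlation"
        )
      )
    })
  })
}

#' Position-frequency matrix of a peptide set
#'
#' Residue frequencies per position (20 x k matrix, columns summing to 1),
#' e.g. the binding motif of the screen-positive peptides of one allele.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param pseudocount Added to every cell before normalization.
#' @return A 20 x k numeric matrix of class `pfm` (rows: residues,
#'   columns: positions).
#' @export
build_motif <- function(peptides, pseudocount = 0) {
  assert_protein_sequence(peptides, "peptides")
  k <- unique(nchar(peptides))
  if (length(k) != 1) abort("motif peptides must all have the same length")
  mat <- matrix(pseudocount, nrow = 20, ncol = k,
                dimnames = list(AA_ALPHABET_20, seq_len(k)))
  chars <- do.call(rbind, strsplit(peptides, "", fixed = TRUE))
  for (j in seq_len(k)) {
    tab <- table(factor(chars[, j], levels = AA_ALPHABET_20))
    mat[, j] <- mat[, j] + as.numeric(tab)
  }
  mat <- sweep(mat, 2, colSums(mat), "/")
  structure(mat, class = c("pfm", "matrix"))
}

#' Capture percentage against an external hit set
#'
#' Per allele, the fraction of externally detected (e.g. MS-eluted)
#' (peptide, allele) pairs that the screen also calls positive. An allele
#' with no external hits has no defined capture and is flagged.
#'
#' @param calls Binder calls from [call_binders()].
#' @param hits Data frame of detected pairs (`peptide`, `allele`).
#' @return A tibble (`allele`, `n_hits`, `n_captured`, `capture`,
#'   `flagged`).
#' @export
capture_percentage <- function(calls, hits) {
  hits <- distinct(as_tibble(hits), .data$peptide, .data$allele)
  calls <- as_tibble(calls)
  per <- hits |>
    left_join(select(calls, "peptide", "allele", "binder"),
              by = c("peptide", "allele")) |>
    group_by(.data$allele) |>
    summarise(
      n_hits = n(),
      n_captured = sum(.data$binder %in% TRUE),
      .groups = "drop"
    ) |>
    mutate(capture = .data$n_captured / .data$n_hits, flagged = FALSE)
  # alleles present in calls but absent from hits: undefined capture
  extra <- setdiff(unique(calls$allele), per$allele)
  if (length(extra) > 0) {
    per <- bind_rows(per, tibble(
      allele = extra, n_hits = 0L, n_captured = 0L,
      capture = NA_real_, flagged = TRUE
    ))
  }
  arrange(per, .data$allele)
}

#' Pair mutant and wild-type scores via library provenance
#'
#' Joins a score table with the `pair_id`/`mut_wt` provenance emitted by
#' [design_variant_library()], yielding one row per mutant/wild-type
#' window pair and allele. Pairs missing either member are dropped with a
#' warning.
#'
#' @param escores Score table (per peptide, allele; e.g. from
#'   [aggregate_replicates()]).
#' @param library Library tibble with `peptide`, `variant_tag`, `mut_wt`,
#'   `pair_id`.
#' @param score_col Score column name (auto-detected as in
#'   [call_binders()]).
#' @return A tibble (`pair_id`, `variant_tag`, `allele`, `mut_peptide`,
#'   `wt_peptide`, `mut_escore`, `wt_escore`).
#' @export
pair_mut_wt <- function(escores, library, score_col = NULL) {
  escores <- as_tibble(escores)
  library <- as_tibble(library)
  if (is.null(score_col)) {
    score_col <- intersect(c("mean_escore", "aligned_escore", "raw_escore"),
                           names(escores))[1]
  }
  lib <- library |>
    filter(!is.na(.data$pair_id)) |>
    distinct(.data$pair_id, .data$variant_tag, .data$mut_wt, .data$peptide)
  scored <- lib |>
    inner_join(select(escores, "peptide", "allele",
                      score = dplyr::all_of(score_col)),
               by = "peptide")
  wide <- scored |>
    tidyr::pivot_wider(
      id_cols = c("pair_id", "variant_tag", "allele"),
      names_from = "mut_wt", values_from = c("peptide", "score")
    )
  need <- c("peptide_mut", "peptide_wt", "score_mut", "score_wt")
  missing_cols <- setdiff(need, names(wide))
  for (m in missing_cols) wide[[m]] <- NA
  incomplete <- is.na(wide$score_mut) | is.na(wide$score_wt)
  if (any(incomplete)) {
    warn(sprintf("%d unpaired mutant/wild-type combinations excluded",
                 sum(incomplete)))
  }
  wide |>
    filter(!incomplete) |>
    select(
      "pair_id", "variant_tag", "allele",
      mut_peptide = "peptide_mut", wt_peptide = "peptide_wt",
      mut_escore = "score_mut", wt_escore = "score_wt"
    )
}

QUADRANT_LEVELS <- c("WT-Mut-", "WT+Mut+", "WT+only", "Mut+only")

#' Classify mutant/wild-type score pairs into presentation quadrants
#'
#' A pair falls into one of four classes against a common threshold:
#' neither presented, both presented, wild-type only (mutation enables
#' immune escape), or mutant only (mutation confers novel binding -- the
#' prime neoantigen candidates, since no tolerance exists against a
#' non-presented wild-type).
#'
#' @param pairs Output of [pair_mut_wt()] (columns `mut_escore`,
#'   `wt_escore`).
#' @param threshold E-score threshold (strict `>`); default the
#'   combinatorial cutoff.
#' @return The input with an added `class` factor column.
#' @export
quadrant_classify <- function(pairs, threshold = default_threshold("combinatorial")) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("mut_escore", "wt_escore") %in% names(pairs)))
  mutate(pairs, class = factor(case_when(
    .data$mut_escore > threshold & .data$wt_escore > threshold ~ "WT+Mut+",
    .data$mut_escore > threshold ~ "Mut+only",
    .data$wt_escore > threshold ~ "WT+only",
    TRUE ~ "WT-Mut-"
  ), levels = QUADRANT_LEVELS))
}

#' Per-allele quadrant percentages
#'
#' @param quadrants Output of [quadrant_classify()].
#' @return A tibble (`allele`, `class`, `n`, `percent`).
#' @export
quadrant_summary <- function(quadrants) {
  as_tibble(quadrants) |>
    group_by(.data$allele, .data$class, .drop = FALSE) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' How many alleles present each peptide
#'
#' @param calls Binder calls (per peptide, allele; column `binder`).
#' @return A tibble (`peptide`, `n_alleles`): the number of alleles
#'   calling the peptide a binder (0 for peptides presented by none).
#' @export
allele_sharing <- function(calls) {
  as_tibble(calls) |>
    group_by(.data$peptide) |>
    summarise(n_alleles = sum(.data$binder %in% TRUE), .groups = "drop")
}

#' Presented tiling peptides per (mutation, allele)
#'
#' For every variant and allele, the number of its tiling windows called
#' positive, out of the number designed (e.g. "out of nine" for a 9-mer
#' scan of a point mutation).
#'
#' @param calls Binder calls (per peptide, allele).
#' @param library Library tibble with `peptide` and `variant_tag`
#'   (wild-type windows, `mut_wt == "wt"`, are excluded when the column is
#'   present).
#' @return A tibble (`variant_tag`, `allele`, `n_windows`, `n_presented`).
#' @export
mutation_presentation <- function(calls, library) {
  library <- as_tibble(library)
  if ("mut_wt" %in% names(library)) {
    library <- filter(library, .data$mut_wt != "wt")
  }
  lib <- distinct(library, .data$variant_tag, .data$peptide)
  lib |>
    inner_join(select(as_tibble(calls), "peptide", "allele", "binder"),
               by = "peptide") |>
    group_by(.data$variant_tag, .data$allele) |>
    summarise(
      n_windows = n(),
      n_presented = sum(.data$binder %in% TRUE),
      .groups = "drop"
    )
}
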