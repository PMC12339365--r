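# Population coverage: probability that a random diploid individual (two
# alleles at each of HLA-A, -B, -C, drawn independently from population
# frequencies under Hardy-Weinberg) carries at least one allele that
# presents a given mutation.

as_freq_tbl <- function(freqs) {
  freqs <- as_tibble(freqs)
  stopifnot(all(c("locus", "allele", "frequency") %in% names(freqs)))
  if (nrow(freqs) == 0) abort("empty allele frequency table")
  if (any(freqs$frequency < 0 | freqs$frequency > 1)) {
    abort("frequencies must lie in [0, 1]")
  }
  tot <- freqs |> group_by(.data$locus) |>
    summarise(s = sum(.data$frequency), .groups = "drop")
  if (any(tot$s > 1 + 1e-8)) {
    abort("frequencies at a locus must sum to <= 1 (residual = unpanelled)")
  }
  freqs
}

as_presenting_list <- function(presenting) {
  if (is.character(presenting)) presenting <- list(mutation = presenting)
  if (!is.list(presenting)) abort("presenting must be a character vector or named list")
  presenting
}

#' Closed-form population coverage under Hardy-Weinberg
#'
#' With p_L the summed frequency of presenting alleles at locus L, the
#' chance that neither of an individual's two locus-L alleles presents is
#' (1 - p_L)^2; coverage = 1 - prod over loci of (1 - p_L)^2. Frequency
#' mass not in the table ("other" alleles) never presents -- a
#' conservative convention.
#'
#' @param presenting Character vector of presenting alleles, or a named
#'   list of such vectors (one per mutation).
#' @param freqs Allele frequency table (`locus`, `allele`, `frequency`).
#' @return A tibble (`mutation_id`, `coverage`, `n_presenting`).
#' @export
#' @examples
#' freqs <- data.frame(locus = "A", allele = "A*02:01", frequency = 0.5)
#' analytic_coverage("A*02:01", freqs)  # 1 - 0.5^2 = 0.75
analytic_coverage <- function(presenting, freqs) {
  freqs <- as_freq_tbl(freqs)
  presenting <- as_presenting_list(presenting)
  purrr::imap_dfr(presenting, function(alleles, id) {
    p_locus <- freqs |>
      group_by(.data$locus) |>
      summarise(p = sum(.data$frequency[.data$allele %in% alleles]),
                .groups = "drop")
    tibble(
      mutation_id = id,
      coverage = 1 - prod((1 - p_locus$p)^2),
      n_presenting = sum(unique(alleles) %in% freqs$allele)
    )
  })
}

sample_genotypes <- function(freqs, n_individuals) {
  # 6 allele draws per individual: 2 per locus, independent (HWE);
  # residual frequency mass becomes the never-presenting "<other>"
  loci <- unique(freqs$locus)
  out <- lapply(loci, function(l) {
    f <- freqs[freqs$locus == l, ]
    probs <- c(f$frequency, max(0, 1 - sum(f$frequency)))
    alleles <- c(f$allele, "<other>")
    matrix(sample(alleles, 2 * n_individuals, replace = TRUE, prob = probs),
           ncol = 2)
  })
  do.call(cbind, out)
}

#' Monte-Carlo population coverage
#'
#' Simulates `n_individuals` diploid genotypes (two independent draws per
#' locus under Hardy-Weinberg) and reports, per mutation, the fraction of
#' individuals carrying at least one presenting allele among their six.
#' Agrees with [analytic_coverage()] within Monte-Carlo error.
#'
#' @inheritParams analytic_coverage
#' @param n_individuals Number of simulated individuals.
#' @param seed Optional integer seed.
#' @return A tibble (`mutation_id`, `coverage`, `mc_stderr`,
#'   `n_presenting`).
#' @export
sample_coverage <- function(presenting, freqs, n_individuals = 100000,
                            seed = NULL) {
  freqs <- as_freq_tbl(freqs)
  presenting <- as_presenting_list(presenting)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  geno <- sample_genotypes(freqs, n_individuals)
  purrr::imap_dfr(presenting, function(alleles, id) {
    covered <- matrix(geno %in% alleles, nrow = nrow(geno))
    p <- mean(rowSums(covered) > 0)
    tibble(
      mutation_id = id,
      coverage = p,
      mc_stderr = sqrt(p * (1 - p) / n_individuals),
      n_presenting = sum(unique(alleles) %in% freqs$allele)
    )
  })
}

#' Population-coverage distribution across mutations
#'
#' Derives each mutation's presenting allele set from binder calls (an
#' allele presents a mutation when it presents at least one of its tiling
#' peptides), computes analytic and Monte-Carlo coverage per mutation on a
#' shared simulated individual panel, and summarises the distribution.
#'
#' @param calls Binder calls (`peptide`, `allele`, `binder`).
#' @param library Library with `peptide` and `variant_tag` provenance
#'   (wild-type rows excluded as in [mutation_presentation()]).
#' @param freqs Allele frequency table.
#' @param n_individuals,seed Monte-Carlo settings.
#' @return A list of class `coverage_distribution`: `per_mutation` tibble
#'   (`mutation_id`, `coverage`, `mc_stderr`, `analytic`,
#'   `n_presenting`), and `summary` (fraction of mutations with coverage
#'   > 0, mean and median coverage).
#' @export
coverage_distribution <- function(calls, library, freqs,
                                  n_individuals = 100000, seed = NULL) {
  pres <- mutation_presentation(calls, library) |>
    filter(.data$n_presented > 0)
  muts <- unique(as_tibble(library)$variant_tag)
  muts <- muts[muts != "WT" & !is.na(muts)]
  sets <- lapply(setNames(muts, muts), function(m) {
    pres$allele[pres$variant_tag == m]
  })
  mc <- sample_coverage(sets, freqs, n_individuals = n_individuals,
                        seed = seed)
  an <- analytic_coverage(sets, freqs)
  per <- left_join(mc, select(an, "mutation_id", analytic = "coverage"),
                   by = "mutation_id")
  structure(list(
    per_mutation = per,
    summary = tibble(
      n_mutations = nrow(per),
      frac_covered = mean(per$coverage > 0),
      mean_coverage = mean(per$coverage),
      median_coverage = median(per$coverage)
    )
  ), class = "coverage_distribution")
}

#' @export
print.coverage_distribution <- function(x, ...) {
  cat(sprintf(
    "Coverage over %d mutations: %.1f%% reach any individual; mean %.3f, median %.3f\n",
    x$summary$n_mutations, 100 * x$summary$frac_covered,
    x$summary$mean_coverage, x$summary$median_coverage
  ))
  invisible(x)
}

#' @rdname coverage_distribution
#' @param x A `coverage_distribution` object.
#' @param ... Unused.
#' @export
tidy.coverage_distribution <- function(x, ...) {
  x$per_mutation
}

#' @rdname coverage_distribution
#' @export
glance.coverage_distribution <- function(x, ...) {
  x$summary
}

#' Synthetic allele frequency table for a panel
#'
#' Dirichlet-style frequencies for the panel alleles at each locus with a
#' configurable share of residual (unpanelled, never-presenting) mass.
#' A stand-in for real population frequency tables, used by the simulator
#' and examples.
#'
#' @param panel Data frame (`allele`, `locus`), e.g. [hla_panel_50()].
#' @param residual Fraction of frequency mass left to unpanelled alleles.
#' @param seed Integer seed.
#' @return A frequency tibble (`locus`, `allele`, `frequency`).
#' @export
synthetic_allele_frequencies <- function(panel, residual = 0.1, seed = 1) {
  panel <- as_tibble(panel)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  panel |>
    group_by(.data$locus) |>
    mutate(frequency = {
      w <- stats::rgamma(n(), shape = 2)
      (1 - residual) * w / sum(w)
    }) |>
    ungroup() |>
    select("locus", "allele", "frequency")
}
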