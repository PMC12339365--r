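# Generative model of the sort-seq screen: per-construct presentation
# strength theta maps to a log-normal fluorescence distribution, cells are
# gated into four log-spaced bins, reads are drawn multinomially per bin,
# and barcode recombination is injected at a configurable rate. Emits
# standard FASTQ plus full ground truth, so every pipeline stage is
# testable without external data.

#' Generative parameters of the simulated sorter
#'
#' Defaults mirror the screen geometry: negative (background) peak
#' centered at 100 fluorescence a.u., low/medium/high bins centered at
#' 400/1600/6400, gates at the geometric midpoints (200/800/3200) --
#' "evenly divided bins on log scale". A construct's presentation
#' strength theta in \[0, 1\] maps to its mean log-fluorescence by linear
#' interpolation between the background and high centers (a logistic link
#' is available); log10 fluorescence noise is Gaussian with `sigma`.
#'
#' @param peak_bg,peak_high Fluorescence centers of the background peak
#'   and the strongest-presentation peak (a.u.).
#' @param gates Three increasing gate boundaries (a.u.).
#' @param sigma Standard deviation of log10 fluorescence.
#' @param cells_per_construct Sorted cells per construct per replicate.
#' @param reads_per_bin Sequencing reads per (bin, replicate) file.
#' @param recombination_rate Probability a read's barcode is swapped to a
#'   random other allele (library-PCR chimera model: pairing breaks, the
#'   peptide read stays).
#' @param anchor_error_rate Fraction of reads with a corrupted anchor
#'   (they fail exact matching and are discarded downstream).
#' @param prop_binders Prior fraction of (peptide, allele) constructs that
#'   truly present.
#' @param link `"linear"` or `"logistic"` theta-to-fluorescence link.
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A validated list of class `sorter_model`.
#' @export
sorter_model <- function(peak_bg = 100, peak_high = 6400,
                         gates = c(200, 800, 3200), sigma = 0.12,
                         cells_per_construct = 1000, reads_per_bin = 100000,
                         recombination_rate = 0, anchor_error_rate = 0,
                         prop_binders = 0.1, link = c("linear", "logistic"),
                         seed = 1) {
  link <- match.arg(link)
  if (length(gates) != 3 || any(diff(gates) <= 0)) {
    abort("gates must be three strictly increasing boundaries")
  }
  if (gates[1] <= peak_bg || gates[3] >= peak_high * 10) {
    warn("gates lie outside the usual peak geometry")
  }
  stopifnot(sigma > 0, cells_per_construct >= 1, reads_per_bin >= 0,
            recombination_rate >= 0, recombination_rate <= 1,
            anchor_error_rate >= 0, anchor_error_rate < 1,
            prop_binders >= 0, prop_binders <= 1)
  structure(list(
    peak_bg = peak_bg, peak_high = peak_high, gates = gates, sigma = sigma,
    cells_per_construct = as.integer(cells_per_construct),
    reads_per_bin = as.integer(reads_per_bin),
    recombination_rate = recombination_rate,
    anchor_error_rate = anchor_error_rate,
    prop_binders = prop_binders, link = link, seed = as.integer(seed)
  ), class = "sorter_model")
}

theta_to_mu <- function(theta, model) {
  lo <- log10(model$peak_bg)
  hi <- log10(model$peak_high)
  switch(model$link,
    linear = lo + theta * (hi - lo),
    logistic = lo + (hi - lo) / (1 + exp(-8 * (theta - 0.5)))
  )
}

bin_probabilities <- function(theta, model) {
  # P(cell of strength theta lands in each log-spaced bin)
  mu <- theta_to_mu(theta, model)
  g <- log10(model$gates)
  p1 <- pnorm(g[1], mu, model$sigma)
  p2 <- pnorm(g[2], mu, model$sigma)
  p3 <- pnorm(g[3], mu, model$sigma)
  cbind(bg = p1, low = p2 - p1, med = p3 - p2, high = 1 - p3)
}

#' Check that anchors are unique within every assembled construct
#'
#' A construct read is `flank5 + oligo + flank3 + barcode_flank5 + barcode
#' + barcode_flank3`; demultiplexing requires each of the four anchors to
#' occur exactly once. Returns the offending combinations (zero rows when
#' the design is clean).
#'
#' @param library Encoded library ([encode_oligo()]).
#' @param barcodes Barcode panel ([design_barcodes()]).
#' @param anchors An [anchor_spec()].
#' @return A tibble (`peptide`, `allele`) of ambiguous constructs.
#' @export
validate_constructs <- function(library, barcodes, anchors = anchor_spec()) {
  lib <- distinct(as_tibble(library), .data$peptide, .data$oligo)
  combos <- tidyr::expand_grid(i = seq_len(nrow(lib)),
                               j = seq_len(nrow(barcodes)))
  reads <- assemble_reads(lib$oligo[combos$i],
                          barcodes$barcode_dna[combos$j], anchors)
  bad <- rep(FALSE, length(reads))
  for (a in unlist(anchors)) {
    bad <- bad | stringr::str_count(reads, stringr::fixed(a)) != 1L
  }
  tibble(peptide = lib$peptide[combos$i[bad]],
         allele = barcodes$allele[combos$j[bad]]) |> distinct()
}

assemble_reads <- function(oligos, barcode_dna, anchors) {
  paste0(anchors$peptide_flank5, oligos, anchors$peptide_flank3,
         anchors$barcode_flank5, barcode_dna, anchors$barcode_flank3)
}

write_fastq <- function(seqs, path, id_prefix = "r") {
  if (length(seqs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  rec <- paste0(
    "@", id_prefix, seq_along(seqs), "\n", seqs, "\n+\n",
    strrep("I", nchar(seqs))
  )
  writeLines(rec, path)
  invisible(path)
}

#' Simulate a full sort-seq screen to FASTQ with ground truth
#'
#' Per (peptide, allele) construct a presentation strength theta is drawn
#' (`prop_binders` of constructs are true binders); per replicate,
#' `cells_per_construct` cells are multinomially distributed over the four
#' bins according to the log-normal fluorescence model, and
#' `reads_per_bin` reads per bin are drawn multinomially over constructs
#' proportional to their cell counts. Recombination swaps a read's
#' barcode to a uniformly random other allele with probability
#' `recombination_rate`; `anchor_error_rate` corrupts the first anchor
#' base so the read fails exact matching. One FASTQ per (bin, replicate)
#' is written.
#'
#' @param library Encoded library ([encode_oligo()]).
#' @param barcodes Barcode panel ([design_barcodes()]).
#' @param model A [sorter_model()].
#' @param replicates Number of biological replicates.
#' @param dir Output directory for FASTQ files (created).
#' @param anchors An [anchor_spec()]; must be unique within every
#'   construct ([validate_constructs()]).
#' @param pairing Optional tibble (`peptide`, `allele`) restricting the
#'   true constructs to these pairs (e.g. within-pool spike-in pairing);
#'   default is the full library x panel grid.
#' @return A list of class `screen_sim`: `files` (tibble `path`, `bin`,
#'   `replicate`), `truth` (list with `constructs` = per-construct theta
#'   and binder label, `read_counts` = emitted reads per (peptide,
#'   emitted allele, bin, replicate) with a `chimera` flag,
#'   `cell_counts`), plus `library`, `barcodes`, `anchors`, `model`.
#' @export
simulate_screen <- function(library, barcodes, model = sorter_model(),
                            replicates = 2, dir = tempfile("screen_"),
                            anchors = anchor_spec(), pairing = NULL) {
  library <- as_tibble(library)
  barcodes <- as_tibble(barcodes)
  if (model$reads_per_bin == 0) abort("zero-depth request")
  offenders <- validate_constructs(library, barcodes, anchors)
  if (nrow(offenders) > 0) {
    abort(sprintf(
      "%d construct(s) contain an anchor more than once (first: %s / %s); redesign anchors or peptides",
      nrow(offenders), offenders$peptide[1], offenders$allele[1]
    ))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(model$seed)

  lib <- distinct(library, .data$peptide, .data$oligo)
  constructs <- if (is.null(pairing)) {
    tidyr::expand_grid(peptide = lib$peptide, allele = barcodes$allele)
  } else {
    distinct(as_tibble(pairing), .data$peptide, .data$allele)
  }
  constructs <- constructs |>
    left_join(lib, by = "peptide") |>
    left_join(select(barcodes, "allele", "barcode_dna"), by = "allele")
  if (any(is.na(constructs$oligo)) || any(is.na(constructs$barcode_dna))) {
    abort("pairing refers to peptides/alleles outside library or panel")
  }
  nC <- nrow(constructs)
  binder <- runif(nC) < model$prop_binders
  theta <- if_else(binder, runif(nC, 0.45, 1), rbeta(nC, 1.2, 25))
  constructs$theta <- theta
  constructs$binder <- binder
  pbin <- bin_probabilities(theta, model)

  files <- list()
  read_counts <- list()
  cell_counts <- list()
  alleles <- barcodes$allele
  for (r in seq_len(replicates)) {
    rep_id <- sprintf("R%d", r)
    cells <- apply(pbin, 1, function(p) {
      rmultinom(1, model$cells_per_construct, p)
    })  # 4 x nC
    cell_counts[[rep_id]] <- tibble(
      peptide = rep(constructs$peptide, each = 4),
      allele = rep(constructs$allele, each = 4),
      bin = rep(BIN_LEVELS, nC),
      replicate = rep_id,
      n_cells = as.integer(cells)
    )
    for (b in seq_along(BIN_LEVELS)) {
      bin <- BIN_LEVELS[b]
      w <- cells[b, ]
      nreads <- if (sum(w) == 0) integer(nC)
                else as.integer(rmultinom(1, model$reads_per_bin, w))
      # recombination: per construct, some reads swap barcode
      n_chim <- rbinom(nC, nreads, model$recombination_rate)
      n_keep <- nreads - n_chim
      emitted <- tibble(
        peptide = constructs$peptide, allele = constructs$allele,
        oligo = constructs$oligo, barcode_dna = constructs$barcode_dna,
        count = n_keep, chimera = FALSE
      )
      chim_rows <- which(n_chim > 0)
      if (length(chim_rows) > 0 && length(alleles) > 1) {
        chim <- purrr::map_dfr(chim_rows, function(i) {
          others <- setdiff(alleles, constructs$allele[i])
          tgt <- table(sample(others, n_chim[i], replace = TRUE))
          tibble(
            peptide = constructs$peptide[i],
            allele = names(tgt),
            oligo = constructs$oligo[i],
            barcode_dna = barcodes$barcode_dna[match(names(tgt), alleles)],
            count = as.integer(tgt), chimera = TRUE
          )
        })
        emitted <- bind_rows(emitted, chim)
      }
      emitted <- filter(emitted, .data$count > 0)
      seqs <- rep(
        assemble_reads(emitted$oligo, emitted$barcode_dna, anchors),
        emitted$count
      )
      if (model$anchor_error_rate > 0 && length(seqs) > 0) {
        hit <- runif(length(seqs)) < model$anchor_error_rate
        if (any(hit)) {
          first <- substr(seqs[hit], 1, 1)
          swap <- vapply(first, function(x) {
            sample(setdiff(c("A", "C", "G", "T"), x), 1)
          }, character(1))
          substr(seqs[hit], 1, 1) <- swap
        }
      }
      if (length(seqs) > 0) seqs <- sample(seqs)  # shuffle read order
      path <- file.path(dir, sprintf("%s_%s.fastq", bin, rep_id))
      write_fastq(seqs, path, id_prefix = sprintf("%s_%s_", bin, rep_id))
      files[[length(files) + 1]] <- tibble(path = path, bin = bin,
                                           replicate = rep_id)
      read_counts[[length(read_counts) + 1]] <- emitted |>
        mutate(bin = bin, replicate = rep_id) |>
        select("peptide", "allele", "bin", "replicate", "count", "chimera")
    }
  }
  structure(list(
    files = bind_rows(files),
    truth = list(
      constructs = select(constructs, "peptide", "allele", "theta", "binder"),
      read_counts = bind_rows(read_counts),
      cell_counts = bind_rows(cell_counts)
    ),
    library = library, barcodes = barcodes, anchors = anchors, model = model
  ), class = "screen_sim")
}

#' Exact count table implied by the simulation ground truth
#'
#' The counts a perfect demultiplexer must recover: emitted reads per
#' (peptide, emitted allele, bin, replicate), chimeras included (they
#' carry a valid barcode of the wrong allele and are indistinguishable at
#' the read level), on the complete library x panel grid. With
#' `anchor_error_rate = 0`, [count_reads()] on the simulated FASTQ
#' reproduces this table exactly.
#'
#' @param sim A `screen_sim` from [simulate_screen()].
#' @return A `bin_counts`-shaped tibble (`peptide`, `allele`, `bin`,
#'   `replicate`, `count`).
#' @export
truth_count_table <- function(sim) {
  stopifnot(inherits(sim, "screen_sim"))
  rc <- sim$truth$read_counts |>
    group_by(.data$peptide, .data$allele, .data$bin, .data$replicate) |>
    summarise(count = sum(.data$count), .groups = "drop")
  grid <- tidyr::expand_grid(
    peptide = unique(sim$library$peptide),
    allele = unique(sim$barcodes$allele),
    bin = factor(BIN_LEVELS, levels = BIN_LEVELS),
    replicate = unique(sim$files$replicate)
  )
  grid |>
    left_join(mutate(rc, bin = factor(.data$bin, levels = BIN_LEVELS)),
              by = c("peptide", "allele", "bin", "replicate")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    arrange(.data$peptide, .data$allele, .data$bin, .data$replicate)
}

#' Random canonical peptides
#'
#' @param n Number of peptides.
#' @param k Peptide length.
#' @param seed Integer seed.
#' @return Character vector of `n` distinct peptides.
#' @export
random_peptides <- function(n, k = 9, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out) + 10), function(i) {
      paste(sample(AA_ALPHABET_20, k, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Anchor-clean random peptide library
#'
#' Random peptides, reverse-translated, with any peptide whose assembled
#' construct would contain a demultiplexing anchor more than once
#' regenerated ([validate_constructs()]); the returned library is safe to
#' simulate and demultiplex against the given barcode panel.
#'
#' @param n_peptides Library size.
#' @param k Peptide length.
#' @param barcodes Barcode panel the library will be paired with.
#' @param anchors An [anchor_spec()].
#' @param seed Integer seed.
#' @return An encoded library tibble (see [encode_oligo()]).
#' @export
random_library <- function(n_peptides, k = 9, barcodes,
                           anchors = anchor_spec(), seed = 1) {
  lib <- encode_oligo(tibble(peptide = random_peptides(n_peptides, k, seed)))
  tries <- 0L
  repeat {
    bad <- validate_constructs(lib, barcodes, anchors)
    if (nrow(bad) == 0 || tries > 20L) break
    tries <- tries + 1L
    keep <- setdiff(lib$peptide, bad$peptide)
    extra <- random_peptides(n_peptides - length(keep) + 5L, k = k,
                             seed = seed + 1000L * tries)
    pool <- unique(c(keep, setdiff(extra, keep)))[seq_len(n_peptides)]
    lib <- encode_oligo(tibble(peptide = pool))
  }
  if (nrow(validate_constructs(lib, barcodes, anchors)) > 0) {
    abort("could not build an anchor-clean library; change anchors or seed")
  }
  lib
}

#' Bundled synthetic screen fixtures
#'
#' Self-contained simulated datasets used by the test suite and examples:
#' `tiny` is 20 peptides x 3 alleles at shallow depth (fast, fully
#' deterministic for a fixed seed); `small` is 200 peptides x 10 alleles
#' at default depth. Peptides that would collide with an anchor (so the
#' construct is ambiguous) are regenerated before simulation.
#'
#' @param scale `"tiny"` or `"small"`.
#' @param dir Output directory for the FASTQ files.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sorter_model()].
#' @return A `screen_sim` (see [simulate_screen()]).
#' @export
make_fixture <- function(scale = c("tiny", "small"),
                         dir = tempfile("fixture_"), seed = 42, ...) {
  scale <- match.arg(scale)
  n_pep <- switch(scale, tiny = 20L, small = 200L)
  n_allele <- switch(scale, tiny = 3L, small = 10L)
  model_args <- switch(scale,
    tiny = list(cells_per_construct = 500, reads_per_bin = 5000, seed = seed),
    small = list(cells_per_construct = 1000, reads_per_bin = 100000,
                 seed = seed)
  )
  model_args <- utils::modifyList(model_args, list(...))
  model <- do.call(sorter_model, model_args)
  anchors <- anchor_spec()
  barcodes <- design_barcodes(sprintf("HLA_%02d", seq_len(n_allele)),
                              seed = seed)
  lib <- random_library(n_pep, k = 9, barcodes = barcodes,
                        anchors = anchors, seed = seed)
  simulate_screen(lib, barcodes, model, replicates = 2, dir = dir,
                  anchors = anchors)
}
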