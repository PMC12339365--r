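# Library design: tiling windows, variant application, junction-spanning
# windows, reverse translation with restriction-site screening, and
# synonymous-codon allele barcodes.
#
# All coordinates are 1-based inclusive residue indices.

window_tbl <- function(peptide, source_gene, window_start, k, variant_tag) {
  tibble(
    peptide = peptide,
    source_gene = source_gene,
    window_start = as.integer(window_start),
    length = as.integer(k),
    variant_tag = variant_tag
  )
}

substr_windows <- function(sequence, starts, k) {
  substring(sequence, starts, starts + k - 1L)
}

#' Tile a protein into overlapping k-mer windows
#'
#' Every length-`k` window at a step of `step` residues (default 1,
#' mirroring a 3-bp in-frame shift between neighbouring DNA tiles), ordered
#' by window start. For step 1 a protein of length L yields L - k + 1
#' windows.
#'
#' @param proteins A data frame with columns `id` and `sequence`, or a named
#'   character vector of protein sequences.
#' @param k Window length in residues (typically 8-12; class I ligands).
#' @param step Tiling step in residues.
#' @param variant_tag Provenance tag stored with each window.
#' @return A tibble with columns `peptide`, `source_gene`, `window_start`,
#'   `length`, `variant_tag`.
#' @export
#' @examples
#' tile_protein(c(toy = "MKTAYIAKQRQISFVKSH"), k = 9)
tile_protein <- function(proteins, k = 9, step = 1, variant_tag = "WT") {
  proteins <- as_protein_tbl(proteins)
  k <- as.integer(k)
  step <- as.integer(step)
  stopifnot(k >= 1, step >= 1)
  too_short <- nchar(proteins$sequence) < k
  if (any(too_short)) {
    abort(sprintf(
      "window length k=%d exceeds protein length for: %s (empty library)",
      k, paste(proteins$id[too_short], collapse = ", ")
    ))
  }
  purrr::map2_dfr(proteins$id, proteins$sequence, function(id, seq) {
    starts <- seq.int(1L, nchar(seq) - k + 1L, by = step)
    window_tbl(substr_windows(seq, starts, k), id, starts, k, variant_tag)
  })
}

#' All k-mer windows covering a residue position
#'
#' Returns every length-`k` window of the protein that contains the 1-based
#' `position`. For a position at least k - 1 residues away from both
#' termini there are exactly k such windows (e.g. nine 9-mers tile an
#' interior point mutation).
#'
#' @inheritParams tile_protein
#' @param position 1-based residue index that every window must contain.
#'   Recycled across proteins.
#' @return A tibble of windows as in [tile_protein()].
#' @export
windows_covering_position <- function(proteins, position, k = 9,
                                      variant_tag = "WT") {
  proteins <- as_protein_tbl(proteins)
  k <- as.integer(k)
  position <- vctrs_recycle_int(position, nrow(proteins), "position")
  purrr::pmap_dfr(
    list(proteins$id, proteins$sequence, position),
    function(id, seq, pos) {
      L <- nchar(seq)
      if (pos < 1L || pos > L) {
        abort(sprintf("position %d outside protein %s (length %d)",
                      pos, id, L))
      }
      if (k > L) abort(sprintf("k=%d exceeds protein %s length %d", k, id, L))
      starts <- seq.int(max(1L, pos - k + 1L), min(pos, L - k + 1L))
      window_tbl(substr_windows(seq, starts, k), id, starts, k, variant_tag)
    }
  )
}

vctrs_recycle_int <- function(x, n, what) {
  x <- as.integer(x)
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) abort(sprintf("`%s` must have length 1 or %d", what, n))
  x
}

#' Apply variant specifications to proteins
#'
#' Supported variant kinds: `point` (single substitution), `inframe_del`
#' (removal of `del_length` residues starting at `position`), and `fusion`
#' (left fragment residues 1..`bp_left` of `gene` concatenated with
#' residues `bp_right`..end of `partner`). The reference residue of a point
#' mutation is checked against the protein.
#'
#' @param proteins Protein table or named character vector (see
#'   [tile_protein()]).
#' @param variants Data frame with columns `gene`, `kind` and, depending on
#'   kind: `position`, `ref`, `alt` (point); `position`, `del_length`
#'   (inframe_del); `partner`, `bp_left`, `bp_right` (fusion).
#' @return A tibble with one row per variant: `id`, `sequence`, `kind`,
#'   `source_gene`, `position` (the mutated/junction position in the
#'   *variant* protein; for fusions the last left-fragment residue),
#'   `variant_tag`.
#' @export
#' @examples
#' apply_variant(
#'   c(KRAS = "MTEYKLVVVGAGGVGKSALTIQ"),
#'   data.frame(gene = "KRAS", kind = "point", position = 12,
#'              ref = "G", alt = "D")
#' )
apply_variant <- function(proteins, variants) {
  proteins <- as_protein_tbl(proteins)
  variants <- as_tibble(variants)
  if (!all(c("gene", "kind") %in% names(variants))) {
    abort("variants must have columns `gene` and `kind`")
  }
  get_seq <- function(gene) {
    i <- match(gene, proteins$id)
    if (is.na(i)) abort(sprintf("variant gene %s not in proteins", gene))
    proteins$sequence[i]
  }
  purrr::pmap_dfr(variants, function(...) {
    v <- list(...)
    seq <- get_seq(v$gene)
    L <- nchar(seq)
    switch(v$kind,
      point = {
        pos <- as.integer(v$position)
        if (pos < 1L || pos > L) {
          abort(sprintf("position %d outside %s (length %d)", pos, v$gene, L))
        }
        have <- substr(seq, pos, pos)
        if (!is.null(v$ref) && !is.na(v$ref) && have != v$ref) {
          abort(sprintf(
            "reference mismatch for %s position %d: protein has %s, variant says %s",
            v$gene, pos, have, v$ref
          ))
        }
        assert_protein_sequence(v$alt, "alt residue")
        tag <- sprintf("%s_%s%d%s", v$gene, have, pos, v$alt)
        newseq <- paste0(substr(seq, 1L, pos - 1L), v$alt,
                         substr(seq, pos + 1L, L))
        tibble(id = tag, sequence = newseq, kind = "point",
               source_gene = v$gene, position = pos, variant_tag = tag)
      },
      inframe_del = {
        pos <- as.integer(v$position)
        len <- as.integer(v$del_length)
        if (pos < 1L || pos + len - 1L > L) {
          abort(sprintf("deletion %d..%d outside %s (length %d)",
                        pos, pos + len - 1L, v$gene, L))
        }
        tag <- sprintf("%s_del%d_%d", v$gene, pos, len)
        newseq <- paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + len, L))
        # position = last residue before the deleted segment (junction-like)
        tibble(id = tag, sequence = newseq, kind = "inframe_del",
               source_gene = v$gene, position = max(pos - 1L, 1L),
               variant_tag = tag)
      },
      fusion = {
        pseq <- get_seq(v$partner)
        bl <- as.integer(v$bp_left)
        br <- as.integer(v$bp_right)
        if (bl < 1L || bl > L) {
          abort(sprintf("bp_left %d outside %s (length %d)", bl, v$gene, L))
        }
        if (br < 1L || br > nchar(pseq)) {
          abort(sprintf("bp_right %d outside %s (length %d)",
                        br, v$partner, nchar(pseq)))
        }
        tag <- sprintf("%s_%s_fusion", v$gene, v$partner)
        newseq <- paste0(substr(seq, 1L, bl),
                         substr(pseq, br, nchar(pseq)))
        tibble(id = tag, sequence = newseq, kind = "fusion",
               source_gene = v$gene, position = bl, variant_tag = tag)
      },
      abort(sprintf("unknown variant kind: %s", v$kind))
    )
  })
}

#' Windows spanning a fusion junction
#'
#' Two conventions are supported. `"span"` (default) keeps windows with at
#' least one residue from each side of the junction: k - 1 windows for an
#' interior junction, so summing over k = 8..12 gives 45 windows per
#' target. `"position"` treats the first residue right of the junction as
#' a mutated position and returns the k windows covering it.
#'
#' @param fused Variant protein table as returned by [apply_variant()]
#'   (needs `id`, `sequence` and either a `position` column or the
#'   `junction` argument), or a named character vector plus `junction`.
#' @param junction 1-based index of the last left-fragment residue;
#'   defaults to the `position` column.
#' @param k Window length.
#' @param mode `"span"` or `"position"` (see Details).
#' @return A tibble of windows; `variant_tag` carries the fusion id and
#'   the convention used is recorded in the `junction_mode` column.
#' @export
junction_windows <- function(fused, junction = NULL, k = 9,
                             mode = c("span", "position")) {
  mode <- match.arg(mode)
  fused <- as_protein_tbl(fused)
  k <- as.integer(k)
  if (is.null(junction)) {
    if (!"position" %in% names(fused)) {
      abort("supply `junction` or a `position` column")
    }
    junction <- fused$position
  }
  junction <- vctrs_recycle_int(junction, nrow(fused), "junction")
  tag <- if ("variant_tag" %in% names(fused)) fused$variant_tag else fused$id
  out <- purrr::pmap_dfr(
    list(fused$id, fused$sequence, junction, tag),
    function(id, seq, j, vt) {
      L <- nchar(seq)
      if (j < 1L || j >= L) {
        abort(sprintf(
          "junction %d must be strictly interior to %s (length %d)", j, id, L
        ))
      }
      starts <- if (mode == "span") {
        # >=1 residue each side: start <= j and start + k - 1 >= j + 1
        seq.int(max(1L, j - k + 2L), min(j, L - k + 1L))
      } else {
        seq.int(max(1L, j + 1L - k + 1L), min(j + 1L, L - k + 1L))
      }
      if (length(starts) == 0 || starts[1] > starts[length(starts)]) {
        return(window_tbl(character(), id, integer(), k, character()))
      }
      window_tbl(substr_windows(seq, starts, k), id, starts, k, vt)
    }
  )
  out$junction_mode <- rep(mode, nrow(out))
  out
}

#' Design a paired mutant / wild-type peptide library
#'
#' For each variant, windows covering the variant position (point and
#' in-frame deletions) or spanning the junction (fusions) are generated for
#' every window length in `ks`, together with the corresponding wild-type
#' windows from the unmutated protein at the same source coordinates
#' (fusions have no wild-type counterpart: the junction sequence does not
#' exist in either parent). Mutant and wild-type windows of a point
#' mutation share a `pair_id`, which downstream feeds the mutant versus
#' wild-type quadrant analysis.
#'
#' @inheritParams apply_variant
#' @param ks Integer vector of window lengths (default 9).
#' @param junction_mode Passed to [junction_windows()].
#' @return A tibble of windows with columns of [tile_protein()] plus
#'   `mut_wt` ("mut"/"wt") and `pair_id` (NA for fusions).
#' @export
design_variant_library <- function(proteins, variants, ks = 9,
                                   junction_mode = c("span", "position")) {
  junction_mode <- match.arg(junction_mode)
  proteins <- as_protein_tbl(proteins)
  mutated <- apply_variant(proteins, variants)
  purrr::map_dfr(as.integer(ks), function(k) {
    purrr::map_dfr(seq_len(nrow(mutated)), function(i) {
      m <- mutated[i, ]
      if (m$kind == "fusion") {
        w <- junction_windows(m, k = k, mode = junction_mode)
        w$variant_tag <- m$variant_tag
        w$mut_wt <- "mut"
        w$pair_id <- NA_character_
        w$junction_mode <- NULL
        return(w)
      }
      wm <- windows_covering_position(m[, c("id", "sequence")],
                                      position = m$position, k = k,
                                      variant_tag = m$variant_tag)
      wm$mut_wt <- "mut"
      wm$pair_id <- sprintf("%s_k%d_s%d", m$variant_tag, k, wm$window_start)
      # wild-type counterparts at the same coordinates in the source protein
      src <- proteins[proteins$id == m$source_gene, ]
      ww <- wm
      ww$peptide <- substr_windows(src$sequence, wm$window_start, k)
      ww$source_gene <- src$id
      ww$mut_wt <- "wt"
      if (m$kind == "inframe_del") {
        # deletion shifts downstream coordinates; wild-type windows for a
        # deletion are taken from the unshifted protein and may exceed its
        # tail -- drop incomplete ones
        keep <- nchar(ww$peptide) == k
        ww <- ww[keep, ]
      }
      bind_rows(wm, ww)
    })
  })
}

scan_sites <- function(dna, sites) {
  # number of forbidden-site hits on the given strand and its complement
  hits <- 0L
  for (s in sites) {
    hits <- hits +
      length(gregexpr(s, dna, fixed = TRUE)[[1]] |> (\(x) x[x > 0])()) +
      length(gregexpr(reverse_complement(s), dna, fixed = TRUE)[[1]] |>
               (\(x) x[x > 0])())
  }
  hits
}

encode_one <- function(peptide, flank5, flank3, syn, forbidden) {
  aas <- strsplit(peptide, "", fixed = TRUE)[[1]]
  codons <- vapply(syn[aas], `[[`, character(1), 1L)
  full <- function(cds) paste0(flank5, paste(cds, collapse = ""), flank3)
  if (length(forbidden) == 0 || scan_sites(full(codons), forbidden) == 0) {
    return(paste(codons, collapse = ""))
  }
  # greedy repair: walk codons, trying synonymous alternatives until the
  # construct is clean
  for (i in seq_along(codons)) {
    for (alt in syn[[aas[i]]]) {
      trial <- codons
      trial[i] <- alt
      if (scan_sites(full(trial), forbidden) == 0) {
        return(paste(trial, collapse = ""))
      }
    }
  }
  # pairwise fallback for sites spanning two codons that both need changing
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (j <= i) next
      for (ai in syn[[aas[i]]]) {
        for (aj in syn[[aas[j]]]) {
          trial <- codons
          trial[i] <- ai
          trial[j] <- aj
          if (scan_sites(full(trial), forbidden) == 0) {
            return(paste(trial, collapse = ""))
          }
        }
      }
    }
  }
  abort(sprintf(
    "cannot encode peptide %s without a forbidden restriction site", peptide
  ))
}

#' Reverse-translate a peptide library into synthesis-ready oligos
#'
#' Deterministic codon choice (most-used human codon per residue by
#' default); when the greedy encoding would contain a forbidden restriction
#' site (on either strand, including sites spanning the flank/insert
#' junctions) synonymous alternatives are substituted; an unavoidable site
#' is an error. The coding sequence round-trips: `translate(oligo) ==
#' peptide`.
#'
#' @param library Window tibble from [tile_protein()] and friends (needs a
#'   `peptide` column), or a character vector of peptides.
#' @param flank5,flank3 DNA anchor strings (cloning homology arms), length
#'   >= 6.
#' @param codon_table Named amino-acid-to-codon vector; default
#'   [human_codon_preferences()].
#' @param forbidden_sites DNA strings that must not occur; default the
#'   Esp3I/BsmBI recognition site used for cloning.
#' @return The library tibble with added columns `oligo` (coding sequence
#'   only), `flank5`, `flank3`.
#' @export
encode_oligo <- function(library, flank5 = "GCAGCGGC", flank3 = "GGCGGTTC",
                         codon_table = human_codon_preferences(),
                         forbidden_sites = c(esp3i = "CGTCTC")) {
  if (is.character(library)) library <- tibble(peptide = library)
  library <- as_tibble(library)
  assert_protein_sequence(library$peptide, "peptide")
  assert_dna(c(flank5, flank3), "flank")
  if (nchar(flank5) < 6 || nchar(flank3) < 6) abort("flanks must be >= 6 nt")
  syn <- synonymous_codons()
  # honour a custom preference table by reordering the synonym lists
  for (aa in names(codon_table)) {
    syn[[aa]] <- c(codon_table[[aa]], setdiff(syn[[aa]], codon_table[[aa]]))
  }
  uniq <- unique(library$peptide)
  enc <- vapply(uniq, encode_one, character(1),
                flank5 = flank5, flank3 = flank3, syn = syn,
                forbidden = forbidden_sites)
  library$oligo <- unname(enc[library$peptide])
  library$flank5 <- flank5
  library$flank3 <- flank3
  stopifnot(identical(translate_dna(library$oligo), library$peptide))
  library
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Design synonymous-codon allele barcodes on an invariant protein tail
#'
#' Each HLA allele in a combinatorial screen is tagged by a DNA barcode
#' hidden in synonymous codons of a fixed 12-residue tail of the B2M gene:
#' every barcode translates to the same peptide, so the protein is
#' untouched while sequencing reads identify the allele. Barcodes are
#' selected greedily over a seeded random ordering of the synonymous-codon
#' space, enforcing a minimum pairwise Hamming distance.
#'
#' @param alleles Character vector of allele names, or a single integer
#'   (number of anonymous barcodes).
#' @param b2m_tail_aa Invariant tail; default the 12 C-terminal residues of
#'   mature human B2M.
#' @param min_hamming Minimum pairwise nucleotide Hamming distance.
#' @param seed Integer seed for the random codon sampling.
#' @param max_tries Sampling attempts before giving up.
#' @return A tibble with columns `allele`, `barcode_dna`,
#'   `min_pairwise_hamming` (the realised panel minimum).
#' @export
#' @examples
#' design_barcodes(4, min_hamming = 2, seed = 1)
design_barcodes <- function(alleles, b2m_tail_aa = "SQPKIVKWDRDM",
                            min_hamming = 2, seed = 1, max_tries = 50000) {
  if (is.numeric(alleles) && length(alleles) == 1) {
    alleles <- sprintf("barcode_%02d", seq_len(alleles))
  }
  n <- length(alleles)
  assert_protein_sequence(b2m_tail_aa, "b2m_tail_aa")
  aas <- strsplit(b2m_tail_aa, "", fixed = TRUE)[[1]]
  syn <- synonymous_codons()[aas]
  degeneracy <- prod(vapply(syn, length, integer(1)))
  if (degeneracy < n) {
    abort(sprintf(
      "synonymous space of tail %s holds only %.0f encodings; %d requested",
      b2m_tail_aa, degeneracy, n
    ))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  accepted <- character(0)
  tries <- 0L
  while (length(accepted) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- paste(vapply(syn, function(cods) sample(cods, 1L), character(1)),
                  collapse = "")
    if (length(accepted) == 0 ||
        all(vapply(accepted, hamming, integer(1), b = cand) >= min_hamming)) {
      accepted <- c(accepted, cand)
    }
  }
  if (length(accepted) < n) {
    abort(sprintf(
      "could not place %d barcodes at Hamming >= %d in %d tries (space size %.0f)",
      n, min_hamming, max_tries, degeneracy
    ))
  }
  stopifnot(all(translate_dna(accepted) == b2m_tail_aa))
  realised <- if (n > 1) {
    min(utils::combn(accepted, 2, function(p) hamming(p[1], p[2])))
  } else {
    NA_integer_
  }
  tibble(allele = alleles, barcode_dna = accepted,
         min_pairwise_hamming = realised)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The 50-allele combinatorial screening panel
#'
#' The high-frequency HLA class I panel used for combinatorial screens:
#' 14 HLA-A, 29 HLA-B and 7 HLA-C alleles chosen for world-population
#' coverage, shipped as a plain-text table.
#'
#' @return A tibble with columns `allele` and `locus`.
#' @export
hla_panel_50 <- function() {
  path <- system.file("extdata", "hla_panel_50.tsv", package = "escapeseq")
  readr::read_tsv(path, show_col_types = FALSE)
}
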