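# Allele-allele similarity: BLOSUM62 pseudo-sequence distance, E-score
# profile cosine distance, hierarchical ordering for heatmaps, and 2-D
# embedding.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Pseudo-sequence distance between two alleles
#'
#' HLA alleles are compared through their 34-residue pseudo-sequences (the
#' polymorphic positions within 5 angstrom of the peptide-binding cleft),
#' scored position-wise with BLOSUM62:
#' `1 - sum(AAsim(s1[i], s2[i])) / D` where D is either the product of the
#' two self-similarity sums (`"as_printed"`, the formula as published,
#' under which even identical sequences have nonzero distance) or its
#' square root (`"sqrt_normalized"`, the default, a cosine-style
#' normalization with zero self-distance). Despite the name "similarity"
#' in its source, the quantity has the form of a distance and is named
#' accordingly.
#'
#' @param s1,s2 Pseudo-sequences (34 residues, BLOSUM62 alphabet).
#' @param mode `"sqrt_normalized"` or `"as_printed"`.
#' @return A single number.
#' @export
sequence_similarity <- function(s1, s2,
                                mode = c("sqrt_normalized", "as_printed")) {
  mode <- match.arg(mode)
  if (nchar(s1) != 34 || nchar(s2) != 34) {
    abort("pseudo-sequences must be exactly 34 residues")
  }
  B <- blosum62_matrix()
  a1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  a2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  bad <- setdiff(c(a1, a2), rownames(B))
  if (length(bad) > 0) {
    abort(sprintf("residue(s) outside the BLOSUM62 alphabet: %s",
                  paste(bad, collapse = ", ")))
  }
  num <- sum(B[cbind(a1, a2)])
  d11 <- sum(B[cbind(a1, a1)])
  d22 <- sum(B[cbind(a2, a2)])
  denom <- switch(mode,
    as_printed = d11 * d22,
    sqrt_normalized = sqrt(d11 * d22)
  )
  1 - num / denom
}

#' All-pairs pseudo-sequence distance matrix
#'
#' @param pseudo Data frame with columns `allele` and `pseudo_seq`.
#' @inheritParams sequence_similarity
#' @return A symmetric numeric matrix with allele dimnames; attribute
#'   `mode` records the normalization used.
#' @export
pseudo_distance_matrix <- function(pseudo,
                                   mode = c("sqrt_normalized", "as_printed")) {
  mode <- match.arg(mode)
  pseudo <- as_tibble(pseudo)
  stopifnot(all(c("allele", "pseudo_seq") %in% names(pseudo)))
  n <- nrow(pseudo)
  m <- matrix(0, n, n, dimnames = list(pseudo$allele, pseudo$allele))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) next
      m[i, j] <- sequence_similarity(pseudo$pseudo_seq[i],
                                     pseudo$pseudo_seq[j], mode = mode)
      m[j, i] <- m[i, j]
    }
  }
  attr(m, "mode") <- mode
  m
}

#' Wide allele x peptide score matrix from a long score table
#'
#' @param escores Long score table (`peptide`, `allele`, score column).
#' @param score_col Score column (auto-detected as in [call_binders()]).
#' @return A numeric matrix, rows = alleles, columns = peptides.
#' @export
escore_matrix <- function(escores, score_col = NULL) {
  escores <- as_tibble(escores)
  if (is.null(score_col)) {
    score_col <- intersect(c("mean_escore", "aligned_escore", "raw_escore"),
                           names(escores))[1]
  }
  wide <- tidyr::pivot_wider(
    select(escores, "allele", "peptide", val = dplyr::all_of(score_col)),
    names_from = "peptide", values_from = "val"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$allele
  m
}

#' Cosine distances between allele score profiles
#'
#' Treats each allele's vector of per-peptide E-scores as its functional
#' fingerprint and computes `1 - cosine similarity` for every allele pair.
#' Peptides with any missing score are dropped; alleles with an all-zero
#' profile are excluded with a warning (their cosine is undefined).
#'
#' @param m Allele x peptide matrix (see [escore_matrix()]), or a long
#'   score table which is pivoted first.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
escore_cosine_distances <- function(m) {
  if (is.data.frame(m)) m <- escore_matrix(m)
  keep_col <- colSums(is.na(m)) == 0
  if (!all(keep_col)) {
    warn(sprintf("%d peptide(s) with missing scores dropped",
                 sum(!keep_col)))
    m <- m[, keep_col, drop = FALSE]
  }
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    warn(sprintf("allele(s) with all-zero profile excluded: %s",
                 paste(rownames(m)[zero], collapse = ", ")))
    m <- m[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  sim <- (m %*% t(m)) / outer(norms, norms)
  d <- 1 - sim
  d[d < 0] <- 0  # numerical guard
  diag(d) <- 0
  d
}

#' Embed alleles in two dimensions from a distance matrix
#'
#' Default backend is Kruskal non-metric MDS (seeded via a classical-MDS
#' start; deterministic for a fixed input), which consumes only the
#' distance matrix. A `"umap"` backend is available that delegates to the
#' system Python's umap-learn with the conventional small-panel settings
#' (`n_neighbors = 5`, `min_dist = 0.01`, seed 42); it requires a python
#' on the PATH with umap-learn installed.
#'
#' @param d Symmetric distance matrix with allele dimnames.
#' @param n_neighbors,min_dist UMAP parameters (ignored by the MDS
#'   backend).
#' @param seed Random seed.
#' @param method `"mds"` (default) or `"umap"`.
#' @return A tibble (`allele`, `x`, `y`).
#' @export
embed_2d <- function(d, n_neighbors = 5, min_dist = 0.01, seed = 42,
                     method = c("mds", "umap")) {
  method <- match.arg(method)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < n_neighbors + 1) {
    abort(sprintf("need at least n_neighbors + 1 = %d alleles",
                  n_neighbors + 1))
  }
  alleles <- rownames(d) %||% paste0("allele_", seq_len(nrow(d)))
  if (method == "umap") {
    return(embed_2d_umap(d, alleles, n_neighbors, min_dist, seed))
  }
  # zero distances between distinct points break isoMDS; nudge them
  dd <- d
  off <- dd[upper.tri(dd)]
  eps <- if (any(off > 0)) min(off[off > 0]) * 1e-3 else 1e-6
  dd[dd == 0] <- eps
  diag(dd) <- 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- suppressWarnings(
    MASS::isoMDS(as.dist(dd), y = cmdscale(as.dist(dd), k = 2), k = 2,
                 trace = FALSE)
  )
  tibble(allele = alleles, x = fit$points[, 1], y = fit$points[, 2])
}

embed_2d_umap <- function(d, alleles, n_neighbors, min_dist, seed) {
  py <- Sys.which("python")
  if (py == "") abort("no `python` on PATH for the umap backend")
  din <- tempfile(fileext = ".csv")
  dout <- tempfile(fileext = ".csv")
  utils::write.table(d, din, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(
    paste(
      "import numpy, umap",
      "d = numpy.loadtxt(%s, delimiter=',')",
      "emb = umap.UMAP(n_components=2, n_neighbors=%d, min_dist=%f,",
      "  metric='precomputed', random_state=%d).fit_transform(d)",
      "numpy.savetxt(%s, emb, delimiter=',')",
      sep = "\n"
    ),
    deparse(din), as.integer(n_neighbors), min_dist, as.integer(seed),
    deparse(dout)
  )
  status <- system2(py, c("-c", shQuote(script)), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0 || !file.exists(dout)) {
    abort("umap backend failed; is umap-learn installed for `python`?")
  }
  emb <- utils::read.csv(dout, header = FALSE)
  tibble(allele = alleles, x = emb[[1]], y = emb[[2]])
}

#' Hierarchical ordering of a score matrix for heatmap display
#'
#' Keeps only peptides with at least one above-threshold score, clips the
#' matrix to the display range (default 2-5), and clusters both dimensions
#' hierarchically on cosine distance. The orderings and linkage trees are
#' the artifact; rendering is left to the caller's heatmap engine.
#'
#' @param m Allele x peptide score matrix (or long table; see
#'   [escore_matrix()]).
#' @param threshold Inclusion threshold (strict `>`).
#' @param clip Two-element display range the values are clipped to.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A list of class `heatmap_order`: `matrix` (clipped, filtered),
#'   `row_order`, `col_order` (allele / peptide names in display order),
#'   `row_hclust`, `col_hclust`.
#' @export
cluster_heatmap_order <- function(m, threshold = default_threshold("combinatorial"),
                                  clip = c(2, 5), linkage = "complete") {
  if (is.data.frame(m)) m <- escore_matrix(m)
  keep <- apply(m, 2, function(x) any(!is.na(x) & x > threshold))
  if (!any(keep)) abort("no peptide has any score above threshold")
  m <- m[, keep, drop = FALSE]
  m[is.na(m)] <- clip[1]  # display convention: missing shown at floor
  mc <- pmin(pmax(m, clip[1]), clip[2])
  cos_dist <- function(x) as.dist(escore_cosine_distances(x))
  hc_row <- if (nrow(mc) > 2) hclust(cos_dist(mc), method = linkage) else NULL
  hc_col <- if (ncol(mc) > 2) hclust(cos_dist(t(mc)), method = linkage) else NULL
  list_out <- list(
    matrix = mc,
    row_order = if (is.null(hc_row)) rownames(mc) else rownames(mc)[hc_row$order],
    col_order = if (is.null(hc_col)) colnames(mc) else colnames(mc)[hc_col$order],
    row_hclust = hc_row,
    col_hclust = hc_col
  )
  structure(list_out, class = "heatmap_order")
}
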