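# Population-structure embedding: nearest-neighbour imputation of missing
# allele sets, binary allele-presence encoding, PCA, minimum spanning tree
# on the leading component scores, and the 2N-constrained randomization
# that tests whether clustering is driven by allele counts alone.

#' Nearest-neighbour imputation of missing allele sets
#'
#' Missing data (around 6% in a typical microsatellite run) are replaced by
#' the closest neighbour's data, for the PCA only — distance-based
#' assignment and clone detection always work on the raw table. For each
#' missing cell, the donor is the nearest isolate (allele-sharing distance
#' over mutually non-missing loci) that carries data at that locus; its
#' whole allele set is copied. Ties break toward the smallest strain id,
#' and only a still-tied case (impossible with unique ids) would consult
#' the seed.
#'
#' @param tab An `isolate_table`.
#' @param seed Integer seed, reserved for residual tie-breaking.
#' @return The imputed `isolate_table`, attribute `imputed = TRUE`; cells
#'   with no comparable donor stay missing with a warning.
#' @export
impute_missing_nn <- function(tab, seed = 1L) {
  out <- tab
  missing_rows <- which(rowSums(tab$geno == "") > 0L)
  if (length(missing_rows) == 0L) {
    attr(out, "imputed") <- TRUE
    return(out)
  }
  d <- genotype_distance_matrix(tab)
  diag(d) <- NA_real_
  ids <- tab$meta$strain_id
  id_rank <- rank(ids, ties.method = "first")
  loci <- as.character(tab$panel)
  unfilled <- 0L
  for (i in missing_rows) {
    for (l in loci[tab$geno[i, ] == ""]) {
      cand <- which(!is.na(d[i, ]) & tab$geno[, l] != "")
      if (length(cand) == 0L) { unfilled <- unfilled + 1L; next }
      dmin <- min(d[i, cand])
      best <- cand[d[i, cand] == dmin]
      if (length(best) > 1L) best <- best[order(id_rank[best])]
      out$geno[i, l] <- tab$geno[best[1], l]
    }
  }
  if (unfilled > 0L)
    warning(unfilled, " missing cell(s) had no comparable donor; ",
            "left missing")
  attr(out, "imputed") <- TRUE
  out
}

#' Binary allele-presence encoding
#'
#' Expands a complete (imputed) table into a 0/1 matrix with one column per
#' (locus, allele size) pair observed anywhere in the table. A triploid
#' locus contributes three 1s in its locus block, a heterozygous diploid
#' two, a homozygote one. Presence coding treats diploid and triploid
#' genotypes uniformly, which is what lets mixed-ploidy isolates share one
#' PCA.
#'
#' @param tab An `isolate_table` with no missing cells (see
#'   [impute_missing_nn()]).
#' @return Integer matrix, rows named by strain id, columns `"locus:size"`.
#' @export
encode_alleles <- function(tab) {
  if (any(tab$geno == ""))
    stop("table still has missing cells; run impute_missing_nn() first")
  loci <- as.character(tab$panel)
  blocks <- lapply(loci, function(l) {
    parts <- strsplit(tab$geno[, l], "/", fixed = TRUE)
    alleles <- sort(unique(as.integer(unlist(parts))))
    m <- matrix(0L, nrow = nrow(tab$geno), ncol = length(alleles),
                dimnames = list(NULL, paste0(l, ":", alleles)))
    for (i in seq_along(parts))
      m[i, match(as.integer(parts[[i]]), alleles)] <- 1L
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- tab$meta$strain_id
  out
}

#' Principal component analysis of an allele-presence matrix
#'
#' Columns are centered (not scaled); scores and per-component explained
#' variance fractions are returned for the leading components. The sign of
#' each component is fixed deterministically — the largest-magnitude
#' loading is made positive — so embeddings are stable across platforms.
#'
#' @param m Numeric matrix, e.g. from [encode_alleles()].
#' @param n_components Number of components to keep; truncated to the
#'   matrix rank with a warning if too large.
#' @return Object of class `pca_result`: list with `scores` (n x k),
#'   `explained_variance` (length k, fractions of total variance),
#'   `loadings` (p x k).
#' @export
run_pca <- function(m, n_components = 2L) {
  if (nrow(m) < 2L) stop("PCA needs at least 2 rows")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  var_all <- fit$sdev^2
  if (max(fit$sdev) == 0) stop("matrix has no variance")
  rank <- sum(fit$sdev > max(fit$sdev) * 1e-9)
  if (n_components > rank) {
    warning("n_components = ", n_components, " exceeds rank ", rank,
            "; truncated")
    n_components <- rank
  }
  k <- seq_len(n_components)
  scores <- fit$x[, k, drop = FALSE]
  loadings <- fit$rotation[, k, drop = FALSE]
  for (j in k) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores,
                 explained_variance = var_all[k] / sum(var_all),
                 loadings = loadings),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " individuals, ",
      ncol(x$scores), " components; explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Minimum spanning tree on PCA coordinates
#'
#' Builds the MST under Euclidean distance in the first `n_axes` component
#' scores (the connection network drawn over PC1/PC2 in genotype-network
#' figures). Kruskal's algorithm with edges sorted by weight, then
#' lexicographically by the endpoint strain ids, makes the tree
#' deterministic even with tied or zero-weight edges (co-located clones).
#'
#' @param pca A `pca_result` (or any matrix of coordinates with row names).
#' @param n_axes Number of leading axes used (default 2).
#' @return Object of class `spanning_tree`: data frame with columns `from`,
#'   `to`, `weight`; attribute `total_weight`.
#' @export
minimum_spanning_tree <- function(pca, n_axes = 2L) {
  coords <- if (inherits(pca, "pca_result")) pca$scores else as.matrix(pca)
  if (n_axes > ncol(coords))
    stop("n_axes = ", n_axes, " exceeds available components (",
         ncol(coords), ")")
  coords <- coords[, seq_len(n_axes), drop = FALSE]
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 individuals for a spanning tree")
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- as.matrix(stats::dist(coords))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pair]
  # endpoints ordered so the lexicographically smaller strain id comes first
  a <- pair[, 1]; b <- pair[, 2]
  swap <- ids[a] > ids[b]
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(w, ids[a], ids[b], method = "radix")
  a <- a[ord]; b <- b[ord]; w <- w[ord]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer(n - 1L)
  got <- 0L
  for (e in seq_along(w)) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) {
      parent[ra] <- rb
      got <- got + 1L
      keep[got] <- e
      if (got == n - 1L) break
    }
  }
  edges <- data.frame(from = ids[a[keep]], to = ids[b[keep]],
                      weight = w[keep], stringsAsFactors = FALSE)
  structure(edges, class = c("spanning_tree", "data.frame"),
            total_weight = sum(edges$weight))
}

#' Randomly constrain a table to at most two alleles per locus
#'
#' For every strain-locus cell carrying exactly 3 alleles, one allele is
#' deleted uniformly at random. Re-running the structure analysis on this
#' 2N-constrained table tests whether diploid/triploid clustering is a
#' trivial consequence of allele counts: if clusters persist, the allele
#' identities ("quality"), not their number, carry the signal. Each cell
#' draws from its own (strain, locus)-hashed sub-stream, so the same seed
#' always deletes the same allele regardless of edits elsewhere.
#'
#' @param tab An `isolate_table`.
#' @param seed Integer master seed.
#' @return The constrained `isolate_table`; every locus now has at most 2
#'   alleles.
#' @export
constrain_to_2n <- function(tab, seed = 1L) {
  out <- tab
  loci <- as.character(tab$panel)
  for (i in seq_len(nrow(tab$geno))) {
    for (l in loci) {
      cell <- tab$geno[i, l]
      if (cell == "") next
      a <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
      if (length(a) == 3L) {
        drop_idx <- .with_seed(
          .cell_seed(seed, tab$meta$strain_id[i], l),
          sample.int(3L, 1L))
        out$geno[i, l] <- format_allele_set(a[-drop_idx])
      }
    }
  }
  out
}

#' Concordance between two group assignments
#'
#' Fraction of strains keeping the same group label, e.g. before and after
#' the 2N constraint. A concordance near 1 supports the conclusion that
#' populations cluster on the identity of their alleles, not merely their
#' number.
#'
#' @param full,constrained Two `group_assignment` data frames over the
#'   same strain set.
#' @return Fraction in \[0, 1\], with attribute `per_group`: named vector
#'   of concordance within each group of the `full` assignment.
#' @export
clustering_concordance <- function(full, constrained) {
  if (!setequal(full$strain_id, constrained$strain_id))
    stop("assignments cover different strain sets")
  m <- match(full$strain_id, constrained$strain_id)
  same <- full$group_name == constrained$group_name[m]
  per_group <- tapply(same, full$group_name, mean)
  structure(mean(same), per_group = per_group)
}
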