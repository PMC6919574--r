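# Fixtures are built in code: tiny hand-written tables for exact-value
# checks, and small simulation configs for recovery checks.

test_panel <- function() locus_panel(sprintf("M%02d", 1:12))

# Build an isolate table from a list of 12-cell character vectors.
make_table <- function(cells, ids = NULL, ...) {
  geno <- do.call(rbind, cells)
  colnames(geno) <- as.character(test_panel())
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(geno)))
  meta <- data.frame(strain_id = ids, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  isolate_table(meta, geno, test_panel())
}

# A genotype as a named list of allele vectors; unspecified loci missing.
make_genotype <- function(...) {
  g <- stats::setNames(rep(list(integer(0)), 12),
                       as.character(test_panel()))
  spec <- list(...)
  for (nm in names(spec)) g[[nm]] <- as.integer(spec[[nm]])
  g
}

# Uniform random genotype over the panel (for property tests).
random_genotype <- function(missing_prob = 0) {
  g <- lapply(1:12, function(l) {
    if (stats::runif(1) < missing_prob) return(integer(0))
    sort(sample(seq(100L, 140L, by = 2L), sample(1:3, 1)))
  })
  stats::setNames(g, as.character(test_panel()))
}

# Small, fast simulation config for recovery tests.
small_sim_config <- function(seed = 5L, ...) {
  args <- list(
    groups = data.frame(
      group_name = c("A", "B", "C"),
      color = c("red", "blue", "green"),
      reference_strain_id = c("SYN-R1", "SYN-R2", "SYN-R3"),
      putative_ploidy = c(2L, 3L, 3L),
      n_isolates = c(80L, 60L, 40L),
      n_genotypes = c(10L, 8L, 6L),
      stringsAsFactors = FALSE),
    seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Key -> list of per-locus allele vectors (independent of genotype_sets).
parse_key <- function(key) {
  cells <- strsplit(key, "|", fixed = TRUE)[[1]]
  lapply(cells, function(cell) {
    if (cell == ".") integer(0)
    else as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
  })
}

# Exhaustive minimum spanning tree weight by enumerating all edge subsets
# of size n-1 (oracle for small n).
brute_force_mst_weight <- function(coords) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  edges <- t(utils::combn(n, 2L))
  w <- d[edges]
  best <- Inf
  for (sel in utils::combn(nrow(edges), n - 1L, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}
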