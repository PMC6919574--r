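# Per-cell seed derivation. Stochastic per-cell operations (random allele
# removal, mutation draws) derive an independent sub-stream for every
# (strain, locus) cell by hashing the cell address together with the master
# seed, so that edits elsewhere in a table never shift the draws of an
# unrelated cell.

# FNV-1a style string hash folded into [0, 2^31 - 2].
.str_hash <- function(s) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  h
}

.cell_seed <- function(master_seed, strain_id, locus) {
  h <- .str_hash(paste(strain_id, locus, sep = "\r"))
  as.integer((master_seed %% 2147483647 + h) %% 2147483647)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
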