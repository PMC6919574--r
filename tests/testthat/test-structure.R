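# Imputation, allele-presence encoding, PCA, MST and the 2N-constrained
# randomization.

test_that("imputation is the identity on complete tables", {
  tab <- make_table(list(rep("100/102", 12), rep("104", 12)))
  imp <- impute_missing_nn(tab, seed = 1)
  expect_identical(imp$geno, tab$geno)
  expect_true(attr(imp, "imputed"))
})

test_that("a missing locus is filled from the forced nearest neighbour", {
  base <- rep("100/102", 12)
  far <- rep("300/302", 12)
  holed <- c("", base[2:12])
  tab <- make_table(list(base, far, holed), ids = c("s1", "s2", "s3"))
  imp <- impute_missing_nn(tab, seed = 1)
  expect_identical(unname(imp$geno[3, 1]), "100/102")  # from s1, not s2
  expect_equal(sum(imp$geno == ""), 0L)
})

test_that("imputation recovers >= 80% of punched cells in clonal data", {
  cfg <- small_sim_config(seed = 41L,
                          groups = data.frame(
                            group_name = c("A", "B"),
                            color = c("r", "b"),
                            reference_strain_id = c("SYN-R1", "SYN-R2"),
                            putative_ploidy = c(2L, 3L),
                            n_isolates = c(120L, 90L),
                            n_genotypes = c(5L, 4L),
                            stringsAsFactors = FALSE),
                          plate_offset_choices = 0L)
  sim <- simulate_population(cfg)
  tab <- drop_controls(sim$table, sim$control)
  imp <- impute_missing_nn(tab, seed = 2)
  truth <- sim$truth
  m <- match(tab$meta$strain_id, truth$strain_id)
  hits <- 0L; total <- 0L
  for (i in seq_len(n_isolates(tab))) {
    true_cells <- vapply(parse_key(truth$genotype_key_true[m[i]]),
                         format_allele_set, character(1))
    holes <- which(tab$geno[i, ] == "" & true_cells != "")
    total <- total + length(holes)
    hits <- hits + sum(imp$geno[i, holes] == true_cells[holes])
  }
  expect_gt(total, 50)
  expect_gte(hits / total, 0.80)
})

test_that("allele-presence encoding expands loci into per-allele indicators", {
  tab <- make_table(list(c("228/234", rep("100", 11)),
                         c("228/234", rep("100", 11)),
                         c("228/234/240", rep("102", 11))))
  m <- encode_alleles(tab)
  expect_identical(unname(m[1, c("M01:228", "M01:234")]), c(1L, 1L))
  expect_identical(m[1, ], m[2, ])                   # identical isolates
  expect_identical(ncol(m), 3L + 2L * 11L)           # sum of distinct alleles
  expect_identical(sum(m[3, startsWith(colnames(m), "M01:")]), 3L)
  holed <- make_table(list(c("", rep("100", 11))))
  expect_error(encode_alleles(holed), "impute_missing_nn")
})

test_that("PCA scores agree with an independent eigendecomposition oracle", {
  set.seed(13)
  x <- matrix(rbinom(40, 1, 0.5), nrow = 5, ncol = 8)
  rownames(x) <- paste0("s", 1:5)
  p <- run_pca(x, n_components = 3)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(x), symmetric = TRUE)
  oracle_scores <- xc %*% eig$vectors[, 1:3]
  for (j in 1:3)
    expect_equal(abs(unname(p$scores[, j])), abs(unname(oracle_scores[, j])),
                 tolerance = 1e-8)
  expect_equal(p$explained_variance,
               (eig$values / sum(eig$values))[1:3], tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
})

test_that("PCA handles rank deficiency and duplicate rows", {
  two <- matrix(c(0, 0, 1, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  p <- run_pca(two, n_components = 1)
  expect_equal(p$explained_variance[1], 1)
  expect_warning(run_pca(two, n_components = 2), "rank")
  dup <- matrix(c(0, 0, 1,
                  0, 0, 1,
                  1, 0, 0,
                  0, 1, 0), nrow = 4, byrow = TRUE,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  p2 <- run_pca(dup, n_components = 2)
  expect_equal(p2$scores["a", ], p2$scores["b", ])
  # sign convention + row-permutation invariance of explained variance
  p3 <- run_pca(dup[c(3, 1, 4, 2), ], n_components = 2)
  expect_equal(p3$explained_variance, p2$explained_variance)
})

test_that("MST of collinear points is the chain with the exact total weight", {
  coords <- matrix(c(0, 1, 3), ncol = 1,
                   dimnames = list(c("a", "b", "c"), NULL))
  mst <- minimum_spanning_tree(coords, n_axes = 1)
  expect_identical(nrow(mst), 2L)
  expect_setequal(paste(mst$from, mst$to), c("a b", "b c"))
  expect_equal(attr(mst, "total_weight"), 3)
})

test_that("MST is a spanning tree and matches the brute-force optimum", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 6L
    coords <- matrix(stats::rnorm(2 * n), ncol = 2,
                     dimnames = list(paste0("s", 1:n), NULL))
    mst <- minimum_spanning_tree(coords, n_axes = 2)
    expect_identical(nrow(mst), n - 1L)
    expect_setequal(union(mst$from, mst$to), rownames(coords))
    expect_equal(attr(mst, "total_weight"), brute_force_mst_weight(coords),
                 tolerance = 1e-12)
  }
})

test_that("MST total weight matches igraph's independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(19)
  coords <- matrix(stats::rnorm(60), ncol = 2,
                   dimnames = list(paste0("s", 1:30), NULL))
  mst <- minimum_spanning_tree(coords, n_axes = 2)
  g <- igraph::graph_from_adjacency_matrix(
    as.matrix(stats::dist(coords)), mode = "undirected", weighted = TRUE)
  ig <- igraph::mst(g)
  expect_equal(attr(mst, "total_weight"),
               sum(igraph::E(ig)$weight), tolerance = 1e-10)
})

test_that("2N constraint removes exactly one allele per triploid cell", {
  tab <- make_table(list(c("100/102/104", "200/202", rep("120/122/124", 10)),
                         rep("100/102", 12)))
  con <- constrain_to_2n(tab, seed = 3)
  sets <- genotype_sets(con)
  expect_true(all(vapply(sets, infer_ploidy, integer(1)) <= 2L))
  n3_before <- sum(vapply(genotype_sets(tab), function(g)
    sum(lengths(g) == 3L), integer(1)))
  removed <- sum(nchar(gsub("[^/]", "", tab$geno))) -
             sum(nchar(gsub("[^/]", "", con$geno)))
  expect_identical(removed, n3_before)
  # diploid cells untouched
  expect_identical(unname(con$geno[1, 2]), "200/202")
  expect_identical(con$geno[2, ], tab$geno[2, ])
  # reproducible, and a different seed may differ
  expect_identical(constrain_to_2n(tab, seed = 3)$geno, con$geno)
  # all-diploid table is a fixed point
  dip <- make_table(list(rep("100/102", 12)))
  expect_identical(constrain_to_2n(dip, seed = 1)$geno, dip$geno)
})

test_that("per-cell sub-streams do not shift when other rows change", {
  tab <- make_table(list(rep("100/102/104", 12), rep("200/202/204", 12)),
                    ids = c("s1", "s2"))
  solo <- make_table(list(rep("100/102/104", 12)), ids = "s1")
  expect_identical(constrain_to_2n(tab, seed = 9)$geno[1, ],
                   constrain_to_2n(solo, seed = 9)$geno[1, ])
})

test_that("clustering concordance counts label agreement per group", {
  a <- data.frame(strain_id = c("x", "y", "z"),
                  group_name = c("A", "A", "B"))
  expect_equal(as.numeric(clustering_concordance(a, a)), 1)
  b <- a; b$group_name <- c("B", "B", "A")
  expect_equal(as.numeric(clustering_concordance(a, b)), 0)
  c3 <- a; c3$group_name <- c("A", "B", "B")
  cc <- clustering_concordance(a, c3)
  expect_equal(as.numeric(cc), 2 / 3)
  expect_equal(unname(attr(cc, "per_group")[["A"]]), 0.5)
  expect_error(clustering_concordance(a, a[1:2, ]), "different strain sets")
})

test_that("2N-constrained reassignment keeps >= 90% of labels on separated groups", {
  sim <- simulate_population(small_sim_config(seed = 51L))
  tab <- drop_controls(normalize_plates(sim$table, sim$control),
                       sim$control)
  full <- assign_groups(tab, sim$refs)
  con <- assign_groups(constrain_to_2n(tab, seed = 4), sim$refs)
  expect_gte(as.numeric(clustering_concordance(full, con)), 0.9)
})
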