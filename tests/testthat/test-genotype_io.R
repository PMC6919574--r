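# Allele-field parsing, table IO round trips, genotype keys and
# microplate-control normalization.

test_that("allele cells parse, collapse duplicates and enforce the ploidy bound", {
  expect_identical(parse_allele_field("228/234/240"), c(228L, 234L, 240L))
  expect_identical(parse_allele_field("NA"), integer(0))
  expect_identical(parse_allele_field(""), integer(0))
  expect_identical(parse_allele_field("228/228/234"), c(228L, 234L))
  expect_identical(parse_allele_field("234/228"), c(228L, 234L))
  expect_error(parse_allele_field("100/102/104/106"), "triploid bound")
  expect_error(parse_allele_field("22x/234", context = "r1/M01"), "r1/M01")
  expect_identical(format_allele_set(c(240L, 228L, 228L)), "228/240")
})

test_that("table construction validates ids, coordinates and year ordering", {
  cells <- rep(list(rep("100/102", 12)), 2)
  expect_error(make_table(cells, ids = c("a", "a")), "duplicate strain_id")
  expect_error(make_table(cells, latitude = c(95, 0)), "latitude")
  expect_error(make_table(cells, vintage_year = c(2010L, NA),
                          isolation_year = c(2005L, NA)),
               "vintage_year after isolation_year")
})

test_that("write/read round-trips tables, preserving missing cells", {
  tab <- make_table(list(c("228/234", rep("100", 10), ""),
                         rep("102/104/106", 12),
                         c("", rep("120", 11))),
                    winery = c("W1", "W1", NA),
                    latitude = c(44.8, NA, -33.9),
                    longitude = c(-0.6, NA, 18.9),
                    vintage_year = c(1990L, 2010L, NA),
                    isolation_year = c(2005L, 2010L, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_isolates(tab, path)
  back <- suppressMessages(read_isolates(path, test_panel()))
  expect_identical(back$geno, tab$geno)
  expect_identical(back$meta, tab$meta)
  # byte-stable: writing the re-read table reproduces the file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_isolates(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("an empty table writes a header-only file", {
  tab <- make_table(list(rep("100", 12)))[0]
  path <- withr::local_tempfile(fileext = ".csv")
  write_isolates(tab, path)
  expect_length(readLines(path), 1L)
})

test_that("read_isolates reports the missing-cell fraction and rejects bad files", {
  tab <- make_table(list(c("", rep("100", 11)),
                         rep("102", 12), rep("104", 12)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_isolates(tab, path)
  expect_message(read_isolates(path, test_panel()), "1 missing cells \\(2\\.78%\\)")
  # missing locus column
  df <- utils::read.csv(path, check.names = FALSE)
  df$M12 <- NULL
  path_bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path_bad, row.names = FALSE)
  expect_error(suppressMessages(read_isolates(path_bad, test_panel())),
               "M12")
})

test_that("genotype keys canonicalize order and expose missing loci", {
  g1 <- make_genotype(M01 = c(234, 228), M02 = 100)
  g2 <- make_genotype(M01 = c(228, 234), M02 = 100)
  expect_identical(genotype_key(g1), genotype_key(g2))
  g3 <- make_genotype(M01 = c(228, 236), M02 = 100)
  expect_false(genotype_key(g1) == genotype_key(g3))
  expect_match(genotype_key(g1), "\\|\\.\\|")  # missing token at M03
})

test_that("genotype keys are injective over distinct genotypes of a table", {
  set.seed(42)
  tabs <- replicate(30, random_genotype(missing_prob = 0.2),
                    simplify = FALSE)
  keys <- vapply(tabs, genotype_key, character(1))
  for (i in seq_along(tabs))
    for (j in seq_along(tabs))
      expect_identical(keys[i] == keys[j],
                       identical(tabs[[i]], tabs[[j]]))
})

test_that("plate normalization undoes a constructed +2 bp shift and is idempotent", {
  base <- c("228/234", "100/102/104", rep("120", 10))
  shifted <- c("230/236", "102/104/106", rep("122", 10))
  tab <- make_table(list(base, base, shifted, shifted, c(shifted[1:11], "")),
                    ids = c("CTRL", "x1", "CTRL@P2", "x2", "x3"),
                    plate_id = c("P1", "P1", "P2", "P2", "P2"))
  ctrl <- plate_control("CTRL", "P1")
  norm <- normalize_plates(tab, ctrl)
  off <- attr(norm, "plate_offsets")
  expect_true(all(off["P2", ] == 2L))
  expect_true(all(off["P1", ] == 0L))
  # plate-2 rows now equal the reference genotype; missing stays missing
  expect_identical(unname(norm$geno[3, ]), base)
  expect_identical(unname(norm$geno[4, ]), base)
  expect_identical(unname(norm$geno[5, 12]), "")
  # idempotent
  norm2 <- normalize_plates(norm, ctrl)
  expect_identical(norm2$geno, norm$geno)
  expect_true(all(attr(norm2, "plate_offsets") == 0L))
  # identical controls across plates leave the table unchanged
  tab_id <- make_table(list(base, base, base),
                       ids = c("CTRL", "CTRL@P2", "y"),
                       plate_id = c("P1", "P2", "P2"))
  expect_identical(normalize_plates(tab_id, ctrl)$geno, tab_id$geno)
  # control absent from a plate is an error naming the plate
  tab_bad <- make_table(list(base, base), ids = c("CTRL", "z"),
                        plate_id = c("P1", "P3"))
  expect_error(normalize_plates(tab_bad, ctrl), "P3")
})

test_that("generator-planted plate offsets are recovered exactly", {
  sim <- simulate_population(small_sim_config(seed = 21L))
  norm <- normalize_plates(sim$table, sim$control)
  expect_identical(attr(norm, "plate_offsets"), sim$plate_offsets)
  # and normalization restores the pre-offset genotypes of complete cells
  clean <- drop_controls(norm, sim$control)
  keys <- genotype_keys(clean)
  complete <- rowSums(clean$geno == "") == 0L
  truth <- sim$truth
  m <- match(truth$strain_id, clean$meta$strain_id)
  same <- keys[m][complete[m]] == truth$genotype_key_true[complete[m]]
  expect_true(all(same))
})

test_that("drop_controls removes exactly the control replicates", {
  sim <- simulate_population(small_sim_config(seed = 22L))
  clean <- drop_controls(sim$table, sim$control)
  expect_setequal(clean$meta$strain_id, sim$truth$strain_id)
})
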