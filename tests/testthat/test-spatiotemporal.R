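# Clone detection, winery persistence, dispersal distances and classes,
# regional/sample composition, and vintage binning.

test_that("clone groups partition identical complete genotypes", {
  base <- rep("100/102", 12)
  variant <- c("100/104", base[2:12])
  holed <- c("", base[2:12])
  tab <- make_table(list(base, base, variant, holed),
                    ids = c("s1", "s2", "s3", "s4"))
  expect_warning(cl <- find_clone_groups(tab), "missing loci")
  expect_identical(nrow(cl$groups), 1L)
  expect_setequal(cl$members[[1]], c("s1", "s2"))
  expect_setequal(cl$singletons, c("s3", "s4"))  # missing locus: no clone
})

test_that("the clone relation is an equivalence on complete genotypes", {
  set.seed(43)
  cells <- replicate(6, vapply(random_genotype(), format_allele_set,
                               character(1)), simplify = FALSE)
  cells <- cells[c(1, 2, 3, 1, 2, 1, 4, 5, 6)]  # planted duplicates
  tab <- make_table(cells)
  cl <- find_clone_groups(tab)
  all_members <- c(unlist(cl$members), cl$singletons)
  expect_setequal(all_members, tab$meta$strain_id)     # partition
  expect_identical(anyDuplicated(all_members), 0L)
  keys <- genotype_keys(tab)
  for (grp in cl$members)                              # members share keys
    expect_length(unique(keys[grp]), 1L)
  group_keys <- vapply(cl$members, function(g) keys[[g[1]]], character(1))
  expect_identical(anyDuplicated(group_keys), 0L)      # groups are maximal
})

test_that("planted clone partition is recovered exactly without missing data", {
  sim <- simulate_population(small_sim_config(seed = 61L,
                                              missing_rate = 0,
                                              plate_offset_choices = 0L))
  tab <- drop_controls(sim$table, sim$control)
  cl <- find_clone_groups(tab)
  truth_split <- split(sim$truth$strain_id, sim$truth$clone_id)
  planted <- unname(lapply(truth_split[lengths(truth_split) >= 2], sort))
  found <- unname(lapply(cl$members, sort))
  expect_setequal(
    vapply(found, paste, character(1), collapse = ","),
    vapply(planted, paste, character(1), collapse = ","))
})

test_that("winery persistence reports sorted vintages and intervals", {
  base <- rep("100/102", 12)
  tab <- make_table(rep(list(base), 6),
                    ids = paste0("s", 1:6),
                    winery = c("B1", "B1", "A1", "A1", "A1", "C1"),
                    vintage_year = c(2012L, 1926L, 1948L, 1970L, 1909L,
                                     2000L),
                    isolation_year = rep(2015L, 6))
  cl <- find_clone_groups(tab)
  pers <- winery_persistence(cl, tab)
  b1 <- pers[pers$winery == "B1", ]
  expect_identical(b1$interval_years, 86L)              # 2012 - 1926
  expect_identical(b1$vintages, "1926,2012")
  a1 <- pers[pers$winery == "A1", ]
  expect_identical(a1$interval_years, 61L)              # 1970 - 1909
  expect_identical(a1$vintages, "1909,1948,1970")
  expect_false("C1" %in% pers$winery)                   # single vintage
})

test_that("haversine distances match analytic great-circle arcs", {
  expect_equal(haversine_km(44.8, -0.6, 44.8, -0.6), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088,
               tolerance = 1e-6)
  expect_equal(haversine_km(90, 0, -90, 0), pi * 6371.0088,
               tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 1), 6371.0088 * pi / 180,
               tolerance = 1e-6)
  expect_true(is.na(haversine_km(NA, 0, 0, 1)))
})

test_that("haversine is symmetric and obeys the triangle inequality", {
  set.seed(47)
  for (rep in 1:30) {
    lat <- stats::runif(3, -90, 90); lon <- stats::runif(3, -180, 180)
    d12 <- haversine_km(lat[1], lon[1], lat[2], lon[2])
    d21 <- haversine_km(lat[2], lon[2], lat[1], lon[1])
    d13 <- haversine_km(lat[1], lon[1], lat[3], lon[3])
    d23 <- haversine_km(lat[2], lon[2], lat[3], lon[3])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-6)
  }
})

test_that("clone pair distances enumerate all member pairs", {
  base <- rep("100/102", 12)
  tab <- make_table(rep(list(base), 3), ids = c("a", "b", "c"),
                    latitude = c(44.8, 44.8, 44.8),
                    longitude = c(-0.6, -0.6, -0.6))
  cl <- find_clone_groups(tab)
  pd <- clone_pair_distances(cl, tab)
  expect_identical(nrow(pd), 3L)                       # C(3,2)
  expect_equal(pd$km, rep(0, 3))
})

test_that("a planted remote clone member yields the planted dispersal distance", {
  wn <- data.frame(
    winery = c("W_HOME", "W_FAR"), region = c("Bordeaux", "Barossa"),
    country = c("France", "Australia"),
    latitude = c(44.84, -34.53), longitude = c(-0.58, 138.95),
    weight = c(1, 1e-9))
  cfg <- small_sim_config(
    seed = 71L, wineries = wn, dispersal_prob = 0.15,
    missing_rate = 0, plate_offset_choices = 0L)
  sim <- simulate_population(cfg)
  expect_gt(sum(sim$truth$dispersed), 0)
  tab <- drop_controls(sim$table, sim$control)
  cl <- find_clone_groups(tab)
  pd <- clone_pair_distances(cl, tab)
  planted <- max(sim$truth$planted_km)
  expect_equal(max(pd$km), planted, tolerance = 1e-3)  # within 0.1%
})

test_that("distance classes use half-open bins and a derived local fraction", {
  bd <- bin_distances(c(0.4, 55, 300, 5500))
  expect_identical(bd$count, c(1L, 1L, 1L, 0L, 1L))
  expect_equal(attr(bd, "local_fraction"), 0.5)
  expect_equal(sum(bd$fraction), 1)
  zero <- bin_distances(rep(0, 5))
  expect_equal(attr(zero, "local_fraction"), 1)
  expect_equal(zero$fraction[1], 1)
  edge <- bin_distances(100)
  expect_identical(edge$count[3], 1L)                  # 100 km -> [100,750)
  expect_warning(empty <- bin_distances(numeric(0)), "no pair distances")
  expect_identical(sum(empty$count), 0L)
})

test_that("regional group composition reproduces known fractions", {
  n <- c(345L, 373L, 14L)
  tab <- make_table(rep(list(rep("100", 12)), sum(n)),
                    region = rep("Bordeaux", sum(n)),
                    group_label = rep(c("Wine 2N", "1st Wine 3N",
                                        "Wine/Kombucha 2N"), n))
  dist <- region_group_distribution(tab, "region")
  expect_equal(dist$fractions["Bordeaux", "Wine 2N"], 345 / 732)
  expect_equal(dist$fractions["Bordeaux", "1st Wine 3N"], 373 / 732)
  expect_equal(sum(dist$fractions["Bordeaux", ]), 1)
  expect_identical(sum(dist$counts), 732L)             # conservation
})

test_that("sample diversity flags multi-group samples above the size threshold", {
  tab <- make_table(rep(list(rep("100", 12)), 9),
                    sample_id = c(rep("s_big", 5), rep("s_small", 4)),
                    group_label = c("A", "A", "B", "A", "B",
                                    "A", "B", "A", "B"))
  sd <- sample_group_diversity(tab, min_isolates = 5)
  expect_identical(sd$sample_id, "s_big")              # s_small excluded
  expect_true(sd$multi_group)
  expect_identical(sd$n_groups, 2L)
  expect_identical(attr(sd, "n_multi_group"), 1L)
})

test_that("vintage bins anchor on the published 20-year intervals", {
  expect_identical(vintage_bin(1990), "1981-2000")
  expect_identical(vintage_bin(2001), "2001-2020")
  expect_identical(vintage_bin(1980), "1961-1980")
  expect_identical(vintage_bin(2000), "1981-2000")
  expect_identical(vintage_bin(1909), "1901-1920")
  expect_error(vintage_bin(1700), "plausible range")
})

test_that("temporal proportions are seed-stable with conserved counts", {
  base <- rep("100/102", 12)
  tab <- make_table(rep(list(base), 10),
                    group_label = c(rep("A", 4), rep("B", 2), rep("A", 4)),
                    vintage_year = c(rep(1990L, 6), rep(2010L, 4)),
                    isolation_year = rep(2015L, 10))
  tp <- temporal_group_proportions(tab, n_boot = 50, seed = 3)
  expect_identical(unique(tp$bin), c("1981-2000", "2001-2020"))
  old <- tp[tp$bin == "1981-2000", ]
  expect_equal(old$fraction[old$group_name == "A"], 4 / 6)
  expect_equal(sum(old$count), 6L)                     # conservation
  single <- tp[tp$bin == "2001-2020", ]
  expect_identical(single$group_name, "A")             # single-group bin
  expect_equal(single$fraction, 1)
  expect_equal(c(single$ci_lo, single$ci_hi), c(1, 1))
  tp2 <- temporal_group_proportions(tab, n_boot = 50, seed = 3)
  expect_identical(tp, tp2)
})
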