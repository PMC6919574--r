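# Ground-truthed synthetic genotype tables. The generator emulates the
# statistical structure the analysis pipeline assumes for a worldwide wine
# collection of a mixed-ploidy clonal yeast: five reference-anchored
# genetic groups (two putative diploid, three putative triploid), within-
# group genotypes derived from the group founder by stepwise mutation,
# heavily skewed clone sizes, winery/region/vintage metadata with a
# diploid-only era before the triploid onset, rare long-range clone
# dispersal, microplate sizing offsets, and ~6% missing data. Every
# corruption (offset, hole punching) is recorded in a truth table first,
# so recovery tests never have to reach into generator internals.

#' Built-in winery set of the default simulation
#'
#' Fourteen wineries across nine countries with approximate coordinates
#' and sampling weights skewed toward Bordeaux, mirroring the sampling
#' imbalance typical of large spoilage-yeast collections.
#'
#' @return Data frame: `winery`, `region`, `country`, `latitude`,
#'   `longitude`, `weight`.
#' @export
default_wineries <- function() {
  data.frame(
    winery = c("W_BDX1", "W_BDX2", "W_BGD", "W_LGD", "W_JUR", "W_CDR",
               "W_TSC", "W_PUG", "W_CAT", "W_DOU", "W_CPH", "W_NAP",
               "W_STB", "W_BAR"),
    region = c("Bordeaux", "Bordeaux", "Burgundy", "Languedoc", "Jura",
               "Cotes-du-Rhone", "Tuscany", "Puglia", "Catalonia", "Douro",
               "Zealand", "California", "Stellenbosch", "Barossa"),
    country = c("France", "France", "France", "France", "France", "France",
                "Italy", "Italy", "Spain", "Portugal", "Denmark", "USA",
                "South Africa", "Australia"),
    latitude = c(44.84, 44.90, 47.03, 43.61, 46.74, 44.93, 43.47, 40.99,
                 41.38, 41.16, 55.68, 38.50, -33.94, -34.53),
    longitude = c(-0.58, -0.45, 4.84, 3.88, 5.66, 4.89, 11.14, 16.87,
                  1.52, -7.78, 12.57, -122.43, 18.86, 138.95),
    weight = c(30, 22, 11, 8, 2, 3, 6, 4, 5, 2, 2, 3, 2, 2),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults encode the study conditions of the wine cohort the pipeline is
#' designed for: five genetic groups with the published isolate and
#' genotype counts (521/58, 69/50, 229/88, 551/118, 40/26 for the Wine 2N,
#' Wine/Kombucha 2N, Wine/Beer 3N, 1st Wine 3N and 2nd Wine 3N groups),
#' 12 loci, a 2 bp repeat unit, ~6% missing data, per-plate sizing offsets
#' in \{-2, 0, +2\} bp, and a 1990 onset for the triploid groups (vintages
#' before that year are diploid-only).
#'
#' @param groups Data frame (`group_name`, `color`, `reference_strain_id`,
#'   `putative_ploidy`, `n_isolates`, `n_genotypes`).
#' @param n_loci Number of loci (12).
#' @param repeat_step Repeat-unit length in bp.
#' @param allele_base_range Range the per-locus base allele size is drawn
#'   from (bp).
#' @param allele_window Number of repeat-unit steps a locus's alleles span.
#' @param mu Per-allele mutation probability per mutation round.
#' @param depth_lambda Mean extra mutation rounds per derived genotype
#'   (rounds = 1 + Poisson(depth_lambda)).
#' @param min_separation Minimum pairwise allele-sharing distance between
#'   group founders (rejection sampling).
#' @param zipf_s Zipf exponent of within-group clone sizes (1.1 reproduces
#'   a largest-clone share near the published 114/521).
#' @param wineries Winery data frame (see [default_wineries()]).
#' @param vintage_range Integer range of vintages.
#' @param triploid_onset First vintage year triploid groups may appear in.
#' @param dispersal_prob Probability that an isolate of a clone is
#'   relocated to a winery in another country.
#' @param missing_rate Fraction of allele cells punched to missing.
#' @param plate_size Isolates per microplate (94 wells + controls).
#' @param plate_offset_choices Candidate per-plate/locus sizing offsets in
#'   bp.
#' @param jitter_deg Uniform coordinate jitter (degrees) around the winery.
#' @param seed Master seed; the whole build is a pure function of the
#'   config including this seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(
    groups = data.frame(
      group_name = c("Wine 2N", "Wine/Kombucha 2N", "Wine/Beer 3N",
                     "1st Wine 3N", "2nd Wine 3N"),
      color = c("darkcyan", "lightgreen", "orange", "red", "turquoise"),
      reference_strain_id = c("SYN-CBS2499", "SYN-L14165", "SYN-AWRI1608",
                              "SYN-AWRI1499", "SYN-L0308"),
      putative_ploidy = c(2L, 2L, 3L, 3L, 3L),
      n_isolates = c(521L, 69L, 229L, 551L, 40L),
      n_genotypes = c(58L, 50L, 88L, 118L, 26L),
      stringsAsFactors = FALSE),
    n_loci = 12L,
    repeat_step = 2L,
    allele_base_range = c(100L, 300L),
    allele_window = 15L,
    mu = 0.05,
    depth_lambda = 2,
    min_separation = 0.6,
    zipf_s = 1.1,
    wineries = default_wineries(),
    vintage_range = c(1921L, 2020L),
    triploid_onset = 1990L,
    dispersal_prob = 0.05,
    missing_rate = 0.06,
    plate_size = 94L,
    plate_offset_choices = c(-2L, 0L, 2L),
    jitter_deg = 0.002,
    seed = 1L) {
  stopifnot(all(groups$n_genotypes >= 1L),
            all(groups$n_isolates >= groups$n_genotypes),
            missing_rate >= 0, missing_rate <= 1,
            dispersal_prob >= 0, dispersal_prob <= 1,
            mu >= 0, mu <= 1)
  cfg <- list(groups = groups, n_loci = as.integer(n_loci),
              repeat_step = as.integer(repeat_step),
              allele_base_range = as.integer(allele_base_range),
              allele_window = as.integer(allele_window),
              mu = mu, depth_lambda = depth_lambda,
              min_separation = min_separation, zipf_s = zipf_s,
              wineries = wineries,
              vintage_range = as.integer(vintage_range),
              triploid_onset = as.integer(triploid_onset),
              dispersal_prob = dispersal_prob, missing_rate = missing_rate,
              plate_size = as.integer(plate_size),
              plate_offset_choices = as.integer(plate_offset_choices),
              jitter_deg = jitter_deg, seed = as.integer(seed))
  cfg$panel <- locus_panel(sprintf("M%02d", seq_len(cfg$n_loci)),
                           n_loci = cfg$n_loci)
  class(cfg) <- "sim_config"
  cfg
}

# Draw one founder genotype: per-locus allele counts given the ploidy,
# with at least one locus realizing the ploidy-defining count.
.draw_founder <- function(ploidy, locus_bases, window, step) {
  n_loci <- length(locus_bases)
  counts <- if (ploidy == 2L) sample(1:2, n_loci, replace = TRUE)
            else sample(2:3, n_loci, replace = TRUE)
  if (!any(counts == ploidy)) counts[sample.int(n_loci, 1L)] <- ploidy
  g <- lapply(seq_len(n_loci), function(l) {
    sizes <- locus_bases[l] + step * (0:(window - 1L))
    sort(sample(sizes, counts[l]))
  })
  names(g) <- names(locus_bases)
  g
}

#' Draw the reference panel of founder genotypes
#'
#' One founder multilocus genotype per genetic group, rejected and redrawn
#' until all pairwise allele-sharing distances reach
#' `cfg$min_separation`, so that groups are genuinely separated in allele
#' space. Diploid founders carry 1--2 alleles per locus, triploid founders
#' 2--3 (with the ploidy-defining count realized at least once).
#'
#' @param cfg A [sim_config()].
#' @return A [reference_panel()] whose reference strains are the synthetic
#'   founders.
#' @export
make_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, .make_founders_impl(cfg))
}

.make_founders_impl <- function(cfg) {
  n_groups <- nrow(cfg$groups)
  bases <- sample(seq(cfg$allele_base_range[1], cfg$allele_base_range[2],
                      by = cfg$repeat_step), cfg$n_loci)
  names(bases) <- as.character(cfg$panel)
  for (attempt in seq_len(1000L)) {
    founders <- lapply(seq_len(n_groups), function(gi)
      .draw_founder(cfg$groups$putative_ploidy[gi], bases,
                    cfg$allele_window, cfg$repeat_step))
    ok <- TRUE
    for (i in seq_len(n_groups - 1L))
      for (j in seq((i + 1L), n_groups))
        if (allele_sharing_distance(founders[[i]], founders[[j]]) <
            cfg$min_separation) ok <- FALSE
    if (ok) {
      geno <- do.call(rbind, lapply(founders, function(g)
        vapply(g, format_allele_set, character(1))))
      colnames(geno) <- as.character(cfg$panel)
      return(reference_panel(cfg$groups[, c("group_name", "color",
                                            "reference_strain_id",
                                            "putative_ploidy")],
                             geno, cfg$panel))
    }
  }
  stop("could not separate ", n_groups, " founders by ",
       cfg$min_separation, " in 1000 attempts; widen the allele range")
}

#' Stepwise mutation of a multilocus genotype
#'
#' Each allele independently moves by one repeat unit (direction uniform)
#' with probability `mu`. The allele count per locus is preserved: a shift
#' that collides with an existing allele of the same locus is redrawn, and
#' an allele that cannot move without colliding stays put.
#'
#' @param g Named list of integer allele vectors.
#' @param mu Per-allele mutation probability.
#' @param seed Integer seed.
#' @param step Repeat-unit length in bp (default 2).
#' @return The mutated genotype (same shape as `g`).
#' @export
mutate_genotype <- function(g, mu, seed = 1L, step = 2L) {
  .with_seed(seed, {
    lapply(g, function(alleles) {
      if (length(alleles) == 0L) return(alleles)
      for (k in seq_along(alleles)) {
        if (stats::runif(1) >= mu) next
        for (try in 1:10) {
          cand <- alleles[k] + step * sample(c(-1L, 1L), 1L)
          if (cand > 0L && !(cand %in% alleles[-k])) {
            alleles[k] <- cand
            break
          }
        }
      }
      sort(alleles)
    })
  })
}

# Zipf-shaped integer composition: sizes of R clones summing to n, each
# >= 1, proportional to rank^(-s) (largest-remainder rounding).
.zipf_sizes <- function(n, R, s) {
  w <- seq_len(R)^(-s)
  raw <- w / sum(w) * (n - R)   # reserve 1 isolate per genotype
  sizes <- 1L + floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    extra <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  sizes
}

# Vintage sampler. Diploid groups span the whole calendar with the
# sampling imbalance of real collections (old vintages are rare); triploid
# groups only exist from the onset year on.
.draw_vintage <- function(ploidy, cfg) {
  y0 <- cfg$vintage_range[1]; y1 <- cfg$vintage_range[2]
  onset <- cfg$triploid_onset
  if (ploidy >= 3L) {
    lo <- max(onset, y0)
    if (stats::runif(1) < 0.2) sample(lo:min(2000L, y1), 1L)
    else sample(max(lo, 2001L):y1, 1L)
  } else {
    u <- stats::runif(1)
    if (u < 0.10) sample(y0:(onset - 1L), 1L)
    else if (u < 0.30) sample(max(y0, 1981L):2000L, 1L)
    else sample(2001L:y1, 1L)
  }
}

#' Simulate a ground-truthed isolate table
#'
#' Builds the full synthetic cohort: founders, derived genotypes (stepwise
#' mutants with globally unique genotype keys), Zipf-sized clones with a
#' home winery each, vintages (triploid groups only from the onset year),
#' coordinates (winery plus jitter), cross-country dispersal, microplates
#' with control replicates and sizing offsets, and missing-data punching.
#' The truth table snapshots each isolate's group, clone, genotype key and
#' planted dispersal distance *before* offsets and holes corrupt the
#' emitted table.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_result`: `table` (the corrupted
#'   `isolate_table` as a genotyping run would deliver it), `truth` (data
#'   frame, one row per non-control isolate), `refs` (the founder
#'   [reference_panel()]), `plate_offsets` (plates x loci integer matrix),
#'   `control` (the [plate_control()] needed to undo the offsets), and
#'   `config`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, .simulate_impl(cfg))
}

.simulate_impl <- function(cfg) {
  refs <- .make_founders_impl(cfg)
  loci <- as.character(cfg$panel)
  ref_sets <- genotype_sets(
    structure(list(panel = cfg$panel,
                   meta = data.frame(strain_id = refs$groups$group_name),
                   geno = refs$geno), class = "isolate_table"))
  n_groups <- nrow(cfg$groups)
  wn <- cfg$wineries

  # derived genotypes per group, globally unique keys
  genotypes <- list(); g_group <- integer(0); g_home <- integer(0)
  seen <- character(0)
  for (gi in seq_len(n_groups)) {
    for (j in seq_len(cfg$groups$n_genotypes[gi])) {
      if (j == 1L) {
        g <- ref_sets[[gi]]
      } else {
        for (try in seq_len(50L)) {
          rounds <- 1L + stats::rpois(1, cfg$depth_lambda) + (try - 1L)
          g <- ref_sets[[gi]]
          for (r in seq_len(rounds))
            g <- mutate_genotype(g, cfg$mu,
                                 seed = sample.int(2^30, 1L),
                                 step = cfg$repeat_step)
          if (!(genotype_key(g) %in% seen)) break
        }
      }
      key <- genotype_key(g)
      if (key %in% seen)
        stop("could not generate a unique genotype for group ",
             cfg$groups$group_name[gi])
      seen <- c(seen, key)
      genotypes[[length(genotypes) + 1L]] <- g
      g_group <- c(g_group, gi)
      g_home <- c(g_home, sample.int(nrow(wn), 1L, prob = wn$weight))
    }
  }

  # isolates
  rows <- list(); truth <- list()
  iso <- 0L
  clone_sizes <- integer(length(genotypes))
  for (gi in seq_len(n_groups)) {
    idx <- which(g_group == gi)
    clone_sizes[idx] <- .zipf_sizes(cfg$groups$n_isolates[gi],
                                    length(idx), cfg$zipf_s)
  }
  for (gid in seq_along(genotypes)) {
    gi <- g_group[gid]
    ploidy <- cfg$groups$putative_ploidy[gi]
    home <- g_home[gid]
    for (m in seq_len(clone_sizes[gid])) {
      iso <- iso + 1L
      dispersed <- stats::runif(1) < cfg$dispersal_prob
      wi <- home
      if (dispersed) {
        other <- which(wn$country != wn$country[home])
        if (length(other)) wi <- sample(other, 1L) else dispersed <- FALSE
      }
      vintage <- .draw_vintage(ploidy, cfg)
      isolation <- if (vintage >= 2003L)
        min(2020L, vintage + sample(0:2, 1L)) else sample(2003:2020, 1L)
      lat <- wn$latitude[wi] + stats::runif(1, -cfg$jitter_deg, cfg$jitter_deg)
      lon <- wn$longitude[wi] + stats::runif(1, -cfg$jitter_deg, cfg$jitter_deg)
      rows[[iso]] <- list(
        strain_id = sprintf("S%04d", iso),
        winery = wn$winery[wi], region = wn$region[wi],
        country = wn$country[wi],
        sample_id = paste(wn$winery[wi], vintage, sep = ":"),
        latitude = lat, longitude = lon,
        vintage_year = vintage, isolation_year = isolation,
        gid = gid)
      truth[[iso]] <- data.frame(
        strain_id = sprintf("S%04d", iso),
        true_group = cfg$groups$group_name[gi],
        clone_id = gid,
        genotype_key_true = genotype_key(genotypes[[gid]]),
        home_winery = wn$winery[home],
        winery = wn$winery[wi],
        dispersed = dispersed,
        planted_km = if (dispersed)
          haversine_km(lat, lon, wn$latitude[home], wn$longitude[home])
          else 0,
        vintage_year = vintage,
        stringsAsFactors = FALSE)
    }
  }
  n <- iso

  # plates and offsets (reference plate P01 has offset 0 everywhere)
  n_plates <- max(1L, ceiling(n / cfg$plate_size))
  plate_ids <- sprintf("P%02d", seq_len(n_plates))
  plate_of <- rep(plate_ids, each = cfg$plate_size)[seq_len(n)]
  offsets <- matrix(0L, n_plates, cfg$n_loci,
                    dimnames = list(plate_ids, loci))
  if (n_plates > 1L)
    offsets[-1L, ] <- sample(cfg$plate_offset_choices,
                             (n_plates - 1L) * cfg$n_loci, replace = TRUE)

  control_id <- refs$groups$reference_strain_id[1]
  ctrl_geno <- ref_sets[[1]]

  geno <- matrix("", nrow = n + n_plates, ncol = cfg$n_loci,
                 dimnames = list(NULL, loci))
  meta_rows <- vector("list", n + n_plates)
  truth_df <- do.call(rbind, truth)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    g <- genotypes[[r$gid]]
    p <- plate_of[i]
    for (l in seq_along(loci)) {
      a <- g[[l]] + offsets[p, l]
      if (cfg$missing_rate > 0 && stats::runif(1) < cfg$missing_rate) {
        geno[i, l] <- ""
      } else geno[i, l] <- format_allele_set(a)
    }
    meta_rows[[i]] <- data.frame(
      strain_id = r$strain_id, winery = r$winery, sample_id = r$sample_id,
      region = r$region, country = r$country, latitude = r$latitude,
      longitude = r$longitude, vintage_year = r$vintage_year,
      isolation_year = r$isolation_year, plate_id = p,
      group_label = NA_character_, stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_plates)) {
    i <- n + k
    p <- plate_ids[k]
    for (l in seq_along(loci))
      geno[i, l] <- format_allele_set(ctrl_geno[[l]] + offsets[p, l])
    meta_rows[[i]] <- data.frame(
      strain_id = if (k == 1L) control_id else paste0(control_id, "@", p),
      winery = NA_character_, sample_id = NA_character_,
      region = NA_character_, country = NA_character_,
      latitude = NA_real_, longitude = NA_real_,
      vintage_year = NA_integer_, isolation_year = NA_integer_,
      plate_id = p, group_label = NA_character_, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta_rows)
  tab <- isolate_table(meta, geno, cfg$panel)
  structure(list(table = tab, truth = truth_df, refs = refs,
                 plate_offsets = offsets,
                 control = plate_control(control_id, "P01"),
                 config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", nrow(x$truth), " isolates + ",
      nrow(x$plate_offsets), " plate controls; ",
      length(unique(x$truth$clone_id)), " planted genotypes in ",
      nrow(x$config$groups), " groups\n", sep = "")
  invisible(x)
}

#' Write a simulation to CSV files
#'
#' @param sim A `sim_result`.
#' @param table_path,truth_path,refs_path Output CSV paths (truth and refs
#'   optional).
#' @return `table_path`, invisibly.
#' @export
write_simulation <- function(sim, table_path, truth_path = NULL,
                             refs_path = NULL) {
  write_isolates(sim$table, table_path)
  if (!is.null(truth_path))
    utils::write.csv(sim$truth, truth_path, row.names = FALSE, na = "")
  if (!is.null(refs_path)) write_reference_panel(sim$refs, refs_path)
  invisible(table_path)
}
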