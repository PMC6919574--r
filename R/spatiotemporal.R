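# Clone detection and the space-time behaviour of clones: persistence of a
# genotype inside one winery across vintages, great-circle dispersal
# distances between clone mates, distance-class distributions, regional
# group composition, within-sample group diversity, and 20-year
# vintage-binned temporal dynamics of the genetic groups.

#' Detect clone groups
#'
#' "Clones" are isolates genetically identical at all 12 microsatellite
#' loci. Identity is evaluated on the raw (non-imputed) genotypes, and an
#' isolate with any missing locus cannot be declared identical to another,
#' so such isolates are excluded from multi-member groups and kept as
#' singletons (their count is reported in a warning). Groups are sorted by
#' decreasing size, then by genotype key.
#'
#' @param tab An `isolate_table`.
#' @param min_size Minimum members for a reported group (default 2;
#'   singletons are returned separately).
#' @return Object of class `clone_groups`: list with `groups` (data frame:
#'   `clone_id`, `genotype_key`, `size`, `n_wineries`, `n_countries`,
#'   `vintage_span`), `members` (list of strain-id vectors per group) and
#'   `singletons` (strain ids).
#' @export
find_clone_groups <- function(tab, min_size = 2L) {
  keys <- genotype_keys(tab)
  complete <- rowSums(tab$geno == "") == 0L
  n_incomplete <- sum(!complete)
  if (n_incomplete > 0L)
    warning(n_incomplete, " isolate(s) with missing loci excluded from ",
            "multi-member clone groups (kept as singletons)")
  tab_keys <- ifelse(complete, keys, paste0("__incomplete__", seq_along(keys)))
  split_members <- split(tab$meta$strain_id, tab_keys)
  sizes <- lengths(split_members)
  is_group <- sizes >= min_size & !startsWith(names(split_members),
                                              "__incomplete__")
  groups_keys <- names(split_members)[is_group]
  ord <- order(-sizes[is_group], groups_keys)
  groups_keys <- groups_keys[ord]
  members <- split_members[groups_keys]
  meta <- tab$meta
  info <- lapply(seq_along(groups_keys), function(k) {
    idx <- match(members[[k]], meta$strain_id)
    vint <- meta$vintage_year[idx]
    data.frame(
      clone_id = k, genotype_key = groups_keys[k],
      size = length(idx),
      n_wineries = length(unique(stats::na.omit(meta$winery[idx]))),
      n_countries = length(unique(stats::na.omit(meta$country[idx]))),
      vintage_span = if (sum(!is.na(vint)) >= 2L)
        diff(range(vint, na.rm = TRUE)) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  groups <- if (length(info)) do.call(rbind, info) else
    data.frame(clone_id = integer(0), genotype_key = character(0),
               size = integer(0), n_wineries = integer(0),
               n_countries = integer(0), vintage_span = integer(0))
  names(members) <- NULL
  singles <- unlist(split_members[!is_group], use.names = FALSE)
  structure(list(groups = groups, members = members, singletons = singles),
            class = "clone_groups")
}

#' @export
print.clone_groups <- function(x, ...) {
  cat("<clone_groups> ", nrow(x$groups), " groups of >=2 clones (sizes ",
      if (nrow(x$groups)) paste0(min(x$groups$size), "-", max(x$groups$size))
      else "-", "), ", length(x$singletons), " singletons\n", sep = "")
  invisible(x)
}

#' Winery persistence of clone groups
#'
#' For every (winery, clone group) pair whose members were isolated from
#' wines of at least two distinct vintages, reports the sorted vintages and
#' the persistence interval (newest minus oldest vintage, in years) — the
#' signature of a genotype residing in one cellar across decades.
#'
#' @param clones A `clone_groups` object.
#' @param tab The `isolate_table` the clones were detected in.
#' @return Data frame with columns `winery`, `clone_id`, `n_isolates`,
#'   `vintages` (comma-joined), `interval_years`, sorted by decreasing
#'   interval.
#' @export
winery_persistence <- function(clones, tab) {
  meta <- tab$meta
  rows <- list()
  for (k in seq_along(clones$members)) {
    idx <- match(clones$members[[k]], meta$strain_id)
    ok <- !is.na(meta$winery[idx]) & !is.na(meta$vintage_year[idx])
    if (sum(!ok) > 0L)
      message("clone ", k, ": ", sum(!ok),
              " member(s) lack winery or vintage; skipped")
    idx <- idx[ok]
    if (length(idx) == 0L) next
    for (w in unique(meta$winery[idx])) {
      vint <- sort(unique(meta$vintage_year[idx][meta$winery[idx] == w]))
      if (length(vint) < 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        winery = w, clone_id = k,
        n_isolates = sum(meta$winery[idx] == w),
        vintages = paste(vint, collapse = ","),
        interval_years = max(vint) - min(vint),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(winery = character(0), clone_id = integer(0),
               n_isolates = integer(0), vintages = character(0),
               interval_years = integer(0))
  out[order(-out$interval_years, out$winery, out$clone_id), , drop = FALSE]
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius); no ellipsoidal correction.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km; `NA` where any coordinate is missing.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  ok <- !(is.na(lat1) | is.na(lon1) | is.na(lat2) | is.na(lon2))
  out <- rep(NA_real_, n)
  if (any(ok))
    out[ok] <- geosphere::distHaversine(cbind(lon1, lat1)[ok, , drop = FALSE],
                                        cbind(lon2, lat2)[ok, , drop = FALSE],
                                        r = 6371.0088)
  out
}

#' Pairwise distances between clone mates
#'
#' For each clone group, computes the great-circle distance for every
#' unordered pair of members with known coordinates. Pairs from the same
#' wine sample are deliberately included, which drifts the distribution
#' toward zero; interpret the sub-1 km class accordingly.
#'
#' @param clones A `clone_groups` object.
#' @param tab The matching `isolate_table`.
#' @return Data frame with columns `clone_id`, `strain_a`, `strain_b`,
#'   `km`. Pairs with a missing coordinate are dropped (count messaged).
#' @export
clone_pair_distances <- function(clones, tab) {
  meta <- tab$meta
  rows <- list()
  n_skipped <- 0L
  for (k in seq_along(clones$members)) {
    idx <- match(clones$members[[k]], meta$strain_id)
    if (length(idx) < 2L) next
    pr <- utils::combn(idx, 2L)
    km <- haversine_km(meta$latitude[pr[1, ]], meta$longitude[pr[1, ]],
                       meta$latitude[pr[2, ]], meta$longitude[pr[2, ]])
    drop <- is.na(km)
    n_skipped <- n_skipped + sum(drop)
    if (all(drop)) next
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = k,
      strain_a = meta$strain_id[pr[1, !drop]],
      strain_b = meta$strain_id[pr[2, !drop]],
      km = km[!drop], stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    message(n_skipped, " clone pair(s) lacked coordinates; skipped")
  if (length(rows)) do.call(rbind, rows) else
    data.frame(clone_id = integer(0), strain_a = character(0),
               strain_b = character(0), km = numeric(0))
}

#' Distance-class distribution of clone pairs
#'
#' Bins pair distances into the half-open classes \[0,1), \[1,100),
#' \[100,750), \[750,1000) and \[1000, Inf) km, and derives the "local"
#' fraction (< 100 km, the reach of natural vectors such as insects and
#' birds); larger classes indicate human-mediated transport.
#'
#' @param km Numeric vector of pair distances in km.
#' @return Object of class `distance_classes`: data frame with `class`,
#'   `count`, `fraction`; attribute `local_fraction`.
#' @export
bin_distances <- function(km) {
  breaks <- c(0, 1, 100, 750, 1000, Inf)
  labels <- c("[0,1)", "[1,100)", "[100,750)", "[750,1000)", "[1000,Inf)")
  if (length(km) == 0L) {
    warning("no pair distances; all-zero distribution")
    counts <- rep(0L, length(labels))
    frac <- rep(0, length(labels))
  } else {
    cl <- cut(km, breaks = breaks, labels = labels, right = FALSE,
              include.lowest = FALSE)
    counts <- as.integer(table(cl))
    frac <- counts / sum(counts)
  }
  out <- data.frame(class = labels, count = counts, fraction = frac,
                    stringsAsFactors = FALSE)
  structure(out, class = c("distance_classes", "data.frame"),
            local_fraction = sum(frac[1:2]))
}

#' Regional composition of genetic groups
#'
#' Cross-tabulates isolates by area (region or country) and genetic group,
#' with per-area fractions — the tabular form of per-region group pies.
#'
#' @param tab An `isolate_table` with group labels.
#' @param by `"region"` or `"country"`.
#' @return List with `counts` (area x group integer matrix) and
#'   `fractions` (rows sum to 1).
#' @export
region_group_distribution <- function(tab, by = c("region", "country")) {
  by <- match.arg(by)
  area <- tab$meta[[by]]
  grp <- tab$meta$group_label
  keep <- !is.na(area) & !is.na(grp)
  counts <- table(area = area[keep], group = grp[keep])
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  fractions <- counts / rowSums(counts)
  list(counts = counts, fractions = fractions)
}

#' Within-sample genetic-group diversity
#'
#' For every wine sample with at least `min_isolates` isolates, counts the
#' distinct genetic groups and genotypes found in it. Multiple groups
#' coexisting in one sample is the signature of diverse spoilage
#' populations inside a single wine.
#'
#' @param tab An `isolate_table` with group labels and `sample_id`.
#' @param min_isolates Minimum isolates per sample (default 5).
#' @return Data frame (`sample_id`, `n_isolates`, `n_groups`,
#'   `n_genotypes`, `multi_group`), with attribute `n_multi_group` — the
#'   number of qualifying samples holding >= 2 groups.
#' @export
sample_group_diversity <- function(tab, min_isolates = 5L) {
  keep <- !is.na(tab$meta$sample_id)
  sub <- tab[keep]
  keys <- genotype_keys(sub)
  samples <- split(seq_len(n_isolates(sub)), sub$meta$sample_id)
  samples <- samples[lengths(samples) >= min_isolates]
  rows <- lapply(names(samples), function(s) {
    idx <- samples[[s]]
    grp <- unique(stats::na.omit(sub$meta$group_label[idx]))
    data.frame(sample_id = s, n_isolates = length(idx),
               n_groups = length(grp),
               n_genotypes = length(unique(keys[idx])),
               multi_group = length(grp) >= 2L,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), n_isolates = integer(0),
               n_groups = integer(0), n_genotypes = integer(0),
               multi_group = logical(0))
  structure(out, n_multi_group = sum(out$multi_group))
}

#' 20-year vintage bin of a year
#'
#' Bins are anchored so that 1981--2000 and 2001--2020 are bins; i.e. a bin
#' starts at years congruent to 1 modulo 20 and spans 20 calendar years.
#'
#' @param year Integer year(s), plausible range 1800--2100.
#' @return Character label(s) like `"1981-2000"`.
#' @export
vintage_bin <- function(year) {
  year <- as.integer(year)
  if (any(!is.na(year) & (year < 1800L | year > 2100L)))
    stop("year outside plausible range 1800-2100")
  start <- 20L * ((year - 1L) %/% 20L) + 1L
  ifelse(is.na(year), NA_character_, paste0(start, "-", start + 19L))
}

#' Temporal dynamics of genetic groups over vintages
#'
#' Fractions of each genetic group among the isolates of every 20-year
#' vintage bin, with 95% percentile bootstrap confidence intervals obtained
#' by resampling the isolates of the bin. The vintage (year the wine was
#' produced), not the isolation year, drives the binning: an isolate taken
#' in 2006 from a 1909 wine witnesses the 1909 population.
#'
#' @param tab An `isolate_table` with group labels and vintage years.
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return Data frame with columns `bin`, `group_name`, `n_bin`, `count`,
#'   `fraction`, `ci_lo`, `ci_hi`, bins in chronological order; empty bins
#'   omitted.
#' @export
temporal_group_proportions <- function(tab, n_boot = 100L, seed = 1L) {
  keep <- !is.na(tab$meta$vintage_year) & !is.na(tab$meta$group_label)
  sub <- tab[keep]
  bins <- vintage_bin(sub$meta$vintage_year)
  groups <- sort(unique(sub$meta$group_label))
  bin_levels <- unique(bins[order(sub$meta$vintage_year)])
  rows <- list()
  for (b in bin_levels) {
    lab <- sub$meta$group_label[bins == b]
    n_bin <- length(lab)
    boots <- .with_seed(seed + .str_hash(b) %% 1000L, {
      vapply(seq_len(n_boot), function(r) {
        res <- sample(lab, n_bin, replace = TRUE)
        vapply(groups, function(g) mean(res == g), numeric(1))
      }, numeric(length(groups)))
    })
    if (is.null(dim(boots))) boots <- matrix(boots, nrow = length(groups))
    for (gi in seq_along(groups)) {
      cnt <- sum(lab == groups[gi])
      if (cnt == 0L) next
      ci <- stats::quantile(boots[gi, ], c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, group_name = groups[gi], n_bin = n_bin, count = cnt,
        fraction = cnt / n_bin, ci_lo = ci[1], ci_hi = ci[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
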