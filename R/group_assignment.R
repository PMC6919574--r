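# Putative-ploidy inference and nearest-reference genetic-group assignment.
#
# Microsatellite markers are codominant, so the maximum number of distinct
# alleles seen at any locus bounds the copy number: at most 2 alleles at
# every locus reads as a putative diploid, a locus with 3 alleles flags a
# putative triploid. Each isolate is then assigned to the genetic group
# whose reference genotype it shares the most alleles with.

#' The six published genetic groups
#'
#' Group names, plot colors, reference strains and putative ploidies of the
#' six reference-anchored genetic groups of *Brettanomyces bruxellensis*,
#' in canonical (report and tie-break) order. Reference genotypes are not
#' part of this table; attach them with [reference_panel()].
#'
#' @return Data frame with columns `group_name`, `color`,
#'   `reference_strain_id`, `putative_ploidy`.
#' @export
brett_reference_groups <- function() {
  data.frame(
    group_name = c("Wine 2N", "Wine/Kombucha 2N", "Wine/Beer 3N",
                   "1st Wine 3N", "Tequila/Bioethanol 3N", "2nd Wine 3N"),
    color = c("darkcyan", "lightgreen", "orange", "red", "darkblue",
              "turquoise"),
    reference_strain_id = c("CBS 2499", "L14165", "AWRI1608", "AWRI1499",
                            "CBS 5512", "L0308"),
    putative_ploidy = c(2L, 2L, 3L, 3L, 3L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Build a reference panel
#'
#' A reference panel anchors each genetic group on one reference genotype.
#' Group order is meaningful: assignment ties break toward the earlier
#' group and reports follow panel order.
#'
#' @param groups Data frame with columns `group_name`, `color`,
#'   `reference_strain_id`, `putative_ploidy`.
#' @param genotypes Character matrix of canonical allele-set cells, one row
#'   per group (in `groups` order), columns named by the locus panel.
#' @param panel A [locus_panel()].
#' @return Object of class `reference_panel`: list with `groups` (the
#'   annotated data frame), `panel`, and `geno` (the cell matrix).
#' @export
reference_panel <- function(groups, genotypes, panel) {
  panel <- if (inherits(panel, "locus_panel")) panel else locus_panel(panel)
  need <- c("group_name", "color", "reference_strain_id", "putative_ploidy")
  if (!all(need %in% names(groups)))
    stop("groups needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(groups$group_name))
    stop("group names must be unique")
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(groups))
    stop("one reference genotype row per group required")
  if (!setequal(colnames(genotypes), as.character(panel)))
    stop("reference genotype columns must match the panel")
  genotypes <- genotypes[, as.character(panel), drop = FALSE]
  for (j in seq_len(ncol(genotypes)))
    for (i in seq_len(nrow(genotypes)))
      genotypes[i, j] <- .canonicalize_cell(genotypes[i, j])
  rownames(genotypes) <- groups$group_name
  structure(list(groups = as.data.frame(groups, stringsAsFactors = FALSE),
                 panel = panel, geno = genotypes),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel> ", nrow(x$groups), " groups on ",
      length(x$panel), " loci\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Read / write a reference panel CSV
#'
#' The CSV uses the same locus-column dialect as isolate tables, plus
#' `group_name`, `color`, `reference_strain_id` and `putative_ploidy`
#' columns.
#'
#' @param path CSV path.
#' @param panel A [locus_panel()]; if `NULL`, inferred from the non-group
#'   columns.
#' @return A `reference_panel`.
#' @export
read_reference_panel <- function(path, panel = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  meta <- c("group_name", "color", "reference_strain_id", "putative_ploidy")
  if (!all(meta %in% names(df)))
    stop("reference CSV lacks columns: ",
         paste(setdiff(meta, names(df)), collapse = ", "))
  if (is.null(panel)) panel <- locus_panel(setdiff(names(df), meta))
  groups <- df[, meta]
  groups$putative_ploidy <- as.integer(groups$putative_ploidy)
  reference_panel(groups, as.matrix(df[, as.character(panel), drop = FALSE]),
                  panel)
}

#' @rdname read_reference_panel
#' @param refs A `reference_panel` to write.
#' @export
write_reference_panel <- function(refs, path) {
  df <- cbind(refs$groups,
              as.data.frame(refs$geno, stringsAsFactors = FALSE,
                            row.names = NULL))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Infer putative ploidy from a multilocus genotype
#'
#' The putative ploidy is the maximum number of distinct alleles observed
#' at any locus: 1 or 2 reads as putative diploid (single-allele loci are
#' homozygous, not haploid), 3 as putative triploid. Reported as
#' `max(2, max allele count)` so a fully homozygous genotype is still a
#' putative diploid.
#'
#' @param genotype Named list of integer allele vectors (one per locus).
#' @return Integer putative ploidy (2 or 3).
#' @export
infer_ploidy <- function(genotype) {
  counts <- lengths(genotype)
  if (all(counts == 0L))
    stop("cannot infer ploidy: all loci missing")
  max(2L, max(counts))
}

#' Putative ploidy for every isolate in a table
#'
#' @param tab An `isolate_table`.
#' @return Integer vector named by strain id; `NA` for all-missing
#'   genotypes.
#' @export
table_ploidies <- function(tab) {
  sets <- genotype_sets(tab)
  out <- vapply(sets, function(g) {
    if (all(lengths(g) == 0L)) NA_integer_ else infer_ploidy(g)
  }, integer(1))
  names(out) <- tab$meta$strain_id
  out
}

#' Allele-sharing (Dice) distance between two genotypes
#'
#' Mean over mutually non-missing loci of `1 - 2|A n B| / (|A| + |B|)`.
#' Size-agnostic: only allele identity matters, so diploid and triploid
#' loci are compared on the same footing. Symmetric, zero on identical
#' genotypes, and bounded in \[0, 1\].
#'
#' @param a,b Named lists of integer allele vectors over the same panel.
#' @return Distance in \[0, 1\].
#' @seealso [stepwise_distance()] for a repeat-unit-aware alternative.
#' @export
allele_sharing_distance <- function(a, b) {
  per_locus <- mapply(function(x, y) {
    if (length(x) == 0L || length(y) == 0L) return(NA_real_)
    1 - 2 * length(intersect(x, y)) / (length(x) + length(y))
  }, a, b)
  if (all(is.na(per_locus)))
    stop("genotypes share no mutually non-missing locus")
  mean(per_locus, na.rm = TRUE)
}

#' Stepwise-mutation-aware genotype distance
#'
#' A Bruvo-style alternative to [allele_sharing_distance()]: per locus,
#' alleles of the two sets are greedily matched and each matched pair
#' contributes `1 - 2^(-|size difference| / step)`; unmatched alleles (when
#' set sizes differ) contribute 1. The per-locus mean over matched slots is
#' averaged over mutually non-missing loci. Small size differences (a few
#' repeat units) therefore cost little, which respects the stepwise
#' mutation model of microsatellites.
#'
#' @param a,b Named lists of integer allele vectors over the same panel.
#' @param step Repeat-unit length in bp (default 2).
#' @return Distance in \[0, 1\].
#' @export
stepwise_distance <- function(a, b, step = 2L) {
  per_locus <- mapply(function(x, y) {
    if (length(x) == 0L || length(y) == 0L) return(NA_real_)
    if (length(x) < length(y)) { tmp <- x; x <- y; y <- tmp }
    used <- logical(length(x))
    d <- numeric(0)
    for (al in y) {
      cand <- which(!used)
      j <- cand[which.min(abs(x[cand] - al))]
      used[j] <- TRUE
      d <- c(d, 1 - 2^(-abs(x[j] - al) / step))
    }
    sum_d <- sum(d) + (length(x) - length(y))  # unmatched alleles cost 1
    sum_d / length(x)
  }, a, b)
  if (all(is.na(per_locus)))
    stop("genotypes share no mutually non-missing locus")
  mean(per_locus, na.rm = TRUE)
}

# Pairwise allele-sharing distance matrix between the rows of two cell
# matrices, vectorized through per-locus presence indicators. Loci missing
# in either member of a pair are excluded for that pair; a pair with no
# shared non-missing locus gets NA.
.dice_cross <- function(cells_a, cells_b) {
  loci <- colnames(cells_a)
  na_ <- nrow(cells_a); nb <- nrow(cells_b)
  acc <- matrix(0, na_, nb)
  cnt <- matrix(0L, na_, nb)
  for (l in loci) {
    col_a <- cells_a[, l]; col_b <- cells_b[, l]
    alleles <- unique(unlist(strsplit(c(col_a[col_a != ""],
                                        col_b[col_b != ""]), "/",
                                      fixed = TRUE)))
    if (length(alleles) == 0L) next
    pres <- function(col) {
      m <- matrix(0L, length(col), length(alleles))
      has <- which(col != "")
      if (length(has)) {
        parts <- strsplit(col[has], "/", fixed = TRUE)
        for (k in seq_along(has))
          m[has[k], match(parts[[k]], alleles)] <- 1L
      }
      m
    }
    pa <- pres(col_a); pb <- pres(col_b)
    inter <- pa %*% t(pb)
    sza <- rowSums(pa); szb <- rowSums(pb)
    denom <- outer(sza, szb, "+")
    valid <- outer(sza > 0L, szb > 0L, "&")
    d <- 1 - 2 * inter / denom
    d[!valid] <- 0
    acc <- acc + d
    cnt <- cnt + valid
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Pairwise allele-sharing distance matrix of a table
#'
#' @param tab An `isolate_table`.
#' @return Symmetric numeric matrix (isolates x isolates), `NA` where a
#'   pair shares no non-missing locus.
#' @export
genotype_distance_matrix <- function(tab) {
  d <- .dice_cross(tab$geno, tab$geno)
  dimnames(d) <- list(tab$meta$strain_id, tab$meta$strain_id)
  d
}

#' Assign isolates to their nearest reference group
#'
#' Each isolate is labeled with the genetic group whose reference genotype
#' lies closest under the allele-sharing distance, computed over loci
#' non-missing in both (no imputation: imputed data are reserved for the
#' PCA). Ties break toward the earlier group in the reference panel. The
#' runner-up margin (second-best minus best distance) is reported as a
#' confidence proxy: peripheral, poorly resolved isolates show small
#' margins.
#'
#' @param tab An `isolate_table`.
#' @param refs A [reference_panel()].
#' @return Data frame of class `group_assignment` with columns `strain_id`,
#'   `group_name`, `distance_to_reference`, `runner_up_margin`. Isolates
#'   comparable with no reference are labeled `"unassigned"` with a
#'   warning. The input table with `group_label` filled is attached as
#'   attribute `table`.
#' @export
assign_groups <- function(tab, refs) {
  stopifnot(inherits(refs, "reference_panel"))
  if (!setequal(as.character(refs$panel), as.character(tab$panel)))
    stop("reference panel loci differ from the table's panel")
  d <- .dice_cross(tab$geno, refs$geno[, as.character(tab$panel),
                                       drop = FALSE])
  n <- nrow(d)
  group_names <- refs$groups$group_name
  label <- character(n); best <- numeric(n); margin <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    if (all(is.na(di))) {
      label[i] <- "unassigned"; best[i] <- NA_real_; margin[i] <- NA_real_
      next
    }
    ord <- order(di)  # stable: ties keep panel order
    label[i] <- group_names[ord[1]]
    best[i] <- di[ord[1]]
    margin[i] <- if (length(di) > 1L) di[ord[2]] - di[ord[1]] else NA_real_
  }
  if (any(label == "unassigned"))
    warning(sum(label == "unassigned"),
            " isolate(s) comparable with no reference; labeled unassigned")
  out <- data.frame(strain_id = tab$meta$strain_id, group_name = label,
                    distance_to_reference = best, runner_up_margin = margin,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_assignment", class(out))
  tab$meta$group_label <- label
  attr(out, "table") <- tab
  out
}

#' Table with group labels applied
#'
#' Convenience accessor for the labeled `isolate_table` produced by
#' [assign_groups()].
#'
#' @param assignment A `group_assignment`.
#' @return The labeled `isolate_table`.
#' @export
assigned_table <- function(assignment) attr(assignment, "table")
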