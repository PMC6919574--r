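# Data model and input/output for multilocus microsatellite genotype tables.
#
# A genotype table ("isolate_table") couples a fixed 12-locus panel with one
# row per isolate: provenance metadata plus one allele-set cell per locus.
# Allele sets are stored canonically as "/"-separated ascending integer sizes
# in bp ("228/234/240"); an empty string marks a missing datum.

#' Metadata columns of an isolate table
#'
#' The fixed provenance columns every isolate CSV must carry, in canonical
#' order: strain identifier, winery, wine sample, geography, coordinates,
#' vintage (year the wine was produced) and isolation year, microplate, and
#' the genetic-group label filled in by [assign_groups()].
#' @export
ISOLATE_META_COLS <- c(
  "strain_id", "winery", "sample_id", "region", "country",
  "latitude", "longitude", "vintage_year", "isolation_year",
  "plate_id", "group_label"
)

.META_CHR <- c("strain_id", "winery", "sample_id", "region", "country",
               "plate_id", "group_label")
.META_NUM <- c("latitude", "longitude", "vintage_year", "isolation_year")

#' Define a locus panel
#'
#' A locus panel is the ordered set of microsatellite marker names shared by
#' every genotype in a table. The panel used throughout this package has
#' exactly 12 loci, the number of codominant markers needed to resolve
#' putative ploidy (up to 3 alleles per locus) and clonal identity.
#'
#' @param names Character vector of locus names.
#' @param n_loci Required panel size (default 12).
#' @return Character vector of class `locus_panel`.
#' @export
locus_panel <- function(names, n_loci = 12L) {
  names <- as.character(names)
  if (length(names) != n_loci)
    stop("locus panel must have exactly ", n_loci, " loci, got ", length(names))
  if (anyDuplicated(names))
    stop("locus panel names must be unique")
  if (any(!nzchar(names)) || anyNA(names))
    stop("locus panel names must be non-empty")
  structure(names, class = "locus_panel")
}

#' Parse one allele-set cell
#'
#' Cells hold 0--3 integer allele sizes (bp) separated by "/". An empty
#' string or "NA" is a missing datum. Duplicated sizes (e.g. a homozygous
#' call written twice) collapse to one allele.
#'
#' @param raw Single character cell, e.g. `"228/234/240"`.
#' @param context Optional label (row/column) used in error messages.
#' @return Sorted integer vector of distinct allele sizes; `integer(0)` if
#'   missing.
#' @examples
#' parse_allele_field("228/234/240")
#' parse_allele_field("228/228/234")  # collapses to 228/234
#' parse_allele_field("NA")           # integer(0)
#' @export
parse_allele_field <- function(raw, context = NULL) {
  ctx <- if (is.null(context)) "" else paste0(" [", context, "]")
  if (length(raw) != 1L)
    stop("parse_allele_field() expects a single cell", ctx)
  if (is.na(raw)) return(integer(0))
  raw <- trimws(as.character(raw))
  if (raw == "" || toupper(raw) == "NA") return(integer(0))
  tok <- trimws(strsplit(raw, "/", fixed = TRUE)[[1]])
  tok <- tok[nzchar(tok)]
  if (!all(grepl("^[0-9]+$", tok)))
    stop("non-integer allele token in \"", raw, "\"", ctx)
  sizes <- sort(unique(as.integer(tok)))
  if (any(sizes <= 0L))
    stop("allele sizes must be strictly positive", ctx)
  if (length(sizes) > 3L)
    stop("more than 3 distinct alleles (\"", raw, "\") exceeds the ",
         "triploid bound", ctx)
  sizes
}

#' Format an allele set as a canonical cell string
#'
#' @param alleles Integer vector of allele sizes (possibly empty).
#' @return Canonical cell: ascending sizes joined by "/", `""` if missing.
#' @export
format_allele_set <- function(alleles) {
  if (length(alleles) == 0L) return("")
  paste(sort(unique(as.integer(alleles))), collapse = "/")
}

.canonicalize_cell <- function(raw, context = NULL) {
  format_allele_set(parse_allele_field(raw, context))
}

#' Construct an isolate table
#'
#' Binds a locus panel, a metadata data frame and a genotype cell matrix into
#' the central container of the pipeline. Cells are canonicalized (ascending
#' order, duplicates collapsed) on construction.
#'
#' @param meta Data frame with the columns in [ISOLATE_META_COLS]; missing
#'   columns are added as `NA`.
#' @param geno Character matrix (isolates x loci) of allele-set cells, with
#'   column names equal to the panel.
#' @param panel A [locus_panel()].
#' @return Object of class `isolate_table`: a list with elements `panel`,
#'   `meta` and `geno`.
#' @export
isolate_table <- function(meta, geno, panel) {
  panel <- if (inherits(panel, "locus_panel")) panel else locus_panel(panel)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in setdiff(ISOLATE_META_COLS, names(meta)))
    meta[[col]] <- NA
  meta <- meta[, ISOLATE_META_COLS, drop = FALSE]
  for (col in .META_CHR) meta[[col]] <- as.character(meta[[col]])
  for (col in c("latitude", "longitude")) meta[[col]] <- as.numeric(meta[[col]])
  for (col in c("vintage_year", "isolation_year"))
    meta[[col]] <- as.integer(meta[[col]])
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(meta))
    stop("geno and meta must have the same number of rows")
  if (!setequal(colnames(geno), as.character(panel)))
    stop("genotype columns must match the locus panel")
  geno <- geno[, as.character(panel), drop = FALSE]
  geno[is.na(geno)] <- ""
  # canonicalize unique cell values once; on failure fall back to the slow
  # per-cell pass so the error names the offending strain and locus
  u <- unique(as.vector(geno))
  cu <- tryCatch(vapply(u, .canonicalize_cell, character(1)),
                 error = function(e) NULL)
  if (!is.null(cu)) {
    geno[] <- cu[match(geno, u)]
  } else {
    for (j in seq_len(ncol(geno))) {
      for (i in seq_len(nrow(geno))) {
        geno[i, j] <- .canonicalize_cell(
          geno[i, j],
          context = paste0("strain ", meta$strain_id[i], ", locus ",
                           panel[j]))
      }
    }
  }
  rownames(geno) <- NULL
  rownames(meta) <- NULL
  tab <- structure(list(panel = panel, meta = meta, geno = geno),
                   class = "isolate_table")
  validate_isolate_table(tab)
  tab
}

#' Validate an isolate table's invariants
#'
#' Checks unique strain identifiers, coordinate ranges, the vintage-before-
#' isolation ordering, and the per-cell allele bound.
#'
#' @param tab An `isolate_table`.
#' @return The table, invisibly; errors on violation.
#' @export
validate_isolate_table <- function(tab) {
  stopifnot(inherits(tab, "isolate_table"))
  ids <- tab$meta$strain_id
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("every isolate needs a non-empty strain_id")
  if (anyDuplicated(ids))
    stop("duplicate strain_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lat <- tab$meta$latitude; lon <- tab$meta$longitude
  if (any(!is.na(lat) & (lat < -90 | lat > 90)))
    stop("latitude out of [-90, 90]")
  if (any(!is.na(lon) & (lon < -180 | lon > 180)))
    stop("longitude out of [-180, 180]")
  vy <- tab$meta$vintage_year; iy <- tab$meta$isolation_year
  bad <- !is.na(vy) & !is.na(iy) & vy > iy
  if (any(bad))
    stop("vintage_year after isolation_year for: ",
         paste(ids[bad], collapse = ", "))
  invisible(tab)
}

#' @export
print.isolate_table <- function(x, ...) {
  miss <- sum(x$geno == "")
  cat("<isolate_table> ", nrow(x$meta), " isolates x ",
      length(x$panel), " loci; ", miss, " missing cells (",
      sprintf("%.1f%%", 100 * miss / length(x$geno)), ")\n", sep = "")
  grp <- x$meta$group_label
  if (any(!is.na(grp))) {
    tb <- table(grp, useNA = "no")
    cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of isolates in a table
#' @param tab An `isolate_table`.
#' @return Integer count.
#' @export
n_isolates <- function(tab) nrow(tab$meta)

#' Flatten an isolate table to a data frame
#'
#' @param x An `isolate_table`.
#' @param row.names,optional,... Ignored; present for generic consistency.
#' @return Data frame of metadata columns followed by one character column
#'   per locus.
#' @export
as.data.frame.isolate_table <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  cbind(x$meta, as.data.frame(x$geno, stringsAsFactors = FALSE))
}

#' Subset an isolate table by row
#' @param x An `isolate_table`.
#' @param i Row index (integer or logical).
#' @param ... Ignored.
#' @return The subset `isolate_table`.
#' @export
`[.isolate_table` <- function(x, i, ...) {
  structure(list(panel = x$panel,
                 meta = x$meta[i, , drop = FALSE],
                 geno = x$geno[i, , drop = FALSE]),
            class = "isolate_table")
}

#' Parsed allele sets of a table
#'
#' @param tab An `isolate_table`.
#' @return List (one element per isolate) of named lists mapping locus name
#'   to a sorted integer allele vector (`integer(0)` = missing).
#' @export
genotype_sets <- function(tab) {
  loci <- as.character(tab$panel)
  lapply(seq_len(nrow(tab$geno)), function(i) {
    g <- lapply(tab$geno[i, ], function(cell) {
      if (cell == "") integer(0)
      else as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
    })
    names(g) <- loci
    g
  })
}

#' Canonical genotype key
#'
#' Serializes a multilocus genotype into a deterministic string: loci in
#' panel order joined by "|", alleles ascending joined by "/", a missing
#' locus written as ".". Two genotypes are equal iff their keys are equal,
#' which makes the key the unit of clone identity.
#'
#' @param genotype Named list of integer allele vectors (as returned by
#'   [genotype_sets()]), or a character vector of canonical cells in panel
#'   order.
#' @return Single character key.
#' @export
genotype_key <- function(genotype) {
  if (is.list(genotype)) {
    cells <- vapply(genotype, format_allele_set, character(1))
  } else {
    cells <- vapply(as.character(genotype), .canonicalize_cell, character(1))
  }
  cells[!nzchar(cells)] <- "."
  paste(cells, collapse = "|")
}

#' Genotype keys for every isolate of a table
#'
#' @param tab An `isolate_table`.
#' @return Character vector of keys, one per isolate, named by strain.
#' @export
genotype_keys <- function(tab) {
  cells <- tab$geno
  cells[cells == ""] <- "."
  keys <- apply(cells, 1L, paste, collapse = "|")
  names(keys) <- tab$meta$strain_id
  keys
}

#' Read an isolate CSV
#'
#' Expects a UTF-8 comma-separated file whose header contains every
#' metadata column ([ISOLATE_META_COLS]) and one column per panel locus.
#' Allele cells use "/"-separated integer sizes; empty or "NA" cells are
#' missing data. The count and fraction of missing allele cells is reported
#' on stderr, because missingness feeds the nearest-neighbour imputation
#' step upstream of the PCA.
#'
#' @param path CSV file path.
#' @param panel A [locus_panel()]. If `NULL`, the locus columns are taken to
#'   be every non-metadata column, in file order.
#' @return A validated `isolate_table`.
#' @export
read_isolates <- function(path, panel = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_meta <- setdiff(ISOLATE_META_COLS, names(df))
  if (length(missing_meta))
    stop("isolate CSV lacks metadata columns: ",
         paste(missing_meta, collapse = ", "))
  if (is.null(panel)) {
    panel <- locus_panel(setdiff(names(df), ISOLATE_META_COLS))
  } else {
    panel <- if (inherits(panel, "locus_panel")) panel else locus_panel(panel)
    missing_loci <- setdiff(as.character(panel), names(df))
    if (length(missing_loci))
      stop("isolate CSV lacks locus columns: ",
           paste(missing_loci, collapse = ", "))
  }
  meta <- df[, ISOLATE_META_COLS, drop = FALSE]
  meta[meta == ""] <- NA
  geno <- as.matrix(df[, as.character(panel), drop = FALSE])
  tab <- isolate_table(meta, geno, panel)
  n_missing <- sum(tab$geno == "")
  message(sprintf("read %d isolates x %d loci from %s: %d missing cells (%.2f%%)",
                  n_isolates(tab), length(panel), path, n_missing,
                  100 * n_missing / max(1L, length(tab$geno))))
  tab
}

#' Write an isolate table to CSV
#'
#' Inverse of [read_isolates()]: metadata columns first, then one canonical
#' allele-set column per locus, missing cells written as empty strings.
#' Reading the written file back reproduces the table exactly.
#'
#' @param tab An `isolate_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_isolates <- function(tab, path) {
  validate_isolate_table(tab)
  df <- as.data.frame(tab)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Declare the microplate control strain
#'
#' Genotyping runs spread over many 96-well microplates can drift by a few
#' bp between plates; a control strain genotyped on every plate exposes the
#' per-plate offset relative to a reference plate.
#'
#' @param control_strain_id Strain id of the control. Control replicates on
#'   other plates may carry a `"@<plate_id>"` suffix (e.g. `"AWRI1499@P03"`)
#'   so that strain ids stay unique.
#' @param reference_plate_id Plate whose sizing is taken as the truth.
#' @return Object of class `plate_control`.
#' @export
plate_control <- function(control_strain_id, reference_plate_id) {
  structure(list(control_strain_id = as.character(control_strain_id),
                 reference_plate_id = as.character(reference_plate_id)),
            class = "plate_control")
}

#' Drop microplate control rows from a table
#'
#' Control replicates exist only to expose plate offsets; once
#' [normalize_plates()] has run they should not enter assignment, clone
#' detection or diversity statistics.
#'
#' @param tab An `isolate_table`.
#' @param control A [plate_control()].
#' @return The table without control rows (plate-offset attribute kept).
#' @export
drop_controls <- function(tab, control) {
  keep <- !.is_control_row(tab, control)
  out <- tab[keep]
  attr(out, "plate_offsets") <- attr(tab, "plate_offsets")
  out
}

.is_control_row <- function(tab, control) {
  ids <- tab$meta$strain_id
  ids == control$control_strain_id |
    startsWith(ids, paste0(control$control_strain_id, "@"))
}

# Modal value of an integer vector; ties broken toward the smallest value.
.int_mode <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Normalize allele sizes across microplates
#'
#' For every plate and locus, the offset is the modal difference between the
#' plate's sorted control alleles and the reference plate's sorted control
#' alleles; that integer is subtracted from every allele called at that
#' locus on that plate. The reference plate is untouched and missing cells
#' stay missing. The operation is idempotent: once the control matches the
#' reference everywhere, all offsets are zero.
#'
#' @param tab An `isolate_table` with `plate_id` filled in.
#' @param control A [plate_control()].
#' @param check_only If `TRUE`, no alleles are shifted; only the offset
#'   matrix is computed (attached as attribute `plate_offsets`).
#' @return The normalized `isolate_table`, with a `plate_offsets` attribute:
#'   an integer matrix (plates x loci) of the offsets that were subtracted.
#' @export
normalize_plates <- function(tab, control, check_only = FALSE) {
  stopifnot(inherits(control, "plate_control"))
  plates <- unique(tab$meta$plate_id)
  plates <- plates[!is.na(plates)]
  if (!(control$reference_plate_id %in% plates))
    stop("reference plate ", control$reference_plate_id, " not in table")
  is_ctrl <- .is_control_row(tab, control)
  ctrl_plate <- function(p) {
    idx <- which(is_ctrl & tab$meta$plate_id == p)
    if (length(idx) == 0L)
      stop("control strain ", control$control_strain_id,
           " absent from plate ", p)
    idx[1]
  }
  ref_row <- ctrl_plate(control$reference_plate_id)
  loci <- as.character(tab$panel)
  sets <- genotype_sets(tab)
  offsets <- matrix(0L, nrow = length(plates), ncol = length(loci),
                    dimnames = list(plates, loci))
  for (p in setdiff(plates, control$reference_plate_id)) {
    crow <- ctrl_plate(p)
    for (l in loci) {
      a_ref <- sets[[ref_row]][[l]]
      a_pl <- sets[[crow]][[l]]
      if (length(a_ref) == 0L || length(a_pl) == 0L ||
          length(a_ref) != length(a_pl)) {
        warning("control allele-count mismatch at locus ", l, " on plate ",
                p, "; locus skipped for that plate")
        next
      }
      offsets[p, l] <- .int_mode(sort(a_pl) - sort(a_ref))
    }
  }
  out <- tab
  if (!check_only) {
    for (p in plates) {
      rows <- which(tab$meta$plate_id == p)
      for (l in loci) {
        off <- offsets[p, l]
        if (off == 0L) next
        for (i in rows) {
          cell <- out$geno[i, l]
          if (cell == "") next
          a <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1]]) - off
          out$geno[i, l] <- format_allele_set(a)
        }
      }
    }
  }
  attr(out, "plate_offsets") <- offsets
  out
}
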