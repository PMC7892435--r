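# Data model and I/O for STR marker maps and phased haplotype panels.
#
# The interchange formats are deliberately simple text tables:
#   marker map TSV:  marker  side  dist_cM  repeat_unit  mu
#   haplotype TSV:   chrom_id  family_id  group  independent  <marker1> ...
# PED/MAP import is supported but the two allele columns per locus are taken
# as two ALREADY-PHASED chromosomes, which is not the usual PED semantics.

.sides <- c("proximal", "distal")
.groups <- c("carrier", "control")

#' Construct a marker map
#'
#' A marker map is an ordered table of STR loci flanking a disease locus.
#' Each locus carries its side relative to the mutation (`proximal` or
#' `distal`), its genetic distance from the mutation in centimorgans, its
#' repeat-unit length in bases (2 for dinucleotide, 4 for tetranucleotide
#' repeats) and a per-meiosis mutation rate. Within each side, markers are
#' stored by increasing distance from the mutation, i.e. in the outward
#' order in which an ancestral segment is lost to recombination.
#'
#' @param df data.frame with columns `marker`, `side`, `dist_cM`,
#'   `repeat_unit`, `mu`.
#' @return An object of class `marker_map` (a validated, side-sorted
#'   data.frame with an additional `theta` column, `NA` until a map
#'   function is applied; see [cm_to_theta()]).
#' @seealso [read_marker_map()], [atbp3_marker_map()]
#' @export
marker_map <- function(df) {
  required <- c("marker", "side", "dist_cM", "repeat_unit", "mu")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("marker map lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$marker <- as.character(df$marker)
  df$side <- as.character(df$side)
  if (nrow(df) < 1) stop("marker map must contain at least one marker")
  if (anyDuplicated(df$marker)) {
    stop("duplicate marker name(s): ",
         paste(unique(df$marker[duplicated(df$marker)]), collapse = ", "))
  }
  bad_side <- !df$side %in% .sides
  if (any(bad_side)) {
    stop("unknown side token '", df$side[which(bad_side)[1]],
         "' for marker ", df$marker[which(bad_side)[1]],
         " (expected 'proximal' or 'distal')")
  }
  if (any(!is.finite(df$dist_cM) | df$dist_cM <= 0)) {
    stop("non-positive genetic distance for marker ",
         df$marker[which(!is.finite(df$dist_cM) | df$dist_cM <= 0)[1]])
  }
  if (any(!is.finite(df$mu) | df$mu < 0 | df$mu >= 1)) {
    stop("mutation rate must satisfy 0 <= mu < 1")
  }
  # outward order: proximal block then distal block, each ascending dist_cM
  df <- df[order(match(df$side, .sides), df$dist_cM), , drop = FALSE]
  for (s in .sides) {
    d <- df$dist_cM[df$side == s]
    if (any(diff(d) <= 0)) {
      stop("distances within side '", s, "' must be strictly increasing ",
           "(two markers at the same cM position?)")
    }
  }
  df$theta <- NA_real_
  rownames(df) <- NULL
  structure(df, class = c("marker_map", "data.frame"))
}

#' Read a marker map from TSV
#'
#' @param path path to a tab-separated file with header
#'   `marker side dist_cM repeat_unit mu`.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop("marker map file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse marker map ", path, ": ",
                             conditionMessage(e))
  )
  tryCatch(marker_map(df), error = function(e) {
    stop("invalid marker map in ", path, ": ", conditionMessage(e))
  })
}

#' Attach recombination fractions to a map
#'
#' Converts each marker's `dist_cM` to a recombination fraction using the
#' chosen map function and stores it in the `theta` column.
#'
#' @param map a [marker_map()].
#' @param map_function `"linear"` (theta = cM/100, the package default),
#'   `"haldane"` or `"kosambi"`. See [cm_to_theta()].
#' @return The map with `theta` filled in.
#' @export
set_map_theta <- function(map, map_function = c("linear", "haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  map$theta <- cm_to_theta(map$dist_cM, map_function)
  map
}

#' Markers on one side of the mutation, in outward order
#'
#' @param map a [marker_map()].
#' @param side `"proximal"` or `"distal"`.
#' @return The rows of `map` on that side, ordered by increasing distance.
#' @export
map_side <- function(map, side = c("proximal", "distal")) {
  side <- match.arg(side)
  map[map$side == side, , drop = FALSE]
}

#' @export
print.marker_map <- function(x, ...) {
  cat("Marker map:", nrow(x), "STR loci (",
      sum(x$side == "proximal"), "proximal,",
      sum(x$side == "distal"), "distal )\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Construct a phased haplotype set
#'
#' @param map a [marker_map()].
#' @param records data.frame with columns `chrom_id`, `family_id`, `group`
#'   (`carrier` or `control`), `independent` (logical), then one integer
#'   allele column per map marker (`NA` = missing). Carrier records describe
#'   the mutation-bearing chromosome only.
#' @return An object of class `haplotype_set`: a list with elements `map`
#'   and `records` (allele columns reordered to match the map).
#' @export
haplotype_set <- function(map, records) {
  stopifnot(inherits(map, "marker_map"))
  meta <- c("chrom_id", "family_id", "group", "independent")
  missing_cols <- setdiff(meta, names(records))
  if (length(missing_cols) > 0) {
    stop("haplotype records lack column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(records), meta)
  if (!setequal(extra, map$marker)) {
    stop("allele columns do not match the marker map (missing: ",
         paste(setdiff(map$marker, extra), collapse = ", "),
         "; unexpected: ", paste(setdiff(extra, map$marker), collapse = ", "),
         ")")
  }
  records <- as.data.frame(records)[c(meta, map$marker)]
  records$chrom_id <- as.character(records$chrom_id)
  records$family_id <- as.character(records$family_id)
  records$group <- as.character(records$group)
  records$independent <- as.logical(records$independent)
  if (nrow(records) > 0) {
    if (any(!records$group %in% .groups)) {
      stop("group must be 'carrier' or 'control' (row ",
           which(!records$group %in% .groups)[1], ")")
    }
    if (anyDuplicated(records$chrom_id)) stop("duplicate chrom_id")
    for (m in map$marker) {
      v <- records[[m]]
      if (!is.numeric(v) && !all(is.na(v))) {
        stop("non-integer allele in column ", m)
      }
      v <- suppressWarnings(as.integer(v))
      bad <- !is.na(records[[m]]) & (is.na(v) | v <= 0 |
               suppressWarnings(as.numeric(records[[m]])) != v)
      if (any(bad)) {
        stop("allele values must be positive integers (column ", m,
             ", row ", which(bad)[1], ")")
      }
      records[[m]] <- v
    }
  } else {
    for (m in map$marker) records[[m]] <- integer(0)
  }
  rownames(records) <- NULL
  structure(list(map = map, records = records), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  r <- x$records
  cat("Phased haplotype set:", nrow(r), "chromosomes (",
      sum(r$group == "carrier"), "carrier /",
      sum(r$group == "control"), "control ),",
      nrow(x$map), "markers\n")
  cat("Independent carrier chromosomes:",
      sum(r$group == "carrier" & r$independent), "\n")
  invisible(x)
}

#' Read phased haplotypes
#'
#' Two dialects are supported.
#'
#' * `tsv`: one row per phased chromosome with columns `chrom_id`,
#'   `family_id`, `group`, `independent`, then one integer column per
#'   marker (`NA` for missing alleles).
#' * `pedmap`: a standard PED/MAP pair. **The two allele columns per locus
#'   are treated as two already-phased chromosomes** — PED files are
#'   normally unphased, so only use this dialect for panels that were
#'   phased upstream (e.g. through family members). The PED phenotype
#'   column sets the group (2 = carrier, 1 = control); both chromosomes of
#'   an individual inherit it, so for carrier individuals keep only the
#'   mutation-bearing chromosome downstream or pre-filter the file.
#'
#' @param path path to the haplotype TSV (or the PED file for `pedmap`).
#' @param map a [marker_map()].
#' @param dialect `"tsv"` or `"pedmap"`.
#' @param map_path for `pedmap`: path to the companion MAP file naming the
#'   loci in PED column order (second MAP column = marker name).
#' @return A [haplotype_set()].
#' @export
read_haplotypes <- function(path, map, dialect = c("tsv", "pedmap"),
                            map_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("haplotype file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (nrow(df) == 0 && ncol(df) == 0) stop("empty haplotype file: ", path)
    meta <- c("chrom_id", "family_id", "group", "independent")
    for (m in setdiff(names(df), meta)) {
      v <- df[[m]]
      num <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & v != "NA" & is.na(num)
      if (any(bad)) {
        stop("non-integer allele '", v[which(bad)[1]], "' at row ",
             which(bad)[1], ", column ", m, " of ", path)
      }
      df[[m]] <- num
    }
    if (nrow(df) > 0) df$independent <- as.logical(df$independent)
    else df$independent <- logical(0)
    return(haplotype_set(map, df))
  }
  # pedmap
  if (is.null(map_path)) stop("pedmap dialect requires map_path")
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  loci <- utils::read.table(map_path, stringsAsFactors = FALSE)
  locus_names <- as.character(loci[[min(2, ncol(loci))]])
  ped <- utils::read.table(path, stringsAsFactors = FALSE)
  if (nrow(ped) == 0) stop("empty PED file: ", path)
  expected_cols <- 6 + 2 * length(locus_names)
  if (ncol(ped) != expected_cols) {
    stop("PED file has ", ncol(ped), " columns; expected ", expected_cols,
         " for ", length(locus_names), " loci")
  }
  recs <- vector("list", 2 * nrow(ped))
  for (i in seq_len(nrow(ped))) {
    fam <- as.character(ped[i, 1]); ind <- as.character(ped[i, 2])
    pheno <- as.integer(ped[i, 6])
    group <- if (!is.na(pheno) && pheno == 2) "carrier" else "control"
    for (h in 1:2) {
      alleles <- as.numeric(ped[i, 6 + 2 * seq_along(locus_names) - 2 + h])
      alleles[alleles == 0] <- NA  # PED missing code
      row <- as.list(alleles)
      names(row) <- locus_names
      recs[[2 * (i - 1) + h]] <- c(
        list(chrom_id = paste0(fam, "_", ind, "_", c("A", "B")[h]),
             family_id = fam, group = group, independent = TRUE),
        row)
    }
  }
  records <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  haplotype_set(map, records)
}

#' Write a haplotype set to canonical TSV
#'
#' Round-trips exactly: `read_haplotypes(write_haplotypes(x), map)`
#' reproduces `x` field for field, missing alleles included.
#'
#' @param set a [haplotype_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(set, path) {
  stopifnot(inherits(set, "haplotype_set"))
  utils::write.table(set$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' The packaged SERPINC1 eight-marker STR panel
#'
#' The map of eight microsatellites flanking the antithrombin gene used to
#' date the Budapest 3 founder allele: five proximal (D1S2790, D1S1165,
#' D1S2815, D1S196, D1S460) and three distal (D1S218, D1S2659, D1S212)
#' loci, with distances in centimorgans from the mutation and per-class
#' stepwise mutation rates (2.1e-3 for the tetranucleotide D1S1165, 5.6e-4
#' for the dinucleotide repeats).
#'
#' @return A [marker_map()] of 8 loci.
#' @export
atbp3_marker_map <- function() {
  read_marker_map(system.file("extdata", "atbp3_markers.tsv",
                              package = "founderage", mustWork = TRUE))
}

#' Published per-marker LD table for the Budapest 3 allele
#'
#' The printed per-marker Bengtsson-Thomson delta values with their
#' centimorgan distances, as a data.frame usable by
#' [moment_age_from_delta()].
#'
#' @return data.frame with columns `marker`, `dist_cM`, `delta`.
#' @export
atbp3_delta_table <- function() {
  utils::read.delim(system.file("extdata", "atbp3_table1_delta.tsv",
                                package = "founderage", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' The conserved ancestral Budapest 3 haplotype
#'
#' The fully conserved founder haplotype observed on independent carrier
#' chromosomes; D1S218 is bi-allelic (repeat numbers 24 and 25).
#'
#' @return An [ancestral_haplotype()].
#' @export
atbp3_ancestral <- function() {
  df <- utils::read.delim(system.file("extdata", "atbp3_ancestral.tsv",
                                      package = "founderage", mustWork = TRUE),
                          stringsAsFactors = FALSE)
  sets <- lapply(strsplit(df$alleles, "/", fixed = TRUE), as.integer)
  names(sets) <- df$marker
  ancestral_haplotype(sets, atbp3_marker_map())
}
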