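#' Codominant multi-locus genotype table
#'
#' The central container for microsatellite data: one row per individual,
#' an unordered pair of positive-integer allele codes per locus (0 = missing),
#' plus population, generation (parent/offspring), maternal-family and
#' coordinate metadata.
#'
#' @param samples character vector of unique sample IDs.
#' @param population population label per sample.
#' @param generation `"parent"` or `"offspring"` per sample.
#' @param mother maternal sample ID per sample, `NA` for none. Every
#'   non-missing reference must resolve to a sample with
#'   `generation == "parent"`.
#' @param alleles integer matrix with `2 * length(loci)` columns; columns
#'   `2j - 1` and `2j` hold the allele pair at locus `j`. Both entries of a
#'   pair are 0 (missing) or both are positive.
#' @param loci character vector of locus names.
#' @param lat,lon optional numeric coordinates per sample (decimal degrees or
#'   planar units, see `coord_type`).
#' @param coord_type `"latlon"` or `"planar"`. The study's field collections
#'   carry decimal lat/lon; simulations use planar coordinates.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, population, generation, mother,
                           alleles, loci,
                           lat = NULL, lon = NULL,
                           coord_type = c("planar", "latlon")) {
  coord_type <- match.arg(coord_type)
  n <- length(samples)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  population <- rep_len(as.character(population), n)
  generation <- rep_len(as.character(generation), n)
  if (!all(generation %in% c("parent", "offspring")))
    stop("generation must be 'parent' or 'offspring'")
  mother <- rep_len(as.character(mother), n)
  mother[!is.na(mother) & mother == ""] <- NA_character_
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != n) stop("alleles must have one row per sample")
  if (ncol(alleles) %% 2L != 0L)
    stop("odd allele-column count: expected two columns per locus")
  if (ncol(alleles) != 2L * length(loci))
    stop("allele columns do not match locus count")
  if (any(alleles < 0L, na.rm = TRUE) || anyNA(alleles))
    stop("allele codes must be non-negative integers (0 = missing)")
  a1 <- alleles[, seq(1L, ncol(alleles), by = 2L), drop = FALSE]
  a2 <- alleles[, seq(2L, ncol(alleles), by = 2L), drop = FALSE]
  if (any((a1 == 0L) != (a2 == 0L)))
    stop("half-missing genotype: allele pair mixes 0 with a present allele")
  bad <- !is.na(mother) & !(mother %in% samples[generation == "parent"])
  if (any(bad))
    stop("unresolvable mother ID: ", paste(unique(mother[bad]), collapse = ", "))
  if (is.null(lat)) lat <- rep(NA_real_, n)
  if (is.null(lon)) lon <- rep(NA_real_, n)
  colnames(alleles) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  structure(
    list(samples = samples, population = population, generation = generation,
         mother = mother, lat = as.numeric(rep_len(lat, n)),
         lon = as.numeric(rep_len(lon, n)), loci = as.character(loci),
         alleles = alleles, coord_type = coord_type),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples, %d loci, %d populations\n",
              length(x$samples), length(x$loci),
              length(unique(x$population))))
  cat(sprintf("  parents: %d, offspring: %d, families: %d\n",
              sum(x$generation == "parent"),
              sum(x$generation == "offspring"),
              length(unique(stats::na.omit(x$mother)))))
  invisible(x)
}

#' Number of samples in a genotype table
#' @param gt a [genotype_table()].
#' @return integer count.
#' @export
n_samples <- function(gt) length(gt$samples)

#' Subset a genotype table by row
#'
#' Mother links pointing outside the subset are severed (set to `NA`) so the
#' result is always a valid table.
#'
#' @param gt a [genotype_table()].
#' @param idx logical or integer row index.
#' @return a `genotype_table`.
#' @export
subset_genotypes <- function(gt, idx) {
  keep <- seq_along(gt$samples)[idx]
  mother <- gt$mother[keep]
  mother[!is.na(mother) & !(mother %in% gt$samples[keep])] <- NA_character_
  genotype_table(gt$samples[keep], gt$population[keep], gt$generation[keep],
                 mother, gt$alleles[keep, , drop = FALSE], gt$loci,
                 lat = gt$lat[keep], lon = gt$lon[keep],
                 coord_type = gt$coord_type)
}

#' Allele pair matrix for one locus
#' @param gt a [genotype_table()].
#' @param locus locus name or index.
#' @return integer matrix with two columns (0 = missing).
#' @export
locus_alleles <- function(gt, locus) {
  j <- if (is.character(locus)) match(locus, gt$loci) else as.integer(locus)
  if (is.na(j) || j < 1L || j > length(gt$loci)) stop("unknown locus")
  gt$alleles[, c(2L * j - 1L, 2L * j), drop = FALSE]
}

#' Read a genotype table from CSV
#'
#' Dialect: header row with columns `sample, population, generation, mother,
#' lat, lon` followed by paired allele columns `<locus>_1, <locus>_2`.
#' Missing alleles are coded 0; missing mother/coordinates are empty fields.
#'
#' @param path file path.
#' @param coord_type `"latlon"` or `"planar"`; recorded on the table since a
#'   CSV cannot distinguish the two.
#' @return a [genotype_table()], row order preserved.
#' @export
load_genotype_table <- function(path, coord_type = c("planar", "latlon")) {
  coord_type <- match.arg(coord_type)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample = "character",
                                       mother = "character"))
  meta <- c("sample", "population", "generation", "mother", "lat", "lon")
  if (!all(meta %in% names(df)))
    stop("genotype CSV must contain columns: ", paste(meta, collapse = ", "))
  acols <- setdiff(names(df), meta)
  if (length(acols) == 0L) stop("no allele columns found")
  if (length(acols) %% 2L != 0L)
    stop("odd allele-column count: expected <locus>_1,<locus>_2 pairs")
  loci <- unique(sub("_[12]$", "", acols))
  expect <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  if (!identical(sort(acols), sort(expect)) || !identical(acols, expect))
    stop("allele columns must be ordered <locus>_1,<locus>_2 per locus")
  genotype_table(df$sample, df$population, df$generation, df$mother,
                 as.matrix(df[expect]), loci,
                 lat = df$lat, lon = df$lon, coord_type = coord_type)
}

#' Write a genotype table as CSV
#'
#' Emits the exact dialect [load_genotype_table()] reads, so a write/read
#' round trip is the identity.
#'
#' @param gt a [genotype_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  df <- data.frame(sample = gt$samples, population = gt$population,
                   generation = gt$generation,
                   mother = ifelse(is.na(gt$mother), "", gt$mother),
                   lat = gt$lat, lon = gt$lon,
                   gt$alleles, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
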