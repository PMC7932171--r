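#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF whose GT fields are phased (`|` separator), assigns each
#' variant a genetic position by linear interpolation of the supplied map,
#' and returns a [haplotype_panel()]. Multi-allelic records and (by
#' default) records with missing genotypes are dropped; an unphased GT is
#' an error naming the first offending record.
#'
#' @param path path to an uncompressed VCF file.
#' @param genetic_map data.frame as from [read_genetic_map()], covering all
#'   chromosomes present in the VCF.
#' @param missing how to treat records with missing genotypes:
#'   `"drop-variant"` (default) removes the record, `"reject-file"` errors.
#' @return a `haplotype_panel`.
#' @export
read_phased_vcf <- function(path, genetic_map, missing = c("drop-variant", "reject-file")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  ids <- colnames(gt)

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  alt <- as.character(fix[, "ALT"])

  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    first <- which(unphased, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unphased genotype at %s:%d (sample %s)",
      chrom[first[1]], pos[first[1]], ids[first[2]]
    ))
  }

  keep <- !grepl(",", alt, fixed = TRUE)  # biallelic only
  miss_row <- apply(gt, 1, function(r) any(is.na(r) | grepl(".", r, fixed = TRUE)))
  if (any(miss_row)) {
    if (missing == "reject-file") {
      i <- which(miss_row)[1]
      stop(sprintf("missing genotype at %s:%d", chrom[i], pos[i]))
    }
    keep <- keep & !miss_row
  }
  if (!any(keep)) stop("no usable biallelic phased records in ", path)

  chrom <- chrom[keep]; pos <- pos[keep]; gt <- gt[keep, , drop = FALSE]

  n_ind <- length(ids)
  chroms <- list()
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    sel <- sel[order(pos[sel])]
    L <- length(sel)
    H <- matrix(0L, nrow = 2L * n_ind, ncol = L)
    for (j in seq_len(L)) {
      parts <- strsplit(gt[sel[j], ], "|", fixed = TRUE)
      a <- vapply(parts, function(p) as.integer(p[1]), integer(1))
      b <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      H[seq(1L, 2L * n_ind, by = 2L), j] <- a
      H[seq(2L, 2L * n_ind, by = 2L), j] <- b
    }
    chroms[[cc]] <- list(
      positions = pos[sel],
      cm = interpolate_cm(genetic_map, cc, pos[sel]),
      haplotypes = H
    )
  }
  haplotype_panel(chroms, ids)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits an uncompressed, minimal VCFv4.2 file (GT only, phased) that
#' round-trips through [read_phased_vcf()] losslessly. Missing alleles are
#' written as `.`.
#'
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=finescale",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individual_ids), collapse = "\t")
  ), con)
  for (nm in names(panel$chromosomes)) {
    ch <- panel$chromosomes[[nm]]
    H <- ch$haplotypes
    Hc <- ifelse(is.na(H), ".", as.character(H))
    i1 <- seq(1L, nrow(H), by = 2L)
    for (j in seq_along(ch$positions)) {
      gtj <- paste(Hc[i1, j], Hc[i1 + 1L, j], sep = "|")
      writeLines(paste(c(
        nm, ch$positions[j], paste0(nm, "_", ch$positions[j]),
        "A", "G", ".", "PASS", ".", "GT", gtj
      ), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Tab-separated table with header; expected columns `id`, `birth_year`,
#' `x`, `y` (birth coordinates, km on a planar grid), optional
#' `parent1_x`, `parent1_y`, `parent2_x`, `parent2_y`, `region`,
#' `municipality_id`. Empty fields become `NA`.
#'
#' @param path path to the TSV.
#' @param birth_year_range allowed birth-year span (inclusive); rows outside
#'   it are an error.
#' @return a data.frame.
#' @export
read_sample_metadata <- function(path, birth_year_range = c(1923, 1987)) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("id", "birth_year") %in% names(md))) {
    stop("metadata needs at least columns id, birth_year")
  }
  md$id <- as.character(md$id)
  bad <- !is.na(md$birth_year) &
    (md$birth_year < birth_year_range[1] | md$birth_year > birth_year_range[2])
  if (any(bad)) {
    stop("birth_year outside configured span for ids: ",
         paste(utils::head(md$id[bad], 5), collapse = ", "))
  }
  num_cols <- intersect(
    c("x", "y", "parent1_x", "parent1_y", "parent2_x", "parent2_y"), names(md))
  for (cl in num_cols) {
    if (any(is.infinite(md[[cl]]), na.rm = TRUE)) stop("non-finite coordinate in ", cl)
  }
  md
}

#' Read a municipality table
#'
#' Tab-separated table with header and columns `municipality_id`, `name`,
#' `x`, `y` (planar centre coordinates, km).
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
read_municipalities <- function(path) {
  mt <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("municipality_id", "name", "x", "y")
  if (!all(need %in% names(mt))) {
    stop("municipality table needs columns ", paste(need, collapse = ", "))
  }
  mt
}
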