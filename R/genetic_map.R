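#' Read a genetic map
#'
#' Reads a whitespace-delimited recombination map with columns
#' `chrom`, `position` (bp), `rate` (cM/Mb) and `map` (cM), one row per
#' map point, in the conventional HapMap-style layout.
#'
#' @param path path to the map file (plain text, header line required).
#' @return a data.frame with columns `chrom`, `position`, `rate`, `map`.
#' @export
read_genetic_map <- function(path) {
  gm <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(gm) < 4L) stop("genetic map needs columns chrom, position, rate, map")
  names(gm)[1:4] <- c("chrom", "position", "rate", "map")
  gm$chrom <- as.character(gm$chrom)
  gm
}

#' Build a uniform-rate genetic map
#'
#' Convenience constructor for synthetic genomes: each chromosome gets two
#' map points (start and end) at a constant rate, so interpolation is linear
#' in physical position.
#'
#' @param chrom_lengths_bp named numeric vector of chromosome lengths (bp).
#' @param rate_cm_per_mb recombination rate, cM per Mb (default 1).
#' @return a data.frame in the same layout as [read_genetic_map()].
#' @export
uniform_genetic_map <- function(chrom_lengths_bp, rate_cm_per_mb = 1) {
  stopifnot(length(chrom_lengths_bp) >= 1L, all(chrom_lengths_bp > 0))
  if (is.null(names(chrom_lengths_bp))) {
    names(chrom_lengths_bp) <- paste0("chr", seq_along(chrom_lengths_bp))
  }
  do.call(rbind, lapply(names(chrom_lengths_bp), function(nm) {
    len <- chrom_lengths_bp[[nm]]
    data.frame(
      chrom = nm,
      position = c(1, len),
      rate = rate_cm_per_mb,
      map = c(0, (len - 1) / 1e6 * rate_cm_per_mb),
      stringsAsFactors = FALSE
    )
  }))
}

#' Interpolate genetic positions for physical positions
#'
#' Linear interpolation of the cumulative map (cM) at the requested bp
#' positions; positions outside the map span are clamped to the nearest
#' map endpoint with a warning.
#'
#' @param genetic_map data.frame as returned by [read_genetic_map()].
#' @param chrom chromosome label.
#' @param positions physical positions (bp).
#' @return numeric vector of cM positions.
#' @export
interpolate_cm <- function(genetic_map, chrom, positions) {
  gm <- genetic_map[genetic_map$chrom == chrom, , drop = FALSE]
  if (!nrow(gm)) stop("genetic map has no points for chromosome ", chrom)
  gm <- gm[order(gm$position), , drop = FALSE]
  if (any(positions < min(gm$position)) || any(positions > max(gm$position))) {
    warning("positions outside map span on ", chrom, "; clamped to map endpoints")
  }
  if (nrow(gm) == 1L) return(rep(gm$map, length(positions)))
  stats::approx(gm$position, gm$map, xout = positions, rule = 2)$y
}
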