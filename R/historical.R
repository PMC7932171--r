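#' Historical Karelian evacuee counts by region (1950)
#'
#' Public historical statistics used to contextualize the war-time
#' migration signal: per region, the 1950 total population, the number of
#' resettled Karelian evacuees, and the evacuee proportion as convention
#' rounds it (two decimals).
#'
#' @return data.frame with columns `region`, `total_population`,
#'   `n_evacuees`, `printed_proportion`, plus `proportion` recomputed from
#'   the counts.
#' @export
evacuee_table <- function() {
  path <- system.file("extdata", "evacuees_1950.tsv", package = "finescale")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$proportion <- tab$n_evacuees / tab$total_population
  tab
}
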