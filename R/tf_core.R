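# Preserved transcription factors: TFs whose expression is maintained across
# a large fraction of a population's cells.

#' Select preserved transcription factors for one population
#'
#' Among the measured TFs (those with a regulon and present in the matrix),
#' each TF's expressed-cell fraction is computed and the TFs in the top tail
#' are kept. Two readings of the cut are supported:
#'
#' * `mode = "distribution"` (default): keep TFs whose fraction is at least
#'   the `percentile` quantile (type 7, linear interpolation) of the TF
#'   fraction distribution — the top 5% of TFs at the default 0.95.
#' * `mode = "absolute"`: keep TFs expressed in at least a `percentile`
#'   fraction of cells (e.g. in >= 95% of cells at 0.95).
#'
#' With the inclusive comparison at least one TF is returned whenever any TF
#' has a positive fraction (in distribution mode the maximum always clears
#' its own quantile).
#'
#' @param profile a `population_profile`.
#' @param tfs character vector of TF symbols (the regulon keys).
#' @param percentile quantile (distribution mode) or fraction cutoff
#'   (absolute mode); default 0.95.
#' @param mode `"distribution"` or `"absolute"`.
#' @return object of class `preserved_tfs`: list with `population`, `tfs`
#'   (sorted by expressed fraction descending, ties by symbol), and
#'   `threshold_fraction` (the applied cut).
#' @export
preserved_tfs <- function(profile, tfs, percentile = 0.95,
                          mode = c("distribution", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(percentile >= 0, percentile <= 1)
  measured <- intersect(tfs, profile$gene)
  if (length(measured) == 0L) {
    abort_validation("no regulon TF is measured in population %s",
                     attr(profile, "population"))
  }
  frac <- profile[measured, "expressed_fraction"]
  names(frac) <- measured
  if (all(frac == 0)) {
    abort_validation("all measured TFs have zero expressed fraction in population %s",
                     attr(profile, "population"))
  }
  cut <- if (mode == "distribution") {
    stats::quantile(frac, probs = percentile, type = 7, names = FALSE)
  } else {
    percentile
  }
  keep <- frac >= cut
  kept <- names(frac)[keep]
  ord <- order(-frac[kept], kept)
  structure(list(population = attr(profile, "population"),
                 tfs = kept[ord],
                 threshold_fraction = cut),
            class = "preserved_tfs")
}

#' @export
print.preserved_tfs <- function(x, ...) {
  cat("preserved_tfs[", x$population, "]: ", length(x$tfs),
      " TF(s) at fraction >= ", signif(x$threshold_fraction, 4), "\n", sep = "")
  invisible(x)
}
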