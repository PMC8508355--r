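# Full 490-feature extraction: graph (441) + stochastic geometry (39) +
# information theory (6) + fractality (4), in that fixed order.

#' Feature schema
#'
#' @return data.frame with columns `name` and `family`
#'   (graph/pointprocess/entropy/fractal), 490 rows, in extraction order.
#' @export
feature_schema <- function() {
  gnames <- character(0)
  for (t in GRAPH_THRESHOLDS_UM) {
    for (metric in LOCAL_METRICS)
      gnames <- c(gnames, sprintf("g%d_%s_%s", t, metric, SUMMARY_STATS))
    gnames <- c(gnames, sprintf("g%d_%s", t, GLOBAL_METRICS))
  }
  pnames <- c("pp_intensity", sprintf("pp_K_%g", PP_RADII_UM),
              sprintf("pp_L_%g", PP_RADII_UM))
  enames <- sprintf("H_%gum", ENTROPY_SIDES_UM)
  fnames <- c("frac_boxcount", "frac_higuchi_h", "frac_higuchi_v",
              "frac_higuchi_avg")
  data.frame(
    name = c(gnames, pnames, enames, fnames),
    family = c(rep("graph", length(gnames)),
               rep("pointprocess", length(pnames)),
               rep("entropy", length(enames)),
               rep("fractal", length(fnames))),
    stringsAsFactors = FALSE)
}

#' Extract the full 490-feature vector of a cell pattern
#'
#' @param pattern `cell_pattern`.
#' @param resolution_um_per_px pixel size used for the fractal projection
#'   series.
#' @return named numeric vector of length 490 matching [feature_schema()].
#' @export
extract_features <- function(pattern, resolution_um_per_px = 0.454) {
  out <- c(graph_feature_block(pattern),
           pp_feature_block(pattern),
           entropy_block(pattern),
           fractal_block(pattern, resolution_um_per_px))
  stopifnot(identical(names(out), feature_schema()$name))
  out
}
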