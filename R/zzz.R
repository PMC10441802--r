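#' @useDynLib bmaclust, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom mclust Mclust mclustBIC adjustedRandIndex
#' @importFrom stats dist hclust kmeans cutree quantile
NULL

.onLoad <- function(libname, pkgname) {
  register_civi("ch", calinski_harabasz, "maximise")
  register_civi("ch_pairwise", calinski_harabasz_pairwise, "maximise")
  register_civi("sdbw", s_dbw, "minimise")
  register_civi("silhouette", function(features, labels) {
    mean(cluster::silhouette(labels, stats::dist(features))[, "sil_width"])
  }, "maximise")
}
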