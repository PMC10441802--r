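#' Export model weights as JSON
#'
#' Writes one JSON object per model: raw index score, normalised weight,
#' and the index name and direction used. Requires \pkg{jsonlite}.
#'
#' @param weights a \code{bma_weights} object.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_weights <- function(weights, file) {
  stopifnot(inherits(weights, "bma_weights"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write JSON")
  out <- lapply(seq_len(nrow(weights)), function(i)
    list(raw = weights$raw[i], normalised = weights$weight[i],
         index = attr(weights, "index"),
         direction = attr(weights, "direction")))
  names(out) <- weights$model
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Export a model-averaged clustering fit
#'
#' Writes the per-observation results (allocation probabilities, hard
#' label, uncertainty) as CSV and, optionally, a JSON run summary (model
#' weights, surviving clusters, iterations, final objective).
#'
#' @param fit a \code{bmaclust} object.
#' @param file CSV path for the per-observation table.
#' @param summary_file optional JSON path for the run summary (requires
#'   \pkg{jsonlite}).
#' @return \code{file}, invisibly.
#' @export
write_ensemble_result <- function(fit, file, summary_file = NULL) {
  stopifnot(inherits(fit, "bmaclust"))
  df <- data.frame(id = paste0("obs_", seq_len(fit$n_obs)),
                   fit$allocations, label = fit$labels,
                   uncertainty = fit$uncertainty, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(summary_file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write JSON")
    s <- list(models = fit$input_models$model,
              input_k = fit$input_models$k,
              weights = fit$weights$weight,
              raw_scores = fit$weights$raw,
              index = attr(fit$weights, "index"),
              k_bma = fit$k_bma,
              surviving_clusters = fit$surviving_clusters,
              iterations = length(fit$objective_trace) - 1L,
              objective = fit$objective,
              converged = fit$converged)
    jsonlite::write_json(s, summary_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
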