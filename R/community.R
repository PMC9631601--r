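## Community-level pond importance: per-species abundances scaled globally and
## summed per pond, combining species richness and relative population sizes.

#' Community importance index
#'
#' Each species' abundance vector across ponds is scaled by its global
#' maximum (an all-zero species stays zero and contributes nothing); the
#' per-pond index is the sum of scaled values over species, so it ranges from
#' 0 to the number of species. Min-max and z-score scalings are offered as
#' alternatives since "scaling" conventions differ between studies.
#'
#' @param abundance numeric matrix, species x ponds (dimnames used for
#'   labels), all values >= 0.
#' @param method `"max"` (default), `"minmax"` or `"zscore"`.
#' @return data.frame with `pond`, one scaled column per species, and
#'   `index`.
#' @export
community_index <- function(abundance, method = c("max", "minmax", "zscore")) {
  method <- match.arg(method)
  if (length(abundance) == 0 || nrow(abundance) == 0 || ncol(abundance) == 0) {
    return(data.frame(pond = character(), index = numeric(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.matrix(abundance), all(abundance >= 0))
  scaled <- abundance
  for (i in seq_len(nrow(abundance))) {
    v <- abundance[i, ]
    scaled[i, ] <- switch(method,
      max = if (max(v) > 0) v / max(v) else v,
      minmax = if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else v * 0,
      zscore = if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0)
  }
  ponds <- colnames(abundance) %||% sprintf("P%02d", seq_len(ncol(abundance)))
  out <- data.frame(pond = ponds, t(scaled), index = colSums(scaled),
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out
}
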