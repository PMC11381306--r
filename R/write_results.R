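#' Write a stage result to disk in a standard format
#'
#' Serialization is deterministic: keys sorted, numbers at 6 significant
#' digits, so identical inputs produce byte-identical files.
#'
#' @param results A data.frame (tsv), list (json), or \code{cooc_network}
#'   (graphml / edge-list).
#' @param path Output file path.
#' @param format One of \code{"tsv"}, \code{"json"}, \code{"graphml"},
#'   \code{"edge-list"}.
#' @export
write_results <- function(results, path,
                          format = c("tsv", "json", "graphml", "edge-list")) {
  supported <- c("tsv", "json", "graphml", "edge-list")
  if (!is.character(format) || !format[1] %in% supported)
    stop("unsupported format '", format[1], "'; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  format <- match.arg(format)
  switch(format,
    tsv = {
      df <- as.data.frame(results)
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], signif, digits = 6)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    json = {
      x <- sort_keys(signif_rec(results))
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    },
    graphml = {
      g <- as_igraph(results)
      igraph::write_graph(g, path, format = "graphml")
    },
    `edge-list` = {
      el <- network_edges(results)
      el$rho <- signif(el$rho, 6)
      utils::write.table(el[, c("source", "target", "rho")], path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  invisible(path)
}

signif_rec <- function(x) {
  if (is.list(x)) lapply(x, signif_rec)
  else if (is.double(x)) signif(x, 6)
  else x
}

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x))))
    lapply(x[order(names(x))], sort_keys)
  else if (is.list(x)) lapply(x, sort_keys)
  else x
}
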