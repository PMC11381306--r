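#' Construct an OTU/ASV count table
#'
#' The central data container of the package: a samples x taxa matrix of
#' non-negative integer counts, with optional taxonomy lineages per taxon and
#' a categorical group label (e.g. season) per sample.
#'
#' @param counts Numeric matrix, samples in rows, taxa in columns. Must be
#'   non-negative integers; dimnames are used as sample/taxon identifiers.
#' @param taxonomy Optional character vector of lineage strings, one per
#'   taxon (semicolon-delimited ranks, rank prefixes allowed).
#' @param groups Optional factor/character vector of group labels, one per
#'   sample.
#' @return An object of class \code{otu_table}: a list with elements
#'   \code{counts}, \code{sample_ids}, \code{taxon_ids}, \code{taxonomy},
#'   \code{groups}, \code{flags} (e.g. taxa with zero total count).
#' @export
otu_table <- function(counts, taxonomy = NULL, groups = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  storage <- counts
  if (!is.numeric(storage))
    stop("counts must be numeric", call. = FALSE)
  if (any(!is.finite(storage)))
    stop("counts contain non-finite values", call. = FALSE)
  if (any(storage < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(abs(storage - round(storage)) > 1e-8)) {
    bad <- which(abs(storage - round(storage)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', taxon '%s'",
                 rownames(storage)[bad[1]], colnames(storage)[bad[2]]),
         call. = FALSE)
  }
  storage <- round(storage)
  mode(storage) <- "integer"
  if (anyDuplicated(rownames(storage)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(storage)[duplicated(rownames(storage))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(storage)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(storage)[duplicated(colnames(storage))]),
               collapse = ", "), call. = FALSE)
  if (any(rowSums(storage) == 0))
    stop("samples with zero total count: ",
         paste(rownames(storage)[rowSums(storage) == 0], collapse = ", "),
         call. = FALSE)
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != ncol(storage))
      stop("taxonomy length must equal number of taxa", call. = FALSE)
    names(taxonomy) <- colnames(storage)
  }
  if (!is.null(groups)) {
    if (length(groups) != nrow(storage))
      stop("groups length must equal number of samples", call. = FALSE)
    groups <- factor(groups)
    names(groups) <- rownames(storage)
  }
  empty_taxa <- colnames(storage)[colSums(storage) == 0]
  structure(list(counts = storage,
                 sample_ids = rownames(storage),
                 taxon_ids = colnames(storage),
                 taxonomy = taxonomy,
                 groups = groups,
                 flags = list(empty_taxa = empty_taxa)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total reads: %d (depth %s-%s)\n", sum(x$counts),
              format(min(rowSums(x$counts))), format(max(rowSums(x$counts)))))
  if (!is.null(x$groups))
    cat("  groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                                   tabulate(x$groups)), collapse = ", "), "\n")
  if (length(x$flags$empty_taxa))
    cat(sprintf("  %d taxa with zero total count (flagged)\n",
                length(x$flags$empty_taxa)))
  invisible(x)
}

#' Relative abundances of an OTU table
#'
#' @param x An \code{otu_table}.
#' @return Samples x taxa matrix of proportions (rows sum to 1).
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  sweep(x$counts, 1, rowSums(x$counts), "/")
}

#' Subset an otu_table by samples and/or taxa
#'
#' @param x An \code{otu_table}.
#' @param samples,taxa Character or integer index of samples/taxa to keep.
#' @param drop_empty_taxa Drop taxa whose total count becomes zero.
#' @return A new \code{otu_table}.
#' @export
subset_otu <- function(x, samples = NULL, taxa = NULL,
                       drop_empty_taxa = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  cc <- x$counts
  if (!is.null(samples)) cc <- cc[samples, , drop = FALSE]
  if (!is.null(taxa)) cc <- cc[, taxa, drop = FALSE]
  if (drop_empty_taxa) cc <- cc[, colSums(cc) > 0, drop = FALSE]
  otu_table(cc,
            taxonomy = if (!is.null(x$taxonomy)) x$taxonomy[colnames(cc)],
            groups = if (!is.null(x$groups)) x$groups[rownames(cc)])
}

#' Read an OTU table from a tab-separated file
#'
#' Default layout is the common QIIME-style export: taxa as rows, first
#' column the taxon id, remaining columns samples, with an optional final
#' \code{taxonomy} column. Use \code{orientation = "samples_rows"} for the
#' transposed layout.
#'
#' @param path File path.
#' @param orientation \code{"taxa_rows"} (default) or \code{"samples_rows"}.
#' @param groups Optional named vector of group labels keyed by sample id.
#' @return An \code{otu_table}.
#' @export
read_otu_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                           groups = NULL) {
  orientation <- match.arg(orientation)
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr))
    stop("duplicate column in file: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "),
         call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  ids <- as.character(raw[[1]])
  raw <- raw[, -1, drop = FALSE]
  taxonomy <- NULL
  tax_col <- which(tolower(names(raw)) == "taxonomy")
  if (length(tax_col)) {
    taxonomy <- as.character(raw[[tax_col[1]]])
    raw <- raw[, -tax_col, drop = FALSE]
  }
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (any(is.na(v) & !is.na(raw[[j]])))
      stop(sprintf("non-numeric cell in column '%s' (row id '%s')",
                   names(raw)[j],
                   ids[which(is.na(v) & !is.na(raw[[j]]))[1]]),
           call. = FALSE)
    raw[[j]] <- v
  }
  m <- as.matrix(raw)
  rownames(m) <- ids
  if (orientation == "taxa_rows") {
    m <- t(m)
    if (!is.null(taxonomy)) names(taxonomy) <- colnames(m)
  } else if (!is.null(taxonomy)) {
    stop("taxonomy column only supported with taxa_rows orientation",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample identifiers in file: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  g <- if (!is.null(groups)) groups[rownames(m)] else NULL
  otu_table(m, taxonomy = taxonomy, groups = g)
}

#' Write an OTU table to a tab-separated file
#'
#' Writes in the taxa-as-rows layout read back by \code{read_otu_table}.
#'
#' @param x An \code{otu_table}.
#' @param path Output file path.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(`#OTU ID` = x$taxon_ids, t(x$counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata / environmental matrix from CSV
#'
#' First column is the sample id; a column named by \code{group_col} (if
#' present) is treated as the categorical group label; all remaining columns
#' must be numeric environmental variables.
#'
#' @param path CSV file path.
#' @param group_col Name of the group-label column (default \code{"group"}).
#' @return A list of class \code{env_matrix}: \code{env} (samples x variables
#'   numeric matrix), \code{groups} (factor or NULL).
#' @export
read_env <- function(path, group_col = "group") {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample identifiers in metadata", call. = FALSE)
  raw <- raw[, -1, drop = FALSE]
  groups <- NULL
  if (group_col %in% names(raw)) {
    groups <- factor(raw[[group_col]])
    names(groups) <- ids
    raw <- raw[, setdiff(names(raw), group_col), drop = FALSE]
  }
  env <- as.matrix(raw)
  if (!is.numeric(env))
    stop("environmental variables must be numeric", call. = FALSE)
  rownames(env) <- ids
  env_matrix(env, groups)
}

#' Construct an environmental matrix object
#'
#' @param env Samples x variables numeric matrix with dimnames.
#' @param groups Optional group factor, one label per sample.
#' @return An \code{env_matrix} object.
#' @export
env_matrix <- function(env, groups = NULL) {
  stopifnot(is.matrix(env), is.numeric(env))
  if (is.null(rownames(env)))
    stop("env matrix needs sample ids as rownames", call. = FALSE)
  const <- apply(env, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    warning("constant environmental variable(s): ",
            paste(colnames(env)[const], collapse = ", "))
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (length(groups) != nrow(env))
      stop("groups length must equal number of samples", call. = FALSE)
    names(groups) <- rownames(env)
  }
  structure(list(env = env, groups = groups), class = "env_matrix")
}

#' Write an environmental matrix to CSV
#'
#' @param x An \code{env_matrix}.
#' @param path Output path.
#' @param group_col Column name used for the group label.
#' @export
write_env <- function(x, path, group_col = "group") {
  stopifnot(inherits(x, "env_matrix"))
  df <- data.frame(sample = rownames(x$env), check.names = FALSE)
  if (!is.null(x$groups)) df[[group_col]] <- as.character(x$groups)
  df <- cbind(df, as.data.frame(x$env, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
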