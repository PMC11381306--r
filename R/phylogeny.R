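#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around \code{ape::read.tree} adding the validation the rest
#' of the pipeline relies on: unique tip labels and branch lengths present
#' (missing lengths are set to 0 with a warning).
#'
#' @param path Newick file path.
#' @return An \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: no tree found", call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (anyDuplicated(tree$tip.label))
    stop("tip labels not unique: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  tree
}

#' Patristic (cophenetic) distance matrix of a tree
#'
#' @param tree An \code{ape::phylo} tree with branch lengths.
#' @param tips Optional tip subset/order for the returned matrix.
#' @return Symmetric matrix of path-length distances between tips.
#' @export
patristic_distance <- function(tree, tips = NULL) {
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(tips)) {
    missing <- setdiff(tips, rownames(d))
    if (length(missing))
      stop("taxa absent from tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    d <- d[tips, tips, drop = FALSE]
  }
  d
}

#' Align an OTU table, a phylogeny and an environmental matrix
#'
#' Restricts the three inputs to their shared samples and taxa, in one
#' canonical order (the table's order after dropping), and reports what was
#' removed. Tree and env are optional.
#'
#' @param table An \code{otu_table}.
#' @param tree Optional \code{phylo}; pruned to the table's taxa.
#' @param env Optional \code{env_matrix}; restricted to shared samples.
#' @return List with \code{table}, \code{tree}, \code{env} and a
#'   \code{report} of dropped samples/taxa/tips.
#' @export
align_inputs <- function(table, tree = NULL, env = NULL) {
  stopifnot(inherits(table, "otu_table"))
  report <- list(dropped_samples = character(), dropped_taxa = character(),
                 pruned_tips = character())
  samples <- table$sample_ids
  if (!is.null(env)) {
    stopifnot(inherits(env, "env_matrix"))
    shared <- intersect(samples, rownames(env$env))
    if (!length(shared))
      stop("no samples shared between table and metadata", call. = FALSE)
    report$dropped_samples <- union(setdiff(samples, shared),
                                    setdiff(rownames(env$env), shared))
    samples <- samples[samples %in% shared]
  }
  taxa <- table$taxon_ids
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    shared_t <- intersect(taxa, tree$tip.label)
    if (!length(shared_t))
      stop("no taxa shared between table and tree", call. = FALSE)
    report$dropped_taxa <- setdiff(taxa, shared_t)
    report$pruned_tips <- setdiff(tree$tip.label, shared_t)
    taxa <- taxa[taxa %in% shared_t]
    if (length(report$pruned_tips))
      tree <- ape::keep.tip(tree, taxa)
  }
  tab <- subset_otu(table, samples = samples, taxa = taxa)
  if (!is.null(env))
    env <- env_matrix(env$env[samples, , drop = FALSE],
                      if (!is.null(env$groups)) env$groups[samples])
  if (length(report$dropped_samples) || length(report$dropped_taxa))
    message("align_inputs: dropped ", length(report$dropped_samples),
            " sample(s), ", length(report$dropped_taxa), " taxon/taxa; pruned ",
            length(report$pruned_tips), " tip(s)")
  list(table = tab, tree = tree, env = env, report = report)
}
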