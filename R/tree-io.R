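#' Read a time-calibrated tree from a newick file
#'
#' Parses a rooted newick tree with branch lengths and validates it for
#' use as a chronogram: all branch lengths must be present (a missing
#' root edge is treated as 0) and non-negative. Polytomies are preserved.
#'
#' @param path Path to a newick file, or a newick string ending in ";".
#' @return An [ape::read.tree()] `phylo` object with a `depth_myr`
#'   attribute (maximum root-to-tip path length, in the tree's time
#'   units).
#' @seealso [validate_ultrametric()], [scale_to_unit_depth()]
#' @export
read_tree <- function(path) {
  txt <- if (file.exists(path[1])) paste(readLines(path, warn = FALSE),
                                         collapse = "")
         else if (grepl("\\(", path[1])) path[1]
         else stop("file not found: ", path[1], call. = FALSE)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick format error: could not parse '", substr(txt, 1, 60), "'",
         call. = FALSE)
  if (ape::Ntip(tree) < 2)
    stop("tree must have at least 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("tip labels are not unique", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("newick format error: tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length))
    stop("newick format error: missing branch lengths", call. = FALSE)
  neg <- which(tree$edge.length < 0)
  if (length(neg) > 0) {
    lab <- node_label(tree, tree$edge[neg[1], 2])
    stop("validation error: negative branch length on edge to '", lab, "'",
         call. = FALSE)
  }
  if (!is.null(tree$root.edge) && is.na(tree$root.edge)) tree$root.edge <- 0
  attr(tree, "depth_myr") <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  tree
}

node_label <- function(tree, node) {
  if (node <= ape::Ntip(tree)) tree$tip.label[node] else paste0("node_", node)
}

#' Write a tree to newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Check that a tree is ultrametric
#'
#' A chronogram must have equal root-to-tip path lengths. Published
#' chronograms typically carry rounding error, so the check is relative:
#' the tree passes iff `max |path_i - depth| / depth <= rel_tol`, where
#' `depth` is the maximum root-to-tip distance.
#'
#' @param tree A `phylo` object.
#' @param rel_tol Relative tolerance; 1e-3 is a reasonable default for
#'   real chronograms, tighten to 1e-6 or below for exact/simulated
#'   trees.
#' @return Logical scalar with attributes `max_deviation` (relative) and
#'   `worst_tip` (tip label with the largest deviation). The reference
#'   depth is the median root-to-tip distance, so a single deviant tip
#'   is flagged rather than shifting the reference.
#' @export
validate_ultrametric <- function(tree, rel_tol = 1e-3) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 2)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  depth <- median(depths)
  dev <- abs(depths - depth) / depth
  worst <- which.max(dev)
  ok <- max(dev) <= rel_tol
  structure(ok, max_deviation = max(dev), worst_tip = tree$tip.label[worst])
}

#' Rescale a tree to unit depth
#'
#' All rate inference in this package is done on unit-depth trees for
#' numerical conditioning; fitted rates are "events per unit tree depth"
#' and are converted back to events/Myr with the returned `depth_myr`
#' (see [dysploidy_rate_per_myr()]). Applying the operation to an
#' already unit-depth tree is the identity.
#'
#' @param tree An ultrametric `phylo` object.
#' @return A list with `tree` (unit depth, `depth_myr` attribute 1) and
#'   `depth_myr`, the original root-to-tip depth.
#' @export
scale_to_unit_depth <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  if (!is.finite(depth) || depth <= 0)
    stop("degenerate tree: depth is 0", call. = FALSE)
  tree$edge.length <- tree$edge.length / depth
  if (!is.null(tree$root.edge)) tree$root.edge <- tree$root.edge / depth
  attr(tree, "depth_myr") <- 1
  list(tree = tree, depth_myr = depth)
}

#' Read a karyotype table from CSV
#'
#' Expects a header `species,haploid_n`. Haploid counts must be positive
#' integers; non-integer counts are rejected by default rather than
#' rounded (rounding would fabricate states). With `strict = FALSE` they
#' are dropped with a warning.
#'
#' @param path CSV file path.
#' @param strict Reject non-integer / non-positive counts (default) or
#'   drop them with a warning.
#' @return A `data.frame` with columns `species` (character, unique) and
#'   `haploid_n` (integer).
#' @export
read_karyotypes <- function(path, strict = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "haploid_n") %in% names(df)))
    stop("karyotype CSV must have header 'species,haploid_n'", call. = FALSE)
  karyotype_table(df$species, df$haploid_n, strict = strict)
}

#' Construct and validate a karyotype table
#'
#' @param species Character vector of unique species names.
#' @param haploid_n Positive integer haploid chromosome counts (NA marks
#'   a species whose count is unknown / ambiguous).
#' @param strict See [read_karyotypes()].
#' @return A validated `data.frame(species, haploid_n)`.
#' @export
karyotype_table <- function(species, haploid_n, strict = TRUE) {
  species <- as.character(species)
  if (anyDuplicated(species))
    stop("duplicate species in karyotype table: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  n <- suppressWarnings(as.numeric(haploid_n))
  bad <- !is.na(n) & (!is.finite(n) | n < 1 | n != round(n))
  if (any(bad)) {
    msg <- paste0("non-integer or non-positive haploid counts for: ",
                  paste(species[bad], collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " — dropped", call. = FALSE)
    species <- species[!bad]; n <- n[!bad]
  }
  data.frame(species = species, haploid_n = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Match a tree to a karyotype table
#'
#' Co-prunes a tree and a karyotype table so that downstream analyses see
#' a consistent pair. Table rows without a matching tip are dropped with
#' a warning. Tips without a count are either pruned
#' (`missing_policy = "drop"`, the default; pruning merges the branch
#' lengths of removed unifurcations so root-to-tip distances are
#' preserved) or retained with `haploid_n = NA`, which the likelihood
#' treats as a fully ambiguous state (`missing_policy = "ambiguous"`).
#'
#' @param tree A `phylo` object.
#' @param karyotypes A karyotype table ([karyotype_table()]).
#' @param missing_policy `"drop"` or `"ambiguous"`.
#' @return A list with `tree` (pruned), `karyotypes` (aligned to the
#'   tree's tips, one row per tip), `n_dropped_tips` and
#'   `n_dropped_rows`.
#' @export
match_tree_data <- function(tree, karyotypes,
                            missing_policy = c("drop", "ambiguous")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(tree, "phylo"))
  shared <- intersect(tree$tip.label, karyotypes$species)
  if (length(shared) < 2)
    stop("insufficient overlap: fewer than 2 species shared between tree ",
         "and karyotype table", call. = FALSE)
  extra_rows <- setdiff(karyotypes$species, tree$tip.label)
  if (length(extra_rows) > 0)
    warning(length(extra_rows), " karyotype rows have no matching tip and ",
            "were dropped", call. = FALSE)
  missing_tips <- setdiff(tree$tip.label, karyotypes$species)
  depth0 <- attr(tree, "depth_myr")
  if (missing_policy == "drop" && length(missing_tips) > 0) {
    tree <- ape::keep.tip(tree, shared)
  }
  keep <- karyotypes[match(tree$tip.label, karyotypes$species), , drop = FALSE]
  keep$species <- tree$tip.label   # fills NA species for ambiguous tips
  rownames(keep) <- NULL
  if (is.null(depth0))
    depth0 <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  attr(tree, "depth_myr") <- depth0
  list(tree = tree, karyotypes = keep,
       n_dropped_tips = if (missing_policy == "drop") length(missing_tips) else 0L,
       n_dropped_rows = length(extra_rows))
}
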