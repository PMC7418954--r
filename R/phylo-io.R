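#' Read a phylogenetic tree from Newick or Nexus input
#'
#' Thin wrapper around [ape::read.tree()] / [ape::read.nexus()] that
#' normalizes tip labels (spaces become underscores, case preserved),
#' validates branch lengths, and flags non-ultrametric trees.
#'
#' Branch lengths are treated as absolute time in million years (My)
#' throughout the package. Ultrametricity is checked within a relative
#' tolerance of tree depth and *warned* about, never enforced, because
#' published supertrees are often ultrametric only to file precision.
#'
#' @param x A Newick string (anything containing `(`), or a path to a
#'   Newick or Nexus file. Nexus input is detected by a leading `#NEXUS`.
#' @param synonyms Optional named character vector mapping tip labels to
#'   replacement labels (applied after normalization), e.g.
#'   `c(Herpailurus_yagouaroundi = "Puma_yagouaroundi")`.
#' @param ultrametric_tol Relative tolerance (fraction of tree depth) for
#'   the ultrametricity check. Default `1e-6`.
#'
#' @return An [ape::phylo] object with attribute `"ultrametric"` (logical).
#' @examples
#' tr <- read_tree("(A:1,(B:0.5,C:0.5):0.5);")
#' ape::Ntip(tr)
#' @export
read_tree <- function(x, synonyms = NULL, ultrametric_tol = 1e-6) {
  stopifnot(is.character(x), length(x) == 1)
  is_string <- grepl("(", x, fixed = TRUE)
  txt <- if (is_string) x else {
    if (!file.exists(x)) abort(paste0("tree file not found: ", x))
    paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  tree <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    writeLines(txt, tf)
    on.exit(unlink(tf), add = TRUE)
    tryCatch(ape::read.nexus(tf), error = function(e) {
      abort(paste0("failed to parse Nexus tree: ", conditionMessage(e)))
    })
  } else {
    tryCatch(ape::read.tree(text = txt), error = function(e) {
      abort(paste0(
        "failed to parse Newick string near position ",
        .newick_error_position(txt), ": ", conditionMessage(e)
      ))
    })
  }
  if (is.null(tree)) {
    abort(paste0(
      "failed to parse Newick string near position ",
      .newick_error_position(txt)
    ))
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree,
    synonyms = synonyms,
    ultrametric_tol = ultrametric_tol
  )
}

# Crude localization of the first syntactically suspicious character,
# used only to make parse errors actionable.
.newick_error_position <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  bad <- which(depth < 0)
  if (length(bad)) return(bad[1])
  if (all(depth != 0) || !any(chars == ";")) return(length(chars))
  length(chars)
}

#' Validate and normalize a phylogeny
#'
#' @param tree An [ape::phylo] object.
#' @inheritParams read_tree
#' @return The tree, tip labels normalized, with attribute `"ultrametric"`.
#' @export
validate_tree <- function(tree, synonyms = NULL, ultrametric_tol = 1e-6) {
  if (!inherits(tree, "phylo")) abort("not a 'phylo' object")
  if (is.null(tree$edge.length) ||
    length(tree$edge.length) != nrow(tree$edge)) {
    abort("tree has missing branch lengths")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    abort("tree has non-finite branch lengths")
  }
  if (any(tree$edge.length <= 0)) {
    abort("all branch lengths must be > 0")
  }
  if (ape::Ntip(tree) > 1 && !ape::is.rooted(tree)) {
    abort("tree must be rooted")
  }
  tree$tip.label <- normalize_labels(tree$tip.label, synonyms)
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0(
      "duplicated tip labels after normalization: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
        collapse = ", "
      )
    ))
  }
  depth <- tree_depth(tree)
  tip_depths <- node_heights(tree)[seq_len(ape::Ntip(tree))]
  ultra <- diff(range(tip_depths)) <= ultrametric_tol * depth
  if (!ultra) {
    warn(paste0(
      "tree is not ultrametric within tolerance (tip depth spread ",
      signif(diff(range(tip_depths)), 3), " vs depth ", signif(depth, 3), ")"
    ))
  }
  attr(tree, "ultrametric") <- ultra
  tree
}

#' Normalize taxon labels
#'
#' Spaces become underscores; case is preserved; an optional synonym map is
#' applied afterwards.
#'
#' @param x Character vector of labels.
#' @param synonyms Optional named character vector, `old = "new"`.
#' @return Character vector.
#' @export
normalize_labels <- function(x, synonyms = NULL) {
  out <- gsub("^['\"]+|['\"]+$", "", trimws(x))
  out <- gsub("[ ]+", "_", out)
  if (!is.null(synonyms)) {
    keys <- gsub("[ ]+", "_", names(synonyms))
    hit <- match(out, keys)
    out[!is.na(hit)] <- unname(synonyms)[hit[!is.na(hit)]]
    out <- gsub("[ ]+", "_", out)
  }
  out
}

#' Tree depth and node heights
#'
#' `node_heights()` returns the distance from the root to every node (tips
#' first, in `ape` node order); the root has height 0. `tree_depth()` is the
#' maximum root-to-tip distance.
#'
#' @param tree An [ape::phylo] object.
#' @return Numeric vector (heights) or scalar (depth), in branch-length
#'   units (My).
#' @export
node_heights <- function(tree) {
  if (ape::Ntip(tree) == 1) {
    h <- numeric(ape::Ntip(tree) + tree$Nnode)
    # single-tip chain: accumulate along the edge list
    ord <- order(tree$edge[, 1])
    for (i in ord) {
      h[tree$edge[i, 2]] <- h[tree$edge[i, 1]] + tree$edge.length[i]
    }
    return(h)
  }
  ape::node.depth.edgelength(tree)
}

#' @rdname node_heights
#' @export
tree_depth <- function(tree) max(node_heights(tree))

#' Join two clade trees under a new root
#'
#' Creates a new root with the two input trees as its children; each stem
#' branch is `root_age - depth(tree)`, so if both inputs are ultrametric the
#' result is ultrametric with depth `root_age`. The joining age is a free
#' analysis parameter (the default 79 My is a conventional
#' primate-carnivoran split); cross-clade statistics reported by the
#' pipeline should be insensitive to it because the two clades share no
#' post-root history.
#'
#' @param t1,t2 [ape::phylo] objects with branch lengths in My.
#' @param root_age Age of the new root (My); must be at least the depth of
#'   both trees (strictly greater unless you accept zero-length stems; a
#'   stem of exactly 0 is rejected because branch lengths must be > 0).
#' @return A single [ape::phylo] with the union of tips.
#' @examples
#' p <- read_tree("(A:1,B:1);")
#' c <- read_tree("(X:0.5,Y:0.5);")
#' tree_depth(graft_trees(p, c, root_age = 2))
#' @export
graft_trees <- function(t1, t2, root_age = 79) {
  d1 <- tree_depth(t1)
  d2 <- tree_depth(t2)
  if (root_age < max(d1, d2)) {
    abort(sprintf(
      "root_age (%g) is younger than the deepest input tree (%g)",
      root_age, max(d1, d2)
    ))
  }
  s1 <- root_age - d1
  s2 <- root_age - d2
  if (s1 <= 0 || s2 <= 0) {
    abort("root_age leaves a zero-length stem; increase root_age")
  }
  nw <- paste0(
    "(", .subtree_newick(t1, s1), ",", .subtree_newick(t2, s2), ");"
  )
  out <- ape::read.tree(text = nw)
  validate_tree(out)
}

# subtree serialization with its stem; a single-tip "tree" collapses its
# degree-2 root, so stem and depth merge into one terminal branch
.subtree_newick <- function(tree, stem) {
  if (ape::Ntip(tree) == 1) {
    return(paste0(
      tree$tip.label, ":",
      format(tree_depth(tree) + stem, digits = 15)
    ))
  }
  paste0(
    sub(";\\s*$", "", ape::write.tree(tree, digits = 12)),
    ":", format(stem, digits = 15)
  )
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian motion with unit rate, the covariance of two tips equals
#' the shared root-to-MRCA path length and the variance of a tip equals its
#' root-to-tip path length. The trait-scale rate multiplier lives in the
#' regression fit, not here.
#'
#' @param tree An [ape::phylo] object.
#' @return Symmetric positive-definite matrix with tip labels as dimnames.
#' @export
vcv_bm <- function(tree) {
  ape::vcv(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' untouched: `lambda = 1` is pure Brownian motion, `lambda = 0` a star
#' phylogeny. Values outside `[0, 1]` are rejected (matching the tool
#' convention of the field; values above 1 can break positive
#' definiteness).
#'
#' @param V Covariance matrix from [vcv_bm()].
#' @param lambda Scalar in `[0, 1]`.
#' @return Transformed covariance matrix.
#' @export
apply_lambda <- function(V, lambda) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (!is.numeric(lambda) || length(lambda) != 1 ||
    is.na(lambda) || lambda < 0 || lambda > 1) {
    abort("lambda must be a single value in [0, 1]")
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Match a specimen table to a tree
#'
#' Prunes the tree to the species present in the table and reorders the
#' table rows to the tree's tip order, after normalizing labels on both
#' sides. Dropped names on either side are reported via attributes (and a
#' message).
#'
#' @param tree An [ape::phylo] object.
#' @param data A data frame with a species column.
#' @param species_col Name of the species column. Default `"species"`.
#' @param synonyms Optional synonym map, see [normalize_labels()].
#' @param quiet Suppress the drop report message.
#' @return A list with elements `tree` (pruned), `data` (tibble reordered to
#'   tip order), `dropped_tips`, `dropped_rows`.
#' @export
match_taxa <- function(tree, data, species_col = "species", synonyms = NULL,
                       quiet = FALSE) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(data))
  if (!species_col %in% names(data)) {
    abort(paste0("no column '", species_col, "' in data"))
  }
  data <- as_tibble(data)
  data[[species_col]] <- normalize_labels(data[[species_col]], synonyms)
  if (anyDuplicated(data[[species_col]])) {
    abort("species labels in data are not unique after normalization")
  }
  tips <- normalize_labels(tree$tip.label, synonyms)
  tree$tip.label <- tips
  common <- intersect(tips, data[[species_col]])
  if (length(common) == 0) {
    sugg <- .nearest_names(data[[species_col]], tips)
    abort(paste0(
      "no species shared between tree and table; nearest tip names: ",
      paste(utils::head(sugg, 5), collapse = ", ")
    ))
  }
  dropped_tips <- setdiff(tips, common)
  dropped_rows <- setdiff(data[[species_col]], common)
  pruned <- if (length(dropped_tips)) ape::keep.tip(tree, common) else tree
  ord <- match(pruned$tip.label, data[[species_col]])
  out_data <- data[ord, , drop = FALSE]
  if (!quiet) {
    inform(sprintf(
      "matched %d taxa (dropped %d tips, %d table rows)",
      length(common), length(dropped_tips), length(dropped_rows)
    ))
  }
  structure(
    list(
      tree = pruned, data = out_data,
      dropped_tips = dropped_tips, dropped_rows = dropped_rows
    ),
    class = "taxa_match"
  )
}

.nearest_names <- function(wanted, have) {
  d <- utils::adist(wanted, have, ignore.case = TRUE)
  have[unique(apply(d, 1, which.min))]
}
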