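#' Build a clonal propagation tree
#'
#' A rooted tree whose leaves are accessions of a clonally propagated crop.
#' Somatic mutations are assigned to branches and accumulate from the root
#' down: a leaf carries exactly the mutations on its root-to-leaf path. An
#' outgroup clade (one or more leaves) is used downstream to polarize alleles
#' into ancestral and derived states.
#'
#' @param edges data frame with columns `parent`, `child` and optionally
#'   `n_mut` (relative mutation weight per branch; defaults to 1)
#' @param outgroup character vector of leaf ids forming the outgroup clade
#' @return an object of class `clone_tree`
#' @export
clone_tree <- function(edges, outgroup = character()) {
  stopifnot(all(c("parent", "child") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (is.null(edges$n_mut)) edges$n_mut <- 1
  if (anyDuplicated(edges$child))
    stop("tree is not a tree: a node has two parents")
  nodes <- unique(c(edges$parent, edges$child))
  root <- setdiff(edges$parent, edges$child)
  if (length(root) != 1) stop("tree must have exactly one root")
  leaves <- setdiff(edges$child, edges$parent)
  # cycle check via topological walk from the root
  seen <- root
  frontier <- root
  while (length(frontier)) {
    kids <- edges$child[edges$parent %in% frontier]
    if (any(kids %in% seen)) stop("tree contains a cycle")
    seen <- c(seen, kids)
    frontier <- kids
  }
  if (!setequal(seen, nodes)) stop("tree contains a cycle or disconnected nodes")
  if (length(outgroup) && !all(outgroup %in% leaves))
    stop("outgroup ids must be leaves")
  edges$branch_id <- paste0(edges$parent, ">", edges$child)
  structure(list(edges = edges, root = root, leaves = leaves,
                 outgroup = as.character(outgroup)),
            class = "clone_tree")
}

#' Branches on the root-to-leaf path of a leaf
#' @param tree a `clone_tree`
#' @param leaf leaf id
#' @return character vector of branch ids, root first
#' @export
leaf_path <- function(tree, leaf) {
  stopifnot(leaf %in% tree$leaves)
  e <- tree$edges
  path <- character()
  node <- leaf
  while (node != tree$root) {
    i <- match(node, e$child)
    path <- c(e$branch_id[i], path)
    node <- e$parent[i]
  }
  path
}

#' A balanced binary clone tree with an attached outgroup clade
#'
#' Builds a tree with `n_ingroup` ingroup leaves (balanced bifurcating) and
#' `n_outgroup` outgroup leaves hanging off a basal branch, mirroring the use
#' of an early-diverging clade to polarize somatic alleles.
#'
#' @param n_ingroup,n_outgroup leaf counts
#' @param n_mut mutation weight per branch
#' @export
balanced_clone_tree <- function(n_ingroup = 8, n_outgroup = 3, n_mut = 1) {
  stopifnot(n_ingroup >= 1, n_outgroup >= 1)
  edges <- data.frame(parent = character(), child = character(),
                      stringsAsFactors = FALSE)
  grow <- function(prefix, leaves_ids) {
    n <- length(leaves_ids)
    if (n == 1) return(NULL)
    half <- ceiling(n / 2)
    l <- leaves_ids[seq_len(half)]; r <- leaves_ids[-seq_len(half)]
    lid <- if (length(l) == 1) l else paste0(prefix, "L")
    rid <- if (length(r) == 1) r else paste0(prefix, "R")
    rbind(data.frame(parent = prefix, child = lid, stringsAsFactors = FALSE),
          data.frame(parent = prefix, child = rid, stringsAsFactors = FALSE),
          grow(lid, l), grow(rid, r))
  }
  ing <- paste0("acc", seq_len(n_ingroup))
  outg <- paste0("out", seq_len(n_outgroup))
  e <- rbind(data.frame(parent = "root", child = "ogclade", stringsAsFactors = FALSE),
             data.frame(parent = "root", child = if (n_ingroup == 1) ing else "ingclade",
                        stringsAsFactors = FALSE),
             if (n_outgroup == 1) {
               data.frame(parent = "ogclade", child = outg, stringsAsFactors = FALSE)
             } else grow("ogclade", outg),
             if (n_ingroup > 1) grow("ingclade", ing))
  # n_outgroup == 1 with a unary internal node: collapse
  if (n_outgroup == 1) {
    e$child[e$child == "ogclade"] <- outg
    e <- e[!(e$parent == "ogclade"), , drop = FALSE]
  }
  e$n_mut <- n_mut
  clone_tree(e, outgroup = outg)
}

#' Export a clone tree as newick
#' @param tree a `clone_tree`
#' @param file optional path; if `NULL` the newick string is returned
#' @export
tree_newick <- function(tree, file = NULL) {
  build <- function(node) {
    kids <- tree$edges$child[tree$edges$parent == node]
    if (!length(kids)) return(node)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","), ")", node)
  }
  nwk <- paste0(build(tree$root), ";")
  # validate through ape's parser
  ph <- ape::read.tree(text = nwk)
  stopifnot(setequal(ph$tip.label, tree$leaves))
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(file))
  }
  nwk
}
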