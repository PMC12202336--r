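# Newick tree I/O, delegated to ape.  Trees are ape "phylo" objects; node
# labels carry bootstrap supports where present.

#' Read a Newick tree
#'
#' @param path file containing a single Newick string, optionally with
#'   branch lengths and support values (retained as node labels).
#' @return an ape \code{phylo} object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label in ", path, ": ",
         tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' Write a tree as Newick
#' @param tree ape \code{phylo}
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
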