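## Tree data model and I/O.  Trees are ape "phylo" objects throughout; this
## file adds the validation layer every downstream likelihood relies on:
## branch lengths present, finite and non-negative, unique tip labels,
## binary topology (polytomies resolved to zero-length branches on load).

#' Parse a phylogenetic tree from text
#'
#' Reads a rooted tree with branch lengths from a Newick or Nexus string and
#' validates it for comparative analysis.  Polytomies are resolved to
#' zero-length branches (with a warning); all likelihoods in this package are
#' invariant to the resolution order.  Missing branch lengths are an error,
#' never silently replaced: the methods assume time-calibrated branches.
#'
#' @param text character scalar holding the serialized tree.
#' @param format `"newick"` or `"nexus"`.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- parse_phylo("((A:1,B:1):1,C:2);")
#' @export
parse_phylo <- function(text, format = c("newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(is.character(text), length(text) == 1L)
  if (format == "newick") {
    check_newick_syntax(text)
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  } else {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    tr <- tryCatch(ape::read.nexus(tf), error = function(e) NULL)
    if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("tree parse error: text is not a valid ", format, " tree")
  validate_phylo(tr)
}

#' Read a phylogenetic tree from a file
#'
#' @param file path to a Newick or Nexus file.
#' @param format `"newick"` or `"nexus"`; guessed from the extension
#'   (`.nex`/`.nexus` vs anything else) when omitted.
#' @return An object of class `"phylo"`.
#' @export
read_phylo <- function(file, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.nex(us)?$", file, ignore.case = TRUE))
      "nexus" else "newick"
  }
  parse_phylo(paste(readLines(file, warn = FALSE), collapse = "\n"), format)
}

#' Write a tree to Newick or Nexus
#'
#' Branch lengths are written with 10 significant digits so that a
#' write/parse round trip preserves them.
#'
#' @param tree a `phylo` object.
#' @param file output path, or `NULL` to return the serialization.
#' @param format `"newick"` or `"nexus"`.
#' @return The file path, or the serialized text when `file` is `NULL`.
#' @export
write_phylo <- function(tree, file = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "newick") {
    txt <- ape::write.tree(tree, digits = 10)
    if (is.null(file)) return(txt)
    writeLines(txt, file)
  } else {
    if (is.null(file)) {
      file <- tempfile(fileext = ".nex")
      ape::write.nexus(tree, file = file, digits = 10)
      return(paste(readLines(file, warn = FALSE), collapse = "\n"))
    }
    ape::write.nexus(tree, file = file, digits = 10)
  }
  invisible(file)
}

## cheap structural scan so malformed Newick reports a character position
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("tree parse error: unbalanced ')' at character ", i)
    }
  }
  if (depth > 0L)
    stop("tree parse error: ", depth,
         " unclosed '(' (last opened before character ", nchar(text), ")")
  if (!grepl(";", text, fixed = TRUE))
    stop("tree parse error: missing terminating ';' at character ",
         nchar(text))
  invisible(TRUE)
}

validate_phylo <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; time-calibrated branches are required")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree has missing or non-finite branch lengths")
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    warning("polytomies resolved to zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Test whether a tree is ultrametric to a relative tolerance
#'
#' All root-to-tip path lengths must agree with their mean within
#' `rel_tol * mean`.  Ultrametricity is a precondition of the
#' diversification likelihoods.
#'
#' @param tree a `phylo` object with at least 2 tips.
#' @param rel_tol relative tolerance (fraction of the mean depth).
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric_tol <- function(tree, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2L)
  d <- tip_depths(tree)
  all(abs(d - mean(d)) <= rel_tol * mean(d))
}

## root-to-tip path lengths, named by tip label
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' Entry (a, b) is the shared root-path length of tips a and b, i.e. the
#' depth of their most recent common ancestor.  This is the error covariance
#' (up to the rate constant) of any trait evolving by Brownian motion on the
#' tree, used by [pgls_fit()] and [simulate_bm_traits()].
#'
#' @param tree a `phylo` object.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::vcv(tree)
}

#' Reconcile tree tips against a trait table
#'
#' Matching is exact and case-sensitive.  Always reports both directions of
#' mismatch; optionally prunes unmatched tips.
#'
#' @param tree a `phylo` object.
#' @param species character vector of species present in the trait data.
#' @param prune drop unmatched tips from the returned tree?
#' @return A list with `tree` (possibly pruned), `tips_missing_traits`,
#'   `traits_missing_tips` and `matched`.
#' @export
reconcile_species <- function(tree, species, prune = FALSE) {
  tips <- tree$tip.label
  miss_tr <- setdiff(tips, species)
  miss_tip <- setdiff(species, tips)
  out <- list(tree = tree,
              tips_missing_traits = miss_tr,
              traits_missing_tips = miss_tip,
              matched = intersect(tips, species))
  if (prune && length(miss_tr)) {
    if (length(out$matched) < 2L)
      stop("pruning would leave fewer than 2 tips")
    out$tree <- ape::drop.tip(tree, miss_tr)
  }
  out
}
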