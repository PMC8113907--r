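#' Read a Newick tree
#'
#' Parses a Newick string or file into an [ape::phylo] object.  Internal node
#' labels, when numeric (as in bootstrap-annotated maximum-likelihood trees),
#' are additionally exposed through the `"support"` attribute.  Quoted labels
#' and underscores are passed through verbatim.
#'
#' @param text A Newick string (possibly ending in `;`).  Ignored when `file`
#'   is given.
#' @param file Path to a Newick file; one tree per line yields a `multiPhylo`.
#' @param missing_lengths How to treat absent branch lengths: `"error"`
#'   (default) or `"zero"` to substitute 0.
#' @return A `phylo` (single tree) or `multiPhylo` (several trees).  Each
#'   `phylo` carries a numeric `support` attribute (NA where the label is
#'   absent or non-numeric), one entry per internal node.
#' @examples
#' tr <- read_newick("((A:1,B:1)95:1,C:2);")
#' attr(tr, "support")
#' @seealso [write_newick()], [check_ultrametric()]
#' @export
read_newick <- function(text = NULL, file = NULL,
                        missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  if (is.null(text) && is.null(file)) {
    stop("supply either `text` or `file`")
  }
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("no trees found in ", file)
    trees <- lapply(lines, read_newick, missing_lengths = missing_lengths)
    if (length(trees) == 1L) return(trees[[1L]])
    class(trees) <- "multiPhylo"
    return(trees)
  }
  check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = ensure_semicolon(text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(tr)) stop("Newick parse error: unreadable tree string")
  if (is.null(tr$edge.length)) {
    if (missing_lengths == "error") {
      stop("tree has no branch lengths; use missing_lengths = \"zero\" to default them")
    }
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (missing_lengths == "error") {
      stop("some branches lack lengths; use missing_lengths = \"zero\" to default them")
    }
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  attr(tr, "support") <- parse_support(tr)
  tr
}

# Minimal structural validation with a character offset, ahead of ape's parser.
check_newick_syntax <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at character ", i)
      }
    }
  }
  if (in_quote) stop("Newick parse error: unterminated quoted label")
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of string")
  }
  invisible(TRUE)
}

ensure_semicolon <- function(text) {
  text <- trimws(text)
  if (!endsWith(text, ";")) text <- paste0(text, ";")
  text
}

parse_support <- function(tr) {
  lab <- tr$node.label
  if (is.null(lab)) return(rep(NA_real_, tr$Nnode))
  suppressWarnings(as.numeric(lab))
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param file Optional output path; when `NULL` the Newick string(s) are
#'   returned.
#' @param digits Significant digits for branch lengths.
#' @return Invisibly (or visibly when `file = NULL`) the Newick string(s).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  out <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Read a species-by-trait table of binary codings
#'
#' Expects a delimited file whose header holds a `species` column followed by
#' binary trait columns.  Cells must be `0`, `1`, `?` or `NA`; the latter two
#' are treated as missing (and handled downstream as ambiguous tip states).
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `"\t"` by default, use `","` for CSV.
#' @param species_column Name of the species identifier column.
#' @return A data frame with rownames set to species names and integer trait
#'   columns in `{0, 1, NA}`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("species\tbrush_organ", "sp1\t1", "sp2\t?"), f)
#' read_trait_table(f)
#' @export
read_trait_table <- function(path, sep = "\t", species_column = "species") {
  raw <- read.table(path, header = TRUE, sep = sep, na.strings = c("NA", "?"),
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!species_column %in% names(raw)) {
    stop("no `", species_column, "` column in ", path)
  }
  sp <- raw[[species_column]]
  if (anyDuplicated(sp)) {
    stop("duplicate species: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "))
  }
  traits <- raw[setdiff(names(raw), species_column)]
  for (j in seq_along(traits)) {
    col <- traits[[j]]
    bad <- !is.na(col) & !col %in% c("0", "1")
    if (any(bad)) {
      stop(sprintf("non-binary value %s at species %s, column %s",
                   dQuote(col[which(bad)[1L]]), sp[which(bad)[1L]],
                   names(traits)[j]))
    }
    if (all(is.na(col))) {
      warning("trait column ", names(traits)[j], " is entirely missing")
    }
    traits[[j]] <- as.integer(col)
  }
  rownames(traits) <- sp
  traits
}

#' Standard androconial organ vocabulary
#'
#' The seven male secondary sexual organ types scored in Eumaeini surveys:
#' brush organ, scent pad, scent patch, and the four positional wing
#' androconia (costal-subcostal, dorsal hindwing, ventral forewing, ventral
#' hindwing).
#'
#' @return Character vector of canonical trait column names.
#' @export
organ_vocabulary <- function() {
  c("brush_organ", "scent_pad", "scent_patch",
    "CSbA", "DHwA", "VFwA", "VHwA")
}

#' Check a tree for ultrametricity
#'
#' A tree is accepted as ultrametric when the spread of root-to-tip depths is
#' at most `rel_tol` times the maximum depth, which absorbs floating-point
#' noise from time-calibration software without masking genuine rate trees.
#'
#' @param tree A `phylo` with branch lengths.
#' @param rel_tol Relative tolerance on the depth spread (default `1e-6`).
#' @return `TRUE` or `FALSE`.
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  dmax <- max(depths)
  if (dmax <= 0) stop("tree has zero depth; no branch length information")
  (dmax - min(depths)) <= rel_tol * dmax
}

#' Sample trees from a tree set
#'
#' Reproducible sub-sampling of a bootstrap (or otherwise replicated) tree
#' collection, as when 1000 trees are drawn from 10 000 bootstrap replicates
#' to propagate phylogenetic uncertainty through a comparative analysis.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) source set.
#' @param n Number of trees to draw.
#' @param seed Integer seed; the same seed always yields the same selection.
#' @param replace Sample with replacement?  Without replacement `n` must not
#'   exceed the source size.
#' @return A `multiPhylo` of `n` trees with a `"provenance"` attribute.
#' @export
sample_tree_set <- function(trees, n, seed = NULL, replace = FALSE) {
  trees <- as_tree_list(trees)
  if (length(trees) == 0L) stop("empty tree set")
  if (!replace && n > length(trees)) {
    stop("cannot draw ", n, " trees from ", length(trees),
         " without replacement")
  }
  idx <- with_seed(seed, sample.int(length(trees), n, replace = replace))
  out <- trees[idx]
  class(out) <- "multiPhylo"
  attr(out, "provenance") <- "subsample"
  attr(out, "source_index") <- idx
  out
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!inherits(trees, "multiPhylo")) {
    stopifnot(is.list(trees), all(vapply(trees, inherits, TRUE, "phylo")))
    class(trees) <- "multiPhylo"
  }
  trees
}

#' Prune a tree and trait table to their shared species
#'
#' @param tree A `phylo`.
#' @param traits Data frame from [read_trait_table()] (species as rownames).
#' @param quiet Suppress the message stating the intersection size?
#' @return List with elements `tree`, `traits` and `n_shared`.
#' @export
prune_to_shared <- function(tree, traits, quiet = FALSE) {
  shared <- intersect(tree$tip.label, rownames(traits))
  if (length(shared) < 2L) stop("fewer than two species shared between tree and traits")
  if (!quiet) {
    message(length(shared), " species shared between tree (",
            ape::Ntip(tree), " tips) and trait table (", nrow(traits), " rows)")
  }
  drop <- setdiff(tree$tip.label, shared)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  list(tree = tree, traits = traits[tree$tip.label, , drop = FALSE],
       n_shared = length(shared))
}
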