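#' Parse / write newick trees
#'
#' Thin wrappers over ape's newick reader and writer with the package's
#' taxon-name normalization applied to tip labels, so that tips match
#' specimen tables and stratigraphic-range tables regardless of
#' underscore/quote typography. Round-trip (parse, write, parse) is
#' topology-stable.
#'
#' @param text a newick string (\code{parse_newick}) or a \code{phylo}
#'   object (\code{write_newick}).
#' @return \code{parse_newick}: an \code{ape::phylo};
#'   \code{write_newick}: a newick string.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed newick string: ", substr(text, 1, 60))
  tr$tip.label <- normalize_taxon(tr$tip.label)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels after normalization")
  tr
}

#' @rdname parse_newick
#' @param tree a \code{phylo}.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Read a stratigraphic-range (FAD/LAD) table
#'
#' CSV with columns \code{taxon}, \code{FAD_Ma}, \code{LAD_Ma}: first
#' and last appearance data in millions of years before present. FAD >=
#' LAD >= 0 is enforced; taxon names are normalized for matching.
#'
#' @param path CSV path or data.frame in that shape.
#' @return data.frame with columns \code{taxon}, \code{FAD}, \code{LAD}.
#' @export
read_ranges <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "FAD_Ma", "LAD_Ma") %in% names(df))) {
    if (all(c("taxon", "FAD", "LAD") %in% names(df))) {
      df$FAD_Ma <- df$FAD; df$LAD_Ma <- df$LAD
    } else stop("ranges table needs columns taxon, FAD_Ma, LAD_Ma")
  }
  out <- data.frame(taxon = normalize_taxon(df$taxon),
                    FAD = as.numeric(df$FAD_Ma),
                    LAD = as.numeric(df$LAD_Ma),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$FAD) | is.na(out$LAD))) stop("missing FAD/LAD values")
  if (any(out$LAD < 0) || any(out$FAD < out$LAD))
    stop("ranges must satisfy FAD >= LAD >= 0")
  if (anyDuplicated(out$taxon)) stop("duplicate taxa in ranges table")
  out
}

#' Time-calibrate a tree from first/last appearance data
#'
#' Turns an undated (or partially dated) supertree into a tree with all
#' branch lengths positive, in Ma, using the taxon ranges:
#' \enumerate{
#'   \item \emph{Basic dating}: each internal node is placed at the
#'     oldest FAD among its descendant tips (ties resolved by the max
#'     rule, deterministically).
#'   \item \emph{Terminal ranges} (\code{add_term = TRUE}): each tip is
#'     placed at its LAD, so fossil tips end at last appearance and
#'     extant tips (LAD = 0) reach the present. With
#'     \code{add_term = FALSE} tips sit at their FAD.
#'   \item \emph{Zero-length-branch adjustment}: any branch of length
#'     zero (a node dated equal to its oldest child) is opened up by
#'     shifting the ancestral node older by \code{vartime}; the shift
#'     propagates rootward so no branch becomes negative.
#' }
#' Input branch lengths are ignored; only the topology and the ranges
#' determine the output. The root age is recorded in
#' \code{$root.time}.
#'
#' @param tree a \code{phylo}; tip labels must all appear in
#'   \code{ranges} after normalization.
#' @param ranges data.frame from [read_ranges()] (columns \code{taxon},
#'   \code{FAD}, \code{LAD}).
#' @param vartime positive age increment (Ma) used to open zero-length
#'   branches; default 1.
#' @param add_term extend terminal branches to the tips' LADs
#'   (default TRUE).
#' @return the dated \code{phylo}, with \code{edge.length} in Ma and
#'   attribute \code{root.time}.
#' @export
time_calibrate <- function(tree, ranges, vartime = 1, add_term = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (vartime <= 0) stop("'vartime' must be > 0")
  if (is.data.frame(ranges)) {
    if (!all(c("FAD", "LAD") %in% names(ranges))) ranges <- read_ranges(ranges)
  } else stop("'ranges' must be a data.frame")
  tree$tip.label <- normalize_taxon(tree$tip.label)
  m <- match(tree$tip.label, normalize_taxon(ranges$taxon))
  if (anyNA(m))
    stop("tip(s) missing from ranges table: ",
         paste(tree$tip.label[is.na(m)], collapse = ", "))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  fad <- ranges$FAD[m]
  lad <- ranges$LAD[m]

  # postorder edge walk: children before parents
  tr <- ape::reorder.phylo(tree, "postorder")
  fad_age <- numeric(ntip + nnode)           # node ages from FADs
  fad_age[seq_len(ntip)] <- fad
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    fad_age[p] <- max(fad_age[p], fad_age[ch])
  }

  # endpoint of each node's subtending branch: tips at LAD (add_term) or
  # FAD; internal nodes at their (possibly adjusted) age
  age <- fad_age
  endpt <- function(v) if (v <= ntip) (if (add_term) lad[v] else fad[v]) else age[v]
  # zero-length-branch adjustment, children first so shifts propagate
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    kids <- tr$edge[tr$edge[, 1] == p, 2]
    maxend <- max(vapply(kids, endpt, numeric(1)))
    if (age[p] <= maxend) age[p] <- maxend + vartime
  }

  out <- tr
  out$edge.length <- vapply(seq_len(nrow(tr$edge)), function(i) {
    age[tr$edge[i, 1]] - endpt(tr$edge[i, 2])
  }, numeric(1))
  if (any(out$edge.length <= 0))
    stop("internal error: non-positive branch length after calibration")
  out <- ape::reorder.phylo(out, "cladewise")
  out$root.time <- age[ntip + 1L]
  out
}

#' Phylogenetic covariance matrix of a dated tree
#'
#' The standard Brownian-motion covariance structure: entry (i, j) is
#' the branch length shared by the root-to-tip paths of tips i and j
#' (the depth of their most recent common ancestor below the root);
#' the diagonal holds each tip's root-to-tip distance. The tree need
#' not be ultrametric -- fossil tips that end before the present simply
#' have smaller diagonal entries.
#'
#' @param tree a \code{phylo} with positive branch lengths.
#' @return symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::vcv.phylo(tree)
}
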