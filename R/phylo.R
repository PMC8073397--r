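#' Cavalli-Sforza-Edwards chord distance on a presence/absence matrix
#'
#' Treats each MSS as a biallelic locus with allele frequencies in
#' `{0, 1}` per genome. For one locus with binary states `x`, `y` the
#' chord distance is `(2/pi) * sqrt(2 * (1 - cos(theta)))` with
#' `cos(theta) = 1` when the states agree and `0` otherwise; averaging
#' over loci gives `D = (2 * sqrt(2) / pi) * h`, where `h` is the
#' Hamming fraction. For binary profiles this is a metric (a positive
#' scaling of Hamming distance), so any reasonable variant of the chord
#' distance yields the same UPGMA topology.
#'
#' @param presence logical (or 0/1) matrix, rows = loci (MSSs), columns
#'   = genomes; or an [MssSet-class].
#' @return symmetric numeric distance matrix with zero diagonal, labeled
#'   by genome ids.
#' @examples
#' m <- cbind(a = c(TRUE, TRUE), b = c(TRUE, FALSE))
#' cseDistance(m)["a", "b"]  # 0.5 * 2*sqrt(2)/pi
#' @export
cseDistance <- function(presence) {
  if (is(presence, "MssSet")) presence <- presenceMatrix(presence)
  x <- matrix(as.numeric(presence), nrow = nrow(presence),
              dimnames = dimnames(presence))
  if (nrow(x) < 1L) stop("at least one locus required")
  if (ncol(x) < 2L) stop("at least two genomes required")
  L <- nrow(x)
  mism <- (t(x) %*% (1 - x) + t(1 - x) %*% x) / L
  d <- (2 * sqrt(2) / pi) * mism
  diag(d) <- 0
  (d + t(d)) / 2
}

#' UPGMA clustering with deterministic tie-breaking
#'
#' Standard UPGMA: repeatedly merge the two clusters at the smallest
#' distance, at height `d/2`, updating distances by the size-weighted
#' (proportional) arithmetic average. Ties are broken by the
#' lexicographically smallest pair of cluster labels, a cluster being
#' labeled by its smallest member. The result is a rooted ultrametric
#' tree (all leaves at height 0, every root-to-leaf path equal).
#'
#' @param d symmetric distance matrix with labels (e.g. from
#'   [cseDistance()]), or a `dist` object.
#' @return an object of class `upgmaTree`: a recursive node list (leaf
#'   nodes carry `label`; internal nodes carry `left`, `right`,
#'   `height`) with attributes `labels` and `order`.
#' @seealso [newickString()], [writeNewick()]
#' @export
upgmaTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop("at least two taxa required")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  labs <- rownames(d)
  nodes <- lapply(labs, function(l)
    structure(list(label = l, height = 0), class = "upgmaNode"))
  sizes <- rep(1L, n)
  keys <- labs                      # smallest member label per cluster
  active <- seq_len(n)
  dm <- d
  while (length(active) > 1L) {
    # find minimal pair with lexicographic tie-break on (keyA, keyB)
    best <- NULL
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1L)) {
      a <- active[jj]; b <- active[ii]
      ka <- keys[a]; kb <- keys[b]
      if (ka > kb) { tmp <- a; a <- b; b <- tmp; tmp <- ka; ka <- kb; kb <- tmp }
      dd <- dm[a, b]
      if (is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
           (ka < best$ka || (ka == best$ka && kb < best$kb)))) {
        best <- list(a = a, b = b, d = dd, ka = ka, kb = kb)
      }
    }
    a <- best$a; b <- best$b
    h <- best$d / 2
    node <- structure(list(left = nodes[[a]], right = nodes[[b]],
                           height = h), class = "upgmaNode")
    nodes[[a]] <- node
    sz <- sizes[a] + sizes[b]
    for (k in setdiff(active, c(a, b)))
      dm[a, k] <- dm[k, a] <-
        (sizes[a] * dm[a, k] + sizes[b] * dm[b, k]) / sz
    sizes[a] <- sz
    keys[a] <- min(keys[a], keys[b])
    active <- setdiff(active, b)
  }
  structure(nodes[[active]], class = c("upgmaTree", "upgmaNode"),
            labels = labs)
}

.nwkLabel <- function(label) {
  if (grepl("[][ \t();:,']", label))
    paste0("'", gsub("'", "''", label), "'")
  else label
}

.nwkNode <- function(node, parentHeight) {
  bl <- round(parentHeight - node$height, 10)  # zap float noise on ties
  blStr <- if (is.na(bl)) "" else sprintf(":%g", bl)
  if (!is.null(node$label))
    return(paste0(.nwkLabel(node$label), blStr))
  paste0("(", .nwkNode(node$left, node$height), ",",
         .nwkNode(node$right, node$height), ")", blStr)
}

#' Newick serialization of a UPGMA tree
#'
#' Branch lengths are height differences (ultrametric); labels containing
#' spaces or Newick metacharacters are single-quoted.
#'
#' @param tree an `upgmaTree` from [upgmaTree()].
#' @return single Newick string terminated by `";"`.
#' @export
newickString <- function(tree) {
  paste0("(", .nwkNode(tree$left, tree$height), ",",
         .nwkNode(tree$right, tree$height), ");")
}

#' Write a UPGMA tree as a Newick file
#'
#' @param tree an `upgmaTree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  writeLines(newickString(tree), path)
  invisible(path)
}

#' @export
print.upgmaTree <- function(x, ...) {
  cat("UPGMA tree with", length(attr(x, "labels")), "leaves, height",
      format(x$height), "\n")
  cat(newickString(x), "\n")
  invisible(x)
}

# Leaf labels of each subtree, used by topology checks.
.treeLeaves <- function(node) {
  if (!is.null(node$label)) return(node$label)
  c(.treeLeaves(node$left), .treeLeaves(node$right))
}

#' Monophyly check on a UPGMA tree
#'
#' `TRUE` when some subtree contains exactly the given labels — used for
#' qualitative topology assertions (e.g. that a query mitotype clusters
#' with its nearest relatives).
#'
#' @param tree an `upgmaTree`.
#' @param labels character vector of leaf labels.
#' @return logical.
#' @export
isMonophyletic <- function(tree, labels) {
  found <- FALSE
  walk <- function(node) {
    if (found) return(invisible())
    lv <- .treeLeaves(node)
    if (setequal(lv, labels)) { found <<- TRUE; return(invisible()) }
    if (is.null(node$label)) { walk(node$left); walk(node$right) }
    invisible()
  }
  walk(tree)
  found
}
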