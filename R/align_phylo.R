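# Alignment editing, distance/NJ trees with bootstrap, newick I/O and
# reference-guided clade assignment. The internal NJ + classical bootstrap
# is a desk-scale tree builder; externally computed maximum-likelihood
# trees are first-class inputs via read_newick().

#' Read / write an aligned FASTA file
#'
#' An alignment is a named character vector of equal-length gapped (`-`)
#' sequences.
#'
#' @param path File path.
#' @return Named character vector (ids -> aligned sequences).
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("[[:space:]].*$", "", names(seqs))
  validate_alignment(out)
  out
}

#' @rdname read_alignment
#' @param alignment Named character vector of equal-length rows.
#' @export
write_alignment <- function(alignment, path) {
  validate_alignment(alignment)
  hdr <- names(alignment)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(alignment)) {
    writeLines(paste0(">", hdr[i]), con)
    s <- alignment[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

validate_alignment <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  if (is.null(names(alignment)) || anyDuplicated(names(alignment)))
    stop("alignment rows must have unique ids")
  if (length(unique(nchar(alignment))) != 1L)
    stop("ragged alignment: rows differ in length")
  invisible(alignment)
}

alignment_matrix <- function(alignment) {
  validate_alignment(alignment)
  do.call(rbind, strsplit(alignment, ""))
}

#' Remove high-gap alignment columns
#'
#' Removes every column whose gap fraction is strictly greater than
#' `threshold` (a column at exactly the threshold is kept), mirroring the
#' common manual editing step of deleting regions containing more than 50%
#' gaps before tree inference. Idempotent.
#'
#' @param alignment Named character vector of equal-length rows.
#' @param threshold Gap-fraction threshold, default 0.5.
#' @return List with `alignment` (edited) and `removed` (0-based indices of
#'   removed columns, as reported by common alignment editors).
#' @export
filter_gap_columns <- function(alignment, threshold = 0.5) {
  m <- alignment_matrix(alignment)
  gap_frac <- colMeans(m == "-")
  drop <- which(gap_frac > threshold)
  kept <- if (length(drop)) m[, -drop, drop = FALSE] else m
  out <- apply(kept, 1L, paste, collapse = "")
  names(out) <- rownames(m) <- names(alignment)
  list(alignment = out, removed = as.integer(drop - 1L))
}

#' Pairwise distance matrix from a protein alignment
#'
#' Pairs are compared over mutually ungapped columns (pairwise deletion).
#' `U` (selenocysteine) is treated as `C` for distance purposes. The
#' Poisson correction is d = -ln(1 - p).
#'
#' @param alignment Named character vector of equal-length rows.
#' @param model `"p"` (proportion of differing sites) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- alignment_matrix(chartr("U", "C", alignment))
  n <- nrow(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop(sprintf("no mutually ungapped columns for pair %s / %s",
                   rownames(m)[i], rownames(m)[j]))
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  if (model == "poisson") {
    if (any(d[upper.tri(d)] >= 1))
      stop("Poisson correction undefined: a pair differs at every compared site (p = 1)")
    d <- -log(1 - d)
  }
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' Classical neighbor-joining on a symmetric distance matrix. Negative
#' branch lengths (an NJ artefact) are clamped to zero, with the total
#' clamped deficit recorded in the `clamped_deficit` attribute.
#'
#' @param d Symmetric distance matrix (n >= 3) with labelled rows.
#' @param tol Allowed asymmetry before erroring.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Classical column-resampling bootstrap: `B` replicate alignments are
#' drawn by sampling columns with replacement, a NJ tree is built from
#' each, and the support of every internal bipartition of the full-data
#' tree is the percentage of replicate trees containing it. Supports are
#' stored as node labels. Reproducible given `seed`.
#'
#' @param alignment Named character vector of equal-length rows.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param model Distance model, see [distance_matrix()].
#' @return A `phylo` tree with `node.label` holding supports in [0, 100].
#' @export
bootstrap_support <- function(alignment, B = 100L, seed = 1L,
                              model = c("p", "poisson")) {
  model <- match.arg(model)
  if (B < 1L) stop("B must be >= 1")
  m <- alignment_matrix(alignment)
  ref <- nj_tree(distance_matrix(alignment, model = model))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(rep_aln) <- rownames(m)
    reps[[b]] <- nj_tree(distance_matrix(rep_aln, model = model))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / B, 1))
  ref
}

#' Read / write newick trees
#'
#' Thin wrappers preserving topology, branch lengths and internal-node
#' support labels (as written by common tree builders).
#'
#' @param path File path.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty newick file: ", path)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

edge_tip_sets <- function(tree) {
  # tips (labels) below the child node of every edge, in edge order
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  # postorder guarantees children are resolved before their parents
  for (k in ape::postorder(tree)) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) below[[tree$edge[k, 2]]])
}

#' Assign a subfamily label to a query leaf from labelled reference leaves
#'
#' Finds the smallest clade (bipartition side of an edge of the unrooted
#' tree) containing the query and at least one reference leaf. The label is
#' assigned iff all reference leaves inside that clade carry one common
#' label and, when `min_support` is given, the defining edge's support is
#' at least `min_support`. Otherwise no label is assigned and the cause is
#' reported (`mixed`, `low_support`, or `no_labeled_clade`).
#'
#' @param tree A `phylo` tree whose `node.label`, if present, holds numeric
#'   supports.
#' @param ref_labels Named character vector, reference leaf -> label.
#' @param query Query tip label.
#' @param min_support Optional minimum support for the defining edge.
#' @return List of class `clade_assignment` with `query`, `label` (or
#'   `NA`), `support`, `clade_size`, `cause`.
#' @export
assign_clade <- function(tree, ref_labels, query, min_support = NULL) {
  if (!query %in% tree$tip.label) stop("query not in tree: ", query)
  refs <- intersect(names(ref_labels), tree$tip.label)
  if (length(refs) == 0L) stop("no reference leaf present in the tree")
  ntip <- length(tree$tip.label)
  all_tips <- tree$tip.label
  sets <- edge_tip_sets(tree)
  supports <- rep(NA_real_, nrow(tree$edge))
  if (!is.null(tree$node.label)) {
    child <- tree$edge[, 2]
    internal <- child > ntip
    supports[internal] <- suppressWarnings(
      as.numeric(tree$node.label[child[internal] - ntip]))
  }
  best <- NULL
  for (k in seq_len(nrow(tree$edge))) {
    side <- sets[[k]]
    if (!query %in% side) side <- setdiff(all_tips, side)
    side_refs <- intersect(side, refs)
    side_refs <- setdiff(side_refs, query)
    if (length(side_refs) == 0L) next
    key <- list(size = length(side), tips = paste(sort(side), collapse = "|"),
                refs = side_refs, support = supports[k])
    if (is.null(best) || key$size < best$size ||
        (key$size == best$size && key$tips < best$tips))
      best <- key
  }
  out <- list(query = query, label = NA_character_, support = NA_real_,
              clade_size = NA_integer_, cause = "no_labeled_clade")
  if (!is.null(best)) {
    labs <- unique(unname(ref_labels[best$refs]))
    out$support <- best$support
    out$clade_size <- best$size
    if (length(labs) > 1L) {
      out$cause <- "mixed"
    } else if (!is.null(min_support) &&
               (is.na(best$support) || best$support < min_support)) {
      out$cause <- "low_support"
    } else {
      out$label <- labs
      out$cause <- NA_character_
    }
  }
  structure(out, class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("clade assignment for '%s': %s (clade size %s, support %s%s)\n",
              x$query,
              if (is.na(x$label)) paste0("none [", x$cause, "]") else x$label,
              x$clade_size, x$support,
              ""))
  invisible(x)
}
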