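# Independent brute-force oracles used to cross-check the implementation.

aa20 <- setdiff(aa_alphabet(), c("U", "X"))

random_seq <- function(n, alphabet = aa20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Motif oracle: translate the restricted grammar to a PCRE with lazy
# bounded gaps and a lookahead capture, so overlapping matches are found
# by the regex engine rather than by our scanner.
oracle_scan <- function(sequence, spec) {
  rx <- gsub("X\\{(\\d+),(\\d+)\\}", ".{\\1,\\2}?", spec)
  rx <- gsub("X", ".", rx, fixed = TRUE)   # no bundled class contains X
  m <- gregexpr(paste0("(?=(", rx, "))"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  cap_len <- attr(m, "capture.length")[, 1]
  data.frame(start = as.integer(m), end = as.integer(m) + cap_len - 1L)
}

# p-distance oracle: direct pairwise counting over mutually ungapped
# columns, U folded into C.
oracle_pdist <- function(alignment) {
  rows <- strsplit(chartr("U", "C", alignment), "")
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- rows[[i]] != "-" & rows[[j]] != "-"
    d[i, j] <- sum(rows[[i]][ok] != rows[[j]][ok]) / sum(ok)
  }
  d
}

# Gap-column oracle: per-column gap fraction by explicit counting.
oracle_gap_columns <- function(alignment, threshold = 0.5) {
  m <- do.call(rbind, strsplit(alignment, ""))
  which(vapply(seq_len(ncol(m)), function(j)
    mean(m[, j] == "-") > threshold, logical(1)))
}

# Clade-assignment oracle: enumerate every bipartition by deleting each
# edge of the tree graph and taking connected components (igraph), then
# apply the smallest-enclosing-pure-clade rule directly.
oracle_assign <- function(tree, ref_labels, query) {
  ntip <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  qnode <- as.character(match(query, tree$tip.label))
  best <- NULL
  for (e in seq_len(igraph::ecount(g))) {
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership   # named by vertex name
    side_ids <- as.integer(names(comp)[comp == comp[[qnode]]])
    side <- tree$tip.label[side_ids[side_ids <= ntip]]
    side_refs <- setdiff(intersect(side, names(ref_labels)), query)
    if (length(side_refs) == 0L) next
    key <- list(size = length(side),
                tips = paste(sort(side), collapse = "|"),
                refs = side_refs)
    if (is.null(best) || key$size < best$size ||
        (key$size == best$size && key$tips < best$tips))
      best <- key
  }
  if (is.null(best)) return(NA_character_)
  labs <- unique(unname(ref_labels[best$refs]))
  if (length(labs) == 1L) labs else NA_character_
}

# End-to-end synthetic run helper.
run_synthetic <- function(config) {
  ds <- generate_dataset(config)
  d <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_dataset(ds, d)
  res <- run_classify(paths$manifest, paths$domtblout, file.path(d, "out"))
  list(ds = ds, res = res, dir = d, paths = paths)
}

census_as_plain <- function(census, template) {
  out <- as.data.frame(census)[, names(template)]
  rownames(out) <- NULL
  out
}

# Filler sequence over an alphabet that cannot complete any bundled motif
# (no C, F, G, H, P, S, W, Y), so planted motifs are the only matches.
random_seq_fixed <- function(n) {
  paste(sample(c("A", "D", "E", "I", "K", "L", "M", "N", "Q", "R", "T", "V"),
               n, replace = TRUE), collapse = "")
}

# Compact constructor for domain-hit rows: list(protein, accession, start,
# end, evalue[, score]).
mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], accession = r[[2]], domain_name = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               score = ifelse(length(r) >= 6, as.numeric(r[[6]]), 100),
               evalue = as.numeric(r[[5]]), stringsAsFactors = FALSE)))
}
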