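test_that("gap-column editing uses a strict threshold and is idempotent", {
  aln <- c(a = "A-AC", b = "A-AC", c = "AAA-", d = "A-AC")
  # column 2 has gap fraction 0.75 -> removed; column 4 has 0.25 -> kept
  out <- filter_gap_columns(aln)
  expect_equal(out$removed, 1L)   # 0-based index of column 2
  expect_equal(unname(out$alignment), c("AAC", "AAC", "AA-", "AAC"))
  # the exact-0.5 boundary column is kept
  aln2 <- c(a = "A-", b = "A-", c = "AA", d = "AA")
  expect_length(filter_gap_columns(aln2)$removed, 0L)
  # gap-free alignments pass through unchanged; editing is idempotent
  clean <- c(a = "ACDE", b = "ACDF")
  expect_equal(filter_gap_columns(clean)$alignment, clean)
  again <- filter_gap_columns(out$alignment)
  expect_equal(again$alignment, out$alignment)
  expect_length(again$removed, 0L)
  expect_error(filter_gap_columns(c(a = "AC", b = "A")), "ragged")
})

test_that("gap filtering matches the per-column counting oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:10, 1); L <- sample(20:60, 1)
    m <- matrix(sample(c(aa20, "-"), n * L, replace = TRUE,
                       prob = c(rep(1, 20), 8)), nrow = n)
    aln <- apply(m, 1, paste, collapse = "")
    names(aln) <- paste0("s", seq_len(n))
    expect_equal(filter_gap_columns(aln)$removed,
                 as.integer(oracle_gap_columns(aln) - 1L))
  }
})

test_that("distances follow pairwise deletion and the Poisson correction", {
  aln <- c(a = "AAAA", b = "AAAT", c = "AAAA")
  d <- distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(unname(diag(d)), rep(0, 3))
  dp <- distance_matrix(aln, model = "poisson")
  expect_equal(dp["a", "b"], -log(1 - 0.25))
  # U is folded into C for distance purposes
  expect_equal(distance_matrix(c(a = "UCAA", b = "CCAA"))["a", "b"], 0)
  # a pair with no mutually ungapped columns is an error
  expect_error(distance_matrix(c(a = "A--A", b = "-AA-", c = "AAAA")),
               "mutually ungapped")
  expect_error(distance_matrix(c(a = "AC", b = "CA"), model = "poisson"),
               "p = 1")
})

test_that("distance matrices equal the brute-force counting oracle", {
  set.seed(33)
  for (i in 1:10) {
    g <- generate_subfamily_alignment(members = 3L, length = 40L,
                                      gap_fractions = c(0.3, 0.3), seed = i)
    d <- distance_matrix(g$alignment)
    expect_equal(d, oracle_pdist(g$alignment)[rownames(d), colnames(d)],
                 tolerance = 1e-12)
  }
})

test_that("neighbor-joining recovers additive trees exactly", {
  # a fixed 4-taxon additive matrix from tree ((a:1,b:2):1,(c:3,d:1));
  D <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_equal(max(abs(stats::cophenetic(tr)[letters[1:4], letters[1:4]] - D)), 0)
  # star-like equidistant matrix: zero-length internal branch
  S <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4])); diag(S) <- 0
  st <- nj_tree(S)
  internal <- st$edge[, 2] > length(st$tip.label)
  expect_equal(sum(st$edge.length[internal]), 0)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  A <- D; A[1, 2] <- 9
  expect_error(nj_tree(A), "symmetric")
})

test_that("negative NJ branch lengths are clamped and logged", {
  # a non-additive matrix whose NJ estimate has a negative branch
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D[upper.tri(D)] <- c(1.917, 1.491, 1.444, 0.593, 0.809, 0.765)
  D <- D + t(D)
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "clamped_deficit"), 0)
})

test_that("bootstrap supports are seed-deterministic and bounded", {
  g <- generate_subfamily_alignment(members = 4L, length = 80L, seed = 5)
  b1 <- bootstrap_support(g$alignment, B = 30, seed = 99)
  b2 <- bootstrap_support(g$alignment, B = 30, seed = 99)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- as.numeric(b1$node.label)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("newick round trips preserve topology, lengths and supports", {
  pnw <- withr::local_tempfile(lines = "((a:1,b:1)90:0.5,c:2,(d:1,e:1)75:0.3);")
  t1 <- read_newick(pnw)
  expect_equal(sort(t1$tip.label), letters[1:5])
  expect_true("90" %in% t1$node.label)
  set.seed(17)
  for (i in 1:50) {
    tr <- ape::rtree(sample(4:12, 1))
    p <- withr::local_tempfile()
    write_newick(tr, p)
    back <- read_newick(p)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }
  p2 <- withr::local_tempfile(lines = "((a,b,c);")
  expect_error(read_newick(p2))
  p3 <- withr::local_tempfile(lines = character())
  expect_error(read_newick(p3), "empty")
})

test_that("clade assignment follows the smallest-pure-clade rule", {
  tr <- ape::read.tree(text = "((q,(r1,r2)),((r3,r4),(s1,s2)));")
  refs <- c(r1 = "PRX6", r2 = "PRX6", r3 = "PRX6", r4 = "PRX6",
            s1 = "PRX5", s2 = "PRX5")
  a <- assign_clade(tr, refs, "q")
  expect_equal(a$label, "PRX6")
  expect_equal(a$clade_size, 3L)
  # smallest enclosing clade mixing labels -> none, cause mixed
  refs2 <- c(r1 = "PRX5", r2 = "PRX6", r3 = "PRX6", r4 = "PRX6")
  a2 <- assign_clade(tr, refs2, "q")
  expect_true(is.na(a2$label))
  expect_equal(a2$cause, "mixed")
  expect_error(assign_clade(tr, refs, "nope"), "not in tree")
})

test_that("low support blocks assignment when a floor is set", {
  tr <- ape::read.tree(text = "((q:1,(r1:1,r2:1)40:1)90:1,(r3:1,r4:1)99:1);")
  refs <- c(r1 = "A", r2 = "A", r3 = "B", r4 = "B")
  free <- assign_clade(tr, refs, "q")
  expect_equal(free$label, "A")
  gated <- assign_clade(tr, refs, "q", min_support = 95)
  expect_true(is.na(gated$label))
  expect_equal(gated$cause, "low_support")
})

test_that("clade assignment equals bipartition enumeration on random trees", {
  set.seed(55)
  for (i in 1:40) {
    n <- sample(6:16, 1)
    tr <- ape::rtree(n)
    tips <- tr$tip.label
    q <- sample(tips, 1)
    nref <- sample(2:(n - 1), 1)
    refs <- stats::setNames(sample(c("A", "B", "C"), nref, replace = TRUE),
                            sample(setdiff(tips, q), nref))
    got <- assign_clade(tr, refs, q)
    want <- oracle_assign(tr, refs, q)
    expect_identical(got$label, want, label = sprintf("tree %d", i))
  }
})
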