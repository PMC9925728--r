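test_that("the pattern grammar compiles fixed residues, alternations and gaps", {
  p <- compile_pattern("PXXX[TS]XXC")
  expect_length(p$elements, 8L)
  expect_equal(p$elements[[1]]$residues, "P")
  expect_equal(sort(p$elements[[5]]$residues), c("S", "T"))
  expect_equal(p$elements[[8]]$residues, "C")
  expect_equal(c(p$min_len, p$max_len), c(8L, 8L))

  p2 <- compile_pattern("F[SG]GCHR")
  expect_length(p2$elements, 6L)
  expect_equal(sort(p2$elements[[2]]$residues), c("G", "S"))

  p3 <- compile_pattern("HX{0,40}SX{0,40}D")
  expect_equal(p3$elements[[2]]$type, "gap")
  expect_equal(c(p3$elements[[2]]$min, p3$elements[[2]]$max), c(0L, 40L))
  expect_equal(c(p3$min_len, p3$max_len), c(3L, 83L))

  expect_error(compile_pattern("P[TS"), "column")
  expect_error(compile_pattern("PX{2,1}C"), "min > max")
  expect_error(compile_pattern("XXX"), "non-wildcard")
  expect_error(compile_pattern("P1C"), "column 2")
})

test_that("C_P scanning accepts the motif and rejects the T/S violation", {
  m <- scan_motif("MKPVDFTFVCR", "PXXX[TS]XXC")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(3L, 10L))
  expect_equal(m$match, "PVDFTFVC")
  expect_equal(nrow(scan_motif("MKPVDFAFVCR", "PXXX[TS]XXC")), 0L)
  cp <- find_cp("MKPVDFTFVCR")
  expect_equal(cp$cp_pos, 10L)
})

test_that("scanner output equals the exhaustive regex oracle", {
  set.seed(42)
  pats <- c("PXXX[TS]XXC", "F[SG]GCHR", "GGLG", "YF", "GXSXG",
            "HX{0,60}SX{0,60}D")
  for (i in 1:100) {
    s <- random_seq(300)
    for (spec in pats) {
      got <- scan_motif(s, spec)
      want <- oracle_scan(s, spec)
      expect_equal(got$start, want$start, info = spec)
      expect_equal(got$end, want$end, info = spec)
    }
  }
})

test_that("leftmost C_P is reported with the alternatives counted", {
  s <- paste0("AA", "PVDFTFVC", "AAAA", "PQQQSQQC", "AA")
  cp <- find_cp(s)
  expect_equal(cp$start, 3L)
  expect_equal(cp$n_matches, 2L)
  # knocking the catalytic cysteine out to serine removes the site
  s2 <- sub("PVDFTFVC", "PVDFTFVS", s)
  expect_equal(find_cp(s2)$start, 15L)
})

test_that("C_R status distinguishes present, substituted and absent", {
  base <- paste0(random_seq_fixed(60), "HGEVCPAGW", random_seq_fixed(10))
  r <- find_cr(base, "AhpC-PRX1")
  expect_equal(r$status, "present")
  expect_equal(substring(base, r$position, r$position), "C")
  val <- sub("HGEVCPAGW", "HGEVVPAGW", base)
  rv <- find_cr(val, "AhpC-PRX1")
  expect_equal(rv$status, "substituted")
  expect_equal(rv$residue, "V")
  trunc <- substring(base, 1, 50)
  expect_equal(find_cr(trunc, "AhpC-PRX1")$status, "absent")
})

test_that("PLA2 triad requires ordered H-S-D within gap bounds", {
  full <- "AAHAAAGASMGAAADAA"
  expect_equal(pla2_triad(full)$status, "full")
  expect_equal(unname(pla2_triad(full)$positions),
               c(3L, 9L, 15L))   # S from the GXSXG match
  # D preceding H: order violated, all roles present -> absent
  expect_equal(pla2_triad("AADAAASAAAHAA", gap_max = 5)$status, "absent")
  # serine knocked out -> partial, missing S
  part <- pla2_triad("AAHAAAGAAMGAAADAA")
  expect_equal(part$status, "partial")
  expect_equal(part$missing, "S")
  # gap bound enforced
  far <- paste0("H", strrep("A", 70), "S", "D")
  expect_equal(pla2_triad(far, gap_max = 60)$status, "absent")
  expect_equal(pla2_triad(far, gap_max = 80)$status, "full")
})

test_that("GXSXG detection is exact", {
  expect_true(gxsxg("AAGASTGAA"))
  expect_false(gxsxg("AAGASTAAA"))
  set.seed(9)
  for (i in 1:50) {
    s <- random_seq(200)
    expect_equal(gxsxg(s), nrow(oracle_scan(s, "GXSXG")) > 0L)
  }
})

test_that("GPX tetrad typing follows the catalytic residue", {
  ref <- gpx_reference()
  t_sec <- gpx_tetrad(ref$sequence)
  expect_equal(t_sec$type, "selenium-dependent")
  expect_equal(unname(t_sec$residues), c("U", "Q", "W", "N"))
  expect_equal(unname(t_sec$positions), unname(ref$tetrad))
  t_cys <- gpx_tetrad(chartr("U", "C", ref$sequence))
  expect_equal(t_cys$type, "cysteine-dependent")
  # catalytic slot deleted -> undetermined
  chars <- strsplit(ref$sequence, "")[[1]]
  gone <- paste(chars[-ref$tetrad[["catalytic"]]], collapse = "")
  expect_equal(gpx_tetrad(gone)$type, "undetermined")
  # unrelated sequence: coverage failure, undetermined with reason
  t_bad <- gpx_tetrad(random_seq_fixed(40))
  expect_equal(t_bad$type, "undetermined")
})

test_that("hyperoxidation motifs are found in the C-terminal half", {
  s <- paste0(random_seq_fixed(120), "WHEPNGS", random_seq_fixed(10),
              "CEVDKSL", random_seq_fixed(5), "GGLG", random_seq_fixed(5),
              "YF", random_seq_fixed(10))
  hx <- hyperox_motifs(s)
  expect_true(hx$gglg)
  expect_true(hx$yf)
  expect_equal(nrow(hx$ab_substitutions), 0L)
  # YF deleted: yf absent, gglg untouched
  s_noyf <- sub("YF", "AA", s)
  hx2 <- hyperox_motifs(s_noyf)
  expect_false(hx2$yf)
  expect_true(hx2$gglg)
  # a-motif His -> Ala is reported as a substitution at the His role
  s_sub <- sub("WHEPNGS", "WAEPNGS", s)
  hx3 <- hyperox_motifs(s_sub)
  expect_true(any(hx3$ab_substitutions$motif == "a" &
                  hx3$ab_substitutions$role == "His" &
                  hx3$ab_substitutions$observed == "A"))
  # a GGLG in the N-terminal half is outside the default search space
  s_n <- paste0("AAGGLGAA", random_seq_fixed(200))
  expect_false(hyperox_motifs(s_n)$gglg)
  expect_true(hyperox_motifs(s_n, search = "full")$gglg)
})

test_that("the SRX binding motif accepts both alternation branches only", {
  expect_true(srx_motif("AAFSGCHRAA"))
  expect_true(srx_motif("AAFGGCHRAA"))
  expect_false(srx_motif("AAFAGCHRAA"))
  set.seed(13)
  for (i in 1:50) {
    s <- random_seq(200)
    expect_equal(srx_motif(s), nrow(oracle_scan(s, "F[SG]GCHR")) > 0L)
  }
})

test_that("corrupting a fixed residue removes exactly that motif", {
  s <- paste0("AAA", "PVDFTFVC", "AAA", "FSGCHR", "AAA", "GGLG", "AAA")
  pats <- list(cp = "PXXX[TS]XXC", srx = "F[SG]GCHR", gglg = "GGLG")
  before <- vapply(pats, function(p) nrow(scan_motif(s, p)), integer(1))
  expect_true(all(before == 1L))
  s_mut <- sub("FSGCHR", "FSGAHR", s)   # break the SRX cysteine
  after <- vapply(pats, function(p) nrow(scan_motif(s_mut, p)), integer(1))
  expect_equal(unname(after), c(1L, 0L, 1L))
})

test_that("region constraints restrict match starts and are monotone", {
  s <- paste0("GGLG", strrep("A", 50), "GGLG", strrep("A", 50))
  expect_equal(scan_motif(s, "GGLG")$start, c(1L, 55L))
  expect_equal(scan_motif(s, "GGLG", region = c(40L, 108L))$start, 55L)
  expect_equal(scan_motif(s, "GGLG", region = c(50L, 54L), flank = 5L)$start, 55L)
  # shrinking a region never adds matches
  wide <- scan_motif(s, "GGLG", region = c(1L, 108L))
  narrow <- scan_motif(s, "GGLG", region = c(30L, 80L))
  expect_true(all(narrow$start %in% wide$start))
  expect_error(scan_motif(s, "GGLG", region = c(0L, 10L)), "region")
})

test_that("selenocysteine matches C-fixed slots only under the flag", {
  s <- "AAPVDFTFVUR"   # U where the C_P cysteine would sit
  expect_equal(nrow(scan_motif(s, "PXXX[TS]XXC")), 0L)
  expect_equal(nrow(scan_motif(s, "PXXX[TS]XXC", sec_equivalence = TRUE)), 1L)
})
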