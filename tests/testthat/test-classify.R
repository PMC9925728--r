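one_rec <- function(id, seq, sp = "sp1") {
  data.frame(protein_id = id, species_id = sp, sequence = seq,
             description = "", stringsAsFactors = FALSE)
}

prx_hits <- function(id) mk_hits(list(id, "PF00578", 20, 160, 1e-30),
                                 list(id, "PF10417", 170, 200, 1e-12))

test_that("PRX acceptance requires the C_P motif", {
  set.seed(2)
  with_cp <- paste0(random_seq_fixed(40), "PVDFTFVC", random_seq_fixed(200))
  rec <- one_rec("prx_ok", with_cp)
  call <- call_family(rec, prx_hits("prx_ok"), "PRX")
  expect_equal(call$status, "accepted")
  expect_equal(call$family, "PRX")
  expect_equal(call$evidence$cp$cp_pos, 48L)

  rec2 <- one_rec("prx_bad", random_seq_fixed(250))
  call2 <- call_family(rec2, prx_hits("prx_bad"), "PRX")
  expect_equal(call2$status, "rejected")
  expect_equal(call2$reject_reasons, "missing_CP")
})

test_that("CAT acceptance uses architecture plus the optional length floor", {
  set.seed(3)
  cat_hits <- mk_hits(list("c1", "PF00199", 10, 390, 1e-40),
                      list("c1", "PF06628", 400, 470, 1e-30))
  long <- one_rec("c1", random_seq_fixed(480))
  expect_equal(call_family(long, cat_hits, "CAT")$status, "accepted")
  short <- one_rec("c1", random_seq_fixed(300))
  sc <- call_family(short, cat_hits, "CAT")
  expect_equal(sc$status, "rejected")
  expect_match(sc$reject_reasons, "below_length_floor")
  no_floor <- classify_config(cat_length_floor = NULL)
  expect_equal(call_family(short, cat_hits, "CAT", no_floor)$status, "accepted")
})

test_that("GPX acceptance requires a resolved catalytic tetrad", {
  ref <- gpx_reference()
  g_hits <- mk_hits(list("g1", "PF00255", 1, 140, 1e-50))
  ok <- call_family(one_rec("g1", ref$sequence), g_hits, "GPX")
  expect_equal(ok$status, "accepted")
  expect_equal(ok$evidence$tetrad$type, "selenium-dependent")
  chars <- strsplit(ref$sequence, "")[[1]]
  chars[ref$tetrad[["catalytic"]]] <- "R"
  bad <- call_family(one_rec("g1", paste(chars, collapse = "")), g_hits, "GPX")
  expect_equal(bad$status, "rejected")
  expect_match(bad$reject_reasons, "tetrad_undetermined")
})

test_that("multi-family nominations resolve to the higher-scoring family", {
  set.seed(4)
  h <- mk_hits(list("x", "PF00199", 10, 390, 1e-40, 250),
               list("x", "PF06628", 400, 470, 1e-30, 90),
               list("x", "PF00255", 480, 600, 1e-10, 40))
  rec <- one_rec("x", random_seq_fixed(620))
  call <- call_family(rec, h, c("CAT", "GPX"))
  expect_equal(call$family, "CAT")
  expect_equal(call$evidence$conflicts, "GPX")
})

test_that("active-site profiles recover their own consensus subfamily", {
  profiles <- prx_cp_profiles()
  for (sf in names(profiles)) {
    win <- prx_cp_consensus()[[sf]]
    seqs <- paste0(random_seq_fixed(43), win, random_seq_fixed(100))
    rec <- one_rec("q", seqs)
    cp <- find_cp(seqs)
    expect_equal(cp$cp_pos, 51L)
    call <- classify_prx_subfamily(rec, cp, profiles)
    expect_equal(call$label, sf)
    expect_gt(call$margin, 1)
  }
})

test_that("a margin below threshold yields unclassified, monotonically", {
  profiles <- prx_cp_profiles()
  win <- prx_cp_consensus()[["PRX6"]]
  seqs <- paste0(random_seq_fixed(43), win, random_seq_fixed(100))
  rec <- one_rec("q", seqs)
  cp <- find_cp(seqs)
  strict <- classify_prx_subfamily(rec, cp, profiles,
                                   config = classify_config(profile_margin = 1e6))
  expect_true(is.na(strict$label))
  expect_equal(strict$cause, "margin_below_threshold")
  # raising the margin can only lose labels, never gain them
  lax <- classify_prx_subfamily(rec, cp, profiles,
                                config = classify_config(profile_margin = 0.1))
  expect_false(is.na(lax$label))
})

test_that("clade placement overrides the profile label with a flag", {
  profiles <- prx_cp_profiles()
  win <- prx_cp_consensus()[["AhpC-PRX1"]]
  seqs <- paste0(random_seq_fixed(43), win, random_seq_fixed(100))
  rec <- one_rec("q", seqs)
  cp <- find_cp(seqs)
  clade <- structure(list(query = "q", label = "PRX4-like", support = 99,
                          clade_size = 5L, cause = NA_character_),
                     class = "clade_assignment")
  call <- classify_prx_subfamily(rec, cp, profiles, clade = clade)
  expect_equal(call$label, "PRX4-like")
  expect_equal(call$method, "both")
  expect_false(call$agreement)
})

test_that("truncated C_P windows are scored over available positions", {
  profiles <- prx_cp_profiles()
  win <- prx_cp_consensus()[["PRX5"]]
  seqs <- paste0("PGAFTPGC", "SKT")   # window truncated at both sequence ends
  rec <- one_rec("q", seqs)
  cp <- find_cp(seqs)
  call <- classify_prx_subfamily(rec, cp, profiles)
  expect_true(call$truncated)
  expect_equal(call$label, "PRX5")
})

test_that("GPX subfamily labels come from clade placement only", {
  rec <- one_rec("g", gpx_reference()$sequence)
  clade <- structure(list(query = "g", label = "GPX7/8", support = 99,
                          clade_size = 4L, cause = NA_character_),
                     class = "clade_assignment")
  expect_equal(classify_gpx_subfamily(rec, clade)$label, "GPX7/8")
  none <- classify_gpx_subfamily(rec, NULL)
  expect_true(is.na(none$label))
  expect_equal(none$cause, "no_clade_assignment")
})

test_that("species SRX status is the documented tri-state", {
  set.seed(8)
  srx_ok <- paste0(random_seq_fixed(90), "FSGCHR", random_seq_fixed(20))
  srx_no <- random_seq_fixed(120)
  h <- mk_hits(list("s1", "PF02195", 15, 95, 1e-20))
  expect_equal(species_srx_status(one_rec("s1", srx_ok), h)$status, "competent")
  expect_equal(species_srx_status(one_rec("s1", srx_no), h)$status, "domain_only")
  empty_hits <- h[0, ]
  expect_equal(species_srx_status(one_rec("s1", srx_ok), empty_hits)$status,
               "absent")
})

test_that("localization tables attach compartments and report orphans", {
  calls <- list(p1 = list(protein_id = "p1", evidence = list()),
                p2 = list(protein_id = "p2", evidence = list()))
  tab <- withr::local_tempfile(lines = c("p1\tCytoplasm|Peroxisome",
                                         "p2\tCytoplasm",
                                         "ghost\tNucleus"))
  out <- ingest_localization(calls, tab)
  expect_equal(sort(out$calls$p1$evidence$localization),
               c("Cytoplasm", "Peroxisome"))
  expect_equal(out$orphans, "ghost")
  # tally equals a brute-force count over the ingested rows
  expect_equal(out$tally[["Cytoplasm"]], 2L)
  expect_equal(out$tally[["Peroxisome"]], 1L)
  expect_false("Nucleus" %in% names(out$tally))
  bad <- withr::local_tempfile(lines = c("p1\tCytoplasm", "orphanrow"))
  expect_error(ingest_localization(calls, bad), "line 2")
})

test_that("the census counts unique sequences with duplicate superscripts", {
  set.seed(12)
  cat_seq <- random_seq_fixed(450)
  recs <- rbind(one_rec("catA", cat_seq), one_rec("catA2", cat_seq),
                one_rec("catB", random_seq_fixed(460)))
  dedup <- dedupe_exact(recs)
  calls <- list(
    catA = list(protein_id = "catA", species_id = "sp1", family = "CAT",
                status = "accepted", reject_reasons = character(),
                evidence = list()),
    catB = list(protein_id = "catB", species_id = "sp1", family = "CAT",
                status = "accepted", reject_reasons = character(),
                evidence = list()))
  srx <- list(sp1 = list(species_id = "sp1", status = "absent"))
  cen <- summarize_species(calls, list(), dedup, srx)
  expect_equal(cen$CAT, 2L)
  expect_equal(cen$CAT_dups, 1L)
  expect_equal(cen$SRX_status, "absent")
  fmt <- format_census(cen)
  expect_equal(unname(fmt["sp1", "CAT"]), "2^1")
  expect_equal(unname(fmt["sp1", "PRX5"]), "–")
})
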