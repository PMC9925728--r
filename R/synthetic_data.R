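# Seeded synthetic proteomes with planted antioxidant-family members, a
# matching HMMER3 per-domain hit table, and a truth ledger. Domain
# "presence" is asserted via the emitted hit table, not via sequence
# realism: profile-HMM search is out of scope and the pipeline's contract
# is hit-table-driven. Motifs, by contrast, are literally planted in the
# emitted sequences at recorded coordinates (unless lesioned), and
# accidental copies of filter motifs are scrubbed from candidate sequences
# so that the ledger is the exact truth.

pfam_meta <- function() {
  data.frame(
    accession = c("PF00199", "PF06628", "PF00578", "PF08534", "PF10417",
                  "PF00255", "PF02195"),
    name = c("Catalase", "Catalase-rel", "AhpC-TSA", "Redoxin",
             "1-cysPrx_C", "GSHPx", "ParBc"),
    tlen = c(385L, 85L, 140L, 45L, 40L, 135L, 80L),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a 19-species survey with roughly one hundred proteins
#' per species: a realistic per-species complement of planted family
#' members (two catalases, three typical 2-Cys PRXs, one atypical 2-Cys,
#' two 1-Cys, one GPX per evolutionary group, one sulfiredoxin), a few
#' planted hard negatives (PRX architecture without the C_P motif, a
#' core-domain-only PRX, a truncated catalase, a GPX with a corrupted
#' catalytic slot), and a background of unrelated proteins. Corruption
#' rates are all zero by default; they introduce the specific lesions the
#' pipeline's filters are meant to catch.
#'
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param n_species Number of synthetic species.
#' @param composition Named integer vector of planted members per species.
#' @param decoys Named integer vector of planted negatives per species.
#' @param n_background Unrelated background proteins per species.
#' @param corruption Named rates in [0, 1] for lesion types `cp_knockout`,
#'   `cr_to_val`, `sec_to_cys`, `gglg_loss`, `yf_loss`,
#'   `srx_motif_degradation`, `truncation`.
#' @param duplicate_rate Probability that a planted protein receives one
#'   additional exact-copy record (a synthetic "exact sequence variant").
#' @param srx_status Per-species SRX design, recycled over species:
#'   `"competent"`, `"domain_only"` or `"absent"`.
#' @param bg_freqs Optional named residue frequencies for background
#'   sequence; default uniform over the 20 standard residues.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_species = 19L,
                             composition = c("CAT" = 2L, "AhpC-PRX1" = 3L,
                                             "PRX5" = 1L, "PRX6" = 2L,
                                             "GPX1/2" = 1L, "GPX3/5/6" = 1L,
                                             "GPX4/PHGPX" = 1L, "GPX7/8" = 1L,
                                             "SRX" = 1L),
                             decoys = c(prx_no_cp = 2L, prx_core_only = 1L,
                                        cat_short = 1L, gpx_bad_slot = 1L),
                             n_background = 80L,
                             corruption = c(cp_knockout = 0, cr_to_val = 0,
                                            sec_to_cys = 0, gglg_loss = 0,
                                            yf_loss = 0,
                                            srx_motif_degradation = 0,
                                            truncation = 0),
                             duplicate_rate = 0.1,
                             srx_status = "competent",
                             bg_freqs = NULL) {
  full <- c(cp_knockout = 0, cr_to_val = 0, sec_to_cys = 0, gglg_loss = 0,
            yf_loss = 0, srx_motif_degradation = 0, truncation = 0)
  full[names(corruption)] <- corruption
  if (any(full < 0 | full > 1)) stop("corruption rates must lie in [0, 1]")
  if (any(composition < 0) || any(decoys < 0) || n_background < 0)
    stop("counts must be >= 0")
  if (duplicate_rate < 0 || duplicate_rate > 1)
    stop("duplicate_rate must lie in [0, 1]")
  if (!all(srx_status %in% c("competent", "domain_only", "absent")))
    stop("srx_status values must be competent/domain_only/absent")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 composition = composition, decoys = decoys,
                 n_background = as.integer(n_background),
                 corruption = full, duplicate_rate = duplicate_rate,
                 srx_status = srx_status, bg_freqs = bg_freqs),
            class = "synthetic_config")
}

rand_seq <- function(n, freqs = NULL) {
  res <- setdiff(aa_alphabet(), c("U", "X"))
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  sample(res, n, replace = TRUE, prob = freqs)
}

plant <- function(chars, pos, motif) {
  mm <- strsplit(motif, "")[[1]]
  if (pos + length(mm) - 1L > length(chars)) stop("motif extends past scaffold")
  chars[pos:(pos + length(mm) - 1L)] <- mm
  chars
}

sample_profile_window <- function(profile) {
  vapply(seq_len(ncol(profile)), function(p) {
    sample(rownames(profile), 1L, prob = profile[, p])
  }, character(1))
}

other_residue <- function(ch, avoid = character()) {
  res <- setdiff(setdiff(aa_alphabet(), c("U", "X")), c(ch, avoid))
  res[1L]
}

# Scrub accidental copies of filter motifs from a candidate sequence,
# leaving protected (planted, surviving) positions untouched. For each
# accidental match, one fixed-element position lying outside every
# protected interval is mutated to a residue the element does not accept.
sanitize_sequence <- function(chars, protected) {
  ctx <- cr_contexts()
  full_pats <- c(list(bundled_motifs()$cp, bundled_motifs()$srx),
                 lapply(ctx, function(cc) compile_pattern(cc$pattern)))
  half_pats <- list(bundled_motifs()$gglg, bundled_motifs()$yf)
  in_protected <- function(pos) {
    nrow(protected) > 0L && any(pos >= protected$start & pos <= protected$end)
  }
  for (iter in 1:25) {
    sq <- paste(chars, collapse = "")
    n <- nchar(sq)
    dirty <- FALSE
    todo <- c(lapply(full_pats, function(p) list(p = p, m = scan_motif(sq, p))),
              lapply(half_pats, function(p)
                list(p = p, m = if (n >= 4L)
                  scan_motif(sq, p, region = c(max(1L, floor(n / 2)), n))
                  else scan_motif(sq, p))))
    for (t in todo) {
      m <- t$m
      if (nrow(m) == 0L) next
      fixed_off <- which(vapply(t$p$elements, function(e) e$type == "set",
                                logical(1)))
      for (r in seq_len(nrow(m))) {
        pos_cand <- m$start[r] + fixed_off - 1L
        pos_cand <- pos_cand[!vapply(pos_cand, in_protected, logical(1))]
        if (length(pos_cand) == 0L) next   # the planted copy itself
        pos <- pos_cand[length(pos_cand)]
        el <- t$p$elements[[fixed_off[m$start[r] + fixed_off - 1L == pos][1L]]]
        chars[pos] <- other_residue(chars[pos], avoid = el$residues)
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  chars
}

lesion_roll <- function(rate) rate > 0 && stats::runif(1) < rate

build_hit <- function(protein_id, accession, start, end) {
  data.frame(protein_id = protein_id, accession = accession,
             domain_name = pfam_meta()$name[pfam_meta()$accession == accession],
             start = as.integer(start), end = as.integer(end),
             score = round(stats::runif(1, 80, 300), 1),
             evalue = signif(10^stats::runif(1, -50, -20), 3),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic dataset with a truth ledger
#'
#' Each planted protein is a random background scaffold carrying
#' family-appropriate domain blocks (asserted through synthetic hit rows
#' with the family's Pfam accessions) and literally planted motifs at
#' recorded coordinates. Lesions are applied at the configured rates and
#' recorded; exact-copy duplicates are injected after lesioning so that
#' duplicate groups remain identical. Fully reproducible from the seed.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_dataset`: `records` (protein set),
#'   `hits` (domain-hit data frame), `ledger` (list with `proteins`,
#'   `species`, `census` - the expected pipeline outcome), `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  profiles <- prx_cp_profiles()
  gref <- gpx_reference()
  ctx <- cr_contexts()
  comp <- config$composition
  cor <- config$corruption
  srx_plan <- rep(config$srx_status, length.out = config$n_species)

  recs <- list(); hits <- list(); led <- list()
  for (s in seq_len(config$n_species)) {
    sp <- sprintf("sp%02d", s)
    pc <- 0L
    next_id <- function() {
      pc <<- pc + 1L
      sprintf("%s_p%03d", sp, pc)
    }
    add <- function(pid, chars, hit_rows, family, subfamily, accepted,
                    category, lesions, motifs, extra = list()) {
      recs[[length(recs) + 1L]] <<- new_protein_set(
        pid, sp, paste(chars, collapse = ""), "synthetic")
      if (!is.null(hit_rows)) hits[[length(hits) + 1L]] <<- hit_rows
      led[[length(led) + 1L]] <<- c(list(
        protein_id = pid, species_id = sp, family = family,
        subfamily = subfamily, accepted = accepted, category = category,
        lesions = paste(lesions, collapse = ","),
        length = length(chars), dup_of = NA_character_,
        motifs = motifs), extra)
    }

    make_prx <- function(subfam, plant_cp = TRUE) {
      pid <- next_id()
      len <- 250L
      chars <- rand_seq(len, config$bg_freqs)
      lesions <- character()
      motifs <- list()
      cp_start <- 44L
      if (plant_cp) {
        win <- sample_profile_window(profiles[[subfam]])
        chars <- plant(chars, cp_start, paste(win, collapse = ""))
        # window position 8 is the catalytic cysteine
        motifs$cp <- c(start = cp_start, end = cp_start + 7L,
                       cp_pos = cp_start + 7L)
      }
      if (subfam == "AhpC-PRX1") {
        chars <- plant(chars, 150L, "WHEPNGS")   # motif a
        chars <- plant(chars, 165L, "CEVDKSL")   # motif b
        chars <- plant(chars, 185L, "GGLG")
        chars <- plant(chars, 195L, "YF")
        chars <- plant(chars, 210L, "HGEVCPAGW")
        motifs$gglg <- c(start = 185L, end = 188L)
        motifs$yf <- c(start = 195L, end = 196L)
        motifs$cr <- c(start = 210L, end = 218L,
                       slot = 210L + ctx[["AhpC-PRX1"]]$slot - 1L)
      } else if (subfam == "PRX5") {
        chars <- plant(chars, 200L, "GWKPGCDAV")
        motifs$cr <- c(start = 200L, end = 208L,
                       slot = 200L + ctx[["PRX5"]]$slot - 1L)
      } else if (subfam == "PRX6") {
        chars <- plant(chars, 170L, "H")
        chars <- plant(chars, 180L, "GASMG")
        chars <- plant(chars, 195L, "D")
        motifs$pla2 <- c(H = 170L, S = 182L, D = 195L)
        motifs$gxsxg <- c(start = 180L, end = 184L)
      }
      acc2 <- if (subfam == "PRX5") "PF08534" else "PF10417"
      hit_rows <- rbind(build_hit(pid, "PF00578", 20L, 160L),
                        build_hit(pid, acc2, 170L, 210L))
      # lesions
      if (plant_cp && lesion_roll(cor["cp_knockout"])) {
        chars[motifs$cp["cp_pos"]] <- "S"
        motifs$cp <- NULL
        lesions <- c(lesions, "cp_knockout")
      }
      if (!is.null(motifs$cr) && lesion_roll(cor["cr_to_val"])) {
        chars[motifs$cr["slot"]] <- "V"
        lesions <- c(lesions, "cr_to_val")
      }
      if (!is.null(motifs$gglg) && lesion_roll(cor["gglg_loss"])) {
        chars[motifs$gglg["start"] + 2L] <- "A"
        motifs$gglg <- NULL
        lesions <- c(lesions, "gglg_loss")
      }
      if (!is.null(motifs$yf) && lesion_roll(cor["yf_loss"])) {
        chars[motifs$yf["start"]] <- "A"
        motifs$yf <- NULL
        lesions <- c(lesions, "yf_loss")
      }
      if (lesion_roll(cor["truncation"])) {
        newlen <- 150L
        chars <- chars[1:newlen]
        motifs <- Filter(function(m)
          all(m[intersect(names(m), c("start", "end", "H", "S", "D", "slot",
                                      "cp_pos"))] <= newlen), motifs)
        hit_rows <- hit_rows[hit_rows$end <= newlen, , drop = FALSE]
        lesions <- c(lesions, "truncation")
      }
      prot <- do.call(rbind, lapply(motifs, function(m)
        data.frame(start = if ("start" %in% names(m)) m[["start"]] else min(m),
                   end = if ("end" %in% names(m)) m[["end"]] else max(m))))
      if (is.null(prot)) prot <- data.frame(start = integer(), end = integer())
      chars <- sanitize_sequence(chars, prot)
      nominated <- "PF00578" %in% hit_rows$accession &&
        any(c("PF08534", "PF10417") %in% hit_rows$accession)
      accepted <- nominated && !is.null(motifs$cp)
      category <- if (accepted) subfam else NA_character_
      add(pid, chars, hit_rows, if (plant_cp) "PRX" else "PRX",
          if (accepted) subfam else NA_character_, accepted, category,
          lesions, motifs,
          extra = list(hyperox_expected =
            subfam == "AhpC-PRX1" && !is.null(motifs$gglg) && !is.null(motifs$yf)))
      pid
    }

    make_cat <- function(short = FALSE) {
      pid <- next_id()
      len <- if (short) 300L else sample(450:550, 1L)
      chars <- rand_seq(len, config$bg_freqs)
      lesions <- character()
      hit_rows <- if (short)
        rbind(build_hit(pid, "PF00199", 10L, 250L),
              build_hit(pid, "PF06628", 255L, 295L))
      else
        rbind(build_hit(pid, "PF00199", 10L, 390L),
              build_hit(pid, "PF06628", 400L, min(480L, len - 5L)))
      if (!short && lesion_roll(cor["truncation"])) {
        len <- 300L
        chars <- chars[1:len]
        hit_rows <- hit_rows[hit_rows$end <= len, , drop = FALSE]
        lesions <- c(lesions, "truncation")
      }
      chars <- sanitize_sequence(chars, data.frame(start = integer(), end = integer()))
      nominated <- all(c("PF00199", "PF06628") %in% hit_rows$accession)
      accepted <- nominated && len >= 400L
      add(pid, chars, hit_rows, "CAT", NA_character_, accepted,
          if (accepted) "CAT" else NA_character_, lesions, list())
      pid
    }

    make_gpx <- function(group, bad_slot = FALSE) {
      pid <- next_id()
      body <- strsplit(gref$sequence, "")[[1]]
      mut <- setdiff(which(stats::runif(length(body)) < 0.06), gref$tetrad)
      for (i in mut) body[i] <- sample(setdiff(setdiff(aa_alphabet(),
                                       c("U", "X")), body[i]), 1L)
      catalytic <- if (bad_slot) "R" else if (group == "GPX7/8") "C" else "U"
      body[gref$tetrad["catalytic"]] <- catalytic
      lesions <- character()
      if (!bad_slot && catalytic == "U" && lesion_roll(cor["sec_to_cys"])) {
        catalytic <- "C"
        body[gref$tetrad["catalytic"]] <- "C"
        lesions <- c(lesions, "sec_to_cys")
      }
      fl <- rand_seq(5L, config$bg_freqs)
      chars <- c(fl, body, rand_seq(5L, config$bg_freqs))
      off <- length(fl)
      hit_rows <- build_hit(pid, "PF00255", off + 1L, off + length(body))
      prot <- data.frame(start = off + gref$tetrad, end = off + gref$tetrad)
      chars <- sanitize_sequence(chars, prot)
      accepted <- !bad_slot
      add(pid, chars, hit_rows, "GPX", if (accepted) group else NA_character_,
          accepted, if (accepted) "GPX" else NA_character_, lesions,
          list(tetrad = off + gref$tetrad),
          extra = list(catalysis_expected = if (bad_slot) "undetermined"
                       else if (catalytic == "U") "selenium-dependent"
                       else "cysteine-dependent"))
      pid
    }

    make_srx <- function(design) {
      pid <- next_id()
      len <- 150L
      chars <- rand_seq(len, config$bg_freqs)
      chars <- plant(chars, 100L, "FSGCHR")
      motifs <- list(srx = c(start = 100L, end = 105L))
      lesions <- character()
      degraded <- design == "domain_only" || lesion_roll(cor["srx_motif_degradation"])
      if (degraded) {
        chars[103L] <- "A"    # the motif cysteine
        motifs$srx <- NULL
        lesions <- c(lesions, "srx_motif_degradation")
      }
      hit_rows <- build_hit(pid, "PF02195", 15L, 95L)
      prot <- if (is.null(motifs$srx)) data.frame(start = integer(), end = integer())
              else data.frame(start = 100L, end = 105L)
      chars <- sanitize_sequence(chars, prot)
      add(pid, chars, hit_rows, "SRX", NA_character_, FALSE, NA_character_,
          lesions, motifs,
          extra = list(srx_motif_expected = !degraded))
      pid
    }

    make_decoy <- function(kind) {
      if (kind == "prx_no_cp") make_prx("AhpC-PRX1", plant_cp = FALSE)
      else if (kind == "prx_core_only") {
        pid <- next_id()
        chars <- rand_seq(250L, config$bg_freqs)
        hit_rows <- build_hit(pid, "PF00578", 20L, 160L)
        chars <- sanitize_sequence(chars, data.frame(start = integer(), end = integer()))
        add(pid, chars, hit_rows, "PRX", NA_character_, FALSE, NA_character_,
            character(), list())
      } else if (kind == "cat_short") make_cat(short = TRUE)
      else if (kind == "gpx_bad_slot") make_gpx("GPX4/PHGPX", bad_slot = TRUE)
    }

    for (f in names(comp)) {
      k <- comp[[f]]
      if (k == 0L) next
      for (i in seq_len(k)) {
        if (f == "CAT") make_cat()
        else if (f %in% c("AhpC-PRX1", "PRX5", "PRX6")) make_prx(f)
        else if (startsWith(f, "GPX")) make_gpx(f)
        else if (f == "SRX") { if (srx_plan[s] != "absent") make_srx(srx_plan[s]) }
      }
    }
    for (k in names(config$decoys))
      for (i in seq_len(config$decoys[[k]])) make_decoy(k)
    for (i in seq_len(config$n_background)) {
      pid <- next_id()
      chars <- rand_seq(sample(150:350, 1L), config$bg_freqs)
      add(pid, chars, NULL, "none", NA_character_, FALSE, NA_character_,
          character(), list())
    }
  }

  records <- do.call(rbind, recs)
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(protein_id = character(), accession = character(),
                       domain_name = character(), start = integer(),
                       end = integer(), score = numeric(), evalue = numeric(),
                       stringsAsFactors = FALSE)
  rownames(records) <- rownames(hits) <- NULL

  proteins <- do.call(rbind, lapply(led, function(x)
    data.frame(protein_id = x$protein_id, species_id = x$species_id,
               family = x$family, subfamily = x$subfamily,
               accepted = x$accepted, category = x$category,
               lesions = x$lesions, length = x$length, dup_of = x$dup_of,
               hyperox_expected = x$hyperox_expected %||% NA,
               catalysis_expected = x$catalysis_expected %||% NA_character_,
               srx_motif_expected = x$srx_motif_expected %||% NA,
               stringsAsFactors = FALSE)))
  motif_coords <- stats::setNames(lapply(led, function(x) x$motifs),
                                  vapply(led, function(x) x$protein_id, character(1)))

  # exact-copy duplicates, injected after lesioning
  dup_rows <- proteins$family != "none" &
    stats::runif(nrow(proteins)) < config$duplicate_rate
  if (any(dup_rows)) {
    for (i in which(dup_rows)) {
      base <- proteins$protein_id[i]
      did <- paste0(base, "v2")
      r <- records[records$protein_id == base, , drop = FALSE]
      r$protein_id <- did
      records <- rbind(records, r)
      h <- hits[hits$protein_id == base, , drop = FALSE]
      if (nrow(h)) { h$protein_id <- did; hits <- rbind(hits, h) }
      dd <- proteins[i, , drop = FALSE]
      dd$protein_id <- did
      dd$dup_of <- base
      proteins <- rbind(proteins, dd)
    }
  }
  records <- records[order(records$species_id, records$protein_id), , drop = FALSE]
  hits <- hits[order(hits$protein_id, hits$start), , drop = FALSE]
  proteins <- proteins[order(proteins$species_id, proteins$protein_id), , drop = FALSE]
  rownames(records) <- rownames(hits) <- rownames(proteins) <- NULL

  base <- proteins[is.na(proteins$dup_of), , drop = FALSE]
  dups <- proteins[!is.na(proteins$dup_of), , drop = FALSE]
  cats <- census_categories()
  census <- do.call(rbind, lapply(sort(unique(proteins$species_id)), function(sp) {
    b <- base[base$species_id == sp, , drop = FALSE]
    d <- dups[dups$species_id == sp, , drop = FALSE]
    row <- data.frame(species_id = sp, stringsAsFactors = FALSE)
    for (cc in cats) {
      ids <- b$protein_id[!is.na(b$category) & b$category == cc]
      row[[gsub("[/-]", "_", cc)]] <- length(ids)
      row[[paste0(gsub("[/-]", "_", cc), "_dups")]] <- sum(d$dup_of %in% ids)
    }
    row$SRX_status <- srx_plan[as.integer(sub("sp", "", sp))]
    row
  }))
  rownames(census) <- NULL

  species <- data.frame(species_id = sprintf("sp%02d", seq_len(config$n_species)),
                        srx_status = srx_plan, stringsAsFactors = FALSE)

  structure(list(records = records, hits = hits,
                 ledger = list(proteins = proteins, species = species,
                               census = census, motif_coords = motif_coords),
                 config = config),
            class = "synthetic_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits one FASTA per species, a species manifest, a HMMER3 domtblout hit
#' table, and the truth ledger as TSV.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- dataset$records
  species <- sort(unique(records$species_id))
  fasta_paths <- character()
  for (sp in species) {
    p <- file.path(dir, paste0(sp, ".fasta"))
    write_fasta(records[records$species_id == sp, , drop = FALSE], p)
    fasta_paths[sp] <- p
  }
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(paste(species, paste0(species, ".fasta"), sep = "\t"), manifest)
  dom <- file.path(dir, "hits.domtblout")
  write_domtblout(dataset$hits, records, dom)
  lp <- file.path(dir, "ledger_proteins.tsv")
  utils::write.table(dataset$ledger$proteins, lp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lc <- file.path(dir, "ledger_census.tsv")
  utils::write.table(dataset$ledger$census, lc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta_paths, manifest = manifest, domtblout = dom,
       ledger_proteins = lp, ledger_census = lc)
}

write_domtblout <- function(hits, records, path) {
  meta <- pfam_meta()
  qlen <- stats::setNames(nchar(records$sequence), records$protein_id)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# synthetic per-domain hits (hmmscan domtblout dialect)",
               "#"), con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    tlen <- meta$tlen[meta$accession == h$accession]
    line <- paste(h$domain_name, paste0(h$accession, ".1"), tlen,
                  h$protein_id, "-", qlen[[h$protein_id]],
                  format(h$evalue, scientific = TRUE), h$score, "0.1",
                  1, 1,
                  format(h$evalue, scientific = TRUE),
                  format(h$evalue, scientific = TRUE), h$score, "0.1",
                  1, tlen, h$start, h$end, h$start, h$end, "0.95",
                  "synthetic planted domain", sep = " ")
    writeLines(line, con)
  }
  invisible(path)
}

#' Generate a synthetic grouped alignment for tree inference
#'
#' Groups are evolved from distinct group consensus sequences (each a
#' mutated copy of one root), with within-group divergence strictly below
#' between-group divergence, so group monophyly is recoverable. Gap
#' columns of known gap fraction can be injected at recorded indices.
#'
#' @param groups Group labels (>= 2).
#' @param members Members per group (>= 3).
#' @param length Alignment length in columns.
#' @param within Per-site substitution probability within a group.
#' @param between Per-site substitution probability from the root to each
#'   group consensus; must exceed `within`.
#' @param gap_fractions Numeric vector: one injected gap column per entry,
#'   with that fraction of rows gapped (rounded to whole rows).
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector), `labels`
#'   (named character: row -> group), `gap_columns` (data frame `column`
#'   (1-based), `fraction`).
#' @export
generate_subfamily_alignment <- function(groups = c("G1", "G2", "G3", "G4"),
                                         members = 6L, length = 120L,
                                         within = 0.03, between = 0.35,
                                         gap_fractions = numeric(),
                                         seed = 1L) {
  if (length(groups) < 2L || members < 3L)
    stop("need >= 2 groups with >= 3 members each")
  if (within >= between)
    stop("within-group divergence must be below between-group divergence")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  res20 <- setdiff(aa_alphabet(), c("U", "X"))
  mutate <- function(chars, rate) {
    hit <- which(stats::runif(length(chars)) < rate)
    for (i in hit) chars[i] <- sample(setdiff(res20, chars[i]), 1L)
    chars
  }
  root <- rand_seq(length)
  rows <- list(); labels <- character()
  for (g in seq_along(groups)) {
    consensus <- mutate(root, between)
    for (m in seq_len(members)) {
      id <- sprintf("%s_m%02d", groups[g], m)
      rows[[id]] <- mutate(consensus, within)
      labels[id] <- groups[g]
    }
  }
  mat <- do.call(rbind, rows)
  gap_cols <- data.frame(column = integer(), fraction = numeric())
  if (length(gap_fractions)) {
    cols <- sample.int(length, base::length(gap_fractions))
    for (i in seq_along(gap_fractions)) {
      k <- round(gap_fractions[i] * nrow(mat))
      gap_rows <- sample.int(nrow(mat), k)
      mat[gap_rows, cols[i]] <- "-"
      gap_cols <- rbind(gap_cols,
                        data.frame(column = cols[i], fraction = k / nrow(mat)))
    }
    gap_cols <- gap_cols[order(gap_cols$column), , drop = FALSE]
    rownames(gap_cols) <- NULL
  }
  aln <- apply(mat, 1L, paste, collapse = "")
  names(aln) <- rownames(mat)
  list(alignment = aln, labels = labels, gap_columns = gap_cols)
}
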