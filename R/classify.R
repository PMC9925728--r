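# Integration stage: domains + motifs (+ optional clade placements) ->
# per-protein family/subfamily calls, species SRX status, and the census.

#' Default classification configuration
#'
#' @param max_evalue Domain-hit e-value ceiling.
#' @param cat_length_floor Minimum CAT sequence length (residues); an
#'   approximation of manual structural curation of truncated catalase
#'   models. Set `NULL` to disable.
#' @param profile_margin Minimum lead of the best active-site profile score
#'   over the runner-up for a PRX subfamily call (mean log-odds units).
#' @param cp_window Half-width of the window around the peroxidatic
#'   cysteine scored against the subfamily profiles.
#' @param clade_min_support Optional minimum bootstrap support for clade
#'   assignment.
#' @param prx_any_optional Relax the PRX accessory-domain requirement.
#' @return Named list of settings.
#' @export
classify_config <- function(max_evalue = 1e-5, cat_length_floor = 400L,
                            profile_margin = 1.0, cp_window = 7L,
                            clade_min_support = NULL,
                            prx_any_optional = FALSE) {
  list(max_evalue = max_evalue, cat_length_floor = cat_length_floor,
       profile_margin = profile_margin, cp_window = cp_window,
       clade_min_support = clade_min_support,
       prx_any_optional = prx_any_optional)
}

#' Family-level call for one protein
#'
#' Applies the per-family acceptance rules to a nominated candidate:
#' CAT is accepted on architecture alone, subject only to the optional
#' length floor (flagged as an approximation of manual curation); PRX
#' requires the architecture plus the C_P active-site motif; GPX requires
#' the GSHPx domain plus a resolved catalytic-tetrad first role; SRX
#' candidates are recorded (domain + motif evidence) but reported through
#' the species SRX status, not the census. When one protein is nominated by
#' several families it is called under the family with the higher total
#' domain bit score, and the conflict is logged in the evidence.
#'
#' @param record One-row protein-set data frame.
#' @param hits Domain hits for this protein (already thresholded).
#' @param families Families that nominated this protein.
#' @param config [classify_config()] list.
#' @return List of class `family_call`: `protein_id`, `species_id`,
#'   `family`, `status` (`accepted`/`rejected`), `reject_reasons`,
#'   `evidence` (list incl. motif results used).
#' @export
call_family <- function(record, hits, families, config = classify_config()) {
  pid <- record$protein_id[1L]
  seqs <- record$sequence[1L]
  evidence <- list(hits = hits, conflicts = character())
  if (length(families) > 1L) {
    sc <- vapply(families, function(f) {
      accs <- family_accessions(f, config)
      sum(hits$score[hits$accession %in% accs])
    }, numeric(1))
    winner <- families[order(-sc, families)][1L]
    evidence$conflicts <- setdiff(families, winner)
    families <- winner
  }
  fam <- families[1L]
  reasons <- character()
  if (fam == "CAT") {
    if (!is.null(config$cat_length_floor) &&
        nchar(seqs) < config$cat_length_floor)
      reasons <- c(reasons, sprintf("below_length_floor(%d<%d)",
                                    nchar(seqs), config$cat_length_floor))
  } else if (fam == "PRX") {
    cp <- find_cp(seqs)
    evidence$cp <- cp
    if (is.null(cp)) reasons <- c(reasons, "missing_CP")
  } else if (fam == "GPX") {
    dom <- hits[hits$accession == "PF00255", , drop = FALSE]
    region <- if (nrow(dom)) c(min(dom$start), max(dom$end)) else NULL
    tet <- gpx_tetrad(seqs, region = region)
    evidence$tetrad <- tet
    if (tet$type == "undetermined")
      reasons <- c(reasons, paste0("tetrad_undetermined(", tet$reason, ")"))
  } else if (fam == "SRX") {
    evidence$srx_motif <- srx_motif(seqs)
  }
  structure(list(protein_id = pid, species_id = record$species_id[1L],
                 family = fam,
                 status = if (length(reasons)) "rejected" else "accepted",
                 reject_reasons = reasons, evidence = evidence),
            class = "family_call")
}

family_accessions <- function(family, config = classify_config()) {
  r <- default_architecture_rules(config$prx_any_optional)[[family]]
  c(r$require_all, r$require_any)
}

#' Classify an accepted PRX into its animal subfamily
#'
#' A window of +/- `cp_window` residues around the peroxidatic cysteine is
#' scored against each bundled subfamily active-site profile (mean
#' per-position log-odds against a uniform background); the best label is
#' assigned when its margin over the runner-up exceeds
#' `config$profile_margin`, else the call is `unclassified`. When a clade
#' assignment is supplied, `method = "both"` and agreement is recorded; on
#' disagreement the clade label wins (final subfamily labels follow tree
#' placement) with the agreement flag lowered.
#'
#' @param record One-row protein-set data frame.
#' @param cp C_P match from [find_cp()].
#' @param profiles Profile list from [prx_cp_profiles()].
#' @param clade Optional [assign_clade()] result.
#' @param config [classify_config()] list.
#' @return List of class `subfamily_call`: `protein_id`, `label`,
#'   `method`, `agreement`, `scores`, `margin`, `cause`, `truncated`.
#' @export
classify_prx_subfamily <- function(record, cp, profiles = prx_cp_profiles(),
                                   clade = NULL, config = classify_config()) {
  seqs <- record$sequence[1L]
  w <- config$cp_window
  n <- nchar(seqs)
  idx <- (cp$cp_pos - w):(cp$cp_pos + w)
  win <- rep(NA_character_, length(idx))
  ok <- idx >= 1L & idx <= n
  win[ok] <- strsplit(substring(seqs, max(1L, cp$cp_pos - w),
                                min(n, cp$cp_pos + w)), "")[[1]]
  truncated <- any(!ok)
  scores <- vapply(profiles, function(p) score_cp_window(win, p), numeric(1))
  o <- order(-scores, names(scores))
  margin <- scores[o[1]] - scores[o[2]]
  prof_label <- if (margin > config$profile_margin) names(scores)[o[1]] else NA_character_
  label <- prof_label
  method <- "active_site_profile"
  agreement <- NA
  cause <- if (is.na(prof_label)) "margin_below_threshold" else NA_character_
  if (!is.null(clade)) {
    method <- "both"
    clade_label <- clade$label
    if (!is.na(clade_label)) {
      agreement <- identical(prof_label, clade_label)
      label <- clade_label            # final labels follow tree placement
      cause <- NA_character_
    } else {
      agreement <- FALSE
      cause <- if (is.na(label)) paste0("clade_", clade$cause) else cause
    }
  }
  structure(list(protein_id = record$protein_id[1L], label = label,
                 method = method, agreement = agreement,
                 scores = scores, margin = unname(margin),
                 cause = cause, truncated = truncated),
            class = "subfamily_call")
}

#' Classify an accepted GPX into its evolutionary group
#'
#' GPX groups (GPX1/2, GPX3/5/6, GPX4/PHGPX, GPX7/8) are assigned purely
#' from clade placement among labelled references - there is no
#' active-site-profile fallback, since the group structure is an
#' evolutionary, not a motif, signature. Without a placement the call is
#' unclassified.
#'
#' @param record One-row protein-set data frame.
#' @param clade Optional [assign_clade()] result.
#' @return A `subfamily_call` list.
#' @export
classify_gpx_subfamily <- function(record, clade = NULL) {
  label <- NA_character_
  cause <- "no_clade_assignment"
  support <- NA_real_
  if (!is.null(clade)) {
    label <- clade$label
    cause <- if (is.na(label)) paste0("clade_", clade$cause) else NA_character_
    support <- clade$support
  }
  structure(list(protein_id = record$protein_id[1L], label = label,
                 method = "clade_placement", agreement = NA,
                 scores = c(support = support), margin = NA_real_,
                 cause = cause, truncated = FALSE),
            class = "subfamily_call")
}

#' Hyperoxidation-sensitivity call for an AhpC-PRX1 protein
#'
#' @param record One-row protein-set data frame.
#' @return List with `protein_id`, `sensitive` (GGLG and YF both present),
#'   `ab_substitution_count`, `detail` (the [hyperox_motifs()] result).
#' @export
hyperox_call <- function(record) {
  hx <- hyperox_motifs(record$sequence[1L])
  list(protein_id = record$protein_id[1L],
       sensitive = hx$gglg && hx$yf,
       ab_substitution_count = nrow(hx$ab_substitutions),
       detail = hx)
}

#' Species-level sulfiredoxin status
#'
#' `competent`: at least one protein carries the ParB-like nuclease domain
#' (PF02195) and the F[SG]GCHR binding motif; `domain_only`: the domain
#' occurs but the motif is absent from every carrier; `absent`: no ParBc
#' hit at all.
#'
#' @param records Protein-set data frame for one species.
#' @param hits Thresholded domain hits for the same proteins.
#' @return List with `species_id`, `status`, `carriers` (ids with the
#'   domain), `competent_ids`.
#' @export
species_srx_status <- function(records, hits) {
  sp <- unique(records$species_id)
  if (length(sp) != 1L) stop("species_srx_status expects one species at a time")
  carriers <- unique(hits$protein_id[hits$accession == "PF02195"])
  carriers <- intersect(carriers, records$protein_id)
  if (length(carriers) == 0L)
    return(list(species_id = sp, status = "absent",
                carriers = character(), competent_ids = character()))
  has_motif <- vapply(carriers, function(id)
    srx_motif(records$sequence[records$protein_id == id]), logical(1))
  list(species_id = sp,
       status = if (any(has_motif)) "competent" else "domain_only",
       carriers = carriers, competent_ids = carriers[has_motif])
}

#' Attach subcellular-localization predictions to calls
#'
#' Ingests the output table of an external localization predictor:
#' tab-separated, `protein_id` then one or more compartment labels
#' separated by `|` (multi-compartment predictions allowed). Prediction
#' itself is out of scope here.
#'
#' @param calls List of `family_call` objects (named by protein id).
#' @param path Path to the TSV.
#' @return List with `calls` (localization attached to each call's
#'   evidence), `orphans` (table ids not among the calls) and `tally`
#'   (named count of calls per compartment).
#' @export
ingest_localization <- function(calls, path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  ids <- character(); comps <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 2L)
      stop(sprintf("malformed localization row (line %d): need id and compartments", i))
    ids[i] <- trimws(f[1])
    comps[[i]] <- trimws(unlist(strsplit(f[-1], "\\|")))
  }
  known <- names(calls)
  orphans <- setdiff(ids, known)
  for (i in seq_along(ids)) {
    if (ids[i] %in% known)
      calls[[ids[i]]]$evidence$localization <- comps[[i]]
  }
  tally <- table(unlist(comps[ids %in% known]))
  list(calls = calls, orphans = orphans,
       tally = stats::setNames(as.integer(tally), names(tally)))
}

census_categories <- function() c("CAT", "AhpC-PRX1", "PRX5", "PRX6", "GPX")

#' Per-species census of accepted antioxidant enzymes
#'
#' Builds the species x category census: unique accepted sequences per
#' category (CAT, AhpC-PRX1, PRX5, PRX6, GPX), plus the number of
#' additional exact sequence duplicates per category (the census reports
#' unique sequences, with duplicates as a separate superscript-style
#' count), plus the species SRX status. Accepted PRX proteins whose
#' subfamily is unclassified are tallied in `PRX_unclassified`.
#'
#' @param calls List of `family_call` objects for retained (deduplicated)
#'   proteins.
#' @param subfamilies Named list of `subfamily_call` objects (PRX/GPX ids).
#' @param dedup A `dedup_report` covering the full record set.
#' @param srx Named list of species SRX status results.
#' @param species Optional character vector of species to report (so that
#'   species with no accepted proteins still get an all-zero row); default
#'   the species seen among the calls.
#' @return Data frame of class `census` with one row per species.
#' @export
summarize_species <- function(calls, subfamilies, dedup, srx, species = NULL) {
  cats <- census_categories()
  if (is.null(species))
    species <- sort(unique(vapply(calls, function(x) x$species_id, character(1))))
  dup_of <- dedup$duplicate_counts
  category_of <- function(call) {
    if (call$status != "accepted") return(NA_character_)
    if (call$family == "CAT") return("CAT")
    if (call$family == "GPX") return("GPX")
    if (call$family == "PRX") {
      sf <- subfamilies[[call$protein_id]]
      if (is.null(sf) || is.na(sf$label)) return("PRX_unclassified")
      # phylogeny-only refinements of AhpC-PRX1 stay in its census column
      if (sf$label %in% c("PRX4-like", "CNID-PRX-like")) return("AhpC-PRX1")
      return(sf$label)
    }
    NA_character_   # SRX reported via its own status, not the census
  }
  rows <- lapply(species, function(sp) {
    sp_calls <- Filter(function(x) x$species_id == sp, calls)
    cat_of <- vapply(sp_calls, category_of, character(1))
    ids <- vapply(sp_calls, function(x) x$protein_id, character(1))
    counts <- vapply(c(cats, "PRX_unclassified"), function(cc)
      sum(!is.na(cat_of) & cat_of == cc), integer(1))
    dups <- vapply(c(cats, "PRX_unclassified"), function(cc) {
      in_cat <- ids[!is.na(cat_of) & cat_of == cc]
      sum(dup_of[names(dup_of) %in% in_cat])
    }, numeric(1))
    st <- srx[[sp]]
    out <- data.frame(species_id = sp, stringsAsFactors = FALSE)
    for (cc in c(cats, "PRX_unclassified")) {
      out[[gsub("[/-]", "_", cc)]] <- counts[[cc]]
      out[[paste0(gsub("[/-]", "_", cc), "_dups")]] <- as.integer(dups[[cc]])
    }
    out$SRX_status <- if (is.null(st)) NA_character_ else st$status
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("census", class(out))
  out
}

#' Render a census in superscript style
#'
#' Formats each cell as `n^d` (unique count, superscript duplicate count)
#' with zero counts printed as a dash, mirroring the typography of
#' published gene-census tables.
#'
#' @param census A `census` data frame from [summarize_species()].
#' @return Character matrix (species x categories).
#' @export
format_census <- function(census) {
  cats <- gsub("[/-]", "_", census_categories())
  m <- sapply(cats, function(cc) {
    n <- census[[cc]]; d <- census[[paste0(cc, "_dups")]]
    ifelse(n == 0L, "–", ifelse(d > 0L, paste0(n, "^", d), as.character(n)))
  })
  m <- matrix(m, nrow = nrow(census),
              dimnames = list(census$species_id, census_categories()))
  m
}

#' @export
print.census <- function(x, ...) {
  cat("antioxidant enzyme census (unique counts, ^duplicates):\n")
  print(format_census(x), quote = FALSE)
  invisible(x)
}
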