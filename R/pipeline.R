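# End-to-end runners mirroring the published workflow: scan (domains ->
# candidates), classify (motif filters -> calls -> census), tree (edit ->
# NJ + bootstrap -> clade assignment), simulate. Each writes plain TSV/JSON
# and a per-stage funnel log so filter chains are auditable. All of them
# are deterministic given their inputs and seed.

#' Read a run configuration file
#'
#' YAML file whose keys mirror the arguments of the `run_*` functions
#' (`manifest`, `domtblout`, `out_dir`, `max_evalue`, `cat_length_floor`,
#' `profile_margin`, `gap_threshold`, `clade_min_support`, `seed`, ...).
#' Explicit function arguments override configuration values.
#'
#' @param path YAML config path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  yaml::read_yaml(path)
}

stage_log <- function(out_dir, stage, counts) {
  p <- file.path(out_dir, paste0(stage, "_funnel.tsv"))
  df <- data.frame(step = names(counts), count = unname(unlist(counts)))
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' Scan stage: domain hits to family candidates
#'
#' Parses the per-domain table, applies the e-value threshold and the
#' family architecture rules, and writes the candidate table plus a funnel
#' log (hits parsed, hits kept, candidates per family).
#'
#' @param manifest Species manifest path.
#' @param domtblout HMMER3 per-domain table path.
#' @param out_dir Output directory.
#' @param config A [classify_config()] list.
#' @return Invisibly, a list with `records`, `hits`, `candidates`.
#' @export
run_scan <- function(manifest, domtblout, out_dir,
                     config = classify_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_proteomes(manifest)
  hits_all <- parse_domtblout(domtblout)
  hits <- filter_hits(hits_all, max_evalue = config$max_evalue)
  rules <- default_architecture_rules(config$prx_any_optional)
  cand <- nominate_families(hits, rules)
  cand$species_id <- records$species_id[match(cand$protein_id, records$protein_id)]
  cand <- cand[order(cand$protein_id, cand$family), , drop = FALSE]
  utils::write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  funnel <- c(sequences = nrow(records), hits_parsed = nrow(hits_all),
              hits_kept = nrow(hits))
  for (f in names(rules))
    funnel[[paste0("candidates_", f)]] <- sum(cand$family == f)
  stage_log(out_dir, "scan", funnel)
  invisible(list(records = records, hits = hits, candidates = cand))
}

#' Classify stage: candidates to calls and census
#'
#' Runs the full filter chain - deduplication, family calls (architecture +
#' catalytic-motif filters), PRX subfamily classification from the
#' active-site profile, GPX catalysis typing, species SRX status - and
#' writes the census (TSV and JSON), a per-protein evidence JSON, and an
#' audit table in which every input sequence appears exactly once
#' (accepted, rejected with reasons, or duplicate of a retained record).
#'
#' @inheritParams run_scan
#' @param localization Optional localization TSV to merge.
#' @return Invisibly, a list with `calls`, `subfamilies`, `census`,
#'   `audit`, `srx`.
#' @export
run_classify <- function(manifest, domtblout, out_dir,
                         config = classify_config(), localization = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scan <- run_scan(manifest, domtblout, out_dir, config)
  records <- scan$records; hits <- scan$hits
  dedup <- dedupe_exact(records)
  retained <- dedup$unique_records
  dup_map <- duplicate_map(records, retained)
  cand <- scan$candidates[scan$candidates$protein_id %in% retained$protein_id, ,
                          drop = FALSE]
  fam_by_prot <- split(cand$family, cand$protein_id)

  profiles <- prx_cp_profiles()
  calls <- list(); subfams <- list()
  for (pid in names(fam_by_prot)) {
    rec <- retained[retained$protein_id == pid, , drop = FALSE]
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    call <- call_family(rec, h, fam_by_prot[[pid]], config)
    if (call$status == "accepted" && call$family == "PRX") {
      sf <- classify_prx_subfamily(rec, call$evidence$cp, profiles,
                                   config = config)
      subfams[[pid]] <- sf
      if (!is.na(sf$label) && sf$label != "PRX6")
        call$evidence$cr <- find_cr(rec, sf$label)
      if (identical(sf$label, "AhpC-PRX1"))
        call$evidence$hyperox <- hyperox_call(rec)
    }
    calls[[pid]] <- call
  }
  orphans <- character(); loc_tally <- integer()
  if (!is.null(localization)) {
    li <- ingest_localization(calls, localization)
    calls <- li$calls; orphans <- li$orphans; loc_tally <- li$tally
  }
  srx <- list()
  for (sp in sort(unique(records$species_id))) {
    sp_rec <- retained[retained$species_id == sp, , drop = FALSE]
    srx[[sp]] <- species_srx_status(sp_rec, hits[hits$protein_id %in%
                                                   sp_rec$protein_id, , drop = FALSE])
  }
  census <- summarize_species(calls, subfams, dedup, srx,
                              species = sort(unique(records$species_id)))

  audit <- build_audit(records, retained, dup_map, calls)
  utils::write.table(audit, file.path(out_dir, "audit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(census, file.path(out_dir, "census.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(census, file.path(out_dir, "census.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  evidence <- lapply(calls, evidence_summary, subfams = subfams)
  jsonlite::write_json(evidence, file.path(out_dir, "evidence.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  funnel <- c(input_sequences = nrow(records),
              unique_sequences = nrow(retained),
              candidates = length(calls),
              accepted = sum(vapply(calls, function(x)
                x$status == "accepted", logical(1))),
              rejected = sum(vapply(calls, function(x)
                x$status == "rejected", logical(1))))
  stage_log(out_dir, "classify", funnel)
  invisible(list(calls = calls, subfamilies = subfams, census = census,
                 audit = audit, srx = srx, dedup = dedup,
                 localization_orphans = orphans,
                 localization_tally = loc_tally))
}

duplicate_map <- function(records, retained) {
  # duplicate id -> retained id with the identical sequence (same species)
  kept_key <- paste(retained$species_id, retained$sequence, sep = "\r")
  key <- paste(records$species_id, records$sequence, sep = "\r")
  dup <- !(records$protein_id %in% retained$protein_id)
  stats::setNames(retained$protein_id[match(key[dup], kept_key)],
                  records$protein_id[dup])
}

build_audit <- function(records, retained, dup_map, calls) {
  disposition <- character(nrow(records))
  detail <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    pid <- records$protein_id[i]
    if (pid %in% names(dup_map)) {
      disposition[i] <- "duplicate"
      detail[i] <- paste0("identical_to:", dup_map[[pid]])
    } else if (!is.null(calls[[pid]])) {
      disposition[i] <- calls[[pid]]$status
      detail[i] <- if (calls[[pid]]$status == "accepted") calls[[pid]]$family
        else paste(calls[[pid]]$reject_reasons, collapse = ";")
    } else {
      disposition[i] <- "rejected"
      detail[i] <- "no_family_architecture"
    }
  }
  data.frame(protein_id = records$protein_id,
             species_id = records$species_id,
             disposition = disposition, detail = detail,
             stringsAsFactors = FALSE)
}

evidence_summary <- function(call, subfams) {
  ev <- list(protein_id = call$protein_id, species_id = call$species_id,
             family = call$family, status = call$status,
             reject_reasons = call$reject_reasons,
             domains = call$evidence$hits[, c("accession", "start", "end",
                                              "evalue")],
             conflicts = call$evidence$conflicts)
  if (!is.null(call$evidence$cp))
    ev$cp <- call$evidence$cp[c("start", "cp_pos", "n_matches")]
  if (!is.null(call$evidence$tetrad))
    ev$tetrad <- list(type = call$evidence$tetrad$type,
                      residues = as.list(call$evidence$tetrad$residues))
  if (!is.null(call$evidence$cr))
    ev$cr <- call$evidence$cr[c("status", "residue", "position")]
  if (!is.null(call$evidence$hyperox))
    ev$hyperox <- list(sensitive = call$evidence$hyperox$sensitive,
                       ab_substitutions =
                         call$evidence$hyperox$ab_substitution_count)
  if (!is.null(call$evidence$localization))
    ev$localization <- call$evidence$localization
  sf <- subfams[[call$protein_id]]
  if (!is.null(sf))
    ev$subfamily <- list(label = sf$label, margin = sf$margin,
                         method = sf$method)
  ev
}

#' Tree stage: alignment editing, NJ + bootstrap, clade assignment
#'
#' Gap-filters the alignment, builds a neighbor-joining tree with
#' column-resampling bootstrap supports (or accepts an externally built
#' newick tree as-is), and assigns every unlabelled leaf a subfamily from
#' the labelled reference leaves.
#'
#' @param alignment_path Aligned FASTA path.
#' @param labels Named character vector (reference leaf -> label) or a
#'   two-column TSV path.
#' @param out_dir Output directory.
#' @param newick Optional externally built tree; skips NJ when given.
#' @param B Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param gap_threshold Gap-fraction threshold for column removal.
#' @param min_support Optional minimum support for clade assignment.
#' @return Invisibly, a list with `tree`, `assignments`, `removed_columns`.
#' @export
run_tree <- function(alignment_path, labels, out_dir, newick = NULL,
                     B = 100L, seed = 1L, gap_threshold = 0.5,
                     min_support = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lt <- utils::read.delim(labels, header = FALSE, stringsAsFactors = FALSE)
    labels <- stats::setNames(lt[[2]], lt[[1]])
  }
  removed <- integer()
  if (!is.null(newick)) {
    tree <- read_newick(newick)
  } else {
    aln <- read_alignment(alignment_path)
    ed <- filter_gap_columns(aln, threshold = gap_threshold)
    removed <- ed$removed
    write_alignment(ed$alignment, file.path(out_dir, "edited_alignment.fasta"))
    tree <- bootstrap_support(ed$alignment, B = B, seed = seed)
  }
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  queries <- setdiff(tree$tip.label, names(labels))
  rows <- lapply(queries, function(q) {
    a <- assign_clade(tree, labels, q, min_support = min_support)
    data.frame(query = q, label = ifelse(is.na(a$label), "unclassified", a$label),
               support = a$support, clade_size = a$clade_size,
               cause = ifelse(is.na(a$cause), "", a$cause),
               stringsAsFactors = FALSE)
  })
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), label = character(), support = numeric(),
               clade_size = integer(), cause = character())
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(tree = tree, assignments = assignments,
                 removed_columns = removed))
}

#' Simulate stage: write a synthetic dataset to disk
#'
#' @param out_dir Output directory.
#' @param config A [synthetic_config()].
#' @return Invisibly, the written paths (see [write_dataset()]).
#' @export
run_simulate <- function(out_dir, config = synthetic_config()) {
  ds <- generate_dataset(config)
  paths <- write_dataset(ds, out_dir)
  invisible(paths)
}
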