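#' @importFrom utils read.delim write.table head tail
NULL

#' Amino-acid alphabet accepted by the pipeline
#'
#' The 20 standard residues plus selenocysteine (`U`) and the unknown-residue
#' code `X`. Selenocysteine is kept as `U` throughout: whether a catalytic
#' position holds Sec or Cys is itself a classification output.
#'
#' @return Character vector of allowed single-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
    "P", "Q", "R", "S", "T", "V", "W", "Y", "U", "X")
}

new_protein_set <- function(protein_id, species_id, sequence, description) {
  data.frame(protein_id = as.character(protein_id),
             species_id = as.character(species_id),
             sequence = as.character(sequence),
             description = as.character(description),
             stringsAsFactors = FALSE)
}

validate_protein_set <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "species_id", "sequence") %in% names(records)))
  if (anyDuplicated(records$protein_id))
    stop("duplicated protein_id: ",
         paste(unique(records$protein_id[duplicated(records$protein_id)]), collapse = ", "))
  if (any(grepl("[[:space:]]", records$protein_id)))
    stop("protein_id must not contain whitespace")
  if (any(nchar(records$sequence) < 1L))
    stop("zero-length sequence for: ",
         paste(records$protein_id[nchar(records$sequence) < 1L], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), records$sequence)
  if (any(bad))
    stop("illegal residue in record(s): ",
         paste(records$protein_id[bad], collapse = ", "))
  invisible(records)
}

#' Read a protein FASTA file
#'
#' Reads amino-acid FASTA into a protein-set data frame (columns
#' `protein_id`, `species_id`, `sequence`, `description`). Selenocysteine
#' `U` is preserved verbatim. Trailing stop characters (`*`) are stripped;
#' internal stops are an error, as they indicate a broken gene model.
#'
#' Species provenance: an explicit `species_id` argument wins; otherwise the
#' filename stem is used.
#'
#' @param path Path to a FASTA file.
#' @param species_id Species tag for every record; default: filename stem.
#' @param lenient If `TRUE`, residues outside the accepted alphabet are
#'   mapped to `X` instead of raising an error.
#' @return A protein-set data frame, zero rows (with a warning) for an empty
#'   file.
#' @export
read_fasta <- function(path, species_id = NULL, lenient = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(species_id))
    species_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(new_protein_set(character(), character(), character(), character()))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA (%s, line %d): first record must start with '>'",
                 path, nonblank[1]))
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  sq <- toupper(as.character(seqs))
  sq <- sub("\\*+$", "", sq)            # trailing stop codons from predicted models
  if (any(grepl("\\*", sq)))
    stop("internal stop character in record(s): ",
         paste(ids[grepl("\\*", sq)], collapse = ", "))
  bad_re <- sprintf("[^%s]", paste(aa_alphabet(), collapse = ""))
  if (lenient) {
    sq <- gsub(bad_re, "X", sq)
  } else if (any(grepl(bad_re, sq))) {
    stop("illegal residue in record(s): ",
         paste(ids[grepl(bad_re, sq)], collapse = ", "),
         " (use lenient = TRUE to map unknowns to X)")
  }
  out <- new_protein_set(ids, species_id, sq, desc)
  validate_protein_set(out)
  out
}

#' Write a protein set to FASTA
#'
#' @param records Protein-set data frame.
#' @param path Output path.
#' @param width Line-wrap width (columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_protein_set(records)
  hdr <- ifelse(nzchar(records$description),
                paste(records$protein_id, records$description),
                records$protein_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a species manifest
#'
#' Two-column tab-separated file mapping `species_id` to a FASTA path. The
#' manifest is the authoritative source of species provenance; relative
#' paths are resolved against the manifest's own directory.
#'
#' @param path Manifest path.
#' @return Data frame with columns `species_id` and `path`.
#' @export
read_species_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  m <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(m) < 2L) stop("manifest must have two tab-separated columns")
  names(m)[1:2] <- c("species_id", "path")
  dir <- dirname(path)
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path, file.path(dir, m$path))
  data.frame(species_id = as.character(m$species_id), path = abs,
             stringsAsFactors = FALSE)
}

#' Read all proteomes listed in a manifest
#'
#' @inheritParams read_fasta
#' @param manifest_path Path to a species manifest (see
#'   [read_species_manifest()]).
#' @return One protein-set data frame for all species combined.
#' @export
read_proteomes <- function(manifest_path, lenient = FALSE) {
  m <- read_species_manifest(manifest_path)
  out <- lapply(seq_len(nrow(m)), function(i)
    read_fasta(m$path[i], species_id = m$species_id[i], lenient = lenient))
  out <- do.call(rbind, out)
  validate_protein_set(out)
  out
}

#' Collapse exact sequence duplicates within each species
#'
#' Proteomes predicted from genomes frequently contain exact sequence
#' variants (isoforms, split gene models). Grouping is by exact string
#' identity of the sequence within one species; the lexicographically
#' smallest `protein_id` of each group is retained so that results are
#' platform-independent. The census reports retained (unique) counts and the
#' number of additional identical copies separately.
#'
#' @param records Protein-set data frame.
#' @return An object of class `dedup_report`: a list with `unique_records`
#'   (protein-set data frame) and `duplicate_counts` (named integer vector,
#'   retained id -> number of additional identical sequences; ids with no
#'   duplicates are omitted).
#' @export
dedupe_exact <- function(records) {
  validate_protein_set(records)
  if (nrow(records) == 0L) {
    return(structure(list(unique_records = records,
                          duplicate_counts = integer()),
                     class = "dedup_report"))
  }
  key <- paste(records$species_id, records$sequence, sep = "\r")
  keep <- integer(0)
  dup_counts <- integer(0)
  for (grp in split(seq_len(nrow(records)), key)) {
    ids <- records$protein_id[grp]
    kept <- grp[order(ids)[1L]]
    keep <- c(keep, kept)
    if (length(grp) > 1L) {
      dc <- length(grp) - 1L
      names(dc) <- records$protein_id[kept]
      dup_counts <- c(dup_counts, dc)
    }
  }
  keep <- sort(keep)   # preserve input order
  structure(list(unique_records = records[keep, , drop = FALSE],
                 duplicate_counts = dup_counts),
            class = "dedup_report")
}

#' @export
print.dedup_report <- function(x, ...) {
  cat(sprintf("dedup report: %d unique record(s), %d additional identical cop(y/ies)\n",
              nrow(x$unique_records), sum(x$duplicate_counts)))
  invisible(x)
}
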