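#' Parse a HMMER3 per-domain table (domtblout)
#'
#' One row per domain hit. Envelope coordinates (`env from`/`env to`) are
#' taken as the domain interval: the envelope is the conventional inclusive
#' extent of a domain in per-domain tables. The per-domain independent
#' e-value (`i-Evalue`) and per-domain bit score are retained.
#'
#' Orientation (`hmmscan`: target = Pfam model, query = protein; `hmmsearch`:
#' the reverse) is auto-detected from which accession column carries a Pfam
#' accession, and can be forced with `orientation`.
#'
#' @param path Path to a domtblout file.
#' @param orientation `"auto"`, `"hmmscan"` or `"hmmsearch"`.
#' @return Data frame of domain hits with columns `protein_id`, `accession`
#'   (version suffix stripped), `domain_name`, `start`, `end`, `score`,
#'   `evalue`.
#' @export
parse_domtblout <- function(path, orientation = c("auto", "hmmscan", "hmmsearch")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  hits <- data.frame(protein_id = character(), accession = character(),
                     domain_name = character(), start = integer(),
                     end = integer(), score = numeric(), evalue = numeric(),
                     stringsAsFactors = FALSE)
  if (length(keep) == 0L) return(hits)
  rows <- lapply(keep, function(ln) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop(sprintf("unparseable domtblout row (%s, line %d): expected >= 22 fields, got %d",
                   path, ln, length(f)))
    ori <- orientation
    if (ori == "auto") {
      if (grepl("^PF\\d{5}", f[2])) ori <- "hmmscan"
      else if (grepl("^PF\\d{5}", f[5])) ori <- "hmmsearch"
      else ori <- "hmmscan"   # fall back to the scanner convention
    }
    if (ori == "hmmscan") {
      prot <- f[4]; acc <- f[2]; dom <- f[1]
    } else {
      prot <- f[1]; acc <- f[5]; dom <- f[4]
    }
    start <- suppressWarnings(as.integer(f[20]))
    end <- suppressWarnings(as.integer(f[21]))
    ieval <- suppressWarnings(as.numeric(f[13]))
    score <- suppressWarnings(as.numeric(f[14]))
    if (anyNA(c(start, end, ieval, score)))
      stop(sprintf("unparseable domtblout row (%s, line %d): non-numeric coordinate/score fields",
                   path, ln))
    if (start > end || start < 1L)
      stop(sprintf("invalid envelope coordinates (%s, line %d): %d-%d", path, ln, start, end))
    if (ieval < 0)
      stop(sprintf("negative e-value (%s, line %d)", path, ln))
    data.frame(protein_id = prot, accession = sub("\\..*$", "", acc),
               domain_name = dom, start = start, end = end,
               score = score, evalue = ieval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Threshold domain hits on e-value and score
#'
#' @param hits Domain-hit data frame from [parse_domtblout()].
#' @param max_evalue Keep hits with independent e-value at or below this;
#'   default `1e-5`.
#' @param min_score Optional bit-score floor; `NULL` means no floor.
#' @return The surviving rows, input order preserved.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_score = NULL) {
  if (!is.numeric(max_evalue) || max_evalue < 0)
    stop("max_evalue must be a non-negative number")
  keep <- hits$evalue <= max_evalue
  if (!is.null(min_score)) {
    if (!is.numeric(min_score)) stop("min_score must be numeric or NULL")
    keep <- keep & hits$score >= min_score
  }
  hits[keep, , drop = FALSE]
}

#' Bundled family domain-architecture rules
#'
#' CAT requires co-occurrence of the catalase (PF00199) and
#' catalase-related (PF06628) domains; PRX requires the core
#' thiol-peroxidase domain PF00578 plus at least one of PF08534 and
#' PF10417 (the C-terminal / accessory domains; set `prx_any_optional =
#' TRUE` to accept PF00578 alone); GPX requires the GSHPx domain PF00255;
#' SRX requires the ParB-like nuclease domain PF02195. Rules are plain
#' lists so curated alternatives can be supplied.
#'
#' @param prx_any_optional If `TRUE` the PRX accessory-domain requirement is
#'   relaxed to optional.
#' @return Named list of rules, each `list(family, require_all, require_any)`.
#' @export
default_architecture_rules <- function(prx_any_optional = FALSE) {
  list(
    CAT = architecture_rule("CAT", require_all = c("PF00199", "PF06628")),
    PRX = architecture_rule("PRX", require_all = "PF00578",
                            require_any = if (prx_any_optional) character()
                                          else c("PF08534", "PF10417")),
    GPX = architecture_rule("GPX", require_all = "PF00255"),
    SRX = architecture_rule("SRX", require_all = "PF02195")
  )
}

#' Construct a domain-architecture rule
#'
#' @param family One of `"CAT"`, `"PRX"`, `"GPX"`, `"SRX"`.
#' @param require_all Accessions that must all be present.
#' @param require_any Accessions of which at least one must be present; an
#'   empty set is vacuously satisfied.
#' @return A list of class `architecture_rule`.
#' @export
architecture_rule <- function(family, require_all = character(),
                              require_any = character()) {
  if (!family %in% c("CAT", "PRX", "GPX", "SRX"))
    stop("unknown family in rule: ", family)
  require_all <- as.character(require_all)
  require_any <- as.character(require_any)
  if (length(intersect(require_all, require_any)))
    stop("require_all and require_any must be disjoint")
  structure(list(family = family, require_all = require_all,
                 require_any = require_any),
            class = "architecture_rule")
}

#' Nominate candidate proteins under one architecture rule
#'
#' A protein is nominated iff every `require_all` accession is present among
#' its hits and (when `require_any` is non-empty) at least one
#' `require_any` accession is present. Multiple hits of the same accession
#' count once.
#'
#' @param hits Thresholded domain-hit data frame.
#' @param rule An [architecture_rule()].
#' @return Sorted character vector of nominated `protein_id`s.
#' @export
apply_architecture_rule <- function(hits, rule) {
  if (!inherits(rule, "architecture_rule")) stop("rule must be an architecture_rule")
  if (nrow(hits) == 0L) return(character())
  accs <- split(hits$accession, hits$protein_id)
  ok <- vapply(accs, function(a) {
    all(rule$require_all %in% a) &&
      (length(rule$require_any) == 0L || any(rule$require_any %in% a))
  }, logical(1))
  sort(names(accs)[ok])
}

#' Nominate candidates for every family
#'
#' @param hits Thresholded domain-hit data frame.
#' @param rules Named list of rules, default [default_architecture_rules()].
#' @return Data frame `protein_id`, `family` (a protein may be nominated by
#'   more than one family; conflicts are resolved downstream).
#' @export
nominate_families <- function(hits, rules = default_architecture_rules()) {
  out <- lapply(rules, function(r) {
    ids <- apply_architecture_rule(hits, r)
    if (length(ids) == 0L) return(NULL)
    data.frame(protein_id = ids, family = r$family, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein_id = character(), family = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-protein domain layout
#'
#' Orders each protein's domain intervals by start coordinate and flags
#' proteins where any two intervals intersect (overlapping hits are
#' permitted but worth inspecting).
#'
#' @param hits Domain-hit data frame.
#' @return Named list (by `protein_id`) of `list(intervals = data.frame(
#'   accession, start, end), overlapping = logical)`.
#' @export
domain_layout <- function(hits) {
  if (nrow(hits) == 0L) return(structure(list(), names = character()))
  lapply(split(hits, hits$protein_id), function(h) {
    o <- order(h$start, h$end)
    iv <- h[o, c("accession", "start", "end"), drop = FALSE]
    rownames(iv) <- NULL
    overlapping <- FALSE
    if (nrow(iv) > 1L)
      overlapping <- any(iv$start[-1L] <= cummax(iv$end)[-nrow(iv)])
    list(intervals = iv, overlapping = overlapping)
  })
}
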