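# Bundled reference data: PRX active-site profiles, the GPX tetrad
# reference, resolving-cysteine context patterns and a/b motif definitions.
# All of these ship as editable data (or plain constants) so curated sets
# can be substituted; several are provisional defaults, flagged as such.

#' Subfamily consensus windows around the peroxidatic cysteine
#'
#' Fifteen-residue windows (C_P cysteine at position 8) used both as the
#' centre of the bundled active-site profiles and as the planting template
#' of the synthetic generator.
#'
#' @return Named character vector (subfamily -> 15-residue window).
#' @export
prx_cp_consensus <- function() {
  c("AhpC-PRX1" = "PLDFTFVCPTEIIAF",
    "PRX5"      = "PGAFTPGCSKTHLPG",
    "PRX6"      = "PGDFTPVCTTELGRA")
}

#' Load PRX active-site profiles
#'
#' Position-specific residue frequencies over the 15-residue window centred
#' on the peroxidatic cysteine, one profile per animal PRX subfamily
#' (AhpC-PRX1, PRX5, PRX6). Shipped as a plain TSV
#' (`subfamily`, `position`, `residue`, `freq`) so users can substitute
#' curated profiles.
#'
#' @param path Profile TSV; default the bundled file.
#' @return Named list of 20 x 15 frequency matrices (residues x positions),
#'   columns summing to 1.
#' @export
prx_cp_profiles <- function(path = system.file("extdata", "prx_cp_profiles.tsv",
                                               package = "antioxscan")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subfamily", "position", "residue", "freq") %in% names(tab)))
  res <- setdiff(aa_alphabet(), c("U", "X"))
  lapply(split(tab, tab$subfamily), function(t1) {
    w <- max(t1$position)
    m <- matrix(0, nrow = length(res), ncol = w, dimnames = list(res, NULL))
    m[cbind(match(t1$residue, res), t1$position)] <- t1$freq
    sw <- colSums(m)
    bad <- abs(sw - 1) > 1e-6
    if (any(bad)) stop("profile columns must sum to 1 (position ",
                       paste(which(bad), collapse = ","), ")")
    m
  })
}

#' Score a C_P window against one profile
#'
#' Mean per-position log-odds of the observed residues against a uniform
#' background of 1/20, with additive smoothing so unseen residues get a
#' finite penalty. Positions outside the sequence (window truncated at a
#' sequence end) are passed as `NA` and skipped.
#'
#' @param window Character vector of residues, length equal to the profile
#'   width, `NA` for unavailable positions.
#' @param profile Frequency matrix from [prx_cp_profiles()].
#' @param pseudo Additive pseudocount applied to the frequencies.
#' @return Mean log-odds (natural log) over the scored positions.
#' @export
score_cp_window <- function(window, profile, pseudo = 0.01) {
  stopifnot(length(window) == ncol(profile))
  bg <- 1 / nrow(profile)
  sc <- vapply(seq_along(window), function(p) {
    ch <- window[p]
    if (is.na(ch)) return(NA_real_)
    f <- if (ch %in% rownames(profile)) profile[ch, p] else 0
    log(((f + pseudo) / (1 + nrow(profile) * pseudo)) / bg)
  }, numeric(1))
  mean(sc, na.rm = TRUE)
}

#' Synthetic reference GPX with annotated catalytic tetrad
#'
#' A fixed synthetic reference sequence (140 residues) carrying the GPX
#' catalytic tetrad - Sec (U), Gln (Q), Trp (W), Asn (N) - at annotated
#' positions. It is a constructed stand-in, not a curated GPX entry;
#' substitute a curated reference (sequence plus four tetrad coordinates)
#' for production annotation.
#'
#' @return List with `sequence` and `tetrad` (named integer positions,
#'   roles `catalytic`, `Gln`, `Trp`, `Asn`).
#' @export
gpx_reference <- function() {
  list(
    sequence = paste0(
      "YAARDQISYKIPSCFSKKPRDTCGFCNMNGCYGSVAFRM", "U",
      "EWNKIAQTYACHRIFEPYWGPVWEEFLANEIWLGQIWHNFRSGNDFWKKPGYLDSNSQHMWMDVQNIL",
      "FPLERAKDNVMAADKVIICVSWVETHNALKFP"),
    tetrad = c(catalytic = 40L, Gln = 75L, Trp = 130L, Asn = 135L)
  )
}

#' Resolving-cysteine (C_R) context patterns
#'
#' Subfamily-specific context patterns locating the resolving cysteine:
#' the conserved flanking residues with the cysteine slot wildcarded, plus
#' the slot index. The AhpC-PRX1 context is the conserved C-terminal
#' `HGEVCPAGW` region of typical 2-Cys peroxiredoxins; the PRX5 context is
#' a provisional default (atypical 2-Cys C_R surroundings are poorly
#' standardised). Both are overridable.
#'
#' @return Named list of `list(pattern, slot)`; `slot` is the 1-based
#'   index of the cysteine slot within the pattern.
#' @export
cr_contexts <- function() {
  list(
    "AhpC-PRX1" = list(pattern = "HGEVXPAGW", slot = 5L),
    "PRX5"      = list(pattern = "GWKPGXDAV", slot = 6L)
  )
}

#' Provisional a/b hyperoxidation-modulating motif definitions
#'
#' The a and b motifs modulate the degree of sensitivity to hyperoxidation
#' in typical 2-Cys peroxiredoxins. Their exact residue content is not
#' standardised; these definitions are provisional defaults (anchor
#' residues with wildcarded role slots) intended to be replaced by curated
#' ones. Each definition gives the scan pattern, the role slots (1-based
#' offsets within the pattern) and the expected residue per role.
#'
#' @return List of `list(name, pattern, slots, roles)`.
#' @export
ab_motif_defs <- function() {
  list(
    list(name = "a", pattern = "WXEPXGS",
         slots = list(His = 2L, Asn = 5L),
         roles = list(His = "H", Asn = "N")),
    list(name = "b", pattern = "CEVXKSL",
         slots = list(Asp = 4L),
         roles = list(Asp = "D"))
  )
}
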