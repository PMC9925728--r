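# Restricted motif grammar and scanner.
#
# Grammar (one token per element):
#   A..Z (not X)   fixed residue
#   X              wildcard (any residue, including U)
#   [TS]           alternation over the listed residues
#   X{min,max}     bounded gap: between min and max residues of any kind
#
# Deliberately NOT a general regular-expression engine: no anchors,
# backreferences or unbounded repeats. Gaps expand minimally, leftmost
# first, so every matching start offset yields exactly one reported match.

#' Compile a motif pattern specification
#'
#' @param spec Pattern string, e.g. `"PXXX[TS]XXC"`, `"F[SG]GCHR"`,
#'   `"HX{0,60}SX{0,60}D"`.
#' @param name Optional motif name carried into match reports.
#' @return Object of class `motif_pattern`.
#' @export
compile_pattern <- function(spec, name = spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec))
    stop("pattern spec must be a non-empty string")
  chars <- strsplit(spec, "")[[1]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  push <- function(el) elements[[length(elements) + 1L]] <<- el
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character()
      while (j <= n && chars[j] != "]") {
        if (!chars[j] %in% LETTERS)
          stop(sprintf("pattern syntax error at column %d: '%s' not a residue", j, chars[j]))
        set <- c(set, chars[j]); j <- j + 1L
      }
      if (j > n) stop(sprintf("pattern syntax error at column %d: unterminated '['", i))
      if (length(set) == 0L) stop(sprintf("pattern syntax error at column %d: empty set", i))
      push(list(type = "set", residues = unique(set)))
      i <- j + 1L
    } else if (ch %in% LETTERS) {
      if (i < n && chars[i + 1L] == "{") {
        if (ch != "X")
          stop(sprintf("pattern syntax error at column %d: bounds only follow X", i + 1L))
        j <- i + 2L
        body <- character()
        while (j <= n && chars[j] != "}") { body <- c(body, chars[j]); j <- j + 1L }
        if (j > n) stop(sprintf("pattern syntax error at column %d: unterminated '{'", i + 1L))
        body <- paste(body, collapse = "")
        if (!grepl("^[0-9]+,[0-9]+$", body))
          stop(sprintf("pattern syntax error at column %d: bounds must be {min,max}", i + 1L))
        mm <- as.integer(strsplit(body, ",")[[1]])
        if (mm[1] > mm[2])
          stop(sprintf("pattern syntax error at column %d: min > max", i + 1L))
        push(list(type = "gap", min = mm[1], max = mm[2]))
        i <- j + 1L
      } else if (ch == "X") {
        push(list(type = "any"))
        i <- i + 1L
      } else {
        push(list(type = "set", residues = ch))
        i <- i + 1L
      }
    } else {
      stop(sprintf("pattern syntax error at column %d: unexpected '%s'", i, ch))
    }
  }
  if (!any(vapply(elements, function(e) e$type == "set", logical(1))))
    stop("pattern must contain at least one non-wildcard element")
  min_len <- sum(vapply(elements, function(e)
    switch(e$type, gap = e$min, 1L), numeric(1)))
  max_len <- sum(vapply(elements, function(e)
    switch(e$type, gap = e$max, 1L), numeric(1)))
  structure(list(name = name, spec = spec, elements = elements,
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("motif '%s' (%s): %d elements, match length %d-%d\n",
              x$name, x$spec, length(x$elements), x$min_len, x$max_len))
  invisible(x)
}

has_gaps <- function(pattern) {
  any(vapply(pattern$elements, function(e) e$type == "gap", logical(1)))
}

# Try to match `elements` at `pos` in character vector `chars`.
# Gaps expand minimally, leftmost first (backtracking). Returns the end
# index of the first (shortest-leftmost) match, or NA.
match_at <- function(chars, pos, elements, sec_equivalence = FALSE) {
  n <- length(chars)
  rec <- function(p, ei) {
    if (ei > length(elements)) return(p - 1L)
    el <- elements[[ei]]
    if (el$type == "gap") {
      for (g in el$min:el$max) {
        if (p + g - 1L > n) break
        r <- rec(p + g, ei + 1L)
        if (!is.na(r)) return(r)
      }
      return(NA_integer_)
    }
    if (p > n) return(NA_integer_)
    ch <- chars[p]
    ok <- switch(el$type,
      any = TRUE,
      set = ch %in% el$residues ||
        (sec_equivalence && ch == "U" && "C" %in% el$residues))
    if (!ok) return(NA_integer_)
    rec(p + 1L, ei + 1L)
  }
  rec(pos, 1L)
}

#' Scan a sequence for a motif
#'
#' Reports every start offset at which the pattern matches (overlapping
#' matches allowed), left to right. At a given start, bounded gaps expand
#' minimally (leftmost gap first), so each matching start yields one match.
#'
#' @param sequence A sequence string, or a one-row protein-set data frame.
#' @param pattern A [compile_pattern()] object (a plain string is compiled
#'   on the fly).
#' @param region Optional `c(start, end)` (1-based inclusive): match starts
#'   are restricted to `region` expanded by `flank` on both sides.
#' @param flank Non-negative flank width added to `region`.
#' @param sec_equivalence If `TRUE`, selenocysteine `U` satisfies
#'   `C`-containing fixed positions (used for the GPX catalytic residue,
#'   where Sec/Cys typing is the output, not a mismatch).
#' @return Data frame with columns `start`, `end`, `match` (the matched
#'   substring), `motif`.
#' @export
scan_motif <- function(sequence, pattern, region = NULL, flank = 0L,
                       sec_equivalence = FALSE) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1L]
  if (!inherits(pattern, "motif_pattern")) pattern <- compile_pattern(pattern)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  lo <- 1L; hi <- n
  if (!is.null(region)) {
    region <- as.integer(region)
    if (region[1] < 1L || region[2] > n || region[1] > region[2])
      stop(sprintf("region %d-%d outside sequence of length %d",
                   region[1], region[2], n))
    lo <- max(1L, region[1] - as.integer(flank))
    hi <- min(n, region[2] + as.integer(flank))
  }
  starts <- integer(0); ends <- integer(0)
  if (hi - lo + 1L >= pattern$min_len) {
    cand <- lo:(hi - pattern$min_len + 1L)
    if (!has_gaps(pattern)) {
      # fixed-length fast path: vectorised set membership per element
      k <- length(pattern$elements)
      ok <- rep(TRUE, length(cand))
      for (j in seq_len(k)) {
        el <- pattern$elements[[j]]
        if (el$type == "any") next
        res <- el$residues
        if (sec_equivalence && "C" %in% res) res <- union(res, "U")
        ok <- ok & chars[cand + j - 1L] %in% res
        if (!any(ok)) break
      }
      starts <- cand[ok]
      ends <- starts + k - 1L
    } else {
      for (p in cand) {
        e <- match_at(chars, p, pattern$elements, sec_equivalence)
        if (!is.na(e)) { starts <- c(starts, p); ends <- c(ends, e) }
      }
    }
  }
  data.frame(start = starts, end = ends,
             match = if (length(starts)) substring(sequence, starts, ends)
                     else character(),
             motif = rep(pattern$name, length(starts)),
             stringsAsFactors = FALSE)
}

#' Bundled motif patterns
#'
#' The catalytic and functional motifs used as filters or annotations:
#' the peroxidatic-cysteine (C_P) active-site motif `PXXX[TS]XXC`, the
#' sulfiredoxin N-terminal binding motif `F[SG]GCHR`, the
#' hyperoxidation-sensitivity motifs `GGLG` and `YF`, the lipase motif
#' `GXSXG`, and the gapped phospholipase A2 triad `HX{0,60}SX{0,60}D`
#' (gap bounds are a tunable default; see the methods vignette).
#'
#' @param pla2_gap Maximum residues between consecutive triad roles.
#' @return Named list of compiled `motif_pattern`s.
#' @export
bundled_motifs <- function(pla2_gap = 60L) {
  list(
    cp = compile_pattern("PXXX[TS]XXC", "C_P"),
    srx = compile_pattern("F[SG]GCHR", "SRX_N"),
    gglg = compile_pattern("GGLG", "GGLG"),
    yf = compile_pattern("YF", "YF"),
    gxsxg = compile_pattern("GXSXG", "GXSXG"),
    pla2 = compile_pattern(sprintf("HX{0,%d}SX{0,%d}D", pla2_gap, pla2_gap), "PLA2_triad")
  )
}

#' Locate the peroxidatic cysteine (C_P) motif
#'
#' Finds the strictly conserved `PXXX[TS]XXC` active-site motif. Absence is
#' a definitive negative: candidates without it are excluded from the PRX
#' census. When several matches occur the leftmost is "the" catalytic site;
#' the others are retained as a count.
#'
#' @param sequence Sequence string or one-row protein-set data frame.
#' @return `NULL` when absent, else a list with `start`, `end`, `cp_pos`
#'   (index of the catalytic cysteine), `match`, `n_matches`.
#' @export
find_cp <- function(sequence) {
  m <- scan_motif(sequence, bundled_motifs()$cp)
  if (nrow(m) == 0L) return(NULL)
  list(start = m$start[1L], end = m$end[1L], cp_pos = m$end[1L],
       match = m$match[1L], n_matches = nrow(m))
}

#' Resolve the resolving-cysteine (C_R) status
#'
#' The resolving cysteine is located through a subfamily-specific context
#' pattern (the conserved residues flanking the C_R slot). If the context
#' matches but the cysteine slot holds another residue - e.g. the valine
#' substitution seen in some sponge PRX5 sequences - the status is
#' `substituted` with that residue; with no context match it is `absent`.
#' Context patterns are provisional defaults and fully overridable.
#'
#' @param sequence Sequence string or one-row protein-set data frame.
#' @param subfamily `"AhpC-PRX1"` or `"PRX5"` (PRX6 has no C_R).
#' @param contexts Context definitions, default [cr_contexts()].
#' @return List with `status` (`"present"`, `"substituted"`, `"absent"`),
#'   `residue` and `position` (NA when absent).
#' @export
find_cr <- function(sequence, subfamily, contexts = cr_contexts()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1L]
  ctx <- contexts[[subfamily]]
  if (is.null(ctx)) return(list(status = "absent", residue = NA_character_,
                                position = NA_integer_))
  m <- scan_motif(sequence, compile_pattern(ctx$pattern, paste0("C_R_", subfamily)))
  if (nrow(m) == 0L)
    return(list(status = "absent", residue = NA_character_, position = NA_integer_))
  pos <- m$start[1L] + ctx$slot - 1L
  res <- substring(sequence, pos, pos)
  list(status = if (res == "C") "present" else "substituted",
       residue = res, position = pos)
}

#' Phospholipase A2 catalytic-triad status
#'
#' PRX6 moonlights as a phospholipase; its catalytic triad is His, then
#' Ser, then Asp in sequence order. `full` requires an ordered H-S-D chain
#' with each inter-role gap within `gap_max`; the serine of a `GXSXG`
#' match is preferred as the triad serine when one exists. If only a proper
#' subset of the three roles occurs in the region the status is `partial`
#' (listing the missing roles); if all three occur but cannot be chained in
#' order, or none occurs, the status is `absent`.
#'
#' @param sequence Sequence string or one-row protein-set data frame.
#' @param region Optional `c(start, end)` restricting the search (usually
#'   the PRX domain layout).
#' @param gap_max Maximum residues between consecutive roles.
#' @return List with `status` (`"full"`, `"partial"`, `"absent"`),
#'   `missing` (character vector), and `positions` (named, when full).
#' @export
pla2_triad <- function(sequence, region = NULL, gap_max = 60L) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1L]
  chars <- strsplit(sequence, "")[[1]]
  lo <- 1L; hi <- length(chars)
  if (!is.null(region)) {
    if (region[1] < 1L || region[2] > length(chars)) stop("region outside sequence")
    lo <- region[1]; hi <- region[2]
  }
  idx <- lo:hi
  hpos <- idx[chars[idx] == "H"]
  dpos <- idx[chars[idx] == "D"]
  gx <- scan_motif(sequence, bundled_motifs()$gxsxg, region = c(lo, hi))
  spos <- if (nrow(gx) > 0L) gx$start + 2L else idx[chars[idx] == "S"]
  present <- c(H = length(hpos) > 0L, S = length(spos) > 0L, D = length(dpos) > 0L)
  if (!any(present)) return(list(status = "absent", missing = c("H", "S", "D"),
                                 positions = NULL))
  if (!all(present)) return(list(status = "partial",
                                 missing = names(present)[!present],
                                 positions = NULL))
  for (h in hpos) {
    s_ok <- spos[spos > h & spos - h - 1L <= gap_max]
    for (s in s_ok) {
      d_ok <- dpos[dpos > s & dpos - s - 1L <= gap_max]
      if (length(d_ok) > 0L)
        return(list(status = "full", missing = character(),
                    positions = c(H = h, S = s, D = min(d_ok))))
    }
  }
  list(status = "absent", missing = character(), positions = NULL)
}

#' Lipase GXSXG motif presence
#'
#' @inheritParams pla2_triad
#' @return `TRUE`/`FALSE`.
#' @export
gxsxg <- function(sequence, region = NULL) {
  nrow(scan_motif(sequence, bundled_motifs()$gxsxg, region = region)) > 0L
}

#' Hyperoxidation-sensitivity motifs (GGLG, YF, a/b motifs)
#'
#' Sensitivity of typical 2-Cys peroxiredoxins (AhpC-PRX1) to
#' hyperoxidation is conferred by the C-terminal GGLG and YF motifs and
#' modulated by the a and b motifs. GGLG and YF are searched in the
#' C-terminal half of the sequence by default (both are C-terminal motifs
#' in this family); the a/b motifs are evaluated against configurable
#' reference definitions with per-role substitution reporting.
#'
#' @param sequence Sequence string or one-row protein-set data frame.
#' @param search `"cterm_half"` (default) or `"full"` for the GGLG/YF scan.
#' @param ab_defs a/b motif definitions, default [ab_motif_defs()]
#'   (provisional; see the methods vignette).
#' @return List with logicals `gglg`, `yf`, and `ab_substitutions`, a data
#'   frame (motif, role, expected, observed) with one row per substituted
#'   or unlocated role.
#' @export
hyperox_motifs <- function(sequence, search = c("cterm_half", "full"),
                           ab_defs = ab_motif_defs()) {
  search <- match.arg(search)
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1L]
  n <- nchar(sequence)
  region <- if (search == "cterm_half") c(max(1L, floor(n / 2)), n) else NULL
  bm <- bundled_motifs()
  gglg <- nrow(scan_motif(sequence, bm$gglg, region = region)) > 0L
  yf <- nrow(scan_motif(sequence, bm$yf, region = region)) > 0L
  subs <- data.frame(motif = character(), role = character(),
                     expected = character(), observed = character(),
                     stringsAsFactors = FALSE)
  for (def in ab_defs) {
    m <- scan_motif(sequence, compile_pattern(def$pattern, def$name))
    if (nrow(m) == 0L) {
      subs <- rbind(subs, data.frame(motif = def$name, role = names(def$roles),
                                     expected = unlist(def$roles,
                                                       use.names = FALSE),
                                     observed = NA_character_,
                                     stringsAsFactors = FALSE))
      next
    }
    for (rn in names(def$roles)) {
      pos <- m$start[1L] + def$slots[[rn]] - 1L
      obs <- substring(sequence, pos, pos)
      if (obs != def$roles[[rn]])
        subs <- rbind(subs, data.frame(motif = def$name, role = rn,
                                       expected = def$roles[[rn]],
                                       observed = obs, stringsAsFactors = FALSE))
    }
  }
  list(gglg = gglg, yf = yf, ab_substitutions = subs)
}

#' Sulfiredoxin N-terminal binding motif presence
#'
#' Scans the full sequence for the strictly conserved `F[SG]GCHR` motif
#' required for SRX catalytic activity.
#'
#' @param sequence Sequence string or one-row protein-set data frame.
#' @return `TRUE`/`FALSE`.
#' @export
srx_motif <- function(sequence) {
  nrow(scan_motif(sequence, bundled_motifs()$srx)) > 0L
}

#' Locate the GPX catalytic tetrad and type the catalysis
#'
#' The glutathione-peroxidase catalytic tetrad is Sec/Cys (U/C), Gln (Q),
#' Trp (W) and Asn (N). The four roles are located by globally aligning the
#' query (or its GSHPx-domain region) to a bundled reference GPX sequence
#' with annotated tetrad positions, then reading the query residues mapped
#' to those positions. Role 1 = `U` gives selenium-dependent catalysis,
#' `C` gives cysteine-dependent, anything else (or insufficient alignment
#' coverage) is undetermined.
#'
#' @param sequence Sequence string or one-row protein-set data frame.
#' @param region Optional `c(start, end)` restricting the query to the
#'   GSHPx domain region (with a 20-residue flank).
#' @param reference Reference definition, default [gpx_reference()].
#' @param min_coverage Minimum fraction of reference positions that must be
#'   aligned to query residues.
#' @return List with `residues` (named character, roles `catalytic`,
#'   `Gln`, `Trp`, `Asn`), `positions` (query coordinates, NA when
#'   unaligned), `type` (`"selenium-dependent"`, `"cysteine-dependent"`,
#'   `"undetermined"`) and `reason`.
#' @export
gpx_tetrad <- function(sequence, region = NULL, reference = gpx_reference(),
                       min_coverage = 0.6) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1L]
  n <- nchar(sequence)
  off <- 0L
  query <- sequence
  if (!is.null(region)) {
    if (region[1] < 1L || region[2] > n) stop("region outside sequence")
    lo <- max(1L, region[1] - 20L); hi <- min(n, region[2] + 20L)
    query <- substring(sequence, lo, hi)
    off <- lo - 1L
  }
  # U has no substitution-matrix row; score it as C (chemically analogous),
  # but read residues back from the original query.
  q_sc <- chartr("U", "C", query)
  r_sc <- chartr("U", "C", reference$sequence)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q_sc), Biostrings::AAString(r_sc),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  # map reference position -> query position
  qpos <- 0L; rpos <- 0L
  map <- rep(NA_integer_, nchar(reference$sequence))
  for (i in seq_along(ap)) {
    if (ap[i] != "-") qpos <- qpos + 1L
    if (as_[i] != "-") {
      rpos <- rpos + 1L
      if (ap[i] != "-") map[rpos] <- qpos
    }
  }
  coverage <- mean(!is.na(map))
  roles <- c("catalytic", "Gln", "Trp", "Asn")
  pos <- map[reference$tetrad]
  res <- rep(NA_character_, 4L)
  res[!is.na(pos)] <- substring(query, pos[!is.na(pos)], pos[!is.na(pos)])
  names(res) <- roles
  pos_out <- ifelse(is.na(pos), NA_integer_, pos + off)
  names(pos_out) <- roles
  if (coverage < min_coverage)
    return(list(residues = res, positions = pos_out, type = "undetermined",
                reason = sprintf("alignment coverage %.2f below %.2f",
                                 coverage, min_coverage)))
  type <- if (is.na(res[["catalytic"]])) "undetermined"
          else if (res[["catalytic"]] == "U") "selenium-dependent"
          else if (res[["catalytic"]] == "C") "cysteine-dependent"
          else "undetermined"
  reason <- if (type == "undetermined")
    sprintf("catalytic slot holds '%s'", res[["catalytic"]]) else NA_character_
  list(residues = res, positions = pos_out, type = type, reason = reason)
}
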