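#' Physicochemical similarity grouping of the amino acids
#'
#' The default partition used for percent-similarity scoring: aliphatic
#' \{A,V,L,I,M\}, aromatic \{F,Y,W\}, basic \{K,R,H\}, acidic \{D,E\},
#' amide \{N,Q\}, hydroxyl \{S,T\}, and singletons \{G\}, \{P\}, \{C\}.
#' Two residues are similar iff they share a class. `X` belongs to no class.
#'
#' @return Named character vector mapping each residue to its class label.
#' @export
similarity_grouping <- function() {
  groups <- list(aliphatic = c("A", "V", "L", "I", "M"),
                 aromatic  = c("F", "Y", "W"),
                 basic     = c("K", "R", "H"),
                 acidic    = c("D", "E"),
                 amide     = c("N", "Q"),
                 hydroxyl  = c("S", "T"),
                 glycine   = "G", proline = "P", cysteine = "C")
  out <- character()
  for (g in names(groups)) out[groups[[g]]] <- g
  out
}

#' Consensus motif patterns
#'
#' A consensus pattern is an ordered list of scored positions — each a fixed
#' residue or an alternative set such as F/L — with at most one bounded-gap
#' internal spacer whose residues are not scored. Three patterns are
#' built in:
#' \describe{
#'   \item{ZFNC}{`GAF(F/L)RYMRQP-(0-7AA)-IKQE`, the conserved region found
#'     immediately N-terminal to ZF1 in Zic proteins.}
#'   \item{ZOC_revised}{`RDFL-(1-2AA)-RR`, the revised Zic1-3 odd-paired
#'     conserved domain consensus.}
#'   \item{ZOC_published}{`(S/T)RDFLxxxR`, the earlier published ZOC
#'     consensus (fixed three-residue spacer).}
#' }
#'
#' @param name One of `"ZFNC"`, `"ZOC_revised"`, `"ZOC_published"`.
#' @return An object of class `consensus_pattern`: list with `name`, `pre`
#'   (list of allowed-residue sets before the spacer), `spacer_min`,
#'   `spacer_max`, `post` (sets after the spacer).
#' @export
consensus_pattern <- function(name = c("ZFNC", "ZOC_revised",
                                       "ZOC_published")) {
  name <- match.arg(name)
  sets <- function(s) lapply(strsplit(s, "", fixed = TRUE)[[1]], identity)
  p <- switch(name,
    ZFNC = list(pre = c(sets("GAF"), list(c("F", "L")), sets("RYMRQP")),
                spacer_min = 0L, spacer_max = 7L, post = sets("IKQE")),
    ZOC_revised = list(pre = sets("RDFL"),
                       spacer_min = 1L, spacer_max = 2L, post = sets("RR")),
    ZOC_published = list(pre = c(list(c("S", "T")), sets("RDFL")),
                         spacer_min = 3L, spacer_max = 3L, post = sets("R")))
  structure(c(list(name = name), p), class = "consensus_pattern")
}

n_scored <- function(pattern) length(pattern$pre) + length(pattern$post)

# Positions as a flat list of allowed sets (spacer excluded).
scored_sets <- function(pattern) c(pattern$pre, pattern$post)

match_counts <- function(query, sets, grouping) {
  qc <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  if (length(qc) != length(sets))
    stop(sprintf("query length %d does not match %d scored positions",
                 length(qc), length(sets)))
  ident <- simil <- logical(length(qc))
  for (i in seq_along(qc)) {
    allowed <- sets[[i]]
    if (qc[i] == "X") next          # X never matches, never similar
    ident[i] <- qc[i] %in% allowed
    cls <- grouping[qc[i]]
    simil[i] <- ident[i] ||
      (!is.na(cls) && any(grouping[allowed] == cls, na.rm = TRUE))
  }
  list(ident = ident, simil = simil)
}

as_sets <- function(consensus) {
  if (inherits(consensus, "consensus_pattern")) scored_sets(consensus)
  else if (is.list(consensus)) consensus
  else lapply(strsplit(toupper(consensus), "", fixed = TRUE)[[1]], identity)
}

#' Percent identity of a query against consensus positions
#'
#' The fraction of scored consensus positions at which the query residue is
#' the consensus residue (or any member of an alternative set such as F/L),
#' times 100. Spacer residues are never scored; `X` never matches.
#'
#' @param query Residue string, one residue per scored position.
#' @param consensus A [consensus_pattern()], a plain residue string, or a
#'   list of allowed-residue sets.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(query, consensus) {
  sets <- as_sets(consensus)
  mc <- match_counts(query, sets, similarity_grouping())
  100 * sum(mc$ident) / length(sets)
}

#' Percent similarity of a query against consensus positions
#'
#' Like [percent_identity()], but a position also counts when the query
#' residue shares a physicochemical class with the consensus residue (or
#' with any member of an alternative set). Identity implies similarity, so
#' `percent_identity(q, c) <= percent_similarity(q, c)` always.
#'
#' @inheritParams percent_identity
#' @param grouping Residue-to-class map; defaults to [similarity_grouping()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_similarity <- function(query, consensus,
                               grouping = similarity_grouping()) {
  sets <- as_sets(consensus)
  mc <- match_counts(query, sets, grouping)
  100 * sum(mc$simil) / length(sets)
}

#' Scan a region for a consensus motif
#'
#' Scores every start offset and every admissible internal spacer length of
#' the pattern against the region, gaplessly within each segment. Matches
#' whose percent similarity meets `min_similarity` are returned best-first
#' (similarity, then identity, then leftmost start, then shortest spacer).
#' Set `min_similarity = 0` to see the complete ranking (used to report the
#' best "motif-like" candidate when no match clears the threshold).
#'
#' @param region Residue string (typically the output of
#'   [trim_nterm_region()]).
#' @param pattern A [consensus_pattern()].
#' @param min_similarity Reporting threshold in percent (default 70).
#' @return A data.frame with columns `pattern`, `start`, `end`, `spacer`,
#'   `identity`, `similarity` (1-based inclusive coordinates).
#' @export
scan_motif <- function(region, pattern, min_similarity = 70) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  region <- toupper(region)
  n <- nchar(region)
  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  npre <- length(pattern$pre); npost <- length(pattern$post)
  nsc <- npre + npost
  grouping <- similarity_grouping()
  sets <- c(pattern$pre, pattern$post)
  set_classes <- lapply(sets, function(a)
    unique(grouping[a][!is.na(grouping[a])]))
  rows <- list(); k <- 0L
  for (spacer in pattern$spacer_min:pattern$spacer_max) {
    width <- npre + spacer + npost
    if (width > n) next
    starts <- seq_len(n - width + 1L)
    # within-window offset of each scored position (spacer skipped)
    deltas <- c(seq_len(npre), npre + spacer + seq_len(npost)) - 1L
    nid <- nsim <- numeric(length(starts))
    for (j in seq_len(nsc)) {
      qc <- chars[starts + deltas[j]]
      cls <- unname(grouping[qc])
      id <- qc %in% sets[[j]] & qc != "X"
      sim <- id | (!is.na(cls) & cls %in% set_classes[[j]] & qc != "X")
      nid <- nid + id
      nsim <- nsim + sim
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      pattern = pattern$name, start = starts, end = starts + width - 1L,
      spacer = spacer, identity = 100 * nid / nsc,
      similarity = 100 * nsim / nsc, stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(pattern = character(), start = integer(),
                      end = integer(), spacer = integer(),
                      identity = numeric(), similarity = numeric()))
  res <- do.call(rbind, rows)
  res <- res[res$similarity >= min_similarity, , drop = FALSE]
  res <- res[order(-res$similarity, -res$identity, res$start, res$spacer), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Check that a ZF-NC match lies immediately N-terminal to ZF1
#'
#' @param match One row of a [scan_motif()] result (coordinates relative to
#'   the full sequence, or to a prefix of it that ends at/after the match).
#' @param arch The record's `zf_architecture`.
#' @param max_gap Maximum number of residues allowed between the match end
#'   and ZF1 Cys1 (default 30).
#' @return `TRUE` iff the match ends before Cys1 by at most `max_gap`
#'   residues.
#' @export
zfnc_location_check <- function(match, arch, max_gap = 30L) {
  stopifnot(inherits(arch, "zf_architecture"))
  c1 <- arch$hits$c1[1L]
  gap <- c1 - match$end - 1L
  gap >= 0L && gap <= max_gap
}

#' Tabulate motif matches for a set of records
#'
#' Scans each record's N-terminal region (when an architecture is found;
#' otherwise the whole sequence) for the ZOC (revised and published) and
#' ZF-NC consensus patterns. Sub-threshold best candidates are reported
#' with `passed = FALSE` ("motif-like"), mirroring weakly conserved
#' putative domains.
#'
#' @param records List of [protein_record()] objects.
#' @param params A [scan_params()] object.
#' @param min_similarity Threshold for calling a domain present (default 70).
#' @param max_gap ZF-NC location-check gap (default 30).
#' @return A data.frame: id, pattern, start, end, spacer, identity,
#'   similarity, located (ZF-NC only), passed.
#' @export
motif_report <- function(records, params = scan_params(),
                         min_similarity = 70, max_gap = 30L) {
  patterns <- list(consensus_pattern("ZOC_revised"),
                   consensus_pattern("ZOC_published"),
                   consensus_pattern("ZFNC"))
  rows <- list(); k <- 0L
  for (rec in records) {
    arch <- assemble_architecture(find_c2h2_hits(rec, params), params,
                                  partial = TRUE)
    region <- if (is.null(arch)) rec$sequence else
      suppressWarnings(trim_nterm_region(rec, arch))
    for (pat in patterns) {
      m <- scan_motif(region, pat, min_similarity = 0)
      if (nrow(m) == 0L) next
      best <- m[1L, , drop = FALSE]
      located <- if (pat$name == "ZFNC" && !is.null(arch))
        zfnc_location_check(best, arch, max_gap) else NA
      k <- k + 1L
      rows[[k]] <- cbind(data.frame(id = rec$id, stringsAsFactors = FALSE),
                         best,
                         data.frame(located = located,
                                    passed = best$similarity >=
                                      min_similarity &&
                                      (is.na(located) || located)))
    }
  }
  if (k == 0L)
    return(data.frame(id = character(), pattern = character(),
                      start = integer(), end = integer(), spacer = integer(),
                      identity = numeric(), similarity = numeric(),
                      located = logical(), passed = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
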