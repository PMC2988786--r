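SUBFAMILY_LABELS <- c("zic", "gli", "glis", "nkl", "gli/glis/nkl-like",
                      "non-family")

#' Rule-based subfamily classification of one record
#'
#' Combines the tandem five-finger architecture, the ZF1 inter-cysteine
#' spacing diagnostic and the ZOC / ZF-NC motif evidence into a call:
#' no architecture gives `non-family`; an architecture without zic evidence
#' gives `gli/glis/nkl-like`; an expanded ZF1 spacer gives `zic`, as does a
#' passing ZOC/ZF-NC motif when the architecture is partial and ZF1 spacing
#' is therefore unavailable. The evidence trail lists every criterion with
#' its value and outcome, so calls are auditable.
#'
#' @param record A [protein_record()].
#' @param params A [scan_params()] object.
#' @param min_similarity Motif-presence threshold in percent (default 70).
#' @param max_gap ZF-NC location-check gap (default 30).
#' @param partial Allow flagged 4-finger architectures (default `TRUE`).
#' @return An object of class `subfamily_call`: list with `id`, `label`,
#'   `partial`, `evidence` (data.frame criterion/value/passed), `arch`.
#' @export
rule_classify <- function(record, params = scan_params(),
                          min_similarity = 70, max_gap = 30L,
                          partial = TRUE) {
  arch <- assemble_architecture(find_c2h2_hits(record, params), params,
                                partial = partial)
  ev <- data.frame(criterion = character(), value = character(),
                   passed = logical(), stringsAsFactors = FALSE)
  add_ev <- function(criterion, value, passed) {
    rbind(ev, data.frame(criterion = criterion, value = as.character(value),
                         passed = passed, stringsAsFactors = FALSE))
  }
  if (is.null(arch)) {
    ev <- add_ev("five_tandem_zf", "0", FALSE)
    return(structure(list(id = record$id, label = "non-family",
                          partial = NA, evidence = ev, arch = NULL),
                     class = "subfamily_call"))
  }
  ev <- add_ev("five_tandem_zf",
               sprintf("%d%s", nrow(arch$hits),
                       if (arch$partial) " (partial)" else ""), TRUE)
  spacing_ok <- zf1_spacing_diagnostic(arch, params$zf1_threshold)
  ev <- add_ev(sprintf("zf1_spacing>=%d", params$zf1_threshold),
               ifelse(is.na(arch$zf1_spacing), "NA", arch$zf1_spacing),
               isTRUE(spacing_ok))
  mrep <- motif_report(list(record), params,
                       min_similarity = min_similarity, max_gap = max_gap)
  zoc <- mrep[mrep$pattern %in% c("ZOC_revised", "ZOC_published"), ,
              drop = FALSE]
  zoc_pass <- nrow(zoc) > 0L && any(zoc$passed)
  ev <- add_ev("zoc_motif",
               if (nrow(zoc)) sprintf("%.1f%% similar", max(zoc$similarity))
               else "none", zoc_pass)
  zfnc <- mrep[mrep$pattern == "ZFNC", , drop = FALSE]
  zfnc_pass <- nrow(zfnc) > 0L && any(zfnc$passed)
  ev <- add_ev("zfnc_motif",
               if (nrow(zfnc)) sprintf("%.1f%% similar",
                                       max(zfnc$similarity))
               else "none", zfnc_pass)
  # The expanded ZF1 spacer is the primary zic diagnostic. Motif evidence
  # decides on its own only when ZF1 spacing is unavailable (partial
  # architecture lacking ZF1): short ZOC-like hits arise by chance in
  # background sequence, so a canonical-spaced ZF1 is not overridden.
  label <- if (isTRUE(spacing_ok) ||
               (is.na(spacing_ok) && (zoc_pass || zfnc_pass))) "zic"
           else "gli/glis/nkl-like"
  structure(list(id = record$id, label = label, partial = arch$partial,
                 evidence = ev, arch = arch),
            class = "subfamily_call")
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat(sprintf("<subfamily_call> %s -> %s%s\n", x$id, x$label,
              if (isTRUE(x$partial)) " [partial architecture]" else ""))
  print(x$evidence, ...)
  invisible(x)
}

#' p-distance between two trimmed finger regions
#'
#' One minus the identical fraction under the best gapless sliding-offset
#' alignment of the shorter sequence against the longer; the denominator is
#' the shorter length. Always in `[0, 1]` and symmetric.
#'
#' @param a,b Non-empty residue strings.
#' @return Numeric distance in `[0, 1]`.
#' @export
pairwise_distance <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0L
  for (off in 0:(nb - na)) {
    ident <- sum(av == bv[(off + 1L):(off + na)])
    if (ident > best) best <- ident
  }
  1 - best / na
}

#' Pairwise distance matrix over trimmed finger regions
#'
#' @param seqs Named character vector of trimmed regions.
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- pairwise_distance(seqs[[i]], seqs[[j]])
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]); the unrooted
#' result is returned rooted at the final join for display.
#'
#' @param D Symmetric distance matrix with at least 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  tr
}

#' Build a labelled reference panel
#'
#' Caches the trimmed five-finger region of each labelled reference record.
#' Records in which no complete architecture is found are dropped with a
#' warning. Placement needs at least two members per labelled subfamily.
#'
#' @param records List of [protein_record()] objects.
#' @param labels Character vector of subfamily labels, parallel to
#'   `records`.
#' @param params A [scan_params()] object.
#' @return An object of class `reference_panel`: data.frame with id, label,
#'   trimmed sequence.
#' @export
reference_panel <- function(records, labels, params = scan_params()) {
  stopifnot(length(records) == length(labels),
            all(labels %in% SUBFAMILY_LABELS))
  rows <- list(); k <- 0L
  for (i in seq_along(records)) {
    arch <- assemble_architecture(find_c2h2_hits(records[[i]], params),
                                  params)
    if (is.null(arch)) {
      warning("panel record '", records[[i]]$id,
              "' has no complete architecture; dropped")
      next
    }
    k <- k + 1L
    rows[[k]] <- data.frame(id = records[[i]]$id, label = labels[i],
                            trimmed = trim_zf_region(records[[i]], arch),
                            stringsAsFactors = FALSE)
  }
  if (k == 0L) stop("no usable panel records")
  panel <- do.call(rbind, rows)
  counts <- table(panel$label)
  if (any(counts < 2L))
    warning("subfamilies with < 2 panel members: ",
            paste(names(counts)[counts < 2L], collapse = ", "))
  structure(panel, class = c("reference_panel", "data.frame"))
}

#' Place a query against a labelled reference panel
#'
#' Assigns the label of the panel subfamily with the smallest mean
#' p-distance to the query's trimmed finger region. Exact ties are broken
#' by a compatible rule-based label when supplied, else lexicographically,
#' and flagged.
#'
#' @param query_trimmed Trimmed finger region of the query (string).
#' @param panel A [reference_panel()].
#' @param rule_label Optional label from [rule_classify()] used to break
#'   ties.
#' @return List with `label`, `distance` (distance to the nearest member of
#'   the chosen subfamily), `tie` flag, and `by_label` (named mean
#'   distances).
#' @export
place_query <- function(query_trimmed, panel, rule_label = NULL) {
  if (is.null(panel) || nrow(panel) == 0L) stop("empty reference panel")
  d <- vapply(panel$trimmed, function(s)
    pairwise_distance(query_trimmed, s), 0)
  by_label <- tapply(d, panel$label, mean)
  by_label <- by_label[order(names(by_label))]
  best <- min(by_label)
  cand <- names(by_label)[by_label == best]
  tie <- length(cand) > 1L
  label <- if (tie && !is.null(rule_label) && rule_label %in% cand)
    rule_label else cand[1L]
  list(label = label,
       distance = min(d[panel$label == label]),  # nearest member
       tie = tie, by_label = by_label)
}

#' Classify a set of records, optionally refining by panel placement
#'
#' Runs [rule_classify()] on every record; records called
#' `gli/glis/nkl-like` are refined into `gli`, `glis` or `nkl` by
#' [place_query()] when a panel is supplied. Placement is advisory: a
#' rule-based `zic` or `non-family` call is never overturned.
#'
#' @param records List of [protein_record()] objects.
#' @param panel Optional [reference_panel()].
#' @param params A [scan_params()] object.
#' @param min_similarity,max_gap,partial Passed to [rule_classify()].
#' @return A data.frame: id, rule_label, label, partial, placement label,
#'   placement distance, tie.
#' @export
classify_records <- function(records, panel = NULL, params = scan_params(),
                             min_similarity = 70, max_gap = 30L,
                             partial = TRUE) {
  rows <- lapply(records, function(rec) {
    call <- rule_classify(rec, params, min_similarity, max_gap, partial)
    out <- data.frame(id = rec$id, rule_label = call$label,
                      label = call$label, partial = call$partial,
                      placed_label = NA_character_,
                      placed_distance = NA_real_, tie = NA,
                      stringsAsFactors = FALSE)
    if (!is.null(panel) && !is.null(call$arch) && !call$arch$partial) {
      pl <- place_query(trim_zf_region(rec, call$arch), panel,
                        rule_label = call$label)
      out$placed_label <- pl$label
      out$placed_distance <- pl$distance
      out$tie <- pl$tie
      if (call$label == "gli/glis/nkl-like" &&
          pl$label %in% c("gli", "glis", "nkl"))
        out$label <- pl$label
    }
    out
  })
  do.call(rbind, rows)
}
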