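#' Scan parameters for C2H2 zinc-finger detection
#'
#' The C2H2 motif is modelled as `C-x(cc_min..cc_max)-C-x(ch_min..ch_max)-`
#' `H-x(hh_min..hh_max)-H`, where `x(a..b)` means between `a` and `b`
#' residues strictly between the flanking coordinating residues. The
#' Cys--Cys upper bound is deliberately wide because the Zic-type first
#' finger (ZF1) carries an expanded inter-cysteine spacer.
#'
#' @param cc_min,cc_max Residues strictly between the two cysteines
#'   (default 2..25).
#' @param ch_min,ch_max Residues strictly between Cys2 and His1
#'   (default 9..16).
#' @param hh_min,hh_max Residues strictly between the two histidines
#'   (default 3..6).
#' @param max_linker Maximum number of residues between the last histidine
#'   of one finger and the first cysteine of the next for the fingers to
#'   count as tandem (default 15).
#' @param zf1_threshold Minimum ZF1 inter-cysteine spacer for the zic
#'   diagnostic (default 8; canonical fingers run 2--4, zic-type are
#'   expanded).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(cc_min = 2L, cc_max = 25L,
                        ch_min = 9L, ch_max = 16L,
                        hh_min = 3L, hh_max = 6L,
                        max_linker = 15L, zf1_threshold = 8L) {
  p <- list(cc_min = as.integer(cc_min), cc_max = as.integer(cc_max),
            ch_min = as.integer(ch_min), ch_max = as.integer(ch_max),
            hh_min = as.integer(hh_min), hh_max = as.integer(hh_max),
            max_linker = as.integer(max_linker),
            zf1_threshold = as.integer(zf1_threshold))
  stopifnot(p$cc_min >= 0, p$cc_min <= p$cc_max,
            p$ch_min >= 0, p$ch_min <= p$ch_max,
            p$hh_min >= 0, p$hh_min <= p$hh_max,
            p$max_linker >= 0)
  structure(p, class = "scan_params")
}

#' Find candidate C2H2 zinc-finger hits
#'
#' Reports every position quadruple (Cys1, Cys2, His1, His2) satisfying the
#' configured spacing bounds, left-to-right by Cys1 then Cys2 then His1 then
#' His2. Overlapping candidates are all reported; chain resolution happens
#' in [assemble_architecture()]. Positions are 1-based.
#'
#' @param record A [protein_record()] (or a plain sequence string).
#' @param params A [scan_params()] object.
#' @return A data.frame with columns `c1`, `c2`, `h1`, `h2`, `spacer_cc`,
#'   `spacer_hh` (one row per candidate; zero rows if none).
#' @export
find_c2h2_hits <- function(record, params = scan_params()) {
  seq <- if (inherits(record, "protein_record")) record$sequence else record
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cpos <- which(chars == "C")
  hpos <- which(chars == "H")
  out <- list()
  k <- 0L
  for (c1 in cpos) {
    c2s <- cpos[cpos - c1 - 1L >= params$cc_min &
                cpos - c1 - 1L <= params$cc_max]
    for (c2 in c2s) {
      h1s <- hpos[hpos - c2 - 1L >= params$ch_min &
                  hpos - c2 - 1L <= params$ch_max]
      for (h1 in h1s) {
        h2s <- hpos[hpos - h1 - 1L >= params$hh_min &
                    hpos - h1 - 1L <= params$hh_max]
        for (h2 in h2s) {
          k <- k + 1L
          out[[k]] <- c(c1, c2, h1, h2)
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(c1 = integer(), c2 = integer(), h1 = integer(),
                      h2 = integer(), spacer_cc = integer(),
                      spacer_hh = integer()))
  }
  m <- do.call(rbind, out)
  hits <- data.frame(c1 = m[, 1], c2 = m[, 2], h1 = m[, 3], h2 = m[, 4])
  hits$spacer_cc <- hits$c2 - hits$c1 - 1L
  hits$spacer_hh <- hits$h2 - hits$h1 - 1L
  hits[order(hits$c1, hits$c2, hits$h1, hits$h2), , drop = FALSE]
}

# Best chain of `n` non-overlapping hits (each hit spans c1..h2) with all
# inter-hit linkers in [0, max_linker]. Score: minimal total span
# (last h2 - first c1), ties broken by leftmost start, then (equivalently)
# shortest span. Dynamic programme over hits sorted by end position.
best_chain <- function(hits, n, max_linker) {
  m <- nrow(hits)
  if (m < n) return(NULL)
  ord <- order(hits$h2, hits$c1)
  hits <- hits[ord, , drop = FALSE]
  # dp[[k]][[j]]: best (span, start, chain) for a k-chain ending at hit j
  NOCH <- list(span = Inf, start = Inf, chain = integer())
  dp <- vector("list", n)
  for (k in seq_len(n)) dp[[k]] <- rep(list(NOCH), m)
  for (j in seq_len(m))
    dp[[1]][[j]] <- list(span = hits$h2[j] - hits$c1[j] + 1L,
                         start = hits$c1[j], chain = j)
  better <- function(a, b) {
    if (a$span != b$span) return(a$span < b$span)
    a$start < b$start
  }
  if (n > 1L) {
    for (k in 2:n) {
      for (j in seq_len(m)) {
        best <- NOCH
        for (i in seq_len(m)) {
          prev <- dp[[k - 1L]][[i]]
          if (!is.finite(prev$span)) next
          gap <- hits$c1[j] - hits$h2[i] - 1L
          if (gap < 0L || gap > max_linker) next
          cand <- list(span = hits$h2[j] - prev$start + 1L,
                       start = prev$start,
                       chain = c(prev$chain, j))
          if (better(cand, best)) best <- cand
        }
        dp[[k]][[j]] <- best
      }
    }
  }
  best <- NOCH
  for (j in seq_len(m)) if (better(dp[[n]][[j]], best)) best <- dp[[n]][[j]]
  if (!is.finite(best$span)) return(NULL)
  hits[best$chain, , drop = FALSE]
}

#' Assemble a tandem five-finger architecture from candidate hits
#'
#' Selects the chain of exactly five non-overlapping C2H2 hits, in sequence
#' order with every inter-finger linker at most `params$max_linker`, that
#' minimises the total span (first Cys1 to last His2); ties are broken by
#' leftmost start. Returns `NULL` when no such chain exists, unless
#' `partial = TRUE`, in which case the best four-finger chain is returned
#' flagged as partial (some superfamily members are classifiable from
#' fingers 2--5 alone when the first finger cannot be recovered).
#'
#' @param hits Candidate hits from [find_c2h2_hits()].
#' @param params A [scan_params()] object.
#' @param partial Allow a flagged 4-finger fallback (default `FALSE`).
#' @return An object of class `zf_architecture` (list with `hits` data.frame,
#'   `linkers`, `zf1_spacing`, `partial`), or `NULL`.
#' @export
assemble_architecture <- function(hits, params = scan_params(),
                                  partial = FALSE) {
  chain <- best_chain(hits, 5L, params$max_linker)
  is_partial <- FALSE
  if (is.null(chain) && isTRUE(partial)) {
    chain <- best_chain(hits, 4L, params$max_linker)
    is_partial <- !is.null(chain)
  }
  if (is.null(chain)) return(NULL)
  rownames(chain) <- NULL
  chain$index <- seq_len(nrow(chain))
  linkers <- if (nrow(chain) > 1L)
    chain$c1[-1L] - chain$h2[-nrow(chain)] - 1L else integer()
  structure(list(hits = chain, linkers = linkers,
                 zf1_spacing = if (is_partial) NA_integer_
                               else chain$spacer_cc[1L],
                 partial = is_partial),
            class = "zf_architecture")
}

#' @export
print.zf_architecture <- function(x, ...) {
  cat(sprintf("<zf_architecture> %d finger(s)%s, zf1 spacing %s\n",
              nrow(x$hits), if (x$partial) " [partial]" else "",
              ifelse(is.na(x$zf1_spacing), "NA", x$zf1_spacing)))
  print(x$hits, ...)
  invisible(x)
}

#' ZF1 inter-cysteine spacing diagnostic for the Zic sub-family
#'
#' Zic-type first fingers carry an expanded spacer between the two
#' coordinating cysteines; canonical Gli/Glis/Nkl-type fingers run 2--4
#' residues. Returns `TRUE` when the architecture's ZF1 spacing meets the
#' threshold. `NA` for partial architectures lacking ZF1.
#'
#' @param arch A `zf_architecture`.
#' @param threshold Minimum spacer length to call zic-like (default 8).
#' @return Logical scalar (or `NA` for partial architectures).
#' @export
zf1_spacing_diagnostic <- function(arch, threshold = 8L) {
  stopifnot(inherits(arch, "zf_architecture"))
  if (is.na(arch$zf1_spacing)) return(NA)
  arch$zf1_spacing >= threshold
}

#' Trim a sequence to its five-finger region
#'
#' Returns the subsequence from the first cysteine of ZF1 through the last
#' histidine of ZF5, inclusive — the region used for distance computation
#' and tree building.
#'
#' @param record A [protein_record()] (or sequence string).
#' @param arch A complete (non-partial) `zf_architecture`.
#' @return Character scalar subsequence.
#' @export
trim_zf_region <- function(record, arch) {
  stopifnot(inherits(arch, "zf_architecture"))
  seq <- if (inherits(record, "protein_record")) record$sequence else record
  substr(seq, arch$hits$c1[1L], arch$hits$h2[nrow(arch$hits)])
}

#' Trim a sequence to its N-terminal region
#'
#' Returns the prefix ending two residues after the first cysteine of ZF1
#' (the prefix of length Cys1 position + 2 in 1-based coordinates) — the
#' region scanned for ZOC and ZF-NC motifs. If the cysteine sits within the
#' first residues so that the full prefix is unavailable, the whole
#' available prefix is returned with a warning.
#'
#' @param record A [protein_record()] (or sequence string).
#' @param arch A `zf_architecture`.
#' @return Character scalar prefix.
#' @export
trim_nterm_region <- function(record, arch) {
  stopifnot(inherits(arch, "zf_architecture"))
  seq <- if (inherits(record, "protein_record")) record$sequence else record
  end <- arch$hits$c1[1L] + 2L
  if (end > nchar(seq)) {
    warning("sequence ends before two residues past ZF1 Cys1; ",
            "returning available prefix")
    end <- nchar(seq)
  }
  substr(seq, 1L, end)
}

#' Tabulate architectures for a set of records
#'
#' Runs the scanner and chain assembly over a list of records and returns
#' the architecture report: per-finger coordinates, spacer list, ZF1
#' spacing and partial flag.
#'
#' @param records List of [protein_record()] objects.
#' @param params A [scan_params()] object.
#' @param partial Allow flagged 4-finger architectures.
#' @return A data.frame with one row per record.
#' @export
architecture_report <- function(records, params = scan_params(),
                                partial = TRUE) {
  rows <- lapply(records, function(rec) {
    arch <- assemble_architecture(find_c2h2_hits(rec, params), params,
                                  partial = partial)
    if (is.null(arch)) {
      data.frame(id = rec$id, n_zf = 0L, partial = NA,
                 zf1_spacing = NA_integer_, zic_spacing = NA,
                 positions = "", spacers_cc = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = rec$id, n_zf = nrow(arch$hits), partial = arch$partial,
                 zf1_spacing = arch$zf1_spacing,
                 zic_spacing = zf1_spacing_diagnostic(arch,
                                                      params$zf1_threshold),
                 positions = paste(sprintf("%d-%d", arch$hits$c1,
                                           arch$hits$h2), collapse = ";"),
                 spacers_cc = paste(arch$hits$spacer_cc, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
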