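# Filler alphabet excludes C and H so that planted coordinating residues
# are the only scanner-visible anchors at mutation rate 0; mutations may
# still introduce C/H.
FILLER_AA <- setdiff(AA20, c("C", "H"))

#' Parameters for the synthetic superfamily-protein generator
#'
#' The generator emulates gli/glis/nkl/zic-superfamily proteins: five
#' tandem C2H2 fingers, a subfamily-dependent ZF1 inter-cysteine spacer
#' (expanded in zic), optional exact-consensus ZOC and ZF-NC instances
#' N-terminal to ZF1 (zic only), background tails, and residue-wise
#' point-mutation noise. The four coordinating residues of each finger are
#' never mutated, so planted architectures remain the ground truth.
#'
#' @param zf1_spacer Named list of candidate ZF1 inter-cysteine spacer
#'   lengths per subfamily; defaults: zic 10--14, gli/glis/nkl 2--4.
#' @param cc,ch,hh Internal geometry of fingers 2--5 (and the non-ZF1
#'   gaps of ZF1): residues between Cys--Cys, Cys2--His1 and His--His.
#' @param linker Inter-finger linker length (fixed per protein).
#' @param zoc_prob,zfnc_prob Probability a zic protein carries an
#'   exact-consensus ZOC / ZF-NC instance.
#' @param ntail_range,ctail_range N-/C-terminal background tail lengths
#'   (uniform integer ranges).
#' @param mu Per-residue point-mutation rate in `[0, 1)`.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(zf1_spacer = list(zic = 10:14, gli = 2:4,
                                               glis = 2:4, nkl = 2:4),
                             cc = 2L, ch = 12L, hh = 3L, linker = 10L,
                             zoc_prob = 0.9, zfnc_prob = 0.9,
                             ntail_range = c(25L, 45L),
                             ctail_range = c(10L, 30L),
                             mu = 0) {
  stopifnot(mu >= 0, mu < 1, zoc_prob >= 0, zoc_prob <= 1,
            zfnc_prob >= 0, zfnc_prob <= 1)
  structure(list(zf1_spacer = zf1_spacer, cc = as.integer(cc),
                 ch = as.integer(ch), hh = as.integer(hh),
                 linker = as.integer(linker), zoc_prob = zoc_prob,
                 zfnc_prob = zfnc_prob,
                 ntail_range = as.integer(ntail_range),
                 ctail_range = as.integer(ctail_range), mu = mu),
            class = "generator_params")
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

filler <- function(n) {
  if (n <= 0L) return("")
  paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")
}

label_seed <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) * 7919L
}

# Deterministic per-subfamily residue template for the five-finger core.
# Fillers are drawn once per label from a label-derived seed, so members of
# one subfamily share a core and p-distance placement has a stable signal.
# The ZF1 spacer filler is generated at the maximum length and truncated to
# the requested spacer so cores with different ZF1 spacings stay aligned
# downstream.
subfamily_core_pool <- function(label, params) {
  with_local_seed(label_seed(label), {
    max_zf1 <- max(params$zf1_spacer[[label]])
    list(zf1_cc = filler(max_zf1),
         cc = replicate(4L, filler(params$cc)),
         ch = replicate(5L, filler(params$ch)),
         hh = replicate(5L, filler(params$hh)),
         linkers = replicate(4L, filler(params$linker)))
  })
}

# Assemble the 5-finger core for one protein; returns sequence and the
# finger coordinates relative to the core start (1-based).
build_core <- function(label, zf1_len, params) {
  pool <- subfamily_core_pool(label, params)
  seq <- ""
  hits <- data.frame(c1 = integer(5), c2 = integer(5), h1 = integer(5),
                     h2 = integer(5))
  pos <- 0L
  for (i in 1:5) {
    cc_fill <- if (i == 1L) substr(pool$zf1_cc, 1L, zf1_len)
               else pool$cc[i - 1L]
    unit <- paste0("C", cc_fill, "C", pool$ch[i], "H", pool$hh[i], "H")
    hits$c1[i] <- pos + 1L
    hits$c2[i] <- pos + 1L + nchar(cc_fill) + 1L
    hits$h1[i] <- hits$c2[i] + params$ch + 1L
    hits$h2[i] <- hits$h1[i] + params$hh + 1L
    seq <- paste0(seq, unit)
    pos <- pos + nchar(unit)
    if (i < 5L) {
      seq <- paste0(seq, pool$linkers[i])
      pos <- pos + params$linker
    }
  }
  list(seq = seq, hits = hits)
}

zoc_instance <- function() {
  spacer <- sample(1:2, 1L)
  paste0("RDFL", filler(spacer), "RR")
}

zfnc_instance <- function() {
  spacer <- sample(0:7, 1L)
  paste0("GAF", sample(c("F", "L"), 1L), "RYMRQP", filler(spacer), "IKQE")
}

#' Generate one synthetic superfamily protein with ground truth
#'
#' Uses the session RNG stream (seed it, or use [make_dataset()] which
#' seeds for you).
#'
#' @param label Subfamily label: `"zic"`, `"gli"`, `"glis"` or `"nkl"`.
#' @param params A [generator_params()] object.
#' @param id Record identifier.
#' @return List with `record` (a [protein_record()]) and `truth` (list:
#'   label, zf1_spacer, finger coordinates, planted motif coordinates,
#'   mutation bookkeeping).
#' @export
make_protein <- function(label, params = generator_params(),
                         id = paste0(label, "_1")) {
  stopifnot(label %in% c("zic", "gli", "glis", "nkl"))
  zf1_len <- if (length(params$zf1_spacer[[label]]) == 1L)
    params$zf1_spacer[[label]] else sample(params$zf1_spacer[[label]], 1L)
  core <- build_core(label, zf1_len, params)
  ntail <- sample(params$ntail_range[1]:params$ntail_range[2], 1L)
  ctail <- sample(params$ctail_range[1]:params$ctail_range[2], 1L)

  zoc <- zfnc <- NULL
  if (label == "zic") {
    if (stats::runif(1) < params$zoc_prob) zoc <- zoc_instance()
    if (stats::runif(1) < params$zfnc_prob) zfnc <- zfnc_instance()
  }
  pre <- filler(ntail)
  zoc_pos <- zfnc_pos <- c(NA_integer_, NA_integer_)
  if (!is.null(zoc)) {
    zoc_pos <- c(nchar(pre) + 1L, nchar(pre) + nchar(zoc))
    pre <- paste0(pre, zoc, filler(sample(2:10, 1L)))
  }
  if (!is.null(zfnc)) {
    zfnc_pos <- c(nchar(pre) + 1L, nchar(pre) + nchar(zfnc))
    pre <- paste0(pre, zfnc, filler(sample(3:10, 1L)))
  }
  offset <- nchar(pre)
  seq <- paste0(pre, core$seq, filler(ctail))
  hits <- core$hits
  for (col in c("c1", "c2", "h1", "h2")) hits[[col]] <- hits[[col]] + offset

  # Point mutations, sparing the 20 coordinating residues. The per-residue
  # uniform and the substitution index are drawn for every eligible residue
  # whatever mu is (common random numbers): datasets generated from one
  # seed at different mutation rates are then identical except that their
  # mutation sets are strictly nested, so degradation with mu is monotone
  # by construction rather than up to sampling noise.
  protected <- unlist(hits[, c("c1", "c2", "h1", "h2")])
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  eligible <- setdiff(seq_along(chars), protected)
  u <- stats::runif(length(eligible))
  sub_idx <- sample.int(19L, length(eligible), replace = TRUE)
  mutated <- which(u < params$mu)
  for (k in mutated) {
    i <- eligible[k]
    chars[i] <- setdiff(AA20, chars[i])[sub_idx[k]]
  }
  n_mut <- length(mutated)
  if (n_mut) seq <- paste(chars, collapse = "")
  list(record = protein_record(id, seq, species = "synthetic"),
       truth = list(label = label, zf1_spacer = zf1_len, hits = hits,
                    zoc_start = zoc_pos[1], zoc_end = zoc_pos[2],
                    zfnc_start = zfnc_pos[1], zfnc_end = zfnc_pos[2],
                    n_mutated = n_mut, n_eligible = length(eligible)))
}

#' Generate a labelled synthetic dataset
#'
#' Reproducible given `seed`. Labels are drawn from `mix` (a named
#' probability vector). Optionally writes a FASTA file and a ground-truth
#' TSV (label, ZF1 spacer, finger and motif coordinates per record).
#'
#' @param n Number of proteins (>= 1).
#' @param mix Named label probabilities, e.g.
#'   `c(zic = .25, gli = .25, glis = .25, nkl = .25)`.
#' @param params A [generator_params()] object.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param fasta,truth_tsv Optional output paths.
#' @return List with `records` (list of [protein_record()]) and `truth`
#'   (data.frame).
#' @export
make_dataset <- function(n, mix = c(zic = .25, gli = .25, glis = .25,
                                    nkl = .25),
                         params = generator_params(), seed,
                         fasta = NULL, truth_tsv = NULL) {
  stopifnot(n >= 1L, !missing(seed), abs(sum(mix) - 1) < 1e-8)
  set.seed(seed)
  labels <- sample(names(mix), n, replace = TRUE, prob = mix)
  records <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    mp <- make_protein(labels[i], params,
                       id = sprintf("%s_%04d", labels[i], i))
    records[[i]] <- mp$record
    tr <- mp$truth
    rows[[i]] <- data.frame(
      id = mp$record$id, label = tr$label, zf1_spacer = tr$zf1_spacer,
      zf_positions = paste(sprintf("%d,%d,%d,%d", tr$hits$c1, tr$hits$c2,
                                   tr$hits$h1, tr$hits$h2),
                           collapse = ";"),
      zoc_start = tr$zoc_start, zoc_end = tr$zoc_end,
      zfnc_start = tr$zfnc_start, zfnc_end = tr$zfnc_end,
      n_mutated = tr$n_mutated, n_eligible = tr$n_eligible,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  if (!is.null(fasta)) write_fasta(records, fasta)
  if (!is.null(truth_tsv))
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(records = records, truth = truth)
}

#' Generate a labelled synthetic reference panel
#'
#' A small panel of lightly mutated proteins per subfamily, used by
#' [place_query()] to refine `gli/glis/nkl-like` calls. The panel is
#' synthetic: its members instantiate the generator's subfamily templates,
#' not real accessions.
#'
#' @param per Members per subfamily (default 4).
#' @param mu Panel mutation rate (default 0.01).
#' @param seed Integer seed.
#' @param params A [generator_params()] object (its `mu` is overridden).
#' @return A [reference_panel()].
#' @export
make_panel <- function(per = 4L, mu = 0.01, seed = 20260101L,
                       params = generator_params()) {
  params$mu <- mu
  params$zoc_prob <- 1; params$zfnc_prob <- 1
  set.seed(seed)
  labels <- rep(c("zic", "gli", "glis", "nkl"), each = per)
  records <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    records[[i]] <- make_protein(labels[i], params,
                                 id = sprintf("panel_%s_%d", labels[i],
                                              i))$record
  }
  reference_panel(records, labels)
}
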