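test_that("find_c2h2_hits detects a constructed C2H2 motif", {
  hits <- find_c2h2_hits("AACAACAAAAAAAAAAAAHAAAHAA")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$spacer_cc, 2L)
  expect_equal(hits$spacer_hh, 3L)
  expect_equal(find_c2h2_hits(strrep("A", 60)) |> nrow(), 0L)
})

test_that("expanded ZF1 spacing is found only when the bounds allow it", {
  # zic-style first finger: 12 residues between the cysteines
  seq <- paste0("C", strrep("A", 12), "C", strrep("A", 12), "H",
                strrep("A", 3), "H")
  wide <- find_c2h2_hits(seq, scan_params())
  expect_equal(nrow(wide), 1L)
  expect_equal(wide$spacer_cc, 12L)
  narrow <- find_c2h2_hits(seq, scan_params(cc_max = 8))
  expect_equal(nrow(narrow), 0L)
})

test_that("scanner equals the cross-product enumeration oracle", {
  set.seed(101)
  params <- scan_params()
  for (i in 1:60) {
    # C/H-enriched so hits actually occur
    seq <- random_aa(sample(20:60, 1),
                     alphabet = c(AA20_T, rep(c("C", "H"), 6)))
    got <- find_c2h2_hits(seq, params)
    want <- oracle_c2h2(seq, params)
    expect_equal(got[, c("c1", "c2", "h1", "h2")], want,
                 ignore_attr = TRUE)
  }
})

test_that("assemble_architecture finds the five-finger chain", {
  unit <- paste0("C", strrep("A", 2), "C", strrep("A", 12), "H",
                 strrep("A", 3), "H")
  five <- paste0(strrep("G", 8), paste(rep(unit, 5), collapse = strrep("G", 7)),
                 strrep("G", 5))
  arch <- assemble_architecture(find_c2h2_hits(five), scan_params())
  expect_s3_class(arch, "zf_architecture")
  expect_equal(nrow(arch$hits), 5L)
  expect_false(arch$partial)
  expect_true(all(arch$linkers == 7L))
  expect_equal(arch$zf1_spacing, 2L)

  four <- paste(rep(unit, 4), collapse = strrep("G", 7))
  expect_null(assemble_architecture(find_c2h2_hits(four), scan_params()))
  p <- assemble_architecture(find_c2h2_hits(four), scan_params(),
                             partial = TRUE)
  expect_equal(nrow(p$hits), 4L)
  expect_true(p$partial)
  expect_true(is.na(p$zf1_spacing))
})

test_that("assembled chain is optimal against the exhaustive subset oracle", {
  set.seed(202)
  params <- scan_params()
  checked <- 0L
  while (checked < 25L) {
    seq <- random_aa(sample(120:260, 1),
                     alphabet = c(AA20_T, rep(c("C", "H"), 5)))
    hits <- find_c2h2_hits(seq, params)
    if (nrow(hits) < 5L || nrow(hits) > 12L) next
    arch <- assemble_architecture(hits, params)
    want <- oracle_chain_score(hits, 5L, params$max_linker)
    if (is.null(want)) {
      expect_null(arch)
    } else {
      span <- arch$hits$h2[5] - arch$hits$c1[1] + 1L
      expect_equal(c(span, arch$hits$c1[1]), unname(want))
      # reported chain is a valid tandem chain
      expect_true(all(diff(arch$hits$c1) > 0))
      gaps <- arch$hits$c1[-1] - arch$hits$h2[-5] - 1L
      expect_true(all(gaps >= 0L & gaps <= params$max_linker))
    }
    checked <- checked + 1L
  }
})

test_that("zf1 spacing diagnostic separates zic-like from canonical", {
  arch4 <- list(zf1_spacing = 4L); class(arch4) <- "zf_architecture"
  arch12 <- list(zf1_spacing = 12L); class(arch12) <- "zf_architecture"
  expect_false(zf1_spacing_diagnostic(arch4, 8L))
  expect_true(zf1_spacing_diagnostic(arch12, 8L))

  set.seed(7)
  ds <- make_dataset(40, params = generator_params(mu = 0), seed = 77)
  for (i in seq_len(40)) {
    arch <- assemble_architecture(find_c2h2_hits(ds$records[[i]]),
                                  scan_params())
    expect_equal(zf1_spacing_diagnostic(arch, 8L),
                 ds$truth$label[i] == "zic")
  }
})

test_that("trim_zf_region spans first Cys of ZF1 to last His of ZF5", {
  set.seed(11)
  mp <- make_protein("gli", generator_params(mu = 0))
  arch <- assemble_architecture(find_c2h2_hits(mp$record), scan_params())
  trimmed <- trim_zf_region(mp$record, arch)
  expect_equal(substr(trimmed, 1, 1), "C")
  expect_equal(substr(trimmed, nchar(trimmed), nchar(trimmed)), "H")
  expect_equal(nchar(trimmed),
               arch$hits$h2[5] - arch$hits$c1[1] + 1L)
  # idempotent: trimming the trimmed sequence returns itself
  arch2 <- assemble_architecture(find_c2h2_hits(trimmed), scan_params())
  expect_equal(trim_zf_region(trimmed, arch2), trimmed)
})

test_that("trim_nterm_region keeps the prefix through Cys1 + 2 residues", {
  # Cys at position 5 (1-based): prefix length 7 = whole string
  arch <- list(hits = data.frame(c1 = 5L)); class(arch) <- "zf_architecture"
  expect_equal(trim_nterm_region("MNPMCQR", arch), "MNPMCQR")

  arch1 <- list(hits = data.frame(c1 = 1L)); class(arch1) <- "zf_architecture"
  expect_equal(trim_nterm_region("CQRSTV", arch1), "CQR")

  # degenerate: sequence ends before Cys1 + 2
  archend <- list(hits = data.frame(c1 = 6L))
  class(archend) <- "zf_architecture"
  expect_warning(p <- trim_nterm_region("AAAAAC", archend), "prefix")
  expect_equal(p, "AAAAAC")

  # concatenation: prefix plus remainder reconstitutes the input
  seq <- "MNPMCQRSTVW"
  pre <- trim_nterm_region(seq, arch)
  expect_equal(paste0(pre, substr(seq, nchar(pre) + 1L, nchar(seq))), seq)
})

test_that("noise-free generator proteins are recovered exactly", {
  ds <- make_dataset(30, params = generator_params(mu = 0), seed = 9)
  for (i in seq_len(30)) {
    arch <- assemble_architecture(find_c2h2_hits(ds$records[[i]]),
                                  scan_params())
    expect_equal(nrow(arch$hits), 5L)
    expect_equal(arch$zf1_spacing, ds$truth$zf1_spacer[i])
    want <- paste(sprintf("%d-%d",
                          as.integer(sub(",.*", "",
                                         strsplit(ds$truth$zf_positions[i],
                                                  ";")[[1]])),
                          as.integer(sub(".*,", "",
                                         strsplit(ds$truth$zf_positions[i],
                                                  ";")[[1]]))),
                  collapse = ";")
    got <- paste(sprintf("%d-%d", arch$hits$c1, arch$hits$h2),
                 collapse = ";")
    expect_equal(got, want)
  }
})
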