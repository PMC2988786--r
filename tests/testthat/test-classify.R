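test_that("rule_classify assigns zic from expanded ZF1 plus motifs", {
  set.seed(601)
  p <- generator_params(mu = 0, zoc_prob = 1, zfnc_prob = 1)
  rec <- make_protein("zic", p, id = "z1")$record
  call <- rule_classify(rec)
  expect_equal(call$label, "zic")
  passed <- call$evidence$passed
  names(passed) <- call$evidence$criterion
  expect_true(passed[["zf1_spacing>=8"]])
  expect_true(passed[["zoc_motif"]])
  expect_true(passed[["zfnc_motif"]])
})

test_that("rule_classify: canonical architecture without zic evidence", {
  set.seed(602)
  rec <- make_protein("gli", generator_params(mu = 0), id = "g1")$record
  call <- rule_classify(rec)
  expect_equal(call$label, "gli/glis/nkl-like")
  expect_false(call$partial)

  # no architecture at all
  none <- rule_classify(protein_record("bg", random_aa(120)))
  expect_equal(none$label, "non-family")
  expect_equal(nrow(none$evidence), 1L)
})

test_that("partial four-finger architecture with motifs is zic (flagged)", {
  set.seed(603)
  p <- generator_params(mu = 0, zoc_prob = 1, zfnc_prob = 1)
  mp <- make_protein("zic", p, id = "z2")
  seq <- mp$record$sequence
  h <- mp$truth$hits
  # excise ZF1 (Cys1..His2): four fingers and the N-terminal motifs remain
  seq4 <- paste0(substr(seq, 1, h$c1[1] - 1L),
                 substr(seq, h$h2[1] + 1L, nchar(seq)))
  call <- rule_classify(protein_record("z2_4zf", seq4))
  expect_equal(call$label, "zic")
  expect_true(call$partial)
})

test_that("zic calls always carry at least one passed zic criterion", {
  ds <- make_dataset(60, params = generator_params(mu = 0.05), seed = 604)
  for (rec in ds$records) {
    call <- rule_classify(rec)
    if (call$label == "zic") {
      zic_ev <- call$evidence[grepl("zf1_spacing|zoc|zfnc",
                                    call$evidence$criterion), ]
      expect_true(any(zic_ev$passed))
    }
  }
})

test_that("pairwise p-distance: bounds, symmetry, sliding alignment", {
  expect_equal(pairwise_distance("CKHH", "CKHH"), 0)
  expect_equal(pairwise_distance("AAAA", "VVVV"), 1)
  # shorter slides along longer: exact substring gives 0
  expect_equal(pairwise_distance("KLM", "AAKLMAA"), 0)
  set.seed(605)
  for (i in 1:25) {
    a <- random_aa(sample(5:60, 1)); b <- random_aa(sample(5:60, 1))
    d1 <- pairwise_distance(a, b); d2 <- pairwise_distance(b, a)
    expect_equal(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("neighbor joining recovers additive topologies", {
  set.seed(606)
  for (i in 1:10) {
    tr <- ape::rtree(sample(c(4L, 8L), 1))
    D <- ape::cophenetic.phylo(tr)
    nj1 <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj1)), 0,
                 ignore_attr = TRUE)
    # permuting taxon order leaves the topology invariant
    perm <- sample(nrow(D))
    nj2 <- nj_tree(D[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(nj1), ape::unroot(nj2)), 0,
                 ignore_attr = TRUE)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("place_query: exact member, generator queries, tie rule", {
  panel <- make_panel(per = 3, mu = 0.01, seed = 607)
  zic_member <- panel$trimmed[panel$label == "zic"][1]
  pl <- place_query(zic_member, panel)
  expect_equal(pl$label, "zic")
  expect_equal(pl$distance, 0)

  set.seed(608)
  for (lab in c("gli", "glis", "nkl")) {
    q <- make_protein(lab, generator_params(mu = 0.02), id = "q")$record
    arch <- assemble_architecture(find_c2h2_hits(q), scan_params())
    got <- place_query(trim_zf_region(q, arch), panel)
    expect_equal(got$label, lab)
  }

  tiny <- structure(data.frame(id = c("p1", "p2"),
                               label = c("gli", "glis"),
                               trimmed = c("CKHHA", "CKHHA"),
                               stringsAsFactors = FALSE),
                    class = c("reference_panel", "data.frame"))
  tie <- place_query("CKHHA", tiny)
  expect_true(tie$tie)
  expect_equal(tie$label, "gli")     # lexicographic fallback
  tie2 <- place_query("CKHHA", tiny, rule_label = "glis")
  expect_equal(tie2$label, "glis")   # compatible rule label wins
  expect_error(place_query("CKHH", tiny[0, ]), "empty")
})

test_that("classification labels survive noise, monotonically in mu", {
  panel <- make_panel(seed = 609)
  acc <- vapply(c(0, 0.02, 0.1), function(mu) {
    ds <- make_dataset(80, params = generator_params(mu = mu), seed = 610)
    calls <- classify_records(ds$records, panel = panel)
    mean(calls$label == ds$truth$label)
  }, 0)
  expect_equal(acc[1], 1)
  expect_gte(acc[1], acc[2])
  expect_gte(acc[2], acc[3])
})

test_that("placement never overturns a rule-based zic call", {
  # panel deliberately lacking zic: zic queries keep their rule label
  set.seed(611)
  p <- generator_params(mu = 0)
  recs <- list(); labs <- character()
  for (lab in c("gli", "glis", "nkl")) for (i in 1:2) {
    recs <- c(recs, list(make_protein(lab, p,
                                      id = paste0(lab, i))$record))
    labs <- c(labs, lab)
  }
  panel <- reference_panel(recs, labs)
  zq <- make_protein("zic", p, id = "zq")$record
  calls <- classify_records(list(zq), panel = panel)
  expect_equal(calls$label, "zic")
})
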