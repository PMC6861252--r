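test_that("heterokaryotype models report their break counts, pathways and side products", {
  o4 <- apply_nhej4(het_st_12)
  o3 <- apply_nhej3(het_st_12)
  ob <- apply_bir_nhej(het_st_12)

  expect_identical(o4$n_breaks, 4L)
  expect_identical(o3$n_breaks, 3L)
  expect_identical(ob$n_breaks, 2L)
  expect_identical(o4$pathways, "NHEJ")
  expect_setequal(ob$pathways, c("BIR", "NHEJ"))

  # NHEJ-4: reciprocal joint flagged non-surviving
  expect_true(length(o4$side_products) >= 1)
  expect_true(all(vapply(o4$side_products, function(s) isFALSE(s$surviving), logical(1))))

  # NHEJ-3: a standard chromosome lacking A_d and B_p (but keeping an A_p)
  sp3 <- o3$side_products[[1]]
  expect_false(any(sp3$fragments$name %in% c("A_d", "B_p")))
  expect_true("A_p" %in% sp3$fragments$name)
  expect_false(isTRUE(sp3$surviving))

  # BIR-NHEJ: the standard homolog survives untouched
  spb <- ob$side_products[[1]]
  expect_identical(spb$name, "E_st")
  expect_identical(fragment_signature(spb), fragment_signature(canon[["E_st"]]))
  expect_true(isTRUE(spb$surviving))
})

test_that("all heterokaryotype models derive the same fragment order with AK and GAL junctions", {
  outs <- list(apply_nhej4(het_st_12), apply_nhej3(het_st_12), apply_bir_nhej(het_st_12))
  sigs <- lapply(outs, function(o) fragment_signature(o$derived))
  expect_identical(sigs[[1]], sigs[[2]])
  expect_identical(sigs[[1]], sigs[[3]])
  expect_identical(sigs[[1]], fragment_signature(canon[["E_1+2+9"]]))
  for (o in outs) {
    rn <- region_names(o$derived)
    expect_true(all(c("AK", "GAL") %in% rn))
    expect_false("AG" %in% rn)
    expect_setequal(rn, region_names(canon[["E_1+2+9"]]))
    gal <- breakpoint_regions(o$derived)[["GAL"]]
    expect_identical(gal$fragments$name, c("G", "A_d", "L"))
  }
})

test_that("provenance of the A window discriminates the models as predicted", {
  o4 <- apply_nhej4(het_st_12)$derived$fragments
  o3 <- apply_nhej3(het_st_12)$derived$fragments
  ob <- apply_bir_nhej(het_st_12)$derived$fragments
  for (f in list(o4, o3, ob)) {
    # proximal copies captured/copied from the standard homolog
    expect_identical(f$provenance[f$name == "A_d"][1], "E_st")
    expect_identical(f$provenance[f$name == "B_p"][1], "E_st")
    # the duplicated GAL copy keeps the doubly inverted lineage
    expect_identical(f$provenance[f$name == "A_d"][2], "E_1+2")
  }
  # A_p provenance differs between pure-NHEJ capture and BIR copy-repair
  expect_identical(o4$provenance[o4$name == "A_p"], "E_st")
  expect_identical(ob$provenance[ob$name == "A_p"], "E_1+2")
  expect_true(ob$bir_copy[which(ob$name == "A_d")[1]])
  expect_true(ob$bir_copy[which(ob$name == "B_p")[1]])
  expect_false(any(o4$bir_copy))
})

test_that("fragment accounting balances for every model", {
  n_in <- nrow(canon[["E_st"]]$fragments) + nrow(canon[["E_1+2"]]$fragments)
  count_out <- function(o) {
    nrow(o$derived$fragments) +
      sum(vapply(o$side_products, function(s) nrow(s$fragments), integer(1)))
  }
  expect_identical(count_out(apply_nhej4(het_st_12)), n_in)
  expect_identical(count_out(apply_nhej3(het_st_12)), n_in)
  # BIR creates exactly one extra (A_d, B_p) copy pair
  expect_identical(count_out(apply_bir_nhej(het_st_12)), n_in + 2L)

  # isochromatid / chromatid duplicate exactly the staggered stretch (A_d)
  e12 <- canon[["E_1+2"]]
  iso <- apply_isochromatid(
    e12, list(chromatid_break(c("A_p", "A_d")), chromatid_break(c("A_d", "G"))),
    chromatid_break(c("K", "L")))
  expect_identical(nrow(iso$derived$fragments), nrow(e12$fragments) + 1L)
  expect_identical(sum(iso$derived$fragments$name == "A_d"), 2L)
  chr <- apply_chromatid(e12, list(chromatid_break(c("A_p", "A_d")),
                                   chromatid_break(c("A_d", "G")),
                                   chromatid_break(c("K", "L"))))
  expect_identical(fragment_signature(chr$derived), fragment_signature(iso$derived))
  expect_identical(chr$n_breaks, 4L)
  expect_identical(iso$n_breaks, 3L)
})

test_that("heterokaryotype models require a standard/doubly-inverted heterokaryotype", {
  homo <- karyotype(canon[["E_st"]], canon[["E_st"]])
  expect_error(apply_nhej4(homo), "heterokaryotypic")
  expect_error(apply_nhej3(homo), "heterokaryotypic")
  expect_error(apply_bir_nhej(homo), "heterokaryotypic")
  wrong <- karyotype(canon[["E_st"]], canon[["E_1+2+9"]])
  expect_error(apply_nhej4(wrong), "E_st/E_1\\+2")
})

test_that("cut-and-paste inverts without duplication and validates its breaks", {
  e12 <- canon[["E_1+2"]]
  b_prox <- break_spec("E_1+2", c("A_p", "A_d"))
  b_dist <- break_spec("E_1+2", c("K", "L"))
  out <- apply_cut_and_paste(e12, b_prox, b_dist)
  expect_identical(out$n_breaks, 2L)
  f <- out$derived$fragments
  expect_identical(sum(f$name == "A_d"), 1L)
  # no B_p capture: the proximal junction (A_p|K) matches no named region
  expect_warning(rn <- region_names(out$derived), "unknown junction A_p\\|K")
  expect_false("AK" %in% rn)
  expect_identical(sort(f$name), sort(e12$fragments$name))  # multiset conserved

  # identical breaks at the same boundary are rejected
  expect_error(apply_cut_and_paste(e12, b_prox, b_prox), "distinct boundaries")
  expect_error(apply_cut_and_paste(e12, break_spec("E_st", c("B_p", "B_d")), b_dist),
               "same homolog")
})

test_that("the inverse cut-and-paste restores fragment order", {
  e12 <- canon[["E_1+2"]]
  out <- apply_cut_and_paste(e12, break_spec("E_1+2", c("A_p", "A_d")),
                             break_spec("E_1+2", c("K", "L")))
  d <- out$derived; d$name <- "E_1+2"
  sig2 <- fragment_signature(d)
  i <- which(sig2 == "A_p") ; j <- which(sig2 == "L") - 1L
  restored <- invert_segment(d, i + 1L, j)
  expect_identical(fragment_signature(restored), fragment_signature(e12))
})

test_that("isochromatid staggering duplicates the stretch at both junctions", {
  e12 <- canon[["E_1+2"]]
  iso <- apply_isochromatid(
    e12, list(chromatid_break(c("A_p", "A_d")), chromatid_break(c("A_d", "G"))),
    chromatid_break(c("K", "L")))
  sig <- fragment_signature(iso$derived)
  expect_identical(sig[1:2], c("A_p", "A_d"))       # upright proximal copy
  expect_true("A_d-" %in% sig)                      # inverted distal copy
  f <- iso$derived$fragments
  expect_true(all(f$provenance[f$name == "A_d"] == "E_1+2"))
  # no captured B_p adjacent to the proximal A window
  expect_false("AK" %in% suppressWarnings(region_names(iso$derived)))

  # zero-width stagger degenerates to the cut-and-paste product
  iso0 <- apply_isochromatid(
    e12, list(chromatid_break(c("A_p", "A_d")), chromatid_break(c("A_p", "A_d"))),
    chromatid_break(c("K", "L")))
  cp <- apply_cut_and_paste(e12, break_spec("E_1+2", c("A_p", "A_d")),
                            break_spec("E_1+2", c("K", "L")))
  expect_identical(fragment_signature(iso0$derived), fragment_signature(cp$derived))

  # mis-ordered stagger and wrong scope flags are rejected
  expect_error(apply_isochromatid(
    e12, list(chromatid_break(c("A_d", "G")), chromatid_break(c("A_p", "A_d"))),
    chromatid_break(c("K", "L"))), "not nested/ordered")
  expect_error(apply_isochromatid(
    e12, list(break_spec("E_1+2", c("A_p", "A_d")), chromatid_break(c("A_d", "G"))),
    chromatid_break(c("K", "L"))), "chromatid scope")
  expect_error(apply_chromatid(e12, list(break_spec("E_1+2", c("A_p", "A_d")),
                                         chromatid_break(c("A_d", "G")),
                                         chromatid_break(c("K", "L")))),
               "chromatid scope")
})

test_that("clade constraints follow fragment provenance", {
  for (m in c("nhej4", "nhej3", "bir_nhej")) {
    cc <- predict_clade_constraints(m)
    focal <- lapply(cc, `[[`, "focal_regions")
    sister <- vapply(cc, `[[`, character(1), "predicted_sister")
    expect_setequal(focal[[1]], c("AK", "AH2"))
    expect_identical(sister[[1]], "AB")
    expect_identical(focal[[2]], "GAL")
    expect_identical(sister[[2]], "AG")
  }
  for (m in c("cut_and_paste", "isochromatid", "chromatid")) {
    cc <- predict_clade_constraints(m)
    expect_length(cc, 1L)
    expect_setequal(cc[[1]]$focal_regions, c("AK", "AH2", "GAL"))
    expect_identical(cc[[1]]$predicted_sister, "AG")
  }
  expect_error(predict_clade_constraints("foo"), "unknown origin model")
})
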