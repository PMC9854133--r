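test_that("the bundled snapshot loads with the five PIK3CA hotspots", {
  kb <- load_kb()
  hs <- kb[kb$alteration_kind == "variant_hotspot" & kb$gene == "PIK3CA", ]
  expect_equal(nrow(hs), 5)
  expect_setequal(hs$protein_change,
                  c("p.Asn345Lys", "p.Glu545Lys", "p.His1047Arg",
                    "p.His1047Leu", "p.Gly1049Arg"))
  expect_setequal(kb$gene[kb$alteration_kind == "germline_gene"],
                  c("BRCA1", "BRCA2", "PALB2"))
})

test_that("knowledge-base validation rejects duplicates and malformed entries", {
  kb <- load_kb()
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(rbind(kb, kb[1, ]), p, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  expect_error(load_kb(p), "duplicate", class = "oncopanel_schema_error")

  bad <- kb
  bad$protein_change[bad$alteration_kind == "variant_hotspot"][1] <- NA
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, p2, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  expect_error(load_kb(p2), class = "oncopanel_schema_error")
})

test_that("protein-change matching is case- and notation-invariant", {
  expect_equal(normalize_hgvs_p("p.His1047Arg"), normalize_hgvs_p("p.H1047R"))
  expect_equal(normalize_hgvs_p("p.(Lys662Ter)"), normalize_hgvs_p("p.K662*"))
  profs <- fixture_profiles()
  p3 <- profs$MBC03
  p3$drivers$hgvs_p[p3$drivers$gene == "PIK3CA"] <- "p.H1047R"
  p3$drivers$gene[p3$drivers$gene == "PIK3CA"] <- "pik3ca"
  findings <- annotate_sample(p3)
  expect_true(any(findings$alteration_kind == "variant_hotspot"))
})

test_that("findings cover hotspot, germline, TMB and MSI triggers in order", {
  profs <- fixture_profiles()
  # PIK3CA hotspot + TMB-high sample
  f3 <- profs$MBC03$findings
  expect_equal(nrow(f3), 2)
  expect_equal(f3$alteration_kind, c("variant_hotspot", "tmb_high"))
  expect_match(f3$therapy[1], "alpelisib")
  # germline carrier with LOH + TMB-high
  f1 <- profs$MBC01$findings
  expect_equal(f1$alteration_kind, c("germline_gene", "tmb_high"))
  expect_match(f1$trigger[1], "LOH")
  expect_match(f1$therapy[1], "PARP")
  # NO-LOH carriers still count as actionable
  f4 <- profs$MBC04$findings
  expect_equal(f4$alteration_kind, "germline_gene")
  expect_match(f4$trigger, "NO_LOH")
  # alteration-free sample
  expect_equal(nrow(profs$MBC06$findings), 0)
  # MSI-high only
  f8 <- profs$MBC08$findings
  expect_equal(f8$alteration_kind, "msi_high")
})

test_that("an empty knowledge base yields no findings anywhere", {
  kb <- load_kb()
  empty_kb <- kb[0, ]
  profs <- fixture_profiles()
  for (p in profs) {
    expect_equal(nrow(annotate_sample(p, empty_kb)), 0)
  }
})

test_that("exactly the eleven expected fixture samples are actionable", {
  profs <- fixture_profiles()
  actionable <- names(profs)[vapply(profs,
                                    function(p) nrow(p$findings) > 0, NA)]
  expect_length(actionable, 11)
  expect_setequal(actionable,
                  sprintf("MBC%02d", c(1, 2, 3, 4, 5, 7, 8, 10, 11, 12, 15)))
})
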