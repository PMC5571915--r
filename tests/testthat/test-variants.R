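# Variant parsing, numbering reconciliation, annotation and the census.

hs_line <- function(gene, acc, ftid, sub, cat, dbsnp = "-", phen = "-") {
  sprintf("%-9s %-10s %-11s %-14s %-13s %-10s %s",
          gene, acc, ftid, sub, cat, dbsnp, phen)
}

test_that("humsavar-dialect lines parse into typed records", {
  v <- parse_variant_table(hs_line("ELANE", "P08246", "VAR_000001",
                                   "p.Ile104Asn", "Disease", "-",
                                   "Cyclic haematopoiesis (CH) [MIM:162800]"))
  expect_equal(v$position, 104L)
  expect_equal(v$wt_aa, "I")
  expect_equal(v$mut_aa, "N")
  expect_equal(as.character(v$category), "DISEASE")
  expect_match(v$phenotype, "162800")
})

test_that("silent and malformed substitutions are rejected", {
  expect_warning(
    v <- parse_variant_table(hs_line("G1", "P1", "VAR_1", "p.Ala10Ala",
                                     "Disease")),
    "silent")
  expect_equal(nrow(v), 0)
  expect_error(parse_variant_table(hs_line("G1", "P1", "VAR_1", "p.Xxx10Ala",
                                           "Disease"), strict = TRUE),
               "unknown amino acid")
  # header and prose lines are ignored
  v2 <- parse_variant_table(c("Gene  AC  FTId  Change  Type",
                              hs_line("G1", "P1", "VAR_1", "p.Gly7Arg",
                                      "Polymorphism")))
  expect_equal(nrow(v2), 1)
})

test_that("category tokens map to the three classes", {
  lines <- c(hs_line("G1", "P1", "VAR_1", "p.Ala10Val", "Disease"),
             hs_line("G1", "P1", "VAR_2", "p.Ala11Val", "Disease"),
             hs_line("G1", "P1", "VAR_3", "p.Ala12Val", "Polymorphism"),
             hs_line("G1", "P1", "VAR_4", "p.Ala13Val", "Polymorphism"),
             hs_line("G1", "P1", "VAR_5", "p.Ala14Val", "Unclassified"),
             hs_line("G1", "P1", "VAR_6", "p.Ala15Val", "Unclassified"))
  v <- parse_variant_table(lines)
  expect_equal(nrow(v), 6)
  expect_equal(as.vector(table(v$category)), c(2, 2, 2))
  # modern vocabulary behind the flag
  vm <- parse_variant_table(hs_line("G1", "P1", "VAR_7", "p.Ala16Val",
                                    "LP/P"), modern_categories = TRUE)
  expect_equal(as.character(vm$category), "DISEASE")
})

# sequence helpers for the numbering map tests
seq30 <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLI"
structure_for <- function(seq_, resno) {
  aa1 <- strsplit(seq_, "")[[1]]
  three <- vapply(aa1, function(a) {
    names(which(c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y",
                  VAL = "V") == a))
  }, character(1))
  structure_model(tibble::tibble(
    chain = "A", resno = resno, resname = three, atom = "CA",
    element = "C", x = seq_along(resno) * 3.8, y = 0, z = 0))
}

test_that("matching numbering yields the identity map", {
  st <- structure_for(seq30, 1:30)
  map <- build_numbering_map(seq30, st)
  expect_equal(map$position, 1:30)
  expect_equal(map$res_key, paste0("A:", 1:30))
  expect_equal(attr(map, "identity"), 1)
})

test_that("shifted author numbering is reconciled by alignment", {
  st <- structure_for(seq30, 25:54) # +24 expression-tag shift
  map <- build_numbering_map(seq30, st)
  expect_equal(map$res_key, paste0("A:", map$position + 24))
  # round-trip: mapping back from res_key recovers the position
  back <- as.integer(sub("A:", "", map$res_key)) - 24L
  expect_equal(back, map$position)
})

test_that("an unrelated sequence is rejected below the identity floor", {
  st <- structure_for(seq30, 1:30)
  other <- paste(rep("W", 40), collapse = "")
  expect_error(build_numbering_map(other, st), "identity")
})

test_that("annotation combines structure and docking evidence", {
  st <- structure_for(seq30, 1:30)
  map <- build_numbering_map(seq30, st)
  labels <- tibble::tibble(
    res_key = paste0("A:", 1:30), chain = "A", resno = 1:30, ins = "",
    resname = "ALA", asa = 50, rasa = rep(c(0.5, 0.05), 15),
    label = c("INTERFACE", rep("NON_INTERFACE_SURFACE", 9),
              rep("CORE", 10), rep("NON_INTERFACE_SURFACE", 10)))
  labels$label[seq(2, 30, 2)] <- "CORE"
  labels$label[1] <- "INTERFACE"
  labels$label[3] <- "NON_INTERFACE_SURFACE"
  prof <- structure(tibble::tibble(
    res_key = paste0("A:", 1:30), chain = "A", resno = 1:30, ins = "",
    resname = "ALA", asa_unbound = 50, rasa = rep(c(0.5, 0.05), 15),
    abs = 0, nip = c(0.9, rep(0, 2), 0.5, rep(0, 26)),
    hotspot = c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 26)),
    extended_interface = c(TRUE, FALSE, TRUE, TRUE, rep(FALSE, 26))),
    class = c("nip_profile", class(tibble::tibble())))
  aa1 <- strsplit(seq30, "")[[1]]
  vars <- tibble::tibble(
    gene = "G", accession = "P1", ftid = paste0("VAR_", 1:4),
    position = c(1L, 3L, 5L, 9999L),
    wt_aa = c(aa1[1], aa1[3], aa1[5], "A"),
    mut_aa = "X9" , dbsnp = "-", phenotype = "-",
    category = factor("DISEASE", levels = c("DISEASE", "POLYMORPHISM",
                                            "UNCLASSIFIED")))
  vars$mut_aa <- c("V", "V", "V", "V")
  ann <- annotate_variants(vars, structure_labels = labels,
                           docking_profiles = list(prof), map = map)
  # interface in structure, also docking patch -> BOTH
  expect_equal(as.character(ann$location[1]), "INTERFACE")
  expect_equal(as.character(ann$evidence[1]), "BOTH")
  expect_true(ann$hotspot[1])
  # non-interface by structure but inside the docking patch -> INTERFACE
  expect_equal(as.character(ann$location[2]), "INTERFACE")
  # surface residue, no interface evidence
  expect_equal(as.character(ann$location[3]), "NON_INTERFACE_SURFACE")
  expect_false(ann$hotspot[3])
  # beyond all structures
  expect_equal(as.character(ann$location[4]), "UNMAPPED")
  expect_equal(as.character(ann$evidence[4]), "NONE")
  # invariant: hotspot implies interface; NONE iff unmapped
  expect_true(all(ann$location[ann$hotspot] == "INTERFACE"))
  expect_equal(ann$evidence == "NONE", ann$location == "UNMAPPED")
})

test_that("wild-type mismatches fall back to UNMAPPED (or error in strict)", {
  st <- structure_for(seq30, 1:30)
  map <- build_numbering_map(seq30, st)
  vars <- tibble::tibble(
    gene = "G", accession = "P1", ftid = "VAR_1", position = 1L,
    wt_aa = "W", mut_aa = "V", dbsnp = "-", phenotype = "-",
    category = factor("DISEASE", levels = c("DISEASE", "POLYMORPHISM",
                                            "UNCLASSIFIED")))
  labels <- tibble::tibble(res_key = paste0("A:", 1:30), rasa = 0.5,
                           label = "NON_INTERFACE_SURFACE")
  expect_warning(
    ann <- annotate_variants(vars, structure_labels = labels, map = map),
    "mismatch")
  expect_equal(as.character(ann$location), "UNMAPPED")
  expect_error(
    suppressWarnings(annotate_variants(vars, structure_labels = labels,
                                       map = map, strict = TRUE)),
    "mismatch")
})

test_that("the census tallies locations and is order-invariant", {
  ann <- tibble::tibble(
    category = factor(rep(c("DISEASE", "POLYMORPHISM"), c(6, 4)),
                      levels = c("DISEASE", "POLYMORPHISM", "UNCLASSIFIED")),
    location = factor(c("CORE", "CORE", "INTERFACE", "INTERFACE",
                        "NON_INTERFACE_SURFACE", "UNMAPPED",
                        "CORE", "INTERFACE", "NON_INTERFACE_SURFACE",
                        "NON_INTERFACE_SURFACE"),
                      levels = c("CORE", "INTERFACE",
                                 "NON_INTERFACE_SURFACE", "UNMAPPED")),
    hotspot = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, FALSE))
  labels <- tibble::tibble(label = rep(c("CORE", "INTERFACE",
                                         "NON_INTERFACE_SURFACE"), 4),
                           hotspot = rep(c(FALSE, TRUE, FALSE), 4))
  cen <- region_census(ann, labels, context = "structural")
  expect_equal(census_count(cen, "DISEASE", "core"), 2)
  expect_equal(census_count(cen, "DISEASE", "interface"), 2)
  expect_equal(census_count(cen, "DISEASE", "hotspot_interface"), 1)
  expect_equal(census_count(cen, "DISEASE", "unmapped"), 1)
  expect_equal(census_count(cen, "DISEASE", "total"), 5) # mapped only
  expect_equal(census_count(cen, "POLYMORPHISM", "non_interface"), 2)
  expect_equal(census_count(cen, "residues", "total"), 12)
  expect_equal(census_count(cen, "residues", "hotspot_interface"), 4)
  shuffled <- region_census(ann[sample(nrow(ann)), ], labels,
                            context = "structural")
  expect_equal(as.data.frame(cen), as.data.frame(shuffled))
  # empty annotations -> all-zero variant counts
  empty <- region_census(ann[0, ], labels)
  expect_equal(census_count(empty, "DISEASE", "total"), 0)
})

test_that("the packaged census satisfies its internal constraints", {
  for (ctx in c("structural", "docking", "combined")) {
    cen <- interaction_census(ctx)
    for (cat in c("DISEASE", "POLYMORPHISM", "UNCLASSIFIED")) {
      parts <- census_count(cen, cat, "core") +
        census_count(cen, cat, "interface") +
        census_count(cen, cat, "non_interface")
      expect_lte(parts, census_count(cen, cat, "total"))
      expect_lte(census_count(cen, cat, "hotspot_interface"),
                 census_count(cen, cat, "interface"))
    }
    regions <- census_count(cen, "residues", "core") +
      census_count(cen, "residues", "interface") +
      census_count(cen, "residues", "non_interface")
    expect_equal(regions, census_count(cen, "residues", "total"))
  }
  cen_s <- interaction_census("structural")
  expect_equal(census_count(cen_s, "DISEASE", "total") +
                 census_count(cen_s, "POLYMORPHISM", "total") +
                 census_count(cen_s, "UNCLASSIFIED", "total"), 1624)
  expect_equal(census_count(cen_s, "DISEASE", "interface"), 183)
  expect_equal(census_count(interaction_census("docking"),
                            "DISEASE", "total") +
                 census_count(interaction_census("docking"),
                              "POLYMORPHISM", "total") +
                 census_count(interaction_census("docking"),
                              "UNCLASSIFIED", "total"), 2615)
  expect_equal(census_count(interaction_census("combined"),
                            "DISEASE", "hotspot_interface"), 109)
})

test_that("combined-context interface counts dominate single contexts", {
  # union rule on a shared variant set: interface in combined >= interface
  # in either single-evidence annotation
  st <- structure_for(seq30, 1:30)
  map <- build_numbering_map(seq30, st)
  labels <- tibble::tibble(res_key = paste0("A:", 1:30), rasa = 0.5,
                           label = c(rep("INTERFACE", 5),
                                     rep("NON_INTERFACE_SURFACE", 25)))
  prof <- structure(tibble::tibble(
    res_key = paste0("A:", 1:30), chain = "A", resno = 1:30, ins = "",
    resname = "ALA", asa_unbound = 50, rasa = 0.5, abs = 0, nip = 0,
    hotspot = FALSE,
    extended_interface = c(rep(FALSE, 3), rep(TRUE, 5), rep(FALSE, 22))),
    class = c("nip_profile", class(tibble::tibble())))
  aa1 <- strsplit(seq30, "")[[1]]
  vars <- tibble::tibble(
    gene = "G", accession = "P1", ftid = paste0("VAR_", 1:10),
    position = 1:10, wt_aa = aa1[1:10], mut_aa = "V",
    dbsnp = "-", phenotype = "-",
    category = factor("DISEASE", levels = c("DISEASE", "POLYMORPHISM",
                                            "UNCLASSIFIED")))
  vars$mut_aa[vars$wt_aa == "V"] <- "L"
  n_if <- function(ann) sum(ann$location == "INTERFACE")
  both <- annotate_variants(vars, labels, list(prof), map)
  only_s <- annotate_variants(vars, labels, list(), map)
  only_d <- annotate_variants(vars, NULL, list(prof), map)
  expect_gte(n_if(both), n_if(only_s))
  expect_gte(n_if(both), n_if(only_d))
  expect_equal(n_if(both), 8) # union of residues 1:5 and 4:8
})
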