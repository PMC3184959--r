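test_that("ligand extraction maps reference columns through the alignment", {
  ref <- reference_pcld()
  self <- extract_ligand_sites(ref$seq)
  expect_equal(unname(self$ligands), c("H", "C", "H", "M"))
  expect_true(self$disulfide_ok)
  # axial Met -> Gln point mutant
  s <- strsplit(ref$seq, "")[[1]]
  s[ref$ligand_columns[4]] <- "Q"
  expect_equal(unname(extract_ligand_sites(paste(s, collapse = ""))$ligands),
               c("H", "C", "H", "Q"))
  # first ligand His deleted: gap maps to absent
  del <- paste(strsplit(ref$seq, "")[[1]][-ref$ligand_columns[1]],
               collapse = "")
  expect_equal(unname(extract_ligand_sites(del)$ligands)[1], "-")
  # disulfide Cys lost
  s2 <- strsplit(ref$seq, "")[[1]]
  s2[ref$disulfide_columns[1]] <- "S"
  expect_false(extract_ligand_sites(paste(s2, collapse = ""))$disulfide_ok)
})

test_that("an unrelated query signals a low-confidence alignment", {
  junk <- strrep("GK", 20)
  expect_error(extract_ligand_sites(junk), class = "pcfam_low_confidence")
})

test_that("subfamily assignment follows the ligand tuple exactly", {
  expect_equal(classify_subfamily(c("H", "C", "H", "M")), "UCL")
  expect_equal(classify_subfamily(c("H", "C", "H", "Q")), "SCL")
  expect_equal(classify_subfamily(c("H", "C", "H", "L")), "ENODL")
  expect_equal(classify_subfamily(c("-", "C", "H", "M")), "ENODL")
  expect_equal(classify_subfamily(c("-", "-", "-", "-")), "ENODL")
})

test_that("architecture truth table matches the hand enumeration", {
  # independently enumerated (sp, n_pcld, alr, gas) -> type map
  expected <- list(
    list(TRUE, 1L, TRUE, TRUE, "I"),
    list(TRUE, 1L, TRUE, FALSE, "II"),
    list(TRUE, 1L, FALSE, TRUE, "III"),
    list(TRUE, 1L, FALSE, FALSE, "IV"),
    list(FALSE, 1L, FALSE, FALSE, "V"),
    list(TRUE, 2L, FALSE, FALSE, "VI"))
  typed <- 0L
  for (sp in c(TRUE, FALSE)) for (np in 1:2)
    for (alr in c(TRUE, FALSE)) for (gas in c(TRUE, FALSE)) {
      got <- classify_architecture(sp, np, alr, gas)
      hit <- Filter(function(e) identical(e[1:4], list(sp, np, alr, gas)),
                    expected)
      if (length(hit)) {
        expect_equal(got, hit[[1]][[5]])
        typed <- typed + 1L
      } else {
        expect_equal(got, "UNCLASSIFIED")
      }
    }
  expect_equal(typed, 6L)
  expect_error(classify_architecture(TRUE, 0L, TRUE, TRUE), "no PCLD")
})

test_that("classification recovers planted labels from sequence alone", {
  cases <- list(c("UCL", "I"), c("SCL", "III"), c("ENODL", "IV"),
                c("UCL", "V"), c("ENODL", "I"), c("SCL", "II"))
  for (i in seq_along(cases)) {
    g <- gen_pc_protein(cases[[i]][1], cases[[i]][2], seed = 100 + i)
    row <- classify_protein(g$record)
    expect_equal(row$subfamily, cases[[i]][1], label = paste(cases[[i]], collapse = "/"))
    expect_equal(row$arch_type, cases[[i]][2], label = paste(cases[[i]], collapse = "/"))
    expect_equal(row$chimeric_agp, cases[[i]][2] %in% c("I", "II"))
  }
})

test_that("a protein with SP and two PCLDs but no ALR/GAS is type VI", {
  g <- gen_pc_protein("UCL", "VI", seed = 9)
  row <- classify_protein(g$record)
  expect_equal(row$n_pcld, 2L)
  expect_equal(row$arch_type, "VI")
  expect_false(row$chimeric_agp)
})

test_that("a protein without a detectable PCLD errors by id", {
  rec <- protein_record("nopc", strrep("GKE", 40))
  expect_error(classify_protein(rec), "nopc")
})

test_that("externally supplied annotation flags override the heuristics", {
  g <- gen_pc_protein("UCL", "IV", seed = 12)
  rec <- g$record
  rec$sp_flag <- FALSE  # forces the SP/no-ALR/no-GAS combination off-table
  row <- classify_protein(rec)
  expect_equal(row$arch_type, "V")
})

test_that("type summaries count cells and conserve the total", {
  one <- data.frame(subfamily = "UCL", arch_type = "I")
  s <- summarize_types(one)
  expect_equal(s["I", "UCL"], 1L)
  expect_equal(s["Total", "Total"], 1L)
  empty <- summarize_types(data.frame(subfamily = character(),
                                      arch_type = character()))
  expect_true(all(empty == 0L))
  fam <- classify_family(gen_family_fixture(
    counts = {m <- matrix(0L, 6, 3,
                          dimnames = list(c("I", "II", "III", "IV", "V", "VI"),
                                          c("UCL", "SCL", "ENODL")))
              m["I", "UCL"] <- 2L; m["IV", "ENODL"] <- 1L; m}, seed = 5)$records)
  s2 <- summarize_types(fam)
  expect_equal(s2["Total", "Total"], nrow(fam))
  expect_equal(s2["I", "UCL"], 2L)
  expect_equal(s2["IV", "ENODL"], 1L)
})

test_that("expression-evidence percentages come from the two counts", {
  expect_equal(round(expressed_percent(38, 62), 2), 61.29)
  expect_equal(expressed_percent(0, 10), 0)
  expect_error(expressed_percent(11, 10))
})
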