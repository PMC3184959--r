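test_that("PAST fraction counts P/A/S/T residues over the interval", {
  expect_equal(past_fraction("PAST"), 1)
  expect_equal(past_fraction("GGGG"), 0)
  expect_equal(past_fraction("APAPSPTPGG"), 0.8)
  expect_equal(past_fraction("GGPAST", interval = c(3, 6)), 1)
  expect_error(past_fraction(""), "empty")
  expect_error(past_fraction("GG", interval = c(1, 5)), "out of bounds")
})

test_that("PAST fraction is invariant under residue permutation", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_biased_seq(sample(10:50, 1))
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(past_fraction(s), past_fraction(perm))
  }
})

test_that("Pro-rich regions chain Pro residues with gaps of at most 11", {
  expect_equal(nrow(find_pro_rich_regions("MAGSAKE")), 0L)
  r <- find_pro_rich_regions("MAPAAPAA")  # Pro at 3 and 6, gap 2
  expect_equal(r$start, 3L)
  expect_equal(r$end, 6L)
  expect_equal(r$pro_count, 2L)
  # 12 residues between two Pro: both runs are singletons, discarded
  far <- paste0("AP", strrep("G", 12), "PA")
  expect_equal(nrow(find_pro_rich_regions(far)), 0L)
  # exactly 11 between: one region
  near <- paste0("AP", strrep("G", 11), "PA")
  expect_equal(nrow(find_pro_rich_regions(near)), 1L)
})

test_that("glycomodules keep noncontiguous [AST]P dipeptides clustered", {
  r <- find_pro_rich_regions("APAP")
  m <- find_glycomodules("APAP", r[1, ])
  expect_length(m, 1L)
  expect_equal(m[[1]]$starts, c(1L, 3L))
  expect_equal(m[[1]]$size, 2L)
  # every Pro adjacent to another Pro: no module
  r2 <- find_pro_rich_regions("SPPSPP")
  expect_length(find_glycomodules("SPPSPP", r2[1, ]), 0L)
  # three noncontiguous heads within the spacing bound
  s3 <- "TPXXSPXXAP"
  r3 <- find_pro_rich_regions(s3)
  m3 <- find_glycomodules(s3, r3[1, ])
  expect_length(m3, 1L)
  expect_equal(m3[[1]]$size, 3L)
})

test_that("glycomodule scanner matches the brute-force oracle", {
  set.seed(101)
  for (i in 1:1000) {
    s <- random_biased_seq(sample(10:60, 1))
    regions <- find_pro_rich_regions(s)
    oracle_regions <- oracle_pro_regions(s)
    expect_equal(unname(Map(c, regions$start, regions$end)),
                 unname(oracle_regions))
    if (nrow(regions) == 0) next
    for (k in seq_len(nrow(regions))) {
      got <- mods_as_starts(find_glycomodules(s, regions[k, ]))
      want <- oracle_glycomodules(s, regions$start[k], regions$end[k])
      expect_equal(got, unname(want), label = s)
    }
  }
})

test_that("appending non-Pro residues never removes reported glycomodules", {
  set.seed(77)
  for (i in 1:50) {
    s <- random_biased_seq(sample(15:40, 1))
    regions <- find_pro_rich_regions(s)
    if (nrow(regions) == 0) next
    before <- unlist(lapply(seq_len(nrow(regions)), function(k)
      unlist(mods_as_starts(find_glycomodules(s, regions[k, ])))))
    s2 <- paste0(s, paste(sample(c("G", "K", "E"), 10, replace = TRUE),
                          collapse = ""))
    regions2 <- find_pro_rich_regions(s2)
    after <- unlist(lapply(seq_len(nrow(regions2)), function(k)
      unlist(mods_as_starts(find_glycomodules(s2, regions2[k, ])))))
    expect_true(all(before %in% after))
  }
})

test_that("ALR calls require three dipeptides outside excluded intervals", {
  core <- strrep("APSG", 4)  # 4 noncontiguous AP dipeptides
  seq <- paste0(strrep("G", 10), core, strrep("G", 10))
  pos <- call_alr(seq)
  expect_true(pos$present)
  expect_equal(pos$n_dipeptides, 4L)
  expect_gt(pos$region_past, 0.35)
  # Pro-free linker: negative
  expect_false(call_alr(strrep("GKE", 20))$present)
  # dipeptides only inside the excluded (PCLD) interval: negative
  masked <- call_alr(seq, excluded = list(c(11L, 10L + nchar(core))))
  expect_false(masked$present)
  expect_equal(masked$n_dipeptides, 0L)
  expect_error(call_alr(seq, excluded = list(c(1L, 1000L))), "out of bounds")
})

test_that("SP and GAS heuristics accept planted cassettes and reject others", {
  sp_seq <- paste0("MK", strrep("L", 10), strrep("G", 40))
  expect_true(heuristic_sp(sp_seq))
  expect_false(heuristic_gas(paste0(strrep("K", 40), strrep("G", 25))))
  g <- gen_pc_protein("UCL", "III", seed = 3)
  expect_true(heuristic_sp(g$record$seq))
  expect_true(heuristic_gas(g$record$seq))
  g5 <- gen_pc_protein("UCL", "V", seed = 3)
  expect_false(heuristic_sp(g5$record$seq))
  expect_false(heuristic_gas(g5$record$seq))
  expect_error(heuristic_sp("MKLLLL"), "shorter than 40")
  expect_error(heuristic_gas("MKLLLL"), "shorter than 40")
})

test_that("feature report summarizes one row per protein", {
  recs <- list(gen_pc_protein("UCL", "I", seed = 1)$record,
               gen_pc_protein("UCL", "IV", seed = 2)$record)
  rep <- feature_report(recs)
  expect_equal(nrow(rep), 2L)
  expect_true(rep$alr_present[1])
  expect_false(rep$alr_present[2])
})
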