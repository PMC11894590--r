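toy_atlas_for_perturb <- function() {
  rs <- keep_reagents(load_rules(), c("Trypsin", "CNBr", "Thermolysin",
                                      "Glutamyl endopeptidase"))
  recs <- list(protein_record("p1", "GSKGSMGSEGSKGSWGS"),
               protein_record("p2", "GSKGSNGSEGSKGSWGS"))
  list(rs = rs, recs = recs, atlas = build_atlas(recs, rs))
}

test_that("identity mutation gains and loses nothing", {
  env <- toy_atlas_for_perturb()
  ref <- substr(env$recs[[1]]$sequence, 6, 6)
  d <- mutation_differential(env$recs[[1]], paste0(ref, "6", ref),
                             env$atlas, env$rs, alpha = 0.01)
  expect_identical(d$gained, character(0))
  expect_identical(d$lost, character(0))
})

test_that("destroying a cleavage site loses every fragment using it", {
  rs <- load_rules(single_rule_table()) # cleave after K only
  rec <- protein_record("toy", "GGKGGKGG")
  atlas <- build_atlas(list(rec), rs)
  # sites {3, 6} -> hand-enumerated distinct pool
  expect_setequal(atlas$index$sequence, c("GGK", "GGKGGK", "GGKGG", "GG"))
  d <- mutation_differential(rec, "K6N", atlas, rs, alpha = 0.01)
  # fragments bounded at 6 (GGKGGK, GG) disappear, as does the span
  # covering the substituted residue; only GGK survives intact
  expect_setequal(d$lost, c("GGKGGK", "GGKGG", "GG"))
  expect_setequal(d$gained, "GGNGG")
  # a mutation erasing every site leaves an empty pool, which is an error
  rec1 <- protein_record("one", "GGSKGGS")
  atlas1 <- build_atlas(list(rec1), rs)
  expect_error(mutation_differential(rec1, "K4N", atlas1, rs),
               "empty mutant pool")
})

test_that("mutation differential equals a brute-force recomputation", {
  env <- toy_atlas_for_perturb()
  rec <- env$recs[[1]]
  spec <- "M6W"
  d <- mutation_differential(rec, spec, env$atlas, env$rs, alpha = 0.01)
  mut <- apply_mutation(rec, spec)
  mut_seqs <- unique(brute_fragments(
    mut$sequence, site_positions(find_sites(mut, env$rs)))$sequence)
  ref_all <- unique(env$atlas$membership$sequence)
  wt_seqs <- env$atlas$index$sequence[env$atlas$index$isoform == rec$id]
  other <- env$atlas$index$sequence[env$atlas$index$isoform != rec$id]
  expect_setequal(d$gained, setdiff(mut_seqs, ref_all))
  expect_setequal(d$lost, setdiff(setdiff(wt_seqs, mut_seqs), other))
  expect_length(intersect(d$gained, d$lost), 0)
})

test_that("substitutions preserve fragments outside the context window", {
  rs <- load_rules(terminal = "strict")
  set.seed(17)
  rec <- random_protein(50)
  p <- 25L
  alt <- sample(setdiff(AA_ALPHABET_TEST, substr(rec$sequence, p, p)), 1)
  mut <- apply_mutation(rec, paste0(substr(rec$sequence, p, p), p, alt))
  fr_wt <- enumerate_fragments(rec, find_sites(rec, rs))
  fr_mut <- enumerate_fragments(mut, find_sites(mut, rs))
  # fragments wholly left or right of the window, with unchanged boundaries
  untouched <- fr_wt[fr_wt$end < p - 5L | fr_wt$start > p + 5L, ]
  keys <- paste(fr_mut$start, fr_mut$end, fr_mut$sequence)
  kept <- paste(untouched$start, untouched$end, untouched$sequence) %in% keys
  expect_true(all(kept))
})

test_that("inhibition removes fragments monotonically", {
  env <- toy_atlas_for_perturb()
  d <- inhibition_differential(env$atlas, env$rs, "CNBr", alpha = 0.01)
  expect_identical(d$gained, character(0))
  pert <- build_atlas(env$recs, drop_reagent(env$rs, "CNBr"))
  # site maps without the reagent are subsets of the reference maps
  for (id in names(env$atlas$sitemaps)) {
    expect_true(all(site_positions(pert$sitemaps[[id]]) %in%
                      site_positions(env$atlas$sitemaps[[id]])))
    expect_true(all(
      paste(pert$fragments$start, pert$fragments$end)[pert$fragments$isoform == id] %in%
        paste(env$atlas$fragments$start, env$atlas$fragments$end)[env$atlas$fragments$isoform == id]))
  }
  # p2 has no methionine, so nothing changes there
  expect_identical(site_positions(pert$sitemaps$p2),
                   site_positions(env$atlas$sitemaps$p2))
  expect_true(all(d$direction[, "p2"] == "unchanged"))
  expect_error(inhibition_differential(env$atlas, env$rs, "nope"),
               "unknown reagent")
})

test_that("removing a reagent with no exclusive sites changes nothing", {
  # Arg-C and clostripain are fully redundant with each other (and trypsin)
  # on R positions without P context
  rs <- keep_reagents(load_rules(), c("Arg-C proteinase", "Clostripain"))
  rec <- protein_record("r", "GGSRGGSRGG")
  atlas <- build_atlas(list(rec), rs)
  d <- inhibition_differential(atlas, rs, "Clostripain", alpha = 0.01)
  expect_length(d$lost, 0)
  expect_true(all(d$direction == "unchanged"))
})

test_that("batch reports run in order and survive failing elements", {
  env <- toy_atlas_for_perturb()
  empty <- batch_perturbation_report(character(0), "inhibition",
                                     env$atlas, env$rs)
  expect_identical(nrow(empty), 0L)
  rep <- batch_perturbation_report(
    c("CNBr", "CNBr", "not an enzyme"), "inhibition",
    env$atlas, env$rs, alpha = 0.01)
  expect_identical(nrow(rep), 3L)
  # duplicates give identical blocks
  expect_identical(rep$gained[1], rep$gained[2])
  expect_identical(rep$lost[1], rep$lost[2])
  res <- attr(rep, "results")
  expect_identical(res[[1]]$profile, res[[2]]$profile)
  # the failing element is reported, not fatal
  expect_match(rep$error[3], "unknown reagent")
  expect_true(is.na(rep$gained[3]))
})
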