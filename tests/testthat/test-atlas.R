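toy_k_ruleset <- function() load_rules(single_rule_table())

toy_sitemap <- function(rec, rs) find_sites(rec, rs)

test_that("count_possible evaluates the combinatorial formula exactly", {
  expect_identical(count_possible(0), 0)
  expect_identical(count_possible(1), 2)
  expect_identical(count_possible(2), 5)
  expect_identical(count_possible(c(10, 100)), c(65, 5150))
  expect_error(count_possible(-1), "non-negative")
  expect_error(count_possible(2.5), "non-negative integer")
})

test_that("enumerate_fragments matches the worked toy examples", {
  rs <- toy_k_ruleset()
  rec <- protein_record("t", "AGKD") # K at 3 -> boundaries {0,3,4}
  fr <- enumerate_fragments(rec, find_sites(rec, rs))
  expect_setequal(fr$sequence, c("AGK", "D"))

  # two interior boundaries -> Z(2) = 5 fragments
  rec2 <- protein_record("t", "AKGKCD") # sites 2, 4
  fr2 <- enumerate_fragments(rec2, find_sites(rec2, rs))
  expect_setequal(fr2$sequence, c("AK", "AKGK", "GK", "GKCD", "CD"))
  expect_identical(nrow(fr2), as.integer(count_possible(2)))
  expect_identical(fr2$fragment_id[1], "t:1-2")
})

test_that("enumeration equals the brute-force boundary-pair oracle", {
  rs <- load_rules()
  set.seed(3)
  for (i in 1:20) {
    rec <- random_protein(sample(5:40, 1))
    sub <- keep_reagents(rs, sample(reagent_names(rs), 6))
    sm <- find_sites(rec, sub)
    got <- enumerate_fragments(rec, sm)
    want <- brute_fragments(rec$sequence, site_positions(sm))
    expect_equal(got[order(got$start, got$end), c("start", "end", "sequence")],
                 want[order(want$start, want$end), ],
                 ignore_attr = TRUE)
  }
})

test_that("formula and enumeration agree when no site touches a terminus", {
  rs <- load_rules(terminal = "strict")
  set.seed(5)
  tried <- 0L
  for (i in 1:40) {
    rec <- random_protein(sample(6:40, 1))
    sub <- keep_reagents(rs, sample(reagent_names(rs), 5))
    sm <- find_sites(rec, sub)
    tried <- tried + 1L
    expect_identical(nrow(enumerate_fragments(rec, sm)),
                     as.integer(count_possible(sm$x)))
  }
  expect_gte(tried, 40L)
})

test_that("every fragment is the substring at its coordinates", {
  rs <- load_rules()
  set.seed(9)
  rec <- random_protein(60)
  fr <- enumerate_fragments(rec, find_sites(rec, rs))
  expect_identical(fr$sequence,
                   substring(rec$sequence, fr$start, fr$end))
  expect_true(all(fr$start >= 1 & fr$start <= fr$end & fr$end <= rec$length))
  expect_false(any(fr$start == 1 & fr$end == rec$length))
})

test_that("atlas dedup, membership and counts behave on toys", {
  rs <- toy_k_ruleset()
  # no sites -> empty degradome
  rec0 <- protein_record("bare", "GGSSGG")
  a0 <- build_atlas(list(rec0), rs)
  expect_identical(nrow(a0$fragments), 0L)
  expect_identical(a0$counts$distinct, 0)

  # two identical records (different ids) share every sequence
  r1 <- protein_record("a", "GKAYKW")
  r2 <- protein_record("b", "GKAYKW")
  a2 <- build_atlas(list(r1, r2), rs)
  expect_true(all(a2$membership$n_iso == 2L))
  expect_identical(unique_sequences(a2, "a"), character(0))
  expect_error(build_atlas(list(r1, r1), rs), "duplicate record id")

  # within-isoform duplicates collapse but are counted
  r3 <- protein_record("c", "AKAKAK") # fragments repeat "AK"
  a3 <- build_atlas(list(r3), rs)
  expect_lt(nrow(a3$index), nrow(a3$fragments))
  expect_identical(sum(a3$index$copies), nrow(a3$fragments))
  expect_true(all(a3$counts$distinct <= a3$counts$enumerated))
})

test_that("pan and unique classes partition distinct sequences", {
  rs <- toy_k_ruleset()
  r1 <- protein_record("a", "MKAY")
  r2 <- protein_record("b", "MKAW")
  atlas <- build_atlas(list(r1, r2), rs)
  expect_identical(unique_sequences(atlas, "a"), "AY")
  expect_identical(unique_sequences(atlas, "b"), "AW")
  pan <- pan_sequences(atlas, min_len = 1)
  expect_identical(pan, "MK")
  expect_error(unique_sequences(atlas, "zz"), "unknown isoform")
  # pan over disjoint alphabets is empty
  d <- build_atlas(list(protein_record("x", "GKGG"),
                        protein_record("y", "WKWW")), rs)
  expect_identical(pan_sequences(d, 1), character(0))
  # pan, unique and shared-but-not-pan classes cover everything once
  m <- atlas$membership
  expect_identical(sort(c(unique_sequences(atlas, "a"),
                          unique_sequences(atlas, "b"),
                          pan_sequences(atlas, 1))),
                   sort(m$sequence))
})

test_that("pan respects the minimum length and sort order", {
  rs <- toy_k_ruleset()
  r1 <- protein_record("a", "AAKGGKDD")
  r2 <- protein_record("b", "AAKGGKEE")
  atlas <- build_atlas(list(r1, r2), rs)
  pan5 <- pan_sequences(atlas, 5)
  expect_true(all(nchar(pan5) >= 5))
  pan1 <- pan_sequences(atlas, 1)
  expect_true(all(diff(nchar(pan1)) <= 0)) # descending length
  expect_true("AAK" %in% pan1 && !"AAK" %in% pan5)
})

test_that("export produces unique FASTA headers and round-trips", {
  rs <- toy_k_ruleset()
  set.seed(13)
  rec <- random_protein(30)
  atlas <- build_atlas(list(rec), load_rules())
  dir <- tempfile()
  files <- export_atlas(atlas, dir, format = c("fasta", "tsv"))
  fa <- load_fasta(file.path(dir, "atlas.fasta"))
  expect_identical(length(fa), nrow(atlas$fragments))
  ids <- vapply(fa, `[[`, "", "id")
  expect_identical(anyDuplicated(ids), 0L)
  # FASTA sequences equal the recorded fragments
  expect_setequal(
    paste(ids, vapply(fa, `[[`, "", "sequence")),
    paste(paste0(rec$id, ":", atlas$fragments$start, "-", atlas$fragments$end),
          substring(rec$sequence, atlas$fragments$start, atlas$fragments$end)))
  tab <- utils::read.delim(file.path(dir, "atlas.tsv"))
  expect_identical(nrow(tab), nrow(atlas$index))
})
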