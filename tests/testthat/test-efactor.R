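test_that("a POI identical to its background has E-factor 1 everywhere", {
  codons <- random_codons(60L, toy_codon_pool)
  t <- make_transcriptome(list(codons))
  bg <- pooled_background_frequencies(t, toy_assignment)
  pf <- poi_frequencies(t$records[[1L]], toy_assignment)
  et <- compute_efactors(pf, bg, toy_pairs)
  expect_true(all(et$efactor[et$f_bg > 0] == 1))
  expect_true(all(et$efactor[et$f_bg == 0] == 0))
})

test_that("zero numerator gives E = 0; zero background gives the Inf sentinel", {
  bg <- poi_frequencies(make_cds(c("AUG", "AUA", "AUA")), pkg_assignment)
  poi <- poi_frequencies(make_cds(c("GGG", "GGG", "GGG")), pkg_assignment)
  et <- compute_efactors(poi, bg, pkg_pairs)
  row <- et[et$pair_id == "Ile-UAU:Ile-UAU", ]
  expect_equal(row$efactor, 0)                       # in bg, not in POI
  row <- et[et$pair_id == "Gly-CCC:Gly-CCC", ]
  expect_equal(row$efactor, Inf)                     # in POI, not in bg
  expect_equal(row$flags, "zero_background")
  # the Inf record outranks all finite ones in the sorted table
  expect_equal(et$pair_id[1L], "Gly-CCC:Gly-CCC")
})

test_that("pseudocount policy keeps every E-factor finite and flags rows", {
  bg <- poi_frequencies(make_cds(c("AUG", "AUA", "AUA")), pkg_assignment)
  poi <- poi_frequencies(make_cds(c("GGG", "GGG", "GGG")), pkg_assignment)
  et <- compute_efactors(poi, bg, pkg_pairs, zero_policy = "pseudocount")
  expect_true(all(is.finite(et$efactor)))
  expect_true(all(et$flags == "pseudocounted"))
  expect_equal(sum(et$f_bg), 1, tolerance = 1e-12)
})

test_that("frequencies outside the declared universe are an error", {
  # Trp-CCA pairs exist under the packaged table but not in the toy universe
  bg <- poi_frequencies(make_cds(c("UGG", "UGG", "UGG")), pkg_assignment)
  expect_error(compute_efactors(bg, bg, toy_pairs), "universe")
})

test_that("background rarity rank uses competition ranking", {
  lists <- list(c("AUA", "AUA", "AUA", "AUG", "GGG", "GGG"))
  bg <- pooled_background_frequencies(make_transcriptome(lists),
                                      pkg_assignment)
  pf <- poi_frequencies(make_cds(c("AUA", "AUA")), pkg_assignment)
  et <- compute_efactors(pf, bg, pkg_pairs)
  # 1171 of 1176 pairs are absent from this toy background: all share rank 1
  absent <- et$bg_rank_rarity[et$f_bg == 0]
  expect_true(all(absent == 1L))
  # the most common pair is the 1176th rarest
  expect_equal(et$bg_rank_rarity[which.max(et$f_bg)], 1176L)
})

test_that("leading pair follows the documented tie-break", {
  t <- structure(data.frame(
    pair_id = c("B:B", "A:A", "C:C"),
    f_poi = c(0.2, 0.2, 0.1),
    f_bg = c(0.02, 0.01, 0.001),
    efactor = c(10, 20, 100),
    bg_rank_rarity = c(3L, 2L, 1L),
    flags = "", stringsAsFactors = FALSE),
    poi_id = "x", background_label = "y", mode = "pooled",
    zero_policy = "sentinel",
    class = c("efactor_table", "data.frame"))
  expect_equal(leading_pair(t)$pair_id, "C:C")       # unique maximum
  t$efactor <- c(20, 20, 5)
  expect_equal(leading_pair(t)$pair_id, "A:A")       # tie: lower f_bg wins
  t$f_bg <- c(0.01, 0.01, 0.001)
  expect_equal(leading_pair(t)$pair_id, "A:A")       # tie: lexicographic id
  t$efactor <- c(0, 0, 0)
  lp <- leading_pair(t)
  expect_equal(lp$flag, "no_signal")

  # random tables agree with a brute-force maximum under the same ordering
  set.seed(77)
  for (rep in 1:20) {
    n <- 30L
    tt <- t[rep(1L, n), ]
    tt$pair_id <- paste0("P", sprintf("%02d", sample(n)))
    tt$efactor <- sample(c(0, 1, 5, 5, 10), n, replace = TRUE)
    tt$f_bg <- sample(c(0.01, 0.02, 0.02), n, replace = TRUE)
    ord <- order(-tt$efactor, tt$f_bg, tt$pair_id)
    expect_equal(leading_pair(tt)$pair_id, tt$pair_id[ord[1L]])
  }
})

test_that("control-pair selection finds absent-in-POI, common-in-bg pairs", {
  # POI uses only Ile/Met pairs; background also contains a common Gly:Gly
  poi <- poi_frequencies(make_cds(c("AUG", "AUA", "AUA")), pkg_assignment)
  bg_list <- list(c(rep("GGG", 6L), "AUG", "AUA", "AUA", "AUG"))
  bg <- pooled_background_frequencies(make_transcriptome(bg_list),
                                      pkg_assignment)
  ctl <- select_control_pair(poi, bg, pkg_pairs, min_bg_multiple = 2)
  expect_equal(ctl$pair_id[1L], "Gly-CCC:Gly-CCC")
  expect_false(any(ctl$pair_id %in% names(poi$freqs)))
  # a POI that uses every pair of a tiny universe leaves nothing admissible
  uni <- c("Ile-UAU:Ile-UAU", "Ile-UAU:Met-CAU")
  ctl <- select_control_pair(poi, bg, uni)
  expect_equal(nrow(ctl), 0L)
})

test_that("E-factors are invariant to scaling background counts", {
  set.seed(88)
  lists <- lapply(1:3, function(i) random_codons(30L, toy_codon_pool))
  poi <- poi_frequencies(make_cds(random_codons(25L, toy_codon_pool)),
                         toy_assignment)
  bg1 <- pooled_background_frequencies(make_transcriptome(lists),
                                       toy_assignment)
  # triplicate every record (scales all pooled counts by 3)
  bg3 <- pooled_background_frequencies(make_transcriptome(rep(lists, 3L)),
                                       toy_assignment)
  e1 <- compute_efactors(poi, bg1, toy_pairs)
  e3 <- compute_efactors(poi, bg3, toy_pairs)
  expect_equal(e1$efactor, e3$efactor, tolerance = 1e-12)
})

test_that("swapping one POI dicodon toward the target raises its E-factor", {
  bg <- pooled_background_frequencies(
    make_transcriptome(list(c(rep("AUA", 5L),
                              random_codons(200L, toy_codon_pool)))),
    toy_assignment)
  base <- c(rep("AUA", 3L), rep("GGG", 10L), rep("CCC", 10L))
  more <- c(rep("AUA", 4L), rep("GGG", 10L), rep("CCC", 9L))  # same length
  e_base <- compute_efactors(poi_frequencies(make_cds(base), toy_assignment),
                             bg, toy_pairs)
  e_more <- compute_efactors(poi_frequencies(make_cds(more), toy_assignment),
                             bg, toy_pairs)
  target <- "Ile-UAU:Ile-UAU"
  expect_gt(e_more$efactor[e_more$pair_id == target],
            e_base$efactor[e_base$pair_id == target])
})

test_that("full tables match the brute-force oracle on micro-transcriptomes", {
  set.seed(99)
  amap <- as.list(toy_assignment$table)
  for (rep in 1:25) {
    bg_lists <- lapply(seq_len(sample(2:6, 1L)), function(i)
      random_codons(sample(5:30, 1L), toy_codon_pool))
    poi_codons <- random_codons(sample(5:30, 1L), toy_codon_pool)
    bg <- pooled_background_frequencies(make_transcriptome(bg_lists),
                                        toy_assignment)
    pf <- poi_frequencies(make_cds(poi_codons), toy_assignment)
    et <- compute_efactors(pf, bg, toy_pairs)
    oracle <- oracle_efactor(poi_codons, bg_lists, amap, toy_pairs$pair_id)
    merged <- merge(as.data.frame(et), oracle, by = "pair_id",
                    suffixes = c("", ".o"))
    expect_equal(nrow(merged), nrow(toy_pairs))
    expect_equal(merged$f_poi, merged$f_poi.o, tolerance = 1e-12)
    expect_equal(merged$f_bg, merged$f_bg.o, tolerance = 1e-12)
    expect_equal(merged$efactor, merged$efactor.o, tolerance = 1e-12)
    expect_identical(merged$bg_rank_rarity, merged$bg_rank_rarity.o)
  }
})

test_that("self-survey of a homogeneous transcriptome is all ones", {
  codons <- random_codons(80L, toy_codon_pool)
  t <- make_transcriptome(rep(list(codons), 5L))
  bg <- pooled_background_frequencies(t, toy_assignment)
  s <- survey_transcriptome(t, bg, toy_assignment, toy_pairs)
  expect_equal(s$n_transcripts, 5L)
  expect_true(all(s$leading$efactor == 1))
  expect_equal(unname(s$fraction_above["100"]), 0)
  expect_equal(unname(s$fraction_below["10"]), 1)
})

test_that("survey counts planted high-enrichment transcripts correctly", {
  # background dominated by Gly/Pro codons; k of n target records carry a
  # large planted run of AUA so their leading pair is hugely enriched
  set.seed(104)
  pool <- c("GGG", "GGC", "CCU", "CCC", "CCA", "AUG", "AAA", "GAA")
  bg_lists <- lapply(1:30, function(i) {
    x <- random_codons(60L, pool)
    if (i == 1L) x[10:11] <- "AUA"  # the target pair exists in the pool
    x
  })
  t_bg <- make_transcriptome(bg_lists, "bg")
  bg <- pooled_background_frequencies(t_bg, toy_assignment)
  k <- 3L
  target_lists <- c(lapply(seq_len(k), function(i)
    c(rep("AUA", 21L), random_codons(40L, pool))),
    lapply(1:7, function(i) random_codons(60L, pool)))
  targets <- make_transcriptome(target_lists, "targets")
  s <- survey_transcriptome(targets, bg, toy_assignment, toy_pairs)
  expect_equal(unname(s$fraction_above["100"]), k / 10)
})

test_that("self-survey leading E-factors are always >= 1", {
  set.seed(105)
  lists <- lapply(1:8, function(i) random_codons(sample(20:60, 1L),
                                                 toy_codon_pool))
  t <- make_transcriptome(lists)
  bg <- pooled_background_frequencies(t, toy_assignment)
  s <- survey_transcriptome(t, bg, toy_assignment, toy_pairs)
  expect_true(all(s$leading$efactor >= 1))
})

test_that("survey exports a per-transcript TSV and a JSON summary", {
  codons <- random_codons(40L, toy_codon_pool)
  t <- make_transcriptome(rep(list(codons), 3L))
  bg <- pooled_background_frequencies(t, toy_assignment)
  s <- survey_transcriptome(t, bg, toy_assignment, toy_pairs)
  prefix <- tempfile()
  write_survey(s, prefix)
  leading <- utils::read.delim(paste0(prefix, "_leading.tsv"))
  expect_equal(nrow(leading), 3L)
  js <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(js$n_transcripts, 3L)
  expect_equal(js$fraction_above$`100`, 0)
})
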