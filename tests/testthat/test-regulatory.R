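toy_pwm <- function() {
  # informative core at positions 2-5, uniform flanks
  counts <- rbind(c(1, 1, 1, 1),
                  c(9, 0, 0, 1),
                  c(0, 10, 0, 0),
                  c(0, 0, 10, 0),
                  c(0, 1, 0, 9),
                  c(2, 2, 3, 3))
  pwm("toy6", counts)
}

test_that("conservation index spans 0-100 and the core maximizes it", {
  p <- pwm("ci", rbind(c(1, 0, 0, 0),
                       c(0.25, 0.25, 0.25, 0.25),
                       c(0.5, 0.5, 0, 0),
                       c(1, 0, 0, 0),
                       c(2, 2, 2, 2)))
  prof <- conservation_index(p)
  expect_equal(prof$ci[1], 100)
  expect_equal(prof$ci[2], 0)
  expect_equal(prof$ci[3], 100 * (1 - log(2) / log(4)))  # = 50
  expect_equal(prof$ci[5], 0)

  # core = 4 consecutive positions with highest summed ci; leftmost on ties
  expect_equal(prof$core_start, 1L)
  p2 <- pwm("uniform", matrix(1, 5, 4))
  expect_equal(conservation_index(p2)$core_start, 1L)
  p3 <- toy_pwm()
  expect_equal(conservation_index(p3)$core_start, 2L)
})

test_that("similarity is 1 on the consensus and matches the direct formula", {
  p <- toy_pwm()
  prof <- conservation_index(p)
  consensus <- paste(colnames(p$freq)[max.col(p$freq, "first")],
                     collapse = "")
  expect_equal(similarity(p, prof, consensus, "all"), 1)
  expect_equal(similarity(p, prof, consensus, "core"), 1)
  # consensus core with non-consensus flanks still scores core = 1
  flanked <- paste0("T", substr(consensus, 2, 5), "A")
  expect_equal(similarity(p, prof, flanked, "core"), 1)
  expect_lt(similarity(p, prof, flanked, "all"), 1)

  # hand evaluation of the formula on a 4-position toy matrix
  q <- pwm("hand", rbind(c(.8, .1, .05, .05),
                         c(.25, .25, .25, .25),
                         c(.1, .8, .05, .05),
                         c(.7, .1, .1, .1)))
  qp <- conservation_index(q)
  win <- "ACCA"
  ci <- qp$ci
  f <- q$freq
  obs <- ci[1] * f[1, "A"] + ci[2] * f[2, "C"] + ci[3] * f[3, "C"] +
    ci[4] * f[4, "A"]
  best <- ci[1] * .8 + ci[2] * .25 + ci[3] * .8 + ci[4] * .7
  expect_equal(similarity(q, qp, win, "all"), unname(obs / best),
               tolerance = 1e-12)

  # rescaling all counts leaves the score unchanged
  p10 <- pwm("toy6x10", toy_pwm()$counts * 10)
  expect_equal(similarity(p10, conservation_index(p10), flanked, "all"),
               similarity(p, prof, flanked, "all"), tolerance = 1e-12)

  expect_true(is.na(similarity(p, prof, "ANGTAC", "all")))
  expect_error(similarity(p, prof, "ACGT", "all"), "length")
})

test_that("scan recovers planted consensus sites on both strands", {
  p <- toy_pwm()
  sim <- simulate_sequences(
    n_promoters = 3, promoter_length = 200, pwm = p,
    planted_sites = data.frame(seq_index = c(1, 2, 3),
                               start = c(30, 100, 150),
                               strand = c("+", "-", "+")),
    rng_seed = 71)
  hits <- scan_pwm(sim$promoters, p, core_min = 0.75, matrix_min = 0.80)
  for (k in 1:3) {
    pl <- sim$plants[k, ]
    match <- hits[hits$seq_id == pl$seq_id & hits$start == pl$start &
                    hits$strand == pl$strand, ]
    expect_equal(nrow(match), 1L)
    expect_equal(match$end, pl$end)
    expect_equal(match$matrix_similarity, 1)
  }

  # an unattainable core threshold yields no hits at all
  expect_equal(nrow(scan_pwm(sim$promoters, p, core_min = 1.01)), 0L)
})

test_that("unthresholded scan scores every window once per strand", {
  p <- toy_pwm()
  set.seed(3)
  seqs <- c(s1 = random_dna(40), s2 = random_dna(25))
  hits <- scan_pwm(seqs, p, core_min = 0, matrix_min = 0)
  expect_equal(nrow(hits), ((40 - 6 + 1) + (25 - 6 + 1)) * 2)
  expect_true(all(hits$end - hits$start == 6))
  expect_true(all(hits$matrix_similarity >= 0 & hits$matrix_similarity <= 1))
  expect_true(all(hits$core_similarity >= 0 & hits$core_similarity <= 1))

  # too-short sequences report no windows
  expect_message(h0 <- scan_pwm(c(tiny = "ACG"), p), "shorter")
  expect_equal(nrow(h0), 0L)
})

test_that("seed search finds the textbook perfect site", {
  mir <- c(`mir-x` = "AUGCACGUUAA")
  hits <- seed_sites(c(utr1 = "GGCGTGCAGG"), mir)
  perfect <- hits[hits$edit_type == "perfect", ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(perfect$start, 2L)
  expect_equal(perfect$end, 8L)
  expect_equal(perfect$score, 0L)
  # a reported perfect site is the exact reverse complement of the seed
  seed <- substr(chartr("T", "U", mir), 2, 7)
  site <- substr("GGCGTGCAGG", perfect$start + 1, perfect$end)
  expect_equal(chartr("ACGT", "UGCA",
                      paste(rev(strsplit(site, "")[[1]]), collapse = "")),
               seed, ignore_attr = TRUE)

  # single-substitution variants label as the pairing table dictates
  hitsG <- seed_sites(c(u = "CGTGCG"), mir)   # A->G opposite seed U: wobble
  expect_true("wobble" %in% hitsG$edit_type[hitsG$end - hitsG$start == 6])
  hitsC <- seed_sites(c(u = "CGTGCC"), mir)   # A->C opposite seed U: mismatch
  expect_true("mismatch" %in% hitsC$edit_type[hitsC$end - hitsC$start == 6])

  # far-from-seed sequence gives no hits
  expect_equal(nrow(seed_sites(c(u = "AAAAAAAAAA"), mir)), 0L)
  expect_error(seed_sites(c(u = "ACGUAC"), c(m = "ACGUA")), "shorter than 7")
})

test_that("seed search agrees exactly with the brute-force duplex oracle", {
  set.seed(2024)
  for (i in 1:60) {
    utr <- random_dna(120)
    mir <- random_rna(sample(18:23, 1))
    got <- seed_sites(stats::setNames(utr, "u"), stats::setNames(mir, "m"))
    want <- oracle_seed_sites(utr, mir)
    got_cmp <- got[, c("start", "end", "edit_type", "edit_position")]
    rownames(got_cmp) <- rownames(want) <- NULL
    expect_identical(got_cmp, want)
  }
})

test_that("interior-only mode rejects edits at seed boundary positions", {
  mir <- c(m = "AAUGCACGUU")        # seed = AUGCAC
  seed <- "AUGCAC"
  # mutate the site base opposite seed position 2 (site index 6)
  perfect <- "GUGCAU"
  boundary_var <- paste0(substr(perfect, 1, 5), "C")  # opposite miRNA pos 2
  hits_all <- seed_sites(c(u = boundary_var), mir)
  hits_int <- seed_sites(c(u = boundary_var), mir, interior_only = TRUE)
  has6 <- function(h) any(h$end - h$start == 6 & h$edit_type != "perfect")
  expect_true(has6(hits_all))
  expect_false(has6(hits_int))
})

test_that("planted single-edit seed sites are recovered with their labels", {
  mir <- c(`mir-t` = "UAGCUUAUCAGACUGAUGUUGA")  # seed AGCUUA
  plants <- data.frame(seq_index = 1:5, start = c(10, 40, 80, 120, 160),
                       edit_type = c("perfect", "wobble", "mismatch",
                                     "deletion", "insertion"))
  sim <- simulate_sequences(n_utrs = 5, utr_length = 220, mirna = mir,
                            planted_seed_sites = plants, rng_seed = 12)
  hits <- scan_seed_sites(sim$utrs, mir)
  for (k in seq_len(nrow(plants))) {
    pl <- sim$plants[k, ]
    match <- hits[hits$seq_id == pl$seq_id & hits$start == pl$start &
                    hits$end == pl$end & hits$edit_type == pl$edit_type, ]
    expect_gte(nrow(match), 1L)
  }
  expect_error(simulate_sequences(
    n_utrs = 1, utr_length = 100, mirna = mir,
    planted_seed_sites = data.frame(seq_index = c(1, 1), start = c(10, 12),
                                    edit_type = c("perfect", "perfect")),
    rng_seed = 1), "overlap")
})
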