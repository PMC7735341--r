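test_that("corpus generation is deterministic for a fixed seed", {
  cfg <- table3_scenario()
  c1 <- generate_corpus(cfg, seed = 11)
  c2 <- generate_corpus(cfg, seed = 11)
  expect_identical(c1$phrases, c2$phrases)
  expect_identical(c1$songs, c2$songs)
  c3 <- generate_corpus(cfg, seed = 12)
  expect_false(identical(c1$phrases, c3$phrases))
})

test_that("the default scenario carries 16 themes, five with phrase variants", {
  cfg <- table3_scenario()
  corp <- generate_corpus(cfg, seed = 2)
  expect_identical(count_themes(corp$songs), 16L)
  expect_identical(count_variant_themes(corp$phrases), 5L)
  # the two lineages share no themes (cultural revolution)
  gt <- cfg$scenario
  green <- unlist(lapply(strsplit(gt$themes[gt$lineage == "green"], " "),
                         as.integer))
  blue <- unlist(lapply(strsplit(gt$themes[gt$lineage == "blue"], " "),
                        as.integer))
  expect_length(intersect(green, blue), 0)
})

test_that("zero-noise lineages have within-similarity 1 and zero between", {
  cfg <- table3_scenario(noise = c(substitution = 0, insertion = 0,
                                   deletion = 0),
                         songs_per_recording = 2L)
  corp <- generate_corpus(cfg, seed = 5)
  m <- song_lsi_matrix(corp$songs, "median")
  gt <- corp$ground_truth
  green <- gt$lineages$green
  blue <- gt$lineages$blue
  expect_true(all(m[green, blue] == 0))
  # identical scenario rows cluster at similarity 1 within a lineage-year
  nc15a <- grep("NewCaledonia_2015_A", rownames(m), value = TRUE)
  expect_true(all(m[nc15a, nc15a] == 1))
})

test_that("theme presence follows the majority of song cycles", {
  cfg <- table3_scenario(noise = c(substitution = 0, insertion = 0,
                                   deletion = 0))
  corp <- generate_corpus(cfg, seed = 8)
  sets <- presence_sets(corp$presence)
  truth <- corp$ground_truth$recordings
  for (i in seq_len(nrow(truth))) {
    expect_identical(sets[[truth$label[i]]],
                     sort(as.integer(strsplit(truth$themes[i], " ")[[1]])))
  }
})

test_that("generative scenarios evolve gradually and revolt disjointly", {
  sc0 <- random_scenario(evolution_rate = 0, seed = 31)
  sets0 <- lapply(strsplit(sc0$themes, " "), as.integer)
  by_pop <- split(sets0, sc0$population)
  for (p in by_pop) {
    for (i in seq_along(p)[-1]) expect_identical(p[[i]], p[[1]])
  }

  set.seed(1)
  for (s in 1:10) {
    rev <- data.frame(population = "PopB", year = 2016)
    sc <- random_scenario(evolution_rate = 0.5, revolutions = rev,
                          inventory = 60, seed = s)
    sets <- lapply(strsplit(sc$themes, " "), as.integer)
    # evolution: consecutive years within a lineage share >= 1 theme
    for (p in unique(sc$population)) {
      rows <- which(sc$population == p)
      for (i in rows[-1]) {
        if (sc$lineage[i] == sc$lineage[i - 1]) {
          expect_gte(length(intersect(sets[[i]], sets[[i - 1]])), 1)
        } else {
          # revolution: no shared themes with the replaced song
          expect_length(intersect(sets[[i]], sets[[i - 1]]), 0)
        }
      }
    }
  }

  expect_error(random_scenario(themes_per_song = 30, inventory = 40,
                               seed = 1),
               "inventory exhausted")
})

test_that("median strings recover the generating templates at low noise", {
  # noise 0.05 per unit, >= 10 renditions per phrase type
  cfg <- table3_scenario(phrase_repeats = c(10L, 12L),
                         recordings_per_group = 1L,
                         songs_per_recording = 2L)
  corp <- generate_corpus(cfg, seed = 6)
  seqs <- strsplit(corp$phrases$units, " ", fixed = TRUE)
  types <- as.character(corp$phrases$phrase_type)
  tpl <- corp$ground_truth$templates
  hits <- vapply(unique(types), function(t) {
    med <- median_string(seqs[types == t])$string
    identical(med, tpl[[t]])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ground-truth Dice sharing is exact for known theme sets", {
  cfg <- table3_scenario()
  sets <- cfg$theme_sets
  labels <- with(cfg$scenario,
                 recording_label(population, year, song_type_tag))
  names(sets) <- labels
  m <- dsi_matrix(sets)
  # shared-k of sizes (na, nb) formula 2k/(na+nb), checked from truth
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      k <- length(intersect(sets[[i]], sets[[j]]))
      expect_equal(m[i, j],
                   2 * k / (length(sets[[i]]) + length(sets[[j]])))
    }
  }
  # New Zealand 2016 main song vs East Australia southbound 2016 pattern
  expect_equal(dice_similarity(1:5, c(3, 9, 10, 11)), 0.2222,
               tolerance = 1e-3)
})

test_that("synthetic unit measurements honour the acoustic invariants", {
  u <- generate_unit_features(n_classes = 5, separation = 3,
                              n_per_class = 40, seed = 21)
  expect_true(all(u$high_frequency >= u$low_frequency))
  expect_true(all(u$low_frequency > 0))
  expect_true(all(u$frequency_range >= 1))
  expect_equal(u$bandwidth, u$high_frequency - u$low_frequency)
  expect_equal(u$frequency_trend,
               u$start_frequency / u$end_frequency)
  expect_true(all(u$inflections >= 0))
  expect_true(all(u$pulse_rate >= 0))
  expect_identical(nrow(u), 200L)
  # single-member classes surface the downstream precondition error
  tiny <- generate_unit_features(n_classes = 2, separation = 5,
                                 n_per_class = 1, seed = 2)
  expect_error(rf_agreement(tiny), "at least 2 observations")
})
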