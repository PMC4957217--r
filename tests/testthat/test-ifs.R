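# Small planted-signal dataset reused across IFS tests; explicit (C, gamma)
# keeps every 400-step curve cheap and removes grid-search variation.
ifs_data <- generate_dataset(synth_spec(n_pos = 10L, n_neg = 10L,
                                        length_range = c(60L, 120L),
                                        effect = 0.05, seed = 21L))
ifs_fm <- build_feature_matrix(ifs_data$records, ifs_data$labels, g = 6)
ifs_tbl <- fscore_table(ifs_fm)
ifs_cfg <- svm_config(C = 8, gamma = 0.125, folds = 5, seed = 6)
ifs_curve_main <- incremental_feature_selection(ifs_fm, rank_features(ifs_tbl),
                                                ifs_cfg)

test_that("the IFS curve covers every prefix size once, in order", {
  curve <- ifs_curve_main
  expect_s3_class(curve, "ifs_curve")
  expect_identical(curve$points$size, 1:400)
  expect_identical(nrow(curve$points), 400L)
  expect_true(all(curve$points$OA >= 0 & curve$points$OA <= 1))
  # best point is the smallest size attaining the maximum
  expect_identical(curve$best_OA, max(curve$points$OA))
  expect_identical(curve$best_size,
                   min(which(curve$points$OA == curve$best_OA)))
  # prefix-of-everything: the size-400 point is plain CV on the full matrix
  full <- cross_validate(ifs_fm, ifs_cfg)
  expect_identical(curve$points$OA[400L], full$OA)
  # ... and is unchanged if the ranking is reshuffled
  withr::with_seed(1, shuffled <- sample(rank_features(ifs_tbl)))
  curve2 <- incremental_feature_selection(ifs_fm, shuffled, ifs_cfg)
  expect_identical(curve2$points$OA[400L], curve$points$OA[400L])
  # identical seeds give identical curves
  curve3 <- incremental_feature_selection(ifs_fm, rank_features(ifs_tbl),
                                          ifs_cfg)
  expect_identical(curve3$points, curve$points)
})

test_that("rankings that are not permutations are rejected", {
  expect_error(incremental_feature_selection(ifs_fm, 1:399, ifs_cfg),
               "permutation")
  expect_error(incremental_feature_selection(ifs_fm, c(1L, 1:399), ifs_cfg),
               "permutation")
  expect_error(incremental_feature_selection(ifs_fm, rep("AA", 400), ifs_cfg),
               "permutation")
})

test_that("select_optimal_subset returns the smallest argmax prefix", {
  fake <- function(oas) {
    best <- min(which(oas == max(oas)))
    structure(list(g = 6L,
                   points = data.frame(size = seq_along(oas), OA = oas),
                   best_size = best, best_OA = max(oas),
                   ranking = dipeptide_names()[seq_along(oas)]),
              class = "ifs_curve")
  }
  s <- select_optimal_subset(fake(c(0.8, 0.9, 0.9)))
  expect_identical(s$best_size, 2L)
  expect_identical(s$features, dipeptide_names()[1:2])
  expect_identical(select_optimal_subset(fake(c(0.5, 0.7, 0.9)))$best_size, 3L)
  expect_identical(select_optimal_subset(fake(0.6))$best_size, 1L)
  empty <- structure(list(points = data.frame()), class = "ifs_curve")
  expect_error(select_optimal_subset(empty), "non-empty")
})

test_that("planted signal is found by a small subset with high accuracy", {
  curve <- ifs_curve_main
  expect_lte(curve$best_size, 40L)
  expect_gte(curve$best_OA, 0.95)
  # oracle: the known planted features alone already separate the classes
  truth_pairs <- paste0(ifs_data$truth$planted_pairs$first,
                        ifs_data$truth$planted_pairs$second)
  planted_rep <- cross_validate(ifs_fm, ifs_cfg, features = truth_pairs)
  expect_gte(planted_rep$OA, 0.95)
})

test_that("sweep_g returns one curve per usable gap and a global summary", {
  sw <- sweep_g(ifs_data$records, ifs_data$labels, g_values = 6L,
                config = ifs_cfg)
  expect_length(sw$curves, 1L)
  expect_identical(names(sw$curves), "g6")
  expect_identical(sw$best$g, 6L)
  expect_identical(sw$best$OA, sw$curves$g6$best_OA)
  expect_identical(sw$best$features,
                   sw$curves$g6$ranking[seq_len(sw$best$size)])
})

test_that("sweep_g drops too-short sequences per g and can refuse a sweep", {
  recs <- rbind(ifs_data$records,
                data.frame(id = "tiny", sequence = "MKLVAC", length = 6L))
  labels <- c(as.character(ifs_data$labels), "positive")
  expect_warning(sw <- sweep_g(recs, labels, g_values = 6L, config = ifs_cfg),
                 "dropped 1")
  expect_length(sw$curves, 1L)
  short <- data.frame(id = c("a", "b", "c", "d"),
                      sequence = c("MKL", "MKV", "ACD", "ACE"),
                      stringsAsFactors = FALSE)
  expect_error(
    suppressWarnings(sweep_g(short, c(1, 1, 0, 0), g_values = 6L,
                             config = ifs_cfg)),
    "no gap size")
})

test_that("IFS curve TSV and sweep summary JSON exports are faithful", {
  curve <- ifs_curve_main
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ifs_curve(curve, tsv)
  back <- utils::read.delim(tsv)
  expect_identical(nrow(back), 400L)
  expect_equal(back$OA, curve$points$OA, tolerance = 1e-9)
  sw <- structure(list(curves = list(g6 = curve),
                       best = list(g = 6L, size = curve$best_size,
                                   OA = curve$best_OA,
                                   features = curve$ranking[1:2])),
                  class = "ifs_sweep")
  js <- withr::local_tempfile(fileext = ".json")
  write_sweep_summary(sw, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$best$g, 6L)
  expect_equal(parsed$best$OA, curve$best_OA)
})
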