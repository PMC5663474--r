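make_two_species <- function() {
  # p_A = (0.8, 0.2), p_B = (0.3, 0.7) over bins [300,305) and [305,310)
  a <- build_distribution(c(rep(302, 8), rep(307, 2)), range = c(300, 310),
                          label = "A")
  b <- build_distribution(c(rep(302, 3), rep(307, 7)), range = c(300, 310),
                          label = "B")
  reference_library(list(A = a, B = b))
}

test_that("summed likelihood matches a hand-summed oracle and never vetoes", {
  lib <- make_two_species()
  # trace hitting bins (1, 1, 2): score_A = .8+.8+.2, score_B = .3+.3+.7
  s <- mle_likelihoods(c(302, 303, 306), lib)
  expect_equal(unname(s["A"]), 1.8)
  expect_equal(unname(s["B"]), 1.3)
  # an outlier window with zero mass everywhere cannot veto
  s2 <- mle_likelihoods(c(302, 303, 306, 650), lib)
  expect_equal(unname(s2["A"]), 1.8)
  expect_gt(unname(s2["A"]), 0)
  expect_error(mle_likelihoods(numeric(0), lib), "empty")
  s3 <- mle_likelihoods(c(650, 660), lib)
  expect_true(attr(s3, "all_zero"))
})

test_that("species with exclusive support gets all the mass", {
  a <- uniform_dist(300, 350, label = "A")
  b <- uniform_dist(500, 550, label = "B")
  lib <- reference_library(list(A = a, B = b))
  s <- mle_likelihoods(c(310, 320, 330), lib)
  expect_gt(s["A"], 0)
  expect_identical(unname(s["B"]), 0)
  r <- classify_trace(c(310, 320, 330), lib)
  expect_identical(r$predicted_species, "A")
  expect_equal(unname(r$confidence["A"]), 1)
})

test_that("identical distributions tie, broken lexicographically and flagged", {
  a <- uniform_dist(400, 450, label = "zeta")
  b <- uniform_dist(400, 450, label = "alpha")
  lib <- reference_library(list(zeta = a, alpha = b))
  r <- classify_trace(c(410, 420), lib)
  expect_true(r$tie)
  expect_identical(r$predicted_species, "alpha")
})

test_that("location filter restricts candidates and errors loudly", {
  lib <- make_two_species()
  pres <- matrix(c(1, 1, 0, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("KE", "TH")))
  lm <- location_matrix(pres)
  sub <- filter_by_location(lib, lm, "ke")
  expect_identical(sub$species, "A")
  all_in <- filter_by_location(lib, lm, "TH")
  expect_setequal(all_in$species, c("A", "B"))
  expect_error(filter_by_location(lib, lm, "XX"), "unknown country")
  pres0 <- matrix(c(0, 1, 0, 1), nrow = 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("KE", "TH")))
  expect_error(location_matrix(pres0 * 0), "at least one")
})

test_that("a locally absent high scorer is beaten by a present species", {
  # B would win on frequency alone, but is absent from the query country
  a <- build_distribution(c(rep(402, 5), rep(407, 5)), label = "A")
  b <- build_distribution(rep(402, 10), label = "B")
  lib <- reference_library(list(A = a, B = b))
  lm <- location_matrix(matrix(c(1, 0, 1, 1), nrow = 2,
                               dimnames = list(c("A", "B"), c("MG", "TH"))))
  trace <- rep(402, 6)
  unfiltered <- classify_trace(trace, lib)
  expect_identical(unfiltered$predicted_species, "B")
  filtered <- classify_trace(trace, lib, matrix = lm, country = "MG")
  expect_identical(filtered$predicted_species, "A")
  expect_true(filtered$filter_applied)
  # metadata-supplied country works the same way
  meta <- validate_metadata(recording_metadata(country = "mg"))
  via_meta <- classify_trace(trace, lib, matrix = lm, meta = meta)
  expect_identical(via_meta$predicted_species, "A")
})

test_that("all-zero scores yield an explicit unclassifiable result", {
  lib <- make_two_species()
  r <- classify_trace(c(650, 655), lib)
  expect_true(r$unclassifiable)
  expect_equal(unname(r$confidence), rep(0.5, 2))
})

test_that("location matrix CSV round-trips", {
  pres <- matrix(c(1, 0, 1, 1, 1, 1), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("KE", "TH")))
  lm <- location_matrix(pres)
  path <- withr::local_tempfile(fileext = ".csv")
  write_location_csv(lm, path)
  back <- read_location_csv(path)
  expect_equal(back$presence, lm$presence)
})

test_that("bootstrap confusion matrix is column-stochastic and seeded", {
  toy <- toy_library()
  cm <- bootstrap_confusion_matrix(toy$library, toy$raw, n_trials = 300,
                                   subset_size = 60, seed = 9)
  expect_equal(unname(colSums(cm$fractions)), rep(1, 3))
  cm2 <- bootstrap_confusion_matrix(toy$library, toy$raw, n_trials = 300,
                                    subset_size = 60, seed = 9)
  expect_identical(cm$fractions, cm2$fractions)
  expect_error(
    bootstrap_confusion_matrix(toy$library, toy$raw, subset_size = 1e6),
    "subset_size")
})

test_that("a species with no overlap classifies almost perfectly", {
  toy <- toy_library(centers = c(iso = 250, x = 500, y = 520, z = 540))
  cm <- bootstrap_confusion_matrix(toy$library, toy$raw, n_trials = 2000,
                                   subset_size = 60, seed = 17)
  expect_gte(cm$fractions["iso", "iso"], 0.99)
})

test_that("exact duplicate species confuse symmetrically at ~0.5", {
  a <- uniform_dist(400, 500, n = 2000, label = "dupA")
  b <- a; b$label <- "dupB"
  lib <- reference_library(list(dupA = a, dupB = b))
  raw <- list(dupA = rep(seq(402.5, 497.5, by = 5), 100),
              dupB = rep(seq(402.5, 497.5, by = 5), 100))
  cm <- bootstrap_confusion_matrix(lib, raw, n_trials = 10000,
                                   subset_size = 60, seed = 23)
  expect_lt(abs(cm$fractions["dupA", "dupA"] - 0.5), 0.02)
  expect_lt(abs(cm$fractions["dupB", "dupA"] - 0.5), 0.02)
})

test_that("K-fold validation: disjoint folds, near-perfect on disjoint supports", {
  toy <- toy_library(centers = c(A = 260, B = 540))
  cm <- kfold_validation(toy$raw, K = 2, queries_per_fold = 200, seed = 31)
  expect_equal(unname(colSums(cm$fractions)), rep(1, 2))
  expect_gte(cm$fractions["A", "A"], 0.99)
  expect_gte(cm$fractions["B", "B"], 0.99)
  expect_error(kfold_validation(toy$raw, K = 15), "between 2 and 10")
})

test_that("K-fold and bootstrap matrices agree on the same library", {
  toy <- toy_library(centers = c(A = 300, B = 450, C = 480), seed = 207)
  bs <- bootstrap_confusion_matrix(toy$library, toy$raw, n_trials = 1000,
                                   subset_size = 60, seed = 41)
  kf <- kfold_validation(toy$raw, K = 5, queries_per_fold = 200,
                         subset_size = 60, seed = 43)
  expect_lt(max(abs(bs$fractions - kf$fractions)), 0.05)
})

test_that("pairwise distance matrix enumerates all unordered pairs", {
  toy <- toy_library(centers = c(A = 250, B = 350, C = 450, D = 550))
  m <- pairwise_distance_matrix(toy$library)
  expect_equal(attr(m, "n_pairs"), 6)
  expect_true(all(is.na(diag(m))))
  # lower triangle JSD symmetric under swap by construction; check a pair
  expect_equal(m["B", "A"],
               jensen_shannon_divergence(toy$library$distributions$A,
                                         toy$library$distributions$B))
  expect_equal(m["A", "B"],
               bhattacharyya_coefficient(toy$library$distributions$A,
                                         toy$library$distributions$B))
})

test_that("location filtering never hurts a present species' diagonal", {
  toy <- toy_library(centers = c(A = 420, B = 450, C = 480), seed = 303)
  cm_all <- bootstrap_confusion_matrix(toy$library, toy$raw, n_trials = 500,
                                       subset_size = 30, seed = 51)
  # restrict to a country where only A and C occur
  lm <- location_matrix(matrix(c(1, 0, 1, 1, 1, 1), nrow = 3,
                               dimnames = list(c("A", "B", "C"),
                                               c("MG", "TH"))))
  sub <- filter_by_location(toy$library, lm, "MG")
  cm_sub <- bootstrap_confusion_matrix(sub, toy$raw[c("A", "C")],
                                       n_trials = 500, subset_size = 30,
                                       seed = 51)
  expect_gte(cm_sub$fractions["A", "A"] + 1e-9, cm_all$fractions["A", "A"])
  expect_gte(cm_sub$fractions["C", "C"] + 1e-9, cm_all$fractions["C", "C"])
})
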