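test_that("pearson_r matches the textbook formula and guards inputs", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:3, 1:4), "equal length")

  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(100); b <- 0.4 * a + rnorm(100)
    got <- pearson_r(a, b)
    want <- oracle_pearson(a, b)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

make_predictions <- function(whole, odd, even, ids = NULL) {
  dims <- c("int", "dep", "anx", "hos", "pho", "psy")
  n <- nrow(whole)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  purrr::map_dfr(seq_along(dims), function(d) {
    tibble::tibble(
      participant_id = rep(ids, 3),
      dimension = dims[d],
      variant = rep(c("whole", "odd", "even"), each = n),
      .pred = c(whole[, d], odd[, d], even[, d]),
      fold = 1L
    )
  })
}

make_scores <- function(mat, ids = sprintf("P%04d", seq_len(nrow(mat)))) {
  dims <- c("int", "dep", "anx", "hos", "pho", "psy")
  purrr::map_dfr(seq_along(dims), function(d) {
    tibble::tibble(participant_id = ids, dimension = dims[d],
                   raw = mat[, d])
  })
}

test_that("split-half reliability is 1 for identical halves, null for noise", {
  set.seed(3)
  m <- matrix(rnorm(50 * 6), 50, 6)
  preds <- make_predictions(m, m, m)
  rel <- split_half_reliability(preds)
  expect_equal(rel$r1, rep(1, 6))
  expect_equal(rel$r1_spearman_brown, rep(1, 6))

  # independent-noise halves across replicates: centred on zero
  r1s <- replicate(200, {
    odd <- matrix(rnorm(30 * 6), 30, 6)
    even <- matrix(rnorm(30 * 6), 30, 6)
    split_half_reliability(make_predictions(even, odd, even))$r1[1]
  })
  expect_lt(abs(mean(r1s)), 0.05)
  expect_gt(sd(r1s), 0.05)
})

test_that("criterion validity is 1 on itself and null after shuffling", {
  set.seed(4)
  m <- matrix(rnorm(60 * 6), 60, 6)
  preds <- make_predictions(m, m, m)
  scores <- make_scores(m)
  val <- criterion_validity(preds, scores)
  expect_equal(val$r2, rep(1, 6))

  r2s <- replicate(200, {
    shuffled <- m[sample(nrow(m)), ]
    criterion_validity(make_predictions(shuffled, shuffled, shuffled),
                       scores)$r2[1]
  })
  expect_lt(abs(mean(r2s)), 0.05)
})

test_that("the MTMM matrix is symmetric with correctly labelled blocks", {
  set.seed(5)
  m <- matrix(rnorm(40 * 6), 40, 6)
  scores <- make_scores(m + matrix(rnorm(240, sd = 0.5), 40, 6))
  mtmm <- mtmm_matrix(make_predictions(m, m, m), scores)
  expect_s3_class(mtmm, "mtmm_matrix")
  expect_equal(unclass(mtmm), t(unclass(mtmm)), ignore_attr = TRUE)
  expect_equal(unname(diag(mtmm)), rep(1, 12))

  pairs <- tidy(mtmm)
  expect_equal(nrow(pairs), 66)
  expect_equal(sum(pairs$block == "monotrait_heteromethod"), 6)
  expect_equal(sum(pairs$block == "heterotrait_monomethod"), 30)
  expect_equal(sum(pairs$block == "heterotrait_heteromethod"), 30)
  expect_equal(
    pairs$block[pairs$var1 == "INT1" & pairs$var2 == "INT2"],
    "monotrait_heteromethod"
  )
  expect_equal(
    pairs$block[pairs$var1 == "INT1" & pairs$var2 == "DEP1"],
    "heterotrait_monomethod"
  )
  expect_equal(
    pairs$block[pairs$var1 == "INT1" & pairs$var2 == "DEP2"],
    "heterotrait_heteromethod"
  )

  # scores duplicated as predictions: validity diagonal all 1
  preds_dup <- make_predictions(m, m, m)
  mtmm_dup <- mtmm_matrix(preds_dup, make_scores(m))
  expect_equal(validity_diagonal(mtmm_dup)$r, rep(1, 6))
})

test_that("convergent and discriminant verdicts follow strict dominance", {
  build <- function(diag_r, mono = 0.1, hh = 0.1) {
    m <- diag(12)
    v <- facemotion:::.mtmm_vars()
    dimnames(m) <- list(v, v)
    for (i in 1:6) for (j in 1:6) {
      if (i != j) {
        m[i, j] <- mono; m[i + 6, j + 6] <- mono
        m[i, j + 6] <- hh; m[j + 6, i] <- hh
      }
    }
    for (i in 1:6) { m[i, i + 6] <- diag_r[i]; m[i + 6, i] <- diag_r[i] }
    as_mtmm(m)
  }
  all_pass <- build(rep(0.9, 6), mono = 0.1, hh = 0.1)
  expect_true(all(assess_convergent(all_pass)$pass))
  expect_true(all(assess_discriminant(all_pass)$pass))

  all_fail <- build(rep(0, 6), mono = 0.2, hh = 0.2)
  expect_false(any(assess_convergent(all_fail)$pass))
  expect_false(any(assess_discriminant(all_fail)$pass))

  # equality with a triangle entry fails the strict rule
  tie <- build(rep(0.3, 6), mono = 0.3, hh = 0.1)
  expect_false(any(assess_discriminant(tie)$pass))
  expect_true(all(assess_convergent(tie)$pass))
})

test_that("the published reference matrix reproduces its reported verdicts", {
  path <- system.file("extdata", "reference_mtmm.csv", package = "facemotion")
  m <- read_mtmm(path)
  vd <- validity_diagonal(m)
  expect_equal(min(vd$r), 0.26)
  expect_equal(max(vd$r), 0.42)
  expect_equal(vd$r, c(0.38, 0.26, 0.31, 0.42, 0.35, 0.38))

  conv <- assess_convergent(m)
  expect_equal(as.character(conv$dimension[!conv$pass]), "dep")
  disc <- assess_discriminant(m)
  expect_gt(sum(!disc$pass), 0)
})

test_that("statistics are invariant to consistent participant relabelling", {
  set.seed(6)
  m <- matrix(rnorm(30 * 6), 30, 6)
  s <- m + matrix(rnorm(180, sd = 0.7), 30, 6)
  preds <- make_predictions(m, m + 0.1, m - 0.1)
  scores <- make_scores(s)
  base <- evaluate_models(preds, scores)

  perm <- sample(30)
  relabel <- sprintf("Q%04d", seq_len(30))
  preds2 <- preds
  preds2$participant_id <- relabel[match(preds$participant_id,
                                         sprintf("P%04d", 1:30))]
  scores2 <- scores
  scores2$participant_id <- relabel[match(scores$participant_id,
                                          sprintf("P%04d", 1:30))]
  other <- evaluate_models(preds2, scores2)
  expect_equal(base$reliability$r1, other$reliability$r1)
  expect_equal(base$validity$r2, other$validity$r2)
  expect_equal(unclass(base$mtmm), unclass(other$mtmm))
})

test_that("evaluation objects tidy and plot cleanly", {
  set.seed(7)
  m <- matrix(rnorm(30 * 6), 30, 6)
  preds <- make_predictions(m, m + rnorm(180, sd = 0.3),
                            m + rnorm(180, sd = 0.3))
  scores <- make_scores(m + matrix(rnorm(180, sd = 0.8), 30, 6))
  ev <- evaluate_models(preds, scores)
  td <- tidy(ev)
  expect_equal(nrow(td), 6)
  expect_true(all(c("r1", "r2", "convergent", "discriminant") %in% names(td)))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(ev$mtmm), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("the dependent-correlation z test behaves sensibly", {
  same <- steiger_z(0.4, 0.4, 0.3, 100)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  diff_big <- steiger_z(0.7, 0.1, 0.3, 100)
  expect_gt(diff_big$z, 0)
  expect_lt(diff_big$p, 0.001)
  expect_equal(steiger_z(0.1, 0.7, 0.3, 100)$z, -diff_big$z)
  expect_error(steiger_z(0.5, 0.4, 0.3, 3), "n >= 4")

  # near-nominal size under a simulated null of dependent correlations
  set.seed(202)
  n <- 120
  rej <- replicate(400, {
    j <- rnorm(n)
    k <- 0.4 * j + rnorm(n, sd = sqrt(1 - 0.16))
    h <- 0.4 * j + rnorm(n, sd = sqrt(1 - 0.16))
    st <- steiger_z(cor(j, k), cor(j, h), cor(k, h), n)
    st$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
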