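test_that("path-outcome cross-tabulation counts patients exactly", {
  fus <- read_fusions(data.frame(patient_id = sprintf("p%d", 1:6),
                                 uiv = "T4", liv = "L1"))
  g <- assign_fusion_groups(fus)
  po <- setNames(rep(3L, 6), fus$patient_id)
  ep <- setNames(rep(1L, 6), fus$patient_id)
  y2 <- setNames(c(1L, 1L, 1L, 1L, 1L, 2L), fus$patient_id)
  tab <- path_outcome_table(build_paths(po, ep, g), y2)
  expect_identical(unname(tab[1, ]), c(5L, 1L))
  expect_identical(rownames(tab), "PO3-EP1-F1")

  expect_error(path_outcome_table(build_paths(po, ep, g), y2[-3]),
               "no 2Y cluster label")
})

test_that("the reference path table carries the published marginals", {
  tab <- reference_path_outcomes()
  expect_identical(nrow(tab), 17L)
  expect_identical(sum(tab), 64L)
  expect_identical(unname(tab["PO3-EP1-F6", ]), c(5L, 1L, 0L))
})

test_that("saturated-path LR chi-square has its closed-form values", {
  # diagonal 2x2: chi-square = 40 ln 2, df = (2-1)(2-1) = 1
  po <- rep(1:2, each = 10); ep <- rep(1, 20); fg <- rep(1, 20)
  y2 <- rep(1:2, each = 10)
  fit <- fit_multinomial(po, ep, fg, y2, encoding = "saturated")
  expect_equal(fit$lr$chi_square, 40 * log(2), tolerance = 1e-12)
  expect_identical(fit$lr$df, 1L)
  expect_true(fit$separation)   # zero cells imply infinite logits

  # perfectly independent table: chi-square = 0
  po0 <- rep(1:2, each = 10)
  y20 <- rep(rep(1:2, each = 5), 2)
  fit0 <- fit_multinomial(po0, rep(1, 20), rep(1, 20), y20,
                          encoding = "saturated")
  expect_equal(fit0$lr$chi_square, 0, tolerance = 1e-12)
  expect_false(fit0$separation)
})

test_that("saturated-path LR equals the contingency G-statistic on random tables", {
  set.seed(14)
  for (rep in 1:20) {
    npath <- sample(2:6, 1); K <- sample(2:3, 1)
    m <- matrix(rpois(npath * K, 3), npath, K)
    m[1, ] <- m[1, ] + 1          # keep every path and outcome populated
    m[, 1] <- m[, 1] + 1
    if (any(rowSums(m) == 0) || sum(colSums(m) > 0) < 2) next
    po <- rep(seq_len(npath), rowSums(m))
    y2 <- unlist(lapply(seq_len(npath), function(i) rep(seq_len(K), m[i, ])))
    fit <- fit_multinomial(po, rep(1, length(po)), rep(1, length(po)), y2,
                           encoding = "saturated")
    expect_equal(fit$lr$chi_square, oracle_g_statistic(m), tolerance = 1e-10)
  }
})

test_that("main-effects multinomial fit yields valid probabilities and df", {
  set.seed(5)
  n <- 120
  po <- sample(1:3, n, TRUE); ep <- sample(1:2, n, TRUE)
  fg <- sample(1:4, n, TRUE)
  # outcome depends weakly on po
  y2 <- ifelse(runif(n) < 0.3 + 0.2 * (po == 1), 1, sample(2:3, n, TRUE))
  fit <- fit_multinomial(po, ep, fg, y2, encoding = "main")
  # df = ((3-1) + (2-1) + (4-1)) * (K-1)
  expect_identical(fit$lr$df, 6L * (length(unique(y2)) - 1L))
  expect_gte(fit$lr$chi_square, 0)
  pr <- predict(fit$model, type = "probs")
  expect_equal(unname(rowSums(pr)), rep(1, n), tolerance = 1e-10)
  # the model-based predictor returns a class for every seen triple
  pred <- predict_outcome(data.frame(po = po, ep = ep, fusion_group = fg), fit)
  expect_true(all(pred$status %in% c("ok", "ambiguous")))
  expect_true(all(pred$outcome %in% sort(unique(y2))))
  # an unseen factor level yields an explicit no-data result
  unseen <- predict_outcome(data.frame(po = 9, ep = 1, fusion_group = 1), fit)
  expect_identical(unseen$status, "no-data")
})

test_that("concordance reports per-path majorities, rounding and coverage", {
  tab <- as_path_outcome_table(rbind(c(5, 1, 0), c(1, 1, 0), c(0, 0, 4)),
                               c("PO3-EP1-F6", "PO1-EP1-F1", "PO2-EP2-F3"))
  cc <- concordance(tab, min_path_n = 3L)
  expect_identical(cc$n_paths, 2L)
  p1 <- cc$per_path[cc$per_path$path == "PO3-EP1-F6", ]
  expect_identical(as.integer(p1$majority), 1L)
  expect_identical(p1$percent, 83)          # 5/6 rounds to 83%
  p2 <- cc$per_path[cc$per_path$path == "PO2-EP2-F3", ]
  expect_identical(p2$percent, 100)
  expect_identical(cc$patients_covered, 10L)
  expect_equal(cc$coverage, 10 / 12)
})

test_that("empirical outcome prediction is modal with explicit no-data and ties", {
  tab <- reference_path_outcomes()
  expect_identical(predict_outcome("PO3-EP1-F6", tab)$outcome, 1L)
  expect_identical(predict_outcome("PO9-EP9-F9", tab)$status, "no-data")
  tie <- as_path_outcome_table(matrix(c(3, 3, 0), 1), "PO1-EP1-F1")
  res <- predict_outcome("PO1-EP1-F1", tie)
  expect_identical(res$outcome, 1L)         # tie broken toward lower index
  expect_identical(res$status, "ambiguous")
})
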