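test_that("connectivity strength is an area-weighted mean with closed forms", {
  tmat <- matrix(c(1, 3), 1, 2)
  tmat <- rbind(tmat, tmat) # Q = 2
  mask <- matrix(TRUE, 2, 2)
  expect_equal(unname(connectivity_strength(tmat, mask, c(3, 1))),
               c(1.5, 1.5))
  # constant t on the mask is returned whatever the areas
  tc <- matrix(4.2, 2, 10)
  expect_equal(unname(connectivity_strength(tc, matrix(TRUE, 2, 10),
                                            runif(10, 0.5, 2))),
               c(4.2, 4.2))
})

test_that("connectivity strength matches a naive loop and scales out area units", {
  tmat <- withr::with_seed(1, matrix(rnorm(3 * 50), 3, 50))
  mask <- withr::with_seed(2, matrix(runif(150) < 0.5, 3, 50))
  area <- withr::with_seed(3, runif(50, 0.5, 3))
  got <- connectivity_strength(tmat, mask, area)
  oracle <- sapply(1:3, function(q) {
    num <- den <- 0
    for (v in 1:50) if (mask[q, v]) {
      num <- num + area[v] * tmat[q, v]; den <- den + area[v]
    }
    num / den
  })
  expect_equal(unname(got), oracle)
  expect_equal(connectivity_strength(tmat, mask, area * 100), got)
  # empty mask -> flagged undefined with a warning, not zero
  mask[2, ] <- FALSE
  expect_warning(s2 <- connectivity_strength(tmat, mask, area), "IC2")
  expect_true(is.na(s2[2]) && !is.na(s2[1]))
})

test_that("partial Spearman recovers a planted monotone effect", {
  withr::with_seed(4, {
    x <- rnorm(50)
    y <- exp(x) # strictly increasing in x
    covs <- cbind(rnorm(50), rnorm(50))
    res <- partial_spearman(x, y, covs)
    expect_gt(res$rho, 0.95)
    expect_lt(res$p, 1e-6)
    expect_equal(res$df, 50 - 2 - 2)
  })
})

test_that("without covariates partial Spearman is classical Spearman", {
  withr::with_seed(5, {
    x <- rnorm(40); y <- rnorm(40) # continuous: no ties
    res <- partial_spearman(x, y)
    expect_equal(res$rho, spearman_direct(x, y), tolerance = 1e-12)
    expect_equal(res$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  })
})

test_that("partial Spearman is invariant under increasing transforms", {
  withr::with_seed(6, {
    x <- rexp(30); y <- rnorm(30); covs <- cbind(rnorm(30))
    a <- partial_spearman(x, y, covs)
    b <- partial_spearman(log(x), exp(y / 3), covs)
    expect_equal(a$rho, b$rho, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  })
})

test_that("partial Spearman guards degenerate inputs and drops incomplete rows", {
  expect_error(partial_spearman(1:4, 1:4, cbind(1:4)), "K \\+ 4")
  expect_warning(res <- partial_spearman(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(res$rho))
  x <- c(1:9, NA)
  expect_message(res2 <- partial_spearman(x, 1:10), "dropped 1")
  expect_equal(res2$n, 9L)
})

test_that("the age table has one row per network with Bonferroni columns", {
  withr::with_seed(7, {
    n <- 40
    cohort <- tibble::tibble(
      age_pma_weeks = runif(n, 37, 45), sex = rbinom(n, 1, 0.5),
      motion = rgamma(n, 2),
      strength_IC1 = 0.5 * age_pma_weeks + rnorm(n),
      strength_IC2 = rnorm(n)
    )
    tab <- age_association_table(cohort)
    expect_equal(nrow(tab), 2L)
    expect_named(tab, c("ic", "rho", "p", "p_bonferroni", "n"))
    expect_true(all(tab$p_bonferroni >= tab$p))
    expect_lt(tab$p[tab$ic == "IC1"], 0.001)
    expect_gt(tab$rho[tab$ic == "IC1"], 0.5)
  })
})

test_that("networks with too few complete records are skipped with a warning", {
  withr::with_seed(8, {
    cohort <- tibble::tibble(
      age_pma_weeks = runif(20, 37, 45), sex = rbinom(20, 1, 0.5),
      motion = rgamma(20, 2),
      strength_IC1 = rnorm(20),
      strength_IC2 = c(rnorm(5), rep(NA, 15))
    )
    expect_warning(tab <- age_association_table(cohort), "IC2")
    expect_equal(tab$ic, "IC1")
  })
})

test_that("frequency maps report the modal label and its prevalence", {
  p1 <- wta_parcellation(rbind(c(3, 3), c(1, 1)))
  fm <- frequency_map(list(p1, p1, p1))
  expect_equal(fm$dominant_pct, c(100, 100))
  p2 <- wta_parcellation(rbind(c(0, 0), c(2, 2)))
  fm2 <- frequency_map(list(p1, p2))
  expect_equal(fm2$dominant_pct, c(50, 50))
  expect_equal(fm2$dominant_label, c(1L, 1L)) # modal tie -> lowest label
})

test_that("random labelings stay in the multinomial agreement band", {
  n <- 300; q <- 3; v <- 50
  parcs <- withr::with_seed(9, lapply(1:n, function(i) {
    structure(list(labels = sample.int(q, v, replace = TRUE),
                   n_networks = q, source = "x",
                   analysis_mask = rep(TRUE, v)),
              class = "parcellation")
  }))
  fm <- frequency_map(parcs)
  # dominant share of a uniform trinomial with n=300 concentrates in 33-45%
  expect_true(all(fm$dominant_pct >= 100 / q - 1e-9))
  expect_true(all(fm$dominant_pct < 48))
  expect_equal(fm$n_subjects, n)
})

test_that("cohort assembly joins covariates and strengths by subject", {
  covs <- tibble::tibble(subject_id = c("a", "b"), age_pma_weeks = c(38, 42),
                         sex = c(0, 1), motion_level = c(3, 1))
  s <- rbind(c(IC1 = 1, IC2 = 2), c(IC1 = 3, IC2 = 4))
  tab <- cohort_table(covs, s)
  expect_named(tab, c("subject_id", "age_pma_weeks", "sex", "motion",
                      "strength_IC1", "strength_IC2"))
  expect_equal(tab$strength_IC2, c(2, 4))
  expect_error(cohort_table(covs, s[1, , drop = FALSE]), "disagree")
})
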