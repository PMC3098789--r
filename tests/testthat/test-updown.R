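test_that("EM recovers a well-separated two-gamma mixture", {
  set.seed(7)
  x <- c(rgamma(1000, shape = 2, scale = 1),
         rgamma(1000, shape = 8, scale = 1))
  fit <- fit_gamma_mixture(x)
  expect_false(fit$degenerate)
  expect_true(fit$converged)
  mean_down <- fit$shape_down * fit$scale_down
  mean_up <- fit$shape_up * fit$scale_up
  expect_lt(abs(mean_down - 2) / 2, 0.1)
  expect_lt(abs(mean_up - 8) / 8, 0.1)
  expect_lt(abs(fit$weight_down - 0.5), 0.05)
  # component ordering invariant
  expect_lte(mean_down, mean_up)
})

test_that("degenerate and undersized inputs are handled as specified", {
  fit <- fit_gamma_mixture(rep(5, 20))
  expect_true(fit$degenerate)
  expect_error(fit_gamma_mixture(c(1, 2, 3)), "at least 8")
  expect_error(fit_gamma_mixture(c(rep(1, 10), NA)), "finite")
  expect_error(posterior_up(1, fit), "degenerate")
})

test_that("two-component fit dominates the single-gamma MLE", {
  set.seed(11)
  x <- rgamma(2000, shape = 4, scale = 1)
  fit2 <- fit_gamma_mixture(x)
  # independent single-component oracle: direct MLE by optimizing the
  # gamma log-likelihood
  nll <- function(par) -sum(dgamma(x, shape = exp(par[1]),
                                   scale = exp(par[2]), log = TRUE))
  opt <- optim(c(log(4), log(1)), nll)
  ll1 <- -opt$value
  expect_gte(fit2$loglik, ll1 - 1e-6)
})

test_that("posterior matches the closed-form density ratio", {
  fit <- structure(list(weight_down = 0.5, shape_down = 2, scale_down = 1,
                        shape_up = 8, scale_up = 1, degenerate = FALSE),
                   class = "gamma_mixture_fit")
  # hand-computed density ratio at x = 4
  x <- 4
  gd <- dgamma(x, 2, scale = 1); gu <- dgamma(x, 8, scale = 1)
  expect_equal(posterior_up(x, fit), 0.5 * gu / (0.5 * gd + 0.5 * gu),
               tolerance = 1e-12)
  # equal-likelihood point gives exactly 0.5: solve w*gd(x) = (1-w)*gu(x)
  xeq <- uniroot(function(z) dgamma(z, 2, scale = 1) -
                   dgamma(z, 8, scale = 1), c(2, 8))$root
  expect_equal(posterior_up(xeq, fit), 0.5, tolerance = 1e-6)
  # likelihood-ratio limit for large x
  expect_gt(posterior_up(40, fit), 0.999)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(3)
  for (rep in 1:5) {
    x <- c(rgamma(150, 2, scale = 1), rgamma(150, 8, scale = 1))
    fit <- fit_gamma_mixture(x)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  }
})

test_that("posterior is monotone in x in the MLR regime", {
  fit <- structure(list(weight_down = 0.4, shape_down = 2, scale_down = 1,
                        shape_up = 6, scale_up = 1.5, degenerate = FALSE),
                   class = "gamma_mixture_fit")
  xs <- seq(0.01, 50, length.out = 400)
  expect_true(all(diff(posterior_up(xs, fit)) >= -1e-12))
})

test_that("posteriors are invariant to intensity rescaling", {
  set.seed(5)
  x <- c(rgamma(100, 2, scale = 1), rgamma(100, 8, scale = 1))
  f1 <- fit_gamma_mixture(x)
  p1 <- posterior_up(x, f1)
  for (c_mult in c(0.01, 7, 1000)) {
    f2 <- fit_gamma_mixture(c_mult * x)
    p2 <- posterior_up(c_mult * x, f2)
    expect_equal(p2, p1, tolerance = 1e-6)
  }
})

test_that("updown_normalize has correct shape, bounds and defaults", {
  set.seed(9)
  gen <- generate_expression(100, 50)
  res <- updown_normalize(gen$expr)
  expect_equal(dim(res$probs), dim(gen$expr))
  expect_true(all(res$probs >= 0 & res$probs <= 1))
  expect_equal(nrow(res$fits), 100L)

  # constant probeset row yields the 0.5 default
  expr <- gen$expr
  expr["p1", ] <- 3.14
  res2 <- updown_normalize(expr)
  expect_true(res2$fits$degenerate[res2$fits$probeset_id == "p1"])
  expect_equal(unname(res2$probs["p1", ]), rep(0.5, 50))

  expect_error(updown_normalize(gen$expr[, 1:4]), "at least")
  expect_error(updown_normalize(unname(gen$expr)), "rownames")
})

test_that("well-separated modes give confident posteriors", {
  set.seed(13)
  n <- 60
  up <- runif(n) > 0.5
  x <- ifelse(up, rgamma(n, shape = 20, scale = 1),
              rgamma(n, shape = 2, scale = 1))
  expr <- matrix(x, 1, n, dimnames = list("p1", paste0("s", 1:n)))
  expr <- rbind(expr, expr)   # min 2 rows for matrix path
  rownames(expr) <- c("p1", "p2")
  res <- updown_normalize(expr)
  expect_true(all(res$probs["p1", up] > 0.9))
  expect_true(all(res$probs["p1", !up] < 0.1))
})

test_that("matrix engine agrees with the single-vector interface", {
  set.seed(17)
  gen <- generate_expression(20, 40)
  res <- updown_normalize(gen$expr)
  for (i in c(1, 10, 20)) {
    fit <- fit_gamma_mixture(gen$expr[i, ])
    expect_equal(res$fits$loglik[i], fit$loglik, tolerance = 1e-8)
    expect_equal(res$fits$shape_up[i], fit$shape_up, tolerance = 1e-6)
  }
})

test_that("weight recovery is accurate over seeded replicates", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- c(rgamma(500, 2, scale = 1), rgamma(500, 8, scale = 1))
    abs(fit_gamma_mixture(x)$weight_down - 0.5)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("expression matrix text round-trip is faithful", {
  set.seed(1)
  gen <- generate_expression(5, 10)
  f <- tempfile()
  write_matrix_tsv(gen$expr, f, id_col = "probeset_id")
  back <- read_expression_matrix(f)
  expect_equal(back, gen$expr, tolerance = 1e-12)
})
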