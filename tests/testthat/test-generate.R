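test_that("cell-type proportions are estimated as label frequencies", {
  expect_equal(estimate_proportions(c("A", "A", "B", "B")),
               c(A = 0.5, B = 0.5))
  expect_equal(estimate_proportions(rep("T", 3793)), c(T = 1))
  expect_error(estimate_proportions(character(0)), "at least one")
  # registry order is respected
  expect_equal(names(estimate_proportions(c("B", "A"), levels = c("A", "B"))),
               c("A", "B"))
})

test_that("multinomial allocation sums to n' and matches its moments", {
  expect_equal(draw_cell_type_counts(10, c(T = 1)), c(T = 10L))
  one <- draw_cell_type_counts(1, c(A = 0.3, B = 0.7))
  expect_equal(sum(one), 1L)

  set.seed(21)
  draws <- replicate(10000, draw_cell_type_counts(100, c(A = 0.3, B = 0.7)))
  expect_true(all(colSums(draws) == 100))
  se <- sqrt(100 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(draws["A", ]) - 30), 3 * se)
})

test_that("depth allocation follows the worked rescaling arithmetic", {
  fake_model <- function(type, N, n) {
    structure(list(cell_type = type, n_cells = n, total_count = N),
              class = "cell_type_model")
  }
  models <- list(fake_model("A", 100, 10), fake_model("B", 300, 30))
  plan <- make_allocation_plan(models, c(20, 30), N_prime = 1000)
  expect_equal(plan$depth_unscaled, c(200, 300))
  expect_equal(attr(plan, "scale_factor"), 2)
  expect_equal(plan$depth_scaled, c(400, 600))

  # identity design: n' = n and N' = N per type gives r = 1 exactly
  plan1 <- make_allocation_plan(models, c(10, 30), N_prime = 400)
  expect_equal(attr(plan1, "scale_factor"), 1)

  # random designs: scaled depths always sum to N'
  set.seed(22)
  for (i in 1:10) {
    K <- sample(2:5, 1)
    ms <- lapply(seq_len(K), function(k) {
      fake_model(paste0("t", k), runif(1, 100, 1e5), sample(10:500, 1))
    })
    nk <- sample(0:50, K, replace = TRUE)
    if (sum(nk) == 0) nk[1] <- 1
    Np <- runif(1, 1e3, 1e6)
    pl <- make_allocation_plan(ms, nk, Np)
    expect_equal(sum(pl$depth_scaled), Np, tolerance = 1e-9)
  }

  expect_error(make_allocation_plan(models, c(0, 0), 100), "at least one",
               ignore.case = TRUE)
})

test_that("generate_cell_type honours the rescaled model", {
  spec <- ground_truth_spec(n_group1 = 8, n_group2 = 2, n_group3 = 2,
                            families = c("NB", "ZINB"),
                            corr = "identity", n_cells = 500, seed = 5)
  gt <- make_ground_truth_model(spec)
  set.seed(23)
  r <- 1.7
  X <- generate_cell_type(gt, 5000, scale_factor = r)
  expect_equal(dim(X), c(12, 5000))

  # group3 rows identically zero
  expect_true(all(X[gt$partition$group3, ] == 0))

  # per-gene mean matches (1 - p) r mu within 3 SE
  for (i in c(gt$partition$group1, gt$partition$group2)) {
    m <- gt$marginals[[gt$gene_names[i]]]
    mu_scaled <- m
    mu_scaled$mu <- m$mu * r
    mom <- marginal_moments(mu_scaled)
    se <- sqrt(mom[["var"]] / 5000)
    expect_lt(abs(mean(X[i, ]) - mom[["mean"]]), 3.5 * se)
  }

  # identity copula: pairwise tau of group1 genes near zero
  taus <- kendall_tau_matrix(X[gt$partition$group1, 1:2000])
  expect_lt(max(abs(taus[upper.tri(taus)])), 0.07)

  expect_error(generate_cell_type(gt, 10, scale_factor = 0), "positive")
})

test_that("generated correlations match the model via the tau link", {
  spec <- ground_truth_spec(n_group1 = 6, corr = list(type = "exchangeable",
                                                      rho = 0.6),
                            families = c("NB", "POISSON"),
                            mu_range = c(5, 15), n_cells = 500, seed = 6)
  gt <- make_ground_truth_model(spec)
  set.seed(24)
  X <- generate_cell_type(gt, 5000)
  tau_hat <- kendall_tau_matrix(X[gt$partition$group1, ])
  implied_R <- tau_to_copula_corr(tau_hat)
  off <- upper.tri(implied_R)
  # counts are discrete, so the attainable tau is attenuated relative to the
  # continuous-margin link; agreement is within a small systematic gap
  expect_lt(mean(abs(implied_R[off] - 0.6)), 0.1)
})

test_that("simulate_counts respects design, labels and determinism", {
  demo <- make_demo_matrix()
  model <- suppressWarnings(fit_count_model(demo$X, demo$labels))
  N <- sum(demo$X)

  sim <- simulate_counts(model, n_prime = 120, N_prime = N, seed = 9)
  expect_equal(ncol(sim$counts), 120)
  expect_equal(nrow(sim$counts), nrow(demo$X))
  expect_setequal(unique(sim$cell_type), c("alpha", "beta"))
  expect_equal(as.vector(table(sim$cell_type)[unique(sim$cell_type)]),
               sim$plan$n_out[match(unique(sim$cell_type),
                                    sim$plan$cell_type)])
  expect_identical(colnames(sim$counts),
                   paste0(sim$cell_type, ".",
                          unlist(lapply(table(sim$cell_type)[unique(sim$cell_type)],
                                        seq_len), use.names = FALSE)))

  # identical seed, identical output
  sim2 <- simulate_counts(model, n_prime = 120, N_prime = N, seed = 9)
  expect_identical(sim$counts, sim2$counts)
  sim3 <- simulate_counts(model, n_prime = 120, N_prime = N, seed = 10)
  expect_false(identical(sim$counts, sim3$counts))

  # no-copula variant keeps marginals but drops dependence
  simnc <- simulate_counts(model, n_prime = 120, N_prime = N, seed = 9,
                           use_copula = FALSE)
  expect_equal(dim(simnc$counts), dim(sim$counts))
})

test_that("expected grand total tracks N' and scales linearly", {
  spec <- ground_truth_spec(n_group1 = 10, corr = "identity",
                            families = c("NB", "POISSON"), n_cells = 200,
                            seed = 8)
  gt <- make_ground_truth_model(spec)
  model <- structure(
    list(models = list(fixture = gt), cell_types = "fixture",
         proportions = c(fixture = 1)),
    class = "count_model"
  )
  N_target <- 60000
  set.seed(31)
  totals <- replicate(100, sum(simulate_counts(model, n_prime = 50,
                                               N_prime = N_target)$counts))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - N_target), 3 * se)

  # doubling N' doubles per-gene expected counts
  set.seed(32)
  lo <- generate_cell_type(gt, 5000, scale_factor = 1)
  hi <- generate_cell_type(gt, 5000, scale_factor = 2)
  ratio <- rowMeans(hi)[1:10] / rowMeans(lo)[1:10]
  expect_equal(unname(ratio), rep(2, 10), tolerance = 0.1)
})

test_that("one-type identity round trip reproduces training means", {
  demo <- make_demo_matrix(n_per_type = 150)
  X <- demo$X[, demo$labels == "beta"]
  model <- fit_cell_type_model(X, "beta")
  cm <- structure(list(models = list(beta = model), cell_types = "beta",
                       proportions = c(beta = 1)), class = "count_model")
  sim <- simulate_counts(cm, n_prime = ncol(X), N_prime = sum(X), seed = 13)
  expect_equal(attr(sim$plan, "scale_factor"), 1)
  expect_equal(rowMeans(sim$counts), rowMeans(X), tolerance = 0.25)
})
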