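test_that("build_matrix returns the design-ordered complete matrix", {
  sim <- simulate_experiment(simulation_config(), seed = 5)
  scores <- build_score_table(sim$records, sim$config$design)
  m <- build_matrix(scores, 37)
  expect_equal(dim(m), c(10L, 6L))
  expect_identical(rownames(m), sim$config$design$genotypes)
  expect_identical(colnames(m), sim$config$design$carbons)
  expect_equal(attr(m, "temperature_c"), 37)
  expect_identical(unclass(m), unclass(build_matrix(scores, 37)))

  dropped <- scores[!(scores$genotype == "MA03" &
                        scores$carbon == "glucose" &
                        scores$temperature_c == 37), ]
  attr(dropped, "design") <- sim$config$design
  expect_error(build_matrix(dropped, 37), "MA03.*glucose")
  expect_error(build_matrix(scores, 24), "not in the design")
})

test_that("environmental statistics match hand arithmetic", {
  st <- env_stats(proportional_matrix())
  expect_equal(unname(st$sigma_E), c(sqrt(0.02), sqrt(0.08)),
               tolerance = 1e-12)
  expect_equal(st$rho[1, 2], 1, tolerance = 1e-12)
  st <- env_stats(mirrored_matrix())
  expect_equal(st$rho[1, 2], -1, tolerance = 1e-12)
})

test_that("worked 2x2 fixtures give the hand-computed R and I", {
  # mirrored profiles: equal sigmas, rho = -1 -> pure inconsistency
  p <- partition_components(mirrored_matrix())
  expect_equal(p$responsiveness, 0, tolerance = 1e-12)
  expect_equal(p$inconsistency, 0.04, tolerance = 1e-12)
  expect_equal(p$sigma2_GE, 0.04, tolerance = 1e-12)
  expect_equal(p$sigma2_G, 0, tolerance = 1e-12)
  expect_equal(p$sigma2_E, 0, tolerance = 1e-12)
  expect_equal(unname(pairwise_oracle(mirrored_matrix())),
               c(0, 0.04, 0.04), tolerance = 1e-12)

  # proportional profiles: rho = 1 -> pure responsiveness
  p <- partition_components(proportional_matrix())
  expect_equal(p$responsiveness, 0.01, tolerance = 1e-12)
  expect_equal(p$inconsistency, 0, tolerance = 1e-12)
})

test_that("additive and constant matrices carry no interaction", {
  a <- c(0.1, -0.2, 0.05); b <- c(-0.1, 0, 0.1, 0.2)
  m <- outer(a, b, "+")
  p <- partition_components(m)
  expect_equal(p$sigma2_GE, 0, tolerance = 1e-15)
  expect_equal(p$responsiveness, 0, tolerance = 1e-15)
  expect_equal(p$inconsistency, 0, tolerance = 1e-15)
  expect_equal(p$sigma2_G, var(a), tolerance = 1e-12)
  expect_equal(p$sigma2_E, var(b), tolerance = 1e-12)

  p0 <- suppressWarnings(partition_components(matrix(0.3, 4, 5)))
  expect_true(all(abs(unlist(p0[-1])) < 1e-15))
})

test_that("decomposition identity and oracle agreement hold on random matrices", {
  for (k in 1:60) {
    g <- sample(2:12, 1); e <- sample(2:8, 1)
    m <- random_gxe_matrix(g, e, seed = k)
    p <- partition_components(m)
    expect_equal(p$responsiveness + p$inconsistency, p$sigma2_GE,
                 tolerance = 1e-9)
    o <- pairwise_oracle(m)
    expect_equal(p$responsiveness, unname(o["R"]), tolerance = 1e-10)
    expect_equal(p$inconsistency, unname(o["I"]), tolerance = 1e-10)
    expect_equal(p$sigma2_GE, unname(o["sigma2_GE"]), tolerance = 1e-10)
    expect_equal(p$total, p$sigma2_G + p$sigma2_E + p$sigma2_GE,
                 tolerance = 1e-12)
  }
})

test_that("components respond only to the effects that feed them", {
  m <- random_gxe_matrix(6, 5, seed = 99)
  p <- partition_components(m)
  num <- function(x) unlist(x[c("total", "sigma2_G", "sigma2_E",
                                "sigma2_GE", "responsiveness",
                                "inconsistency")])
  # whole-matrix constant: nothing changes
  expect_equal(num(partition_components(m + 0.37)), num(p),
               tolerance = 1e-10)
  # genotype-specific constants: only sigma2_G (and total) move
  pg <- partition_components(m + c(0.1, -0.3, 0.2, 0, 0.05, -0.1))
  expect_equal(pg$sigma2_E, p$sigma2_E, tolerance = 1e-10)
  expect_equal(pg$sigma2_GE, p$sigma2_GE, tolerance = 1e-10)
  expect_equal(pg$responsiveness, p$responsiveness, tolerance = 1e-10)
  expect_equal(pg$inconsistency, p$inconsistency, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pg$sigma2_G, p$sigma2_G)))
  # carbon-specific constants: sigma2_G and sigma2_GE stay put (the R/I
  # split within sigma2_GE may shift, their sum may not)
  pe <- partition_components(m + rep(c(0.2, -0.1, 0, 0.3, -0.2), each = 6))
  expect_equal(pe$sigma2_G, p$sigma2_G, tolerance = 1e-10)
  expect_equal(pe$sigma2_GE, p$sigma2_GE, tolerance = 1e-10)
  expect_equal(pe$responsiveness + pe$inconsistency, p$sigma2_GE,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pe$sigma2_E, p$sigma2_E)))
  # permutation invariance
  pp <- partition_components(m[sample(6), sample(5)])
  expect_equal(num(pp), num(p), tolerance = 1e-10)
})

test_that("zero-variance genotype profiles are flagged and I stays defined", {
  m <- rbind(g1 = c(0.1, 0.1, 0.1), g2 = c(0.2, -0.1, 0.05),
             g3 = c(-0.3, 0.1, 0.2))
  expect_warning(st <- env_stats(m), "zero environmental variance")
  expect_true(is.na(st$rho[1, 2]) && is.na(st$rho[2, 1]))
  expect_false(is.na(st$rho[2, 3]))
  suppressWarnings({
    p <- partition_components(m)
    o <- pairwise_oracle(m)
  })
  expect_true(is.finite(p$inconsistency))
  expect_equal(p$responsiveness + p$inconsistency, p$sigma2_GE,
               tolerance = 1e-9)
  expect_equal(p$inconsistency, unname(o["I"]), tolerance = 1e-10)
})

test_that("incomplete or degenerate matrices are refused", {
  m <- random_gxe_matrix(3, 3, seed = 1)
  m[2, 2] <- NA
  expect_error(partition_components(m), "incomplete")
  expect_error(partition_components(matrix(1, 1, 3)), "G >= 2")
  expect_error(env_stats(matrix(1, 3, 1)), "2 columns")
})
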