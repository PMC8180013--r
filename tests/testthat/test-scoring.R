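test_that("blank subtraction clamps at zero", {
  expect_equal(subtract_blank(250, 40), 210)
  expect_equal(subtract_blank(40, 40), 0)
  expect_equal(subtract_blank(30, 40), 0)
  expect_error(subtract_blank(-1, 0), "non-negative")
})

test_that("replicate averaging is the arithmetic mean and rejects empties", {
  expect_equal(average_replicates(c(210, 200, 190)), 200)
  expect_equal(average_replicates(c(0, 0, 0)), 0)
  expect_equal(average_replicates(137.5), 137.5)
  expect_error(average_replicates(numeric(0), cell = "A/c1/31"), "A/c1/31")
})

test_that("relative growth score matches hand arithmetic and is antisymmetric", {
  expect_equal(relative_growth_score(99, 199), log10(100 / 200),
               tolerance = 1e-12)
  expect_equal(relative_growth_score(199, 99), log10(200 / 100),
               tolerance = 1e-12)
  expect_equal(relative_growth_score(0, 0), 0)
  for (x in c(0, 1, 137.5, 2000)) expect_equal(relative_growth_score(x, x), 0)

  set.seed(1)
  a <- runif(50, 0, 2000); b <- runif(50, 0, 2000)
  expect_equal(relative_growth_score(a, b), -relative_growth_score(b, a),
               tolerance = 1e-15)
  # strictly increasing in the MA net at fixed ancestor net
  xs <- sort(runif(50, 0, 2000))
  expect_true(all(diff(relative_growth_score(xs, 500)) > 0))
  # bounded for realistic mOD ranges
  expect_true(all(abs(relative_growth_score(a, b)) < log10(2001)))
})

test_that("score table matches hand computation on the 2x2x1 toy assay", {
  d <- tiny_design()
  scores <- build_score_table(tiny_records(), d)
  expect_equal(nrow(scores), 4L)
  # blanks: 40 on c1, 50 on c2; replicate means after subtraction:
  # anc: c1 (200+220)/2 = 210, c2 (300+320)/2 = 310
  # A:   c1 110, c2 310;  B: c1 210, c2 110
  key <- paste(scores$genotype, scores$carbon)
  got <- setNames(scores$score, key)
  expect_equal(got[["A c1"]], log10(111 / 211), tolerance = 1e-12)
  expect_equal(got[["A c2"]], log10(311 / 311), tolerance = 1e-12)
  expect_equal(got[["B c1"]], log10(211 / 211), tolerance = 1e-12)
  expect_equal(got[["B c2"]], log10(111 / 311), tolerance = 1e-12)
  expect_false(d$ancestor %in% scores$genotype)
})

test_that("identical MA and ancestor readings give all-zero scores", {
  cfg <- small_sim_config(sigma_delta = 0, sigma_eta = 0, omega0 = 0,
                          omega1 = 0, psi0 = 0, psi1 = 0, sigma_rep = 0,
                          blank_sd = 0)
  sim <- suppressWarnings(simulate_experiment(cfg, seed = 3))
  scores <- build_score_table(sim$records, cfg$design)
  expect_true(all(abs(scores$score) < 1e-12))
})

test_that("a full simulated design yields one score per MA cell", {
  sim <- simulate_experiment(simulation_config(), seed = 11)
  scores <- build_score_table(sim$records, sim$config$design)
  expect_equal(nrow(scores), 10 * 6 * 10)
  expect_true(all(is.finite(scores$score)))
  expect_equal(nrow(attr(scores, "missing_cells")), 0L)
})

test_that("missing cells are reported and the ancestor is required", {
  d <- tiny_design()
  rec <- tiny_records()
  # drop both replicates of B on c2
  rec2 <- rec[!(rec$genotype == "B" & rec$carbon == "c2"), ]
  expect_warning(scores <- build_score_table(rec2, d), "B/c2")
  expect_equal(nrow(attr(scores, "missing_cells")), 1L)
  expect_error(build_score_table(rec2, d, on_missing = "error"), "B/c2")
  # drop the ancestor from c1 entirely
  rec3 <- rec[!(rec$genotype == "anc" & rec$carbon == "c1"), ]
  expect_error(build_score_table(rec3, d), "anc")
})

test_that("score-then-average agrees on noiseless data and differs on noisy", {
  d <- tiny_design()
  rec <- tiny_records()
  s1 <- build_score_table(rec, d)
  s2 <- build_score_table(rec, d, score_then_average = TRUE)
  # log10 is concave, so averaging scores gives a value <= averaging nets
  expect_true(all(s2$score <= s1$score + 1e-12))
  # with equal replicates the two orders coincide
  rec_eq <- rec
  rec_eq$mOD[!rec_eq$is_blank] <-
    ave(rec_eq$mOD[!rec_eq$is_blank],
        paste(rec_eq$genotype, rec_eq$carbon)[!rec_eq$is_blank])
  expect_equal(build_score_table(rec_eq, d)$score,
               build_score_table(rec_eq, d, score_then_average = TRUE)$score,
               tolerance = 1e-12)
})

test_that("carbon molarity reproduces the printed media values", {
  src <- davis_carbon_sources()
  mm <- vapply(src, function(s) signif(carbon_molarity(s), 3), numeric(1))
  expect_equal(unname(mm[c("glucose", "fructose", "galactose")]),
               c(13.3, 13.3, 13.3))
  expect_equal(unname(mm[["glycerol"]]), 13.0)
  expect_equal(unname(mm[c("maltose", "trehalose")]), c(14.0, 14.0))
})

test_that("formula parsing and molar mass behave", {
  expect_equal(parse_empirical_formula("C6H12O6"),
               c(C = 6L, H = 12L, O = 6L))
  expect_equal(molar_mass("C6H12O6"), 6 * 12.011 + 12 * 1.008 + 6 * 15.999,
               tolerance = 1e-12)
  expect_error(parse_empirical_formula("c6"), "parse")
  expect_error(molar_mass("C2Xx4"), "Xx")
  expect_error(carbon_source("water", "H2O"), "carbon")
})
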