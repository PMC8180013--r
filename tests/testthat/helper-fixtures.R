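# Shared fixtures, all built in code.

tiny_design <- function() {
  experiment_design(genotypes = c("A", "B"), carbons = c("c1", "c2"),
                    temperatures = 31, replicates = 2L, ancestor = "anc")
}

# Records for tiny_design with hand-picked readings: blanks 40 (c1) and
# 50 (c2); each culture has two replicates.
tiny_records <- function() {
  rows <- list(
    c("",    "c1", 31, 1, 40, TRUE),
    c("",    "c2", 31, 1, 50, TRUE),
    c("anc", "c1", 31, 1, 240, FALSE), c("anc", "c1", 31, 2, 260, FALSE),
    c("anc", "c2", 31, 1, 350, FALSE), c("anc", "c2", 31, 2, 370, FALSE),
    c("A",   "c1", 31, 1, 140, FALSE), c("A",   "c1", 31, 2, 160, FALSE),
    c("A",   "c2", 31, 1, 350, FALSE), c("A",   "c2", 31, 2, 370, FALSE),
    c("B",   "c1", 31, 1, 240, FALSE), c("B",   "c1", 31, 2, 260, FALSE),
    c("B",   "c2", 31, 1, 150, FALSE), c("B",   "c2", 31, 2, 170, FALSE)
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("genotype", "carbon", "temperature_c", "replicate",
                 "mOD", "is_blank")
  df$temperature_c <- as.numeric(df$temperature_c)
  df$replicate <- as.integer(df$replicate)
  df$mOD <- as.numeric(df$mOD)
  df$is_blank <- as.logical(df$is_blank)
  df
}

# A smaller simulated assay for fast structural tests.
small_sim_config <- function(...) {
  d <- experiment_design(genotypes = sprintf("g%d", 1:4),
                         carbons = c("c1", "c2", "c3"),
                         temperatures = c(25, 29, 33, 37),
                         replicates = 2L)
  simulation_config(design = d, a_max = c(900, 700, 500),
                    t_opt = c(34, 35, 36), breadth = c(10, 11, 12), ...)
}

# Seeded random G x E matrix with mild structure, for property tests.
random_gxe_matrix <- function(g, e, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(g * e, sd = 0.1), g, e,
              dimnames = list(paste0("g", seq_len(g)),
                              paste0("c", seq_len(e))))
  m <- m + stats::rnorm(g, sd = 0.05) + rep(stats::rnorm(e, sd = 0.05),
                                            each = g)
  attr(m, "temperature_c") <- 30
  m
}

# The two hand-computed 2 x 2 fixtures used repeatedly: mirrored profiles
# (pure inconsistency) and proportional profiles (pure responsiveness).
mirrored_matrix <- function() {
  m <- matrix(c(0.1, -0.1, -0.1, 0.1), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  attr(m, "temperature_c") <- 30
  m
}

proportional_matrix <- function() {
  m <- matrix(c(0.1, -0.1, 0.2, -0.2), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  attr(m, "temperature_c") <- 30
  m
}
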