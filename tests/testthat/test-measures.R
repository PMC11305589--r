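test_that("information change is the normalised change in total information", {
  p <- pattern_from_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
  expect_equal(information_change_series(p), 0.25)
  p2 <- pattern_from_matrix(rbind(c(1, 1, 1, 0), c(1, 1, 0, 0)))
  expect_equal(information_change_series(p2), -0.25)
  p3 <- pattern_from_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(information_change_series(p3), 0)
})

test_that("Euclidean distance is normalised by u * sqrt(n)", {
  p <- pattern_from_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(euclidean_distance_series(p), 1)
  pu <- pattern_from_matrix(rbind(c(2, 2, 0, 0), c(0, 0, 2, 2)), u = 2)
  expect_equal(euclidean_distance_series(pu), 1)
  same <- pattern_from_matrix(rbind(c(1, 0, 1, 0), c(1, 0, 1, 0)))
  expect_equal(euclidean_distance_series(same), 0)
})

test_that("relative distance divides by the successor's magnitude", {
  p <- pattern_from_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(relative_distance_series(p), sqrt(2))
  p2 <- pattern_from_matrix(rbind(c(1, 0, 0, 0), c(2, 0, 0, 0)))
  expect_equal(relative_distance_series(p2), 0.5)
})

test_that("cosine similarity lies in [0, 1] with the expected values", {
  same <- pattern_from_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(cosine_similarity_series(same), 1)
  disjoint <- pattern_from_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(cosine_similarity_series(disjoint), 0)
  half <- pattern_from_matrix(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(cosine_similarity_series(half), 0.5)
})

test_that("series summaries use the arithmetic mean and unbiased variance", {
  s <- summarize_series(c(0.1, 0.3))
  expect_equal(s$mean, 0.2)
  expect_equal(s$variance, 0.02)
  s2 <- summarize_series(c(1, 1, 0, 1, 1))
  expect_equal(s2$mean, 0.8)
  expect_equal(s2$variance, 0.2)
  expect_equal(summarize_series(rep(0.4, 6))$variance, 0)
  expect_error(summarize_series(numeric(0)), "empty")
  expect_error(summarize_series(1), ">= 2 transitions")
  expect_equal(summarize_series(1, require_variance = FALSE)$mean, 1)
})

test_that("a constant pattern has all three measures exactly zero", {
  m <- mixbiotic_measures(toy_constant())
  expect_identical(m$M_mob, 0)
  expect_identical(m$M_atom, 0)
  expect_identical(m$M_mix, 0)
  expect_equal(m$mu_S, 1)
  expect_equal(m$var_S, 0)
})

test_that("strict alternation of disjoint half-supports hits its closed forms", {
  m <- mixbiotic_measures(toy_alternation())
  expect_equal(m$mu_L, 1)
  expect_equal(m$var_L, 0)
  expect_equal(m$mu_S, 0)
  expect_equal(m$M_mix, 0)
  expect_equal(m$mu_LR, sqrt(2))
  expect_equal(m$n_transitions, 5L)
})

test_that("the block-rotation toy peaks M_mix between the order extremes", {
  m <- mixbiotic_measures(toy_block())
  expect_equal(cosine_similarity_series(toy_block()), c(1, 1, 0, 1, 1))
  expect_equal(m$mu_S, 0.8)
  expect_equal(m$var_S, 0.2)
  expect_equal(m$M_mix, 0.16)
  expect_gt(m$M_mix, mixbiotic_measures(toy_constant())$M_mix)
  expect_gt(m$M_mix, mixbiotic_measures(toy_alternation())$M_mix)
})

test_that("measure identities hold by construction", {
  set.seed(5)
  for (rep in 1:5) {
    p <- random_pattern(n = sample(3:8, 1), T = sample(4:12, 1))
    m <- mixbiotic_measures(p)
    expect_identical(m$M_mob, m$mu_L)
    expect_identical(m$M_atom, m$mu_LR)
    expect_identical(m$M_mix, m$mu_S * m$var_S)
    expect_gte(min(m$var_I, m$var_L, m$var_LR, m$var_S), 0)
    expect_true(m$mu_S >= 0 && m$mu_S <= 1)
  }
})

test_that("S and L_R are scale invariant; L and I scale linearly", {
  set.seed(9)
  for (rep in 1:5) {
    p <- random_pattern(n = 6, T = 8, binary = FALSE)
    c0 <- stats::runif(1, 0.5, 4)
    p_scaled <- pattern_from_matrix(as.matrix(p) * c0)
    t1 <- transition_series(p)
    t2 <- transition_series(p_scaled)
    expect_equal(t2$S, t1$S, tolerance = 1e-12)
    expect_equal(t2$L_R, t1$L_R, tolerance = 1e-12)
    expect_equal(t2$L, c0 * t1$L, tolerance = 1e-12)
    expect_equal(t2$I, c0 * t1$I, tolerance = 1e-12)
  }
})

test_that("too-short patterns are rejected with clear messages", {
  p1 <- pattern_from_matrix(matrix(c(1, 1), 1))
  expect_error(transition_series(p1), ">= 2 time steps")
  p2 <- pattern_from_matrix(rbind(c(1, 0), c(0, 1)))
  expect_error(mixbiotic_measures(p2), ">= 3 time steps")
})

test_that("silent grid rows are dropped jointly or rejected under strict", {
  s <- event_stream(data.frame(time = c(0, 1, 30, 31, 32),
                               i = c("A", "B", "A", "B", "C"),
                               j = c("B", "C", "C", "C", "A")))
  p <- build_pattern_sequence(s, timeline = "grid", grid_step = 1)
  ts <- transition_series(p)
  expect_true(all(c("I", "L", "L_R", "S") %in% names(ts)))
  expect_lt(nrow(ts), dim(p)[1] - 1)
  expect_equal(length(unique(vapply(ts[c("I", "L", "L_R", "S")],
                                    length, integer(1)))), 1L)
  expect_error(transition_series(p, zero_policy = "strict"), "silent")
})

test_that("the t_max mean divisor rescales means by (T-1)/T", {
  p <- toy_block()
  m1 <- mixbiotic_measures(p)
  m2 <- mixbiotic_measures(p, mean_divisor = "t_max")
  Tn <- m1$n_steps
  expect_equal(m2$mu_L, m1$mu_L * (Tn - 1) / Tn)
  expect_equal(m2$mu_S, m1$mu_S * (Tn - 1) / Tn)
})

test_that("phase classification follows the rescaled argmax with tie order", {
  sets <- list(constant = mixbiotic_measures(toy_constant()),
               alternation = mixbiotic_measures(toy_alternation()),
               block = mixbiotic_measures(toy_block()))
  ref <- dplyr::bind_rows(sets)
  expect_equal(classify_phase(sets$constant, reference = ref), "nihilism")
  expect_equal(classify_phase(sets$block, reference = ref), "mixism")
  expect_equal(classify_phase(sets$alternation, reference = ref), "mobism")
  zero <- sets$constant
  expect_equal(classify_phase(zero), "nihilism")
  expect_error(classify_phase(sets$block, epsilon = -1), "epsilon")
})

test_that("radar normalisation divides each item by its cross-set maximum", {
  a <- tibble::tibble(community = "a", M_mob = 0.2, M_mix = 0.1, M_atom = 0)
  b <- tibble::tibble(community = "b", M_mob = 0.4, M_mix = 0.05, M_atom = 0)
  expect_warning(prof <- normalize_radar(dplyr::bind_rows(a, b)), "all-zero")
  wide <- tidyr::pivot_wider(prof[, c("community", "item", "normalized")],
                             names_from = "item", values_from = "normalized")
  expect_equal(wide$M_mob, c(0.5, 1))
  expect_equal(wide$M_mix, c(1, 0.5))
  expect_equal(wide$M_atom, c(0, 0))
  single <- normalize_radar(a, items = c("M_mob", "M_mix"))
  expect_true(all(single$normalized == 1))
  for (it in unique(prof$item[prof$value > 0])) {
    expect_equal(max(prof$normalized[prof$item == it]), 1)
  }
})
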