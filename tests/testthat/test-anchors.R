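# small worlds over a 4-letter alphabet keep the bandit fast
tiny_alpha <- c("A", "C", "F", "S")

random_pool <- function(n, len, seed, alpha = tiny_alpha) {
  set.seed(seed)
  seq_set(replicate(n, paste(sample(alpha, len, TRUE), collapse = "")),
          ids = sprintf("r%03d", 1:n), frame_length = len, alphabet = alpha)
}

test_that("rule_applies evaluates conjunctions over the frame", {
  ss <- seq_set(c("CASSLGQ", "CAST"), frame_length = 12)
  expect_true(all(rule_applies(predicates(), ss)))           # vacuous
  expect_equal(rule_applies(predicates(c(0, 3), c("C", "S")), ss),
               c(TRUE, FALSE))
  # position 10 of a 4-residue sequence holds PAD, not A
  expect_equal(rule_applies(predicates(10, "A"), ss), c(FALSE, FALSE))
  # ... but a PAD predicate can match there (length information)
  expect_equal(rule_applies(predicates(10, pad_token()), ss), c(TRUE, TRUE))
})

test_that("rule_coverage counts matching fractions", {
  ss <- seq_set(c("CAAA", "CCCC", "CSSS", "ASSS", "FSSS"), frame_length = 4)
  expect_equal(rule_coverage(predicates(), ss), 1)
  expect_equal(rule_coverage(predicates(0, "W"), ss), 0)
  expect_equal(rule_coverage(predicates(0, "C"), ss), 3 / 5)
  expect_equal(rule_coverage(predicates(c(0, 1), c("C", "S")), ss), 1 / 5)
  expect_error(rule_coverage(predicates(), seq_set(character(0),
                                                   frame_length = 4)),
               "empty")
})

test_that("coverage is monotone in the predicate set", {
  set.seed(21)
  pool <- random_pool(60, 8, seed = 21)
  for (rep in 1:25) {
    pos <- sample(0:7, 3)
    sym <- sample(tiny_alpha, 3, TRUE)
    sub <- predicates(pos[1:2], sym[1:2])
    full <- predicates(pos, sym)
    expect_gte(rule_coverage(sub, pool), rule_coverage(full, pool))
  }
})

test_that("perturbations keep fixed positions and degenerate correctly", {
  pool <- random_pool(50, 6, seed = 3)
  inst <- pool["r001"]
  all_fixed <- sample_perturbations(inst, 0:5, pool, n = 20, seed = 1)
  expect_true(all(frame_matrix(all_fixed) ==
                    matrix(frame_matrix(inst)[1, ], 20, 6, byrow = TRUE)))

  clones <- seq_set(rep(raw_sequences(inst), 30), frame_length = 6,
                    alphabet = tiny_alpha)
  pert <- sample_perturbations(inst, integer(0), clones, n = 20, seed = 2)
  expect_true(all(frame_matrix(pert) ==
                    matrix(frame_matrix(inst)[1, ], 20, 6, byrow = TRUE)))

  expect_error(sample_perturbations(inst, 0, pool, n = 0), "positive")
  expect_identical(
    frame_matrix(sample_perturbations(inst, 2, pool, 50, seed = 9)),
    frame_matrix(sample_perturbations(inst, 2, pool, 50, seed = 9)))
})

test_that("perturbation marginals follow the keep/resample mixture", {
  # one free binary position with pool frequencies 0.8 A / 0.2 G,
  # instance symbol A: expect 0.5 * 1 + 0.5 * 0.8 = 0.9
  pool <- seq_set(c(rep("A", 80), rep("G", 20)), frame_length = 1,
                  alphabet = c("A", "G"))
  inst <- seq_set("A", frame_length = 1, alphabet = c("A", "G"))
  pert <- sample_perturbations(inst, integer(0), pool, n = 10000, seed = 5)
  frac_a <- mean(frame_matrix(pert)[, 1] == "A")
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(frac_a - 0.9), 3 * se)
})

test_that("estimate_precision returns calibrated estimates and bounds", {
  pool <- random_pool(100, 6, seed = 13)
  inst <- pool["r001"]
  const <- constant_model("binding")
  est <- estimate_precision(predicates(), "binding", const, inst, pool,
                            n = 500, seed = 1)
  expect_equal(est$estimate, 1)
  expect_lt(est$lower_bound, 1)
  expect_lte(est$lower_bound, est$estimate)
  expect_lte(est$estimate, est$upper_bound)

  planted <- planted_model(list(predicates(c(0, 3), c("C", "F"))))
  est2 <- estimate_precision(predicates(c(0, 3), c("C", "F")), "binding",
                             planted, inst, pool, n = 500, seed = 2)
  expect_equal(est2$estimate, 1)   # every conforming perturbation binds

  # empty rule base rate, computable in closed form from the mixture:
  # P(pos = sym) = 0.5 * [inst matches] + 0.5 * pool freq
  inst_match <- seq_set("CAAFAA", frame_length = 6, alphabet = tiny_alpha)
  q0 <- mean(frame_matrix(pool)[, 1] == "C")
  q3 <- mean(frame_matrix(pool)[, 4] == "F")
  p_true <- (0.5 + 0.5 * q0) * (0.5 + 0.5 * q3)
  est3 <- estimate_precision(predicates(), "binding", planted, inst_match,
                             pool, n = 10000, seed = 3)
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(est3$estimate - p_true), 3 * se)
})

test_that("find_anchor returns the vacuous rule for a constant model", {
  pool <- random_pool(50, 6, seed = 31)
  a <- find_anchor(pool["r001"], constant_model("binding"), pool,
                   anchor_params(seed = 1))
  expect_equal(nrow(a$predicates), 0)
  expect_equal(a$precision_estimate, 1)
  expect_false(a$below_threshold)
  expect_gte(a$precision_lower_bound, 0.9)
})

test_that("find_anchor recovers planted single rules and conjunctions", {
  pool <- random_pool(200, 6, seed = 41)
  single <- planted_model(list(predicates(0, "C")))
  medoid <- seq_set("CAFSAC", frame_length = 6, alphabet = tiny_alpha,
                    ids = "med")
  hits <- 0L
  for (run in 1:20) {
    a <- find_anchor(medoid, single, pool, anchor_params(seed = run))
    expect_true(rule_applies(a, medoid))   # anchor consistency
    if (identical(a$predicates, predicates(0, "C"))) hits <- hits + 1L
  }
  expect_gte(hits, 19)   # >= 95% of 20 seeded runs

  conj <- planted_model(list(predicates(c(0, 4), c("C", "F"))))
  medoid2 <- seq_set("CASSFC", frame_length = 6, alphabet = tiny_alpha,
                     ids = "med2")
  clean <- 0L
  for (run in 1:20) {
    a <- find_anchor(medoid2, conj, pool, anchor_params(seed = 100 + run))
    keys <- paste(a$predicates$position, a$predicates$symbol)
    if (all(c("0 C", "4 F") %in% keys) && all(keys %in% c("0 C", "4 F"))) {
      clean <- clean + 1L
    }
  }
  expect_gte(clean, 18)   # >= 90% of 20 seeded runs

  expect_error(find_anchor(seq_set("CASS", frame_length = 4,
                                   alphabet = tiny_alpha),
                           single, pool, anchor_params()),
               "frame length")
})

test_that("exhausted budgets return a flagged below-threshold rule", {
  # alternating labels no conjunction can explain: precision stays ~0.5
  pool <- random_pool(100, 4, seed = 51)
  coin <- black_box_model(function(s) {
    ifelse(seq_len(n_samples(s)) %% 2 == 0, "binding", "non-binding")
  })
  a <- find_anchor(pool["r002"], coin, pool,
                   anchor_params(seed = 3, max_pulls = 2000,
                                 max_predicates = 2))
  expect_true(a$below_threshold)
  expect_lt(a$precision_lower_bound, 0.9)
})

test_that("KL bounds bracket the estimate and tighten with n", {
  p1 <- estimate_precision(predicates(), "binding", constant_model("binding"),
                           random_pool(10, 4, 61)["r001"],
                           random_pool(10, 4, 61), n = 50, seed = 1)
  p2 <- estimate_precision(predicates(), "binding", constant_model("binding"),
                           random_pool(10, 4, 61)["r001"],
                           random_pool(10, 4, 61), n = 5000, seed = 1)
  expect_gt(p2$lower_bound, p1$lower_bound)
})

test_that("anchors round-trip through JSON lines and render as IF/THEN text", {
  pool <- random_pool(50, 6, seed = 71)
  med <- seq_set("CAFSAC", frame_length = 6, alphabet = tiny_alpha,
                 ids = "r001")
  a <- find_anchor(med, planted_model(list(predicates(1, "A"))),
                   pool, anchor_params(seed = 2),
                   source = list(split = "binding", cluster = 0L,
                                 medoid_id = "r001"))
  tf <- withr::local_tempfile(fileext = ".jsonl")
  write_anchors_jsonl(list(a), tf)
  back <- read_anchors_jsonl(tf)[[1]]
  expect_equal(back$predicates, a$predicates)
  expect_equal(back$precision_estimate, a$precision_estimate)
  expect_equal(back$source$medoid_id, "r001")

  txt <- format_anchor(a)
  expect_match(txt, "^IF \\(amino acid")
  expect_match(txt, "THEN the sample is binding")
  r2 <- make_rule(c(0, 4), c("C", "F"))
  expect_equal(format_anchor(r2),
               paste("IF (amino acid C is in position 0) AND",
                     "(amino acid F is in position 4)",
                     "THEN the sample is binding"))
})
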