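test_that("the generator is fully reproducible from its seed", {
  s1 <- generate_kam(sim_config(seed = 17))
  s2 <- generate_kam(sim_config(seed = 17))
  expect_true(kam_equal(s1$kam, s2$kam))
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_expression(s1)$matrix, simulate_expression(s2)$matrix)
  expect_identical(simulate_phospho(s1), simulate_phospho(s2))
  s3 <- generate_kam(sim_config(seed = 18))
  expect_false(kam_equal(s1$kam, s3$kam))
})

test_that("sign algebra of the planted truth follows the edge composition", {
  ## no inverting edges: every downstream leaf matches the root direction
  sim <- generate_kam(sim_config(inverting_fraction = 0, contradiction_rate = 0,
                                 seed = 3))
  expect_true(all(sim$truth$leaf_truth$expected_direction == "increase"))
  expect_equal(sim$truth$conflicted_leaves, character(0))

  simd <- generate_kam(sim_config(
    inverting_fraction = 0, contradiction_rate = 0,
    planted_roots = data.frame(entity = "REG001", direction = "decrease"),
    seed = 3))
  expect_true(all(simd$truth$leaf_truth$expected_direction == "decrease"))
})

test_that("generator ground truth agrees with the search engine's polarity", {
  cfg <- sim_config(seed = 21, planted_roots = data.frame(
    entity = c("REG001", "REG002"), direction = c("increase", "decrease")))
  sim <- generate_kam(cfg)
  ## recompute expected leaf directions through the engine's own path search
  acc <- list()
  for (i in seq_len(nrow(sim$truth$planted_roots))) {
    r <- sim$truth$planted_roots[i, ]
    dsgn <- if (r$direction == "increase") 1L else -1L
    dn <- downstream_neighborhood(sim$kam, r$entity, "protein_activity", 2)
    dn <- dn[dn$aspect == "rna_abundance", , drop = FALSE]
    for (j in seq_len(nrow(dn))) {
      s <- c(if (dn$plus[j]) dsgn, if (dn$minus[j]) -dsgn)
      acc[[dn$entity[j]]] <- union(acc[[dn$entity[j]]], s)
    }
  }
  engine_conflicted <- sort(names(acc)[vapply(acc, length, integer(1)) == 2L])
  engine_dir <- vapply(acc[vapply(acc, length, integer(1)) == 1L],
                       function(s) if (s > 0) "increase" else "decrease",
                       character(1))
  expect_equal(engine_conflicted, sim$truth$conflicted_leaves)
  lt <- sim$truth$leaf_truth
  expect_equal(sort(names(engine_dir)), lt$entity)
  expect_equal(unname(engine_dir[lt$entity]), lt$expected_direction)
})

test_that("noiseless simulation recovers exactly the planted leaf set", {
  sim <- generate_kam(sim_config(noise_sd = 0, background_change_rate = 0,
                                 contradiction_rate = 0, seed = 5))
  ex <- simulate_expression(sim)
  calls <- call_rna_state_changes(ex)
  called <- calls[calls$direction != "no_change", ]
  lt <- sim$truth$leaf_truth
  expect_setequal(called$entity, lt$entity)
  expect_equal(called$direction[match(lt$entity, called$entity)],
               lt$expected_direction)
})

test_that("a null simulation produces only test-level false positives", {
  cfg <- sim_config(planted_roots = data.frame(entity = character(),
                                               direction = character()),
                    background_change_rate = 0, seed = 9)
  sim <- generate_kam(cfg)
  calls <- call_rna_state_changes(simulate_expression(sim))
  expect_lte(sum(calls$direction != "no_change"), 2L)
})

test_that("phospho simulation tracks inhibited-root substrates", {
  cfg <- sim_config(seed = 4, n_phospho_per_activity = 5,
                    planted_roots = data.frame(entity = "REG001",
                                               direction = "decrease"))
  sim <- generate_kam(cfg)
  tab <- simulate_phospho(sim)
  calls <- call_phospho_state_changes(tab)
  dn <- calls$entity[calls$direction == "decrease"]
  expect_setequal(dn, sim$truth$phospho_truth$entity)
  expect_equal(length(dn), 5L)
  expect_true(all(calls$direction[!calls$entity %in% dn] == "no_change"))

  ## no planted roots: everything stays inside the no-change band
  cfg0 <- sim_config(seed = 4, n_phospho_per_activity = 3,
                     planted_roots = data.frame(entity = character(),
                                                direction = character()))
  tab0 <- simulate_phospho(generate_kam(cfg0))
  expect_true(all(tab0$ratio > 0.80 & tab0$ratio < 1.50))
  calls0 <- call_phospho_state_changes(tab0)
  expect_true(all(calls0$direction == "no_change"))
})

test_that("the planted root is recovered near the top of the ranking", {
  hits <- 0L
  for (seed in 1:5) {
    sim <- generate_kam(sim_config(seed = seed))
    calls <- call_rna_state_changes(simulate_expression(sim))
    u <- universe_from_changes(calls)
    h <- evaluate_all(sim$kam, u, calls)
    rk <- which(h$root_entity == sim$truth$planted_roots$entity[1])
    if (length(rk) && rk <= 5) hits <- hits + 1L
    sig <- h[h$tier == "significant" &
               h$root_entity == sim$truth$planted_roots$entity[1], ]
    if (nrow(sig))
      expect_equal(sig$direction, sim$truth$planted_roots$direction[1])
  }
  expect_gte(hits, 4L)
})

test_that("the multi-experiment fixture plants an exact shared core", {
  fx <- make_multi_experiment_fixture(config = sim_config(seed = 31))
  expect_equal(nrow(fx$truth$core_pairs), 17L)
  expect_equal(length(fx$experiments), 3L)
  ## the core genes are called with the planted direction in every experiment
  for (ex in fx$experiments) {
    calls <- call_rna_state_changes(ex$expression)
    got <- calls$direction[match(fx$truth$core_pairs$entity, calls$entity)]
    expect_equal(got, fx$truth$core_pairs$direction)
  }
  ## private pools are disjoint across experiments
  priv <- lapply(seq_len(3), function(e) names(fx$truth$leaf_truth[[e]]))
  shared12 <- intersect(setdiff(priv[[1]], fx$truth$core_pairs$entity),
                        setdiff(priv[[2]], fx$truth$core_pairs$entity))
  expect_equal(shared12, character(0))
})

test_that("fixture edge cases: no private mechanisms, single experiment", {
  fx0 <- make_multi_experiment_fixture(private_mechanism_size = 0,
                                       config = sim_config(seed = 8))
  expect_equal(sum(vapply(fx0$truth$private_roots, nrow, integer(1))), 0L)
  fx1 <- make_multi_experiment_fixture(n_experiments = 1,
                                       config = sim_config(seed = 8))
  expect_equal(length(fx1$experiments), 1L)
  expect_error(make_multi_experiment_fixture(shared_change_core = 500,
                                             config = sim_config(seed = 8)),
               "infeasible")
})

test_that("the fixture CNM recovers the planted mechanism backbone", {
  fx <- make_multi_experiment_fixture(shared_mechanism_size = 4,
                                      config = sim_config(seed = 12))
  exps <- lapply(fx$experiments, function(e) {
    calls <- call_rna_state_changes(e$expression)
    u <- universe_from_changes(calls)
    rca_experiment(e$name, u, calls, evaluate_all(fx$kam, u, calls))
  })
  sel <- common_hypotheses(exps)
  sel_keys <- node_key(sel$root_entity, sel$root_aspect)
  ## every planted common root is selected with its planted direction...
  tr <- fx$truth$common_roots
  expect_true(all(node_key(tr$entity, tr$aspect) %in% sel_keys))
  m <- match(node_key(tr$entity, tr$aspect), sel_keys)
  expect_equal(sel$direction[m], tr$direction)
  ## ...and no private root survives the intersection
  priv <- unlist(lapply(fx$truth$private_roots, `[[`, "entity"))
  expect_false(any(priv %in% sel$root_entity))

  ## assembling just the planted roots recovers the planted backbone edges
  planted_sel <- data.frame(root_entity = tr$entity, root_aspect = tr$aspect,
                            direction = tr$direction)
  cnm <- assemble_cnm(planted_sel, fx$kam, exps,
                      perturbation = fx$truth$perturbation)
  got <- cnm$subgraph$edges[, c("source_entity", "target_entity", "sign")]
  want <- fx$truth$backbone_edges[, c("source_entity", "target_entity", "sign")]
  expect_setequal(paste(got$source_entity, got$target_entity, got$sign),
                  paste(want$source_entity, want$target_entity, want$sign))
  expect_true(all(cnm$annotations$downstream_of_perturbation))
})
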