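## Hand-built experiment bundles for the selection logic.
fake_hyps <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(root_entity = r[[1]], root_aspect = "protein_activity",
               direction = r[[2]], tie = FALSE, N = 100, M = 10, P = 5,
               Q = 5, J = 0, K = 5, richness_p = 0.001,
               concordance_p = 0.03125, tier = r[[3]],
               stringsAsFactors = FALSE)))
  class(out) <- c("rca_hypotheses", "data.frame")
  out
}

fake_experiment <- function(name, hyps, changes = helper_changes()) {
  u <- data.frame(entity = sprintf("U%02d", 1:20), aspect = "rna_abundance")
  u <- unique(rbind(u, changes[, c("entity", "aspect")]))
  rca_experiment(name, u, changes, hyps)
}

test_that("common hypotheses require the tier floor in every experiment", {
  e1 <- fake_experiment("e1", fake_hyps(list("R1", "increase", "significant"),
                                        list("R2", "increase", "significant")))
  e2 <- fake_experiment("e2", fake_hyps(list("R1", "increase", "significant"),
                                        list("R2", "increase", "marginal")))
  e3 <- fake_experiment("e3", fake_hyps(list("R1", "increase", "significant")))
  sel <- common_hypotheses(list(e1, e2, e3))
  expect_equal(sel$root_entity, "R1")
  ## R2 meets only the marginal floor in e2 and is absent from e3
  sel_m <- common_hypotheses(list(e1, e2), tier_floor = "marginal")
  expect_setequal(sel_m$root_entity, c("R1", "R2"))
})

test_that("direction consistency is enforced when requested", {
  e1 <- fake_experiment("e1", fake_hyps(list("R1", "increase", "significant")))
  e2 <- fake_experiment("e2", fake_hyps(list("R1", "increase", "significant")))
  e3 <- fake_experiment("e3", fake_hyps(list("R1", "decrease", "significant")))
  expect_equal(nrow(common_hypotheses(list(e1, e2, e3))), 0L)
  expect_equal(nrow(common_hypotheses(list(e1, e2, e3),
                                      require_same_direction = FALSE)), 1L)
  expect_equal(nrow(common_hypotheses(list(e1, e2))), 1L)
})

test_that("selection shrinks as experiments are added", {
  hs <- list(fake_hyps(list("R1", "increase", "significant"),
                       list("R2", "increase", "significant"),
                       list("R3", "decrease", "significant")),
             fake_hyps(list("R1", "increase", "significant"),
                       list("R2", "decrease", "significant")),
             fake_hyps(list("R1", "increase", "significant")))
  exps <- lapply(seq_along(hs), function(i) fake_experiment(paste0("e", i), hs[[i]]))
  full <- common_hypotheses(exps)
  for (idx in list(1, 1:2, 2:3)) {
    sub <- common_hypotheses(exps[idx])
    expect_true(all(node_key(full$root_entity, full$root_aspect) %in%
                      node_key(sub$root_entity, sub$root_aspect)))
  }
})

test_that("change overlap counts shared (entity, direction) pairs", {
  c1 <- helper_changes("A.rna:increase", "B.rna:decrease", "C.rna:increase")
  c2 <- helper_changes("A.rna:increase", "B.rna:increase", "D.rna:decrease")
  e1 <- fake_experiment("e1", fake_hyps(list("R", "increase", "significant")), c1)
  e2 <- fake_experiment("e2", fake_hyps(list("R", "increase", "significant")), c2)
  ov <- change_overlap(list(e1, e2))
  expect_equal(ov$full_intersection, 1L)     # only A increase agrees
  expect_equal(ov$full_intersection_pairs$entity, "A")
  expect_equal(unname(ov$per_experiment), c(3L, 3L))

  ## identical sets: full intersection; disjoint sets: zero
  ov_same <- change_overlap(list(e1, e1))
  expect_equal(ov_same$full_intersection, 3L)
  e3 <- fake_experiment("e3", fake_hyps(list("R", "increase", "significant")),
                        helper_changes("X.rna:increase"))
  expect_equal(change_overlap(list(e1, e3))$full_intersection, 0L)

  ## symmetric under reordering
  ov_rev <- change_overlap(list(e2, e1))
  expect_equal(ov_rev$full_intersection, ov$full_intersection)
  expect_equal(ov_rev$pairwise["e1", "e2"], ov$pairwise["e2", "e1"])
})

test_that("coverage classifies explained, contradicted and conflicted nodes", {
  g <- helper_kam("R.act +> G1.rna", "R.act +> G2.rna", "R.act +> G3.rna",
                  "R.act +> G4.rna", "R.act +> G5.rna")
  chg <- helper_changes("G1.rna:increase", "G2.rna:increase", "G3.rna:increase",
                        "G4.rna:increase", "G5.rna:increase",
                        "X1.rna:increase", "X2.rna:increase", "X3.rna:increase",
                        "X4.rna:increase", "X5.rna:increase")
  e <- fake_experiment("e", fake_hyps(list("R", "increase", "significant")), chg)
  sel <- data.frame(root_entity = "R", root_aspect = "protein_activity",
                    direction = "increase")
  cov <- coverage(sel, list(e), g)
  expect_equal(cov$explained, 5L)
  expect_equal(cov$total_changes, 10L)
  expect_equal(cov$fraction, 0.5)

  ## two selected roots predicting one node both ways: conflicted, not explained
  g2 <- helper_kam("R.act +> G1.rna", "S.act -> G1.rna")
  e2 <- fake_experiment("e2", fake_hyps(list("R", "increase", "significant")),
                        helper_changes("G1.rna:increase"))
  sel2 <- data.frame(root_entity = c("R", "S"),
                     root_aspect = "protein_activity",
                     direction = c("increase", "increase"))
  cov2 <- coverage(sel2, list(e2), g2)
  expect_equal(cov2$explained, 0L)
  expect_equal(cov2$conflicted, 1L)
  expect_equal(cov2$contradicted, 0L)

  ## a root selected as decreased flips its predictions
  sel3 <- data.frame(root_entity = "S", root_aspect = "protein_activity",
                     direction = "decrease")
  cov3 <- coverage(sel3, list(e2), g2)
  expect_equal(cov3$explained, 1L)

  expect_error(coverage(data.frame(root_entity = "Z",
                                   root_aspect = "protein_activity",
                                   direction = "increase"), list(e2), g2),
               "absent")
})

test_that("coverage grows monotonically as consistent roots are added", {
  g <- helper_kam("R.act +> G1.rna", "R.act +> G2.rna",
                  "S.act +> G3.rna", "S.act +> G4.rna")
  chg <- helper_changes("G1.rna:increase", "G2.rna:increase",
                        "G3.rna:increase", "G4.rna:increase",
                        "X1.rna:increase")
  e <- fake_experiment("e", fake_hyps(list("R", "increase", "significant")), chg)
  sel1 <- data.frame(root_entity = "R", root_aspect = "protein_activity",
                     direction = "increase")
  sel2 <- rbind(sel1, data.frame(root_entity = "S",
                                 root_aspect = "protein_activity",
                                 direction = "increase"))
  f1 <- coverage(sel1, list(e), g)$fraction
  f2 <- coverage(sel2, list(e), g)$fraction
  expect_lte(f1, f2)
  expect_lte(f2, 1)
})

test_that("the assembled network contains inter-root paths and vetting flags", {
  g <- helper_kam("D.cpd +> R.act", "R.act +> S.act", "S.act +> G1.rna",
                  "T.act +> G2.rna")
  chg <- helper_changes("G1.rna:increase", "G2.rna:increase", "R.rna:increase")
  e <- fake_experiment("e", fake_hyps(list("R", "increase", "significant")), chg)
  sel <- data.frame(root_entity = c("R", "S", "T"),
                    root_aspect = "protein_activity",
                    direction = "increase")
  cnm <- assemble_cnm(sel, g, list(e), depth = 2,
                      perturbation = list(entity = "D", aspect = "compound"))
  ek <- paste(cnm$subgraph$edges$source_entity, cnm$subgraph$edges$target_entity)
  expect_true("R S" %in% ek)          # direct inter-root edge kept
  expect_true("S G1" %in% ek)         # root-to-explained edge kept
  ann <- cnm$annotations
  expect_equal(ann$downstream_of_perturbation[ann$root_entity == "R"], TRUE)
  expect_equal(ann$downstream_of_perturbation[ann$root_entity == "T"], FALSE)
  expect_true(ann$inter_root_connected[ann$root_entity == "R"])
  expect_false(ann$inter_root_connected[ann$root_entity == "T"])
  ## R's RNA abundance was itself observed changed
  expect_true(ann$is_state_change[ann$root_entity == "R"])
  expect_false(ann$is_state_change[ann$root_entity == "T"])
})

test_that("CNM export writes graph, sidecar and coverage files", {
  g <- helper_kam("R.act +> G1.rna")
  e <- fake_experiment("e", fake_hyps(list("R", "increase", "significant")),
                       helper_changes("G1.rna:increase"))
  sel <- data.frame(root_entity = "R", root_aspect = "protein_activity",
                    direction = "increase")
  cnm <- assemble_cnm(sel, g, list(e))
  dir <- file.path(tempdir(), "cnm_out")
  paths <- write_cnm(cnm, dir)
  expect_true(all(file.exists(paths)))
  side <- jsonlite::read_json(paths[["sidecar"]], simplifyVector = TRUE)
  expect_equal(side$selected$root_entity, "R")
  expect_true(kam_equal(load_kam(paths[["graph"]]), cnm$subgraph))
})
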