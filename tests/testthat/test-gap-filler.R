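# shared scene: one-route toy with the transport reaction deleted,
# plus a universal database holding the repair and assorted decoys
broken_chain <- function() {
  tb <- gen_toy_network(1, yields = 0.5)
  m <- remove_reactions(tb$model, "T_sub")
  validate_model(m)
  m
}

universal_db <- function(model, extra = list()) {
  metabolic_model(
    "universal",
    compartments = c(c = "cytoplasm", e = "extracellular"),
    metabolites = model$metabolites,
    reactions = c(list(
      reaction("U_repair", c(sub_e = -1, sub_c = 1)),
      reaction("U_decoy_backwards", c(sub_c = -1, sub_e = 1)),
      reaction("U_decoy_drain", c(sub_c = -1)),
      reaction("U_decoy_bmsink", c(bm_c = -1)),
      reaction("U_decoy_loop", c(bm_c = -1, sub_c = 1)),
      reaction("U_decoy_dead", c(bm_c = -1, sub_e = 1))),
      extra))
}

test_that("a model that already grows needs no additions", {
  tb <- gen_toy_network(1, yields = 0.5)
  uni <- universal_db(tb$model)
  res <- gapfill(tb$model, uni, target = "BIOMASS",
                 medium = c(EX_sub = 10))
  expect_equal(res$status, "already_feasible")
  expect_length(res$added, 0)
  expect_equal(res$cost, 0)
})

test_that("the deleted reaction is recovered exactly among decoys", {
  m <- broken_chain()
  uni <- universal_db(m)
  res <- gapfill(m, uni, target = "BIOMASS", medium = c(EX_sub = 10))
  expect_equal(res$status, "optimal")
  expect_identical(res$added, "U_repair")
  expect_equal(res$cost, 1)
  expect_gte(res$target_flux, 1e-3)
  # exhaustive subset search agrees
  orc <- gapfill_oracle(m, uni, "BIOMASS", c(EX_sub = 10))
  expect_identical(sort(orc$added), res$added)
  expect_equal(orc$cost, res$cost)
})

test_that("weights steer the choice between alternative repairs", {
  m <- broken_chain()
  uni <- metabolic_model(
    "uni2", c(c = "cytoplasm", e = "extracellular"),
    metabolites = m$metabolites,
    reactions = list(
      reaction("U_cheap", c(sub_e = -1, sub_c = 1)),
      reaction("U_dear", c(sub_e = -1, sub_c = 1))))
  res <- gapfill(m, uni, target = "BIOMASS", medium = c(EX_sub = 10),
                 weights = c(U_dear = 1, U_cheap = 3))
  expect_identical(res$added, "U_dear")
  expect_equal(res$cost, 1)
  # with equal weights the lexicographically smaller id wins
  tie <- gapfill(m, uni, target = "BIOMASS", medium = c(EX_sub = 10))
  expect_identical(tie$added, "U_cheap")
})

test_that("metabolite targets are wrapped in a sink; infeasible named", {
  m <- broken_chain()
  uni <- universal_db(m)
  res <- gapfill(m, uni, target = "bm_c", medium = c(EX_sub = 10))
  expect_equal(res$status, "optimal")
  expect_identical(res$added, "U_repair")

  # no universal reaction can make an unreachable metabolite
  m2 <- m
  m2$metabolites$ghost_c <- metabolite("ghost_c", compartment = "c")
  res2 <- gapfill(m2, uni, target = "ghost_c", medium = c(EX_sub = 10))
  expect_equal(res2$status, "infeasible")
  expect_equal(res2$target, "ghost_c")
  expect_error(gapfill(m, uni, target = "nonexistent"),
               "not resolvable")
})

test_that("MILP cost equals exhaustive minimal-subset search on random universes", {
  # randomized multi-gap scenes: both transport and conversion deleted,
  # so the optimum needs two specific additions among decoys
  tb <- gen_toy_network(1, yields = 0.5)
  m0 <- remove_reactions(tb$model, c("T_sub", "R_route1"))
  set.seed(21)
  for (rep in 1:5) {
    n_dec <- sample(4:9, 1)
    decs <- lapply(seq_len(n_dec), function(i) {
      kind <- sample(3, 1)
      st <- switch(kind,
                   c(sub_c = -1, sub_e = 1),
                   c(bm_c = -1, sub_c = 1),
                   c(sub_c = -1))
      reaction(sprintf("U_dec%02d", i), st)
    })
    uni <- metabolic_model(
      "uniR", c(c = "cytoplasm", e = "extracellular"),
      metabolites = m0$metabolites,
      reactions = c(list(
        reaction("U_fix_transport", c(sub_e = -1, sub_c = 1)),
        reaction("U_fix_route", c(sub_c = -1, bm_c = 0.5))),
        decs))
    expect_lte(length(uni$reactions), 12)
    got <- gapfill(m0, uni, target = "BIOMASS", medium = c(EX_sub = 10))
    want <- gapfill_oracle(m0, uni, "BIOMASS", c(EX_sub = 10))
    expect_equal(got$cost, want$cost, label = paste("rep", rep))
    expect_equal(got$status, "optimal")
    # minimality: no proper subset of the returned set suffices
    if (length(got$added) <= 3 && length(got$added) > 0) {
      for (drop in got$added) {
        sub <- setdiff(got$added, drop)
        aug <- m0
        for (rid in sub) aug <- add_reaction(aug, uni$reactions[[rid]])
        sol <- fba(aug, medium = c(EX_sub = 10), objective = "BIOMASS")
        expect_lt(ifelse(sol$status == "optimal", sol$objective, 0),
                  1e-3)
      }
    }
  }
})

test_that("gap-fill cost is monotone non-decreasing in epsilon", {
  m <- broken_chain()
  # a weaker parallel repair with a tight capacity: cheap but only
  # enough for small targets
  uni <- metabolic_model(
    "uni3", c(c = "cytoplasm", e = "extracellular"),
    metabolites = m$metabolites,
    reactions = list(
      reaction("U_narrow", c(sub_e = -1, sub_c = 1),
               upper_bound = 0.004),
      reaction("U_wide_a", c(sub_e = -1, sub_c = 1)),
      reaction("U_wide_b", c(sub_e = -1, sub_c = 1))))
  costs <- vapply(c(1e-3, 1e-2, 1), function(eps) {
    gapfill(m, uni, target = "BIOMASS", medium = c(EX_sub = 10),
            weights = c(U_narrow = 0.5, U_wide_a = 2, U_wide_b = 2),
            epsilon = eps)$cost
  }, numeric(1))
  expect_true(all(diff(costs) >= -1e-9))
  expect_lt(costs[1], costs[3])
})

test_that("iterative gap filling shares repairs across conditions", {
  m <- broken_chain()
  uni <- universal_db(m)
  conds <- list(
    list(name = "rich", medium = c(EX_sub = 10), target = "BIOMASS"),
    list(name = "lean", medium = c(EX_sub = 2), target = "BIOMASS"))
  res <- iterative_condition_gapfill(m, uni, conds)
  # the shared missing transport is added once, provenance lists both
  expect_identical(res$union, "U_repair")
  expect_identical(res$per_condition$rich$added, "U_repair")
  expect_equal(res$per_condition$lean$status, "already_feasible")
  expect_setequal(
    res$provenance$condition[res$provenance$reaction == "U_repair"],
    c("rich", "lean"))
  # the working model now grows under both conditions
  expect_gt(fba(res$model, medium = c(EX_sub = 2))$objective, 0)
})

test_that("union of disjoint repairs is order-independent", {
  tb <- gen_toy_network(1, yields = 0.5)
  # two independent targets: biomass (needs transport) and an isolated
  # metabolite fed only by a universal reaction
  m <- remove_reactions(tb$model, "T_sub")
  m$metabolites$iso_c <- metabolite("iso_c", compartment = "c")
  uni <- universal_db(m, extra = list(
    reaction("U_iso", c(sub_c = -1, iso_c = 1))))
  conds_ab <- list(
    list(name = "grow", medium = c(EX_sub = 10), target = "BIOMASS"),
    list(name = "iso", medium = c(EX_sub = 10), target = "iso_c"))
  conds_ba <- rev(conds_ab)
  res_ab <- iterative_condition_gapfill(m, uni, conds_ab)
  res_ba <- iterative_condition_gapfill(m, uni, conds_ba)
  expect_identical(res_ab$union, res_ba$union)
  expect_setequal(res_ab$union, c("U_repair", "U_iso"))
})
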