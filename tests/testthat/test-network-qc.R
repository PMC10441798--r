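make_balance_model <- function(drop_h = FALSE) {
  st <- c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1)
  if (drop_h) st <- st[names(st) != "h_c"]
  metabolic_model(
    "hex", c(c = "cytoplasm", p = "periplasm", e = "extracellular"),
    metabolites = list(
      metabolite("glc_c", compartment = "c", formula = "C6H12O6",
                 charge = 0L),
      metabolite("atp_c", compartment = "c", formula = "C10H12N5O13P3",
                 charge = -4L),
      metabolite("g6p_c", compartment = "c", formula = "C6H11O9P",
                 charge = -2L),
      metabolite("adp_c", compartment = "c", formula = "C10H12N5O10P2",
                 charge = -3L),
      metabolite("h_c", compartment = "c", formula = "H", charge = 1L),
      metabolite("A_c", compartment = "c", formula = "C2H4O2",
                 charge = 0L),
      metabolite("A_p", compartment = "p", formula = "C2H4O2",
                 charge = 0L),
      metabolite("mys_c", compartment = "c")),
    reactions = list(
      reaction("HEX", st, gpr = "g1"),
      reaction("TRANS", c(A_c = -1, A_p = 1)),
      reaction("MYST", c(A_c = -1, mys_c = 1)),
      reaction("SK_A", c(A_p = -1), kind = "sink")))
}

test_that("formula parsing follows Hill notation", {
  expect_equal(parse_formula("C6H12O6"),
               c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_formula("H"), c(H = 1L))
  expect_equal(parse_formula("C10H12N5O13P3"),
               c(C = 10L, H = 12L, N = 5L, O = 13L, P = 3L))
  expect_equal(parse_formula("FeS4C2")[["Fe"]], 1L)
  expect_error(parse_formula("C6!H12"), "parse error")
  expect_error(parse_formula(""), "empty")
})

test_that("hexokinase-style reaction balances element by element", {
  ok <- check_balances(make_balance_model())
  hex <- ok$report[ok$report$reaction == "HEX", ]
  expect_equal(hex$status, "balanced")
  expect_equal(hex$net_charge, 0)

  # dropping the proton leaves H: -1 and charge: -1
  bad <- check_balances(make_balance_model(drop_h = TRUE))
  hex2 <- bad$report[bad$report$reaction == "HEX", ]
  expect_equal(hex2$status, "unbalanced")
  expect_match(hex2$imbalance, "H:-1")
  expect_equal(hex2$net_charge, -1)
  expect_false(bad$pass)
})

test_that("transport is balanced, unknown formulas and boundary exempt", {
  rep <- check_balances(make_balance_model())$report
  expect_equal(rep$status[rep$reaction == "TRANS"], "balanced")
  expect_equal(rep$status[rep$reaction == "MYST"], "unknown")
  expect_equal(rep$status[rep$reaction == "SK_A"], "exempt")
})

test_that("balanced reactions conserve every element under random fluxes", {
  m <- make_balance_model()
  rep <- check_balances(m)$report
  balanced <- rep$reaction[rep$status == "balanced"]
  # element content vector of each metabolite
  elems <- c("C", "H", "O", "N", "P")
  content <- sapply(names(m$metabolites), function(mid) {
    f <- m$metabolites[[mid]]$formula
    out <- stats::setNames(numeric(length(elems)), elems)
    if (!is.na(f)) {
      cnt <- parse_formula(f)
      out[names(cnt)] <- cnt
    }
    out
  })
  S <- as.matrix(stoichiometric_matrix(m))
  set.seed(8)
  for (rep_i in 1:10) {
    v <- stats::setNames(stats::runif(ncol(S), -5, 5), colnames(S))
    v[setdiff(colnames(S), balanced)] <- 0
    # net element production under any flux through balanced reactions
    net <- content %*% (S %*% v)
    expect_lt(max(abs(net)), 1e-9)
  }
})

test_that("dead-end classification matches the bipartite oracle on 100 random networks", {
  for (seed in 1:100) {
    m <- random_small_model(seed)
    expect_identical(find_dead_ends(m), dead_end_oracle(m),
                     label = paste("seed", seed))
  }
})

test_that("dead-end report is invariant under reaction reordering", {
  m <- random_small_model(7)
  m2 <- m
  m2$reactions <- rev(m2$reactions)
  expect_identical(find_dead_ends(m), find_dead_ends(m2))
})

test_that("dead-end motives classify as planted", {
  td <- gen_toy_network(1, yields = 0.5, plant_dead_end = TRUE)
  de <- find_dead_ends(td$model)
  expect_true(all(td$truth$dead_ends %in% de$metabolite))
  # waste_c sits in exactly one (irreversible) reaction
  expect_equal(de$class[de$metabolite == "waste_c"], "single_reaction")

  # a terminal chain product with no consumer across two producers
  m <- metabolic_model(
    "term", c(c = "cytoplasm"),
    metabolites = list(metabolite("a_c", compartment = "c"),
                       metabolite("b_c", compartment = "c"),
                       metabolite("z_c", compartment = "c")),
    reactions = list(
      reaction("R1", c(a_c = -1, z_c = 1)),
      reaction("R2", c(b_c = -1, z_c = 1)),
      reaction("R3", c(a_c = -1, b_c = 1))))
  de2 <- find_dead_ends(m)
  expect_equal(de2$class[de2$metabolite == "z_c"], "product_only")
})

test_that("removing an unused dead-end reaction leaves the optimum unchanged", {
  td <- gen_toy_network(1, yields = c(0.5, 0.8), plant_dead_end = TRUE)
  mu0 <- fba(td$model, medium = c(EX_sub = 10))$objective
  # the planted dead-end branch carries no flux at the optimum
  m2 <- remove_reactions(td$model, "D_waste")
  expect_equal(fba(m2, medium = c(EX_sub = 10))$objective, mu0)
})

test_that("orphan listing groups by subsystem and partitions correctly", {
  m <- gen_toy_network(1, yields = c(0.5, 0.8))$model
  expect_length(list_orphans(m)$orphans, 0)

  m$reactions$R_route1$gpr <- ""
  m$reactions$R_route1$gpr_ast <- NULL
  m$reactions$R_route2$gpr <- ""
  m$reactions$R_route2$gpr_ast <- NULL
  orp <- list_orphans(m)
  expect_identical(orp$orphans, c("R_route1", "R_route2"))
  expect_equal(sum(orp$by_subsystem$count), length(orp$orphans))
})
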