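test_that("formulas parse into typed literals", {
  f <- parse_formula("forall p. SPa(p) & MDPa(p) & MAPa(p) & DPa(p) -> HT(p)")
  expect_length(f$antecedents, 4L)
  expect_true(all(vapply(f$antecedents, `[[`, "", "type") == "symptom"))
  expect_identical(vapply(f$antecedents, `[[`, "", "symptom"),
                   c("SP", "MDP", "MAP", "DP"))
  expect_identical(f$consequent, "HT")
  expect_identical(f$connective, "and")

  g <- parse_formula("forall p. MAPb(p) & SPb(p) & Low_BV(p) -> HPT(p)")
  types <- vapply(g$antecedents, `[[`, "", "type")
  expect_identical(types, c("symptom", "symptom", "hypothesis"))
  expect_identical(g$antecedents[[3]]$name, "Low_BV")

  d <- parse_formula("forall p. Xa(p) | Yb(p) -> H(p)")
  expect_identical(d$connective, "or")
})

test_that("unicode dialect is normalized before parsing", {
  u <- parse_formula("∀p·(SPa(p)∧MDPa(p)∧MAPa(p)∧DPa(p) ⟶HT(p))")
  a <- parse_formula("forall p. SPa(p) & MDPa(p) & MAPa(p) & DPa(p) -> HT(p)")
  expect_identical(u$consequent, a$consequent)
  expect_identical(vapply(u$antecedents, `[[`, "", "name"),
                   vapply(a$antecedents, `[[`, "", "name"))
})

test_that("malformed formulas are rejected with a reason", {
  expect_error(parse_formula("forall p. -> X(p)"), "antecedent")
  expect_error(parse_formula("SPa(p) -> HT(p)"), "forall")
  expect_error(parse_formula("forall p. SPa(q) -> HT(p)"), "binds")
  expect_error(parse_formula("forall p. Aa(p) & Bb(p) | Cc(p) -> H(p)"), "mixed")
  expect_error(parse_formula("forall p. Aa(p) & H(p) -> H(p)"), "own antecedents")
})

test_that("a single conjunction formula builds a two-stage net above the symptoms", {
  net <- build_net("forall p. SPa(p) & MDPa(p) & MAPa(p) & DPa(p) -> HT(p)")
  types <- vapply(net$nodes, `[[`, "", "type")
  expect_identical(sum(types == "symptom"), 4L)
  expect_identical(sum(types == "logic"), 1L)
  expect_identical(sum(types == "hypothesis"), 1L)
  stages <- vapply(net$nodes, `[[`, 0L, "stage")
  expect_identical(max(stages), 2L)
  expect_true(all(stages[types == "symptom"] == 0L))
})

test_that("the bundled knowledge base builds the expected topology", {
  kb <- read_knowledge_base()
  expect_length(kb, 12L)
  net <- build_net(kb)
  hyps <- names(Filter(function(n) n$type == "hypothesis", net$nodes))
  expect_length(hyps, 12L)
  expect_setequal(hyps, c("HT", "HPT", "Low_BV", "TC", "BC", "Low_BE",
                          "High_BE", "Low_CPP", "High_CPP", "HV", "HPV",
                          "Dyn_HV"))
  st <- function(n) net$nodes[[n]]$stage
  expect_gt(st("HPT"), st("Low_BV"))
  expect_gt(st("Dyn_HV"), st("HV"))
  # Dyn_HV consumes HV plus 5 symptom literals
  logic <- net$edges$from[net$edges$to == "Dyn_HV"]
  ins <- net$edges$from[net$edges$to == logic]
  expect_length(ins, 6L)
  expect_true("HV" %in% ins)
  expect_length(setdiff(ins, "HV"), 5L)
  # terminal hypotheses have no outbound edges
  for (h in c("TC", "BC", "HPT", "HT", "Dyn_HV", "Low_BE", "High_BE",
              "Low_CPP", "High_CPP"))
    expect_length(net$edges$to[net$edges$from == h], 0L)
})

test_that("stage numbers strictly increase along every edge", {
  net <- build_net(read_knowledge_base())
  st <- vapply(net$nodes, `[[`, 0L, "stage")
  expect_true(all(st[net$edges$to] > st[net$edges$from]))
})

test_that("construction is deterministic under formula reordering", {
  kb <- read_knowledge_base()
  n1 <- build_net(kb)
  n2 <- build_net(rev(kb))
  expect_identical(names(n1$nodes), names(n2$nodes))
  expect_identical(n1$edges, n2$edges)
  expect_identical(vapply(n1$nodes, `[[`, 0L, "stage"),
                   vapply(n2$nodes, `[[`, 0L, "stage"))
})

test_that("cycles and dangling hypothesis literals are build errors", {
  expect_error(build_net(c("forall p. B(p) -> A(p)", "forall p. A(p) -> B(p)")),
               "cyclic")
  expect_error(build_net("forall p. Nowhere(p) -> X(p)"), "dangling")
})

test_that("shared consequents combine through an implicit disjunction node", {
  net <- build_net(c("forall p. Aa(p) & Bb(p) -> H(p)",
                     "forall p. Cc(p) -> H(p)"))
  ops <- vapply(Filter(function(n) n$type == "logic", net$nodes), `[[`, "", "op")
  expect_identical(sort(unname(ops)), c("and", "and", "or"))
  expect_identical(net$edges$from[net$edges$to == "H"], "H:or")
})

test_that("nets round-trip through JSON with quantification intact", {
  net <- assign_poi_params(build_net(read_knowledge_base()))
  net$nodes[["HT"]]$prior <- 0.07  # a user-pinned value must survive
  tmp <- withr::local_tempfile(fileext = ".json")
  net_to_config(net, tmp)
  back <- config_to_net(tmp)
  expect_identical(names(back$nodes), names(net$nodes))
  expect_identical(back$edges, net$edges)
  for (nm in names(net$nodes)) {
    expect_identical(back$nodes[[nm]]$stage, net$nodes[[nm]]$stage)
    expect_equal(back$nodes[[nm]]$prior, net$nodes[[nm]]$prior)
    expect_equal(back$nodes[[nm]]$ls, net$nodes[[nm]]$ls)
    expect_equal(back$nodes[[nm]]$ln, net$nodes[[nm]]$ln)
  }
  expect_equal(back$nodes[["HT"]]$prior, 0.07)
})

test_that("an empty net serializes to an empty config and back", {
  net <- build_net(list())
  tmp <- withr::local_tempfile(fileext = ".json")
  net_to_config(net, tmp)
  expect_length(config_to_net(tmp)$nodes, 0L)
})
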