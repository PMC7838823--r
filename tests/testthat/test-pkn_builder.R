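test_that("signed interaction tables map flags to edges", {
  rows <- data.frame(source = c("A", "A", "A", "B"),
                     target = c("B", "B", "B", "C"),
                     is_stimulation = c(1, 0, 1, 0),
                     is_inhibition = c(0, 0, 1, 1))
  e <- parse_ppi_table(rows)
  expect_true(all(e$provenance == "ppi"))
  # stim-only row -> +1 edge; unsigned row dropped; both flags -> both signs
  expect_setequal(paste(e$source, e$sign, e$target),
                  c("A 1 B", "A -1 B", "B -1 C"))
  expect_error(parse_ppi_table(rows[, -3]), "is_stimulation")
})

test_that("allosteric tables respect score threshold and action mapping", {
  rows <- data.frame(metabolite = c("metab__m1", "metab__m1", "metab__m2"),
                     protein = c("P1", "P2", "P3"),
                     action = c("activation", "activation", "inhibition"),
                     score = c(900, 899, 950))
  e <- parse_allosteric_table(rows, min_score = 900)
  expect_equal(nrow(e), 2L) # 899 falls below the inclusive threshold
  expect_equal(e$sign[e$target == "P1"], 1L)
  expect_equal(e$sign[e$target == "P3"], -1L)
  expect_true(all(e$provenance == "allosteric"))
  rows$action[1] <- "binds"
  expect_error(parse_allosteric_table(rows), "action")
})

test_that("GPR rules expand to minimal DNF", {
  expect_equal(gpr_to_dnf("E"), list("E"))
  expect_equal(gpr_to_dnf("E1 AND E2"), list(c("E1", "E2")))
  expect_equal(gpr_to_dnf("E1 OR E2"), list("E1", "E2"))
  expect_equal(gpr_to_dnf("(A or B) and C"),
               list(c("A", "C"), c("B", "C")))
  # absorption: A OR (A AND B) is just A
  expect_equal(gpr_to_dnf("A OR (A AND B)"), list("A"))
  expect_error(parse_gpr("A AND (B OR"), "unexpected end|unbalanced")
  expect_error(parse_gpr("AND B"), "malformed")
})

test_that("DNF equals truth-table minimal models on random monotone rules", {
  for (seed in 1:25) {
    rule <- random_gpr(seed)
    expect_identical(gpr_to_dnf(rule), truth_table_minimal_models(rule),
                     info = rule)
  }
})

toy_reactions <- function() {
  list(
    list(reaction_id = "R1", reactants = "metab__A", products = "metab__C",
         gpr = "E", is_exchange = FALSE),
    list(reaction_id = "R2", reactants = "metab__A", products = "metab__C",
         gpr = "E1 AND E2", is_exchange = FALSE),
    list(reaction_id = "R3", reactants = "metab__A", products = "metab__C",
         gpr = "E1 OR E2", is_exchange = FALSE),
    # E also catalyzes R4: must not connect metab__D's fate to R1's
    list(reaction_id = "R4", reactants = "metab__D", products = "metab__F",
         gpr = "E", is_exchange = FALSE),
    list(reaction_id = "R5", reactants = "metab__G__e",
         products = "metab__G__c", gpr = "T1", is_exchange = TRUE,
         exchanged_metabolite = "metab__G"))
}

test_that("reaction networks convert to reaction-unique causal edges", {
  pkn <- convert_reaction_network(toy_reactions())
  ek <- paste(pkn$edges$source, pkn$edges$sign, pkn$edges$target)
  expected <- c(
    "metab__A 1 E__R1", "E__R1 1 metab__C",
    "metab__A 1 E1_E2__R2", "E1_E2__R2 1 metab__C",
    "metab__A 1 E1__R3", "E1__R3 1 metab__C",
    "metab__A 1 E2__R3", "E2__R3 1 metab__C",
    "metab__D 1 E__R4", "E__R4 1 metab__F",
    "metab__G__e 1 T1__R5__metab__G", "T1__R5__metab__G 1 metab__G__c")
  expect_setequal(ek, expected)
  expect_equal(unname(pkn$node_kind[["E1_E2__R2"]]), "complex")
  expect_equal(unname(pkn$node_kind[["E__R1"]]), "enzyme_instance")
  # reaction isolation: no directed path from R1's reactant to R4's product
  g <- pkn_to_igraph(pkn)
  d <- igraph::distances(g, v = "metab__A", to = "metab__F", mode = "out")
  expect_true(is.infinite(d[1, 1]))
})

test_that("coenzyme exclusion and the promiscuity filter prune metabolites", {
  rx <- list(
    list(reaction_id = "R1", reactants = c("metab__A", "metab__atp"),
         products = "metab__B", gpr = "E1", is_exchange = FALSE),
    list(reaction_id = "R2", reactants = "metab__B", products = "metab__A",
         gpr = "E2", is_exchange = FALSE))
  pol <- metabolite_policy(coenzyme_ids = "metab__atp",
                           degree_threshold = 338)
  pkn <- convert_reaction_network(rx, pol)
  expect_false("metab__atp" %in% names(pkn$node_kind))
  # hub removal: metab__A has degree 2, drops below a threshold of 1
  pkn2 <- convert_reaction_network(rx, metabolite_policy(
    coenzyme_ids = "metab__atp", degree_threshold = 1))
  expect_false("metab__A" %in% names(pkn2$node_kind))
  # idempotence: re-converting with same policy yields the same network
  expect_identical(
    convert_reaction_network(rx, pol)$edges,
    convert_reaction_network(rx, pol)$edges)
})

test_that("promiscuity filter is monotone in the threshold", {
  set.seed(4)
  rx <- lapply(1:12, function(i) {
    list(reaction_id = paste0("R", i),
         reactants = sample(paste0("metab__m", 1:5), 2),
         products = sample(paste0("metab__m", 6:9), 1),
         gpr = sample(c("E1", "E2", "E1 OR E3"), 1), is_exchange = FALSE)
  })
  counts <- vapply(c(1, 2, 4, 8, 1000), function(th) {
    nrow(convert_reaction_network(
      rx, metabolite_policy(degree_threshold = th))$edges)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("merge_sources deduplicates and assigns node kinds", {
  ppi <- data.frame(source = c("P1", "P2"), sign = 1L,
                    target = c("P2", "P3"), provenance = "ppi")
  alo <- data.frame(source = c("metab__m1", "metab__m2"), sign = -1L,
                    target = c("P1", "P2"), provenance = "allosteric")
  met <- convert_reaction_network(list(
    list(reaction_id = "R1", reactants = "metab__m1",
         products = "metab__m3", gpr = "P9", is_exchange = FALSE)))
  pkn <- merge_sources(ppi, alo, met)
  expect_equal(nrow(pkn$edges), 6L)
  expect_equal(unname(pkn$node_kind[["metab__m1"]]), "metabolite")
  expect_equal(unname(pkn$node_kind[["P1"]]), "protein")
  # duplicate edge keeps first provenance, records both
  dup <- data.frame(source = "P1", sign = 1L, target = "P2",
                    provenance = "transcriptional")
  pkn2 <- merge_sources(ppi, dup)
  expect_equal(nrow(pkn2$edges), 2L)
  expect_equal(pkn2$edges$provenance[pkn2$edges$source == "P1"], "ppi")
  expect_setequal(attr(pkn2, "provenances")[["P1\r1\rP2"]],
                  c("ppi", "transcriptional"))
  expect_equal(nrow(merge_sources()$edges), 0L)
})

test_that("namespace clashes between kinds are rejected", {
  a <- causal_pkn(data.frame(source = "X", sign = 1, target = "P1"),
                  node_kind = c(X = "metabolite", P1 = "protein"))
  b <- causal_pkn(data.frame(source = "X", sign = 1, target = "P2"),
                  node_kind = c(X = "protein", P2 = "protein"))
  expect_error(merge_sources(a, b), "both metabolite and protein")
})

test_that("SIF round-trips through both delimiters", {
  pkn <- causal_pkn(data.frame(
    source = c("A", "metab__x"), sign = c(1, -1), target = c("B", "A"),
    provenance = c("ppi", "allosteric")))
  d <- withr::local_tempdir()
  write_pkn_sif(pkn, file.path(d, "net.sif"), file.path(d, "nodes.tsv"))
  back <- read_pkn_sif(file.path(d, "net.sif"), file.path(d, "nodes.tsv"))
  expect_identical(back$edges, pkn$edges)
  expect_identical(back$node_kind, pkn$node_kind)
  # ";"-delimited dialect
  writeLines(c("source;sign;target", "A;1;B", "B;-1;C"),
             file.path(d, "semi.sif"))
  semi <- read_pkn_sif(file.path(d, "semi.sif"))
  expect_equal(nrow(semi$edges), 2L)
  expect_equal(semi$edges$sign, c(1L, -1L))
})

test_that("reaction tables parse from TSV and JSON dialects", {
  d <- withr::local_tempdir()
  writeLines(c(
    "reaction_id\treactants\tproducts\tgpr\tis_exchange\texchanged_metabolite",
    "R1\tmetab__A,metab__B\tmetab__C\tE1 AND E2\t0\t",
    "R2\tmetab__G__e\tmetab__G__c\tT1\t1\tmetab__G"),
    file.path(d, "rx.tsv"))
  rx <- read_reaction_table(file.path(d, "rx.tsv"))
  expect_length(rx, 2L)
  expect_equal(rx[[1]]$reactants, c("metab__A", "metab__B"))
  expect_true(rx[[2]]$is_exchange)
  jsonlite::write_json(list(list(
    reaction_id = "R9", reactants = list("metab__A"),
    products = list("metab__B"), gpr = "E", is_exchange = FALSE)),
    file.path(d, "rx.json"), auto_unbox = TRUE)
  rxj <- read_reaction_table(file.path(d, "rx.json"))
  expect_equal(rxj[[1]]$reaction_id, "R9")
  expect_equal(rxj[[1]]$gpr, "E")
})
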