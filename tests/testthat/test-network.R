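# independent brute-force enumeration of membrane complexes: count all
# multisets of catalytic-site states per pool and complex size
brute_force_membrane_count <- function(max_m14, n_states = 4, n_pools = 2) {
  per_size <- vapply(seq_len(max_m14), function(n)
    choose(n + n_states - 1, n_states - 1), numeric(1))
  n_pools * sum(per_size)
}

test_that("species enumeration matches an exhaustive composition oracle", {
  net <- build_network(max_m14 = 2)
  mem <- net$species[net$species$type == "membrane", ]
  expect_identical(nrow(mem), as.integer(brute_force_membrane_count(2)))
  expect_true(all(c("M14_D.M14_D.T2.M2", "M14_D.T2.M2.M14_D.T2.M2",
                    "M14_X.M14_X.T2.M2") %in% mem$id))
  expect_false(any(duplicated(net$species$id)))
  # composition bookkeeping: the hexameric dimer-of-trimers
  hex <- net$species[net$species$id == "M14_D.T2.M2.M14_D.T2.M2", ]
  expect_equal(unlist(hex[c("m14", "t2", "m2", "fn")], use.names = FALSE),
               c(2, 2, 2, 0))

  net4 <- enumerate_species(max_m14 = 4)
  expect_identical(sum(net4$type == "membrane"),
                   as.integer(brute_force_membrane_count(4)))
  expect_error(enumerate_species(max_m14 = 1), "dimer")
})

test_that("disabling all binding leaves only monomeric species", {
  rules <- network_rules(dimerization = FALSE, t2_binding = FALSE,
                         m2_binding = FALSE, fn_binding = FALSE)
  sp <- enumerate_species(2, rules)
  expect_true(all(sp$m14 + sp$t2 + sp$m2 + sp$fn == 1))
  expect_identical(sort(sp$id[sp$type == "membrane"]), c("M14_D", "M14_X"))
  # no activation products without the quadruple complex
  expect_false("M2act" %in% sp$id)
})

test_that("every generated reaction conserves the monomer ledgers", {
  net <- build_network(max_m14 = 2)
  # the generator self-checks; verify independently on the exported table
  w <- ledger_weights(net)
  for (i in seq_len(nrow(net$reactions))) {
    lhs <- strsplit(net$reactions$reactants[i], " \\+ ")[[1]]
    rhs <- strsplit(net$reactions$products[i], " \\+ ")[[1]]
    expect_identical(colSums(w[lhs, , drop = FALSE]),
                     colSums(w[rhs, , drop = FALSE]))
  }
  expect_error(
    generate_reactions(enumerate_species(2), rates = list(kon_t2 = 1)),
    "unresolved rate")
})

test_that("network generation is deterministic and canonically ordered", {
  a <- build_network(2)
  b <- build_network(2)
  expect_identical(a$reactions, b$reactions)
  expect_identical(a$species, b$species)
})

test_that("the activation path exists and requires TIMP-2 and dimerization", {
  net <- build_network(2)
  seeds <- c("M14_ves", "M2pro", "fn", "T2")
  reach <- reachable_species(net, seeds)
  # path proMMP-2 -> quadruple complex -> active MMP-2 -> inactivated M2.T2
  expect_true(all(c("M14_D.M14_D.T2.M2", "M2act", "M2act.T2", "fn_deg") %in% reach))
  # without TIMP-2 the quadruple complex is unreachable: no activation
  no_t2 <- reachable_species(net, setdiff(seeds, "T2"))
  expect_false("M2act" %in% no_t2)
  expect_false(any(grepl("T2", no_t2)))
  # without dimerization there is no activation reaction at all
  mono <- build_network(2, rules = network_rules(dimerization = FALSE))
  expect_false(any(grepl("^act:", mono$reactions$id)))
  expect_true(any(grepl("^act:", net$reactions$id)))
})

test_that("reaction TSV export round-trips and counts match", {
  net <- build_network(2)
  p <- withr::local_tempfile(fileext = ".tsv")
  export_network_tsv(net, p)
  hdr <- readLines(p, n = 2)
  expect_identical(hdr, c(paste0("# species: ", nrow(net$species)),
                          paste0("# reactions: ", nrow(net$reactions))))
  back <- import_network_tsv(p)
  expect_equal(back, net$reactions, tolerance = 1e-12)
})

test_that("SBML export is well-formed and complete", {
  skip_if_not_installed("xml2")
  net <- build_network(2)
  p <- withr::local_tempfile(fileext = ".xml")
  export_network_sbml(net, p)
  doc <- xml2::read_xml(p)
  expect_identical(xml2::xml_name(doc), "sbml")
  ns <- xml2::xml_ns(doc)
  sp <- xml2::xml_find_all(doc, ".//d1:species", ns)
  rx <- xml2::xml_find_all(doc, ".//d1:reaction", ns)
  expect_identical(length(sp), nrow(net$species))
  expect_identical(length(rx), nrow(net$reactions))
})
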