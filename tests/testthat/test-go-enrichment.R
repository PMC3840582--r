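test_that("annotation propagation follows the true-path rule and is idempotent", {
  parents <- list(leaf = "mid", mid = "root", root = character(0))
  map <- annotation_map(data.frame(gene = "g1", term = "leaf"), parents)
  p1 <- propagate_annotations(map)
  expect_setequal(names(Filter(function(g) "g1" %in% g, p1$ann)),
                  c("leaf", "mid", "root"))
  p2 <- propagate_annotations(p1)
  expect_identical(p1$ann[order(names(p1$ann))], p2$ann[order(names(p2$ann))])

  # empty ontology leaves the map unchanged
  flat <- annotation_map(data.frame(gene = "g1", term = "t"))
  expect_identical(propagate_annotations(flat)$ann, flat$ann)

  cyc <- annotation_map(data.frame(gene = "g", term = "a"),
                        list(a = "b", b = "a"))
  expect_error(propagate_annotations(cyc), "cycle")
})

test_that("term_for_term reproduces the hand-derived hypergeometric tail", {
  pop <- paste0("g", 1:20)
  df <- rbind(data.frame(gene = paste0("g", 1:5), term = "T"),
              data.frame(gene = pop, term = "ALL"))
  map <- annotation_map(df)
  study <- paste0("g", c(1, 2, 3, 6, 7))   # 3 of 5 annotated to T
  res <- term_for_term(study, pop, map)
  pT <- res$p_raw[res$term == "T"]
  expect_equal(pT, 1126 / 15504, tolerance = 1e-9)
  expect_equal(pT, hyper_tail_oracle(20, 5, 5, 3), tolerance = 1e-12)
  # Bonferroni over the number of tested terms (2 here)
  expect_equal(res$p_adj[res$term == "T"], pT * 2)
  expect_true(all(res$p_adj >= res$p_raw))
  expect_equal(res$study_count[res$term == "T"], 3)
  expect_equal(res$pop_count[res$term == "T"], 5)

  # with ten tested terms the correction factor is 10
  df10 <- rbind(data.frame(gene = paste0("g", 1:5), term = "T"),
                do.call(rbind, lapply(1:9, function(i)
                  data.frame(gene = "g1", term = paste0("X", i)))))
  res10 <- term_for_term(study, pop, annotation_map(df10))
  expect_equal(res10$p_adj[res10$term == "T"],
               min(1, 1126 / 15504 * 10), tolerance = 1e-9)

  # degenerate case: every population gene annotated -> p = 1
  expect_equal(res$p_raw[res$term == "ALL"], 1)
})

test_that("untestable terms and invalid study sets are handled", {
  map <- annotation_map(data.frame(gene = c("g1", "g2"),
                                   term = c("A", "B")))
  res <- term_for_term("g1", c("g1", "g2"), map)
  expect_equal(res$term, "A")   # B has study_count 0: not tested
  expect_equal(res$p_adj, res$p_raw)  # correction factor 1
  expect_error(term_for_term("zz", c("g1", "g2"), map), "subset")
})

test_that("the OBO reader extracts is_a relations and skips obsolete terms", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000002", "name: child",
               "is_a: GO:0000001 ! parent", "",
               "[Term]", "id: GO:0000001", "name: parent", "",
               "[Term]", "id: GO:0000009", "name: gone",
               "is_obsolete: true", "",
               "[Typedef]", "id: part_of"), obo)
  parents <- read_obo(obo)
  expect_setequal(names(parents), c("GO:0000001", "GO:0000002"))
  expect_equal(parents[["GO:0000002"]], "GO:0000001")
  expect_length(parents[["GO:0000001"]], 0)
})
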