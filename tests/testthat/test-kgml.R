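test_that("KGML fixture parses to the hand-counted node and edge sets", {
  pw <- read_kgml(extdata("synthetic_pathway.kgml"))
  kinds <- table(pw$nodes$kind)
  expect_equal(unname(kinds[["protein"]]), 6)
  expect_equal(unname(kinds[["compound"]]), 1)
  expect_equal(unname(kinds[["group"]]), 1)
  expect_equal(nrow(pw$directed_edges), 5)
  expect_setequal(pw$group_members[["group_7"]], c("GENE_D", "GENE_E"))
})

test_that("minimal KGML documents parse entry and relation elements", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<pathway title="two gene toy">',
               '<entry id="1" name="P1" type="gene"/>',
               '<entry id="2" name="P2" type="gene"/>',
               '<relation entry1="1" entry2="2"/>',
               '</pathway>'), f)
  pw <- read_kgml(f)
  expect_equal(sum(pw$nodes$kind == "protein"), 2)
  expect_equal(pw$directed_edges,
               data.frame(from = "P1", to = "P2", stringsAsFactors = FALSE))
  # dangling relation reference
  writeLines(c('<pathway><entry id="1" name="P1" type="gene"/>',
               '<relation entry1="1" entry2="9"/></pathway>'), f)
  expect_error(read_kgml(f), "entry")
})

test_that("pathway conversion drops compounds, expands groups, fixes confidence", {
  pw <- read_kgml(extdata("synthetic_pathway.kgml"))
  net <- suppressMessages(pathway_to_network(pw))
  # all edges carry the uniform pathway confidence
  expect_true(all(net$edges$confidence == 0.6))
  expect_true(all(net$edges$source == "kegg"))
  # no compound-derived node, and no bridging through the dropped compound
  expect_false(any(grepl("cpd:", net$nodes)))
  g <- as.data.frame(net$edges[, c("u", "v")])
  expect_false(any(g$u == "GENE_F" | g$v == "GENE_F"))
  # group of 2: clique edge D-E plus re-attachment B-D, B-E
  keys <- paste(net$edges$u, net$edges$v)
  expect_true(all(c("GENE_D GENE_E", "GENE_B GENE_D", "GENE_B GENE_E")
                  %in% keys))
  expect_equal(nrow(net$edges), 5)
})

test_that("a group of three proteins expands to a three-edge clique", {
  pw <- pathway_graph("toy",
                      data.frame(id = "g1", kind = "group"),
                      group_members = list(g1 = c("P1", "P2", "P3")))
  net <- pathway_to_network(pw)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$confidence == 0.6))
})

test_that("edges into a group re-attach to every member", {
  pw <- pathway_graph("toy",
                      data.frame(id = c("A", "g1"),
                                 kind = c("protein", "group")),
                      data.frame(from = "A", to = "g1"),
                      group_members = list(g1 = c("B", "C")))
  net <- pathway_to_network(pw)
  keys <- paste(net$edges$u, net$edges$v)
  expect_setequal(keys, c("A B", "A C", "B C"))
})

test_that("anchor/terminal extraction follows the degree rule", {
  chain <- pathway_graph("chain",
                         data.frame(id = c("a", "b", "c"), kind = "protein"),
                         data.frame(from = c("a", "b"), to = c("b", "c")))
  at <- extract_anchors_terminals(chain)
  expect_equal(at$anchors, "a")
  expect_equal(at$terminals, "c")

  fan <- pathway_graph("fan",
                       data.frame(id = c("a", "b", "c"), kind = "protein"),
                       data.frame(from = c("a", "a"), to = c("b", "c")))
  at2 <- extract_anchors_terminals(fan)
  expect_equal(at2$anchors, "a")
  expect_setequal(at2$terminals, c("b", "c"))

  # isolated node excluded with a warning; anchors and terminals disjoint
  iso <- pathway_graph("iso",
                       data.frame(id = c("a", "b", "c", "d"),
                                  kind = "protein"),
                       data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_warning(at3 <- extract_anchors_terminals(iso), "isolated")
  expect_equal(at3$anchors, "a")
  expect_equal(at3$terminals, "c")
  expect_length(intersect(at3$anchors, at3$terminals), 0)

  # cycle: no anchors/terminals -> unusable for training
  cyc <- pathway_graph("cyc",
                       data.frame(id = c("a", "b"), kind = "protein"),
                       data.frame(from = c("a", "b"), to = c("b", "a")))
  expect_error(extract_anchors_terminals(cyc), "unusable")
})
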