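test_that("count table round-trips through TSV exactly", {
  m <- matrix(c(5L, 0L, 2L, 7L), 2, dimnames = list(c("S1", "S2"),
                                                    c("F1", "F2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(m, f)
  expect_identical(read_count_table(f), m)
  # and a second write/read of the read result is a fixed point
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(read_count_table(f), f2)
  expect_identical(read_count_table(f2), m)
})

test_that("malformed count tables are rejected, not coerced", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tF1", "S1\t3", "S1\t4"), f)
  expect_error(read_count_table(f), "duplicate sample")
  m <- matrix(c(1, -2, 3, 4), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(validate_count_table(m), "negative or non-integer")
  m2 <- matrix(c(1, 2.5, 3, 4), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(validate_count_table(m2), "negative or non-integer")
})

test_that("transposed count table only read when ids prove orientation", {
  m <- matrix(c(5L, 0L, 2L, 7L), 2, dimnames = list(c("S1", "S2"),
                                                    c("F1", "F2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(t(m), f)   # features as rows
  expect_identical(read_count_table(f, sample_ids = c("S1", "S2")), m)
  expect_error(read_count_table(f, sample_ids = c("Q1", "Q2")),
               "orientation")
})

test_that("lineage strings split into seven ranks", {
  lin <- parse_lineage(
    "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Dorea; s__")
  expect_equal(unname(lin[1, "genus"]), "Dorea")
  expect_equal(unname(lin[1, "species"]), "")
  short <- parse_lineage("k__Bacteria; p__Proteobacteria")
  expect_equal(unname(short[1, "phylum"]), "Proteobacteria")
  expect_equal(unname(short[1, "class"]), "")
})

test_that("taxonomy round-trips and rejects duplicate feature ids", {
  tax <- data.frame(feature_id = c("A1", "A2"),
                    kingdom = "Bacteria", phylum = "Firmicutes",
                    class = "Clostridia", order = "Clostridiales",
                    family = "Lachnospiraceae", genus = c("Dorea", "Blautia"),
                    species = "", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, f)
  expect_equal(read_taxonomy(f)$genus, c("Dorea", "Blautia"))
  writeLines(c("feature_id\tlineage", "A1\tk__B", "A1\tk__B"), f)
  expect_error(read_taxonomy(f), "duplicate feature")
})

test_that("newick trees parse with tips and branch lengths intact", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2):0;", f)
  tree <- read_tree(f)
  expect_equal(sort(tree$tip.label), c("A", "B"))
  expect_equal(sum(tree$edge.length), 3)
  writeLines("((A:1,B:2", f)
  expect_error(read_tree(f))
})

test_that("clinical frames round-trip with declared kinds", {
  fr <- clinical_frame(c("S1", "S2", "S3", "S4"),
                       c("MCU", "MCU", "MUD", "MUD"),
                       variables = list(fatigue = c(0L, 1L, 1L, 1L),
                                        age = c(30.5, 41, 37, 29)),
                       kinds = c(fatigue = "binary", age = "continuous"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(fr, f)
  back <- read_clinical(f)
  expect_equal(back$fatigue, fr$fatigue)
  expect_equal(back$age, fr$age)
  expect_equal(clinical_kinds(back), clinical_kinds(fr))
})

test_that("clinical reader demands a group column and a #types row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage", "#types\tcontinuous", "S1\t30"), f)
  expect_error(read_clinical(f), "group")
  writeLines(c("sample_id\tgroup\tage", "S1\tMCU\t30"), f)
  expect_error(read_clinical(f), "#types")
})

test_that("samples missing from metadata are reported, not dropped silently", {
  m <- matrix(1L, 2, 1, dimnames = list(c("S1", "S9"), "F1"))
  fr <- clinical_frame("S1", "MCU")
  expect_warning(out <- check_sample_coverage(m, fr), "S9")
  expect_equal(out, "S9")
})

test_that("graph export writes all three formats readably", {
  edges <- data.frame(u = c("Dorea", "Dorea"), v = c("fatigue", "craving"),
                      type_u = "genus", type_v = "clinical",
                      rho = c(0.5, -0.4), p = c(0.001, 0.002),
                      p_adj = c(0.01, 0.02), sign = c(1, -1),
                      stringsAsFactors = FALSE)
  net <- undirected_net(edges)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(net, f, "graphml")
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 2)

  f2 <- withr::local_tempfile(fileext = ".gexf")
  write_graph_file(net, f2, "gexf")
  doc <- xml2::read_xml(f2)  # must be well-formed XML
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")), 3)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 2)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_graph_file(net, f3, "edgelist-tsv")
  expect_equal(nrow(utils::read.delim(f3)), 2)

  expect_error(write_graph_file(net, f3, "dot"))
})

test_that("empty network exports a valid zero-edge file", {
  empty <- undirected_net(data.frame(u = character(), v = character(),
                                     type_u = character(),
                                     type_v = character(), rho = numeric(),
                                     p = numeric(), p_adj = numeric(),
                                     sign = numeric()))
  f <- withr::local_tempfile(fileext = ".gexf")
  write_graph_file(empty, f, "gexf")
  doc <- xml2::read_xml(f)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 0)
})
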