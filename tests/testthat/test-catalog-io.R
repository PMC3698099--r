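medicinal_header <- c("medicinal_id", "scientific_name", "lineage",
                      "nature", "flavors", "chemical_ids")

write_med_tsv <- function(rows) {
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- medicinal_header
  write_tsv(df, tempfile(fileext = ".tsv"))
}

test_that("duplicate medicinal ids keep first-occurrence annotations and union chemicals", {
  p <- write_med_tsv(list(
    c("M1", "Panax ginseng", "a|b", "hot", "sweet", "C1;C2"),
    c("M2", "Coptis chinensis", "a|c", "cold", "bitter", "C3"),
    c("M1", "Panax ginseng", "a|b", "cold", "sour", "C4")))
  cat <- read_medicinal_catalog(p)
  expect_equal(nrow(cat), 2L)
  expect_equal(cat$medicinal_id, c("M1", "M2"))
  expect_equal(cat$nature[1L], "hot")
  expect_equal(cat$flavors[[1L]], "sweet")
  expect_setequal(cat$chemical_ids[[1L]], c("C1", "C2", "C4"))
})

test_that("empty data section yields an empty catalog without error", {
  p <- write_tsv(stats::setNames(
    as.data.frame(matrix(character(0), 0, 6)), medicinal_header),
    tempfile(fileext = ".tsv"))
  cat <- read_medicinal_catalog(p)
  expect_s3_class(cat, "tcm_catalog")
  expect_equal(nrow(cat), 0L)
})

test_that("unknown nature token errors in strict mode, is dropped in lenient mode", {
  p <- write_med_tsv(list(c("M1", "X", "", "tepid", "sweet", "C1")))
  expect_error(read_medicinal_catalog(p, strict = TRUE), "tepid")
  expect_error(read_medicinal_catalog(p, strict = TRUE), "row 1")
  expect_warning(cat <- read_medicinal_catalog(p, strict = FALSE), "tepid")
  expect_true(is.na(cat$nature[1L]))
})

test_that("chemical id mapping is applied at load time", {
  p <- write_med_tsv(list(c("M1", "X", "", "hot", "sweet", "CAS1;CAS2")))
  m <- write_tsv(data.frame(from_id = "CAS1", to_id = "PUB9"),
                 tempfile(fileext = ".tsv"))
  cat <- read_medicinal_catalog(p, id_map = m)
  expect_setequal(cat$chemical_ids[[1L]], c("PUB9", "CAS2"))
})

test_that("catalog round-trips through write/read and dedup is idempotent", {
  p <- write_med_tsv(list(
    c("M1", "A", "k|f|g|s", "hot", "sweet;mild pungent", "C1;C2"),
    c("M2", "B", "k|f|g|t", "", "", ""),
    c("M1", "A", "k|f|g|s", "cold", "sour", "C9")))
  cat1 <- read_medicinal_catalog(p)
  out <- tempfile(fileext = ".tsv")
  write_medicinal_catalog(cat1, out)
  cat2 <- read_medicinal_catalog(out)
  expect_equal(cat2, cat1)
})

test_that("interaction table normalizes blank actions and collapses duplicates", {
  p <- write_tsv(data.frame(chemical_id = c("C1", "C1", "C1"),
                            protein_id = c("P1", "P2", "P2"),
                            action = c("", "inhibition", "inhibition")),
                 tempfile(fileext = ".tsv"))
  tab <- read_interaction_table(p)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$action[tab$protein_id == "P1"], "unspecified")
  bad <- write_tsv(data.frame(chemical_id = "C1", protein_id = "P1",
                              action = "binds"), tempfile(fileext = ".tsv"))
  expect_error(read_interaction_table(bad), "binds")
})

test_that("bundled modification fixture yields 18 attributes partitioned 7/10/1", {
  f <- system.file("extdata", "modifications_synthetic_enzymes.tsv",
                   package = "tcmepi")
  mc <- read_modification_catalog(f)
  expect_equal(nrow(mc$attributes), 18L)
  tab <- table(mc$attributes$conformation)
  expect_equal(as.integer(tab[c("euchromatic", "heterochromatic",
                                "ambivalent")]),
               c(7L, 10L, 1L))
  expect_equal(mc$attributes$attribute[mc$attributes$conformation ==
                                         "ambivalent"], "ATP")
})

test_that("modification catalog rejects conflicts and missing attributes", {
  f <- system.file("extdata", "modifications_synthetic_enzymes.tsv",
                   package = "tcmepi")
  df <- utils::read.delim(f, colClasses = "character")
  conflicted <- rbind(df, data.frame(attribute_code = "HDAC",
                                     conformation = "euchromatic",
                                     protein_id = "E_X"))
  expect_error(read_modification_catalog(
    write_tsv(conflicted, tempfile(fileext = ".tsv"))), "HDAC")
  short <- df[df$attribute_code != "H3K9", ]
  expect_error(read_modification_catalog(
    write_tsv(short, tempfile(fileext = ".tsv"))), "H3K9")
})

test_that("modification catalog round-trips through write/read", {
  mc <- make_modcat(3L)
  p <- tempfile(fileext = ".tsv")
  write_modification_catalog(mc, p)
  expect_equal(read_modification_catalog(p), mc)
})

test_that("formulas group members per formula and validate membership", {
  cat <- make_catalog(c("M1", "M2", "M3"))
  p <- write_tsv(data.frame(formula_id = c("F1", "F1", "F1", "F2", "F2", "F2"),
                            member_id = c("M1", "M2", "M3", "M3", "M2", "M1")),
                 tempfile(fileext = ".tsv"))
  f <- read_formulas(p, cat)
  expect_equal(nrow(f), 2L)
  expect_equal(lengths(f$member_ids), c(3L, 3L))
  expect_equal(f$member_ids[[2L]], c("M3", "M2", "M1"))

  bad <- write_tsv(data.frame(formula_id = "F1", member_id = "M9"),
                   tempfile(fileext = ".tsv"))
  expect_error(read_formulas(bad, cat), "F1.*M9")
  dup <- write_tsv(data.frame(formula_id = "F1", member_id = c("M1", "M1")),
                   tempfile(fileext = ".tsv"))
  expect_error(read_formulas(dup, cat), "repeated")
})

test_that("tree reading imputes unit branch lengths and rejects duplicates", {
  p1 <- tempfile(fileext = ".nwk"); writeLines("((A:1,B:1):1,C:2);", p1)
  t1 <- read_tcm_tree(p1)
  expect_equal(sort(t1$tip.label), c("A", "B", "C"))
  expect_equal(unname(cophenetic_distances(t1)["A", "B"]), 2)

  p2 <- tempfile(fileext = ".nwk"); writeLines("((A,B),C);", p2)
  t2 <- read_tcm_tree(p2)
  expect_true(all(t2$edge.length == 1))

  p3 <- tempfile(fileext = ".nwk"); writeLines("((A,A),C);", p3)
  expect_error(read_tcm_tree(p3), "duplicate")
})
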