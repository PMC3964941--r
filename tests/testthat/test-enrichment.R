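test_that("GMT parsing deduplicates genes and drops empty terms", {
  g <- read_gmt(c("T1\tdesc one\tG1\tG2\tg2"), "KEGG")
  expect_equal(g$term_id, "T1")
  expect_equal(g$genes[[1]], c("G1", "G2"))
  expect_equal(g$category, "KEGG")
  expect_warning(g2 <- read_gmt(c("T1\td\tG1", "T2\td")), "dropped")
  expect_equal(g2$term_id, "T1")
})

test_that("a perfectly matching query gives the exact single-draw p-value", {
  universe <- sprintf("U%03d", 1:100)
  term_genes <- universe[1:5]
  cat <- read_gmt(paste(c("T1", "d", term_genes), collapse = "\t"))
  res <- enrich(term_genes, cat, universe = universe)
  expect_equal(res$overlap_count, 5L)
  expect_equal(res$p_value, 1 / choose(100, 5), tolerance = 1e-12)
  # one term tested: Bonferroni is the identity
  expect_equal(res$p_bonferroni, res$p_value)
})

test_that("disjoint queries and query == universe give p = 1", {
  universe <- sprintf("U%03d", 1:60)
  cat <- read_gmt(c(
    paste(c("T1", "d", universe[1:10]), collapse = "\t"),
    paste(c("T2", "d", universe[11:30]), collapse = "\t")
  ))
  res <- enrich(universe[31:40], cat, universe = universe)
  expect_equal(res$overlap_count, c(0L, 0L))
  expect_equal(res$p_value, c(1, 1))
  # drawing the whole universe makes every overlap certain
  full <- enrich(universe, cat, universe = universe)
  expect_equal(full$p_value, c(1, 1))
  expect_equal(full$overlap_count, full$term_size)
})

test_that("corrections are ordered and invariant to term order", {
  set.seed(111)
  universe <- sprintf("U%03d", 1:200)
  lines <- vapply(1:12, function(i) {
    paste(c(sprintf("T%02d", i), "d", sample(universe, sample(10:40, 1))),
          collapse = "\t")
  }, character(1))
  cat <- read_gmt(lines)
  query <- sample(universe, 30)
  res <- enrich(query, cat, universe = universe)
  expect_true(all(res$p_bonferroni >= res$q_value - 1e-15))
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  res2 <- enrich(query, cat[sample.int(nrow(cat)), ], universe = universe)
  expect_equal(res2[order(res2$term_id), ]$q_value,
               res[order(res$term_id), ]$q_value)
  expect_equal(res2[order(res2$term_id), ]$p_bonferroni,
               res[order(res$term_id), ]$p_bonferroni)
})

test_that("universe handling drops outside genes and rejects empty input", {
  cat <- read_gmt(c("T1\td\tG1\tG2\tG3"))
  res <- enrich(c("G1", "NOT_THERE"), cat)
  expect_equal(attr(res, "dropped_query_genes"), 1L)
  expect_equal(res$query_size, 1L)
  expect_error(enrich(character(0), cat), "domain error")
  expect_error(enrich("ZZZ", cat), "domain error")
})

test_that("miRNA-function gene sets are stringency-filtered unions", {
  inter <- tibble::tibble(
    family_id = c("F1", "F1", "F2", "F2"),
    gene_id = c("G1", "G2", "G2", "G3"),
    program_count = c(3L, 1L, 5L, 5L),
    supporting_experiments = c(1L, 1L, 2L, 0L)
  )
  expect_equal(mirfunction_gene_set("F1", inter), c("G1", "G2"))
  expect_equal(mirfunction_gene_set(c("F1", "F2"), inter,
                                    min_programs = 3),
               c("G1", "G2"))
  expect_equal(mirfunction_gene_set("F2", inter, min_experiments = 1),
               "G2")
  expect_error(mirfunction_gene_set("F9", inter), "lookup error")
  expect_error(mirfunction_gene_set(character(0), inter))
})

test_that("ceRNA-function gene sets are thresholded partners", {
  edges <- tibble::tibble(
    gene_a = c("A", "A", "B"), gene_b = c("B", "C", "D"),
    q_value = c(0.01, 0.2, 0.001)
  )
  expect_equal(cernafunction_gene_set("A", edges), "B")
  expect_equal(cernafunction_gene_set("A", edges, fdr_threshold = 0.5),
               c("B", "C"))
  expect_equal(cernafunction_gene_set("A", edges, fdr_threshold = 0), character(0))
  # profiled but edgeless gene: empty set, not an error
  expect_equal(cernafunction_gene_set("E", edges, known_genes = LETTERS[1:5]),
               character(0))
  expect_error(cernafunction_gene_set("Z", edges), "lookup error")
})
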