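test_that("hypergeometric tail matches hand enumeration on worked cases", {
  expect_equal(hypergeom_pvalue(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(4, 2, 2, 1), 5 / 6, tolerance = 1e-12)
  expect_identical(hypergeom_pvalue(37, 12, 9, 0), 1)
  # the planted-pair statistic used throughout the fixtures
  expect_equal(hypergeom_pvalue(150, 10, 10, 8), 3.755713e-10,
               tolerance = 1e-6)
})

test_that("hypergeometric tail equals enumeration and phyper on random tuples", {
  set.seed(505)
  for (i in 1:300) {
    N <- sample(2:40, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    c <- sample(0:min(K, n), 1)
    p <- hypergeom_pvalue(N, K, n, c)
    expect_equal(p, enum_hyper_tail(N, K, n, c), tolerance = 1e-12)
    expect_equal(p, phyper(c - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("tail is monotone in c and symmetric in (K, n)", {
  for (N in c(15, 40)) {
    K <- 7; n <- 9
    p <- hypergeom_pvalue(N, K, n, 0:min(K, n))
    expect_identical(p[1], 1)
    expect_true(all(diff(p) <= 1e-15))
    expect_equal(hypergeom_pvalue(N, K, n, 0:min(K, n)),
                 hypergeom_pvalue(N, n, K, 0:min(K, n)))
  }
})

test_that("hypergeometric domain violations are named errors", {
  expect_error(hypergeom_pvalue(10, 11, 5, 2), "K > N")
  expect_error(hypergeom_pvalue(10, 5, 11, 2), "n > N")
  expect_error(hypergeom_pvalue(10, 5, 5, 6), "c > min")
  expect_error(hypergeom_pvalue(10, 5, 5, -1), "c < 0")
})

test_that("BH step-up matches the textbook definition and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  set.seed(606)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"), tolerance = 1e-14)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output is permutation-equivariant and bounded by p", {
  set.seed(707)
  p <- runif(50)
  q <- bh_fdr(p)
  perm <- sample.int(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(q >= p - 1e-15 & q <= 1))
})

test_that("profiles keep one entry per family regardless of site count", {
  inter <- tibble::tibble(
    gene_id = c("G1", "G1", "G1", "G1", "G2"),
    biotype_class = c(rep("protein_coding", 4), "lncRNA"),
    family_id = c("F1", "F1", "F1", "F2", "F1")
  )
  prof <- build_family_profiles(inter, n_families = 50)
  expect_equal(prof$n_families[prof$gene_id == "G1"], 2L)
  expect_equal(prof$families[prof$gene_id == "G1"], "F1,F2")
  expect_true("F1" %in% strsplit(prof$families[prof$gene_id == "G2"], ",")[[1]])
  expect_equal(attr(prof, "universe_n_families"), 50)
  expect_false("G3" %in% prof$gene_id)
})

make_profiles <- function(sets, N) {
  prof <- tibble::tibble(
    gene_id = names(sets),
    families = vapply(sets, function(f) paste(sort(f), collapse = ","),
                      character(1)),
    n_families = lengths(sets)
  )
  attr(prof, "universe_n_families") <- N
  prof
}

test_that("a lone strong candidate is reported with q equal to p", {
  fams <- sprintf("F%03d", 1:150)
  shared <- fams[1:8]
  sets <- list(
    g = c(shared, fams[9:10]),
    h = c(shared, fams[11:12]),
    z = fams[100:109]  # disjoint from g
  )
  prof <- make_profiles(sets, 150)
  res <- find_cerna_partners(prof, "g", min_common = 3)
  expect_equal(res$gene_b, "h")
  expect_equal(res$c, 8L)
  # single-candidate BH is the identity (z shares nothing, is not tested)
  expect_equal(res$q_value, res$p_value)
  expect_equal(res$p_value, enum_hyper_tail(150, 10, 10, 8),
               tolerance = 1e-12)
  expect_true(res$q_value < 0.05)
})

test_that("sub-threshold sharing is never reported and self-pairs are excluded", {
  fams <- sprintf("F%03d", 1:50)
  sets <- list(a = fams[1:10], b = c(fams[1:2], fams[20:27]),
               c = c(fams[1:5], fams[30:34]))
  prof <- make_profiles(sets, 50)
  res <- find_cerna_partners(prof, "a", min_common = 3, fdr_threshold = 1)
  expect_false("b" %in% res$gene_b)  # c = 2 < min_common
  expect_false("a" %in% res$gene_b)
  expect_true("c" %in% res$gene_b)
  expect_error(find_cerna_partners(prof, "nope"), "lookup error")
  expect_error(find_cerna_partners(prof, "a", min_common = 0),
               "min_common")
})

test_that("network mode tests pairs once, globally corrected, a < b", {
  fams <- sprintf("F%03d", 1:150)
  sets <- list(
    gB = c(fams[1:10]),
    gA = c(fams[1:10]),  # identical profile: c = 10
    n1 = fams[60:69], n2 = fams[80:89], n3 = fams[100:109]
  )
  prof <- make_profiles(sets, 150)
  net <- build_cerna_network(prof, min_common = 3)
  expect_s3_class(net, "cerna_network")
  expect_equal(nrow(net), 1L)
  expect_equal(c(net$gene_a, net$gene_b), c("gA", "gB"))
  expect_equal(net$c, 10L)
  gl <- glance(net)
  expect_equal(gl$n_edges, 1L)
  expect_equal(gl$universe_N, 150L)

  # no pair shares anything: empty edge table
  disjoint <- make_profiles(
    list(a = fams[1:5], b = fams[6:10], c = fams[11:15]), 150)
  expect_equal(nrow(build_cerna_network(disjoint)), 0L)
  expect_error(build_cerna_network(prof[1, ]), "at least two")
})

test_that("edge q-values use the globally corrected test set", {
  # two planted pairs among null genes: BH spans all pairs sharing >= 1
  set.seed(808)
  fams <- sprintf("F%03d", 1:150)
  sets <- c(
    list(p1a = fams[1:10], p1b = c(fams[1:8], fams[20:21]),
         p2a = fams[30:39], p2b = c(fams[30:37], fams[50:51])),
    stats::setNames(
      lapply(1:40, function(i) sample(fams, 10)),
      sprintf("null%02d", 1:40))
  )
  prof <- make_profiles(sets, 150)
  net <- build_cerna_network(prof, min_common = 3)
  planted <- paste(net$gene_a, net$gene_b)
  expect_true(all(c("p1a p1b", "p2a p2b") %in% planted))
  expect_true(attr(net, "n_pairs_tested") >= nrow(net))
  expect_true(all(net$q_value >= net$p_value - 1e-15))
})
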