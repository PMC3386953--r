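# Hypergeometric machinery, footprint overlap, over-representation with the
# minimum-set-size filter, BH adjustment, and the process cross-tab.

test_that("hypergeometric upper tail matches closed forms and enumeration", {
  expect_equal(hypergeometric_upper_tail(10, 5, 5, 5), 1 / choose(10, 5),
               tolerance = 1e-14)
  expect_identical(hypergeometric_upper_tail(10, 5, 5, 0), 1)
  expect_error(hypergeometric_upper_tail(10, 11, 5, 1),
               class = "exonsplice_config_error")
  expect_error(hypergeometric_upper_tail(10, 5, 5, 6),
               class = "exonsplice_config_error")

  # exhaustive enumeration over all draws for small universes
  for (N in c(5, 7, 8)) {
    for (K in 0:N) {
      marked <- seq_len(K)
      for (n in 0:N) {
        draws <- if (n == 0) list(integer(0)) else
          utils::combn(N, n, simplify = FALSE)
        overlap <- vapply(draws, function(d) length(intersect(d, marked)), 1L)
        for (k in 0:min(K, n)) {
          expect_equal(hypergeometric_upper_tail(N, K, n, k),
                       mean(overlap >= k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("upper tail is monotone in k and symmetric in (K, n)", {
  for (i in 1:20) {
    set.seed(i)
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- 0:min(K, n)
    p <- vapply(ks, function(k) hypergeometric_upper_tail(N, K, n, k), 1)
    expect_true(all(diff(p) <= 1e-15))
    k <- sample(ks, 1)
    expect_equal(hypergeometric_upper_tail(N, K, n, k),
                 hypergeometric_upper_tail(N, n, K, k), tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the independent step-up and is well-behaved", {
  expect_identical(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "exonsplice_config_error")

  set.seed(44)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_identical(order(q[order(p)]), seq_along(p))  # monotone step-up
  }
})

test_that("footprint overlap counts and p compose from the primitives", {
  r <- footprint_overlap_test(letters[1:5], letters[10:15], letters)
  expect_identical(r$k, 0L)
  expect_identical(r$p, 1)

  set.seed(3)
  universe <- sprintf("g%04d", 1:1000)
  target <- sample(universe, 33)
  query <- sample(universe, 200)
  r <- footprint_overlap_test(query, target, universe)
  expect_identical(r$k, length(intersect(query, target)))
  expect_setequal(r$overlap_genes, intersect(query, target))
  expect_equal(r$expected, 33 * 200 / 1000)
  expect_equal(r$p, hypergeometric_upper_tail(1000, 33, 200, r$k),
               tolerance = 1e-14)

  # full-query edge: k = K, and p = 1 only when n = N
  rf <- footprint_overlap_test(universe, target, universe)
  expect_identical(rf$k, 33L)
  expect_identical(rf$p, 1)
  # out-of-universe members are dropped with a report
  expect_message(
    r2 <- footprint_overlap_test(c(query, "NOT_A_GENE"), target, universe),
    "1 query")
  expect_identical(r2$dropped_query, "NOT_A_GENE")
  expect_error(footprint_overlap_test("x", target, universe),
               class = "exonsplice_data_error")
})

test_that("random queries give super-uniform footprint p-values", {
  set.seed(21)
  universe <- sprintf("g%04d", 1:800)
  target <- sample(universe, 40)
  p <- replicate(1000,
    footprint_overlap_test(sample(universe, 100), target, universe)$p)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("over-representation applies the in-universe size filter and BH", {
  universe <- sprintf("g%03d", 1:100)
  sets <- gene_set_collection(list(
    big = universe[1:20],
    boundary9 = c(universe[1:9], "OUTSIDE_1"),   # 9 in-universe members
    exactly10 = universe[21:30]))
  query <- universe[1:15]
  tab <- annotation_enrichment(query, sets, universe, min_genes = 10)
  expect_setequal(tab$set_name, c("big", "exactly10"))  # 9-member set excluded
  expect_identical(tab$set_size[tab$set_name == "exactly10"], 10L)
  expect_equal(tab$p[tab$set_name == "big"],
               hypergeometric_upper_tail(100, 20, 15, 15), tolerance = 1e-12)
  expect_equal(tab$adj_p, bh_adjust(tab$p), tolerance = 1e-12)

  # single surviving set: adjusted == raw
  one <- annotation_enrichment(query, sets["big"], universe, min_genes = 10)
  expect_equal(one$adj_p, one$p)

  expect_warning(none <- annotation_enrichment(query, sets["boundary9"],
                                               universe, min_genes = 10),
                 "no gene set")
  expect_identical(nrow(none), 0L)
  expect_error(annotation_enrichment(c(query, "ROGUE"), sets, universe),
               "ROGUE", class = "exonsplice_data_error")

  # BH oracle over 20 random sets
  set.seed(9)
  many <- gene_set_collection(
    stats::setNames(lapply(1:20, function(i) sample(universe, sample(10:40, 1))),
                    sprintf("set%02d", 1:20)))
  tab2 <- annotation_enrichment(sample(universe, 30), many, universe)
  expect_equal(tab2$adj_p, stats::p.adjust(
    stats::setNames(tab2$p, tab2$set_name), "BH")[tab2$set_name],
    ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the process cross-tab flags analysis-unique gene sets", {
  t1 <- structure(data.frame(set_name = c("cycle", "splice"), set_size = 10L,
                             hits = 5L, expected = 2, p = c(0.01, 0.02),
                             adj_p = c(0.02, 0.02), hit_genes = "",
                             stringsAsFactors = FALSE),
                  class = c("enrichment_table", "data.frame"))
  t2 <- structure(data.frame(set_name = c("cycle", "chemotaxis"), set_size = 10L,
                             hits = 4L, expected = 2, p = c(0.03, 0.001),
                             adj_p = c(0.03, 0.002), hit_genes = "",
                             stringsAsFactors = FALSE),
                  class = c("enrichment_table", "data.frame"))
  x <- process_condition_matrix(list(AS_TCR = t1, AS_TCR_CD28 = t2))
  expect_identical(sort(x$set_name), c("chemotaxis", "cycle", "splice"))
  expect_identical(x$unique_to[x$set_name == "splice"], "AS_TCR")
  expect_identical(x$unique_to[x$set_name == "chemotaxis"], "AS_TCR_CD28")
  expect_true(is.na(x$unique_to[x$set_name == "cycle"]))
  expect_identical(x$n_analyses[x$set_name == "cycle"], 2)

  # row/column conservation on random inputs
  set.seed(18)
  mk <- function() {
    nm <- sample(sprintf("proc%02d", 1:15), sample(3:10, 1))
    structure(data.frame(set_name = nm, set_size = 10L, hits = 1L,
                         expected = 1, p = stats::runif(length(nm)),
                         adj_p = stats::runif(length(nm)), hit_genes = "",
                         stringsAsFactors = FALSE),
              class = c("enrichment_table", "data.frame"))
  }
  for (i in 1:20) {
    tabs <- list(a = mk(), b = mk(), c = mk())
    x <- process_condition_matrix(tabs)
    expect_identical(nrow(x),
                     length(unique(unlist(lapply(tabs, `[[`, "set_name")))))
    expect_equal(sum(x$n_analyses),
                 sum(lengths(lapply(tabs, `[[`, "set_name"))))
  }
})
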