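# helpers to build plane_objects-like fixtures without images
fake_objects <- function(n, labels, pixel_size = 1, class = "nucleus",
                         t = 1L, z = 1L, x = NULL, y = NULL) {
  out <- tibble::tibble(
    t = rep(as.integer(t), n), z = rep(as.integer(z), n),
    class = rep(class, n), label = seq_len(n),
    x_um = x %||% rep(0, n), y_um = y %||% rep(0, n),
    area_um2 = rep(1, n))
  attr(out, "labels") <- labels
  attr(out, "pixel_size") <- pixel_size
  attr(out, "t") <- as.integer(t)
  attr(out, "z") <- as.integer(z)
  class(out) <- c("plane_objects", class(out))
  out
}

test_that("PI objects are related to nuclei by the centroid-in-footprint rule", {
  labels <- matrix(0L, 20, 20)
  labels[3:7, 3:7] <- 1L       # nucleus 1 footprint
  labels[12:16, 12:16] <- 2L   # nucleus 2 footprint
  nuclei <- fake_objects(2, labels)

  pi_in <- fake_objects(1, matrix(0L, 20, 20), class = "pi", x = 4.5, y = 4.5)
  expect_equal(relate_pi(pi_in, nuclei), 1L)

  pi_bg <- fake_objects(1, matrix(0L, 20, 20), class = "pi", x = 9.5, y = 9.5)
  expect_equal(relate_pi(pi_bg, nuclei), integer())

  # two PI objects in one nucleus: still one dead nucleus (set semantics)
  pi_two <- fake_objects(2, matrix(0L, 20, 20), class = "pi",
                         x = c(3.5, 5.5), y = c(3.5, 5.5))
  expect_equal(relate_pi(pi_two, nuclei), 1L)
})

test_that("plane counts follow their definitions", {
  labels <- matrix(0L, 30, 30)
  for (k in 1:10) labels[(3 * k - 2):(3 * k - 1), 1:2] <- k
  nuclei <- fake_objects(10, labels)
  pim <- fake_objects(2, matrix(0L, 30, 30), class = "pi",
                      x = c(1, 1), y = c(0.5, 3.5))  # inside nuclei 1 and 2
  tcl <- fake_objects(4, matrix(0L, 30, 30), class = "tcell")
  pc <- plane_counts(nuclei, pim, tcl)
  expect_equal(unlist(pc[c("n_nuclei", "n_dead_nuclei", "n_tcells_inside")]),
               c(n_nuclei = 10, n_dead_nuclei = 2, n_tcells_inside = 4))

  empty <- fake_objects(0, matrix(0L, 30, 30))
  pc0 <- plane_counts(empty, empty, empty)
  expect_equal(unlist(pc0[c("n_nuclei", "n_dead_nuclei", "n_tcells_inside")]),
               c(n_nuclei = 0, n_dead_nuclei = 0, n_tcells_inside = 0))

  other <- fake_objects(1, matrix(0L, 30, 30), z = 2L)
  expect_error(plane_counts(nuclei, pim, other), "planes")
})

test_that("stack aggregation pools planes and flags zero denominators", {
  counts <- tibble::tibble(t = c(1L, 1L), z = 1:2,
                           n_nuclei = c(10L, 10L),
                           n_dead_nuclei = c(2L, 3L),
                           n_tcells_inside = c(1L, 2L))
  agg <- aggregate_stack(counts)
  expect_equal(agg$killing_fraction, 0.25)
  expect_equal(agg$tcell_count, 3)
  expect_false(agg$zero_denominator)

  empty <- tibble::tibble(t = 1L, z = 1:3, n_nuclei = 0L,
                          n_dead_nuclei = 0L, n_tcells_inside = c(1L, 2L, 0L))
  agg0 <- aggregate_stack(empty)
  expect_equal(agg0$killing_fraction, 0)
  expect_true(agg0$zero_denominator)
  expect_equal(agg0$tcell_count, 3)

  expect_error(aggregate_stack(counts[0, ]), "aggregate")
})

test_that("adding a dead nucleus never decreases the killing fraction", {
  base <- tibble::tibble(t = 1L, z = 1L, n_nuclei = 20L,
                         n_dead_nuclei = 5L, n_tcells_inside = 0L)
  f0 <- aggregate_stack(base)$killing_fraction
  for (extra in 1:15) {
    more <- base
    more$n_dead_nuclei <- base$n_dead_nuclei + extra
    expect_gte(aggregate_stack(more)$killing_fraction, f0)
  }
})

test_that("normalisation to the positive control behaves", {
  s <- tibble::tibble(t = 1:3, killing_fraction = c(0.4, 0.8, 0))
  out <- normalize_killing(s, positive_control_fraction = 0.8)
  expect_equal(out$killing_normalized_pct, c(50, 100, 0))
  out2 <- normalize_killing(s, positive_control_fraction = c(0.7, 0.9))
  expect_equal(out2$killing_normalized_pct[2], 100)
  expect_error(normalize_killing(s, 0), "> 0")
})

test_that("killing comparison: identical groups give adjusted p of 1", {
  df <- tidyr::expand_grid(condition = c("a", "b", "c"),
                           concentration = c("lo", "hi"),
                           rep = 1:3)
  df$killing <- rep(c(10, 20, 30), length.out = nrow(df))
  # make groups identical within each concentration
  df$killing <- rep(c(10, 20, 30), times = 6)
  cmp <- compare_killing(df, reference = "a")
  expect_true(all(cmp$contrasts$p_adj > 0.99))
})

test_that("killing comparison separates distant groups and uses Bonferroni", {
  set.seed(42)
  df <- tidyr::expand_grid(condition = c("ctrl", "bsab1", "bsab2"),
                           concentration = c("lo", "hi"), rep = 1:6)
  df$killing <- rnorm(nrow(df))
  df$killing[df$condition == "bsab1"] <- df$killing[df$condition == "bsab1"] + 5
  cmp <- compare_killing(df, reference = "ctrl")
  p_b1 <- cmp$contrasts$p_adj[grepl("bsab1", cmp$contrasts$contrast)]
  expect_true(all(p_b1 < 0.001))
  # Bonferroni definition: adjusted = min(1, m * raw)
  expect_equal(p.adjust(c(0.01, 0.3, 0.9), method = "bonferroni"),
               pmin(1, 3 * c(0.01, 0.3, 0.9)))
  # ANOVA table carries condition and concentration terms
  expect_true(all(c("condition", "concentration") %in% cmp$anova$term))
})

test_that("degenerate designs are rejected", {
  df <- tibble::tibble(condition = "a", killing = 1:4)
  expect_error(compare_killing(df), "two condition")
  df2 <- tibble::tibble(condition = c("a", "b"), killing = 1:2)
  expect_error(compare_killing(df2), "replicates")
})
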