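test_that("FPKM reproduces hand arithmetic and is linear", {
  frag <- matrix(c(10, 0, 20, 20), nrow = 2,
                 dimnames = list(c("t1", "t2"), c("s1", "s2")))
  design <- data.frame(sample = c("s1", "s2"), condition = c("A", "B"),
                       replicate = c(1, 1))
  lens <- c(t1 = 1000, t2 = 2000)
  x <- suppressWarnings(compute_fpkm(frag, lens, c(1e6, 2e6), design))
  expect_equal(x$values["t1", "s1"], 10)   # 10 * 1e9 / (1000 * 1e6)
  expect_equal(x$values["t2", "s1"], 0)
  expect_equal(x$values["t2", "s2"], 5)    # 20 * 1e9 / (2000 * 2e6)
  # linear in fragments, inverse-linear in length and library size
  y <- suppressWarnings(compute_fpkm(frag * 3, lens, c(1e6, 2e6), design))
  expect_equal(y$values, x$values * 3)
  z <- suppressWarnings(compute_fpkm(frag, lens * 2, c(2e6, 4e6), design))
  expect_equal(z$values, x$values / 4)
  expect_error(compute_fpkm(frag, lens, c(0, 1e6), design), "library total")
})

test_that("log2 fold change follows the pseudocount rule and negates on swap", {
  vals <- rbind(t1 = c(8, 8, 2, 2), t2 = c(3, 3, 3, 3),
                t3 = c(0.9, 0.9, 0, 0))
  colnames(vals) <- paste0("s", 1:4)
  x <- simple_expr(vals, c("T", "T", "C", "C"))
  lfc0 <- log2_fold_change(x, "T", "C", pseudocount = 0)
  expect_equal(unname(lfc0["t1"]), 2)
  expect_equal(unname(lfc0["t2"]), 0)
  lfc <- log2_fold_change(x, "T", "C", pseudocount = 0.1)
  expect_equal(unname(lfc["t3"]), log2(1.0 / 0.1))
  expect_equal(log2_fold_change(x, "C", "T", 0.1), -lfc)
})

test_that("the DE test matches t.test and defines the degenerate case", {
  vals <- rbind(flat = c(4, 4, 4, 4, 4, 4),
                alt = c(2, 2.5, 1.9, 8, 9, 8.5))
  colnames(vals) <- paste0("s", 1:6)
  x <- simple_expr(vals, rep(c("T", "C"), each = 3))
  p <- de_test(x, "T", "C", pseudocount = 0.1)
  expect_equal(unname(p["flat"]), 1)  # identical values in both groups
  ref <- stats::t.test(log2(vals["alt", 1:3] + 0.1),
                       log2(vals["alt", 4:6] + 0.1), var.equal = TRUE)$p.value
  expect_equal(unname(p["alt"]), ref, tolerance = 1e-12)
  # vectorized test agrees with t.test across random matrices, in both the
  # pooled (default) and Welch forms
  set.seed(5)
  m <- matrix(2^rnorm(50 * 6, 4), nrow = 50,
              dimnames = list(paste0("t", 1:50), paste0("s", 1:6)))
  x2 <- simple_expr(m, rep(c("T", "C"), each = 3))
  p2 <- de_test(x2, "T", "C")
  pref <- apply(m, 1, function(v)
    stats::t.test(log2(v[1:3] + 0.1), log2(v[4:6] + 0.1),
                  var.equal = TRUE)$p.value)
  expect_equal(unname(p2), unname(pref), tolerance = 1e-10)
  pw <- de_test(x2, "T", "C", var_equal = FALSE)
  prefw <- apply(m, 1, function(v)
    stats::t.test(log2(v[1:3] + 0.1), log2(v[4:6] + 0.1))$p.value)
  expect_equal(unname(pw), unname(prefw), tolerance = 1e-10)
  expect_error(
    de_test(suppressWarnings(simple_expr(m[, c(1, 4, 5), drop = FALSE],
                                         c("T", "C", "C"))), "T", "C"),
    "2 replicates")
})

test_that("DE calls use strict threshold semantics", {
  cfg <- run_config()
  lfc <- c(a = 1.0, b = -1.2, c = 2.0, d = 1.5)
  p <- c(a = 0.01, b = 0.04, c = 0.06, d = 0.001)
  de <- call_de(lfc, p, cfg, "T_vs_C")
  expect_false(de$significant[de$transcript_id == "a"]) # |lfc| not > 1
  row_b <- de[de$transcript_id == "b", ]
  expect_true(row_b$significant)
  expect_equal(row_b$direction, "down")
  expect_false(de$significant[de$transcript_id == "c"]) # p not < 0.05
  expect_equal(de$direction[de$transcript_id == "d"], "up")
  expect_true(all(de$direction[!de$significant] == "none"))
})

test_that("relative expression follows 2^-ddCt exactly", {
  expect_equal(ddct_relative_expression(20, 15, 22, 15), 4)       # ddCt -2
  expect_equal(ddct_relative_expression(20, 15, 20, 15), 1)       # ddCt 0
  expect_equal(ddct_relative_expression(25, 15, 20, 15), 0.03125) # ddCt 5
})

test_that("planted DE direction is recovered with high sensitivity", {
  set.seed(17)
  scfg <- simulation_config()
  n <- 60
  eff <- rep(c(2, -2), each = n / 2)
  hits <- 0
  for (rep in 1:20) {
    base <- rnorm(n, 4, 1)
    mT <- base + eff + matrix(rnorm(n * 3, 0, 0.25), n)
    mC <- base + matrix(rnorm(n * 3, 0, 0.25), n)
    vals <- 2^cbind(mT, mC)
    dimnames(vals) <- list(paste0("t", 1:n), paste0("s", 1:6))
    x <- simple_expr(vals, rep(c("T", "C"), each = 3))
    de <- differential_expression(x, "T", "C")
    ok <- de$significant &
      de$direction == ifelse(eff > 0, "up", "down")
    flips <- de$significant & de$direction != ifelse(eff > 0, "up", "down")
    expect_equal(sum(flips), 0)  # no direction flips among calls
    hits <- hits + sum(ok)
  }
  expect_gte(hits / (20 * n), 0.95)
})
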