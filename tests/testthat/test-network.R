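make_de <- function(ids, dirs, contrast = "T_vs_C", sig = TRUE) {
  data.frame(transcript_id = ids, contrast = contrast,
             log2fc = ifelse(dirs == "up", 2, -2),
             p_value = ifelse(sig, 0.001, 0.5),
             fdr = NA_real_, significant = sig,
             direction = ifelse(sig, dirs, "none"),
             stringsAsFactors = FALSE)
}
make_hits <- function(mirna, rna, type = "target") {
  data.frame(mirna_id = mirna, rna_id = rna, start = 1L, end = 21L,
             score = 0, n_gaps = 0L, strict_penalty = 0,
             nonstrict_penalty = 0, alignment = strrep("|", 21),
             type = type, stringsAsFactors = FALSE)
}

test_that("ceRNA triples require shared miRNA, significance and concordance", {
  etm <- make_hits(c("m1", "m2", "m3", "m4"), c("L1", "L2", "L3", "L4"),
                   "eTM")
  tgt <- make_hits(c("m1", "m2", "m3", "m4"), c("M1", "M2", "M3", "M4"))
  de_lnc <- rbind(make_de(c("L1", "L2"), c("up", "up")),
                  make_de("L3", "up", sig = FALSE),
                  make_de("L4", "down"))
  de_mrna <- rbind(make_de(c("M1", "M3", "M4"), c("up", "up", "up")),
                   make_de("M2", "down"))
  trip <- build_cerna_network(etm, tgt, de_lnc, de_mrna, "T_vs_C")
  # L1/M1: both up and significant -> emitted
  expect_equal(trip$lncrna_id, "L1")
  expect_equal(trip$mrna_id, "M1")
  # L2/M2 discordant, L3 not significant, L4/M4 discordant -> all excluded
  expect_equal(nrow(trip), 1)
  # independent validator pass: every emitted triple satisfies both rules
  expect_true(all(trip$lnc_direction == trip$mrna_direction))
  expect_true(all(trip$lncrna_id %in%
                    de_lnc$transcript_id[de_lnc$significant]))
  expect_true(all(trip$mrna_id %in%
                    de_mrna$transcript_id[de_mrna$significant]))
})

test_that("network assembly is deterministic and order-independent", {
  etm <- make_hits(rep(c("m1", "m2"), each = 2),
                   c("L1", "L2", "L1", "L2"), "eTM")
  tgt <- make_hits(c("m1", "m2"), c("M1", "M2"))
  de_lnc <- make_de(c("L1", "L2"), c("up", "down"))
  de_mrna <- make_de(c("M1", "M2"), c("up", "down"))
  t1 <- build_cerna_network(etm, tgt, de_lnc, de_mrna, "T_vs_C")
  t2 <- build_cerna_network(etm[sample(nrow(etm)), ],
                            tgt[sample(nrow(tgt)), ],
                            de_lnc[2:1, ], de_mrna[2:1, ], "T_vs_C")
  expect_equal(t1, t2)
})

test_that("hub ranking uses distinct-neighbour degree with lexical ties", {
  trip <- data.frame(
    lncrna_id = c("hub", "hub", "hub", "b", "a"),
    mirna_id = c("m1", "m1", "m2", "m3", "m4"),
    mrna_id = c("M1", "M2", "M3", "M4", "M5"),
    stringsAsFactors = FALSE)
  h <- hub_nodes(trip)
  expect_equal(h$lncrna_id[1], "hub")
  expect_equal(h$degree[1], 5)  # m1, m2, M1, M2, M3
  expect_equal(h$lncrna_id[2:3], c("a", "b"))  # equal degree, lexical order
  # oracle: brute-force neighbour counting
  for (l in unique(trip$lncrna_id)) {
    sub <- trip[trip$lncrna_id == l, ]
    expect_equal(h$degree[h$lncrna_id == l],
                 length(unique(c(sub$mirna_id, sub$mrna_id))))
  }
  expect_equal(nrow(hub_nodes(trip[0, ])), 0)
})

test_that("enrichment p-values match the closed-form hypergeometric tail", {
  bg <- paste0("g", 1:20)
  term_map <- list(T1 = paste0("g", 1:5), T2 = paste0("g", 6:15),
                   T0 = paste0("g", 16:20))
  fg <- paste0("g", 1:5)  # all of T1
  res <- enrich_terms(fg, bg, term_map)
  expect_equal(res$p_value[res$term_id == "T1"],
               oracle_hyper_tail(5, 5, 20, 5))
  expect_false("T0" %in% res$term_id)  # zero overlap omitted
  expect_error(enrich_terms(c("g1", "nope"), bg, term_map), "absent")
  # data.frame form of the term map behaves identically
  tm_df <- data.frame(term = rep(names(term_map), lengths(term_map)),
                      gene = unlist(term_map))
  expect_equal(enrich_terms(fg, bg, tm_df), res)
})

test_that("null enrichment p-values are approximately uniform", {
  set.seed(79)
  bg <- paste0("g", 1:200)
  term <- paste0("g", sample(200, 40))
  ps <- replicate(300, {
    fg <- sample(bg, 30)
    enrich_terms(fg, bg, list(T = term))$p_value
  })
  ps <- unlist(ps)
  # hypergeometric tail p-values are discrete and conservative under the
  # null: P(p <= x) <= x, and the mean sits near (just above) 1/2
  for (x in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= x), x + 3 * sqrt(x * (1 - x) / length(ps)))
  expect_gt(mean(ps), 0.45)
})

test_that("network summaries equal brute-force set construction", {
  trip <- data.frame(
    lncrna_id = c("L1", "L1"), mirna_id = c("m1", "m1"),
    mrna_id = c("M1", "M2"), stringsAsFactors = FALSE)
  s <- summarize_network(trip)
  expect_equal(s$n_lncrna, 1); expect_equal(s$n_mirna, 1)
  expect_equal(s$n_mrna, 2)
  expect_equal(s$n_edges, 3)  # L1-m1 (dedup) + m1-M1 + m1-M2
  s1 <- summarize_network(trip[1, ])
  expect_equal(unlist(s1[c("n_lncrna", "n_mirna", "n_mrna", "n_edges")]),
               c(n_lncrna = 1, n_mirna = 1, n_mrna = 1, n_edges = 2))
})
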