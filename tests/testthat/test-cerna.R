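test_that("status attachment joins DE tables and drops NS endpoints", {
  hits <- data.frame(
    mirna_id = c("m1", "m1", "m2"),
    target_id = c("c1", "c2", "c3"),
    total_energy = c(-25, -21, -22), position = c(10L, 20L, 30L),
    stringsAsFactors = FALSE
  )
  de <- list(
    data.frame(feature_id = c("m1", "m2"), status = c("Up", "Up"),
               stringsAsFactors = FALSE),
    data.frame(feature_id = c("c1", "c2", "c3"),
               status = c("Down", "Up", "NS"), stringsAsFactors = FALSE)
  )
  edges <- attach_status(hits, de)
  expect_equal(nrow(edges), 2)            # NS edge dropped
  expect_equal(edges$mirna_status, c("Up", "Up"))
  expect_equal(edges$target_status, c("Down", "Up"))

  bad <- rbind(hits, data.frame(mirna_id = "mX", target_id = "c1",
                                total_energy = -30, position = 1L))
  expect_error(attach_status(bad, de), "mX")
})

test_that("inverse filtering keeps discordant edges and is idempotent", {
  tab <- read_pair_table(pair_table_path())
  edges <- pair_table_edges(tab)
  inv <- inverse_filter(edges)
  expect_equal(nrow(inv), 14)
  expect_true(all(inv$mirna_status != inv$target_status))
  expect_identical(inverse_filter(inv), inv)
  # concordant edges are dropped
  expect_false(any(paste(edges$mirna_status, edges$target_status) %in%
                     c("Up Up", "Down Down") &
                     paste(edges$mirna_id, edges$target_id) %in%
                     paste(inv$mirna_id, inv$target_id)))
})

test_that("triple assembly enumerates all circ x mRNA combinations per shared miRNA", {
  circ_mi <- data.frame(
    mirna_id = "m1", target_id = "c1", target_class = "circRNA",
    mirna_status = "Up", target_status = "Down", total_energy = -25,
    position = 1L, stringsAsFactors = FALSE
  )
  mi_mrna <- data.frame(
    mirna_id = c("m1", "m1", "m9"), target_id = c("g1", "g2", "g3"),
    target_class = "mRNA", mirna_status = c("Up", "Up", "Down"),
    target_status = c("Down", "Down", "Up"), total_energy = -22,
    position = 2L, stringsAsFactors = FALSE
  )
  net <- assemble_triples(circ_mi, mi_mrna)
  expect_equal(nrow(net$triples), 2)
  # m9 has no circRNA edge and contributes nothing
  expect_false("m9" %in% net$nodes$id)
  # every node in the assembled network has degree >= 1
  edge_ids <- c(net$circ_mi$mirna_id, net$circ_mi$target_id,
                net$mi_mrna$mirna_id, net$mi_mrna$target_id)
  expect_true(all(net$nodes$id %in% edge_ids))

  # random bipartite layers vs an exhaustive enumeration oracle
  set.seed(31)
  for (rep in 1:5) {
    cm <- data.frame(
      mirna_id = sample(sprintf("m%d", 1:5), 12, TRUE),
      target_id = sample(sprintf("c%d", 1:6), 12, TRUE),
      target_class = "circRNA", mirna_status = "Up", target_status = "Down",
      total_energy = -25, position = 1L, stringsAsFactors = FALSE
    )
    cm <- unique(cm)
    mm <- data.frame(
      mirna_id = sample(sprintf("m%d", 1:5), 15, TRUE),
      target_id = sample(sprintf("g%d", 1:8), 15, TRUE),
      target_class = "mRNA", mirna_status = "Up", target_status = "Down",
      total_energy = -22, position = 2L, stringsAsFactors = FALSE
    )
    mm <- unique(mm)
    net2 <- assemble_triples(cm, mm)
    oracle <- 0L
    for (m in unique(c(cm$mirna_id, mm$mirna_id))) {
      oracle <- oracle + length(unique(cm$target_id[cm$mirna_id == m])) *
        length(unique(mm$target_id[mm$mirna_id == m]))
    }
    expect_equal(nrow(net2$triples), oracle)
  }
})

test_that("network summaries are exact and invariant to edge order", {
  tab <- read_pair_table(pair_table_path())
  edges <- pair_table_edges(tab)
  s <- network_summary(edges)
  expect_equal(s$n_pairs, 24)
  expect_equal(s$n_distinct_mirna, 10)
  expect_equal(s$n_distinct_circ, 16)
  expect_equal(s$pct_opposite, 58.3)

  set.seed(2)
  s2 <- network_summary(edges[sample(nrow(edges)), ])
  s$mirna_degree <- s$mirna_degree[sort(names(s$mirna_degree))]
  s2$mirna_degree <- s2$mirna_degree[sort(names(s2$mirna_degree))]
  expect_equal(s2, s)

  one <- edges[1, ]
  s1 <- network_summary(one)
  expect_equal(s1$n_pairs, 1)
  expect_true(s1$pct_opposite %in% c(0, 100))
})
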