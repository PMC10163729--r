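test_that("two duplex UMI families at one fragment key form two molecules", {
  reads <- fig1c_reads()
  with_umi <- group_reads(reads, "with_umis")
  expect_identical(count_molecules(with_umi), 2L)
  groups <- summarize_groups(with_umi)
  expect_identical(unique(groups$duplexity), "duplex")
  expect_identical(groups$n_reads_top, c(2L, 2L))
  expect_identical(groups$n_reads_bottom, c(2L, 2L))
  # position-only grouping collapses the key into one molecule
  pos_only <- group_reads(reads, "position_only")
  expect_identical(count_molecules(pos_only), 1L)
})

test_that("UMI mismatch tolerance merges sequencing-error barcodes", {
  calls <- rep(list(stats::setNames("A", 100L)), 4)
  reads <- make_reads(
    n = 4, start = 50L, end = 250L,
    strand = c("top", "top", "top", "bottom"),
    umi1 = c("AAAA", "AAAA", "AAAA", "CCCC"),
    umi2 = c("CCCC", "CCCC", "CCCC", "AAAT"),
    calls = calls
  )
  # canonical pairs AAAACCCC vs AAATCCCC differ at one position
  expect_identical(count_molecules(group_reads(reads, "with_umis", 1L)), 1L)
  expect_identical(count_molecules(group_reads(reads, "with_umis", 0L)), 2L)
})

test_that("single-linkage clustering matches an exhaustive oracle", {
  # oracle: connected components of the <=1-mismatch graph by BFS
  components <- function(umis) {
    uniq <- sort(unique(umis))
    m <- length(uniq)
    adj <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j) {
      a <- strsplit(uniq[i], "")[[1]]; b <- strsplit(uniq[j], "")[[1]]
      sum(a != b) <= 1
    }))
    comp <- rep(NA_integer_, m)
    cid <- 0L
    for (s in seq_len(m)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    comp[match(umis, uniq)]
  }
  set.seed(77)
  for (rep_i in 1:25) {
    umis <- apply(matrix(sample(c("A", "C"), 10 * 4, replace = TRUE), 10), 1,
                  paste, collapse = "")
    got <- umicollide:::cluster_umis(umis, 1L)
    want <- components(umis)
    # same partition (labels may differ)
    expect_identical(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(want, levels = unique(want))))
  }
})

test_that("UMI grouping refines position grouping and partitions the reads", {
  panel <- sim_panel()
  cfg <- test_config(panel, input_ng = 1, vaf = 0.1, seed = 41)
  reads <- simulate_reads(cfg)
  with_umi <- group_reads(reads, "with_umis")
  pos_only <- group_reads(reads, "position_only")
  expect_gte(count_molecules(with_umi), count_molecules(pos_only))
  # each UMI group sits inside exactly one position group
  nesting <- tapply(pos_only$group_id, with_umi$group_id, dplyr::n_distinct)
  expect_true(all(nesting == 1))
  # partition: every read has exactly one group
  expect_false(anyNA(with_umi$group_id))
  expect_identical(nrow(with_umi), nrow(reads))
})

test_that("grouping is independent of read order", {
  panel <- sim_panel()
  cfg <- test_config(panel, input_ng = 1, vaf = 0.1, seed = 43)
  reads <- simulate_reads(cfg)
  shuffled <- reads[sample(nrow(reads)), ]
  g1 <- group_reads(reads, "with_umis")
  g2 <- group_reads(shuffled, "with_umis")
  map1 <- stats::setNames(g1$group_id, g1$read_id)
  map2 <- stats::setNames(g2$group_id, g2$read_id)
  expect_identical(map1[sort(names(map1))], map2[sort(names(map2))])
})

test_that("classification and molecule counting follow the duplex rule", {
  expect_identical(classify_group(tibble::tibble(strand = c("top", "top", "top",
                                                            "bottom", "bottom"))),
                   "duplex")
  expect_identical(classify_group(tibble::tibble(strand = rep("top", 5))),
                   "simplex")
  expect_identical(classify_group(tibble::tibble(strand = "bottom")), "simplex")
  # n reads at n distinct keys -> n molecules; empty input -> 0
  calls <- rep(list(stats::setNames("A", 100L)), 3)
  reads <- make_reads(3, start = c(10L, 20L, 30L), end = c(200L, 210L, 220L),
                      strand = "top", umi1 = "AAAA", umi2 = "CCCC",
                      calls = calls)
  expect_identical(count_molecules(group_reads(reads, "position_only")), 3L)
  empty <- reads[0, ]
  expect_identical(count_molecules(group_reads(empty, "position_only")), 0L)
})

test_that("with-UMIs mode rejects reads without UMIs", {
  calls <- list(stats::setNames("A", 100L))
  reads <- make_reads(1, 50L, 250L, "top", umi1 = "", umi2 = "", calls = calls)
  expect_error(group_reads(reads, "with_umis"), "UMI")
})
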