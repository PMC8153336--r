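test_that("non-host proportion arithmetic and edge cases", {
  counts <- c("Eukaryota;Metazoa;Ixodida;tick" = 9997,
              "Eukaryota;Fungi;fungus" = 3)
  expect_equal(nontick_proportion(counts, "Eukaryota;Metazoa;Ixodida"),
               0.0003)
  expect_equal(nontick_proportion(c("Eukaryota;Metazoa;Ixodida;t" = 10),
                                  "Eukaryota;Metazoa;Ixodida"), 0)
  expect_equal(nontick_proportion(c("Eukaryota;Fungi;f" = 10),
                                  "Eukaryota;Metazoa;Ixodida"), 1)
  expect_true(is.na(nontick_proportion(c(a = 0, b = 0), "a")))
})

test_that("enrichment value is a guarded ratio with identity 1", {
  expect_equal(enrichment_value(0.05, 0.005), 10)
  expect_equal(enrichment_value(0.37, 0.37), 1)
  expect_true(is.na(enrichment_value(0.02, 0)))
})

test_that("a zero non-host control excludes the individual from
           enrichment summaries", {
  gen <- make_count_table(fixture_spec(seed = 3L))
  enr <- enrichment_table(gen$table, gen$truth$host_prefix)
  zt <- gen$truth$zero_control_tick
  flagged <- enr[enr$tick_id == zt & enr$method != "control", ]
  expect_true(all(flagged$excluded))
  expect_true(all(grepl("only host reads", flagged$reason)))
  expect_true(all(is.na(flagged$enrichment)))
  others <- enr[enr$tick_id != zt & enr$method != "control", ]
  expect_true(all(!others$excluded))
  expect_true(all(is.finite(others$enrichment)))
  # summaries only use non-excluded samples and stay finite
  summ <- enrichment_summary(enr)
  expect_true(all(is.finite(summ$median_enrichment)))
  expect_true(all(summ$n_excluded[summ$method != "control"] >= 1L))
})

test_that("host and non-host proportions are complementary", {
  gen <- make_count_table(fixture_spec(seed = 4L))
  ct <- gen$table
  host <- startsWith(colnames(ct$counts), gen$truth$host_prefix)
  for (s in ct$meta$sample[1:10]) {
    p_non <- nontick_proportion(ct$counts[s, ], gen$truth$host_prefix)
    p_host <- sum(ct$counts[s, host]) / sum(ct$counts[s, ])
    expect_equal(p_non + p_host, 1)
  }
})

test_that("pairwise proportion tests match the chi-square transcription", {
  # identical groups: no difference, uncorrected p = 1
  p_same <- pairwise_prop_test(c(a = 30, b = 30), c(a = 100, b = 100),
                               correction = "none")
  expect_equal(p_same["a", "b"], 1, tolerance = 1e-12)

  # 3 groups: 3 pairwise comparisons
  p3 <- pairwise_prop_test(c(x = 5, y = 9, z = 20),
                           c(x = 100, y = 100, z = 100))
  expect_equal(sum(!is.na(p3[upper.tri(p3)])), 3L)
  expect_true(isSymmetric(unclass(p3)))

  withr::with_seed(61, {
    for (i in 1:40) {
      n <- sample(50:500, 2L, replace = TRUE)
      x <- c(rbinom(1L, n[1L], 0.1), rbinom(1L, n[2L], runif(1, 0.05, 0.5)))
      got <- pairwise_prop_test(stats::setNames(x, c("u", "v")),
                                stats::setNames(n, c("u", "v")),
                                correction = "none")
      expect_equal(got["u", "v"], orc_prop_p(x[1L], n[1L], x[2L], n[2L]),
                   tolerance = 1e-10)
    }
  })

  # Bonferroni: p' = min(1, m p), never below the raw p
  adj <- pairwise_prop_test(c(a = 5, b = 10, c = 40),
                            c(a = 200, b = 200, c = 200))
  raw <- attr(adj, "uncorrected")
  off <- !is.na(raw)
  expect_true(all(adj[off] >= raw[off]))
  expect_true(all(adj[off] <= 1))
  expect_equal(adj[off], pmin(1, 3 * raw[off]))

  # zero-total group flagged not evaluable
  z <- pairwise_prop_test(c(a = 0, b = 10), c(a = 0, b = 100))
  expect_true(is.na(z["a", "b"]))
})

test_that("Shannon, observed variants and their invariances", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(c(0, 9, 0)), 0)
  expect_true(is.na(shannon(c(0, 0))))
  withr::with_seed(62, {
    for (i in 1:20) {
      v <- rpois(8, 20) + 1
      p <- v / sum(v)
      expect_equal(shannon(v), -sum(p * log(p)))
      # uniform maximizes over the same support
      expect_lte(shannon(v), log(length(v)) + 1e-12)
      # observed variants ignore rescaling
      expect_equal(observed_asvs(v * 10), observed_asvs(v))
    }
  })
  expect_equal(observed_asvs(c(a = 5, b = 0, c = 1)), 2L)
  expect_equal(observed_asvs(numeric(0)), 0L)
})

test_that("Faith's PD: closed forms, monotonicity and traversal oracle", {
  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  expect_equal(faith_pd(star$tip.label[1:3], star), 3)
  expect_equal(faith_pd(character(), star), 0)
  expect_error(faith_pd("nope", star), "not in tree")

  withr::with_seed(63, {
    for (i in 1:20) {
      tr <- ape::rtree(8)
      tips <- sample(tr$tip.label, sample(1:8, 1L))
      expect_equal(faith_pd(tips, tr), orc_faith_pd(tips, tr),
                   tolerance = 1e-10)
      # adding a taxon never decreases PD
      rest <- setdiff(tr$tip.label, tips)
      if (length(rest) > 0L) {
        extra <- sample(rest, 1L)
        expect_gte(faith_pd(c(tips, extra), tr), faith_pd(tips, tr))
      }
    }
  })
})

test_that("alpha_diversity summarises a generated table", {
  gen <- make_count_table(fixture_spec(seed = 6L, n_ticks = 3L))
  ad <- alpha_diversity(gen$table)
  expect_equal(nrow(ad), nrow(gen$table$counts))
  expect_true(all(ad$observed_asvs >= 1L))
  # non-host-depleted controls are near-monocultures: lower diversity
  expect_lt(mean(ad$shannon[ad$method == "control"]),
            mean(ad$shannon[ad$method == "pna_sizeselect"]))
})

test_that("relative intensity normalizes each trial to its own control", {
  tripl <- data.frame(
    trial = rep(1:3, each = 3),
    dose = rep(c("0", "10", "50"), 3),
    value = c(100, 100, 50, 200, 200, 100, 50, 50, 25))
  rel <- relative_intensity(tripl, control_dose = "0")
  expect_equal(rel$mean_relative[rel$dose == "0"], 1)
  expect_equal(rel$mean_relative[rel$dose == "10"], 1)
  expect_equal(rel$mean_relative[rel$dose == "50"], 0.5)
  expect_equal(rel$n, rep(3L, 3L))

  one <- data.frame(trial = 1, dose = c("0", "100"), value = c(80, 40))
  expect_equal(relative_intensity(one)$mean_relative[2L], 0.5)

  hand <- data.frame(trial = rep(1:3, each = 2),
                     dose = rep(c("0", "50"), 3),
                     value = c(100, 30, 50, 20, 200, 90))
  got <- relative_intensity(hand)
  expect_equal(got$mean_relative[got$dose == "50"],
               mean(c(30 / 100, 20 / 50, 90 / 200)))

  bad <- data.frame(trial = 1, dose = c("0", "50"), value = c(0, 10))
  expect_error(relative_intensity(bad), "positive control")
})

test_that("top_taxa ranks with exclusions and lexicographic ties", {
  ab <- c("Acari;tick" = 0.9, "Fungi;X" = 0.05, "Fungi;Y" = 0.03)
  tt <- top_taxa(ab, n = 10L, exclude = "Acari")
  expect_equal(tt$taxon, c("Fungi;X", "Fungi;Y"))
  # n larger than remaining taxa returns all remaining
  expect_equal(nrow(top_taxa(ab, n = 99L, exclude = "Acari")), 2L)
  # excluding everything yields an empty ranking
  expect_equal(nrow(top_taxa(ab, exclude = c("Acari", "Fungi"))), 0L)
  ties <- c(b = 0.2, a = 0.2, c = 0.1)
  expect_equal(top_taxa(ties, n = 2L)$taxon, c("a", "b"))
})

test_that("detection grids validate codes and summarise per sample", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tick_id\tm1\tm2",
               "s1\tG, A\t-",
               "s2\t-\tG",
               "s3\t-\t-"), f)
  dt <- read_detection_grid(f)
  ds <- detection_summary(dt)
  expect_equal(ds[["G"]], 2L)
  expect_equal(ds[["A"]], 1L)
  expect_equal(ds[["Cr"]], 0L)

  # permuting method columns changes nothing
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tick_id\tm2\tm1",
               "s1\t-\tG, A",
               "s2\tG\t-",
               "s3\t-\t-"), f2)
  expect_equal(detection_summary(read_detection_grid(f2)), ds)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tick_id\tm1", "s1\tZZ"), bad)
  expect_error(read_detection_grid(bad), "unknown detection code")

  # empty grid: all-zero mapping
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tick_id\tm1", "s1\t-"), f3)
  expect_true(all(detection_summary(read_detection_grid(f3)) == 0L))
})

test_that("count table constructor enforces its invariants", {
  counts <- matrix(c(10, 5, 3, 2), 2, 2,
                   dimnames = list(c("s1", "s2"), c("tx1", "tx2")))
  meta <- data.frame(sample = c("s1", "s2"), tick_id = c("t1", "t1"),
                     method = c("control", "pna"))
  expect_s3_class(community_count_table(counts, meta),
                  "community_count_table")
  expect_error(community_count_table(counts - 20, meta), "non-negative")
  meta_bad <- meta
  meta_bad$method <- c("pna", "lna")  # no control for t1
  expect_error(community_count_table(counts, meta_bad), "without a control")
})
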