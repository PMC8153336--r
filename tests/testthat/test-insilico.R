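test_that("insilico_pcr finds the planted amplicon with exact span", {
  prim <- tareuk_primers()
  withr::with_seed(51, {
    insert <- rand_dna(200)
    tmpl <- paste0(rand_dna(30), prim$fwd, insert,
                   reverse_complement(prim$rev), rand_dna(30))
    pred <- insilico_pcr(tmpl, prim$fwd, prim$rev, max_mismatch = 0L)
    expect_equal(nrow(pred), 1L)
    expect_equal(pred$orientation, "sense")
    expect_equal(pred$length,
                 200L + nchar(prim$fwd) + nchar(prim$rev))
    # template lacking the reverse site yields nothing
    no_rev <- paste0(rand_dna(30), prim$fwd, insert, rand_dna(40))
    expect_equal(nrow(insilico_pcr(no_rev, prim$fwd, prim$rev, 0L)), 0L)
    # a reverse-complemented template is found as an antisense product
    pred_rc <- insilico_pcr(reverse_complement(tmpl), prim$fwd, prim$rev, 0L)
    expect_equal(nrow(pred_rc), 1L)
    expect_equal(pred_rc$orientation, "antisense")
    expect_equal(pred_rc$length, pred$length)
  })
})

test_that("insilico_pcr matches brute-force site-pair enumeration", {
  withr::with_seed(52, {
    for (i in 1:25) {
      tmpl <- rand_dna(150)
      fwd <- rand_dna(9)
      rev <- rand_dna(9)
      got <- insilico_pcr(tmpl, fwd, rev, max_mismatch = 2L, max_len = 150L)
      want <- orc_insilico(tmpl, fwd, rev, 2L, 150L)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got) > 0L) {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
      }
    }
  })
})

test_that("nested_pcr respects nesting and maps coordinates back", {
  un <- unonmet_primers()
  withr::with_seed(53, {
    inner_insert <- rand_dna(120)
    inner_block <- paste0(un$inner_fwd, inner_insert,
                          reverse_complement(un$inner_rev))
    tmpl <- paste0(rand_dna(25), un$outer_fwd, rand_dna(40), inner_block,
                   rand_dna(40), reverse_complement(un$outer_rev),
                   rand_dna(25))
    nested <- nested_pcr(tmpl, un$outer_fwd, un$outer_rev,
                         un$inner_fwd, un$inner_rev, max_mismatch = 0L)
    expect_equal(nrow(nested), 1L)
    expect_equal(nested$length,
                 120L + nchar(un$inner_fwd) + nchar(un$inner_rev))
    # the inner span sits inside the outer amplicon
    expect_gte(nested$start, nested$outer_start)

    # outer sites but no inner sites: empty
    tmpl2 <- paste0(rand_dna(25), un$outer_fwd, rand_dna(200),
                    reverse_complement(un$outer_rev), rand_dna(25))
    expect_equal(nrow(nested_pcr(tmpl2, un$outer_fwd, un$outer_rev,
                                 un$inner_fwd, un$inner_rev, 0L)), 0L)

    # inner sites outside any outer amplicon: empty (nesting respected)
    tmpl3 <- paste0(rand_dna(25), inner_block, rand_dna(25))
    expect_equal(nrow(nested_pcr(tmpl3, un$outer_fwd, un$outer_rev,
                                 un$inner_fwd, un$inner_rev, 0L)), 0L)
    # ... although the inner pair alone would amplify there
    whole <- insilico_pcr(tmpl3, un$inner_fwd, un$inner_rev, 0L)
    expect_equal(nrow(whole), 1L)
  })
})

test_that("nested predictions are a subset of whole-template inner
           predictions", {
  un <- unonmet_primers()
  withr::with_seed(54, {
    inner_block <- paste0(un$inner_fwd, rand_dna(90),
                          reverse_complement(un$inner_rev))
    tmpl <- paste0(rand_dna(20), un$outer_fwd, rand_dna(30), inner_block,
                   rand_dna(30), reverse_complement(un$outer_rev),
                   rand_dna(20))
    nested <- nested_pcr(tmpl, un$outer_fwd, un$outer_rev,
                         un$inner_fwd, un$inner_rev, 0L)
    whole <- insilico_pcr(tmpl, un$inner_fwd, un$inner_rev, 0L)
    key_n <- paste(nested$start, nested$end)
    key_w <- paste(whole$start, whole$end)
    expect_true(all(key_n %in% key_w))
  })
})

test_that("trim_tail matches only the 3' bases of adapter-tailed primers", {
  un <- unonmet_primers()
  withr::with_seed(55, {
    core_f <- substr(un$inner_fwd, nchar(un$inner_fwd) - 11L,
                     nchar(un$inner_fwd))
    core_r <- substr(un$inner_rev, nchar(un$inner_rev) - 11L,
                     nchar(un$inner_rev))
    tmpl <- paste0(rand_dna(30), core_f, rand_dna(100),
                   reverse_complement(core_r), rand_dna(30))
    # the full printed 30-mers (with adapter) do not match a natural
    # template, the trimmed 3' cores do
    expect_equal(nrow(insilico_pcr(tmpl, un$inner_fwd, un$inner_rev, 1L)), 0L)
    got <- insilico_pcr(tmpl, un$inner_fwd, un$inner_rev, 1L,
                        trim_tail = 12L)
    expect_equal(nrow(got), 1L)
  })
})

test_that("blocking prediction thresholds mismatches and is monotone", {
  spec <- fixture_spec()
  truth <- fixture_truth(spec)
  hosts <- make_host_family(spec)
  excl <- make_exclusion_seq(spec)
  blocker <- truth$window_consensus

  pred_h <- insilico_pcr(hosts[[2L]], spec$fwd_primer, spec$rev_primer, 2L)
  pred_h <- blocking_prediction(hosts[[2L]], pred_h, blocker)
  expect_true(all(pred_h$blocked))
  expect_equal(unique(pred_h$block_mismatches), 0L)

  pred_e <- insilico_pcr(excl, spec$fwd_primer, spec$rev_primer, 2L)
  pred_e <- blocking_prediction(excl, pred_e, blocker,
                                max_block_mismatch = 1L)
  expect_false(any(pred_e$blocked))
  expect_equal(unique(pred_e$block_mismatches), 3L)

  # raising the tolerance never unblocks; at blocker length all is blocked
  for (t in 0:nchar(blocker)) {
    p <- blocking_prediction(excl, pred_e[, !(names(pred_e) %in%
                                              c("blocked", "block_mismatches"))],
                             blocker, max_block_mismatch = t)
    if (t >= 3L) expect_true(all(p$blocked)) else expect_false(any(p$blocked))
  }
})

test_that("community coverage partitions taxa with proportions summing
           to one", {
  spec <- fixture_spec()
  truth <- fixture_truth(spec)
  com <- make_community(spec, n_other = 3L, n_nosite = 2L)
  cov <- community_coverage(com$seqs, com$taxa, spec$fwd_primer,
                            spec$rev_primer,
                            blocker = truth$window_consensus)
  expect_equal(sort(cov$taxon),
               sort(c("tick", "apicomplexa", "other_eukaryote", "no_site")))
  get <- function(tx) cov[cov$taxon == tx, ]
  expect_equal(get("tick")$blocked, spec$n_host)
  expect_equal(get("tick")$p_blocked, 1)
  expect_equal(get("apicomplexa")$amplifiable, 1L)
  expect_equal(get("other_eukaryote")$amplifiable, 3L)
  expect_equal(get("no_site")$no_site, 2L)
  expect_true(all(abs(cov$p_amplifiable + cov$p_blocked + cov$p_no_site - 1)
                  < 1e-12))

  # without a blocker nothing is classed as blocked
  cov0 <- community_coverage(com$seqs, com$taxa, spec$fwd_primer,
                             spec$rev_primer, blocker = NULL)
  expect_true(all(cov0$blocked == 0L))
})
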